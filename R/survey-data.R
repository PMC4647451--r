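#' @title Coded survey tables
#' @description
#' A survey table has one row per remedy report. Multi-valued cells follow
#' the conventions of the source reports: `/` separates ailment codes,
#' `|` separates remedy alternatives (aligned positionally across the part,
#' preparation and route columns), and `&` (or `or`) joins items co-used
#' within one alternative. [read_survey()] parses these cells into
#' list-columns; [write_survey()] re-serializes them, and the round trip is
#' lossless.
#' @name survey-data
NULL

.survey_cols <- c("voucher", "family", "genus", "species", "authority",
                  "local_name", "ailment_text", "ailments", "parts",
                  "preps", "routes", "area")
.mandatory_cols <- c("voucher", "family", "genus", "ailments", "parts",
                     "preps", "routes", "area")

.split_ailments <- function(x) {
  out <- strsplit(x, "/", fixed = TRUE)
  lapply(out, function(v) {
    v <- stringr::str_squish(v)
    v[nzchar(v)]
  })
}

.split_alternatives <- function(x) {
  out <- strsplit(x, "|", fixed = TRUE)
  lapply(out, function(v) {
    v <- stringr::str_squish(v)
    v[nzchar(v)]
  })
}

.taxon_rank <- function(genus, species) {
  dplyr::case_when(
    !nzchar(genus) ~ "unidentified",
    !nzchar(species) ~ "genus",
    TRUE ~ "species"
  )
}

#' Read a coded survey table
#'
#' Reads a delimited text file in the canonical schema (columns `voucher`,
#' `family`, `genus`, `species`, `authority`, `local_name`, `ailment_text`,
#' `ailments`, `parts`, `preps`, `routes`, `area`) and parses multi-valued
#' cells into list-columns. A `rank` column (`species`, `genus` or
#' `unidentified`) is derived from the taxon fields.
#'
#' @param path Path to a delimited text file with a header row.
#' @param delim Field separator (default tab).
#' @param col_map Optional named character vector mapping canonical column
#'   names to the names used in the file, e.g.
#'   `c(voucher = "VoucherNo", ailments = "AilmentCode")`.
#' @return A tibble with one row per report; `ailments`, `parts`, `preps`
#'   and `routes` are list-columns of character vectors (one element per
#'   code or per remedy alternative).
#' @export
read_survey <- function(path, delim = "\t", col_map = NULL) {
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      if (!col_map[[canon]] %in% names(raw)) {
        stop("column '", col_map[[canon]], "' (mapped to '", canon,
             "') not found in ", path, call. = FALSE)
      }
      names(raw)[names(raw) == col_map[[canon]]] <- canon
    }
  }
  missing <- setdiff(.mandatory_cols, names(raw))
  if (length(missing)) {
    stop("survey table is missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0) stop("survey table has no data rows", call. = FALSE)
  for (opt in setdiff(.survey_cols, names(raw))) raw[[opt]] <- ""
  raw <- raw[, .survey_cols]
  raw[is.na(raw)] <- ""

  dup <- unique(raw$voucher[duplicated(raw$voucher)])
  if (length(dup)) {
    stop("duplicated voucher id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::as_tibble(raw)
  out$ailments <- .split_ailments(out$ailments)
  out$parts <- .split_alternatives(out$parts)
  out$preps <- .split_alternatives(out$preps)
  out$routes <- .split_alternatives(out$routes)
  if (any(lengths(out$ailments) == 0)) {
    stop("record(s) without ailment codes: ",
         paste(out$voucher[lengths(out$ailments) == 0], collapse = ", "),
         call. = FALSE)
  }
  out$rank <- .taxon_rank(out$genus, out$species)
  out
}

#' Write a survey table in the canonical delimited format
#'
#' Inverse of [read_survey()]: list-columns are serialized with the `/` and
#' `|` conventions, so `read_survey(write_survey(x, f))` reproduces `x`.
#'
#' @param records Survey tibble as returned by [read_survey()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_survey <- function(records, path) {
  flat <- records[, setdiff(.survey_cols, c("ailments", "parts", "preps",
                                            "routes"))]
  flat$ailments <- vapply(records$ailments, paste, "", collapse = "/")
  flat$parts <- vapply(records$parts, paste, "", collapse = " | ")
  flat$preps <- vapply(records$preps, paste, "", collapse = " | ")
  flat$routes <- vapply(records$routes, paste, "", collapse = " | ")
  flat <- flat[, .survey_cols]
  readr::write_tsv(flat, path, progress = FALSE)
  invisible(path)
}

#' Validate survey codes against the controlled vocabularies
#'
#' Every atomic token of every record is checked against the vocabulary of
#' its dimension. Tokens inside an alternative that are joined by `&` or
#' `or` are validated individually. Unknown tokens are reported for curator
#' review, never repaired, and the records are not modified.
#'
#' @param records Survey tibble.
#' @param vocabs Vocabularies as returned by [medflora_vocabularies()].
#' @return A tibble with columns `voucher`, `dimension`, `token`; zero rows
#'   when every token is known.
#' @export
validate_codes <- function(records, vocabs = medflora_vocabularies()) {
  atomize <- function(alts) {
    unlist(strsplit(unlist(alts), "\\s*(&|\\bor\\b)\\s*"), use.names = FALSE)
  }
  one <- function(voucher, tokens, dimension) {
    tokens <- stringr::str_squish(tokens)
    tokens <- tokens[nzchar(tokens)]
    bad <- setdiff(tokens, names(vocabs[[dimension]]))
    if (!length(bad)) return(NULL)
    tibble::tibble(voucher = voucher, dimension = dimension, token = bad)
  }
  rows <- purrr::pmap(
    list(records$voucher, records$ailments, records$parts, records$preps,
         records$routes),
    function(v, a, p, pr, r) {
      dplyr::bind_rows(
        one(v, a, "ailment"),
        one(v, atomize(p), "part"),
        one(v, atomize(pr), "preparation"),
        one(v, atomize(r), "route")
      )
    })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(voucher = character(), dimension = character(),
                          token = character())
  }
  out
}

#' Explode survey records into single-code use events
#'
#' Each record is expanded into one event per (ailment code x remedy
#' alternative). The `|`-separated part, preparation and route cells are
#' aligned positionally into alternatives; a cell with a single token is
#' broadcast across all alternatives; `&`-joined items stay together as one
#' event whose code field holds the joined token. Ailment codes are
#' distributed across every alternative.
#'
#' @param records Survey tibble.
#' @return A tibble of use events with columns `voucher`, `area`, `family`,
#'   `genus`, `species`, `rank`, `ailment`, `part`, `prep`, `route`,
#'   `alternative` (1-based index of the remedy alternative).
#' @export
explode_uses <- function(records) {
  rows <- purrr::pmap(
    list(records$voucher, records$area, records$family, records$genus,
         records$species, records$rank, records$ailments, records$parts,
         records$preps, records$routes),
    function(voucher, area, family, genus, species, rank, ail, part, prep,
             route) {
      lens <- c(length(part), length(prep), length(route))
      n_alt <- max(lens, 1L)
      bad <- lens > 1L & lens != n_alt
      if (any(bad)) {
        stop("misaligned '|' alternatives in record ", voucher, ": ",
             paste(lens, collapse = "/"), " part/prep/route tokens",
             call. = FALSE)
      }
      pad <- function(x) {
        if (length(x) == 0) rep(NA_character_, n_alt)
        else if (length(x) == 1) rep(x, n_alt)
        else x
      }
      grid <- expand.grid(alternative = seq_len(n_alt), ailment = ail,
                          stringsAsFactors = FALSE)
      tibble::tibble(
        voucher = voucher, area = area, family = family, genus = genus,
        species = species, rank = rank, ailment = grid$ailment,
        part = pad(part)[grid$alternative],
        prep = pad(prep)[grid$alternative],
        route = pad(route)[grid$alternative],
        alternative = grid$alternative
      )
    })
  dplyr::bind_rows(rows)
}

#' Harmonize plant family names
#'
#' Normalizes case and whitespace, then maps historic family names to their
#' modern (APG-style) equivalents via a synonym table. The default table
#' covers the historic forms that occur in the packaged survey (Labiatae,
#' Gramineae, Guttiferae, Mimosaceae, Asclepiadaceae, Compositae). The
#' mapping is idempotent: canonical names map to themselves.
#'
#' @param family Character vector of family names.
#' @param synonyms Named character vector `alias -> canonical`, as returned
#'   by [default_family_synonyms()]. May be empty.
#' @return Character vector of canonical family names.
#' @export
harmonize_family <- function(family, synonyms = default_family_synonyms()) {
  x <- stringr::str_squish(family)
  x <- ifelse(nzchar(x),
              paste0(toupper(substring(x, 1, 1)),
                     tolower(substring(x, 2))), x)
  hit <- match(x, names(synonyms))
  x[!is.na(hit)] <- unname(synonyms[hit[!is.na(hit)]])
  x
}

#' Deduplicate a flora checklist
#'
#' Applies set semantics on (family, genus, species) triples after
#' whitespace and case normalization, mirroring how regional flora extracts
#' are prepared before family counting.
#'
#' @param rows A data frame with columns `family`, `genus`, `species`
#'   (`species` may be empty for genus-level entries).
#' @return A tibble of unique normalized triples.
#' @export
dedupe_checklist <- function(rows) {
  rows <- tibble::as_tibble(rows)[, c("family", "genus", "species")]
  rows[is.na(rows)] <- ""
  norm_name <- function(x) {
    x <- stringr::str_squish(x)
    ifelse(nzchar(x),
           paste0(toupper(substring(x, 1, 1)), tolower(substring(x, 2))), x)
  }
  rows$family <- norm_name(rows$family)
  rows$genus <- norm_name(rows$genus)
  rows$species <- tolower(stringr::str_squish(rows$species))
  empty <- which(!nzchar(rows$family))
  if (length(empty)) {
    stop("checklist row(s) with empty family: ",
         paste(empty, collapse = ", "), call. = FALSE)
  }
  dplyr::distinct(rows)
}

#' Count checklist taxa per family
#'
#' @param checklist A deduplicated checklist from [dedupe_checklist()] (or
#'   [simulate_flora()]).
#' @return A tibble with columns `family`, `n`, sorted by decreasing count
#'   then family name; counts sum to `nrow(checklist)`.
#' @export
family_counts <- function(checklist) {
  out <- dplyr::count(checklist, .data$family, name = "n")
  dplyr::arrange(out, dplyr::desc(.data$n), .data$family)
}

#' Count medicinally reported taxa (or reports) per family
#'
#' With `unit = "distinct_taxa"` each distinct (family, genus, species)
#' combination counts once and records with unidentified taxa are skipped
#' unless a family is stated for them; with `unit = "entries"` every record
#' counts once. Family names are harmonized first.
#'
#' @param records Survey tibble.
#' @param unit Counting unit, `"distinct_taxa"` or `"entries"`.
#' @param synonyms Family synonym map passed to [harmonize_family()].
#' @return A tibble with columns `family`, `x`.
#' @export
medicinal_family_counts <- function(records,
                                    unit = c("distinct_taxa", "entries"),
                                    synonyms = default_family_synonyms()) {
  unit <- match.arg(unit)
  d <- tibble::tibble(
    family = harmonize_family(records$family, synonyms),
    genus = stringr::str_squish(records$genus),
    species = tolower(stringr::str_squish(records$species))
  )
  if (unit == "distinct_taxa") {
    d <- d[nzchar(d$genus) | !startsWith(tolower(d$family), "not "), ]
    d <- dplyr::distinct(d)
  }
  out <- dplyr::count(d, .data$family, name = "x")
  dplyr::arrange(out, dplyr::desc(.data$x), .data$family)
}
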