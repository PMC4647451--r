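#' Usage frequency profiles
#'
#' Tallies code occurrences for one dimension, per study area or pooled,
#' and expresses them as percentages of the (area) total, as in the survey
#' report's per-area usage-pattern figures. The default counting unit is
#' one count per use event, so a record with two remedy alternatives
#' contributes its part code twice; `unit = "records"` counts each record's
#' distinct codes once.
#'
#' @param events Use events from [explode_uses()].
#' @param dimension One of `"part"`, `"preparation"`, `"route"`,
#'   `"ailment"`.
#' @param per_area Tally per study area (default) or pooled.
#' @param unit `"events"` or `"records"`.
#' @return Tibble with columns `area` (`"all"` when pooled), `dimension`,
#'   `code`, `count`, `percent`. Percentages sum to 100 within each area.
#' @export
usage_frequency <- function(events,
                            dimension = c("part", "preparation", "route",
                                          "ailment"),
                            per_area = TRUE,
                            unit = c("events", "records")) {
  dimension <- match.arg(dimension)
  unit <- match.arg(unit)
  col <- switch(dimension, part = "part", preparation = "prep",
                route = "route", ailment = "ailment")
  d <- tibble::tibble(area = events$area, voucher = events$voucher,
                      code = events[[col]])
  d <- d[!is.na(d$code) & nzchar(d$code), ]
  if (!per_area) d$area <- "all"
  if (unit == "records") d <- dplyr::distinct(d)
  out <- dplyr::count(d, .data$area, .data$code, name = "count")
  out <- dplyr::group_by(out, .data$area)
  out <- dplyr::mutate(out, percent = 100 * .data$count / sum(.data$count))
  out <- dplyr::ungroup(out)
  out$dimension <- dimension
  dplyr::arrange(out[, c("area", "dimension", "code", "count", "percent")],
                 .data$area, dplyr::desc(.data$count), .data$code)
}

#' Most frequently treated conditions
#'
#' Ranks ailment codes by the number of reports citing them. Counting is
#' per record: a report listing `FEV/MAL` adds one to each code no matter
#' how many remedy alternatives it describes (the unit under which the
#' published pooled and per-area tallies reproduce). Ties are broken
#' lexicographically by code.
#'
#' @param records Survey tibble.
#' @param k Number of top conditions to return (`Inf` for all).
#' @param area Optional area identifier to restrict to.
#' @return Tibble with columns `code`, `count`, in decreasing order.
#' @export
top_conditions <- function(records, k = 5, area = NULL) {
  stopifnot(k >= 1)
  if (!is.null(area)) records <- records[records$area %in% area, ]
  codes <- unlist(lapply(records$ailments, unique), use.names = FALSE)
  if (!length(codes)) {
    return(tibble::tibble(code = character(), count = integer()))
  }
  out <- dplyr::count(tibble::tibble(code = codes), .data$code,
                      name = "count")
  out <- dplyr::arrange(out, dplyr::desc(.data$count), .data$code)
  head(out, k)
}

#' Genus citation counts
#'
#' Number of survey records per genus, for records identified at least to
#' genus. Descending by count, ties broken lexicographically.
#'
#' @param records Survey tibble.
#' @return Tibble with columns `genus`, `count`.
#' @export
genus_citation_counts <- function(records) {
  d <- records[records$rank != "unidentified", ]
  out <- dplyr::count(tibble::tibble(genus = d$genus), .data$genus,
                      name = "count")
  dplyr::arrange(out, dplyr::desc(.data$count), .data$genus)
}

.taxon_labels <- function(records, level) {
  g <- stringr::str_squish(records$genus)
  s <- tolower(stringr::str_squish(records$species))
  switch(level,
    species = ifelse(records$rank == "species", paste(g, s), NA_character_),
    taxon = ifelse(records$rank == "unidentified", NA_character_,
                   ifelse(records$rank == "species", paste(g, s),
                          paste(g, "sp."))),
    genus = ifelse(records$rank == "unidentified", NA_character_, g))
}

#' Taxa shared by all study areas and taxa unique to one
#'
#' Computes, at the requested taxonomic resolution, the set of names
#' reported in every study area and the names reported in exactly one.
#' `level = "species"` uses binomials and ignores genus-level records;
#' `level = "taxon"` keeps genus-level records as `"Genus sp."`;
#' `level = "genus"` pools everything by genus. Identity is by name after
#' case/whitespace normalization; authorities and infraspecific ranks are
#' ignored.
#'
#' @param records Survey tibble covering at least two areas.
#' @param level `"species"`, `"taxon"` or `"genus"`.
#' @return List with elements `in_all_areas` (character vector) and
#'   `per_area_unique` (named list of character vectors, one per area).
#' @export
shared_taxa <- function(records, level = c("species", "taxon", "genus")) {
  level <- match.arg(level)
  areas <- sort(unique(records$area))
  if (length(areas) < 2) {
    stop("shared_taxa() needs records from at least two areas",
         call. = FALSE)
  }
  lab <- .taxon_labels(records, level)
  d <- dplyr::distinct(tibble::tibble(name = lab, area = records$area))
  d <- d[!is.na(d$name), ]
  n_areas <- table(d$name)
  in_all <- sort(names(n_areas)[n_areas == length(areas)])
  uniq <- names(n_areas)[n_areas == 1]
  per_area <- lapply(setNames(areas, areas), function(a) {
    sort(intersect(d$name[d$area == a], uniq))
  })
  list(in_all_areas = in_all, per_area_unique = per_area)
}

#' Overlap of genus sets across regions
#'
#' Set-theoretic overlap summary for any number of regions (three for the
#' cross-province comparison): per-region sizes, all pairwise and
#' higher-order intersection sizes, and the union, which satisfies
#' inclusion-exclusion by construction.
#'
#' @param genus_sets Named list of character vectors (genus names per
#'   region).
#' @return List with `sizes` (named integer), `intersections` (tibble with
#'   columns `regions`, `size`), and `union_size`.
#' @export
region_overlap <- function(genus_sets) {
  stopifnot(is.list(genus_sets), length(genus_sets) >= 2,
            !is.null(names(genus_sets)))
  sets <- lapply(genus_sets, unique)
  regions <- names(sets)
  sizes <- vapply(sets, length, 0L)
  combos <- unlist(lapply(2:length(sets), function(k) {
    utils::combn(regions, k, simplify = FALSE)
  }), recursive = FALSE)
  inter <- tibble::tibble(
    regions = vapply(combos, paste, "", collapse = "&"),
    size = vapply(combos, function(rs) {
      length(Reduce(intersect, sets[rs]))
    }, 0L))
  list(sizes = sizes, intersections = inter,
       union_size = length(unique(unlist(sets))))
}

#' Combined per-region genus citation table
#'
#' Restricts to genera cited in every region and reports per-region counts
#' plus the row total, mirroring the published shared-genus table.
#'
#' @param counts Data frame with a `genus` column and one numeric count
#'   column per region.
#' @param min_total Keep only rows with `total >= min_total`.
#' @return Tibble ordered by decreasing total, ties lexicographic.
#' @export
combined_genus_table <- function(counts, min_total = 0) {
  counts <- tibble::as_tibble(counts)
  region_cols <- setdiff(names(counts), "genus")
  keep <- rowSums(counts[region_cols] > 0) == length(region_cols)
  out <- counts[keep, ]
  out$total <- rowSums(out[region_cols])
  out <- out[out$total >= min_total, ]
  dplyr::arrange(out, dplyr::desc(.data$total), .data$genus)
}

#' Screen survey species against a reference list
#'
#' Returns the species-rank binomials present in the survey but absent
#' from the reference species list (exact set difference after name
#' normalization); genus-level and unidentified records are ignored. Used
#' to flag potentially unreported medicinal uses.
#'
#' @param records Survey tibble.
#' @param reference_species Character vector of binomials.
#' @return Sorted character vector of novel binomials.
#' @export
novelty_screen <- function(records, reference_species) {
  sp <- .taxon_labels(records, "species")
  sp <- unique(sp[!is.na(sp)])
  ref <- stringr::str_squish(reference_species)
  sort(setdiff(sp, ref))
}
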