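#' Packaged datasets
#'
#' Accessors for the data shipped with the package: the digitized East
#' Sepik survey table, the controlled code vocabularies, the default family
#' synonym map, the per-family taxon counts of the two reference databases
#' (regional flora extracts and the traditional-medicines database), the
#' printed cross-province shared-genus citation table, and a synthetic
#' stand-in for the medicinal-plants reference species list used by the
#' novelty screen.
#'
#' The survey fixture is a curated digitization of a published table; the
#' file `es_survey_CHANGELOG.md` next to it documents every cell whose
#' published typesetting was ambiguous or inconsistent and how it was
#' resolved.
#'
#' @name medflora-data
NULL

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "medflora")
  if (path == "") {
    # during in-source development
    path <- file.path("inst", "extdata", file)
  }
  path
}

#' @rdname medflora-data
#' @return `es_survey()`: the East Sepik survey as a survey tibble
#'   (299 remedy reports across the DK, BK, GW and MS study areas).
#' @export
es_survey <- function() {
  read_survey(.extdata("es_survey.tsv"))
}

#' @rdname medflora-data
#' @param path Optional path to a JSON document overriding the packaged one.
#' @return `medflora_vocabularies()`: named list with elements `ailment`,
#'   `part`, `preparation`, `route`; each a named character vector mapping
#'   code to description.
#' @export
medflora_vocabularies <- function(path = NULL) {
  p <- if (is.null(path)) .extdata("vocabularies.json") else path
  v <- jsonlite::read_json(p, simplifyVector = TRUE)
  lapply(v, unlist)
}

#' @rdname medflora-data
#' @return `default_family_synonyms()`: named character vector mapping
#'   historic family names to canonical ones.
#' @export
default_family_synonyms <- function(path = NULL) {
  p <- if (is.null(path)) .extdata("family_synonyms.json") else path
  unlist(jsonlite::read_json(p, simplifyVector = TRUE))
}

#' @rdname medflora-data
#' @param reference Which reference database: `"plantdb"` (regional flora
#'   extracts) or `"tmdb"` (traditional-medicines database).
#' @return `reference_family_counts()`: tibble with columns `region`
#'   (ES/EH/BV), `family`, `n_reference`, `x_used`, the printed interval
#'   bounds/margins, and `printed_category`. Rows with `family == "TOTAL"`
#'   carry the whole-dataset totals used as the regional comparator.
#' @export
reference_family_counts <- function(reference = c("plantdb", "tmdb")) {
  reference <- match.arg(reference)
  f <- paste0("family_counts_", reference, ".tsv")
  readr::read_tsv(.extdata(f), col_types = readr::cols(
    region = "c", family = "c", n_reference = "i", x_used = "i",
    printed_inferior = "d", printed_superior = "d", printed_margin = "d",
    printed_category = "c"), progress = FALSE)
}

#' @rdname medflora-data
#' @return `table3_shared_genera()`: tibble of per-province citation counts
#'   for the genera reported in all three provinces.
#' @export
table3_shared_genera <- function() {
  readr::read_tsv(.extdata("table3_shared_genera.tsv"),
                  col_types = "ciii", progress = FALSE)
}

#' @rdname medflora-data
#' @return `reference_species_png()`: character vector of species binomials
#'   in the (synthetic stand-in) medicinal-plants reference list.
#' @export
reference_species_png <- function() {
  readr::read_tsv(.extdata("png_reference_species_synthetic.tsv"),
                  col_types = "c", progress = FALSE)$species
}
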