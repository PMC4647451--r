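#' End-to-end report drivers
#'
#' Thin drivers tying the analysis stages together. Each writes
#' deterministic tab-separated tables (no timestamps), so identical inputs
#' produce byte-identical outputs; numeric interval columns are emitted
#' both at display precision (3 decimals, the precision of the published
#' tables) and at full precision. The numbered scripts under `analysis/`
#' call these drivers on the packaged data.
#' @name report-drivers
NULL

.round3 <- function(x) formatC(round(x, 3), format = "f", digits = 3)

#' @rdname report-drivers
#' @param records Survey tibble.
#' @param out_dir Output directory (created if needed).
#' @return `run_summarize()`: invisibly, the paths written — frequency
#'   profiles per dimension, pooled and per-area top conditions, genus
#'   citation counts, shared/unique taxa, and the code validation report.
#' @export
run_summarize <- function(records, out_dir) {
  if (nrow(records) == 0) stop("empty survey", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  events <- explode_uses(records)
  paths <- character()
  w <- function(d, name) {
    p <- file.path(out_dir, name)
    readr::write_tsv(d, p, progress = FALSE)
    paths <<- c(paths, p)
  }
  for (dim in c("part", "preparation", "route", "ailment")) {
    w(usage_frequency(events, dim), paste0("frequency_", dim, ".tsv"))
  }
  w(top_conditions(records, k = Inf), "top_conditions_pooled.tsv")
  per_area <- dplyr::bind_rows(lapply(sort(unique(records$area)),
    function(a) {
      d <- top_conditions(records, k = Inf, area = a)
      d$area <- a
      d
    }))
  w(per_area, "top_conditions_by_area.tsv")
  w(genus_citation_counts(records), "genus_citations.tsv")
  sh <- shared_taxa(records, level = "species")
  w(tibble::tibble(species = sh$in_all_areas), "species_in_all_areas.tsv")
  uniq <- dplyr::bind_rows(lapply(names(sh$per_area_unique), function(a) {
    tibble::tibble(area = a, species = sh$per_area_unique[[a]])
  }))
  w(uniq, "species_unique_to_area.tsv")
  w(validate_codes(records), "validation_report.tsv")
  invisible(paths)
}

#' @rdname report-drivers
#' @param table Family count table (`family`, `n_reference`, `x_used`).
#' @param total Optional explicit total counts (see
#'   [classify_utilization()]).
#' @param out Output file path.
#' @param level Credibility level.
#' @return `run_utilization()`: the ranked classification tibble,
#'   invisibly; the file mirrors the published table layout (family,
#'   counts, rounded and full-precision bounds, category, margin) plus a
#'   trailing TOTAL row.
#' @export
run_utilization <- function(table, total = NULL, out = NULL, level = 0.95) {
  res <- rank_families(classify_utilization(table, total, level))
  tot <- attr(res, "total")
  if (!is.null(out)) {
    dir.create(dirname(out), showWarnings = FALSE, recursive = TRUE)
    disp <- tibble::tibble(
      family = c(res$family, tot$family),
      n_reference = c(res$n_reference, tot$n_reference),
      x_used = c(res$x_used, tot$x_used),
      inferior = .round3(c(res$inferior, tot$inferior)),
      superior = .round3(c(res$superior, tot$superior)),
      category = c(res$category, "total"),
      margin = c(.round3(res$margin), ""),
      inferior_full = c(res$inferior, tot$inferior),
      superior_full = c(res$superior, tot$superior),
      margin_full = c(res$margin, NA),
      n_families_tested = attr(res, "n_tested"))
    readr::write_tsv(disp, out, progress = FALSE)
  }
  invisible(res)
}

#' @rdname report-drivers
#' @param config A [sim_config()].
#' @return `run_simulate()`: invisibly, paths of the emitted checklist
#'   TSV, survey TSV and truth TSV.
#' @export
run_simulate <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  flora <- simulate_flora(config)
  survey <- simulate_survey(flora, config)
  p1 <- file.path(out_dir, "sim_checklist.tsv")
  readr::write_tsv(flora$checklist, p1, progress = FALSE)
  p2 <- file.path(out_dir, "sim_survey.tsv")
  write_survey(survey, p2)
  p3 <- file.path(out_dir, "sim_truth.tsv")
  x <- medicinal_family_counts(survey, unit = "distinct_taxa",
                               synonyms = character())
  truth <- dplyr::left_join(flora$truth, x, by = "family")
  truth$x <- dplyr::coalesce(truth$x, 0L)
  readr::write_tsv(truth, p3, progress = FALSE)
  invisible(c(p1, p2, p3))
}
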