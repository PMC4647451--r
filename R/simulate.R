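#' Configuration for the synthetic survey generator
#'
#' The generator emulates the statistical structure the utilization
#' analysis assumes: a regional checklist whose family sizes follow a
#' truncated discrete power law (heavy tail: a couple of families hold
#' most species while many hold 1-5), and a survey in which each species
#' is medicinally reported independently with a family-specific
#' probability `min(1, baseline_use_prob * effect)`. Defaults are sized
#' like the East Sepik reference data: about 80 families, around 2,000
#' species in total, and a baseline use probability of 0.09 (close to the
#' observed 207/2258).
#'
#' @param n_families Number of families.
#' @param size_exponent Power-law exponent of the family-size law
#'   (P(s) proportional to s^-exponent).
#' @param size_min,size_max Truncation bounds for family sizes.
#' @param baseline_use_prob Baseline per-species probability of being
#'   medicinally reported.
#' @param effects Named numeric vector of multiplicative effects keyed by
#'   family name (families are named `F001`, `F002`, ...); families not
#'   named are neutral (effect 1). An effect of 0 silences a family.
#' @param fixed_sizes Optional named integer vector pinning the checklist
#'   size of specific families (overrides the drawn size), for designed
#'   power experiments.
#' @param areas Study-area labels assigned round-robin to survey records.
#' @param seed Integer master seed; every derived quantity is
#'   deterministic given the seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_families = 80, size_exponent = 1.3,
                       size_min = 1, size_max = 300,
                       baseline_use_prob = 0.09, effects = NULL,
                       fixed_sizes = NULL,
                       areas = c("DK", "BK", "GW", "MS"), seed = 1) {
  stopifnot(n_families >= 1, size_min >= 1, size_max >= size_min,
            baseline_use_prob > 0, baseline_use_prob <= 1)
  if (!is.null(effects)) {
    stopifnot(!is.null(names(effects)), all(effects >= 0))
  }
  if (!is.null(fixed_sizes)) {
    stopifnot(!is.null(names(fixed_sizes)), all(fixed_sizes >= 1))
  }
  structure(list(n_families = as.integer(n_families),
                 size_exponent = size_exponent,
                 size_min = as.integer(size_min),
                 size_max = as.integer(size_max),
                 baseline_use_prob = baseline_use_prob,
                 effects = effects, fixed_sizes = fixed_sizes,
                 areas = areas,
                 seed = as.integer(seed)),
            class = "sim_config")
}

.family_id <- function(i) sprintf("F%03d", i)

.size_law_probs <- function(config) {
  s <- config$size_min:config$size_max
  p <- s^(-config$size_exponent)
  p / sum(p)
}

#' Simulate a regional flora checklist
#'
#' Draws one size per family from the truncated power law and emits a
#' checklist of unique synthetic taxa (`family`, `genus`, `species`)
#' together with the simulation truth (per-family size, use probability
#' and designated effect class).
#'
#' @param config A [sim_config()].
#' @return List with `checklist` (tibble, one row per species) and `truth`
#'   (tibble, one row per family with columns `family`, `size`,
#'   `use_prob`, `effect`, `class` in over/under/neutral).
#' @export
simulate_flora <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  domain <- config$size_min:config$size_max
  sizes <- domain[sample.int(length(domain), config$n_families,
                             replace = TRUE,
                             prob = .size_law_probs(config))]
  fam <- .family_id(seq_len(config$n_families))
  if (!is.null(config$fixed_sizes)) {
    idx <- match(names(config$fixed_sizes), fam)
    if (anyNA(idx)) {
      stop("fixed_sizes name families that do not exist", call. = FALSE)
    }
    sizes[idx] <- config$fixed_sizes
  }
  eff <- rep(1, config$n_families)
  names(eff) <- fam
  if (!is.null(config$effects)) {
    unknown <- setdiff(names(config$effects), fam)
    if (length(unknown)) {
      stop("effects name families that do not exist: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    eff[names(config$effects)] <- config$effects
  }
  p <- pmin(1, config$baseline_use_prob * eff)
  truth <- tibble::tibble(
    family = fam, size = as.integer(sizes), use_prob = unname(p),
    effect = unname(eff),
    class = dplyr::case_when(eff > 1 ~ "overused", eff < 1 ~ "underused",
                             TRUE ~ "neutral"))
  checklist <- tibble::tibble(
    family = rep(fam, sizes),
    genus = paste0("Genus", rep(sprintf("%03d", seq_len(config$n_families)),
                                sizes)),
    species = sprintf("spec%05d", seq_len(sum(sizes))))
  list(checklist = checklist, truth = truth)
}

#' Simulate a coded survey over a synthetic flora
#'
#' Includes each checklist species as one medicinal report with its
#' family's use probability; included records receive ailment, part,
#' preparation and route codes drawn uniformly from the packaged
#' vocabularies and an area label, so simulated surveys pass
#' [validate_codes()] with an empty report.
#'
#' @param flora Output of [simulate_flora()] (list with `checklist` and
#'   `truth`).
#' @param config The same [sim_config()] used for the flora.
#' @return A survey tibble in the [read_survey()] schema.
#' @export
simulate_survey <- function(flora, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  cl <- flora$checklist
  p <- flora$truth$use_prob[match(cl$family, flora$truth$family)]
  used <- runif(nrow(cl)) < p
  d <- cl[used, ]
  n <- nrow(d)
  vocab <- medflora_vocabularies()
  pick <- function(codes, n) codes[sample.int(length(codes), n,
                                              replace = TRUE)]
  tibble::tibble(
    voucher = sprintf("SIM %04d", seq_len(max(n, 0))),
    family = d$family, genus = d$genus, species = d$species,
    authority = "", local_name = "", ailment_text = "",
    ailments = as.list(pick(names(vocab$ailment), n)),
    parts = as.list(pick(names(vocab$part), n)),
    preps = as.list(pick(names(vocab$preparation), n)),
    routes = as.list(pick(names(vocab$route), n)),
    area = rep_len(config$areas, max(n, 0)),
    rank = rep("species", n))
}

#' Derive per-replicate seeds from a master seed
#'
#' Stable rule used by [recovery_experiment()]: the master seed seeds R's
#' generator once and `n` integer seeds are drawn from it, so replicate i
#' is reproducible in isolation.
#'
#' @param master_seed Integer.
#' @param n Number of replicate seeds.
#' @return Integer vector of length `n`.
#' @export
derive_seeds <- function(master_seed, n) {
  set.seed(as.integer(master_seed))
  sample.int(.Machine$integer.max - 1L, n)
}

#' Parameter-recovery experiment for the utilization classifier
#'
#' Repeatedly simulates a flora and survey, counts used taxa per family,
#' classifies every family against the pooled total with
#' [classify_utilization()], and scores the classifications against the
#' simulation truth. Sensitivity is the fraction of planted biased
#' families recovered with their true category; specificity the fraction
#' of neutral families classified neutral.
#'
#' @param config A [sim_config()]; its `seed` acts as the master seed.
#' @param n_reps Number of replicates.
#' @param level Credibility level for the classifier.
#' @return List with `sensitivity`, `specificity`, `per_family` (tibble of
#'   recovery rates per family) and `reps` (tibble of every per-replicate
#'   classification).
#' @export
recovery_experiment <- function(config, n_reps = 100, level = 0.95) {
  stopifnot(inherits(config, "sim_config"), n_reps >= 1)
  seeds <- derive_seeds(config$seed, n_reps)
  one <- function(rep_i) {
    cfg <- config
    cfg$seed <- seeds[rep_i]
    flora <- simulate_flora(cfg)
    survey <- simulate_survey(flora, cfg)
    counts <- dplyr::left_join(
      flora$truth[, c("family", "size", "class")],
      medicinal_family_counts(survey, unit = "distinct_taxa",
                              synonyms = character()),
      by = "family")
    counts$x <- dplyr::coalesce(counts$x, 0L)
    tab <- tibble::tibble(family = counts$family,
                          n_reference = counts$size, x_used = counts$x)
    res <- classify_utilization(tab, level = level)
    tibble::tibble(rep = rep_i, family = res$family,
                   truth = counts$class, category = res$category)
  }
  reps <- dplyr::bind_rows(lapply(seq_len(n_reps), one))
  per_family <- dplyr::summarise(
    dplyr::group_by(reps, .data$family, .data$truth),
    recovered = mean(.data$category == .data$truth),
    .groups = "drop")
  biased <- reps[reps$truth != "neutral", ]
  neutral <- reps[reps$truth == "neutral", ]
  list(
    sensitivity = if (nrow(biased)) mean(biased$category == biased$truth)
                  else NA_real_,
    specificity = if (nrow(neutral)) mean(neutral$category == "neutral")
                  else NA_real_,
    per_family = per_family,
    reps = reps)
}
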