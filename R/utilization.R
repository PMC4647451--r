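#' Bayesian credible interval for a binomial use proportion
#'
#' Posterior quantiles of the per-family medicinal-use proportion under a
#' uniform Beta(1, 1) prior: with `x` used taxa out of `n` reference taxa
#' the posterior is Beta(x + 1, n - x + 1), and the interval is its
#' (1 - level)/2 and 1 - (1 - level)/2 quantiles ("inferior" and
#' "superior" bounds). This reproduces the spreadsheet `beta.inv`
#' convention used in regional over/under-utilization analyses; e.g.
#' a family with 1 of 1 taxa used gives (sqrt(0.025), sqrt(0.975)) =
#' (0.158, 0.987) at the 95% level.
#'
#' @param x Number of medicinally used taxa (0 <= x <= n). Vectorized.
#' @param n Number of taxa in the reference set (n >= 1). Vectorized.
#' @param level Credibility level in (0, 1), default 0.95.
#' @return Tibble with columns `x`, `n`, `inferior`, `superior`, `level`.
#' @export
beta_credible_interval <- function(x, n, level = 0.95) {
  if (length(level) != 1 || !is.finite(level) || level <= 0 || level >= 1) {
    stop("level must be a single number in (0, 1)", call. = FALSE)
  }
  k <- vctrs_recycle(x, n)
  x <- k$x; n <- k$n
  if (any(n < 1)) stop("n must be >= 1", call. = FALSE)
  if (any(x < 0 | x > n)) stop("x must satisfy 0 <= x <= n", call. = FALSE)
  alpha <- (1 - level) / 2
  tibble::tibble(
    x = x, n = n,
    inferior = qbeta(alpha, x + 1, n - x + 1),
    superior = qbeta(1 - alpha, x + 1, n - x + 1),
    level = level
  )
}

# minimal common-length recycling for the two count vectors
vctrs_recycle <- function(x, n) {
  len <- max(length(x), length(n))
  if (length(x) %in% c(1L, len) && length(n) %in% c(1L, len)) {
    list(x = rep_len(x, len), n = rep_len(n, len))
  } else {
    stop("x and n must have compatible lengths", call. = FALSE)
  }
}

#' Pool a family count table into a total
#'
#' Sums reference and used counts over all families. The regional
#' comparator printed in the published tables is the whole-dataset total,
#' which can exceed the sum over the listed families; callers may therefore
#' also pass explicit totals straight to [classify_utilization()].
#'
#' @param table Data frame with columns `family`, `n_reference`, `x_used`.
#' @return One-row tibble with `family = "TOTAL"`.
#' @export
pooled_total <- function(table) {
  stopifnot(nrow(table) >= 1)
  tibble::tibble(family = "TOTAL",
                 n_reference = sum(table$n_reference),
                 x_used = sum(table$x_used))
}

#' Interval margin between a family and the regional total
#'
#' Signed "difference to interval": for an overused family the gap between
#' its inferior bound and the total's superior bound; for an underused
#' family the (negative) gap between its superior bound and the total's
#' inferior bound; for a neutral family the larger (closest to zero) of
#' the two separation deficits, a non-positive distance to significance.
#' Margins are computed on unrounded bounds.
#'
#' @param family_interval,total_interval One-row interval tibbles from
#'   [beta_credible_interval()] at the same level.
#' @param category `"overused"`, `"underused"` or `"neutral"`.
#' @return Numeric margin.
#' @export
utilization_margin <- function(family_interval, total_interval, category) {
  fi <- family_interval$inferior; fs <- family_interval$superior
  ti <- total_interval$inferior; ts <- total_interval$superior
  switch(category,
    overused = fi - ts,
    underused = fs - ti,
    neutral = pmax(fi - ts, ti - fs),
    stop("unknown category: ", category, call. = FALSE))
}

#' Classify families as medicinally over-, under- or neutrally utilized
#'
#' Computes the credible interval of every family and compares it with the
#' interval of the regional total: a family is overused when its inferior
#' bound lies strictly above the total's superior bound, underused when its
#' superior bound lies strictly below the total's inferior bound, and
#' neutral otherwise (equality counts as neutral). Families absent from
#' the reference set (`n_reference` = 0) are reported as `"unanalyzable"`
#' rather than dropped, and families with `x_used > n_reference` are
#' flagged as inconsistent rather than clamped.
#'
#' @param table Data frame with columns `family`, `n_reference`, `x_used`.
#' @param total Optional one-row data frame with the comparator counts
#'   (`n_reference`, `x_used`); defaults to [pooled_total()] of `table`.
#' @param level Credibility level, default 0.95.
#' @return Tibble with one row per input family: counts, `inferior`,
#'   `superior`, `category`, `margin`, `flag`; the total's counts and
#'   interval and the number of families tested are attached as attributes
#'   `total` and `n_tested`.
#' @export
classify_utilization <- function(table, total = NULL, level = 0.95) {
  table <- tibble::as_tibble(table)
  stopifnot(all(c("family", "n_reference", "x_used") %in% names(table)))
  if (is.null(total)) total <- pooled_total(table)
  tot_int <- beta_credible_interval(total$x_used[1], total$n_reference[1],
                                    level)
  ok <- table$n_reference >= 1 & table$x_used <= table$n_reference &
    table$x_used >= 0
  res <- table[, c("family", "n_reference", "x_used")]
  res$inferior <- NA_real_
  res$superior <- NA_real_
  if (any(ok)) {
    ints <- beta_credible_interval(table$x_used[ok], table$n_reference[ok],
                                   level)
    res$inferior[ok] <- ints$inferior
    res$superior[ok] <- ints$superior
  }
  res$category <- dplyr::case_when(
    !ok ~ "unanalyzable",
    res$inferior > tot_int$superior ~ "overused",
    res$superior < tot_int$inferior ~ "underused",
    TRUE ~ "neutral")
  res$margin <- NA_real_
  for (cat in c("overused", "underused", "neutral")) {
    i <- which(res$category == cat)
    if (length(i)) {
      res$margin[i] <- utilization_margin(
        tibble::tibble(inferior = res$inferior[i],
                       superior = res$superior[i]),
        tot_int, cat)
    }
  }
  res$flag <- dplyr::case_when(
    table$n_reference < 1 ~ "not in reference set",
    table$x_used > table$n_reference ~ "x exceeds n: inconsistent datasets",
    TRUE ~ "")
  res$level <- level
  attr(res, "total") <- tibble::tibble(
    family = "TOTAL", n_reference = total$n_reference[1],
    x_used = total$x_used[1], inferior = tot_int$inferior,
    superior = tot_int$superior, level = level)
  attr(res, "n_tested") <- sum(ok)
  res
}

#' Rank classified families by strength of evidence
#'
#' Orders results overused first (largest margin first), then underused
#' (most negative margin first), then neutral families by distance to
#' significance (margin closest to zero first), then unanalyzable; ties
#' broken lexicographically by family. Determinism is guaranteed.
#'
#' @param results Output of [classify_utilization()].
#' @return The same tibble, reordered.
#' @export
rank_families <- function(results) {
  cat_order <- match(results$category,
                     c("overused", "underused", "neutral", "unanalyzable"))
  key <- numeric(nrow(results))
  key[results$category == "overused"] <-
    -abs(results$margin[results$category == "overused"])
  key[results$category == "underused"] <-
    -abs(results$margin[results$category == "underused"])
  key[results$category == "neutral"] <-
    -results$margin[results$category == "neutral"]
  ord <- order(cat_order, key, results$family)
  out <- results[ord, ]
  attr(out, "total") <- attr(results, "total")
  attr(out, "n_tested") <- attr(results, "n_tested")
  out
}
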