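# Independent quantile oracle for the Beta(x+1, n-x+1) posterior:
# the density is evaluated in closed form, integrated by composite
# Simpson's rule on a fine grid, and the cumulative curve is inverted
# with a monotone spline + root finder. qbeta()/pbeta() are never used.
beta_quantile_oracle <- function(p, x, n, grid_n = 4000) {
  a <- x + 1
  b <- n - x + 1
  t <- seq(0, 1, length.out = grid_n + 1)
  logf <- (a - 1) * log(ifelse(t == 0, 1, t)) +
    (b - 1) * log(ifelse(t == 1, 1, 1 - t)) - lbeta(a, b)
  f <- exp(logf)
  if (a > 1) f[1] <- 0
  if (b > 1) f[length(f)] <- 0
  h <- 1 / grid_n
  # cumulative Simpson over pairs of panels (grid_n is even)
  i <- seq(1, grid_n - 1, by = 2)
  panel <- h / 3 * (f[i] + 4 * f[i + 1] + f[i + 2])
  cdf_even <- c(0, cumsum(panel))          # at t = 0, 2h, 4h, ..., 1
  nodes <- t[seq(1, grid_n + 1, by = 2)]
  cdf_even <- cdf_even / cdf_even[length(cdf_even)]
  cdf_fun <- splinefun(nodes, cdf_even, method = "hyman")
  vapply(p, function(pp) {
    uniroot(function(z) cdf_fun(z) - pp, c(0, 1), tol = 1e-12)$root
  }, 0)
}

# Minimal in-code survey builder used across tests.
make_survey <- function(voucher, area, family = "Testaceae",
                        genus = "Genus", species = "alpha",
                        ailments = "FEV", parts = "L", preps = "D",
                        routes = "O") {
  n <- length(voucher)
  tibble::tibble(
    voucher = voucher,
    family = rep_len(family, n), genus = rep_len(genus, n),
    species = rep_len(species, n), authority = "",
    local_name = "", ailment_text = "",
    ailments = lapply(strsplit(rep_len(ailments, n), "/", fixed = TRUE),
                      trimws),
    parts = lapply(strsplit(rep_len(parts, n), "|", fixed = TRUE), trimws),
    preps = lapply(strsplit(rep_len(preps, n), "|", fixed = TRUE), trimws),
    routes = lapply(strsplit(rep_len(routes, n), "|", fixed = TRUE),
                    trimws),
    area = rep_len(area, n),
    rank = ifelse(nzchar(rep_len(genus, n)),
                  ifelse(nzchar(rep_len(species, n)), "species", "genus"),
                  "unidentified"))
}
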