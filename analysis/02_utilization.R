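#!/usr/bin/env Rscript
# Regional utilization analysis: per-family 95% credible intervals and
# over-/under-utilization classification for the three provinces (ES,
# EH, BV) against both reference databases (regional flora extract and
# traditional-medicines database), from the published per-family counts.
# Tables mirroring the published layout go to results/utilization/.

suppressMessages(library(medflora))

for (ref in c("plantdb", "tmdb")) {
  panel <- reference_family_counts(ref)
  for (reg in unique(panel$region)) {
    fams <- panel[panel$region == reg & panel$family != "TOTAL", ]
    tot <- panel[panel$region == reg & panel$family == "TOTAL", ]
    res <- run_utilization(
      data.frame(family = fams$family, n_reference = fams$n_reference,
                 x_used = fams$x_used),
      total = data.frame(n_reference = tot$n_reference,
                         x_used = tot$x_used),
      out = file.path("results/utilization",
                      paste0(ref, "_", reg, ".tsv")))
    cat(sprintf("%-7s %-3s overused %2d  underused %d  neutral %d\n",
                ref, reg, sum(res$category == "overused"),
                sum(res$category == "underused"),
                sum(res$category == "neutral")))
    if (ref == "plantdb" && reg == "ES") {
      over <- sum(res$category == "overused")
      cat(sprintf("  -> %.2f%% of the %d ES regional plant records\n",
                  100 * over / tot$n_reference, tot$n_reference))
    }
  }
}
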