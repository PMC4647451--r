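---
title: "Methods: utilization classification for coded plant-use surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: utilization classification for coded plant-use surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medflora)
```

## The model

The unit of analysis is the plant family. A reference set (a regional
flora checklist, or a traditional-medicines database) contributes `n`
taxa for a family; the focal survey reports `x` of them as medicinally
used. Treating each taxon's use as an exchangeable Bernoulli event with
family-specific probability `p`, a uniform Beta(1, 1) prior gives the
posterior

`p | x, n ~ Beta(x + 1, n - x + 1)`

whose 0.025 and 0.975 quantiles form the 95% credible interval (the
"inferior" and "superior" bounds). The uniform prior is not an
arbitrary choice here: it is pinned down by the published bound pairs,
e.g. a family with `x = n = 1` prints (0.158, 0.987), which is exactly
(sqrt(0.025), sqrt(0.975)), the quantile pair of Beta(2, 1) — and the
regional total (207 of 2258) prints (0.080, 0.104), which Beta(208,
2052) reproduces. A Jeffreys or other prior would not.

A family is **overused** when its inferior bound lies strictly above
the superior bound of the regional-total interval, **underused** when
its superior bound lies strictly below the total's inferior bound, and
**neutral** otherwise. Interval separation is a deliberately
conservative rule: both intervals must clear each other entirely, which
is stricter than a posterior-probability comparison at the same level.

### Margins

The "difference to interval" column mirrors the published tables:
`inferior(family) - superior(total)` for overused families (positive),
`superior(family) - inferior(total)` for underused ones (negative).
Margins are computed on *unrounded* bounds — the published values prove
this convention, since e.g. the Araceae margin prints 0.184 while
subtracting the rounded bounds would give 0.185. For neutral families
we report the larger (closest to zero) of the two separation deficits,
`max(inf_f - sup_t, inf_t - sup_f)`, a non-positive distance to
significance used only for ranking; for a family whose interval
coincides with the total's this is minus the interval width, which we
prefer over defining it as zero because it still orders near-misses
sensibly.

### What is deliberately absent

No multiple-testing correction is applied: the original procedure
applies none, and the report instead carries the number of families
tested (`n_tested` attribute) so that readers can judge the family-wise
error themselves. Small families are the known weak point: a family
with a single checklist taxon that happens to be used yields the
interval (0.158, 0.987) and is declared overused against any total
below 0.158 — a one-report "significant" family. The simulation study
below quantifies exactly this.

## Data model and parsing

Survey records are one row per remedy report. Multi-valued cells follow
the conventions of the source reports: `/` separates ailment codes,
`|` separates remedy *alternatives* and is aligned positionally across
the part/preparation/route columns, and `&` (or `or`) joins items
co-used within one alternative. `explode_uses()` expands a record into
one event per (ailment x alternative); a cell with a single token is
broadcast across all alternatives, and genuinely misaligned
cardinalities (e.g. 2 parts against 3 preparations) raise an error
naming the voucher. Code validation reports unknown tokens and never
repairs them; the packaged survey deliberately retains oddities of its
source ("S?", "-") so they surface in the validation report.

### Counting units

Published figures of this kind rarely state their counting unit. Two
units are exposed everywhere:

- **per record** (default for `top_conditions()`): each report
  contributes one count per ailment code. Under this unit the packaged
  survey reproduces the published pooled tallies (SKIN 73, RESP 60,
  FEV 39, GAST 36, MAL 29) and all four per-area top-5 lists exactly,
  which is how the unit was fixed.
- **per event** (default for `usage_frequency()`): each exploded
  alternative counts; switchable to per-record via `unit`.

For the family-level classifier the analyzed unit is the *taxon*
(`medicinal_family_counts(unit = "distinct_taxa")`), matching the
reference databases, with `unit = "entries"` available for report-level
denominators.

### Name harmonization

Family names are compared case- and whitespace-insensitively, and a
small user-overridable synonym map resolves the historic family names
present in the survey (Labiatae/Labiate to Lamiaceae, Gramineae to
Poaceae, Guttiferae to Clusiaceae, Mimosaceae to Fabaceae,
Asclepiadaceae to Apocynaceae, Compositae to Asteraceae). Species
identity ignores authority strings and collapses infraspecific ranks to
the binomial. Resolution against live taxonomic services is out of
scope; the one genus-level misspelling in the source ("Ipomea") is kept
verbatim and documented rather than merged.

## The synthetic-data generator

`simulate_flora()` draws per-family checklist sizes from a truncated
discrete power law `P(s) proportional to s^-a` on `[size_min,
size_max]`, which reproduces the heavy-tailed family-size structure of
real regional floras (a few families with close to a hundred or more
species, many singletons). `simulate_survey()` then includes each
species independently with probability `min(1, baseline * effect)`,
with family-specific multiplicative effects — species-level Bernoulli
inclusion, because the classifier's unit is the taxon, not the use
report. Generated records draw their codes from the packaged
vocabularies, so simulated surveys pass validation.

Defaults are sized like the East Sepik reference data and are treated
as the study conditions, not tuning knobs: 80 families, exponent 1.3 on
sizes 1-300 (about 2,000 species in expectation), baseline use
probability 0.09 (close to the observed 207/2258). Replicate seeds are
derived from the master seed by seeding R's generator once and drawing
`n` integers (`derive_seeds()`), so any replicate can be reproduced in
isolation.

The generator emulates the *statistical* structure the classifier
assumes and nothing more. It does not model informant networks, the
shared ethnobotanical knowledge that correlates reports across areas,
name ambiguity, or spatial structure of plant availability — so passing
recovery tests demonstrates the classifier's behavior under its own
assumptions, not robustness to those violations.

### Operating characteristics

`analysis/04_simulation_study.R` estimates, at the package's chosen
problem sizes (500 neutral replicates; 200 replicates per power point —
sizes at which the Monte-Carlo error on a rate is about a percentage
point):

- the per-family false-positive rate under a fully neutral flora, which
  sits just under 5%; nearly all false positives are tiny families with
  one lucky report, the pattern discussed above;
- detection power for a planted 8x-overused family, which rises
  steeply with the family's checklist size and is essentially 1 from
  size ~30 at baseline 0.05.

## Numerical choices

- Quantiles come from R's `qbeta` (absolute accuracy well below 1e-8);
  the test suite cross-checks it against an independent oracle that
  integrates the closed-form Beta density with composite Simpson's rule
  and inverts the cumulative curve by root finding, over every
  `0 <= x <= n <= 50`, at tolerance 1e-6.
- Classification uses strict inequalities; exact bound equality is
  neutral. Ties in every ranking break lexicographically by family or
  code, so all outputs are deterministic.
- Report files show 3-decimal display columns (the precision of the
  published tables, rounded half-even) alongside full-precision
  columns, so rounding can never hide a discrepancy.
- Families absent from the reference set (`n = 0`) are reported as
  unanalyzable instead of being dropped, and `x > n` (possible when the
  survey and reference were harmonized differently) is flagged, not
  clamped.

## Known limitations

- The digitized survey reflects a published table with documented
  typesetting defects; every curated cell is listed in
  `inst/extdata/es_survey_CHANGELOG.md`, and one published aggregate
  (the "80 not-shared genera" tally) is not recoverable from the table
  under any set-theoretic definition.
- The novelty screen ships a *synthetic* reference list reconstructed
  from the survey's own species and the published list of previously
  unreported ones; it exercises the operation but is not a real
  bibliographic database.
- The classifier inherits the original procedure's sensitivity to tiny
  reference families and its lack of multiplicity control; treat
  single-taxon "overused" families as leads, not findings.
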