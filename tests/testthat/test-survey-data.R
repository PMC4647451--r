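test_that("read_survey parses multi-valued cells and preserves row order", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    paste("voucher", "family", "genus", "species", "authority",
          "local_name", "ailment_text", "ailments", "parts", "preps",
          "routes", "area", sep = "\t"),
    paste("GW 56/04", "Meliaceae", "Aglaia", "", "", "Waniembri",
          "Fevers, malaria", "FEV/MAL", "L", "B", "I", "GW", sep = "\t"),
    paste("MS 02/04", "Malvaceae", "Abelmoschus", "manihot", "(L.) Medik",
          "Wasniat", "Uterine contraction", "REP", "L", "D", "O", "MS",
          sep = "\t")), f)
  s <- read_survey(f)
  expect_equal(nrow(s), 2)
  expect_equal(s$ailments[[1]], c("FEV", "MAL"))
  expect_equal(lengths(s$ailments), c(2L, 1L))
  expect_equal(lengths(s$parts), c(1L, 1L))
  expect_equal(s$voucher, c("GW 56/04", "MS 02/04"))
  expect_equal(s$rank, c("genus", "species"))
})

test_that("read_survey reports schema problems by name", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("voucher\tfamily\tgenus", "v1\tF\tG"), f)
  expect_error(read_survey(f), "ailments")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(c("voucher", "family", "genus", "species", "authority",
                     "local_name", "ailment_text", "ailments", "parts",
                     "preps", "routes", "area"), collapse = "\t"), f2)
  expect_error(read_survey(f2), "no data rows")
})

test_that("read_survey rejects duplicate vouchers and empty ailments", {
  f <- withr::local_tempfile(fileext = ".tsv")
  hdr <- paste(c("voucher", "family", "genus", "species", "authority",
                 "local_name", "ailment_text", "ailments", "parts",
                 "preps", "routes", "area"), collapse = "\t")
  row <- paste("v1", "F", "G", "s", "", "", "", "FEV", "L", "D", "O", "A",
               sep = "\t")
  writeLines(c(hdr, row, row), f)
  expect_error(read_survey(f), "duplicated voucher")
  writeLines(c(hdr, paste("v1", "F", "G", "s", "", "", "", "", "L", "D",
                          "O", "A", sep = "\t")), f)
  expect_error(read_survey(f), "without ailment codes")
})

test_that("the digitized survey fixture holds 299 records in 4 areas", {
  s <- es_survey()
  expect_equal(nrow(s), 299)
  expect_setequal(unique(s$area), c("DK", "BK", "GW", "MS"))
  expect_equal(sum(s$rank == "unidentified"), 6)
})

test_that("survey round-trips through the canonical delimited format", {
  s <- es_survey()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_survey(s, f)
  s2 <- read_survey(f)
  expect_equal(as.data.frame(s2), as.data.frame(s))
})

test_that("validate_codes reports unknown tokens without mutating records", {
  ok <- make_survey("v1", "A", ailments = "SKIN", parts = "L",
                    preps = "S", routes = "T")
  expect_equal(nrow(validate_codes(ok)), 0)
  bad <- make_survey("v2", "A", routes = "Q")
  rep <- validate_codes(bad)
  expect_equal(rep$dimension, "route")
  expect_equal(rep$token, "Q")
  expect_equal(rep$voucher, "v2")
  # '&'-joined tokens are validated individually
  joined <- make_survey("v3", "A", parts = "L & yShoot", routes = "O & T")
  expect_equal(nrow(validate_codes(joined)), 0)
})

test_that("fixture validation flags only tokens outside the footnote lists", {
  s <- es_survey()
  rep <- validate_codes(s)
  # every ailment code in the fixture is in the footnote vocabulary
  expect_false("ailment" %in% rep$dimension)
  # the footnote part list is short; the table's extra tokens are flagged
  expect_true(all(c("Sap", "Root", "Whole") %in%
                    rep$token[rep$dimension == "part"]))
  # the two curated oddities surface for review instead of being repaired
  expect_true("S?" %in% rep$token[rep$dimension == "preparation"])
  expect_true("-" %in% rep$token[rep$dimension == "route"])
})

test_that("explode_uses forms the ailment x alternative cross product", {
  one <- make_survey("v1", "A", ailments = "SKIN", parts = "L",
                     preps = "S", routes = "T")
  expect_equal(nrow(explode_uses(one)), 1)
  two <- make_survey("v2", "A", ailments = "FEV/MAL")
  ev <- explode_uses(two)
  expect_equal(nrow(ev), 2)
  expect_equal(sort(ev$ailment), c("FEV", "MAL"))
  expect_equal(unique(ev$part), "L")
  # 4 ailments and 3 aligned alternatives give 12 events, with
  # single-token cells broadcast across alternatives
  rec <- make_survey("BK 022/06", "BK", ailments = "MAL/GAST/RESP/SKIN",
                     parts = "L | Sap | Sap", preps = "D | D | S",
                     routes = "O")
  ev <- explode_uses(rec)
  expect_equal(nrow(ev), 12)
  expect_equal(as.vector(table(ev$alternative)), rep(4L, 3))
  expect_equal(unique(ev$route), "O")
  expect_equal(ev$prep[ev$alternative == 3][1], "S")
})

test_that("explode_uses is lossless and rejects misaligned alternatives", {
  s <- es_survey()
  ev <- explode_uses(s)
  # multiset of ailments over events = record ailments x n alternatives
  n_alt <- vapply(seq_len(nrow(s)), function(i) {
    max(length(s$parts[[i]]), length(s$preps[[i]]),
        length(s$routes[[i]]), 1L)
  }, 0L)
  expect_equal(nrow(ev), sum(lengths(s$ailments) * n_alt))
  expect_equal(sort(unique(ev$ailment)), sort(unique(unlist(s$ailments))))
  bad <- make_survey("vx", "A", parts = "L | B", preps = "D | D | S")
  expect_error(explode_uses(bad), "vx")
})

test_that("harmonize_family maps historic names idempotently", {
  map <- default_family_synonyms()
  expect_equal(harmonize_family("Labiatae", map), "Lamiaceae")
  expect_equal(harmonize_family("Lamiaceae", map), "Lamiaceae")
  expect_equal(harmonize_family(" fabaceae ", character()), "Fabaceae")
  x <- c("Labiatae", "Gramineae", "Compositae", "Rubiaceae")
  once <- harmonize_family(x, map)
  expect_equal(harmonize_family(once, map), once)
})

test_that("dedupe_checklist applies set semantics and flags empty families", {
  rows <- data.frame(family = c("F", "F"), genus = c("G", "G"),
                     species = c("s", "s"))
  expect_equal(nrow(dedupe_checklist(rows)), 1)
  rows2 <- data.frame(family = "F", genus = "G", species = c("s1", "s2"))
  expect_equal(nrow(dedupe_checklist(rows2)), 2)
  rows3 <- data.frame(family = c("F", ""), genus = "G", species = "s")
  expect_error(dedupe_checklist(rows3), "2")
  # planted duplicates: 1000 rows, 100 duplicated -> 900 unique
  set.seed(1)
  base <- data.frame(family = "Fam",
                     genus = paste0("G", rep(1:30, length.out = 900)),
                     species = paste0("s", 1:900))
  dups <- base[sample.int(900, 100), ]
  shuffled <- rbind(base, dups)[sample.int(1000), ]
  expect_equal(nrow(dedupe_checklist(shuffled)), 900)
})

test_that("family_counts is permutation- and duplication-invariant", {
  cl <- dedupe_checklist(data.frame(
    family = c("F1", "F1", "F2"), genus = c("G1", "G2", "G3"),
    species = c("a", "b", "c")))
  fc <- family_counts(cl)
  expect_equal(setNames(fc$n, fc$family), c(F1 = 2L, F2 = 1L))
  expect_equal(sum(fc$n), nrow(cl))
  expect_equal(nrow(family_counts(cl[0, ])), 0)
  set.seed(2)
  rows <- data.frame(family = sample(c("A", "B", "C"), 50, replace = TRUE),
                     genus = sample(paste0("G", 1:10), 50, replace = TRUE),
                     species = sample(paste0("s", 1:15), 50, replace = TRUE))
  a <- family_counts(dedupe_checklist(rows))
  b <- family_counts(dedupe_checklist(rbind(rows[sample.int(50), ], rows)))
  expect_equal(a, b)
})

test_that("medicinal_family_counts supports both counting units", {
  s <- make_survey(c("v1", "v2"), "A", family = "Fam", genus = "G",
                   species = "alpha")
  taxa <- medicinal_family_counts(s, "distinct_taxa")
  expect_equal(taxa$x, 1L)
  entries <- medicinal_family_counts(s, "entries")
  expect_equal(entries$x, 2L)
  # the fixture's entries sum to the published 299
  es <- es_survey()
  expect_equal(sum(medicinal_family_counts(es, "entries")$x), 299)
})
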