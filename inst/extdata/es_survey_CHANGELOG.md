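# Digitization changelog for `es_survey.tsv`

The survey fixture is a digitization of the published combined survey
table for the four East Sepik study areas (DK, BK, GW, MS). The published
typesetting runs all columns together; records were recovered by
splitting the character stream on voucher tokens (each voucher precedes
its record) and peeling the coded fields from the right using the
footnote vocabularies. The recovered table reproduces the published
pooled tallies exactly: 299 entries (6 unidentified), ailment counts
SKIN 73 / RESP 60 / FEV 39 / GAST 36 / MAL 29, and all four per-area
top-5 condition lists.

Cells that could not be digitized verbatim, or that are internally
inconsistent in the published version, are listed here. Odd tokens are
kept verbatim so that `validate_codes()` flags them for review; nothing
was silently repaired.

## Patched rows (unparseable as printed)

- **MS 08/04** (Ocimum basilicum): family printed as "Labiate"; kept
  verbatim (the default synonym map resolves it to Lamiaceae).
- **BK 020/06** (Ipomoea pes-caprae): preparation printed as "S?" and no
  route given; preparation kept as "S?", route recorded as "-" (missing).
- **MS 09/04** (Passiflora foetida): no plant-part token printed; part
  recorded as "-" (missing), preparation R, route T.
- **BK 021/06** (Kalanchoe pinnata): local name and ailment text are
  printed without a separator ("Kulukirknee pain/ache..."); split
  manually as local name "Kulukir".
- **MS 22/04** (not identified): preparation printed as "-"; kept.

## Inconsistencies resolved (flagged, with rationale)

- **Duplicate voucher MS 37/04**: printed for both the Codiaeum
  variegatum "Diripmi" record and the Mucuna novo-guineensis
  "Kilemiesik" record. The second occurrence is stored as "MS 37b/04" to
  restore voucher uniqueness; the true number is unknowable from the
  publication (MS 34/04 and MS 51/04 are absent from the sequence).
- **Zingiber officinale study areas**: the published table assigns its
  four records to BK, DK, DK and MS, yet the published results text
  states the species was reported in every survey (it is one of the four
  species shared by all areas). The DK 39/05 "Huaukuasa" record is
  reassigned to area GW: "Hua-"-prefixed local names otherwise occur
  only in the GW report, and the reassignment leaves every pooled tally
  and the GW top-condition counts unchanged. Consequence: the per-area
  malaria tallies shift by one relative to the published prose (DK 5 to
  4, GW 17 to 18).
- **Genus spelling "Ipomea"** (GW 52/04): kept verbatim; it is counted
  as distinct from "Ipomoea" because nomenclature resolution is out of
  scope.

## Published values not recoverable from the table

- The published tally of "80 genera not shared between any of the four
  study areas" cannot be reproduced under any set-theoretic reading:
  area-unique genera number 83, area-unique taxon names 151, area-unique
  species 96. The published not-shared list is itself inconsistent with
  the survey table (it omits several equally area-unique taxa, e.g.
  Acalypha grandis and Mikania sp., while including Euphorbia
  tithymaloides whose genus occurs in all four areas).
- The published genus tally "Euphorbia (7)": the table contains 8
  Euphorbia records.
- The published totals "205 plants / 139 species / 71 families":
  the digitized table yields 203 distinct taxa, 135 species-rank
  binomials and 70 verbatim family names; drift of this kind is
  acknowledged in the publication as an artifact of family-name
  reconciliation.
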