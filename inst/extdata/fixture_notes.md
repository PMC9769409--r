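# Fixture provenance notes

The four `orchid_*.csv` files transcribe the published screening tables of an
orchid endophytic-actinobacteria campaign verbatim (51 isolates, 10 fungal
pathogens). Where the publication is internally inconsistent, the tables are
kept as printed and the inconsistency is surfaced by the package's validators
and audit rather than silently corrected:

- The source's abstract gives the top phosphate-solubilization value as
  289.7 ± 11.9 µg/ml; its trait table prints 289.7 ± 11.1 for DNRA1. The
  table value is kept (tables are the per-isolate source of truth).
- The roster table and the trait/inhibition tables do not share the same 51
  isolate codes: the roster lists MORA2 but not DMLA1; the trait and
  inhibition tables list DMLA1 but not MORA2. `validate_roster()` reports
  this.
- The roster marks CALA1's tissue as "Root" although its code pattern
  suggests a leaf isolate, and the roster's own tissue counts do not
  reproduce the stated 33 root / 18 leaf split. Kept verbatim.
- The source's prose states 27 isolates antagonized at least one pathogen;
  the inhibition table as printed has 28 rows with at least one value
  (including DMLA1). `antagonism_spectrum()` reports the recomputed 28.
- Prose describes siderophore production as ranging 10–50% while the trait
  table lists 61.2% (RRR46) and 59.4% (DFRA3). Table values kept.
- One inhibition cell is printed with a malformed error term ("51.2 ± 04",
  MOLA1 vs P. theae); the mean parses as 51.2.
- Two rows of the inhibition table have trailing blank cells instead of
  dashes (DMRA2, DMLA1); blanks are read as "no activity", like dashes.
- `orchid_bonitur_published.csv` transcribes the published 41-point score
  table. Two of its rows (DNLA13, VCRA2) disagree with scores recomputed
  from the trait/inhibition tables, and the VCRA2 row's own points sum to
  28, not the printed total of 30. `audit_scores()` flags both.
- Per-isolate genus is only printed for a handful of strains; the roster's
  `genus` column is blank (unknown) elsewhere. Genus totals quoted in the
  source's prose are campaign-level counts, not per-row data.
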