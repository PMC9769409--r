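# pgpscreen

Analytics for screening campaigns of plant-growth-promoting (PGP) and
biocontrol microbial isolates — the kind of study where tens of culturable
endophytes are phenotyped *in vitro* for PGP traits (auxin production,
phosphate solubilization, ammonia, siderophores, hydrolytic enzymes),
confronted with a panel of fungal phytopathogens in dual culture, scored on
an additive multi-trait scale to pick elite strains, and the winners carried
into a pot trial.

The package ships the full analysis as tested, reusable functions, plus a
transcription of a published 51-isolate orchid-endophyte campaign (10
pathogens) as fixtures, and seeded generators that emulate whole campaigns
and pot trials for testing.

## What it computes

**Assay arithmetic.** Standard-curve calibration by ordinary least squares
(`absorbance = slope·c + intercept`, free intercept) and its inversion to
concentrations; dual-culture percent inhibition `100·(C−T)/C` from control
and test mycelium diameters; CAS-shuttle siderophore units
`100·(Ar−As)/Ar` from 630 nm absorbances; germination percentage; and the
DMSO-extract chlorophyll equations
`Chla = 11.75·A663 − 2.35·A645`, `Chlb = 18.61·A645 − 3.96·A663`.

**Bonitur scoring.** The 41-point scale: IAA and phosphate solubilization
binned to 1/2/3 points (thresholds 15/30 and 100/200 µg/ml,
upper-inclusive), one point each for ammonia, N₂ fixation, ACC deaminase,
siderophore and chitinase, and 0–3 points per pathogen from inhibition bins
(10, 30]/(30, 60]/(60, 100]. Dense ranking (ties share a rank), and an
audit that reconciles recomputed score cards against a published score
table instead of trusting it.

**Campaign summaries.** Trait prevalence (not-detected is a first-class
state, never a zero), per-pathogen antagonism spectrum, broad-spectrum
detection, genus/tissue composition, value extremes with isolate
attribution.

**Pot-trial statistics.** Mean ± SE (SE = sd/√n), log2 fold change of
treatment means over control, classic one-way ANOVA per parameter per
timepoint, and PCA on the correlation matrix of the nine vegetative
parameters.

## Worked example

```r
library(pgpscreen)

traits     <- read_trait_table(pgp_fixture("traits"))
inhibition <- read_inhibition_matrix(pgp_fixture("inhibition"))

cards <- score_campaign(traits, inhibition, bonitur_rules())
head(cards[, c("isolate_id", "pgp_subtotal", "antifungal_subtotal", "total", "rank")], 7)
#>   isolate_id pgp_subtotal antifungal_subtotal total rank
#> 1      VCLA3           11                  23    34    1
#> 2      RVRA7           11                  21    32    2
#> 3     DNLA13            5                  26    31    3
#> 4      VCRA2            3                  28    31    3
#> 5      RRR46            7                  14    21    4
#> 6      DNRA5            7                  11    18    5
#> 7      DFLA1            5                  13    18    5
```

VCLA3 tops the ranking with 34 of 41 points (11 from PGP traits, 23 from
antagonism) and RVRA7 follows with 32 — the two strains a campaign like
this would take into pot trials. Auditing against the published score
table flags the rows that do not reconcile:

```r
audit_scores(cards, read_published_scores(pgp_fixture("bonitur_published")))
#> score audit: discrepancies for DNLA13, VCRA2
#> ...
#> published rows whose points do not sum to the printed total:
#>   isolate_id points_sum printed_total consistent
#> 4      VCRA2         28            30      FALSE
```

Community-level description:

```r
trait_prevalence(traits)[1:4, ]
#>         trait positive  n percentage              rule
#> 1         iaa       27 51      52.94 detected (non-ND)
#> 2     p_solub       25 51      49.01 detected (non-ND)
#> 3     ammonia       35 51      68.62 detected (non-ND)
#> 4 siderophore       13 51      25.49 detected (non-ND)

antagonism_spectrum(inhibition)$broad_spectrum
#> [1] "DNLA13" "VCRA2"
```

## The analysis workflow

The `analysis/` directory runs the campaign end to end, writing tables
under `results/`:

| script | stage |
|---|---|
| `01_validate_tables.R` | load + cross-validate the three campaign tables |
| `02_screen_summary.R`  | prevalence, antagonism spectrum, extremes |
| `03_bonitur_ranking.R` | score cards, ranking, audit vs published table |
| `04_assay_calibration.R` | standard curves and closed-form assay checks |
| `05_growth_trial.R`    | synthetic pot trial: SE, log2 FC, ANOVA, PCA |

Run each with `Rscript analysis/01_validate_tables.R` (etc.) from the
repository root.

## Synthetic data

`simulate_screen()` and `simulate_trial()` generate campaigns and trials
with configurable prevalences, value ranges, inhibition sparsity, fold
changes and replicate noise, deterministically from a single master seed
(`screen_sim_config()`, `trial_sim_config()`). Defaults mirror the packaged
campaign's published ranges and rates. `synthetic_standards()` generates
calibration series for the quantification stage.

See `vignettes/pgp-screening-methods.Rmd` for the model, scoring
conventions, numerical choices and limitations.
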