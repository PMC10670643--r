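# ctcpanel

Derivation and clinical evaluation of multigene circulating tumor cell
(CTC) panels measured by RT-qPCR in liquid biopsies.

## The problem

CTCs — tumor cells shed into peripheral blood — are rare enough that
molecular detection is often more sensitive than imaging-based
enumeration. A practical molecular workflow enriches the blood's cell
fraction, measures a small panel of tumor-associated transcripts by
RT-qPCR, and calls a sample CTC-positive when enough panel genes rise
above the healthy-donor background. Deriving such a panel, calling markers
reproducibly, and relating CTC status to clinical variables and survival
each involve specific statistical conventions that are easy to get subtly
wrong. `ctcpanel` packages the whole chain for analysts working with
RT-qPCR liquid-biopsy data (and for anyone who wants a fully synthetic,
ground-truthed testbed for this kind of pipeline).

## What it computes

* **Relative quantification.** The 2^-ddCt method: for gene *g*, sample
  *s*, reference gene *r* and a healthy-donor calibrator,
  `fc(g,s) = 2^-( [Ct(g,s) - Ct(r,s)] - dCt_cal(g) )`, with undetected
  transcripts mapped to fold change 0 and three-level calls
  negative (< 2) / positive (>= 2) / high (>= 5).
* **Panel derivation.** A four-stage cascade with a per-gene audit trail:
  single-cell screen (PBMC mean < 0.10, tumor mean > 1.0), pure-population
  Ct specificity filter (cutoff 30 cycles), spike-in sensitivity (detected
  at 500 spiked cells in every cell line), pilot positivity (>= 30% of
  pilot samples).
* **Classification.** Detected-marker counts per sample; CTC-positive
  (>= 2 markers), CTC-high (>= 5), hybrid-EMT (EpCAM and TWIST1
  co-detected); ROC / Youden-J selection of the count threshold;
  longitudinal trajectories across paired time points.
* **Association tests.** Exact two-sided Fisher tests (hypergeometric
  "sum of small p" enumeration), Pearson chi-square, two-sample
  Kolmogorov–Smirnov, against conventional clinical dichotomies.
* **Survival.** Kaplan–Meier curves and medians, log-rank tests, Cox
  proportional-hazards models (Efron ties) with hazard ratios for marker
  and CTC strata.
* **Synthetic studies.** `sim_config()` / `simulate_study()` generate
  every input — single-cell counts, Ct tables for pure populations,
  spike-in series, pilot samples, and a survival-annotated 55-patient
  cohort — with ground truth, calibrated so the default cohort classifies
  ~83.6% of patients CTC-positive.

## Worked example

```r
library(ctcpanel)

cfg   <- sim_config(seed = 42)          # a full synthetic study
study <- file.path(tempdir(), "study")
out   <- file.path(tempdir(), "out")
simulate_study(cfg, study)              # writes counts, Ct tables, cohort
res <- run_pipeline(study, out, run_config(seed = 42))

res$panel$genes
#>  [1] "CCND1"  "ECT2"   "EpCAM"  "FSCN1"  "KRT5"   "KRT18"  "MET"    "TFRC"
#>  [9] "TWIST1" "VEGFC"

unlist(res$classification$patient_level)
#>                 n ctc_positive_rate     ctc_high_rate   hybrid_emt_rate
#>        55.0000000         0.8363636         0.6363636         0.4363636

round(unlist(res$survival$ctc_high), 4)
#> median_high median_rest   logrank_p          hr       cox_p
#>    165.0000    287.0000      0.0057      2.5529      0.0047
```

The derived panel is exactly the ten ground-truth marker genes (each decoy
candidate was eliminated at the cascade stage it was built to fail); 83.6%
of the 55 synthetic patients are CTC-positive at baseline; CTC-high
patients have a shorter median overall survival (165 vs 287 days) with an
adjusted hazard ratio of 2.55 — the generating model used hazard ratio 2.6.

The exact Fisher machinery reproduces printed-style contingency results
directly from counts:

```r
fisher_exact_two_sided(contingency_2x2(1, 7, 4, 1))
#> Fisher exact test, 2-sided
#>   statistic = 0.03108003, p = 0.03185703   # rounds to 0.032
```

Every `run_pipeline()` output directory contains the tabular exports
(`panel_audit.tsv`, `fold_changes.tsv`, `ctc_status.tsv`,
`associations.tsv`, `cox.tsv`, `km_*.tsv`) plus a `summary.json` that
validates against the schema shipped in `inst/schema/`.

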