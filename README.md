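# promfam

Transcription-factor binding site (TFBS) **family** overrepresentation in
subtype-specific gene promoters — for regulatory genomicists asking why the
gene sets that define expression subtypes (e.g. the five intrinsic breast
cancer subtypes: Luminal A/B, ErbB2+, Basal-like, Normal-like) cluster
together. If those genes are co-regulated, their promoters should share
grammar: enriched binding-site families, ordered motif modules with
constrained spacing, and transcription factors whose own expression tracks
that enrichment.

## The statistics at the core

Promoters are the fixed −500..+100 bp window around the TSS. PWMs are
scanned on both strands with background-calibrated log-odds cutoffs, and
matrix hits are collapsed to **matrix families** (groups of redundant,
position-shifted matrices for the same factor). For a family *X* in a
promoter set:

- **fold factor** — r(X) = n_obs(X) / n_exp(X)
- **z-score** — z(X) = (n_obs(X) − n_exp(X) − 0.5) / S(X)

where n_exp and S are the mean and population SD of the family's hit count
over B = 1000 equal-base-pair resamples of a genomic-promoter background
pool. Families with z ≥ 2 and n_obs > n_exp are called overrepresented;
underrepresentation is never called. Downstream, the family × subtype
fold matrix is analyzed by column-centered PCA with **Hotelling's T²**
(squared Mahalanobis distance from the centroid) ranking families by
between-subtype variability; ordered **promoter frameworks** (e.g.
NF-κB → ETS at 29–79 bp spacing) are mined under order/distance
constraints; and family enrichment is correlated with subtype geometric-mean
TF expression (SAM-style multiclass selection at FDR < 0.1, Wilcoxon
rank-sum marker tests).

A first-class synthetic-data module generates background pools, planted
subtype promoter sets, framework modules and coupled lognormal expression
with a ground-truth ledger, so every statistic is testable end to end.

## Worked example

Simulate a small five-subtype study in which the NF-κB-like family is
planted at 3× background rate in the ERBB2 promoter set, then measure
enrichment and rank families:

```r
library(promfam)

mult <- matrix(1, 12, 5)
mult[1, 3] <- 3          # family 1 (V$NFKB) elevated in subtype 3 (ERBB2)
cfg <- simulation_config(seed = 7, n_families = 12, genes_per_set = 30,
                         n_background = 400, multipliers = mult)
lib <- toy_pwm_library(cfg)

cal <- simulate_background_pool(cfg, lib, n_promoters = 200,
                                planted = FALSE, stage = "calibration")
bg  <- simulate_background_pool(cfg, lib)
th  <- calibrate_thresholds(lib$pwms, cal$promoters, rate = 0.1)
bg_hits <- collapse_family_hits(
  scan_sequences(bg$promoters, lib$pwms, th, lib$map))
bm <- estimate_background(bg$promoters, bg_hits, target_bp = 30 * 600,
                          B = 500, seed = 1)

sub <- simulate_subtype_promoters(cfg, lib)
enr <- lapply(sub$sets, enrich_promoters, pwms = lib$pwms, thresholds = th,
              background = bm, family_map = lib$map)
e <- enr$ERBB2
head(e[order(-e$z), c("family_id", "n_obs", "n_exp", "fold", "z",
                      "overrepresented")], 3)
#>  family_id n_obs  n_exp     fold        z overrepresented
#>     V$NFKB    30 17.124 1.751927 3.123757            TRUE
#>    V$FAM01    22 16.384 1.342773 1.310136           FALSE
#>    V$FAM09    20 15.366 1.301575 1.045994           FALSE
```

The planted family is the only one crossing z ≥ 2: it was seen 30 times
against an expectation of 17.1 (fold 1.75; the observed fold is below the
planted 3× because calibrated scanning also finds chance hits in both
numerator and denominator). Ranking families across all five subtypes:

```r
fm  <- build_fold_matrix(enr)
pca <- run_pca(fm)
cat("cumulative variance (%):",
    paste(sprintf("%.1f", pca$cum_pct), collapse = ", "), "\n")
#> cumulative variance (%): 40.8, 68.2, 85.1, 95.4, 100.0
head(hotelling_t2(pca), 3)
#>  family_id       t2 rank
#>     V$NFKB 8.705154    1
#>    V$FAM08 7.601279    2
#>    V$FAM01 7.026804    3
```

The planted family tops the T² ranking — its fold profile is farthest from
the centroid of the fold matrix (the runners-up reflect chance variation in
unplanted families at this small problem size). `mine_frameworks()` and
`correlate_enrichment_expression()` complete the analysis; `run_full_pipeline()`
drives everything from a YAML config (see
`inst/scripts/run_pipeline.R` for a command-line wrapper), writing
per-stage TSV/JSON outputs stamped with a config hash and reproducible
byte-for-byte from the seed.

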