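---
title: "Promoter TFBS-family overrepresentation analysis: models and methods"
author: "promfam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Promoter TFBS-family overrepresentation analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promfam)
```

## The scientific question

Expression profiling separates breast tumors into five molecular subtypes
(Luminal A, Luminal B, ErbB2+, Basal-like, Normal-like), each defined by a
characteristic set of genes. If those gene sets are co-regulated, their
promoters should share regulatory grammar: binding sites for particular
transcription factor (TF) families should occur more often than chance in
the promoters of one subtype's genes, TF families may be arranged as
ordered modules with constrained spacing, and the implicated TFs should
themselves show subtype-dependent expression. `promfam` implements that
three-part in-silico analysis — family overrepresentation, multivariate
ranking across subtypes, and expression linkage — over open motif formats
and user-supplied (or simulated) sequence data.

## Promoter windows

Promoters are the fixed window from 500 bp upstream to 100 bp downstream
of the transcription start site. Internally all coordinates are 0-based
half-open (BED-native); a plus-strand TSS at genomic position $t$ maps to
$[t-500, t+100)$ and the returned 600-bp sequence always reads 5'→3' with
the TSS as its 501st base. Windows that overhang a contig edge are
N-padded to full length (and flagged) rather than dropped, so that every
promoter set has an exact, comparable base-pair size — the
"equally sized sample" requirement of the background model below depends
on it. N positions can never produce motif matches.

## Motif model and scanning

Motifs are position weight matrices (PWMs) read from JASPAR or MEME
minimal files. Count matrices get an additive pseudocount (default 0.5
per cell) and are row-normalized; probability matrices are floored at
$10^{-3}$. Scanning uses log-odds scores in bits against a background
base composition, on both strands, with a per-matrix cutoff.

The cutoff is calibrated empirically: it is the smallest score whose
empirical hit rate on a background sequence pool does not exceed a target
rate (default 0.1 hits per kb per strand). This replaces proprietary
per-matrix similarity thresholds with a reproducible rule whose single
parameter has transparent units. Calibration should use sequence that is
not itself enriched for the motifs under study; the synthetic generator
therefore emits a motif-free, composition-matched calibration pool. For
real genomic pools the distinction matters little, because genuine
per-family site densities are far below the densities our generator
plants.

Functionally similar matrices are grouped into *families* via a
two-column map. Because family members are redundant and often match the
same site shifted by a few base pairs, matrix-level hits of one family
that overlap by at least 1 bp within a promoter are collapsed into a
single family hit (union interval, maximum score; strand-blind by
default, configurable). Hits of different families never merge.

## The overrepresentation statistics

For a family $X$ scanned over a promoter set, with $n_{obs}(X)$ the
collapsed hit count, the two statistics are

$$r(X) = \frac{n_{obs}(X)}{n_{exp}(X)}, \qquad
  z(X) = \frac{n_{obs}(X) - n_{exp}(X) - 0.5}{S(X)},$$

where $n_{exp}(X)$ and $S(X)$ are the mean and *population* standard
deviation of the family's hit count over $B = 1000$ seeded resamples of
the background promoter pool, each resample drawn without replacement
until it reaches the same total base-pair size as the studied set. The
$-0.5$ is a continuity correction for the discrete count and is applied
exactly as defined, including when $n_{obs} < n_{exp}$. A family is
called overrepresented at $z \ge 2$ (configurable) *and*
$n_{obs} > n_{exp}$; underrepresentation is deliberately never reported
as a finding — small subtype gene sets make depletion calls unreliable —
though the statistics are retained. The $z \ge 2$ rule is a screening
cutoff, not a calibrated significance level: the resampling null is
approximately but not exactly Gaussian, and no multiplicity adjustment is
applied.

Families absent from the background pool ($n_{exp} = 0$ or $S = 0$) have
undefined statistics; they are excluded and reported rather than
silently given infinite fold factors.

## Ranking families across subtypes

Per-subtype fold factors are assembled into a family × subtype matrix
(families undefined in any subtype are dropped and logged; rows ordered
lexicographically for stable output). Three summaries follow:

- the subtype × subtype Pearson correlation matrix of fold vectors;
- PCA of the column-mean-centered matrix (no variance scaling — the
  columns share units, and scaling would erase genuine differences in
  enrichment spread between subtypes; scaling is available as an option);
  component signs are fixed so each loading vector's largest-magnitude
  entry is positive, removing the usual SVD sign ambiguity;
- Hotelling's $T^2$ per family,
  $T^2 = \sum_j s_{j}^2 / \lambda_j$ over all components with eigenvalue
  above $10^{-12} \lambda_{max}$, which equals the squared Mahalanobis
  distance of the family's fold profile from the matrix centroid. All
  above-tolerance components are used — the ranking measures distance
  from the center, not a truncated approximation.

## Promoter frameworks

A promoter module is an ordered arrangement of family elements with a
constrained spacing. The miner enumerates, for every ordered family pair
(A, B) and promoter, co-occurrences where a B hit starts within
`(0, max_gap]` bp after an A hit ends (distance is end-of-first to
start-of-next; strands are recorded, not constrained). It then searches
the realized gaps for the window of span at most `max_span` (default
60 bp, which admits the classic 29–79 bp spacing) covering the largest
fraction of promoters, breaking ties toward smaller span and then
smaller lower bound. A framework is emitted when that coverage reaches
`min_coverage` (default 1.0). Choosing witnesses through a best window —
rather than pooling every co-occurrence — means one stray off-distance
co-occurrence in one promoter cannot veto an otherwise perfectly
consistent module; that choice was open and is this package's documented
resolution. Pairs are directional: (A, B) and (B, A) are distinct
candidates. Length-3 chains can be composed greedily from validated
pairs sharing the identical middle hit.

## Expression linkage

TF genes differentially expressed across the subtype classes are
selected with a SAM-style multiclass statistic on log intensities:
$d_i = \sqrt{MS_{between}} / (s_i + s_0)$, with $s_i$ the pooled
within-class standard deviation and the fudge constant $s_0$ the median
of all $s_i$ (guarding against genes with near-zero variance dominating
the ranking). The null distribution comes from seeded label
permutations; a gene's q-value is the monotonized median permutation
false-positive count over observed count at its threshold, and genes
with $q <$ FDR (default 0.1) are returned. The exact internals of the
original SAM implementation (its $s_0$ grid search) are not specified by
our sources, so this surrogate is fully specified here instead; it has
the same inferential shape (moderated statistic + permutation FDR).

Subtype expression is summarized by the geometric mean
$\exp(\overline{\log x})$, appropriate because intensity values are
approximately lognormal. For every mapped (family, TF gene) pair the
Pearson correlation between the family's fold vector and the gene's
geometric-mean vector across subtypes links promoter composition to TF
activity. Two-group marker comparisons use the Wilcoxon rank-sum test:
exact enumeration (with midranks) for combined $n \le 12$, tie-corrected
normal approximation with continuity correction otherwise.

## The synthetic-data generator

The generator produces every input the pipeline consumes, with a
ground-truth ledger:

- **Background pool** (default 1000 promoters of 600 bp): i.i.d. bases
  from a configurable composition (uniform by default, isolating the
  statistics from composition effects; GC-skewed compositions are one
  argument away), with each family's motifs planted at a baseline
  Poisson rate (default 0.4 plants/promoter/family). Planted instances
  are sampled letter-by-letter from the PWM on a random strand at
  non-overlapping positions, so scanner thresholds are genuinely
  exercised by a realistic spread of site strengths.
- **Toy PWM library**: 20 families, two 10-bp members each, consensus
  probability 0.95 with the second member's consensus offset by 1 bp —
  the shifted-redundant-matrix situation family counting exists to
  absorb. The first two families carry NF-κB-like and ETS-like
  consensi. The sharpness was fixed at design time so that sampled
  plants are detectable (≥90%) at the default calibration rate.
- **Subtype sets** (default five subtypes × 50 genes, mirroring a
  ~200-gene classifier list): per-family rates are baseline ×
  multiplier(family, subtype). The null configuration is multiplier 1
  everywhere.
- **Framework plants**: an ordered pair with uniform gaps (default
  29–79 bp) in every promoter of a designated (default six-gene) set.
  Framework elements are planted as consensus sites and the two
  families' scattered baseline plants are suppressed in that set: the
  module's ground truth is full coverage by strong shared sites, which
  a randomly sampled weak instance would contradict.
- **Expression** (default 23 samples/class ≈ a 114-sample cohort over
  five classes): lognormal intensities (baseline log-mean 6, log-SD 0.5,
  typical microarray scale and spread); each family maps to one TF gene
  whose class log-mean is baseline + coupling × standardized family
  enrichment, with coupling in [0, 1].

Everything is byte-reproducible from the configuration seed through
named per-stage substreams (`derive_seed`). What the generator does
*not* emulate: real promoter sequence structure (CpG islands, repeats,
composition heterogeneity), alternative promoters, chromatin context,
probe-level array artifacts, and correlated motif co-occurrence beyond
the planted framework. Passing tests therefore demonstrate that the
statistics and miners behave correctly under their own model assumptions
— not that any particular biological claim reproduces on real data.

## Numerical choices and degenerate inputs

- Score accumulation is in double precision, positions overlapping N
  score $-\infty$.
- Threshold boundary cases: a rate admitting every position returns the
  minimum attainable score; a vanishing rate returns the maximum
  observed score.
- `fold_factor` and `z_score` refuse $n_{exp} \le 0$ and $S \le 0$
  rather than returning infinities; callers exclude and report such
  families.
- A constant fold matrix has all-zero eigenvalues: PCA flags it and
  $T^2$ is refused.
- Ties in the $T^2$ ranking break lexicographically by family id;
  framework sorting is coverage, then span, then chain.
- Background resampling uses sampling without replacement, so the
  estimated $S$ carries a mild finite-pool shrinkage relative to i.i.d.
  sampling (about 2.5% at the default pool-to-set ratio); the null
  calibration tests bound its practical effect.

## Problem sizes used by the test-suite and acceptance runs

The shipped checks run the study conditions at: background pool 1000
promoters, B = 1000 resamples, 200 replicate null genesets and 50
planted-recovery replicates of 50 promoters each, a six-promoter
framework module, and 100 expression-linkage replicates of 5 × 23
samples. These sizes give Monte-Carlo error comfortably below the
asserted margins while keeping a full run in minutes on one CPU.

## Known limitations

- Absolute hit counts depend entirely on the threshold rule; only the
  enrichment statistics' behaviour, not any proprietary scanner's
  counts, is reproducible.
- The z cutoff is a screen, not a significance test; no multiple-testing
  correction is applied to family calls.
- Framework mining reports observed windows, not significance; a
  coverage-1.0 pair in few promoters can arise by chance for permissive
  `max_gap`.
- With five subtype points, enrichment–expression correlations are
  extremely noisy individually; only their distribution over many
  families/replicates is informative.
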