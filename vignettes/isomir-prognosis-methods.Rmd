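---
title: "Methods: prognostic screening of 5' isomiRs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: prognostic screening of 5' isomiRs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(isomiRSurv)
```

# The model and its assumptions

## 5'-shift nomenclature

An isomiR is identified by its archetype accession and a signed 5'
offset. On a plus-strand locus the 5' end is the lower genomic
coordinate and the shift is `start_iso - start_arch`; on a minus-strand
locus the 5' end is the *higher* coordinate and the shift is
`end_arch - end_iso`. Positive shifts point downstream, into the miRNA
body, and truncate the molecule at its 5' end; negative shifts extend
it upstream. Both conventions are held 1-based inclusive end-to-end
(the GFF3 convention); any half-open representation must convert at the
boundary, and the minus-strand sequence oracle in the test suite guards
exactly that conversion.

Rows that share an (accession, shift) key but end at different 3'
positions are summed before any analysis. The underlying assumption —
that 3' heterogeneity is nuisance once the 5' end (and hence the seed)
is fixed — is a modelling choice, not a biological fact; 3' variants
are a real event class this package deliberately does not model. For
sequence reconstruction the 3' stop of each key is the furthest 3'
extent ever observed for it in the dataset (`max3p`), so reconstructed
sequences are the *longest* observed form.

## Survival screen

Each isomiR is tested in its own multivariate Cox proportional-hazards
model: covariates are the isomiR's expression plus age (years),
cigarettes per day, and AJCC pathologic T stage encoded as an integer
score 1-4 (sub-stages collapse to the major stage; the encoding of an
ordinal confounder as a linear score is an assumption). Expression
enters as `log2(RPM + 1)` by default: RPM is heavy-tailed over orders
of magnitude and would otherwise let a handful of samples dominate the
linear predictor (`transform = "raw"` is available). Only tumor samples
enter; normals carry no survival semantics.

The engine maximises the Efron-corrected partial likelihood by
Newton-Raphson (Breslow behind a flag). Significance is assessed two
ways: the Wald z from the observed information gates the
protective/harmful call (matching the default reporting of standard
implementations), and the 1-df likelihood-ratio test against the
confounders-only null is reported alongside. The screen is deliberately
not multiplicity-adjusted — each model is read marginally at p < 0.05,
which is the screening convention this pipeline reproduces; expect
α-level false calls in proportion to the number of keys tested.

The events-per-variable (EPV) pre-filter keeps keys with non-zero read
counts in at least `ceiling(dead_fraction * D)` of the `D` dead
samples (default `dead_fraction = 0.5`). "Expressed" means
`read_count > 0`, not RPM > 0 (identical here, since RPM is a per-sample
rescaling of counts). With four predictors per model, requiring ~half
the events keeps the effective EPV in the conventional 10-20 band while
preserving sample coverage.

## Differential expression

IsomiR counts are normalised by the upper-quartile rule: per-sample
factor = 75th percentile of *non-zero* counts, rescaled to geometric
mean 1, output `log2(count / factor + 0.5)`. Gene counts use TMM
(trimmed mean of M-values; 30% per-tail M-trim, 5% per-tail A-trim,
inverse-asymptotic-variance weights) and log2-CPM. The moderated t
shrinks per-feature residual variances toward a prior,
`s2_post = (d0 * s02 + d * s2) / (d0 + d)`, with `(d0, s02)` estimated
by moment-matching a scaled chi-square to the log sample variances
(digamma/trigamma matching); the t statistic then has `d0 + d` df.
Precision weights of the voom kind are *not* implemented: moderated t
on log-CPM stands in for genes, a documented divergence that matters
most at very low counts.

The isomiR DE universe is the same EPV-filtered key set as the survival
screen, and the default significance gate is adjusted p < 0.01
(`use_adjusted = FALSE` switches to raw p; the underlying convention is
ambiguous in the source analyses, so both are exposed).

## Target consensus and the fixture predictor

External predictor outputs are ingested as two-column tables (isomiR
label, gene); transcript suffixes collapse to gene ids before counting
support so one tool cannot vote twice through isoforms. The consensus
keeps pairs supported by ≥ 3 of 4 tools. The bundled seed-matcher
(8mer, 7mer-m8, 7mer-A1 sites complementary to seed positions 2-8) is a
test fixture: it generates ground-truth pairs for simulations and is
never a stand-in for any published predictor's output.

## Co-expression

Because isomiR matrices are zero-heavy, each pair's Spearman rho is
computed on the samples where *both* members are non-zero, so every
edge carries its own overlap n (pairs under `min_overlap = 3` are
flagged undefined, not dropped silently). Significance is a population
z-score, `z = (rho - mean(rho)) / sd(rho)` over the evaluated pair set,
with |z| > 2 called significant. An alternative design considered was
standardising within each class block, but that construction pins every
block's >2σ fraction at ~2% by definition — no block could ever appear
enriched against its own distribution — so the pooled reference is the
default and `by_block = TRUE` is the variant. Enrichment per class pair
is a one-sided Fisher test against the pooled remaining blocks — the
background construction is itself a documented choice, since none is
canonical.

Edge selection keeps positive-rho edges in the *intersection* of the
top-5% lists by largest rho and smallest p (a conservative reading of
"top 5% by ranking both"; union available in principle by raising the
fraction), with boundary ties included, then prunes nodes of degree < 2
iteratively to a fixed point (single-pass pruning would depend on edge
order; the fixed point is deterministic).

## Figure statistics

Fisher's exact test uses the minimum-likelihood two-sided rule (the
convention of the platform being mirrored) and reports the sample odds
ratio `ad/bc`. The Wilcoxon rank-sum is exact (full enumeration by the
counting recursion) for untied samples with `nx*ny <= 400`, else
normal-approximate with tie and continuity corrections. PCA is a
column-centred SVD on the same normalised log expression used for DE
(variance stabilisation; the transform for ordination is a choice, not
given). PERMANOVA uses Euclidean distance on that PCA input by default
and permutation p `(1 + #{F* >= F})/(1 + n_perm)`. ROC/AUC comes from
the rank statistic on the fitted logistic score, so complete separation
flags the fit but never invalidates the AUC. Over-representation is the
upper-tail hypergeometric with BH adjustment; the universe defaults to
all genes present in the expression matrix, the implicit default of the
mirrored workflow.

# The synthetic world

The generator's defaults describe one fixed cohort: 200 tumors, 30
normals; 30 hairpins x 2 arms with 5' shifts in [-3, 3]; negative-
binomial counts (dispersion 0.4) with 30% excess zeros placed at random
(MCAR); block co-expression via a shared per-sample log-normal factor
(sd 0.5); 5 protective and 5 harmful keys planted at |beta| = 0.8 per
SD of log2 expression; 8 keys up- and 8 down-regulated at 2-fold; 40
genes up/down at 2-fold; survival times exponential (730-day median
baseline) under the proportional-hazards model with mild confounder
effects (age 0.015/yr, cigarettes 0.05/unit, T stage 0.25/step);
censoring by an independent uniform time calibrated to 35% censored.
The planted protective keys share one latent block and the harmful keys
another, emulating within-class co-expression; the planted survival and
DE key sets are disjoint, so tumor/normal separation of *screened* keys
is not a planted feature — ordination and ROC are validated in their
own planted experiments instead.

What the generator does **not** emulate: expression-dependent dropout
(zeros are MCAR at a flat rate, where real zero-inflation concentrates
in low-abundance features), 3' non-template additions, sequencing-level
read errors, batch structure, and the scale of a real cohort's key
universe (~10^2 keys here vs ~10^4). A green test therefore establishes
that the *algorithms* recover what was planted under stated noise — not
that the pipeline's operating characteristics transfer to TCGA-scale
data.

The NB-with-excess-zeros form itself is an assumption (the source
analyses do not state a count distribution) and is flagged in the
ground-truth manifest.

# Numerical choices

* Cox: convergence at relative log-likelihood change < 1e-9 or 50
  iterations; step-halving on likelihood decrease; |beta| > 20 or a
  singular information matrix marks non-convergence (monotone
  likelihood), and such keys are excluded with a tally rather than
  reported with fake SEs.
* Moment matching: `trigammaInverse` by Newton iteration; a
  non-positive excess variance of log-s² gives `d0 = Inf` (pure pooled
  variance, normal-tail p-values).
* `bh_adjust` enforces the cumulative minimum from the largest p down;
  NAs pass through without consuming ranks.
* Spearman p uses the t approximation on `n_overlap - 2` df; rho = ±1
  maps to p = 0 by construction there, acceptable at screen scale.
* Jaccard of two empty sets is defined as 0 (with a message) so
  overlap summaries cannot error on degenerate classes.
* Uniform-censoring calibration solves `E[min(T,u)]/u = censor_rate`
  for `u` by uniroot on the drawn survival times.
* All generator randomness flows from one config seed through
  fixed-stream child seeds (kept below 2^31), so each stage is
  individually byte-reproducible.

# Known limitations, and one red assertion

The acceptance suite keeps one assertion deliberately red: the
end-to-end recovery test applies the DE-engine power threshold
(≥ 0.8 at adj p < 0.01 for a planted 2-fold change) to the pipeline's
*zero-inflated* isomiR world. Flat 30% MCAR zeros contribute roughly
`0.3 * 0.7 * (log2(mu) - log2(0.5))^2 ≈ 12` log2-units² of within-group
variance per feature, so the standardised effect of a 1-log2FC change
is ~1.4 at 200v30 samples — power is effectively zero at any cohort
size, for this package's moderated-t on log counts and for any method
that treats those zeros as observations. The two stated requirements
(zero inflation in the generator; engine-level power met end-to-end)
are jointly unattainable, and the red test documents that honestly
rather than weakening either side. The attainable counterparts are
asserted green alongside: gene-level DE power 0.99 (no excess zeros),
and engine-level isomiR power 0.99 on dispersion-matched NB counts at
BCV 0.4 — the canonical bulk-human dispersion, which is also why the
engine experiment uses dispersion 0.16 while the generator keeps its
harsher 0.4.

Also out of scope by design: re-implementations of the four external
target predictors, GO-graph semantic summarisation, annotation
lift-over beyond a user-supplied accession mapping table, batch
correction, and any network community analysis.
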