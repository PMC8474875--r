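# isomiRSurv

Prognostic screening and functional analysis of 5′ miRNA isoforms
(isomiRs) in cancer cohorts.

## The problem

Mature miRNAs are not single sequences: imprecise Drosha/Dicer cleavage
produces isoforms whose 5′ end is shifted by a few nucleotides relative
to the canonical ("archetype") miRNA. Because the targeting seed is
nucleotides 2–8 from the 5′ end, a 5′ shift re-targets the molecule —
two isoforms of the same archetype can regulate disjoint gene programs
and even pull patient prognosis in opposite directions. `isomiRSurv`
implements the full analysis path for asking, cohort-wide, *which 5′
isomiRs matter for survival and what they do*:

1. **Nomenclature / quantification** — strand-aware 5′-shift calling
   from a miRBase-style GFF3 plus GDC-style
   `isoforms.quantification.txt` tables. An isomiR is keyed as
   `accession|k` where `k = start_iso − start_arch` on `+` loci and
   `end_arch − end_iso` on `−` loci (positive = downstream, into the
   miRNA body); 3′ variants of the same 5′ end are summed.
2. **Survival screen** — per-isomiR multivariate Cox proportional
   hazards (expression + age + cigarettes/day + T stage), Efron ties,
   Wald and likelihood-ratio tests, an events-per-variable pre-filter
   (keys expressed in ≥ 50% of dead samples), and classification by
   coefficient sign: β < 0 protective, β > 0 harmful (p < 0.05).
3. **Differential expression** — upper-quartile (isomiRs) or TMM
   (genes) normalisation and an empirical-Bayes moderated t with
   `s²_post = (d₀s₀² + d s²)/(d₀ + d)`, BH adjustment.
4. **Targets** — ingestion of external predictor pair tables and a
   ≥ 3-of-4 consensus, crossed with DE direction and survival class
   (up-isomiR/down-gene etc.); a canonical seed-matcher
   (8mer/7mer-m8/7mer-A1) ships as a synthetic fixture predictor.
5. **Co-expression** — Spearman correlation on non-zero sample
   intersections, z-scored over the evaluated pair set, per-class
   enrichment of significant correlations, and the edge selection rule
   (rho > 0, intersection of the top-5% lists by rho and by p, then
   iterative pruning of nodes with degree < 2).
6. **Figure statistics** — Fisher's exact (minimum-likelihood
   two-sided), Wilcoxon rank-sum (exact for small untied samples),
   shift-sign preference per class, PCA, PERMANOVA, logistic-regression
   ROC/AUC, and hypergeometric over-representation on GMT gene sets.

Everything is exercisable offline: a synthetic-cohort generator plants
known survival effects, fold changes, co-expression blocks and seed-match
target pairs, and writes the exact file formats the parsers consume.

## Worked example

```r
library(isomiRSurv)

# the MIMAT0000062 nomenclature examples
arch <- list(chrom = "chr1", start = 100L, end = 121L, strand = "+")
compute_shift(arch, list(chrom = "chr1", start = 98L,  end = 121L, strand = "+"))
#> [1] -2
isomir_label("MIMAT0000062", -2)
#> [1] "MIMAT0000062|-2"

# a full synthetic run: 200 tumors / 30 normals, planted effects
cfg <- pipeline_config(out_dir = "run1", seed = 1)
res <- run_all(cfg)
res$manifest$stage_counts[c("isomir_keys", "keys_after_epv",
                            "protective", "harmful")]
#> $isomir_keys   [1] 224
#> $keys_after_epv [1] 222
#> $protective    [1] 9
#> $harmful       [1] 8
res$recovery$survival_sign_accuracy   # planted beta signs recovered
#> [1] 1
res$recovery$consensus_precision      # >=3-of-4 consensus vs planted pairs
#> [1] 1
```

(Output from an actual run at seed 1; 17 keys reach p < 0.05 of which
the 10 planted effects are all sign-correct, the remainder are the
expected type-I calls at α = 0.05 across 222 models.)

Per-stage outputs (`survival_screen.tsv`, `de_isomir.tsv`,
`target_pairs.tsv`, `network_edges.tsv`, …) and a `manifest.json` with
seeds, thresholds and per-stage counts are written under `out_dir`.

## Command line

```sh
inst/cli/isomir-prognosis simulate  --out data --seed 7
inst/cli/isomir-prognosis quantify  --gff data/mirna.gff3 \
    --input-dir data/isoforms --out run/isomir
inst/cli/isomir-prognosis run-all   --out run --seed 7 \
    --alpha 0.05 --dead-fraction 0.5 --adjp 0.01 --min-support 3
```

## Vignette

`vignettes/isomir-prognosis-methods.Rmd` documents the model choices,
the synthetic world and its limits, numerical details, and known
limitations (including the one deliberately red acceptance assertion).
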