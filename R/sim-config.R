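#' Simulation configuration for the synthetic cohort generator
#'
#' Holds every knob of the synthetic world: cohort sizes, annotation sizes,
#' the range of generated 5' shifts, the negative-binomial noise model, and
#' the planted survival / fold-change / correlation effects.  Defaults
#' describe a desk-scale cohort: 200 tumors and 30 normals, 30 hairpins
#' with two mature arms each, shifts in -3..3, NB dispersion 0.4 with 30%
#' excess zeros, planted log-hazard effects of magnitude 0.8 per unit of
#' standardised log2 expression, planted 2-fold expression changes, and 35%
#' censoring.
#'
#' @param n_tumor,n_normal number of tumor / normal samples.
#' @param n_hairpins number of hairpin loci to simulate.
#' @param mature_per_hairpin mature miRNAs per hairpin (1 or 2 arms).
#' @param shift_range inclusive signed range of generated 5' shifts,
#'   length-2 integer vector.
#' @param nb_dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param zero_rate excess-zero probability per matrix entry, in `[0, 1)`.
#' @param beta_effect magnitude of the planted log-hazard coefficient per
#'   unit of standardised log2(RPM + 1) expression.
#' @param lfc planted log2 fold change for differentially expressed
#'   features (tumor vs normal).
#' @param censor_rate target fraction of censored tumor samples, `[0, 1)`.
#' @param n_protective,n_harmful number of isomiR keys planted with
#'   negative / positive log-hazard effects.
#' @param n_de number of isomiR keys planted up- and downregulated (each).
#' @param n_blocks number of co-expression blocks the isomiR keys are
#'   partitioned into.
#' @param block_sd standard deviation of the shared log-normal latent
#'   factor that induces within-block correlation.
#' @param n_genes number of genes in the simulated count matrix.
#' @param n_gene_de number of genes planted up- and downregulated (each).
#' @param utr_length length of each simulated 3' UTR in nucleotides.
#' @param targets_per_key number of true target genes planted per
#'   target-bearing isomiR key.
#' @param seed master RNG seed; every generator derives its own stream
#'   from it, so each stage is individually reproducible.
#' @return an object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_tumor = 40, n_normal = 10, seed = 7)
sim_config <- function(n_tumor = 200, n_normal = 30,
                       n_hairpins = 30, mature_per_hairpin = 2,
                       shift_range = c(-3L, 3L),
                       nb_dispersion = 0.4, zero_rate = 0.3,
                       beta_effect = 0.8, lfc = 1,
                       censor_rate = 0.35,
                       n_protective = 5, n_harmful = 5,
                       n_de = 8, n_blocks = 8, block_sd = 0.5,
                       n_genes = 400, n_gene_de = 40,
                       utr_length = 1000, targets_per_key = 3,
                       seed = 1L) {
  cfg <- list(
    n_tumor = as.integer(n_tumor), n_normal = as.integer(n_normal),
    n_hairpins = as.integer(n_hairpins),
    mature_per_hairpin = as.integer(mature_per_hairpin),
    shift_range = as.integer(shift_range),
    nb_dispersion = nb_dispersion, zero_rate = zero_rate,
    beta_effect = beta_effect, lfc = lfc, censor_rate = censor_rate,
    n_protective = as.integer(n_protective),
    n_harmful = as.integer(n_harmful),
    n_de = as.integer(n_de), n_blocks = as.integer(n_blocks),
    block_sd = block_sd,
    n_genes = as.integer(n_genes), n_gene_de = as.integer(n_gene_de),
    utr_length = as.integer(utr_length),
    targets_per_key = as.integer(targets_per_key),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' @noRd
validate_sim_config <- function(cfg) {
  pos <- c("n_tumor", "n_normal", "n_hairpins", "mature_per_hairpin",
           "n_blocks", "n_genes", "utr_length")
  for (f in pos)
    if (length(cfg[[f]]) != 1L || is.na(cfg[[f]]) || cfg[[f]] < 1L)
      stopf("sim_config: '%s' must be a positive count", f)
  if (cfg$mature_per_hairpin > 2L)
    stopf("sim_config: at most two mature arms per hairpin are supported")
  if (length(cfg$shift_range) != 2L || cfg$shift_range[1] > cfg$shift_range[2])
    stopf("sim_config: shift_range must be an ordered length-2 integer range")
  if (cfg$zero_rate < 0 || cfg$zero_rate >= 1)
    stopf("sim_config: zero_rate must lie in [0, 1)")
  if (cfg$censor_rate < 0 || cfg$censor_rate >= 1)
    stopf("sim_config: censor_rate must lie in [0, 1)")
  if (cfg$nb_dispersion < 0)
    stopf("sim_config: nb_dispersion must be non-negative")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_tumor, "tumor /", x$n_normal, "normal samples;",
      x$n_hairpins, "hairpins x", x$mature_per_hairpin, "arms; shifts",
      paste0("[", x$shift_range[1], ",", x$shift_range[2], "]"),
      "; seed", x$seed, "\n")
  invisible(x)
}
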