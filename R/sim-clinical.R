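## Synthetic clinical table: survival times from a proportional-hazards
## model with an exponential baseline, planted isomiR effects and
## confounder effects, censored by an independent uniform time.

#' Generate a synthetic clinical table under proportional hazards
#'
#' Draws one survival record per tumor sample.  The log hazard is the sum
#' of the planted per-key effects (`truth$betas`, applied to standardised
#' log2(RPM + 1) expression) plus mild confounder effects of age,
#' cigarettes per day and T stage.  The baseline hazard is exponential
#' with a 730-day median; censoring is by an independent Uniform(0, u)
#' time whose upper bound u is calibrated so the expected censored
#' fraction equals `config$censor_rate`.
#'
#' @param config a [sim_config()].
#' @param expr a `sim_expression` object from [generate_isoform_files()].
#' @param truth ground-truth list carrying `betas` (named by isomiR
#'   label); defaults to `expr$truth`.
#' @return data frame with columns `sample`, `time` (days), `event`
#'   (1 dead / 0 censored), `vital_status`, `age_at_index`,
#'   `cigarettes_per_day`, `ajcc_pathologic_t` — tumor samples only.
#' @export
generate_clinical <- function(config, expr, truth = expr$truth) {
  validate_sim_config(config)
  with_seed(child_seed(config$seed, 3L), {
    tumor <- expr$samples$sample[expr$samples$type == "tumor"]
    n <- length(tumor)
    cnt <- expr$counts[, tumor, drop = FALSE]
    tot <- colSums(cnt)
    rpm <- sweep(cnt, 2, pmax(tot, 1), "/") * 1e6
    x <- log2(rpm + 1)

    age <- pmin(88L, pmax(38L, round(rnorm(n, 67, 9))))
    cig <- round(rgamma(n, shape = 2, scale = 1.5), 1)
    stages <- c("T1", "T1a", "T1b", "T2", "T2a", "T2b", "T3", "T4")
    stage_p <- c(0.08, 0.05, 0.05, 0.25, 0.20, 0.07, 0.20, 0.10)
    t_stage <- sample(stages, n, replace = TRUE, prob = stage_p)
    t_num <- as.integer(substr(t_stage, 2, 2))

    lp <- 0.015 * (age - 67) + 0.05 * (cig - 3) + 0.25 * (t_num - 2)
    for (key in names(truth$betas)) {
      if (!key %in% rownames(x)) next
      v <- x[key, ]
      s <- sd(v)
      if (s > 0) lp <- lp + truth$betas[[key]] * (v - mean(v)) / s
    }

    lambda0 <- log(2) / 730
    tt <- rexp(n, rate = lambda0 * exp(lp))
    if (config$censor_rate <= 0) {
      time <- tt
      event <- rep(1L, n)
    } else {
      # calibrate Uniform(0, u) censoring to the target censored fraction:
      # P(C < T) = E[min(T, u)] / u for C ~ U(0, u)
      f <- function(u) mean(pmin(tt, u)) / u - config$censor_rate
      u <- tryCatch(
        stats::uniroot(f, c(1e-6, max(tt) * 100))$root,
        error = function(e) max(tt))
      cc <- runif(n, 0, u)
      event <- as.integer(tt <= cc)
      time <- pmin(tt, cc)
    }
    data.frame(
      sample = tumor,
      time = pmax(1, round(time, 1)),
      event = event,
      vital_status = ifelse(event == 1L, "Dead", "Alive"),
      age_at_index = age,
      cigarettes_per_day = cig,
      ajcc_pathologic_t = t_stage,
      stringsAsFactors = FALSE
    )
  })
}
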