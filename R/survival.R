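## Per-isomiR multivariate Cox proportional-hazards screening.
##
## The partial-likelihood engine is implemented here (Newton-Raphson on
## the Efron- or Breslow-corrected log partial likelihood, step-halving,
## observed-information standard errors) so that the fitting rule under
## test is the package's own; the survival package serves only as an
## independent oracle in the test suite.

#' Encode AJCC pathologic T stage as an integer score
#'
#' `T1`..`T4` map to 1..4; sub-stages (`T1a`, `T2b`, ...) collapse to the
#' major stage.  Unparseable values become `NA`.
#'
#' @param x character vector of stage labels.
#' @return integer vector.
#' @export
encode_t_stage <- function(x) {
  m <- regmatches(x, regexec("^T([1-4])", as.character(x)))
  vapply(m, function(p) if (length(p) == 2L) as.integer(p[2]) else
    NA_integer_, integer(1))
}

## Efron/Breslow log partial likelihood, gradient and observed information
## at `beta` for design X (n x p), right-censored (time, event).
#' @noRd
cox_lgh <- function(beta, X, time, event, ties = "efron") {
  n <- nrow(X); p <- ncol(X)
  eta <- drop(X %*% beta)
  w <- exp(eta)
  o <- order(time, decreasing = TRUE)   # risk sets become cumulative sums
  ts <- time[o]; ev <- event[o]
  Xs <- X[o, , drop = FALSE]; ws <- w[o]; etas <- eta[o]
  WX <- Xs * ws
  ut <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  WXX <- WX[, ut[, 1], drop = FALSE] * Xs[, ut[, 2], drop = FALSE]
  cS <- cumsum(ws)
  cA <- apply(WX, 2, cumsum)
  cB <- apply(WXX, 2, cumsum)
  if (n == 1L) { cA <- matrix(cA, 1L); cB <- matrix(cB, 1L) }
  unpack <- function(v) {
    M <- matrix(0, p, p)
    M[upper.tri(M, diag = TRUE)] <- v
    M[lower.tri(M)] <- t(M)[lower.tri(M)]
    M
  }
  ll <- 0
  g <- numeric(p)
  I <- matrix(0, p, p)
  for (t_k in unique(ts[ev == 1])) {
    ridx <- sum(ts >= t_k)
    S <- cS[ridx]
    A <- cA[ridx, ]
    B <- unpack(cB[ridx, ])
    D <- which(ev == 1 & ts == t_k)
    d <- length(D)
    s <- sum(ws[D])
    a <- colSums(WX[D, , drop = FALSE])
    b <- unpack(colSums(WXX[D, , drop = FALSE]))
    ll <- ll + sum(etas[D])
    g <- g + colSums(Xs[D, , drop = FALSE])
    frac <- if (ties == "efron") (seq_len(d) - 1) / d else numeric(d)
    for (l in seq_len(d)) {
      den <- S - frac[l] * s
      num <- A - frac[l] * a
      num2 <- B - frac[l] * b
      ll <- ll - log(den)
      g <- g - num / den
      I <- I + num2 / den - tcrossprod(num / den)
    }
  }
  list(loglik = ll, gradient = g, information = I)
}

## Newton-Raphson maximiser of the Cox partial likelihood.
## Convergence: relative log-likelihood change < tol or max_iter;
## step-halving when a step decreases the likelihood.
#' @noRd
cox_engine <- function(X, time, event, ties = "efron",
                       tol = 1e-9, max_iter = 50L) {
  p <- ncol(X)
  beta <- numeric(p)
  cur <- cox_lgh(beta, X, time, event, ties)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    step <- tryCatch(solve(cur$information, cur$gradient),
                     error = function(e) NULL)
    if (is.null(step))
      return(list(beta = beta, se = rep(NA_real_, p), loglik = cur$loglik,
                  converged = FALSE, iter = it, flat = TRUE,
                  grad_norm = sqrt(sum(cur$gradient^2))))
    new_beta <- beta + step
    new <- cox_lgh(new_beta, X, time, event, ties)
    halves <- 0L
    while (new$loglik < cur$loglik && halves < 20L) {
      step <- step / 2
      new_beta <- beta + step
      new <- cox_lgh(new_beta, X, time, event, ties)
      halves <- halves + 1L
    }
    done <- abs(new$loglik - cur$loglik) <
      tol * (abs(cur$loglik) + tol)
    beta <- new_beta
    cur <- new
    if (done) { converged <- TRUE; break }
  }
  # monotone likelihood (perfect separation of the event order) shows up
  # as a drifting coefficient with vanishing curvature
  if (any(abs(beta) > 20)) converged <- FALSE
  se <- tryCatch(sqrt(diag(solve(cur$information))),
                 error = function(e) rep(NA_real_, p))
  list(beta = beta, se = se, loglik = cur$loglik, converged = converged,
       iter = it, flat = FALSE, grad_norm = sqrt(sum(cur$gradient^2)))
}

#' Fit a multivariate Cox model for one isomiR
#'
#' Covariates are the (transformed) expression of the tested isomiR plus
#' the confounding clinical factors (age, cigarettes per day, integer-
#' coded T stage).  The significance of the expression coefficient is
#' assessed by the Wald test (z = beta/se from the observed information)
#' and by a likelihood-ratio test against the confounders-only null model
#' (1 df).  Samples with any missing covariate are dropped (complete
#' case).
#'
#' @param expr named numeric vector of expression values (RPM unless
#'   `transform = "raw"` combined with counts), names are sample ids.
#' @param clinical clinical data frame as from [generate_clinical()]
#'   (columns `sample`, `time`, `event`, `age_at_index`,
#'   `cigarettes_per_day`, `ajcc_pathologic_t`).
#' @param covariates character vector of confounder columns to include;
#'   `ajcc_pathologic_t` is integer-encoded via [encode_t_stage()].
#'   `NULL` fits expression alone.
#' @param transform `"log2p1"` (default, log2(x + 1)) or `"raw"`.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return list of class `cox_result`: `beta`, `se`, `hr`, `wald_z`,
#'   `wald_p`, `lrt_p`, `loglik`, `n_used`, `n_events`, `converged`.
#' @export
fit_cox <- function(expr, clinical,
                    covariates = c("age_at_index", "cigarettes_per_day",
                                   "ajcc_pathologic_t"),
                    transform = c("log2p1", "raw"),
                    ties = c("efron", "breslow")) {
  transform <- match.arg(transform)
  ties <- match.arg(ties)
  i <- match(clinical$sample, names(expr))
  if (all(is.na(i)))
    stopf("fit_cox: no clinical samples found in the expression vector")
  x <- unname(expr[i])
  if (transform == "log2p1") x <- log2(x + 1)
  Z <- NULL
  if (!is.null(covariates) && length(covariates)) {
    Z <- sapply(covariates, function(cv) {
      v <- clinical[[cv]]
      if (cv == "ajcc_pathologic_t") as.numeric(encode_t_stage(v))
      else as.numeric(v)
    })
    Z <- matrix(Z, nrow = nrow(clinical))
  }
  X <- cbind(expr = x, Z)
  ok <- complete.cases(X) & !is.na(clinical$time) & !is.na(clinical$event) &
    clinical$time > 0
  X <- X[ok, , drop = FALSE]
  time <- clinical$time[ok]
  event <- clinical$event[ok]
  if (sum(event) < 2L)
    stopf("fit_cox: fewer than 2 events after complete-case filtering")
  if (sd(X[, 1]) == 0)
    stopf("fit_cox: expression is constant across the used samples")

  fit <- cox_engine(X, time, event, ties)
  if (ncol(X) > 1L) {
    null_fit <- cox_engine(X[, -1, drop = FALSE], time, event, ties)
    ll0 <- null_fit$loglik
  } else {
    ll0 <- cox_lgh(0, X[, 1, drop = FALSE], time, event, ties)$loglik
  }
  beta <- fit$beta[1]
  se <- fit$se[1]
  z <- beta / se
  structure(list(
    beta = beta, se = se, hr = exp(beta),
    wald_z = z, wald_p = 2 * pnorm(-abs(z)),
    lrt = 2 * (fit$loglik - ll0),
    lrt_p = pchisq(2 * (fit$loglik - ll0), df = 1, lower.tail = FALSE),
    loglik = fit$loglik, n_used = nrow(X), n_events = sum(event),
    converged = fit$converged, grad_norm = fit$grad_norm,
    coef_all = fit$beta
  ), class = "cox_result")
}

#' Events-per-variable expression filter
#'
#' Keeps isomiR keys with non-zero read counts in at least
#' `ceiling(dead_fraction * D)` of the D dead (event = 1) tumor samples —
#' the pre-filter that bounds the number of predictors a Cox model is
#' asked to support per observed event.  Keys never expressed anywhere
#' are always dropped.
#'
#' @param mat an `isomir_matrix`.
#' @param clinical clinical table (tumor samples, `event` column).
#' @param dead_fraction required dead-sample coverage fraction, default
#'   0.5.
#' @return character vector of kept key labels, with a `coverage`
#'   attribute (data frame of per-key dead-sample coverage).
#' @export
epv_filter <- function(mat, clinical, dead_fraction = 0.5) {
  stopifnot(dead_fraction >= 0, dead_fraction <= 1)
  dead <- clinical$sample[clinical$event == 1]
  dead <- intersect(dead, colnames(mat$counts))
  if (length(dead) == 0L) stopf("epv_filter: no dead samples")
  cov_dead <- rowSums(mat$counts[, dead, drop = FALSE] > 0)
  expressed <- rowSums(mat$counts > 0) > 0
  thr <- ceiling(dead_fraction * length(dead))
  keep <- cov_dead >= thr & expressed
  out <- rownames(mat$counts)[keep]
  attr(out, "coverage") <- data.frame(
    label = rownames(mat$counts),
    dead_samples = as.integer(cov_dead),
    dead_fraction = cov_dead / length(dead),
    kept = keep, row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "threshold") <- thr
  out
}

#' Screen every isomiR for survival influence
#'
#' Runs [fit_cox()] per key (tumor samples only) and classifies each
#' significant coefficient by sign: negative = protective, positive =
#' harmful.
#'
#' @param mat an `isomir_matrix`.
#' @param clinical clinical table.
#' @param keys keys to test (default: all rows of `mat`; typically the
#'   [epv_filter()] survivors).
#' @param alpha significance level for the class call, default 0.05 (the
#'   screen is deliberately un-adjusted: each model is interpreted
#'   marginally).
#' @param gate which p-value gates the call: `"wald"` (default) or
#'   `"lrt"`.
#' @param ... passed to [fit_cox()].
#' @return data frame with one row per tested key: `label`, `beta`, `hr`,
#'   `se`, `wald_z`, `wald_p`, `lrt_p`, `n_used`, `n_events`, `class`.
#'   Non-converged or degenerate fits are excluded and tallied in the
#'   `excluded` attribute.
#' @export
cox_screen <- function(mat, clinical, keys = rownames(mat$rpm),
                       alpha = 0.05, gate = c("wald", "lrt"), ...) {
  gate <- match.arg(gate)
  tumor <- mat$samples$sample[mat$samples$type == "tumor"]
  cl <- clinical[clinical$sample %in% tumor, , drop = FALSE]
  rows <- vector("list", length(keys))
  excluded <- character(0)
  for (i in seq_along(keys)) {
    k <- keys[i]
    res <- tryCatch(fit_cox(mat$rpm[k, ], cl, ...), error = function(e) e)
    if (inherits(res, "error") || !res$converged || is.na(res$se)) {
      excluded <- c(excluded, k)
      next
    }
    rows[[i]] <- data.frame(
      label = k, beta = res$beta, hr = res$hr, se = res$se,
      wald_z = res$wald_z, wald_p = res$wald_p, lrt_p = res$lrt_p,
      n_used = res$n_used, n_events = res$n_events,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stopf("cox_screen: no key could be fitted")
  out <- classify_survival(out, alpha = alpha, gate = gate)
  attr(out, "excluded") <- excluded
  out
}

#' Classify screened isomiRs as protective or harmful
#'
#' `protective` iff beta < 0 and p < alpha; `harmful` iff beta > 0 and
#' p < alpha; otherwise `nonsignificant`.
#'
#' @param results data frame from [cox_screen()] (columns `beta`,
#'   `wald_p`, `lrt_p`).
#' @param alpha significance level, default 0.05.
#' @param gate `"wald"` or `"lrt"` p-value column to gate on.
#' @return `results` with a `class` column; a `summary` attribute counts
#'   protective/harmful/nonsignificant and archetype vs isomiR members.
#' @export
classify_survival <- function(results, alpha = 0.05,
                              gate = c("wald", "lrt")) {
  gate <- match.arg(gate)
  stopifnot(alpha > 0, alpha < 1)
  p <- if (gate == "wald") results$wald_p else results$lrt_p
  cls <- ifelse(p < alpha & results$beta < 0, "protective",
                ifelse(p < alpha & results$beta > 0, "harmful",
                       "nonsignificant"))
  results$class <- cls
  shift <- parse_isomir_label(results$label)$shift
  attr(results, "summary") <- data.frame(
    class = c("protective", "harmful", "nonsignificant"),
    n = c(sum(cls == "protective"), sum(cls == "harmful"),
          sum(cls == "nonsignificant")),
    n_archetype = c(sum(cls == "protective" & shift == 0),
                    sum(cls == "harmful" & shift == 0),
                    sum(cls == "nonsignificant" & shift == 0)),
    n_isomir = c(sum(cls == "protective" & shift != 0),
                 sum(cls == "harmful" & shift != 0),
                 sum(cls == "nonsignificant" & shift != 0)),
    stringsAsFactors = FALSE)
  results
}
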