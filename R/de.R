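## Differential expression: count normalisation (upper quartile for
## isomiRs, TMM for genes) and an empirical-Bayes moderated t-test.  The
## moderation machinery (scaled-chi-square moment matching of the
## variance distribution) is implemented here; limma/edgeR are used only
## as oracles in the tests.

#' Upper-quartile normalised log2 expression
#'
#' Per-sample scale factor = 75th percentile of that sample's non-zero
#' counts, rescaled so the factors have geometric mean 1; the output is
#' `log2(count / factor + 0.5)` (the 0.5 offset follows the log-CPM
#' convention).  Doubling every count of a sample leaves its normalised
#' profile unchanged.
#'
#' @param counts features x samples numeric matrix.
#' @return matrix of normalised log2 expression, with the scale factors
#'   in attribute `factors`.
#' @export
normalize_uq <- function(counts) {
  stopifnot(is.matrix(counts), ncol(counts) >= 2L)
  uq <- apply(counts, 2, function(v) {
    nz <- v[v > 0]
    if (length(nz) == 0L) return(NA_real_)
    quantile(nz, 0.75, names = FALSE)
  })
  if (anyNA(uq)) {
    bad <- which(is.na(uq))[1]
    nm <- if (is.null(colnames(counts))) as.character(bad)
    else colnames(counts)[bad]
    stopf("normalize_uq: sample '%s' has no non-zero counts", nm)
  }
  f <- uq / geomean(uq)
  out <- log2(sweep(counts, 2, f, "/") + 0.5)
  attr(out, "factors") <- f
  out
}

#' Trimmed-mean-of-M-values (TMM) scale factors
#'
#' For each sample against the reference (by default the sample whose
#' upper quartile of the count proportions is closest to the mean upper
#' quartile), the factor is 2 to the precision-weighted mean of the
#' log-ratios M, after trimming the most extreme 30% of M values and 5%
#' of A values (both tails, rank-based); features zero in either sample
#' are excluded.  Factors are rescaled to geometric mean 1.
#'
#' @param counts features x samples matrix.
#' @param ref reference sample (index or name); `NULL` for the automatic
#'   choice.
#' @param logratio_trim,abundance_trim per-tail trim fractions for M
#'   and A.
#' @return numeric vector of scale factors (one per sample), attribute
#'   `ref` records the reference used.
#' @export
normalize_tmm <- function(counts, ref = NULL,
                          logratio_trim = 0.3, abundance_trim = 0.05) {
  stopifnot(is.matrix(counts), ncol(counts) >= 2L)
  N <- colSums(counts)
  if (any(N == 0)) stopf("normalize_tmm: all-zero sample")
  if (is.null(ref)) {
    f75 <- apply(sweep(counts, 2, N, "/"), 2, quantile, probs = 0.75,
                 names = FALSE)
    ref <- which.min(abs(f75 - mean(f75)))
  } else if (is.character(ref)) ref <- match(ref, colnames(counts))
  r <- counts[, ref]
  Nr <- N[ref]
  f <- vapply(seq_len(ncol(counts)), function(j) {
    if (j == ref) return(1)
    o <- counts[, j]
    use <- o > 0 & r > 0
    if (!any(use))
      stopf("normalize_tmm: no overlapping non-zero features with reference")
    oo <- o[use]; rr <- r[use]
    M <- log2((oo / N[j]) / (rr / Nr))
    A <- 0.5 * log2((oo / N[j]) * (rr / Nr))
    w <- (N[j] - oo) / (N[j] * oo) + (Nr - rr) / (Nr * rr)
    n <- length(M)
    # trim fractions are per tail (the edgeR convention: 0.3 removes the
    # most extreme 30% of M values from each side)
    loM <- floor(n * logratio_trim) + 1
    hiM <- n + 1 - loM
    loA <- floor(n * abundance_trim) + 1
    hiA <- n + 1 - loA
    rM <- rank(M); rA <- rank(A)
    keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    if (!any(keep)) return(1)
    2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
  }, numeric(1))
  f <- f / geomean(f)
  names(f) <- colnames(counts)
  attr(f, "ref") <- ref
  f
}

#' TMM-normalised log2-CPM
#'
#' Convenience wrapper: `log2((count + 0.5) / (lib.size * factor + 1) * 1e6)`.
#'
#' @inheritParams normalize_tmm
#' @return normalised log2-CPM matrix with `factors` attribute.
#' @export
normalize_tmm_logcpm <- function(counts, ref = NULL) {
  f <- normalize_tmm(counts, ref)
  eff <- colSums(counts) * f
  out <- log2(sweep(counts + 0.5, 2, eff + 1, "/") * 1e6)
  attr(out, "factors") <- f
  out
}

## Inverse of the trigamma function by Newton iteration on 1/trigamma
## (monotone, near-linear), as used for moment matching below.
#' @noRd
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif) / x < 1e-8) break
  }
  x
}

## Moment-match a scaled F / scaled-chi-square prior to observed sample
## variances s2 on d df: returns prior df d0 and prior variance s0^2.
## Works on log variances via digamma/trigamma moments.
#' @noRd
fit_variance_prior <- function(s2, d) {
  ok <- is.finite(s2) & s2 > 0
  z <- log(s2[ok])
  e <- z - digamma(d / 2) + log(d / 2)
  ev <- var(e) - trigamma(d / 2)
  if (is.na(ev) || ev <= 0)
    return(list(d0 = Inf, s02 = exp(mean(e))))
  d0 <- 2 * trigamma_inverse(ev)
  s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s02 = s02)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: `p_(i) * n / i` with a cumulative minimum from
#' the largest p downwards, capped at 1.
#'
#' @param p numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stopf("bh_adjust: p-values outside [0, 1]")
  ok <- which(!is.na(p))
  n <- length(ok)
  out <- rep(NA_real_, length(p))
  if (n == 0L) return(out)
  o <- order(p[ok], decreasing = TRUE)
  ro <- ok[o]
  out[ro] <- pmin(1, cummin(n / (n:1) * p[ro]))
  out
}

#' Empirical-Bayes moderated two-group t-test
#'
#' Per feature, an ordinary least-squares two-group contrast on the
#' supplied log-expression grid; the residual variances are shrunk toward
#' a common prior by `s2_post = (d0 * s02 + d * s2) / (d0 + d)`, where the
#' prior df `d0` and prior variance `s02` are estimated by moment-matching
#' a scaled-chi-square distribution to the observed variances.  The
#' moderated t uses `s2_post` on `d0 + d` degrees of freedom; p-values are
#' BH-adjusted.
#'
#' @param x features x samples log-expression matrix.
#' @param group two-level factor/character vector along the columns; the
#'   log2 fold change is `mean(level2) - mean(level1)` of the sorted
#'   unique levels, so with levels `normal`/`tumor` positive means up in
#'   tumor.
#' @param prior_df override for `d0` (`0` forces the ordinary t, `Inf`
#'   full shrinkage to the pooled prior variance); `NULL` (default)
#'   estimates it.
#' @param sig adjusted-p threshold for the `direction` call, default 0.01.
#' @param use_adjusted gate the `direction` call on adjusted (default) or
#'   raw p-values.
#' @return data frame: `feature`, `log2fc`, `t_mod`, `df_total`, `p`,
#'   `adj_p`, `direction` (`up`/`down`/`ns`); attributes `d0`, `s02`.
#' @export
moderated_t <- function(x, group, prior_df = NULL, sig = 0.01,
                        use_adjusted = TRUE) {
  stopifnot(is.matrix(x), ncol(x) == length(group))
  lev <- sort(unique(as.character(group)))
  if (length(lev) != 2L) stopf("moderated_t: need exactly two groups")
  i1 <- which(group == lev[1]); i2 <- which(group == lev[2])
  n1 <- length(i1); n2 <- length(i2)
  if (n1 < 2L || n2 < 2L)
    stopf("moderated_t: each group needs at least 2 samples")
  m1 <- rowMeans(x[, i1, drop = FALSE])
  m2 <- rowMeans(x[, i2, drop = FALSE])
  lfc <- m2 - m1
  d <- n1 + n2 - 2L
  rss <- rowSums((x[, i1, drop = FALSE] - m1)^2) +
    rowSums((x[, i2, drop = FALSE] - m2)^2)
  s2 <- rss / d
  su <- sqrt(1 / n1 + 1 / n2)

  if (is.null(prior_df)) {
    pr <- fit_variance_prior(s2, d)
  } else if (prior_df == 0) {
    pr <- list(d0 = 0, s02 = 0)
  } else if (is.infinite(prior_df)) {
    pr <- list(d0 = Inf, s02 = fit_variance_prior(s2, d)$s02)
  } else {
    pr <- list(d0 = prior_df, s02 = fit_variance_prior(s2, d)$s02)
  }
  if (is.infinite(pr$d0)) {
    s2_post <- rep(pr$s02, length(s2))
    df_total <- Inf
  } else {
    s2_post <- (pr$d0 * pr$s02 + d * s2) / (pr$d0 + d)
    df_total <- pr$d0 + d
  }
  t_mod <- lfc / (sqrt(s2_post) * su)
  p <- if (is.infinite(df_total)) 2 * pnorm(-abs(t_mod))
  else 2 * pt(-abs(t_mod), df = df_total)
  adj <- bh_adjust(p)
  gate <- if (use_adjusted) adj else p
  direction <- ifelse(gate < sig & lfc > 0, "up",
                      ifelse(gate < sig & lfc < 0, "down", "ns"))
  out <- data.frame(feature = rownames(x), log2fc = lfc, t_mod = t_mod,
                    df_total = df_total, p = p, adj_p = adj,
                    direction = direction, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "d0") <- pr$d0
  attr(out, "s02") <- pr$s02
  attr(out, "groups") <- lev
  out
}
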