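## Shared statistics behind the results figures.  Exact tests are
## computed from hypergeometric / rank enumerations implemented here;
## base-R tests and vegan act only as oracles in the test suite.

#' Fisher's exact test for a 2x2 table
#'
#' Conditions on both margins: the first cell follows a hypergeometric
#' distribution.  The two-sided p sums the point masses no larger than
#' the observed one (minimum-likelihood rule); one-sided tails are
#' cumulative sums.  The reported odds ratio is the sample odds ratio
#' `ad / bc` (not the conditional MLE).
#'
#' @param tab 2x2 matrix (or length-4 vector, row-major) of non-negative
#'   counts.
#' @param side `"two.sided"` (default), `"greater"` or `"less"` — tails
#'   for the first cell.
#' @return list: `p`, `odds_ratio`.
#' @export
#' @examples
#' fisher_exact(matrix(c(75, 43, 8, 17), 2, byrow = TRUE))
fisher_exact <- function(tab, side = c("two.sided", "greater", "less")) {
  side <- match.arg(side)
  if (!is.matrix(tab)) tab <- matrix(tab, 2, 2, byrow = TRUE)
  if (any(tab < 0) || any(tab != round(tab)))
    stopf("fisher_exact: cells must be non-negative integers")
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  if (sum(tab) == 0) stopf("fisher_exact: empty table")
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  xs <- lo:hi
  dens <- dhyper(xs, m, n, k)
  obs <- dhyper(a, m, n, k)
  p <- switch(side,
    two.sided = sum(dens[dens <= obs * (1 + 1e-7)]),
    greater = sum(dens[xs >= a]),
    less = sum(dens[xs <= a]))
  or <- (a * d) / (b * c)
  list(p = min(p, 1), odds_ratio = or)
}

## Exact null distribution of the Mann-Whitney U statistic by the
## standard counting recursion c(u; m, n) = c(u - n; m - 1, n) +
## c(u; m, n - 1) (no ties).  Returns the probability mass over
## U = 0..nx*ny.
#' @noRd
mwu_exact_pmf <- function(nx, ny) {
  maxu <- nx * ny
  arr <- array(0, c(nx + 1L, ny + 1L, maxu + 1L))
  arr[1L, , 1L] <- 1
  arr[, 1L, 1L] <- 1
  for (m in seq_len(nx)) for (n in seq_len(ny)) {
    for (k in 0:(m * n)) {
      v <- arr[m + 1L, n, k + 1L]
      if (k - n >= 0L) v <- v + arr[m, n + 1L, k - n + 1L]
      arr[m + 1L, n + 1L, k + 1L] <- v
    }
  }
  cnt <- arr[nx + 1L, ny + 1L, ]
  cnt / sum(cnt)
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Midranks for ties.  Without ties and with `nx * ny <= 400` the exact
#' two-sided p is computed by full enumeration of the U distribution;
#' otherwise the normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param x,y numeric vectors (non-empty).
#' @param side `"two.sided"` (default), `"greater"` or `"less"` (tail
#'   for x tending larger).
#' @return list: `statistic` (U for x), `p`, `exact` flag.
#' @export
wilcoxon_ranksum <- function(x, y, side = c("two.sided", "greater",
                                            "less")) {
  side <- match.arg(side)
  if (length(x) == 0L || length(y) == 0L)
    stopf("wilcoxon_ranksum: empty input")
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  has_ties <- anyDuplicated(c(x, y)) > 0
  if (!has_ties && nx * ny <= 400) {
    pmf <- mwu_exact_pmf(nx, ny)
    ui <- as.integer(u)
    plo <- sum(pmf[seq_len(ui + 1L)])
    phi <- sum(pmf[(ui + 1L):length(pmf)])
    p <- switch(side,
      two.sided = min(1, 2 * min(plo, phi)),
      greater = phi, less = plo)
    return(list(statistic = u, p = p, exact = TRUE))
  }
  N <- nx + ny
  tie_tab <- table(r)
  sigma2 <- nx * ny / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) /
                              (N * (N - 1)))
  mu <- nx * ny / 2
  zc <- function(u_adj) (u_adj - mu) / sqrt(sigma2)
  p <- switch(side,
    two.sided = min(1, 2 * pnorm(-max(0, (abs(u - mu) - 0.5)) /
                                   sqrt(sigma2))),
    greater = pnorm(zc(u - 0.5), lower.tail = FALSE),
    less = pnorm(zc(u + 0.5)))
  list(statistic = u, p = p, exact = FALSE)
}

#' Shift-sign preference per survival class
#'
#' Archetypes (shift 0) are excluded; for each survival class the
#' positive/negative shift split is tested against the split of all
#' remaining (non-zero-shift) isomiRs by Fisher's exact test.
#'
#' @param labels isomiR labels.
#' @param classes survival class per label.
#' @param side tail passed to [fisher_exact()] (first cell = positive
#'   shifts in the class), default two-sided.
#' @return data frame per class: `n_pos`, `n_neg`, `frac_pos`,
#'   `fisher_p`.
#' @export
shift_preference <- function(labels, classes,
                             side = c("two.sided", "greater", "less")) {
  side <- match.arg(side)
  shift <- parse_isomir_label(labels)$shift
  keep <- shift != 0L
  shift <- shift[keep]; classes <- classes[keep]
  pos <- shift > 0L
  out <- do.call(rbind, lapply(sort(unique(classes)), function(cl) {
    a <- classes == cl
    tab <- matrix(c(sum(pos & a), sum(!pos & a),
                    sum(pos & !a), sum(!pos & !a)), 2, byrow = TRUE)
    data.frame(class = cl, n_pos = tab[1, 1], n_neg = tab[1, 2],
               frac_pos = tab[1, 1] / sum(tab[1, ]),
               fisher_p = if (sum(a) == length(a)) NA_real_
               else fisher_exact(tab, side)$p,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Principal component analysis of an expression grid
#'
#' Samples are the observations.  Features are centred; the singular
#' value decomposition gives the sample scores and per-component
#' explained-variance fractions.
#'
#' @param x features x samples numeric matrix.
#' @param k number of components to return (default all).
#' @return list: `scores` (samples x k), `var_explained` (length k),
#'   `rotation`.
#' @export
pca_expression <- function(x, k = NULL) {
  stopifnot(is.matrix(x), nrow(x) >= 2L, ncol(x) >= 2L)
  m <- t(x)                       # samples x features
  m <- sweep(m, 2, colMeans(m))
  if (all(abs(m) < .Machine$double.eps * 100))
    stopf("pca_expression: constant grid")
  sv <- svd(m)
  kk <- if (is.null(k)) length(sv$d) else min(k, length(sv$d))
  scores <- sv$u[, seq_len(kk), drop = FALSE] %*%
    diag(sv$d[seq_len(kk)], kk, kk)
  rownames(scores) <- colnames(x)
  colnames(scores) <- paste0("PC", seq_len(kk))
  list(scores = scores,
       var_explained = (sv$d^2 / sum(sv$d^2))[seq_len(kk)],
       rotation = sv$v[, seq_len(kk), drop = FALSE])
}

#' Permutational multivariate analysis of variance (one factor)
#'
#' Pseudo-F from among/within sums of squared distances; the p-value is
#' `(1 + #{F* >= F}) / (1 + n_perm)` over random label permutations.
#'
#' @param d distance matrix (square symmetric matrix or `dist`).
#' @param labels group label per observation (>= 2 groups).
#' @param n_perm number of permutations, default 999.
#' @param seed RNG seed for the permutations.
#' @return list: `F`, `p`, `df` (c(among, within)).
#' @export
permanova <- function(d, labels, n_perm = 999L, seed = 1L) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  stopifnot(ncol(dm) == n, length(labels) == n)
  labels <- as.character(labels)
  a <- length(unique(labels))
  if (a < 2L) stopf("permanova: need at least two groups")
  if (min(table(labels)) < 2L)
    warnf("permanova: a group has a single member")
  d2 <- dm^2
  sst <- sum(d2[upper.tri(d2)]) / n
  fstat <- function(lab) {
    ssw <- 0
    for (g in unique(lab)) {
      i <- which(lab == g)
      if (length(i) > 1L)
        ssw <- ssw + sum(d2[i, i][upper.tri(d2[i, i])]) / length(i)
    }
    ssa <- sst - ssw
    (ssa / (a - 1)) / (ssw / (n - a))
  }
  f_obs <- fstat(labels)
  with_seed(seed, {
    f_perm <- vapply(seq_len(n_perm), function(i) fstat(sample(labels)),
                     numeric(1))
  })
  list(F = f_obs, p = (1 + sum(f_perm >= f_obs)) / (1 + n_perm),
       df = c(among = a - 1, within = n - a))
}

#' Logistic regression scores and ROC/AUC
#'
#' Fits a logistic model by iteratively reweighted least squares on the
#' supplied score columns (e.g. PC1 and PC2) and computes the ROC and
#' its AUC from the fitted linear predictor by the rank (Mann-Whitney)
#' statistic, midranks for ties.  Complete separation is flagged
#' (`separable = TRUE`); the AUC is still valid since it only uses score
#' ranks.
#'
#' @param scores numeric matrix (samples x predictors) or vector.
#' @param labels binary labels (two levels; the larger sorted level is
#'   the positive class).
#' @param max_iter IRLS iteration cap.
#' @return list: `auc`, `roc` (data frame `fpr`, `tpr`), `coef`,
#'   `fitted`, `separable`.
#' @export
logistic_roc <- function(scores, labels, max_iter = 25L) {
  if (is.vector(scores)) scores <- matrix(scores, ncol = 1L)
  lev <- sort(unique(as.character(labels)))
  if (length(lev) != 2L) stopf("logistic_roc: need exactly two classes")
  y <- as.integer(as.character(labels) == lev[2])
  X <- cbind(1, scores)
  b <- numeric(ncol(X))
  separable <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% b)
    pfit <- 1 / (1 + exp(-eta))
    w <- pmax(pfit * (1 - pfit), 1e-10)
    step <- tryCatch(
      solve(crossprod(X, X * w), crossprod(X, y - pfit)),
      error = function(e) NULL)
    if (is.null(step)) { separable <- TRUE; break }
    b <- b + drop(step)
    if (max(abs(step)) < 1e-10) break
  }
  if (max(abs(b)) > 1e3) separable <- TRUE
  eta <- drop(X %*% b)

  r <- rank(eta)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(Inf, sort(unique(eta), decreasing = TRUE))
  roc <- data.frame(
    fpr = vapply(thr, function(t) mean(eta[y == 0] >= t), numeric(1)),
    tpr = vapply(thr, function(t) mean(eta[y == 1] >= t), numeric(1)))
  list(auc = auc, roc = roc, coef = b, fitted = eta,
       separable = separable)
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric p per gene set
#' (`P(X >= k)` with k hits among the query, K set members in the
#' universe, query size n, universe size N), BH-adjusted, sorted by p.
#' Query genes outside the universe are dropped with a warning.
#'
#' @param query character vector of query genes.
#' @param sets named list of gene sets (e.g. from [read_gmt()]).
#' @param universe character vector, the background gene universe.
#' @return data frame: `set`, `k`, `K`, `n`, `N`, `p`, `adj_p`.
#' @export
ora <- function(query, sets, universe) {
  universe <- unique(universe)
  N <- length(universe)
  if (N == 0L) stopf("ora: empty universe")
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warnf("ora: %d query gene(s) outside the universe dropped",
          length(outside))
    query <- intersect(query, universe)
  }
  n <- length(query)
  rows <- lapply(names(sets), function(s) {
    K <- length(intersect(sets[[s]], universe))
    k <- length(intersect(intersect(sets[[s]], universe), query))
    p <- if (K == 0L || n == 0L) 1
    else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = s, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adj_p <- bh_adjust(out$p)
  out <- out[order(out$p, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}
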