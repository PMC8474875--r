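## Co-expression network on non-zero sample intersections: Spearman
## correlation per pair, population z-scores, per-group enrichment of
## significant correlations, and the edge/node selection rules.

#' Spearman correlation over the non-zero sample intersection
#'
#' Restricts both vectors to the indices where both are non-zero (so the
#' overlap n differs from pair to pair), ranks with midranks for ties,
#' and reports the t-approximation p-value on `n_overlap - 2` df.  An
#' overlap below `min_overlap` yields a flagged-undefined result (`NA`
#' rho and p, `defined = FALSE`) rather than an error.
#'
#' @param a,b numeric vectors of equal length.
#' @param min_overlap minimum shared non-zero samples, default 3.
#' @return list: `rho`, `n_overlap`, `p`, `defined`.
#' @export
spearman_nonzero <- function(a, b, min_overlap = 3L) {
  if (length(a) != length(b))
    stopf("spearman_nonzero: length mismatch (%d vs %d)",
          length(a), length(b))
  use <- which(a != 0 & b != 0 & !is.na(a) & !is.na(b))
  n <- length(use)
  if (n < min_overlap)
    return(list(rho = NA_real_, n_overlap = n, p = NA_real_,
                defined = FALSE))
  ra <- rank(a[use]); rb <- rank(b[use])
  if (sd(ra) == 0 || sd(rb) == 0)
    return(list(rho = NA_real_, n_overlap = n, p = NA_real_,
                defined = FALSE))
  rho <- cor(ra, rb)
  tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tt), df = n - 2)
  list(rho = rho, n_overlap = n, p = min(p, 1), defined = TRUE)
}

#' All pairwise non-zero-overlap Spearman edges
#'
#' @param x features x samples matrix.
#' @param features optional subset of row names.
#' @param min_overlap passed to [spearman_nonzero()].
#' @return data frame `keyA`, `keyB`, `rho`, `n_overlap`, `p`, `defined`
#'   over all unordered pairs.
#' @export
correlation_edges <- function(x, features = rownames(x), min_overlap = 3L) {
  stopifnot(length(features) >= 2L)
  pairs <- combn(features, 2L)
  res <- apply(pairs, 2L, function(pr)
    spearman_nonzero(x[pr[1], ], x[pr[2], ], min_overlap))
  data.frame(
    keyA = pairs[1, ], keyB = pairs[2, ],
    rho = vapply(res, `[[`, numeric(1), "rho"),
    n_overlap = vapply(res, `[[`, integer(1), "n_overlap"),
    p = vapply(res, `[[`, numeric(1), "p"),
    defined = vapply(res, `[[`, logical(1), "defined"),
    stringsAsFactors = FALSE)
}

#' Significance calls and group enrichment for correlation edges
#'
#' Standardises rho over the whole evaluated pair set
#' (`z = (rho - mean(rho)) / sd(rho)`), calls an edge significantly
#' positive when `z > z_threshold` and significantly negative when
#' `z < -z_threshold`, then tests each group-pair block (e.g.
#' protective-protective, harmful-harmful, protective-harmful) for
#' over-representation of each call against the pooled remaining blocks
#' by Fisher's exact test.
#'
#' @param edges data frame from [correlation_edges()] with an added
#'   `group` column labelling each edge's block.
#' @param z_threshold z cut-off, default 2.
#' @param by_block standardise within each block instead of over the
#'   pooled set (changes the question: per-block proportions become
#'   relative to that block's own rho distribution).
#' @return list: `edges` (with `z`, `sig_pos`, `sig_neg`) and
#'   `enrichment` (per block: n, n_sig_pos, n_sig_neg, Fisher p per
#'   direction, one-sided greater).
#' @export
classify_correlation <- function(edges, z_threshold = 2, by_block = FALSE) {
  ed <- edges[edges$defined, , drop = FALSE]
  if (nrow(ed) < 2L) stopf("classify_correlation: too few defined edges")
  zs <- function(r) {
    s <- sd(r)
    if (s == 0) stopf("classify_correlation: degenerate edge set (sd = 0)")
    (r - mean(r)) / s
  }
  ed$z <- if (by_block) ave(ed$rho, ed$group, FUN = zs) else zs(ed$rho)
  ed$sig_pos <- ed$z > z_threshold
  ed$sig_neg <- ed$z < -z_threshold
  groups <- unique(ed$group)
  enr <- do.call(rbind, lapply(groups, function(g) {
    a <- ed$group == g
    fp <- function(flag) {
      tab <- c(sum(flag[a]), sum(!flag[a]), sum(flag[!a]), sum(!flag[!a]))
      fisher_exact(matrix(tab, 2, byrow = TRUE), side = "greater")$p
    }
    data.frame(group = g, n = sum(a),
               n_sig_pos = sum(ed$sig_pos[a]),
               n_sig_neg = sum(ed$sig_neg[a]),
               prop_sig_pos = mean(ed$sig_pos[a]),
               prop_sig_neg = mean(ed$sig_neg[a]),
               fisher_p_pos = if (length(groups) > 1L) fp(ed$sig_pos)
               else NA_real_,
               fisher_p_neg = if (length(groups) > 1L) fp(ed$sig_neg)
               else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(enr) <- NULL
  list(edges = ed, enrichment = enr)
}

#' Select the co-expression subgraph
#'
#' Keeps edges with rho > 0 that sit simultaneously in the top
#' `top_fraction` by largest rho and in the top `top_fraction` by
#' smallest p (intersection of the two ranked lists; boundary ties are
#' included), then iteratively removes nodes of degree below
#' `min_degree` (and their incident edges) until stable.
#'
#' @param edges data frame with `keyA`, `keyB`, `rho`, `p` (undefined
#'   edges are ignored).
#' @param top_fraction fraction of the positive-rho edges kept by each
#'   ranking, default 0.05.
#' @param min_degree minimum node degree retained, default 2.
#' @return data frame of retained edges with a `selected` flag set TRUE;
#'   attribute `nodes` lists the surviving node set.
#' @export
select_edges <- function(edges, top_fraction = 0.05, min_degree = 2L) {
  ed <- edges[!is.na(edges$rho) & edges$rho > 0, , drop = FALSE]
  if (nrow(ed) == 0L) {
    out <- edges[0, , drop = FALSE]
    attr(out, "nodes") <- character(0)
    return(out)
  }
  k <- max(1L, ceiling(top_fraction * nrow(ed)))
  rho_sorted <- sort(ed$rho, decreasing = TRUE)
  p_sorted <- sort(ed$p)
  rho_cut <- rho_sorted[min(k, length(rho_sorted))]
  p_cut <- p_sorted[min(k, length(p_sorted))]
  keep <- ed$rho >= rho_cut & ed$p <= p_cut   # boundary ties included
  sub <- ed[keep, , drop = FALSE]
  repeat {
    if (nrow(sub) == 0L) break
    deg <- table(c(sub$keyA, sub$keyB))
    drop_nodes <- names(deg)[deg < min_degree]
    if (length(drop_nodes) == 0L) break
    sub <- sub[!(sub$keyA %in% drop_nodes) & !(sub$keyB %in% drop_nodes),
               , drop = FALSE]
  }
  sub$selected <- rep(TRUE, nrow(sub))
  rownames(sub) <- NULL
  attr(sub, "nodes") <- sort(unique(c(sub$keyA, sub$keyB)))
  sub
}
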