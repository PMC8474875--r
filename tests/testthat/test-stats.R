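# Figure statistics: Fisher, Wilcoxon, shift preference, PCA, PERMANOVA,
# logistic ROC, over-representation.

test_that("fisher_exact matches base fisher.test across tables", {
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2))$p, 1)
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2))$odds_ratio, 1)

  # the isomiR x prognosis table from the screen summary
  tab <- matrix(c(75, 43, 8, 17), 2, byrow = TRUE)
  expect_equal(fisher_exact(tab)$p,
               fisher.test(tab)$p.value, tolerance = 1e-12)

  # exhaustive oracle on all tables with total <= 14
  for (n in 2:14) {
    comps <- expand.grid(a = 0:n, b = 0:n, c = 0:n)
    comps <- comps[rowSums(comps) <= n, ]
    comps$d <- n - rowSums(comps)
    for (i in seq_len(nrow(comps))) {
      m <- matrix(unlist(comps[i, ]), 2, byrow = TRUE)
      if (sum(m) == 0) next
      expect_equal(fisher_exact(m)$p, fisher.test(m)$p.value,
                   tolerance = 1e-9)
    }
  }

  # random larger tables, all three sides
  set.seed(14)
  for (i in 1:100) {
    m <- matrix(rmultinom(1, sample(20:60, 1), runif(4)), 2)
    ft <- fisher_exact(m)
    expect_equal(ft$p, fisher.test(m)$p.value, tolerance = 1e-9)
    expect_equal(fisher_exact(m, "greater")$p,
                 fisher.test(m, alternative = "greater")$p.value,
                 tolerance = 1e-9)
    expect_equal(fisher_exact(m, "less")$p,
                 fisher.test(m, alternative = "less")$p.value,
                 tolerance = 1e-9)
    # one-sided p never exceeds... the two-sided p never exceeds twice it
    expect_lte(ft$p, 2 * min(fisher_exact(m, "greater")$p,
                             fisher_exact(m, "less")$p) + 1e-12)
  }
  expect_error(fisher_exact(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
})

test_that("wilcoxon_ranksum: exact enumeration and approximation", {
  # x = {1,2}, y = {3,4}: exact two-sided p = 2/6
  expect_equal(wilcoxon_ranksum(c(1, 2), c(3, 4))$p, 2 / 6)
  # identical multisets -> p = 1
  expect_equal(wilcoxon_ranksum(c(1, 2, 3), c(1, 2, 3))$p, 1)
  # strongly shifted -> tiny p
  set.seed(15)
  expect_lt(wilcoxon_ranksum(rnorm(60), rnorm(60) + 3)$p, 1e-4)
  expect_error(wilcoxon_ranksum(numeric(0), 1), "empty")

  # oracle: base wilcox.test, exact branch (no ties)
  for (i in 1:20) {
    set.seed(200 + i)
    x <- sample(1:1000, sample(3:12, 1))
    y <- sample(2000:3000, sample(3:12, 1))
    y <- y + runif(length(y))          # keep values distinct
    mine <- wilcoxon_ranksum(x, y)
    or <- wilcox.test(x, y, exact = TRUE)
    expect_true(mine$exact)
    expect_equal(mine$statistic, unname(or$statistic))
    expect_equal(mine$p, or$p.value, tolerance = 1e-12)
  }
  # approximate branch (ties present) against the continuity-corrected
  # normal approximation
  for (i in 1:10) {
    set.seed(300 + i)
    x <- sample(1:10, 25, TRUE)
    y <- sample(3:12, 25, TRUE)
    mine <- wilcoxon_ranksum(x, y)
    or <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
    expect_false(mine$exact)
    expect_equal(mine$p, or$p.value, tolerance = 1e-9)
  }
})

test_that("shift_preference excludes archetypes and reports per-class splits", {
  labs <- c(sprintf("P%02d|%d", 1:75, c(rep(1, 50), rep(-1, 25))),
            "A1|0", "A2|0",
            sprintf("N%02d|%d", 1:40, c(rep(1, 12), rep(-1, 28))))
  cls <- c(rep("protective", 75), rep("nonsignificant", 2),
           rep("nonsignificant", 40))
  out <- shift_preference(labs, cls)
  prot <- out[out$class == "protective", ]
  expect_equal(prot$n_pos, 50)
  expect_equal(prot$n_neg, 25)
  expect_equal(prot$frac_pos, 2 / 3)
  # archetypes do not count: nonsignificant totals 40 despite 2 zeros
  ns <- out[out$class == "nonsignificant", ]
  expect_equal(ns$n_pos + ns$n_neg, 40)
  # a planted bias is detected
  expect_lt(prot$fisher_p, 0.05)
})

test_that("pca: separation, permutation invariance, reconstruction", {
  set.seed(16)
  base <- matrix(rnorm(20 * 10, sd = 0.05), 20, 10)
  base[1, ] <- c(rep(0, 5), rep(10, 5))    # one separating feature
  colnames(base) <- paste0("s", 1:10)
  pc <- pca_expression(base)
  expect_gt(pc$var_explained[1], 0.99)
  expect_true(max(pc$scores[1:5, 1]) < min(pc$scores[6:10, 1]) ||
                min(pc$scores[1:5, 1]) > max(pc$scores[6:10, 1]))

  # feature-order permutation leaves scores unchanged (up to sign)
  o <- sample(20)
  pc2 <- pca_expression(base[o, ])
  expect_equal(abs(pc2$scores[, 1]), abs(pc$scores[, 1]), tolerance = 1e-8)

  # SVD identity: all components reconstruct the centred grid
  x <- matrix(rnorm(8 * 6), 8, 6, dimnames = list(NULL, paste0("s", 1:6)))
  pcx <- pca_expression(x)
  centred <- sweep(t(x), 2, colMeans(t(x)))
  expect_equal(pcx$scores %*% t(pcx$rotation), centred,
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(pca_expression(matrix(1, 4, 4)), "constant")
})

test_that("permanova: bounds, invariances, vegan oracle", {
  set.seed(17)
  # perfectly separated clusters reach the minimal attainable p
  g <- rep(c("a", "b"), each = 8)
  x <- matrix(rnorm(16 * 4), 16, 4)
  x[g == "b", ] <- x[g == "b", ] + 50
  d <- dist(x)
  out <- permanova(d, g, n_perm = 999, seed = 4)
  expect_equal(out$p, 0.001)

  # relabeling the groups leaves F unchanged
  g2 <- ifelse(g == "a", "z", "q")
  expect_equal(permanova(d, g2, n_perm = 9, seed = 1)$F, out$F)

  # pseudo-F agrees with vegan::adonis2
  y <- matrix(rnorm(16 * 5), 16, 5)
  dy <- dist(y)
  mine <- permanova(dy, g, n_perm = 99, seed = 2)
  vg <- vegan::adonis2(dy ~ g, permutations = 99)
  expect_equal(mine$F, vg$F[1], tolerance = 1e-10)

  # null calibration (reduced here; the full 500-replicate run lives in
  # the acceptance suite)
  hits <- 0
  for (r in 1:60) {
    set.seed(500 + r)
    z <- matrix(rnorm(12 * 3), 12, 3)
    pv <- permanova(dist(z), rep(c("a", "b"), 6), n_perm = 99,
                    seed = 600 + r)$p
    if (pv <= 0.05) hits <- hits + 1
  }
  expect_lte(hits, qbinom(0.999, 60, 0.05) + 1)
})

test_that("logistic_roc: AUC identities and fitting", {
  set.seed(18)
  # perfectly separable -> AUC 1 and separation flag
  s <- c(rnorm(20, -5), rnorm(20, 5))
  y <- rep(c("n", "t"), each = 20)
  out <- logistic_roc(s, y)
  expect_equal(out$auc, 1)

  # AUC equals U / (n1 n2) computed independently
  s2 <- rnorm(50)
  y2 <- sample(c("n", "t"), 50, TRUE, prob = c(0.4, 0.6))
  o2 <- logistic_roc(s2, y2)
  u <- wilcox.test(s2[y2 == "t"] * sign(o2$coef[2]),
                   s2[y2 == "n"] * sign(o2$coef[2]),
                   exact = FALSE)$statistic
  expect_equal(o2$auc, unname(u) / (sum(y2 == "t") * sum(y2 == "n")),
               tolerance = 1e-10)

  # labels independent of scores -> AUC near 0.5 on average.  The fitted
  # coefficient adapts its sign to the data, which folds the null AUC
  # distribution upward by O(1/sqrt(n)); n = 200 keeps that bias small.
  aucs <- replicate(50, {
    ss <- rnorm(200); yy <- rep(c("a", "b"), 100)
    logistic_roc(ss, sample(yy))$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.05)

  # monotone transform of the single score leaves AUC unchanged
  s3 <- runif(30, 1, 2)
  y3 <- rep(c("a", "b"), 15)
  expect_equal(logistic_roc(s3, y3)$auc, logistic_roc(s3^3, y3)$auc)

  # coefficients match glm for a well-behaved fit
  fit <- logistic_roc(s2, y2)
  gl <- glm(I(y2 == "t") ~ s2, family = binomial())
  expect_equal(unname(fit$coef), unname(coef(gl)), tolerance = 1e-6)
})

test_that("ora computes the hypergeometric upper tail with BH", {
  universe <- paste0("g", 1:4)
  sets <- list(all = universe, some = c("g1", "g2"), none = "g4")
  out <- ora(c("g1", "g2", "g3"), sets, universe)
  # query = universe-sized overlaps: p(all) = 1
  expect_equal(out$p[out$set == "all"], 1)
  # hand-summed tail: P(hits >= 2) for K=2, n=3, N=4 = C(2,2)C(2,1)/C(4,3)
  expect_equal(out$p[out$set == "some"], 2 / 4 * 3 / 3 * 1)
  # oracle via direct enumeration
  hand <- sum(dhyper(2:2, 2, 2, 3))
  expect_equal(out$p[out$set == "some"], hand)
  # disjoint query and set -> p = 1
  expect_equal(out$p[out$set == "none"],
               phyper(-1, 1, 3, 3, lower.tail = FALSE))
  expect_true(all(out$adj_p >= out$p))
  expect_error(ora("g1", sets, character(0)), "empty universe")
  expect_warning(ora(c("g1", "zz"), sets, universe), "outside")
})

test_that("gmt round-trips", {
  sets <- list(S1 = c("a", "b", "c"), S2 = c("d", "e"))
  f <- tempfile(fileext = ".gmt")
  write_gmt(sets, f)
  expect_identical(read_gmt(f), sets)
  fb <- tempfile(); writeLines("name\tonly", fb)
  expect_error(read_gmt(fb), "fewer than 3")
})
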