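# Target consensus, pair classification, seed matching, Jaccard.

random_tables <- function(seed, n_keys = 6, n_genes = 10, n_tools = 4) {
  set.seed(seed)
  keys <- sprintf("MIMAT%07d|%d", 1:n_keys, sample(-3:3, n_keys, TRUE))
  genes <- sprintf("G%03d", 1:n_genes)
  all_pairs <- expand.grid(label = keys, gene = genes,
                           stringsAsFactors = FALSE)
  tabs <- lapply(1:n_tools, function(i)
    all_pairs[runif(nrow(all_pairs)) < 0.4, , drop = FALSE])
  names(tabs) <- paste0("tool", 1:n_tools)
  tabs
}

test_that("consensus keeps >=min_support pairs and equals brute force", {
  t1 <- data.frame(label = c("A|1", "B|2"), gene = c("g1", "g2"))
  t2 <- data.frame(label = c("A|1", "B|2"), gene = c("g1", "g3"))
  t3 <- data.frame(label = "A|1", gene = "g1")
  t4 <- data.frame(label = "C|0", gene = "g9")
  out <- consensus(list(a = t1, b = t2, c = t3, d = t4), 3)
  expect_identical(out$label, "A|1")
  expect_identical(out$support, 3L)
  # pair in only two tables dropped
  expect_false("B|2" %in% out$label)
  expect_error(consensus(list(a = t1, a = t2), 1), "unique")

  for (seed in 1:10) {
    tabs <- random_tables(seed)
    got <- consensus(tabs, 3)
    # brute-force enumeration over the union of all pairs
    univ <- unique(do.call(rbind, tabs))
    support <- apply(univ, 1, function(pr)
      sum(vapply(tabs, function(t)
        any(t$label == pr[["label"]] & t$gene == pr[["gene"]]), TRUE)))
    keep <- univ[support >= 3, , drop = FALSE]
    expect_setequal(paste(got$label, got$gene),
                    paste(keep$label, keep$gene))
    # monotone: raising min_support never adds pairs
    for (ms in 1:3) {
      hi <- consensus(tabs, ms + 1)
      lo <- consensus(tabs, ms)
      expect_true(all(paste(hi$label, hi$gene) %in%
                        paste(lo$label, lo$gene)))
    }
  }
})

test_that("pair classification partitions by DE direction and survival class", {
  pairs <- data.frame(label = c("A|1", "A|1", "B|-1", "C|2", "D|0"),
                      gene = c("g1", "g2", "g3", "g1", "gX"))
  iso_de <- data.frame(feature = c("A|1", "B|-1", "C|2", "D|0"),
                       direction = c("up", "down", "ns", "up"))
  gene_de <- data.frame(feature = c("g1", "g2", "g3"),
                        direction = c("down", "up", "up"))
  surv <- data.frame(label = c("A|1", "B|-1", "C|2", "D|0"),
                     class = c("protective", "protective", "harmful",
                               "nonsignificant"))
  out <- classify_target_pairs(pairs, iso_de, gene_de, surv)
  expect_identical(out$pair_class,
                   c("upIso_downGene", "other", "downIso_upGene", "other",
                     "unresolved"))
  # partition: bins are disjoint and cover the input
  expect_identical(nrow(out), nrow(pairs))
  expect_true(all(out$pair_class %in%
                    c("upIso_downGene", "downIso_upGene", "other",
                      "unresolved")))
})

test_that("seed matcher finds planted sites and respects the shifted seed", {
  iso <- "UAGCUUAUCAGACUGAUGUUGA"
  seed <- seed_of(iso)                         # AGCUUAU
  site8 <- "ATAAGCTAA"                         # revcomp(AGCUUAU)+A in DNA
  set.seed(9)
  bg <- paste(sample(c("A", "C"), 300, TRUE), collapse = "")  # no G/T: no sites
  utr_hit <- paste0(substr(bg, 1, 100), site8, substr(bg, 101, 300))
  utr_miss <- bg
  out <- seed_match_predict(c("MIMAT0000062|0" = iso),
                            c(hit = utr_hit, miss = utr_miss))
  expect_identical(out$gene, "hit")
  expect_identical(out$site, "8mer")

  # the +1 isomiR has a different seed: must not match the archetype site
  iso1 <- substr(iso, 2, nchar(iso))
  out1 <- seed_match_predict(c("MIMAT0000062|1" = iso1),
                             c(hit = utr_hit))
  expect_identical(nrow(out1), 0L)

  # destroyed site -> no pair
  shuffled <- paste(sample(strsplit(utr_hit, "")[[1]]), collapse = "")
  if (!grepl("ATAAGCTA", shuffled, fixed = TRUE)) {
    expect_identical(nrow(seed_match_predict(
      c("MIMAT0000062|0" = iso), c(s = shuffled))), 0L)
  }
  expect_error(seed_match_predict(c(k = iso), c(u = "ACGTN")), "non-ACGU")
})

test_that("seed-match hit rate on random UTRs matches the analytic expectation", {
  set.seed(10)
  iso <- paste(sample(c("A", "C", "G", "U"), 22, TRUE), collapse = "")
  L <- 1000
  n <- 400
  utrs <- vapply(1:n, function(i)
    paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = ""),
    character(1))
  names(utrs) <- paste0("u", 1:n)
  hits <- nrow(seed_match_predict(setNames(iso, "k|0"), utrs))
  # P(at least one 7mer-m8 core in L nt) ~ 1 - (1 - 4^-7)^(L - 6);
  # 7mer-A1 sites add a little, so allow generous Monte-Carlo slack
  p7 <- 1 - (1 - 4^-7)^(L - 6)
  expect_gt(hits / n, p7 * 0.5)
  expect_lt(hits / n, 3.5 * p7 + 3 * sqrt(p7 * (1 - p7) / n))
})

test_that("jaccard index matches set arithmetic", {
  expect_equal(jaccard(letters[1:5], letters[1:5]), 1)
  expect_equal(jaccard(letters[1:5], letters[6:10]), 0)
  # the shared-target scenario: |A|=|B|=100, overlap 45 -> 45/155
  a <- paste0("g", 1:100)
  b <- paste0("g", 56:155)
  expect_equal(jaccard(a, b), 45 / 155)
  expect_message(jaccard(character(0), character(0)), "empty")
})

test_that("prediction-table reader validates labels and collapses transcripts", {
  f <- tempfile()
  write.table(data.frame(label = c("A|1", "A|1"),
                         gene = c("G1.2", "G1.3")),
              f, sep = "\t", quote = FALSE, row.names = FALSE)
  out <- read_prediction_table(f)
  expect_identical(nrow(out), 1L)     # transcripts collapse to the gene
  expect_identical(out$gene, "G1")
  fb <- tempfile()
  write.table(data.frame(label = "nolabel", gene = "G1"), fb, sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(read_prediction_table(fb), "malformed")
})
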