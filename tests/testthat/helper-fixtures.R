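# Shared fixtures, built once per test run and memoised.

.fixtures <- new.env(parent = emptyenv())

# Small cohort (60 tumor / 20 normal), written to disk and re-read
# through the parsers so every fixture consumer exercises the IO path.
small_ds <- function() {
  if (is.null(.fixtures$ds)) {
    cfg <- sim_config(n_tumor = 60, n_normal = 20, seed = 101)
    dir <- file.path(tempdir(), "isomirsurv-fixture")
    .fixtures$ds <- simulate_dataset(cfg, dir = dir)
    .fixtures$dir <- dir
  }
  .fixtures$ds
}

small_dir <- function() { small_ds(); .fixtures$dir }

small_matrix <- function() {
  if (is.null(.fixtures$mat)) {
    ds <- small_ds()
    ann <- parse_gff3(file.path(small_dir(), "mirna.gff3"))
    fs <- list.files(file.path(small_dir(), "isoforms"), full.names = TRUE)
    tabs <- lapply(fs, read_isoform_file)
    names(tabs) <- sub("\\.isoforms\\.quantification\\.txt$", "",
                       basename(fs))
    info <- ds$expr$samples[match(names(tabs), ds$expr$samples$sample), ]
    .fixtures$mat <- build_matrix(tabs, ann, info)
  }
  .fixtures$mat
}

# Minimal hand-written annotation (one locus per strand) for coordinate
# arithmetic tests.
toy_annotation <- function() {
  data.frame(
    accession = c("MIMAT0000062", "MIMATMINUS01"),
    name = c("hsa-miR-plus", "hsa-miR-minus"),
    chrom = c("chr1", "chr2"), start = c(100L, 300L),
    end = c(121L, 321L), strand = c("+", "-"),
    hairpin_id = c("MI001", "MI002"), stringsAsFactors = FALSE)
}

# Random NB count matrix with planted two-group fold changes
# (dispersion-matched: same NB noise for null and planted features).
nb_two_group <- function(n_feat, n1, n2, planted_up, planted_down,
                         lfc = 1, dispersion = 0.4, seed = 1) {
  set.seed(seed)
  mu <- exp(rnorm(n_feat, log(80), 1))
  fc <- rep(1, n_feat)
  fc[planted_up] <- 2^lfc
  fc[planted_down] <- 2^(-lfc)
  grp <- rep(c("normal", "tumor"), c(n1, n2))
  m <- sapply(seq_len(n1 + n2), function(j) {
    mj <- if (grp[j] == "tumor") mu * fc else mu
    rnbinom(n_feat, mu = mj, size = 1 / dispersion)
  })
  rownames(m) <- sprintf("F%03d", seq_len(n_feat))
  colnames(m) <- sprintf("S%03d", seq_len(n1 + n2))
  list(counts = m, group = grp)
}
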