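## Synthetic isomiR expression: zero-inflated negative-binomial counts with
## planted co-expression blocks, planted tumor/normal fold changes, and the
## per-sample GDC-style isoform quantification tables derived from them.

#' Generate per-sample isoform quantification tables with planted truth
#'
#' Chooses an isomiR key universe (every mature plus a random subset of
#' non-zero 5' shifts within `config$shift_range`), partitions it into
#' co-expression blocks driven by a shared log-normal latent factor, plants
#' tumor-vs-normal fold changes of `2^config$lfc` on randomly chosen keys
#' and survival effects on disjoint protective/harmful key sets, then draws
#' zero-inflated negative-binomial counts and renders one GDC-dialect
#' quantification table per sample.  Each key's reads are emitted as up to
#' two rows differing only in their 3' end (roughly a 70/30 split) so that
#' downstream aggregation over 3' variants is exercised.
#'
#' @param config a [sim_config()].
#' @param ann annotation from [generate_annotation()].
#' @return list of class `sim_expression`:
#'   \item{files}{named list of per-sample data frames in GDC isoform
#'     dialect (`miRNA_ID`, `isoform_coords`, `read_count`,
#'     `reads_per_million_miRNA_mapped`, `cross-mapped`, `miRNA_region`).}
#'   \item{samples}{data frame of sample ids and `tumor`/`normal` type.}
#'   \item{keys}{data frame of the planted key universe (label, accession,
#'     shift, block, baseline mean).}
#'   \item{counts}{keys x samples matrix of the drawn counts.}
#'   \item{truth}{partial ground-truth list (`protective_keys`,
#'     `harmful_keys`, `betas`, `de_up`, `de_down`, `coexpr_blocks`).}
#' @export
generate_isoform_files <- function(config, ann) {
  validate_sim_config(config)
  with_seed(child_seed(config$seed, 2L), {
    mat <- ann$matures
    shifts_all <- config$shift_range[1]:config$shift_range[2]
    nz <- shifts_all[shifts_all != 0L]
    keys <- do.call(rbind, lapply(seq_len(nrow(mat)), function(i) {
      sh <- c(0L, nz[runif(length(nz)) < 0.45])
      data.frame(accession = mat$accession[i], shift = sort(sh),
                 stringsAsFactors = FALSE)
    }))
    keys$label <- isomir_label(keys$accession, keys$shift)
    nk <- nrow(keys)
    keys$block <- sample(rep_len(seq_len(config$n_blocks), nk))
    keys$mu <- exp(rnorm(nk, log(80), 1))

    pick <- sample(keys$label, config$n_protective + config$n_harmful)
    protective <- pick[seq_len(config$n_protective)]
    harmful <- setdiff(pick, protective)
    # survival-influential keys co-express within their class (shared
    # latent factor), emulating the within-class cooperativity the
    # screen is expected to expose downstream
    keys$block[keys$label %in% protective] <- 1L
    keys$block[keys$label %in% harmful] <- min(2L, config$n_blocks)
    betas <- setNames(c(rep(-config$beta_effect, length(protective)),
                        rep(config$beta_effect, length(harmful))),
                      c(protective, harmful))
    de_pick <- sample(setdiff(keys$label, pick), 2L * config$n_de)
    de_up <- de_pick[seq_len(config$n_de)]
    de_down <- setdiff(de_pick, de_up)

    samples <- data.frame(
      sample = c(sprintf("TCGA-SIM-%04d-01", seq_len(config$n_tumor)),
                 sprintf("TCGA-SIM-%04d-11",
                         config$n_tumor + seq_len(config$n_normal))),
      type = rep(c("tumor", "normal"), c(config$n_tumor, config$n_normal)),
      stringsAsFactors = FALSE
    )
    ns <- nrow(samples)
    is_tumor <- samples$type == "tumor"

    # per-sample per-block latent factor (shared within block -> correlation)
    latent <- matrix(exp(rnorm(config$n_blocks * ns, 0, config$block_sd)),
                     config$n_blocks, ns)
    fc <- rep(1, nk)
    fc[keys$label %in% de_up] <- 2^config$lfc
    fc[keys$label %in% de_down] <- 2^(-config$lfc)

    mu <- outer(keys$mu, rep(1, ns)) * latent[keys$block, , drop = FALSE]
    mu[, is_tumor] <- mu[, is_tumor] * fc
    size <- if (config$nb_dispersion > 0) 1 / config$nb_dispersion else Inf
    counts <- matrix(
      if (is.finite(size)) rnbinom(nk * ns, mu = as.vector(mu), size = size)
      else rpois(nk * ns, as.vector(mu)),
      nk, ns)
    if (config$zero_rate > 0)
      counts[runif(nk * ns) < config$zero_rate] <- 0L
    dimnames(counts) <- list(keys$label, samples$sample)

    mat_idx <- match(keys$accession, mat$accession)
    files <- lapply(seq_len(ns), function(j) {
      render_isoform_table(keys, counts[, j], mat, mat_idx, ann$hairpins)
    })
    names(files) <- samples$sample

    truth <- list(protective_keys = sort(protective),
                  harmful_keys = sort(harmful),
                  betas = betas,
                  de_up = sort(de_up), de_down = sort(de_down),
                  coexpr_blocks = setNames(keys$block, keys$label))
    structure(list(files = files, samples = samples, keys = keys,
                   counts = counts, truth = truth),
              class = "sim_expression")
  })
}

## Render one sample's isoform quantification table: coordinates follow the
## strand-aware 5'-shift rule, counts are split into a primary and an
## extended 3' variant, RPM normalises to the per-sample total.
#' @noRd
render_isoform_table <- function(keys, cnt, mat, mat_idx, hairpins) {
  keep <- which(cnt > 0L)
  rows <- lapply(keep, function(k) {
    i <- mat_idx[k]
    sh <- keys$shift[k]
    if (mat$strand[i] == "+") {
      s0 <- mat$start[i] + sh
      ends <- c(s0 + MATURE_LEN - 1L, s0 + MATURE_LEN + 1L)
      starts <- c(s0, s0)
    } else {
      e0 <- mat$end[i] - sh
      starts <- c(e0 - MATURE_LEN + 1L, e0 - MATURE_LEN - 1L)
      ends <- c(e0, e0)
    }
    n1 <- ceiling(0.7 * cnt[k])
    n2 <- cnt[k] - n1
    take <- if (n2 > 0L) 1:2 else 1L
    data.frame(
      mirna_id = mat$name[i][rep(1L, length(take))],
      chrom = mat$chrom[i], start = starts[take], end = ends[take],
      strand = mat$strand[i], read_count = c(n1, n2)[take],
      accession = mat$accession[i], stringsAsFactors = FALSE
    )
  })
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(mirna_id = character(), chrom = character(),
                     start = integer(), end = integer(), strand = character(),
                     read_count = integer(), accession = character(),
                     stringsAsFactors = FALSE)
  total <- sum(df$read_count)
  rpm <- if (total > 0) df$read_count / total * 1e6 else numeric(nrow(df))
  out <- data.frame(
    miRNA_ID = df$mirna_id,
    isoform_coords = sprintf("hg38:%s:%d-%d:%s", df$chrom, df$start,
                             df$end, df$strand),
    read_count = df$read_count,
    reads_per_million_miRNA_mapped = sprintf("%.6f", rpm),
    `cross-mapped` = "N",
    miRNA_region = paste0("mature,", df$accession),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  out[order(out$isoform_coords), , drop = FALSE]
}

#' Generate a synthetic gene-level count matrix with planted fold changes
#'
#' Negative-binomial gene counts for the same samples as the isomiR
#' matrix, with `config$n_gene_de` genes planted up- and downregulated
#' (each) by `2^config$lfc` in tumors.
#'
#' @param config a [sim_config()].
#' @param samples sample data frame from [generate_isoform_files()].
#' @return list with `counts` (genes x samples integer matrix), `gene_de_up`
#'   and `gene_de_down` (character vectors of planted gene ids).
#' @export
generate_gene_counts <- function(config, samples) {
  validate_sim_config(config)
  with_seed(child_seed(config$seed, 5L), {
    ng <- config$n_genes
    genes <- sprintf("GENE%05d", seq_len(ng))
    ns <- nrow(samples)
    is_tumor <- samples$type == "tumor"
    mu_g <- exp(rnorm(ng, log(200), 1.2))
    pick <- sample(genes, 2L * config$n_gene_de)
    up <- sort(pick[seq_len(config$n_gene_de)])
    down <- sort(setdiff(pick, up))
    fc <- rep(1, ng)
    fc[genes %in% up] <- 2^config$lfc
    fc[genes %in% down] <- 2^(-config$lfc)
    mu <- outer(mu_g, rep(1, ns))
    mu[, is_tumor] <- mu[, is_tumor] * fc
    size <- if (config$nb_dispersion > 0) 1 / config$nb_dispersion else Inf
    counts <- matrix(
      if (is.finite(size)) rnbinom(ng * ns, mu = as.vector(mu), size = size)
      else rpois(ng * ns, as.vector(mu)),
      ng, ns, dimnames = list(genes, samples$sample))
    list(counts = counts, gene_de_up = up, gene_de_down = down)
  })
}
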