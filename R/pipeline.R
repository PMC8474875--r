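## End-to-end orchestration: simulate (or ingest) -> annotate/quantify ->
## EPV filter -> survival screen -> differential expression -> target
## consensus -> co-expression network -> figure statistics, with a
## machine-readable manifest and, on synthetic data, recovery metrics
## against the planted truth.

#' Pipeline configuration
#'
#' @param input_dir directory of pipeline inputs (layout as written by
#'   [write_sim_dataset()]); `NULL` simulates a dataset first.
#' @param out_dir output directory (required by [run_all()]).
#' @param seed master seed (drives the simulation and permutation tests).
#' @param sim a [sim_config()] used when `input_dir` is `NULL`; its seed
#'   is overridden by `seed`.
#' @param alpha survival-screen significance level.
#' @param dead_fraction EPV filter dead-sample coverage fraction.
#' @param de_sig adjusted-p threshold for differential expression.
#' @param min_support consensus support cut-off.
#' @param top_fraction,z_threshold,min_degree,min_overlap network
#'   selection parameters.
#' @param ties Cox tie correction.
#' @param n_perm PERMANOVA permutations.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL, out_dir = NULL, seed = 1L,
                            sim = sim_config(seed = seed),
                            alpha = 0.05, dead_fraction = 0.5,
                            de_sig = 0.01, min_support = 3L,
                            top_fraction = 0.05, z_threshold = 2,
                            min_degree = 2L, min_overlap = 3L,
                            ties = "efron", n_perm = 999L) {
  stopifnot(alpha > 0, alpha < 1, dead_fraction >= 0, dead_fraction <= 1,
            de_sig > 0, de_sig < 1, min_support >= 1L,
            top_fraction > 0, top_fraction <= 1, min_degree >= 0L,
            min_overlap >= 3L, n_perm >= 1L)
  structure(list(input_dir = input_dir, out_dir = out_dir,
                 seed = as.integer(seed), sim = sim, alpha = alpha,
                 dead_fraction = dead_fraction, de_sig = de_sig,
                 min_support = as.integer(min_support),
                 top_fraction = top_fraction, z_threshold = z_threshold,
                 min_degree = as.integer(min_degree),
                 min_overlap = as.integer(min_overlap), ties = ties,
                 n_perm = as.integer(n_perm)),
            class = "pipeline_config")
}

#' Run the whole pipeline
#'
#' Executes every stage on the configured inputs (simulating them first
#' when none are given), writes all stage outputs plus a JSON manifest
#' with seeds, thresholds and per-stage row counts under
#' `config$out_dir`, and — when ground truth is available — computes
#' recovery metrics (survival sign accuracy, DE power and empirical FDR,
#' consensus recall/precision).  Identical config and seed give
#' byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return list with every stage result (`matrix`, `screen`, `de_isomir`,
#'   `de_gene`, `consensus_pairs`, `pair_classes`, `network`, `figstats`,
#'   `recovery`, `manifest`), invisibly also written to disk.
#' @export
run_all <- function(config = pipeline_config()) {
  if (is.null(config$out_dir)) stopf("run_all: out_dir is required")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed [E_%s]: %s", name,
            toupper(name), conditionMessage(e)))
  }

  ## -- inputs -------------------------------------------------------------
  truth <- NULL
  if (is.null(config$input_dir)) {
    sim <- config$sim
    sim$seed <- config$seed
    input_dir <- file.path(config$out_dir, "inputs")
    stage("simulate", simulate_dataset(sim, dir = input_dir))
    truth <- jsonlite::read_json(file.path(input_dir, "ground_truth.json"),
                                 simplifyVector = TRUE)$truth
  } else input_dir <- config$input_dir

  ## -- annotate / quantify ------------------------------------------------
  ann <- stage("annotate", parse_gff3(file.path(input_dir, "mirna.gff3")))
  iso_files <- list.files(file.path(input_dir, "isoforms"),
                          pattern = "\\.isoforms\\.quantification\\.txt$",
                          full.names = TRUE)
  tables <- stage("quantify", lapply(iso_files, read_isoform_file))
  names(tables) <- sub("\\.isoforms\\.quantification\\.txt$", "",
                       basename(iso_files))
  sample_info <- read_tsv(file.path(input_dir, "samples.tsv"))
  sample_info <- sample_info[match(names(tables), sample_info$sample), ]
  mat <- stage("quantify", build_matrix(tables, ann, sample_info))
  write_isomir_matrix(mat, file.path(config$out_dir, "isomir"))
  clinical <- read_tsv(file.path(input_dir, "clinical.tsv"))

  ## -- EPV filter + survival screen --------------------------------------
  kept <- stage("epv_filter",
                epv_filter(mat, clinical, config$dead_fraction))
  write_tsv(attr(kept, "coverage"),
            file.path(config$out_dir, "epv_coverage.tsv"))
  screen <- stage("survival_screen",
                  cox_screen(mat, clinical, keys = kept,
                             alpha = config$alpha, ties = config$ties))
  write_tsv(screen, file.path(config$out_dir, "survival_screen.tsv"))

  ## -- differential expression -------------------------------------------
  grp <- mat$samples$type
  de_iso <- stage("de_isomir", {
    x <- normalize_uq(mat$counts[kept, , drop = FALSE])
    moderated_t(x, grp, sig = config$de_sig)
  })
  write_tsv(de_iso, file.path(config$out_dir, "de_isomir.tsv"))
  gene_tab <- read_tsv(file.path(input_dir, "gene_counts.tsv"))
  gene_counts <- as.matrix(gene_tab[, -1, drop = FALSE])
  rownames(gene_counts) <- gene_tab[[1]]
  gene_grp <- sample_info$type[match(colnames(gene_counts),
                                     sample_info$sample)]
  de_gene <- stage("de_gene", {
    x <- normalize_tmm_logcpm(gene_counts)
    moderated_t(x, gene_grp, sig = config$de_sig)
  })
  write_tsv(de_gene, file.path(config$out_dir, "de_gene.tsv"))

  ## -- target consensus ---------------------------------------------------
  pred_files <- list.files(file.path(input_dir, "predictions"),
                           pattern = "\\.tsv$", full.names = TRUE)
  preds <- lapply(pred_files, read_prediction_table)
  names(preds) <- sub("\\.tsv$", "", basename(pred_files))
  cons <- stage("consensus", consensus(preds, config$min_support))
  pair_cls <- stage("classify_pairs",
                    classify_target_pairs(cons, de_iso, de_gene, screen))
  write_tsv(pair_cls, file.path(config$out_dir, "target_pairs.tsv"))

  ## -- co-expression network ----------------------------------------------
  surv_keys <- screen$label[screen$class != "nonsignificant"]
  network <- NULL
  if (length(surv_keys) >= 4L) {
    tumor <- mat$samples$sample[mat$samples$type == "tumor"]
    edges <- stage("network",
                   correlation_edges(mat$rpm[, tumor, drop = FALSE],
                                     surv_keys, config$min_overlap))
    cls <- setNames(screen$class, screen$label)
    pairlab <- function(a, b) {
      g <- sort(c(cls[[a]], cls[[b]]))
      paste(g, collapse = "-")
    }
    edges$group <- mapply(pairlab, edges$keyA, edges$keyB)
    corr <- stage("network", classify_correlation(edges,
                                                  config$z_threshold))
    sel <- stage("network", select_edges(corr$edges, config$top_fraction,
                                         config$min_degree))
    write_tsv(corr$edges, file.path(config$out_dir, "network_edges.tsv"))
    write_tsv(corr$enrichment,
              file.path(config$out_dir, "network_enrichment.tsv"))
    write_tsv(sel, file.path(config$out_dir, "network_selected.tsv"))
    network <- list(edges = corr$edges, enrichment = corr$enrichment,
                    selected = sel)
  }

  ## -- figure statistics --------------------------------------------------
  figstats <- stage("figures_stats", {
    prot <- screen$label[screen$class == "protective"]
    sp <- shift_preference(screen$label, screen$class)
    fs <- list(shift_preference = sp)
    if (length(prot) >= 2L) {
      x <- normalize_uq(mat$counts[kept, , drop = FALSE])
      xp <- x[prot, , drop = FALSE]
      pc <- pca_expression(xp)
      dmat <- as.matrix(stats::dist(t(xp)))
      pm <- permanova(dmat, grp, n_perm = config$n_perm,
                      seed = child_seed(config$seed, 9L))
      lr <- logistic_roc(pc$scores[, 1:min(2, ncol(pc$scores)),
                                   drop = FALSE], grp)
      fs$pca_var <- pc$var_explained
      fs$permanova <- pm
      fs$auc <- lr$auc
      fs$scores <- pc$scores
    }
    sets <- read_gmt(file.path(input_dir, "gene_sets.gmt"))
    up_prot <- intersect(de_iso$feature[de_iso$direction == "up"],
                         screen$label[screen$class == "protective"])
    tgt <- unique(pair_cls$gene[pair_cls$label %in% up_prot &
                                  !is.na(pair_cls$gene_dir) &
                                  pair_cls$gene_dir == "down"])
    if (length(tgt))
      fs$ora <- ora(tgt, sets, rownames(gene_counts))
    fs
  })
  write_tsv(figstats$shift_preference,
            file.path(config$out_dir, "shift_preference.tsv"))
  if (!is.null(figstats$ora))
    write_tsv(figstats$ora, file.path(config$out_dir, "ora.tsv"))

  ## -- recovery metrics ----------------------------------------------------
  recovery <- NULL
  if (!is.null(truth)) {
    planted <- c(setNames(rep("protective", length(truth$protective_keys)),
                          truth$protective_keys),
                 setNames(rep("harmful", length(truth$harmful_keys)),
                          truth$harmful_keys))
    tested <- intersect(names(planted), screen$label)
    called <- setNames(screen$class, screen$label)[tested]
    sign_acc <- if (length(tested))
      mean(called == planted[tested]) else NA_real_
    de_truth <- c(truth$de_up, truth$de_down)
    de_tested <- intersect(de_truth, de_iso$feature)
    de_called <- de_iso$feature[de_iso$direction != "ns"]
    de_power <- if (length(de_tested))
      mean(de_tested %in% de_called) else NA_real_
    false_calls <- setdiff(de_called, de_truth)
    de_fdr <- if (length(de_called))
      length(false_calls) / length(de_called) else 0
    gene_truth <- c(truth$gene_de_up, truth$gene_de_down)
    gene_called <- de_gene$feature[de_gene$direction != "ns"]
    gene_power <- mean(gene_truth %in% gene_called)
    true_id <- paste(truth$true_pairs$label, truth$true_pairs$gene)
    cons_id <- paste(cons$label, cons$gene)
    recovery <- list(
      survival_sign_accuracy = sign_acc,
      n_planted_tested = length(tested),
      de_power = de_power, de_fdr = de_fdr,
      de_gene_power = gene_power,
      consensus_recall = mean(true_id %in% cons_id),
      consensus_precision = if (length(cons_id))
        mean(cons_id %in% true_id) else NA_real_)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("isomiRSurv")),
    seed = config$seed,
    thresholds = config[c("alpha", "dead_fraction", "de_sig",
                          "min_support", "top_fraction", "z_threshold",
                          "min_degree", "min_overlap", "ties", "n_perm")],
    stage_counts = list(
      mature_records = nrow(ann),
      samples = nrow(mat$samples),
      isomir_keys = nrow(mat$keys),
      keys_after_epv = length(kept),
      keys_screened = nrow(screen),
      protective = sum(screen$class == "protective"),
      harmful = sum(screen$class == "harmful"),
      de_isomir_sig = sum(de_iso$direction != "ns"),
      de_gene_sig = sum(de_gene$direction != "ns"),
      consensus_pairs = nrow(cons),
      network_edges = if (is.null(network)) 0L else nrow(network$edges),
      network_selected = if (is.null(network)) 0L
      else nrow(network$selected)),
    recovery = recovery)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(matrix = mat, screen = screen, de_isomir = de_iso,
                 de_gene = de_gene, consensus_pairs = cons,
                 pair_classes = pair_cls, network = network,
                 figstats = figstats, recovery = recovery,
                 manifest = manifest))
}
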