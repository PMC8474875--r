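#' Simulate a complete synthetic cohort with planted ground truth
#'
#' Runs every generator in order — annotation, isoform quantification
#' tables, gene counts, clinical table, 3' UTRs with planted target sites,
#' predictor tables, gene sets — and assembles the merged ground truth.
#' With `dir` set, all inputs are written to disk in the formats the
#' pipeline parsers consume, alongside a JSON ground-truth manifest.
#' Byte-identical output for a fixed `config`.
#'
#' @param config a [sim_config()].
#' @param dir optional output directory (created if missing).
#' @return list of class `sim_dataset`: `config`, `ann`, `expr`,
#'   `gene_counts`, `clinical`, `utrs`, `predictions`, `gene_sets`, and
#'   `truth` (protective/harmful keys with planted betas, DE keys and
#'   genes, co-expression blocks, true target pairs).
#' @export
simulate_dataset <- function(config = sim_config(), dir = NULL) {
  ann <- generate_annotation(config)
  expr <- generate_isoform_files(config, ann)
  gc <- generate_gene_counts(config, expr$samples)
  clinical <- generate_clinical(config, expr)
  ut <- generate_utrs(config, ann, expr, rownames(gc$counts))
  truth <- expr$truth
  truth$true_pairs <- ut$true_pairs
  truth$gene_de_up <- gc$gene_de_up
  truth$gene_de_down <- gc$gene_de_down
  preds <- generate_predictions(truth, keys = expr$keys$label,
                                genes = rownames(gc$counts),
                                seed = config$seed)
  sets <- generate_gene_sets(config, rownames(gc$counts),
                             ut$true_pairs$gene)
  ds <- structure(
    list(config = config, ann = ann, expr = expr, gene_counts = gc$counts,
         clinical = clinical, utrs = ut$utrs, predictions = preds,
         gene_sets = sets, truth = truth),
    class = "sim_dataset")
  if (!is.null(dir)) write_sim_dataset(ds, dir)
  ds
}

#' Write a simulated dataset to disk in pipeline-consumable formats
#'
#' @param ds a `sim_dataset` from [simulate_dataset()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(ds, dir) {
  dir.create(file.path(dir, "isoforms"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "predictions"), showWarnings = FALSE)
  write_gff3(ds$ann, file.path(dir, "mirna.gff3"))
  write_seq_fasta(ds$ann$seqs, file.path(dir, "genome.fa"))
  for (s in names(ds$expr$files))
    write_tsv(ds$expr$files[[s]],
              file.path(dir, "isoforms",
                        paste0(s, ".isoforms.quantification.txt")))
  gcdf <- data.frame(gene_id = rownames(ds$gene_counts), ds$gene_counts,
                     check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(gcdf, file.path(dir, "gene_counts.tsv"))
  write_tsv(ds$clinical, file.path(dir, "clinical.tsv"))
  write_tsv(ds$expr$samples, file.path(dir, "samples.tsv"))
  write_seq_fasta(ds$utrs, file.path(dir, "utr.fa"))
  for (t in names(ds$predictions))
    write_tsv(ds$predictions[[t]],
              file.path(dir, "predictions", paste0(t, ".tsv")))
  write_gmt(ds$gene_sets, file.path(dir, "gene_sets.gmt"))
  manifest <- list(
    config = unclass(ds$config),
    truth = list(
      protective_keys = ds$truth$protective_keys,
      harmful_keys = ds$truth$harmful_keys,
      betas = as.list(ds$truth$betas),
      de_up = ds$truth$de_up, de_down = ds$truth$de_down,
      gene_de_up = ds$truth$gene_de_up, gene_de_down = ds$truth$gene_de_down,
      coexpr_blocks = as.list(ds$truth$coexpr_blocks),
      true_pairs = ds$truth$true_pairs
    ),
    notes = paste("isomiR counts are zero-inflated negative binomial;",
                  "the count distribution is a modelling assumption of the",
                  "generator, not an estimate from data.")
  )
  jsonlite::write_json(manifest, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
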