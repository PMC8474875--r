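## Target-prediction consensus and regulatory pair classification.  The
## external predictors themselves are ingested, never re-implemented; a
## canonical seed-matcher ships only as a synthetic test-fixture
## predictor.

#' Read a predictor pair table
#'
#' Minimal two-column dialect: isomiR label, gene id (extra columns such
#' as scores are ignored).  Transcript-style gene ids (`GENE.3`,
#' `GENE-201`-like suffixes) can be collapsed to the gene via
#' `strip_transcript`.
#'
#' @param path TSV with header; first two columns are label and gene.
#' @param strip_transcript drop a trailing `.N` transcript suffix.
#' @return data frame `label`, `gene`.
#' @export
read_prediction_table <- function(path, strip_transcript = TRUE) {
  df <- read_tsv(path)
  if (ncol(df) < 2L)
    stopf("read_prediction_table: '%s' needs at least 2 columns", path)
  out <- data.frame(label = as.character(df[[1]]),
                    gene = as.character(df[[2]]),
                    stringsAsFactors = FALSE)
  parse_isomir_label(out$label)  # validates the label syntax
  if (strip_transcript) out$gene <- sub("\\.[0-9]+$", "", out$gene)
  unique(out)
}

#' Consensus of multiple target-predictor tables
#'
#' Keeps the (isomiR, gene) pairs predicted by at least `min_support`
#' tools.  Raising `min_support` can only shrink the result.
#'
#' @param tables named list of data frames (`label`, `gene`), one per
#'   tool; names must be unique.
#' @param min_support minimum number of supporting tools, default 3.
#' @return data frame `label`, `gene`, `support`, sorted by label then
#'   gene.
#' @export
consensus <- function(tables, min_support = 3L) {
  stopifnot(is.list(tables), length(tables) >= 1L)
  if (is.null(names(tables)) || anyDuplicated(names(tables)))
    stopf("consensus: tables must carry unique tool names")
  if (min_support > length(tables))
    stopf("consensus: min_support (%d) exceeds the number of tables (%d)",
          min_support, length(tables))
  ids <- unlist(lapply(tables, function(t)
    unique(paste(t$label, t$gene, sep = "\r"))), use.names = FALSE)
  tab <- table(ids)
  keep <- names(tab)[tab >= min_support]
  if (length(keep) == 0L)
    return(data.frame(label = character(), gene = character(),
                      support = integer(), stringsAsFactors = FALSE))
  parts <- strsplit(keep, "\r", fixed = TRUE)
  out <- data.frame(label = vapply(parts, `[`, "", 1L),
                    gene = vapply(parts, `[`, "", 2L),
                    support = as.integer(tab[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$label, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify consensus pairs by DE direction and survival class
#'
#' Crosses each (isomiR, gene) pair with the isomiR differential
#' expression call, the gene differential expression call, and the
#' isomiR's survival class.  The biologically coherent repression
#' patterns are `upIso_downGene` (isomiR up, target down) and
#' `downIso_upGene`; everything else is `other`.  Pairs whose isomiR or
#' gene is missing from the supplied results land in an `unresolved` bin.
#'
#' @param pairs data frame `label`, `gene` (e.g. from [consensus()]).
#' @param isomir_de [moderated_t()] result for isomiRs.
#' @param gene_de [moderated_t()] result for genes.
#' @param survival [cox_screen()] result (`label`, `class`).
#' @return `pairs` with columns `iso_dir`, `gene_dir`, `surv_class`,
#'   `pair_class`; a `counts` attribute tabulates pair_class within each
#'   survival class.
#' @export
classify_target_pairs <- function(pairs, isomir_de, gene_de, survival) {
  iso_dir <- isomir_de$direction[match(pairs$label, isomir_de$feature)]
  gene_dir <- gene_de$direction[match(pairs$gene, gene_de$feature)]
  surv <- survival$class[match(pairs$label, survival$label)]
  pair_class <- ifelse(is.na(iso_dir) | is.na(gene_dir) | is.na(surv),
                       "unresolved",
                       ifelse(iso_dir == "up" & gene_dir == "down",
                              "upIso_downGene",
                              ifelse(iso_dir == "down" & gene_dir == "up",
                                     "downIso_upGene", "other")))
  out <- cbind(pairs,
               data.frame(iso_dir = iso_dir, gene_dir = gene_dir,
                          surv_class = surv, pair_class = pair_class,
                          stringsAsFactors = FALSE))
  attr(out, "counts") <- as.data.frame(
    table(surv_class = ifelse(is.na(surv), "unresolved", surv),
          pair_class = pair_class),
    stringsAsFactors = FALSE)
  out
}

#' Canonical seed-match fixture predictor
#'
#' Scans 3' UTR sequences for canonical sites complementary to each
#' isomiR's seed (positions 2-8): 8mer (perfect match to seed 2-8 plus a
#' 3'-A opposite position 1), 7mer-m8 (match to 2-8), and 7mer-A1 (match
#' to 2-7 plus the A).  This is a deliberately simple stand-in predictor
#' for tests and simulations — not a re-implementation of any published
#' target predictor, and never compared against their outputs.
#'
#' @param iso_seqs named character vector of isomiR sequences (RNA or
#'   DNA alphabet), names are isomiR labels.
#' @param utrs named character vector of 3' UTR sequences.
#' @return data frame `label`, `gene`, `site` (best site type found).
#' @export
seed_match_predict <- function(iso_seqs, utrs) {
  utrs_rna <- chartr("Tt", "Uu", toupper(utrs))
  bad <- grepl("[^ACGU]", utrs_rna)
  if (any(bad))
    stopf("seed_match_predict: non-ACGU characters in UTR '%s'",
          names(utrs)[bad][1])
  rows <- list()
  for (lab in names(iso_seqs)) {
    s <- chartr("Tt", "Uu", toupper(iso_seqs[[lab]]))
    if (grepl("[^ACGU]", s))
      stopf("seed_match_predict: non-ACGU characters in sequence of '%s'",
            lab)
    seed <- seed_of(s)
    m28 <- chartr("Tt", "Uu", revcomp(seed))            # match to seed 2-8
    m27 <- chartr("Tt", "Uu", revcomp(substr(s, 2, 7))) # match to seed 2-7
    site8 <- paste0(m28, "A")
    site7a1 <- paste0(m27, "A")
    for (g in names(utrs_rna)) {
      u <- utrs_rna[[g]]
      site <- if (grepl(site8, u, fixed = TRUE)) "8mer"
      else if (grepl(m28, u, fixed = TRUE)) "7mer-m8"
      else if (grepl(site7a1, u, fixed = TRUE)) "7mer-A1"
      else NA_character_
      if (!is.na(site))
        rows[[length(rows) + 1L]] <- data.frame(
          label = lab, gene = g, site = site, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(label = character(), gene = character(),
                      site = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
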