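## Synthetic target structure: 3' UTR sequences with planted seed-match
## sites, noisy predictor tables, and gene-set collections.

#' Reverse complement of a nucleotide string (DNA or RNA input)
#' @noRd
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(
    chartr("Uu", "Tt", x))))
}

## Sequence of an isomiR key straight from the chromosome store:
## shifted 5' start, fixed length, reverse-complemented on '-'.
#' @noRd
key_sequence <- function(ann, accession, shift, len = MATURE_LEN) {
  m <- ann$matures[ann$matures$accession == accession, , drop = FALSE]
  if (nrow(m) == 0L) stopf("unknown accession '%s'", accession)
  chrom_seq <- ann$seqs[[m$chrom[1]]]
  if (m$strand[1] == "+") {
    s <- m$start[1] + shift
    dna <- substr(chrom_seq, s, s + len - 1L)
  } else {
    e <- m$end[1] - shift
    dna <- revcomp(substr(chrom_seq, e - len + 1L, e))
  }
  chartr("Tt", "Uu", dna)
}

#' Generate 3' UTR sequences with planted isomiR target sites
#'
#' Every protective/harmful key plus a random sample of other keys is
#' given `config$targets_per_key` target genes; an 8mer site (reverse
#' complement of seed positions 2-8 followed by A) for the key's seed is
#' written into each target gene's random-sequence UTR at a distinct,
#' non-overlapping position.
#'
#' @param config a [sim_config()].
#' @param ann annotation from [generate_annotation()].
#' @param expr `sim_expression` from [generate_isoform_files()].
#' @param genes character vector of gene ids (UTR per gene).
#' @return list with `utrs` (named character vector, DNA alphabet) and
#'   `true_pairs` (data frame `label`, `gene`).
#' @export
generate_utrs <- function(config, ann, expr, genes) {
  validate_sim_config(config)
  with_seed(child_seed(config$seed, 6L), {
    L <- config$utr_length
    utrs <- vapply(genes, function(g)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
      character(1))

    anchor <- union(expr$truth$protective_keys, expr$truth$harmful_keys)
    others <- setdiff(expr$keys$label, anchor)
    bearing <- c(anchor, sample(others, min(20L, length(others))))
    pairs <- do.call(rbind, lapply(bearing, function(lab) {
      data.frame(label = lab,
                 gene = sample(genes, config$targets_per_key),
                 stringsAsFactors = FALSE)
    }))

    # one non-overlapping 12-nt slot per site within each gene's UTR
    for (g in unique(pairs$gene)) {
      labs <- pairs$label[pairs$gene == g]
      slots <- sample(seq_len((L - 20L) %/% 12L), length(labs))
      for (i in seq_along(labs)) {
        p <- parse_isomir_label(labs[i])
        seq_rna <- key_sequence(ann, p$accession, p$shift)
        site <- paste0(revcomp(substr(seq_rna, 2L, 8L)), "A")
        pos <- (slots[i] - 1L) * 12L + 1L
        substr(utrs[[g]], pos, pos + 7L) <- site
      }
    }
    list(utrs = utrs, true_pairs = pairs[order(pairs$label, pairs$gene), ])
  })
}

#' Generate noisy target-predictor tables from planted pairs
#'
#' Each simulated tool reports every true pair with probability equal to
#' its sensitivity and every non-true pair of the (key x gene) universe
#' with probability `1 - specificity`.
#'
#' @param truth list carrying `true_pairs` (data frame `label`, `gene`).
#' @param keys character vector: isomiR-label universe.
#' @param genes character vector: gene universe.
#' @param n_tools number of simulated predictors.
#' @param sensitivity,specificity per-tool probabilities (recycled to
#'   `n_tools`).
#' @param seed RNG seed.
#' @return named list of `n_tools` data frames (`label`, `gene`).
#' @export
generate_predictions <- function(truth, keys, genes, n_tools = 4L,
                                 sensitivity = c(0.9, 0.85, 0.8, 0.9),
                                 specificity = 0.999, seed = 1L) {
  stopifnot(n_tools >= 1L)
  sensitivity <- rep_len(sensitivity, n_tools)
  specificity <- rep_len(specificity, n_tools)
  true_id <- paste(truth$true_pairs$label, truth$true_pairs$gene, sep = "\r")
  with_seed(child_seed(seed, 4L), {
    all_id <- as.vector(outer(keys, genes, paste, sep = "\r"))
    false_id <- setdiff(all_id, true_id)
    out <- lapply(seq_len(n_tools), function(t) {
      keep_t <- true_id[runif(length(true_id)) < sensitivity[t]]
      keep_f <- false_id[runif(length(false_id)) < (1 - specificity[t])]
      ids <- sort(c(keep_t, keep_f))
      parts <- strsplit(ids, "\r", fixed = TRUE)
      data.frame(label = vapply(parts, `[`, "", 1L),
                 gene = vapply(parts, `[`, "", 2L),
                 stringsAsFactors = FALSE)
    })
    names(out) <- paste0("tool", LETTERS[seq_len(n_tools)])
    out
  })
}

#' Generate a synthetic gene-set collection
#'
#' Twelve sets: one deliberately loaded with planted target genes (so
#' over-representation is recoverable) and eleven random filler sets.
#'
#' @param config a [sim_config()].
#' @param genes gene universe.
#' @param target_genes genes participating in planted target pairs.
#' @return named list of character vectors.
#' @export
generate_gene_sets <- function(config, genes, target_genes) {
  with_seed(child_seed(config$seed, 7L), {
    target_genes <- intersect(unique(target_genes), genes)
    n_hit <- min(length(target_genes), 30L)
    loaded <- unique(c(sample(target_genes, n_hit),
                       sample(genes, 10L)))
    sets <- c(list(PLANTED_TARGET_PROGRAM = sort(loaded)),
              lapply(seq_len(11L), function(i) sort(sample(genes, 25L))))
    names(sets)[-1L] <- sprintf("RANDOM_SET_%02d", seq_len(11L))
    sets
  })
}
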