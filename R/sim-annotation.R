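## Synthetic miRBase-style annotation: hairpin + mature records on both
## strands, plus the genome-like sequence store that backs them.

HAIRPIN_LEN <- 80L
MATURE_LEN <- 22L
ARM_MARGIN <- 8L   # room inside the hairpin for 5' shifts and 3' extension
HAIRPIN_GAP <- 120L

#' Generate a synthetic miRBase-style annotation
#'
#' Lays out `n_hairpins` hairpin loci (alternating strand) over a few
#' synthetic chromosomes and places one or two 22-nt mature miRNAs inside
#' each, every mature carrying a MIMAT-style accession.  Random nucleotide
#' sequence is generated for each chromosome so that any isomiR sequence
#' under a hairpin can be reconstructed.  Deterministic given
#' `config$seed`.
#'
#' @param config a [sim_config()].
#' @return a list of class `sim_annotation` with elements `hairpins` and
#'   `matures` (data frames of 1-based inclusive coordinates), and `seqs`,
#'   a named character vector of chromosome sequences.
#' @export
generate_annotation <- function(config) {
  validate_sim_config(config)
  if (config$mature_per_hairpin * MATURE_LEN + 2L * ARM_MARGIN > HAIRPIN_LEN)
    stopf("generate_annotation: %d mature arms do not fit in a %d nt hairpin",
          config$mature_per_hairpin, HAIRPIN_LEN)
  with_seed(child_seed(config$seed, 1L), {
    n <- config$n_hairpins
    n_chrom <- max(1L, min(5L, ceiling(n / 8)))
    chrom <- paste0("chr", ((seq_len(n) - 1L) %% n_chrom) + 1L)
    idx_on_chrom <- ave(seq_len(n), chrom, FUN = seq_along)
    start <- HAIRPIN_GAP + (idx_on_chrom - 1L) * (HAIRPIN_LEN + HAIRPIN_GAP)
    end <- start + HAIRPIN_LEN - 1L
    strand <- ifelse(seq_len(n) %% 2L == 1L, "+", "-")
    hairpins <- data.frame(
      id = sprintf("MISIM%07d", seq_len(n)),
      name = sprintf("hsa-mir-sim%d", seq_len(n)),
      chrom = chrom, start = start, end = end, strand = strand,
      stringsAsFactors = FALSE
    )

    matures <- do.call(rbind, lapply(seq_len(n), function(i) {
      arms <- seq_len(config$mature_per_hairpin)
      ms <- me <- integer(length(arms))
      # 5p arm sits near the hairpin 5' end, 3p arm near the 3' end
      ms[1] <- start[i] + ARM_MARGIN
      me[1] <- ms[1] + MATURE_LEN - 1L
      if (length(arms) > 1L) {
        me[2] <- end[i] - ARM_MARGIN
        ms[2] <- me[2] - MATURE_LEN + 1L
      }
      arm_tag <- if (strand[i] == "+") c("5p", "3p") else c("3p", "5p")
      data.frame(
        accession = sprintf("MIMAT0%06d", (i - 1L) * 2L + arms),
        name = sprintf("hsa-miR-sim%d-%s", i, arm_tag[arms]),
        chrom = chrom[i], start = ms[arms], end = me[arms],
        strand = strand[i], hairpin_id = hairpins$id[i],
        stringsAsFactors = FALSE
      )
    }))
    rownames(matures) <- NULL

    chrom_len <- vapply(split(end, chrom), function(e) max(e) + HAIRPIN_GAP,
                        numeric(1))
    seqs <- vapply(names(chrom_len), function(cn) {
      paste(sample(c("A", "C", "G", "T"), chrom_len[[cn]], replace = TRUE),
            collapse = "")
    }, character(1))

    structure(list(hairpins = hairpins, matures = matures, seqs = seqs),
              class = "sim_annotation")
  })
}

#' Write an annotation as a miRBase-dialect GFF3 file
#'
#' Emits `miRNA_primary_transcript` rows for hairpins and `miRNA` rows
#' (with `Derives_from` parent links) for matures, 1-based inclusive
#' coordinates.  Output is byte-stable for a given annotation.
#'
#' @param ann a `sim_annotation` (or any list with `hairpins`/`matures`
#'   data frames of the same shape).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(ann, path) {
  h <- ann$hairpins
  m <- ann$matures
  lines <- c("##gff-version 3",
             "# synthetic miRNA annotation (miRBase dialect)")
  for (i in seq_len(nrow(h))) {
    lines <- c(lines, paste(
      h$chrom[i], ".", "miRNA_primary_transcript", h$start[i], h$end[i], ".",
      h$strand[i], ".",
      sprintf("ID=%s;Alias=%s;Name=%s", h$id[i], h$id[i], h$name[i]),
      sep = "\t"))
    mi <- m[m$hairpin_id == h$id[i], , drop = FALSE]
    for (j in seq_len(nrow(mi))) {
      lines <- c(lines, paste(
        mi$chrom[j], ".", "miRNA", mi$start[j], mi$end[j], ".",
        mi$strand[j], ".",
        sprintf("ID=%s;Alias=%s;Name=%s;Derives_from=%s",
                mi$accession[j], mi$accession[j], mi$name[j], h$id[i]),
        sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write the chromosome sequence store as FASTA
#'
#' @param seqs named character vector of chromosome sequences.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_seq_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Read a sequence store from FASTA
#'
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
read_seq_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}
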