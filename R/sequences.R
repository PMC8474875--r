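## isomiR sequence reconstruction and the seed region.

#' Reconstruct the nucleotide sequence of an isomiR key
#'
#' The sequence runs from the key's shifted 5' start to the furthest 3'
#' genomic extent observed for that key in the whole dataset (`max3p`
#' recorded by [build_matrix()]), reverse-complemented for minus-strand
#' keys, and returned in the RNA alphabet.
#'
#' @param key isomiR label (`"accession|shift"`).
#' @param mat an `isomir_matrix` (provides `max3p`).
#' @param annotation mature-record data frame from [parse_gff3()].
#' @param seqs named character vector of chromosome sequences
#'   (see [read_seq_fasta()]).
#' @return RNA sequence string (5' to 3').
#' @export
isomir_sequence <- function(key, mat, annotation, seqs) {
  i <- match(key, mat$keys$label)
  if (is.na(i)) stopf("isomir_sequence: key '%s' never observed", key)
  k <- mat$keys[i, ]
  a <- annotation[annotation$accession == k$accession &
                    annotation$chrom == k$chrom &
                    annotation$strand == k$strand, , drop = FALSE]
  if (nrow(a) == 0L)
    stopf("isomir_sequence: no annotation locus for '%s'", key)
  chrom_seq <- seqs[[k$chrom]]
  if (is.null(chrom_seq))
    stopf("isomir_sequence: chromosome '%s' absent from sequence store",
          k$chrom)
  if (k$strand == "+") {
    s <- a$start[1] + k$shift
    dna <- substr(chrom_seq, s, k$max3p)
  } else {
    e <- a$end[1] - k$shift
    dna <- revcomp(substr(chrom_seq, k$max3p, e))
  }
  chartr("Tt", "Uu", dna)
}

#' Seed region of a miRNA sequence
#'
#' Nucleotides 2-8 (1-based) from the 5' end — the 7-nt determinant of
#' canonical target-site complementarity.  A 5' shift of the isomiR moves
#' this window, which is why 5' isomiRs can retarget.
#'
#' @param sequence nucleotide string of length >= 8.
#' @return 7-nt seed string.
#' @export
#' @examples
#' seed_of("UAGCUUAUCAGACUGAUGUUGA")  # "AGCUUAU"
seed_of <- function(sequence) {
  if (nchar(sequence) < 8L)
    stopf("seed_of: sequence shorter than 8 nt")
  substr(sequence, 2L, 8L)
}
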