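## Strand-aware 5'-shift calling and aggregation of isoform rows into the
## isomiR expression matrix.

#' Signed 5' shift of an isoform relative to its archetype
#'
#' The shift is the signed offset of the isoform's 5' start from the
#' archetype's 5' start, positive meaning downstream (into the miRNA
#' body), negative upstream.  On the plus strand the 5' start is the
#' lower genomic coordinate, so `shift = row_start - archetype_start`;
#' on the minus strand the 5' start is the higher coordinate, so
#' `shift = archetype_end - row_end`.
#'
#' @param archetype list or one-row data frame with `chrom`, `start`,
#'   `end`, `strand` (1-based inclusive).
#' @param row isoform row with the same fields.
#' @return integer shift in nucleotides.
#' @export
#' @examples
#' arch <- list(chrom = "chr1", start = 100, end = 121, strand = "+")
#' compute_shift(arch, list(chrom = "chr1", start = 98, end = 121,
#'                          strand = "+"))  # -2
compute_shift <- function(archetype, row) {
  if (archetype$chrom[1] != row$chrom[1])
    stopf("compute_shift: chromosome mismatch (%s vs %s)",
          archetype$chrom[1], row$chrom[1])
  if (archetype$strand[1] != row$strand[1])
    stopf("compute_shift: strand mismatch (%s vs %s)",
          archetype$strand[1], row$strand[1])
  if (archetype$strand[1] == "+")
    as.integer(row$start[1] - archetype$start[1])
  else
    as.integer(archetype$end[1] - row$end[1])
}

#' Aggregate per-sample isoform rows into an isomiR expression matrix
#'
#' Assigns each isoform row to its archetype locus (matching chromosome
#' and strand, overlapping the annotated interval when the accession maps
#' to several loci), computes the strand-aware 5' shift, and sums
#' `read_count` and RPM over rows sharing an (accession, shift) key within
#' a sample — 3' variants of the same 5' end collapse into one feature.
#' The furthest 3' genomic extent ever seen for each key across the whole
#' dataset is recorded (`max3p`) for later sequence reconstruction.
#'
#' Rows whose accession is absent from the annotation, maps only to a
#' different chromosome/strand, or is ambiguous across loci are skipped
#' and tallied in the skip report.
#'
#' @param tables named list (by sample id) of data frames from
#'   [read_isoform_file()].
#' @param annotation mature-record data frame from [parse_gff3()].
#' @param sample_info optional data frame (`sample`, `type`); by default
#'   the type is inferred from a trailing GDC sample-type code in the id
#'   (`-01` tumor, `-11` normal).
#' @return object of class `isomir_matrix`: list with `keys` (label,
#'   accession, shift, chrom, strand, max3p), `samples`, `counts` and
#'   `rpm` (keys x samples numeric matrices) and `skips` (per-sample skip
#'   counts).
#' @export
build_matrix <- function(tables, annotation, sample_info = NULL) {
  stopifnot(is.list(tables), !is.null(names(tables)))
  samples <- names(tables)
  acc_split <- split(seq_len(nrow(annotation)), annotation$accession)

  per_sample <- lapply(samples, function(s) {
    df <- tables[[s]]
    n <- nrow(df)
    shift <- rep(NA_integer_, n)
    skip <- character(n)
    end5 <- integer(n)
    for (r in seq_len(n)) {
      loci <- acc_split[[df$accession[r]]]
      if (is.null(loci)) { skip[r] <- "unknown_accession"; next }
      a <- annotation[loci, , drop = FALSE]
      ok <- a$chrom == df$chrom[r] & a$strand == df$strand[r] &
        a$start <= df$end[r] & a$end >= df$start[r]
      if (sum(ok) == 0L) { skip[r] <- "cross_mapped"; next }
      if (sum(ok) > 1L) { skip[r] <- "ambiguous_locus"; next }
      ai <- a[ok, , drop = FALSE]
      shift[r] <- compute_shift(ai, df[r, , drop = FALSE])
    }
    list(df = df, shift = shift, skip = skip)
  })
  names(per_sample) <- samples

  all_rows <- do.call(rbind, lapply(samples, function(s) {
    ps <- per_sample[[s]]
    keep <- is.na(ps$skip) | ps$skip == ""
    keep <- keep & !is.na(ps$shift)
    df <- ps$df[keep, , drop = FALSE]
    if (nrow(df) == 0L) return(NULL)
    data.frame(sample = s,
               label = isomir_label(df$accession, ps$shift[keep]),
               accession = df$accession, shift = ps$shift[keep],
               chrom = df$chrom, strand = df$strand,
               start = df$start, end = df$end,
               read_count = df$read_count, rpm = df$rpm,
               stringsAsFactors = FALSE)
  }))
  if (is.null(all_rows))
    stopf("build_matrix: no assignable isoform rows")

  key_order <- sort(unique(all_rows$label))
  all_rows$li <- match(all_rows$label, key_order)
  all_rows$si <- match(all_rows$sample, samples)
  nk <- length(key_order); ns <- length(samples)
  counts <- matrix(0, nk, ns, dimnames = list(key_order, samples))
  rpm <- matrix(0, nk, ns, dimnames = list(key_order, samples))
  idx <- cbind(all_rows$li, all_rows$si)
  for (r in seq_len(nrow(all_rows))) {
    counts[idx[r, 1], idx[r, 2]] <- counts[idx[r, 1], idx[r, 2]] +
      all_rows$read_count[r]
    rpm[idx[r, 1], idx[r, 2]] <- rpm[idx[r, 1], idx[r, 2]] + all_rows$rpm[r]
  }

  # furthest 3' extent per key: highest end on '+', lowest start on '-'
  plus <- all_rows$strand == "+"
  ext <- ifelse(plus, all_rows$end, -all_rows$start)
  max_ext <- tapply(ext, all_rows$li, max)
  first <- !duplicated(all_rows$li)
  km <- all_rows[first, c("label", "accession", "shift", "chrom", "strand"),
                 drop = FALSE]
  km <- km[order(km$label), , drop = FALSE]
  stopifnot(identical(km$label, key_order))
  km$max3p <- as.integer(ifelse(km$strand == "+",
                                max_ext[as.character(seq_len(nk))],
                                -max_ext[as.character(seq_len(nk))]))
  rownames(km) <- NULL

  if (is.null(sample_info)) {
    code <- sub("^.*-([0-9]{2})$", "\\1", samples)
    sample_info <- data.frame(
      sample = samples,
      type = ifelse(code %in% c("10", "11", "12", "13", "14"),
                    "normal", "tumor"),
      stringsAsFactors = FALSE)
  }
  skips <- do.call(rbind, lapply(samples, function(s) {
    sk <- per_sample[[s]]$skip
    sk <- sk[nzchar(sk)]
    if (length(sk) == 0L) return(NULL)
    as.data.frame(table(sample = s, reason = sk), stringsAsFactors = FALSE)
  }))
  structure(list(keys = km, samples = sample_info,
                 counts = counts, rpm = rpm,
                 skips = if (is.null(skips)) data.frame() else skips),
            class = "isomir_matrix")
}

#' @export
print.isomir_matrix <- function(x, ...) {
  cat("isomir_matrix:", nrow(x$keys), "isomiR keys x",
      nrow(x$samples), "samples (",
      sum(x$samples$type == "tumor"), "tumor /",
      sum(x$samples$type == "normal"), "normal )\n")
  invisible(x)
}

#' Write an isomiR matrix (counts and RPM) as TSV files
#'
#' @param mat an `isomir_matrix`.
#' @param prefix output path prefix; writes `<prefix>_counts.tsv`,
#'   `<prefix>_rpm.tsv`, `<prefix>_keys.tsv`.
#' @return `prefix`, invisibly.
#' @export
write_isomir_matrix <- function(mat, prefix) {
  cdf <- data.frame(label = rownames(mat$counts), mat$counts,
                    check.names = FALSE)
  rdf <- data.frame(label = rownames(mat$rpm), mat$rpm, check.names = FALSE)
  write_tsv(cdf, paste0(prefix, "_counts.tsv"))
  write_tsv(rdf, paste0(prefix, "_rpm.tsv"))
  write_tsv(mat$keys, paste0(prefix, "_keys.tsv"))
  invisible(prefix)
}
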