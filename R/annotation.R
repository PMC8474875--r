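## Parsers for the miRBase-style GFF3 annotation and GDC-style isoform
## quantification tables, plus the sample-manifest cleaning rules.

#' Parse mature miRNA records from a miRBase-dialect GFF3 file
#'
#' Returns only `miRNA` rows, each linked to its parent hairpin
#' (`miRNA_primary_transcript`) through the `Derives_from` attribute.
#' Coordinates are kept 1-based inclusive as in the file.  A mature
#' record without a resolvable parent is retained with `hairpin_id = NA`
#' and a warning.
#'
#' @param path GFF3 file path.
#' @param mapping optional two-column data frame (`old`, `new`) renaming
#'   accessions, e.g. for a miRBase version lift-over.  Identity by
#'   default.
#' @return data frame with columns `accession`, `name`, `chrom`, `start`,
#'   `end`, `strand`, `hairpin_id`.
#' @export
parse_gff3 <- function(path, mapping = NULL) {
  if (!file.exists(path)) stopf("parse_gff3: no such file '%s'", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  idx <- which(keep)
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  nfield <- vapply(parts, length, 1L)
  if (any(nfield != 9L))
    stopf("parse_gff3: line %d has %d columns, expected 9",
          idx[which(nfield != 9L)[1]], nfield[nfield != 9L][1])
  if (length(parts) == 0L)
    return(data.frame(accession = character(), name = character(),
                      chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      hairpin_id = character(), stringsAsFactors = FALSE))
  type <- vapply(parts, `[`, "", 3L)
  attr_field <- vapply(parts, `[`, "", 9L)
  get_attr <- function(attrs, key) {
    m <- regmatches(attrs, regexec(paste0("(^|;)", key, "=([^;]*)"), attrs))
    vapply(m, function(x) if (length(x) == 3L) x[3] else NA_character_, "")
  }
  id <- get_attr(attr_field, "ID")
  nm <- get_attr(attr_field, "Name")
  hp_ids <- id[type == "miRNA_primary_transcript"]

  mi <- type == "miRNA"
  out <- data.frame(
    accession = id[mi],
    name = nm[mi],
    chrom = vapply(parts[mi], `[`, "", 1L),
    start = as.integer(vapply(parts[mi], `[`, "", 4L)),
    end = as.integer(vapply(parts[mi], `[`, "", 5L)),
    strand = vapply(parts[mi], `[`, "", 7L),
    hairpin_id = get_attr(attr_field[mi], "Derives_from"),
    stringsAsFactors = FALSE
  )
  orphan <- !is.na(out$hairpin_id) & !(out$hairpin_id %in% hp_ids)
  orphan <- orphan | is.na(out$hairpin_id)
  if (any(orphan)) {
    warnf("parse_gff3: %d mature record(s) without a resolvable parent",
          sum(orphan))
    out$hairpin_id[orphan] <- NA_character_
  }
  if (!is.null(mapping)) {
    i <- match(out$accession, mapping$old)
    out$accession[!is.na(i)] <- mapping$new[i[!is.na(i)]]
  }
  rownames(out) <- NULL
  out
}

#' Parse GDC-style genomic region strings
#'
#' Accepts `"assembly:chrom:start-end:strand"` with the leading assembly
#' token optional (`"hg38:chr1:100-121:+"` or `"chr1:100-121:+"`).
#'
#' @param x character vector of region strings.
#' @return data frame with `chrom`, `start`, `end`, `strand`.
#' @export
parse_region <- function(x) {
  m <- regmatches(x, regexec(
    "^(?:[A-Za-z0-9_.]+:)?(chr[^:]+|[^:]+):([0-9]+)-([0-9]+):([+-])$", x))
  bad <- vapply(m, length, 1L) != 5L
  if (any(bad))
    stopf("parse_region: malformed region string '%s'", x[bad][1])
  data.frame(
    chrom = vapply(m, `[`, "", 2L),
    start = as.integer(vapply(m, `[`, "", 3L)),
    end = as.integer(vapply(m, `[`, "", 4L)),
    strand = vapply(m, `[`, "", 5L),
    stringsAsFactors = FALSE
  )
}

#' Read one GDC-style isoform quantification table
#'
#' Keeps mature-region rows (`miRNA_region` of the form
#' `"mature,<accession>"`); other region classes (precursor, stemloop,
#' unannotated) are dropped and counted.
#'
#' @param path tab-separated file with header; must contain
#'   `isoform_coords`, `read_count`, `reads_per_million_miRNA_mapped` and
#'   `miRNA_region` columns.
#' @param mapping optional accession-renaming table as in [parse_gff3()].
#' @return data frame `accession`, `chrom`, `start`, `end`, `strand`,
#'   `read_count`, `rpm`, with attribute `n_dropped` (non-mature rows).
#' @export
read_isoform_file <- function(path, mapping = NULL) {
  df <- read_tsv(path)
  need <- c("isoform_coords", "read_count",
            "reads_per_million_miRNA_mapped", "miRNA_region")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopf("read_isoform_file: '%s' lacks column(s) %s", path,
          paste(miss, collapse = ", "))
  mature <- grepl("^mature,", df$miRNA_region)
  n_dropped <- sum(!mature)
  df <- df[mature, , drop = FALSE]
  reg <- parse_region(df$isoform_coords)
  out <- data.frame(
    accession = sub("^mature,", "", df$miRNA_region),
    reg,
    read_count = as.numeric(df$read_count),
    rpm = as.numeric(df$reads_per_million_miRNA_mapped),
    stringsAsFactors = FALSE
  )
  if (!is.null(mapping)) {
    i <- match(out$accession, mapping$old)
    out$accession[!is.na(i)] <- mapping$new[i[!is.na(i)]]
  }
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Clean a file manifest by the cohort inclusion rules
#'
#' Applies, in order: (1) drop files carrying an annotation flag,
#' (2) drop recurrent-tumor files, (3) keep a single file per participant
#' and sample type, the first by sorted file id.
#'
#' @param manifest data frame with columns `file_id`, `participant`,
#'   `sample_type`, and logical `annotated`.
#' @param recurrent_types sample-type labels treated as recurrent tumors.
#' @return the cleaned manifest, with a `report` attribute (data frame of
#'   counts removed per rule).
#' @export
filter_samples <- function(manifest,
                           recurrent_types = "Recurrent Solid Tumor") {
  stopifnot(all(c("file_id", "participant", "sample_type", "annotated")
                %in% names(manifest)))
  n0 <- nrow(manifest)
  m <- manifest[!manifest$annotated, , drop = FALSE]
  n_ann <- n0 - nrow(m)
  m2 <- m[!(m$sample_type %in% recurrent_types), , drop = FALSE]
  n_rec <- nrow(m) - nrow(m2)
  m2 <- m2[order(m2$file_id), , drop = FALSE]
  dup <- duplicated(m2[, c("participant", "sample_type")])
  n_dup <- sum(dup)
  out <- m2[!dup, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "report") <- data.frame(
    rule = c("annotation_flag", "recurrent_tumor", "duplicate_participant"),
    removed = c(n_ann, n_rec, n_dup),
    stringsAsFactors = FALSE
  )
  out
}
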