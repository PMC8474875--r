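## Internal helpers shared across modules.

#' @noRd
geomean <- function(x) exp(mean(log(x)))

## Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

## Derive a stream-specific child seed below 2^31 from a master seed.
#' @noRd
child_seed <- function(seed, stream) {
  (as.numeric(seed) * 7919 + stream * 104729) %% 2147483647
}

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Write a data frame as a tab-separated file with header
#' @noRd
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @noRd
read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE, ...)
}

#' Render an isomiR label
#'
#' An isomiR is identified by its archetype accession and the signed 5'
#' shift; the archetype itself carries shift 0 (e.g. `"MIMAT0000062|0"`,
#' `"MIMAT0000062|-2"`).
#'
#' @param accession mature miRNA accession (MIMAT-style id).
#' @param shift signed integer 5' shift in nucleotides.
#' @return character label `"accession|shift"`.
#' @export
#' @examples
#' isomir_label("MIMAT0000062", -2)
isomir_label <- function(accession, shift) {
  stopifnot(is.numeric(shift), shift == round(shift))
  paste0(accession, "|", as.integer(shift))
}

#' Parse an isomiR label into accession and shift
#'
#' @param label character vector of `"accession|shift"` labels.
#' @return data frame with columns `accession` and `shift`.
#' @export
parse_isomir_label <- function(label) {
  m <- regmatches(label, regexec("^(.+)\\|(-?[0-9]+)$", label))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad))
    stopf("malformed isomiR label(s): %s", paste(label[bad], collapse = ", "))
  data.frame(
    accession = vapply(m, `[`, "", 2L),
    shift = as.integer(vapply(m, `[`, "", 3L)),
    stringsAsFactors = FALSE
  )
}

#' Jaccard index of two sets
#'
#' \eqn{|A \cap B| / |A \cup B|}; defined as 0 for two empty sets (a
#' message is emitted because the ratio is formally 0/0).
#'
#' @param a,b vectors treated as sets.
#' @return numeric scalar in `[0, 1]`.
#' @export
#' @examples
#' jaccard(1:4, 3:6)
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) {
    message("jaccard of two empty sets: returning 0 by convention")
    return(0)
  }
  length(intersect(a, b)) / u
}
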