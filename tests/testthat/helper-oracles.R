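# Independent oracles shared across test files.

# Cox partial likelihood written out directly (product over event times,
# no ties assumed), maximised on a bounded interval.
brute_force_cox_beta <- function(x, time, event) {
  pl <- function(beta) {
    ll <- 0
    for (i in which(event == 1)) {
      risk <- which(time >= time[i])
      ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
    }
    ll
  }
  optimize(pl, c(-30, 30), maximum = TRUE, tol = 1e-10)$maximum
}

# Reverse complement without Biostrings (sequence-level shift oracle).
rc_chr <- function(s) {
  paste(rev(strsplit(chartr("ACGTU", "TGCAA", s), "")[[1]]), collapse = "")
}

# Midranks computed from first principles (sort + tie averaging), kept
# independent of base rank().
midrank <- function(v) {
  o <- order(v)
  r <- numeric(length(v))
  i <- 1
  while (i <= length(v)) {
    j <- i
    while (j < length(v) && v[o[j + 1]] == v[o[i]]) j <- j + 1
    r[o[i:j]] <- mean(i:j)
    i <- j + 1
  }
  r
}
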