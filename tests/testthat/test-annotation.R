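# GFF3/quantification parsing, strand-aware shift calling, aggregation,
# sequence reconstruction, manifest cleaning.

test_that("parse_gff3 reads mature records and flags malformed input", {
  f <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\t.\tmiRNA_primary_transcript\t100\t180\t.\t+\t.\tID=MI1;Name=hp1",
    "chr1\t.\tmiRNA\t110\t131\t.\t+\t.\tID=MIMAT1;Name=m1;Derives_from=MI1",
    "chr1\t.\tmiRNA\t150\t171\t.\t+\t.\tID=MIMAT2;Name=m2;Derives_from=MI1",
    "chr2\t.\tmiRNA\t50\t71\t.\t-\t.\tID=MIMAT3;Name=m3;Derives_from=MI9"),
    f)
  expect_warning(recs <- parse_gff3(f), "parent")
  expect_identical(nrow(recs), 3L)
  expect_identical(recs$strand, c("+", "+", "-"))
  expect_identical(recs$hairpin_id, c("MI1", "MI1", NA_character_))
  expect_true(all(recs$start <= recs$end))

  # empty file -> empty frame
  f0 <- tempfile(); writeLines("##gff-version 3", f0)
  expect_identical(nrow(parse_gff3(f0)), 0L)

  # malformed column count -> error naming the line
  fb <- tempfile()
  writeLines(c("##gff-version 3", "chr1\tmiRNA\t100"), fb)
  expect_error(parse_gff3(fb), "line 2")

  # accession mapping applied
  mp <- data.frame(old = "MIMAT1", new = "MIMAT0099999")
  expect_true("MIMAT0099999" %in% parse_gff3(f, mp)$accession |> suppressWarnings())
})

test_that("parse_gff3 round-trips the generator's annotation", {
  ds <- small_ds()
  recs <- parse_gff3(file.path(small_dir(), "mirna.gff3"))
  m <- ds$ann$matures
  expect_identical(recs$accession, m$accession)
  expect_identical(recs$start, m$start)
  expect_identical(recs$end, m$end)
  expect_identical(recs$strand, m$strand)
  expect_identical(recs$hairpin_id, m$hairpin_id)
})

test_that("parse_region tolerates a leading assembly token", {
  r <- parse_region(c("hg38:chr1:100-121:+", "chr2:5-30:-"))
  expect_identical(r$chrom, c("chr1", "chr2"))
  expect_identical(r$start, c(100L, 5L))
  expect_identical(r$end, c(121L, 30L))
  expect_identical(r$strand, c("+", "-"))
  expect_error(parse_region("chr1:100-121"), "malformed")
})

test_that("compute_shift follows the strand-aware subtraction rule", {
  ann <- toy_annotation()
  plus <- as.list(ann[1, ])
  minus <- as.list(ann[2, ])

  # plus strand, isoform 5' start two nt upstream -> -2
  expect_identical(
    compute_shift(plus, list(chrom = "chr1", start = 98, end = 121,
                             strand = "+")), -2L)
  # identity
  expect_identical(compute_shift(plus, plus), 0L)
  expect_identical(compute_shift(minus, minus), 0L)
  # minus strand: 5' end is the higher coordinate
  expect_identical(
    compute_shift(minus, list(chrom = "chr2", start = 295, end = 317,
                              strand = "-")), 4L)
  # mismatches are errors (rows get skipped upstream)
  expect_error(compute_shift(plus, list(chrom = "chr9", start = 98,
                                        end = 121, strand = "+")),
               "chromosome")
  expect_error(compute_shift(plus, list(chrom = "chr1", start = 98,
                                        end = 121, strand = "-")),
               "strand")
})

test_that("compute_shift is self-inverse for coordinate reconstruction", {
  set.seed(4)
  for (i in 1:50) {
    strand <- sample(c("+", "-"), 1)
    a <- list(chrom = "chrT", start = sample(1000, 1), strand = strand)
    a$end <- a$start + 21L
    k <- sample(-5:5, 1)
    if (strand == "+") row <- list(chrom = "chrT", start = a$start + k,
                                   end = a$start + k + 21L, strand = strand)
    else row <- list(chrom = "chrT", start = a$end - k - 21L,
                     end = a$end - k, strand = strand)
    expect_identical(compute_shift(a, row), as.integer(k))
    # applying the shift to the archetype 5' coordinate reproduces the
    # observed isoform 5' coordinate
    if (strand == "+") expect_identical(a$start + k, row$start)
    else expect_identical(a$end - k, row$end)
  }
})

test_that("build_matrix aggregates 3' variants and conserves read mass", {
  ann <- toy_annotation()
  tab <- data.frame(
    accession = c("MIMAT0000062", "MIMAT0000062", "MIMAT0000062",
                  "MIMATMINUS01"),
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    start = c(100L, 100L, 98L, 295L),
    end = c(121L, 123L, 119L, 317L),
    strand = c("+", "+", "+", "-"),
    read_count = c(5, 7, 3, 11),
    rpm = c(50, 70, 30, 110), stringsAsFactors = FALSE)
  mat <- build_matrix(list(s1 = tab), ann)
  # two rows with the same key (different 3' ends) collapse: 5 + 7 = 12
  expect_equal(mat$counts["MIMAT0000062|0", "s1"], 12)
  expect_equal(mat$counts["MIMAT0000062|-2", "s1"], 3)
  expect_equal(mat$counts["MIMATMINUS01|4", "s1"], 11)
  # conservation of total read mass
  expect_equal(sum(mat$counts), sum(tab$read_count))
  expect_equal(sum(mat$rpm), sum(tab$rpm))
  # max3p is the furthest 3' extent: highest end on '+'
  expect_identical(mat$keys$max3p[mat$keys$label == "MIMAT0000062|0"], 123L)

  # unknown accession skipped and reported
  tab2 <- rbind(tab, data.frame(accession = "MIMATNOPE", chrom = "chr1",
                                start = 1L, end = 22L, strand = "+",
                                read_count = 99, rpm = 9))
  mat2 <- build_matrix(list(s1 = tab2), ann)
  expect_equal(sum(mat2$counts), sum(tab$read_count))
  expect_true("unknown_accession" %in% mat2$skips$reason)
})

test_that("minus-strand shifts verify at sequence level against the store", {
  ds <- small_ds()
  mat <- small_matrix()
  ann <- ds$ann
  minus <- mat$keys[mat$keys$strand == "-" & mat$keys$shift != 0, ]
  expect_gt(nrow(minus), 0)
  k <- minus[1, ]
  a <- ann$matures[ann$matures$accession == k$accession, ]
  seqs <- read_seq_fasta(file.path(small_dir(), "genome.fa"))
  iso <- isomir_sequence(k$label, mat, ann$matures, seqs)
  # independent oracle: reverse complement of the genomic slice
  slice <- substr(seqs[[k$chrom]], k$max3p, a$end - k$shift)
  oracle <- chartr("Tt", "Uu", as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(slice))))
  expect_identical(iso, oracle)
  # the isomiR 5' base sits |shift| nt away from the archetype 5' base
  arch <- isomir_sequence(isomir_label(k$accession, 0), mat, ann$matures,
                          seqs)
  if (k$shift > 0) expect_identical(substr(iso, 1, 8),
                                    substr(arch, 1 + k$shift, 8 + k$shift))
})

test_that("isomir_sequence string identities on the plus strand", {
  ann <- toy_annotation()
  set.seed(8)
  seqs <- c(chr1 = paste(sample(c("A", "C", "G", "T"), 200, TRUE),
                         collapse = ""))
  # archetype plus a +2-shifted isoform sharing the same 3' stop (121)
  tab <- data.frame(
    accession = "MIMAT0000062", chrom = "chr1",
    start = c(100L, 102L), end = c(121L, 121L), strand = "+",
    read_count = c(5, 5), rpm = c(50, 50), stringsAsFactors = FALSE)
  mat <- build_matrix(list(s1 = tab), ann[1, ])
  s0 <- isomir_sequence("MIMAT0000062|0", mat, ann, seqs)
  s2 <- isomir_sequence("MIMAT0000062|2", mat, ann, seqs)
  # shift 0 with max3p at the archetype 3' end -> archetype exactly
  expect_identical(s0, chartr("Tt", "Uu", substr(seqs[["chr1"]], 100, 121)))
  # shift +2, same 3' stop -> archetype minus its first 2 nt
  expect_identical(s2, substr(s0, 3, nchar(s0)))
  # seed invariant: the shift-0 key's seed is the archetype seed
  expect_identical(seed_of(s0),
                   chartr("Tt", "Uu", substr(seqs[["chr1"]], 101, 107)))
  expect_error(isomir_sequence("MIMATNOPE|0", mat, ann, seqs),
               "never observed")
})

test_that("seed_of returns positions 2-8 and shifts with the 5' end", {
  expect_identical(seed_of("UAGCUUAUCAGACUGAUGUUGA"), "AGCUUAU")
  s <- "UAGCUUAUCAGACUGAUGUUGA"
  s1 <- substr(s, 2, nchar(s))   # the +1 isomiR of the same archetype
  expect_identical(seed_of(s1), substr(s, 3, 9))
  set.seed(1)
  x <- paste(sample(c("A", "C", "G", "U"), 22, TRUE), collapse = "")
  expect_identical(seed_of(x), substr(x, 2, 8))
  expect_error(seed_of("ACGUACG"), "shorter")
})

test_that("filter_samples applies the three exclusion rules with a report", {
  man <- data.frame(
    file_id = sprintf("f%02d", 1:10),
    participant = c("P1", "P1", "P1", "P2", "P3", "P4", "P5", "P6", "P7",
                    "P8"),
    sample_type = c(rep("Primary Tumor", 9), "Recurrent Solid Tumor"),
    annotated = c(rep(FALSE, 8), TRUE, FALSE), stringsAsFactors = FALSE)
  out <- filter_samples(man)
  rep <- attr(out, "report")
  expect_identical(rep$removed[rep$rule == "annotation_flag"], 1L)
  expect_identical(rep$removed[rep$rule == "recurrent_tumor"], 1L)
  # P1 had three files: two duplicates dropped, first by sorted id kept
  expect_identical(rep$removed[rep$rule == "duplicate_participant"], 2L)
  expect_identical(out$file_id[out$participant == "P1"], "f01")
  expect_identical(nrow(out), 6L)

  # no exclusions -> unchanged
  clean <- data.frame(file_id = c("a", "b"), participant = c("X", "Y"),
                      sample_type = "Primary Tumor", annotated = FALSE)
  expect_identical(filter_samples(clean)$file_id, c("a", "b"))
})

test_that("isomiR labels render and parse round-trip", {
  expect_identical(isomir_label("MIMAT0000062", -2), "MIMAT0000062|-2")
  expect_identical(isomir_label("MIMAT0000062", 0), "MIMAT0000062|0")
  p <- parse_isomir_label(c("MIMAT0000062|-2", "MIMAT0000062|4"))
  expect_identical(p$shift, c(-2L, 4L))
  expect_error(parse_isomir_label("MIMAT62"), "malformed")
})
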