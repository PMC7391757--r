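test_that("FASTA round-trip preserves records for both alphabets and widths", {
  recs_nt <- tibble::tibble(
    id = c("TRINITY_DN5503_c0_g1_i1", "b"),
    desc = c("len=900", ""),
    seq = c("ATGACGTACGTN", "ACGTACGT")
  )
  recs_aa <- tibble::tibble(id = c("p1", "p2"), desc = c("", "a peptide"),
                            seq = c("MKVLWX", "ACDEFGHIKLMNPQRSTVWY"))
  for (width in c(1, 7, 60)) {
    f <- withr::local_tempfile(fileext = ".fa")
    write_fasta(recs_nt, f, width = width)
    back <- read_fasta(f, "nucleotide")
    expect_equal(back$id, recs_nt$id)
    expect_equal(back$desc, recs_nt$desc)
    expect_equal(back$seq, recs_nt$seq)
  }
  f <- withr::local_tempfile(fileext = ".fa")
  write_fasta(recs_aa, f)
  expect_equal(read_fasta(f, "protein")$seq, recs_aa$seq)
})

test_that("read_fasta folds case, splits headers, validates alphabet", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "acgt"), f)
  r <- read_fasta(f, "nucleotide")
  expect_equal(r$id, "a")
  expect_equal(r$seq, "ACGT")

  writeLines(c(">TRINITY_DN5503_c0_g1_i1 len=900", "ATGACGT"), f)
  r <- read_fasta(f, "nucleotide")
  expect_equal(r$id, "TRINITY_DN5503_c0_g1_i1")
  expect_equal(r$desc, "len=900")

  writeLines(c(">bad", "ACGU"), f)
  expect_error(read_fasta(f, "nucleotide"), "position 4")
  file.create(f2 <- withr::local_tempfile(fileext = ".fa"))
  expect_error(read_fasta(f2, "nucleotide"), "no records")
})

test_that("AMP reference headers parse at the first underscore, bad ones skip", {
  recs <- tibble::tibble(
    id = c("AP02959_Paralithocin", "AP02147_ALF", "not_an_amp"),
    desc = c("1", "", ""),
    seq = c("GCWSSK", "QKLLED", "AAAAA")
  )
  expect_warning(entries <- parse_amp_reference(recs), "skipped")
  expect_equal(nrow(entries), 2)
  expect_equal(entries$accession, c("AP02959", "AP02147"))
  expect_equal(entries$name, c("Paralithocin 1", "ALF"))
  expect_equal(attr(entries, "n_skipped"), 1)
  expect_true(all(grepl("^AP[0-9]+$", entries$accession)))
})

test_that("counts tables parse with and without TOTAL row and reject bad cells", {
  f <- withr::local_tempfile(fileext = ".tsv")
  libs <- c("B-top", "C-top", "A-belly", "A-legm", "C-legm", "A-legs",
            "C-legs")
  hdr <- paste(c("id", libs), collapse = "\t")
  writeLines(c(hdr,
               paste(c("g1", 1:7), collapse = "\t"),
               paste(c("g2", 8:14), collapse = "\t")), f)
  ct <- read_counts_table(f)
  expect_equal(ct$library_ids, libs)
  expect_equal(unname(ct$library_totals), as.numeric(1:7 + 8:14))

  writeLines(c(hdr,
               paste(c("g1", 1:7), collapse = "\t"),
               paste(c("TOTAL", rep(1000, 7)), collapse = "\t")), f)
  ct <- read_counts_table(f)
  expect_equal(unname(ct$library_totals), rep(1000, 7))
  expect_true(all(ct$library_totals >=
                    tapply(ct$counts$reads, ct$counts$library_id, sum)[
                      ct$library_ids]))

  writeLines(c("id\tlibA", "g1\t-3"), f)
  expect_error(read_counts_table(f), "non-negative")
  writeLines(c("id\tlibA", "g1\t2", "g1\t3"), f)
  expect_error(read_counts_table(f), "duplicate")
  writeLines(c("id\tlibA", "g1\t2.5"), f)
  expect_error(read_counts_table(f), "integer")
})

test_that("counts table round-trips through write_counts_table", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tl1\tl2", "g1\t5\t0", "g2\t2\t7", "TOTAL\t100\t200"), f)
  ct <- read_counts_table(f)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_counts_table(ct, f2)
  ct2 <- read_counts_table(f2)
  expect_equal(dplyr::arrange(ct2$counts, id, library_id),
               dplyr::arrange(ct$counts, id, library_id))
  expect_equal(ct2$library_totals, ct$library_totals)
})

test_that("candidate report has the fixed column order and header-only empty form", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_candidate_table(tibble::tibble(), f)
  lines <- readLines(f)
  expect_length(lines, 1)
  expect_equal(strsplit(lines, "\t")[[1]][1:3],
               c("gene_id", "contig_ids", "best_hit_accession"))
})

test_that("bundled BLOSUM62 matches the published matrix", {
  mat <- read_score_matrix(system.file("extdata", "BLOSUM62.txt",
                                       package = "ampminer"))
  expect_equal(mat["C", "C"], 9L)
  expect_equal(mat["W", "W"], 11L)
  expect_equal(mat["A", "R"], -1L)
  expect_identical(mat, t(mat))
  ref <- local({ e <- new.env(); data("BLOSUM62", package = "Biostrings",
                                     envir = e); e$BLOSUM62 })
  common <- intersect(rownames(mat), rownames(ref))
  expect_equal(mat[common, common], ref[common, common],
               ignore_attr = TRUE)
})
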