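test_that("reverse complement handles N, involution, and rejects junk", {
  expect_equal(reverse_complement("ATGC"), "GCAT")
  expect_equal(reverse_complement("NNN"), "NNN")
  expect_error(reverse_complement("ACGU"), "illegal nucleotide")
  set.seed(11)
  for (i in 1:20) {
    s <- random_nt(sample(10:200, 1), with_n = TRUE)
    expect_equal(reverse_complement(reverse_complement(s)), s)
    expect_equal(nchar(reverse_complement(s)), nchar(s))
  }
})

test_that("frame translation follows the standard code with N -> X", {
  expect_equal(translate_frame("ATGAAA", 1), "MK")
  expect_equal(translate_frame("TTTCAT", -1), "MK")
  expect_equal(translate_frame("ATGANA", 1), "MX")
  expect_equal(translate_frame("TAATGA", 1), "**")
  expect_equal(translate_frame("AT", 1), "")
  # independent codon-by-codon oracle on random 300-mers, all six frames
  set.seed(12)
  for (rep in 1:10) {
    s <- random_nt(300, with_n = TRUE)
    for (f in c(1, 2, 3, -1, -2, -3)) {
      off <- abs(f)
      tmpl <- if (f > 0) s else
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
      n_codon <- (nchar(tmpl) - off + 1) %/% 3
      oracle <- as.character(Biostrings::translate(
        Biostrings::DNAString(substr(tmpl, off, off + 3 * n_codon - 1)),
        if.fuzzy.codon = "X", no.init.codon = TRUE))
      expect_equal(translate_frame(s, f), oracle)
    }
  }
})

test_that("six-frame translation has fixed frame order and consistent maps", {
  ctg <- tibble::tibble(id = "c", seq = random_nt(9))
  ft <- six_frame_translate(ctg)
  expect_equal(ft$frame, c(1L, 2L, 3L, -1L, -2L, -3L))
  expect_equal(nchar(ft$protein), c(3L, 2L, 2L, 3L, 2L, 2L))

  # each mapped codon, read on its strand, retranslates to the same residue
  set.seed(13)
  ctg <- tibble::tibble(id = "c", seq = random_nt(101))
  ft <- six_frame_translate(ctg)
  for (i in seq_len(nrow(ft))) {
    prot <- ft$protein[i]
    for (p in sample(seq_len(nchar(prot)), min(8, nchar(prot)))) {
      sp <- map_protein_span_to_nt(ft$contig_len[i], ft$frame[i], p, p)
      codon <- substr(ctg$seq, sp$start_nt, sp$end_nt)
      if (sp$strand == "-") codon <- reverse_complement(codon)
      expect_equal(translate_frame(codon, 1), substr(prot, p, p))
    }
  }

  # plus frames of a contig equal minus frames of its reverse complement
  rc <- tibble::tibble(id = "rc", seq = reverse_complement(ctg$seq))
  ft_rc <- six_frame_translate(rc)
  expect_equal(ft$protein[1:3], ft_rc$protein[4:6])
  expect_equal(ft$protein[4:6], ft_rc$protein[1:3])
})

test_that("protein spans map to forward-strand nt spans of 3x length", {
  expect_equal(map_protein_span_to_nt(30, 1, 1, 2)[c("start_nt", "end_nt")],
               list(start_nt = 1, end_nt = 6))
  expect_equal(map_protein_span_to_nt(30, 2, 1, 1)[c("start_nt", "end_nt")],
               list(start_nt = 2, end_nt = 4))
  expect_error(map_protein_span_to_nt(30, 1, 1, 11), "out of range")
  set.seed(14)
  for (i in 1:40) {
    len <- sample(30:90, 1)
    f <- sample(c(1, 2, 3, -1, -2, -3), 1)
    nc <- (len - abs(f) + 1) %/% 3
    ps <- sort(sample(nc, 2))
    sp <- map_protein_span_to_nt(len, f, ps[1], ps[2])
    expect_equal(sp$end_nt - sp$start_nt + 1, 3 * (ps[2] - ps[1] + 1))
    expect_gte(sp$start_nt, 1)
    expect_lte(sp$end_nt, len)
  }
})

test_that("find_orfs reports the smallest complete case exactly", {
  orfs <- find_orfs(tibble::tibble(id = "c1", seq = "ATGAAATAA"), min_aa = 1)
  cmpl <- orfs[orfs$completeness == "complete", ]
  expect_equal(nrow(cmpl), 1)
  expect_equal(cmpl$start_nt, 1L)
  expect_equal(cmpl$end_nt, 6L)   # stop codon excluded from the span
  expect_equal(cmpl$protein, "MK")
})

test_that("a planted coding region is recovered at its exact coordinates", {
  set.seed(15)
  prot <- random_orf_protein(72)
  ctg <- plant_orf_contig(prot, orf_start = 148)
  orfs <- find_orfs(ctg, min_aa = 25)
  hit <- orfs[orfs$start_nt == 148 & orfs$end_nt == 363, ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$length_aa, 72L)
  expect_equal(hit$completeness, "complete")
  expect_equal(hit$protein, prot)
})

test_that("every reported ORF satisfies the span and stop-free invariants", {
  set.seed(16)
  for (i in 1:15) {
    ctg <- tibble::tibble(id = "c", seq = random_nt(sample(100:600, 1),
                                                    with_n = TRUE))
    orfs <- find_orfs(ctg, min_aa = 5)
    if (nrow(orfs) == 0) next
    expect_equal(orfs$end_nt - orfs$start_nt + 1, 3L * orfs$length_aa)
    expect_false(any(grepl("*", orfs$protein, fixed = TRUE)))
    expect_true(all(orfs$start_nt >= 1 & orfs$end_nt <= nchar(ctg$seq)))
    complete <- orfs[orfs$completeness == "complete", ]
    if (nrow(complete)) {
      expect_true(all(substr(complete$protein, 1, 1) == "M"))
    }
  }
})

test_that("find_orfs agrees with the exhaustive enumeration oracle", {
  set.seed(17)
  for (i in 1:60) {
    ctg <- tibble::tibble(id = "c",
                          seq = random_nt(sample(60:1000, 1),
                                          with_n = i %% 3 == 0))
    min_aa <- sample(c(5, 15, 25), 1)
    got <- find_orfs(ctg, min_aa = min_aa)
    got <- got[order(got$frame, got$start_nt),
               c("frame", "start_nt", "end_nt", "protein", "completeness")]
    want <- orf_oracle(ctg$seq, min_aa)
    want <- want[order(want$frame, want$start_nt), ]
    expect_equal(as.data.frame(got), want, ignore_attr = TRUE)
  }
})

test_that("contig merging finds the longest exact overlap in both orientations", {
  a <- list(id = "A", seq = "AAACCC")
  b <- list(id = "B", seq = "CCCGGG")
  m <- merge_overlapping_contigs(a, b, min_overlap = 3)
  expect_equal(m$merged$seq, "AAACCCGGG")
  expect_equal(m$merged$id, "A+B")
  expect_equal(m$overlap_len, 3L)

  set.seed(18)
  x <- random_nt(200); y <- random_nt(200)
  expect_null(merge_overlapping_contigs(list(id = "a", seq = x),
                                        list(id = "b", seq = y),
                                        min_overlap = 30))

  # reverse-complement orientation and containment of both inputs
  full <- random_nt(300)
  left <- substr(full, 1, 180)
  right_rc <- reverse_complement(substr(full, 140, 300))
  m <- merge_overlapping_contigs(list(id = "L", seq = left),
                                 list(id = "R", seq = right_rc),
                                 min_overlap = 30)
  expect_equal(m$merged$seq, full)
  expect_equal(m$b_orientation, "revcomp")
  expect_true(grepl(left, m$merged$seq, fixed = TRUE))
  expect_true(grepl(reverse_complement(right_rc), m$merged$seq,
                    fixed = TRUE))
})
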