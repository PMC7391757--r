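test_that("precursor construction is deterministic and family-faithful", {
  a <- generate_precursor("paralithocin", seed = 7)
  b <- generate_precursor("paralithocin", seed = 7)
  expect_identical(a, b)
  set.seed(51)
  # paralithocins carry exactly 8 cysteines (four disulfide bonds)
  expect_equal(stringr::str_count(generate_precursor("paralithocin")$mature,
                                  stringr::fixed("C")), 8)
  # constructive guarantees: domain detectors fire on their own families,
  # every mature passes the physicochemical screen
  for (seed in 1:6) {
    set.seed(seed)
    expect_false(is.null(detect_wap(generate_precursor("crustin")$mature)))
    expect_false(is.null(detect_kazal(generate_precursor("kazal")$mature)))
    expect_false(is.null(detect_alf_loop(generate_precursor("alf")$mature)))
    for (fam in c("paralithocin", "crustin", "alf", "kazal",
                  "buforin_like")) {
      m <- generate_precursor(fam)$mature
      expect_true(physchem_profile(m)$passes_amp_screen, info = fam)
    }
  }
  expect_equal(generate_precursor("buforin_like")$signal_peptide, "")
  expect_error(generate_precursor("not_a_family"))
})

test_that("transcriptome generation is deterministic and honest about truth", {
  simA <- generate_transcriptome(n_planted = 6, n_decoys = 5, seed = 99)
  simB <- generate_transcriptome(n_planted = 6, n_decoys = 5, seed = 99)
  expect_identical(simA$contigs, simB$contigs)
  expect_identical(simA$truth$genes, simB$truth$genes)

  tr <- simA$truth$genes
  # truth span is 3 x the reported protein for every layout
  expect_equal(tr$orf_end_nt - tr$orf_start_nt + 1,
               3L * nchar(tr$expected_protein))
  # unique ids; decoys disjoint from gene contigs
  gene_ctgs <- unlist(strsplit(tr$contig_ids, "+", fixed = TRUE))
  expect_false(any(simA$truth$decoy_ids %in% gene_ctgs))
  expect_false(anyDuplicated(c(gene_ctgs, simA$truth$decoy_ids)) > 0)
  expect_true(all(grepl("^TRINITY_DN[0-9]+_c0_g1_i1$", simA$contigs$id)))
  # the truth span on a single-contig gene retranslates to the precursor
  single <- tr[tr$contig_layout == "single" & tr$strand == "+", ][1, ]
  ctg <- simA$contigs$seq[simA$contigs$id == single$contig_ids]
  orf_nt <- substr(ctg, single$orf_start_nt, single$orf_end_nt)
  expect_equal(translate_frame(orf_nt, 1), single$precursor)
})

test_that("split contig pairs reassemble the planted transcript exactly", {
  sim <- generate_transcriptome(n_planted = 8, n_decoys = 0, seed = 52)
  splits <- sim$truth$genes[sim$truth$genes$contig_layout == "split_pair", ]
  expect_gte(nrow(splits), 1)
  for (i in seq_len(nrow(splits))) {
    ids <- strsplit(splits$contig_ids[i], "+", fixed = TRUE)[[1]]
    a <- sim$contigs[sim$contigs$id == ids[1], ]
    b <- sim$contigs[sim$contigs$id == ids[2], ]
    m <- merge_overlapping_contigs(a, b, min_overlap = 40)
    expect_false(is.null(m))
    expect_gte(m$overlap_len, 40)
    # planted span on the reassembled transcript translates to the precursor
    orf_nt <- substr(m$merged$seq, splits$orf_start_nt[i],
                     splits$orf_end_nt[i])
    if (splits$strand[i] == "-") orf_nt <- reverse_complement(orf_nt)
    expect_equal(translate_frame(orf_nt, 1), splits$precursor[i])
  }
})

test_that("decoys never align to the references near the score filter", {
  sim <- generate_transcriptome(n_planted = 4, n_decoys = 12, seed = 53)
  decoys <- sim$contigs[sim$contigs$id %in% sim$truth$decoy_ids, ]
  hits <- search_amps_vs_sixframe(sim$amp_refs, decoys, min_score = 60)
  expect_equal(nrow(hits), 0)
})

test_that("tiered counts land in their tier with margin, deterministically", {
  truth <- list(genes = tibble::tibble(
    truth_id = c("hi", "med", "lo"), tier = c("high", "medium", "low"),
    contig_ids = c("c_hi", "c_med", "c_lo")
  ), decoy_ids = "c_dec")
  ctsA <- generate_counts(truth, seed = 54)
  ctsB <- generate_counts(truth, seed = 54)
  expect_identical(ctsA, ctsB)
  expect_equal(ctsA$library_ids,
               c("B-top", "C-top", "A-belly", "A-legm", "C-legm",
                 "A-legs", "C-legs"))
  expect_true(all(ctsA$library_totals >=
                    tapply(ctsA$counts$reads, ctsA$counts$library_id, sum)[
                      ctsA$library_ids]))
  # over 100 seeds the high tier clears 3000 reads and the low tier stays
  # under 100 in at least 95 % of draws
  hi_ok <- lo_ok <- dec_ok <- 0
  for (seed in 1:100) {
    cts <- generate_counts(truth, seed = seed)
    tot <- tapply(cts$counts$reads, cts$counts$id, sum)
    hi_ok <- hi_ok + (tot[["c_hi"]] > 3000)
    lo_ok <- lo_ok + (tot[["c_lo"]] < 100)
    dec_ok <- dec_ok + (tot[["c_dec"]] < 100)
  }
  expect_gte(hi_ok, 95)
  expect_gte(lo_ok, 95)
  expect_equal(dec_ok, 100)
})

test_that("truth tables round-trip through JSON", {
  sim <- generate_transcriptome(n_planted = 3, n_decoys = 2, seed = 55)
  f <- withr::local_tempfile(fileext = ".json")
  write_truth(sim$truth, f)
  back <- read_truth(f)
  expect_equal(tibble::as_tibble(back$genes), sim$truth$genes)
  expect_equal(back$decoy_ids, sim$truth$decoy_ids)
  expect_equal(back$seed, 55)
  expect_equal(back$parameters$n_planted, 3)
})
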