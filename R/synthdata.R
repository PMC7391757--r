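# Seeded generator of synthetic transcriptomes with a machine-readable truth
# table. Planted precursors are constructed to satisfy the package's own
# documented rules (signal-peptide heuristic, domain spacing patterns,
# physicochemical screen), so recovery failures point at the pipeline, not
# the fixtures.

.SYNTH_FAMILIES <- c("paralithocin", "crustin", "alf", "kazal",
                     "buforin_like", "decoy_like")

# polar/charged filler: no Met (truncated fragments must stay Met-free), no
# Cys (domain spacing stays exact), no strongly hydrophobic residues (the
# signal h-region must stay the best hydrophobic window)
.FILLER <- c("S", "T", "N", "Q", "G", "K", "R", "D", "E", "P")
.LOOP_NEUTRAL <- c("S", "G", "N", "Q", "T")

.filler <- function(n, pool = .FILLER) {
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

.rand_nt <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# 23-residue signal peptide passing the documented cleavage rules with the
# planted site as unique best candidate (Ala bonus at 23, ties broken toward
# the canonical length)
.synth_signal <- function() {
  paste0("MK", .filler(3, c("N", "S", "T")),
         .filler(11, c("L", "V")),
         .filler(4, c("S", "G", "T")),
         "A", .filler(1, c("S", "G", "N")), "A")
}

.synth_mature <- function(family) {
  f <- .filler
  switch(family,
    paralithocin = paste0(f(2), "C", f(4), "C", f(5), "C", f(3), "C", f(6),
                          "C", f(4), "C", f(3), "C", f(4), "C", f(3)),
    crustin = paste0(f(6), "C", f(5), "C", f(5), "C", f(5), "C", f(8),
                     "C", f(6), "CC", f(4), "C", f(3)),
    alf = paste0(f(8), "C", "KKRK", .filler(16, .LOOP_NEUTRAL), "C", f(8)),
    kazal = paste0(f(4), "C", f(7), "C", f(6), "Y", f(3), "C",
                   f(sample(2:3, 1)), "C", f(5)),
    buforin_like = paste0("M", paste(sample(
      c("K", "R", "A", "G", "S", "T", "Q", "V"), 37, replace = TRUE,
      prob = c(0.25, 0.15, 0.15, 0.15, 0.1, 0.1, 0.05, 0.05)),
      collapse = "")),
    decoy_like = f(40),
    stop("unsupported family '", family, "'")
  )
}

#' Generate a synthetic AMP precursor
#'
#' Builds a signal peptide satisfying the signal-peptide caller's documented
#' rules (charged n-region, >= 7-residue hydrophobic core, small residues at
#' -3/-1, cleavage after residue 23) and a mature peptide satisfying the
#' family's domain spacing pattern and the physicochemical screen.
#' Buforin-like (histone-derived) precursors carry no signal peptide.
#'
#' @param family One of `paralithocin`, `crustin`, `alf`, `kazal`,
#'   `buforin_like`, `decoy_like`.
#' @param seed Optional integer seed.
#' @return List with `signal_peptide` (may be `""`) and `mature`.
#' @export
generate_precursor <- function(family, seed = NULL) {
  family <- match.arg(family, .SYNTH_FAMILIES)
  if (!is.null(seed)) set.seed(seed)
  sp <- if (family %in% c("buforin_like", "decoy_like")) "" else
    .synth_signal()
  list(signal_peptide = sp, mature = .synth_mature(family))
}

.codon_table_env <- new.env(parent = emptyenv())

.codons_by_aa <- function() {
  if (is.null(.codon_table_env$tab)) {
    gc <- Biostrings::GENETIC_CODE
    .codon_table_env$tab <- split(names(gc), unname(gc))
  }
  .codon_table_env$tab
}

#' Reverse-translate a protein with seeded uniform codon choice
#'
#' @param protein Amino-acid sequence (no `*` or `X`).
#' @return A nucleotide sequence of length `3 * nchar(protein)`.
#' @export
reverse_translate <- function(protein) {
  tab <- .codons_by_aa()
  chars <- .chars(protein)
  if (any(!chars %in% .AA20)) stop("cannot reverse-translate residue '",
                                   chars[!chars %in% .AA20][1], "'")
  paste(vapply(chars, function(a) {
    cods <- tab[[a]]
    if (length(cods) == 1) cods else sample(cods, 1)
  }, ""), collapse = "")
}

# forward-strand interval mapped onto the reverse complement of a contig
.flip_span <- function(len, start, end) {
  c(len - end + 1L, len - start + 1L)
}

#' Generate a synthetic transcriptome with planted AMP genes and decoys
#'
#' Each planted gene is a reverse-translated precursor (uniform synonymous
#' codon draw) embedded in random UTRs with an in-frame stop immediately
#' upstream of the initiator ATG and a stop codon after the ORF. Layouts:
#' `single` (one contig), `split_pair` (two contigs sharing a 60-nt exact
#' overlap inside the ORF), `five_prime_truncated` / `three_prime_truncated`
#' (the ORF cut across the contig edge). Roughly half the genes are placed
#' on the minus strand. Decoys are random sequences re-drawn until no
#' reference aligns at score >= `decoy_max_score`. One reference mature
#' peptide per planted gene is emitted with a unique APD-style accession.
#'
#' @param n_planted,n_decoys Gene and decoy counts (defaults 20 and 80).
#' @param layout_mix Named proportions over the four layouts.
#' @param seed Optional integer seed (the generator is fully deterministic
#'   under a fixed seed).
#' @param decoy_max_score Decoy rejection threshold (default 60, safely
#'   below the pipeline's score filter of 90).
#' @return List: `contigs` (tibble `id`, `desc`, `seq`), `amp_refs`
#'   (tibble like [parse_amp_reference()]), `truth` (list: `genes` tibble,
#'   `decoy_ids`, `seed`, `parameters`).
#' @export
generate_transcriptome <- function(n_planted = 20, n_decoys = 80,
                                   layout_mix = c(single = 0.60,
                                                  split_pair = 0.15,
                                                  five_prime_truncated = 0.125,
                                                  three_prime_truncated = 0.125),
                                   seed = NULL, decoy_max_score = 60) {
  stopifnot(n_planted >= 0, n_decoys >= 0)
  if (!is.null(seed)) set.seed(seed)
  fams <- c("paralithocin", "crustin", "alf", "kazal", "buforin_like")
  fam_display <- c(paralithocin = "Paralithocin", crustin = "Crustin",
                   alf = "ALF", kazal = "Kazal-AMP", buforin_like = "Buforin")

  # layout counts from proportions, then per-gene assignment; buforin-like
  # genes (short histone-derived precursors without a signal peptide) are
  # kept on single contigs: split or truncated layouts cannot leave both
  # fragments with enough mature sequence to clear the score filter, and a
  # Met inside the remainder would legitimately change the completeness call
  n_by_layout <- diff(c(0L, round(cumsum(layout_mix) * n_planted)))
  layouts <- rep(names(layout_mix), n_by_layout)
  gene_fams <- rep_len(fams, n_planted)
  if (n_planted > 0) {
    for (i in seq_len(n_planted)) {
      if (gene_fams[i] == "buforin_like" && layouts[i] != "single") {
        j <- which(layouts == "single" & gene_fams != "buforin_like")[1]
        if (!is.na(j)) {
          tmp <- layouts[i]; layouts[i] <- layouts[j]; layouts[j] <- tmp
        } else layouts[i] <- "single"
      }
    }
  }
  strands <- rep_len(c("+", "-"), n_planted)
  tiers <- rep_len(c("high", "high", "high", "high", "high", "high", "high",
                     "medium", "medium", "low"), n_planted)

  n_contigs_planned <- n_planted + sum(layouts == "split_pair") + n_decoys
  dn_pool <- sample.int(999999, n_contigs_planned + 10)
  dn_i <- 0L
  next_id <- function() {
    dn_i <<- dn_i + 1L
    sprintf("TRINITY_DN%d_c0_g1_i1", dn_pool[dn_i])
  }

  genes <- list()
  contigs <- list()
  refs <- list()
  for (i in seq_len(n_planted)) {
    fam <- gene_fams[i]
    prec <- generate_precursor(fam)
    precursor <- paste0(prec$signal_peptide, prec$mature)
    P <- nchar(precursor)
    orf_nt <- reverse_translate(precursor)
    u5 <- sample(45:150, 1)
    utr5 <- .rand_nt(u5)
    substr(utr5, u5 - 2, u5) <- "TAA"   # in-frame stop just upstream of ATG
    utr3 <- .rand_nt(sample(45:150, 1))
    stop_codon <- sample(c("TAA", "TAG", "TGA"), 1)
    transcript <- paste0(utr5, orf_nt, stop_codon, utr3)
    orf_start <- u5 + 1L
    orf_end <- u5 + 3L * P
    L <- nchar(transcript)
    strand <- strands[i]
    layout <- layouts[i]

    if (layout == "single") {
      ids <- next_id()
      seqs <- transcript
      span <- c(orf_start, orf_end)
      clen <- L
      completeness <- "complete"
      prot <- precursor
    } else if (layout == "split_pair") {
      cut <- orf_start + ((99L + 3L * P - 31L) %/% 2L)
      left <- substr(transcript, 1, cut + 30L)
      right <- substr(transcript, cut - 29L, L)
      ids <- c(next_id(), next_id())
      seqs <- c(left, right)
      span <- c(orf_start, orf_end)   # on the reassembled transcript
      clen <- L
      completeness <- "complete"
      prot <- precursor
    } else if (layout == "five_prime_truncated") {
      k <- 10L                        # codons removed, cut within the signal
      ctg <- substr(transcript, orf_start + 3L * k, L)
      ids <- next_id()
      seqs <- ctg
      span <- c(1L, 3L * (P - k))
      clen <- nchar(ctg)
      completeness <- "five_prime_fragment"
      prot <- substr(precursor, k + 1L, P)
    } else {                          # three_prime_truncated
      m <- P - 8L                     # codons kept
      ctg <- substr(transcript, 1, orf_start + 3L * m - 1L)
      ids <- next_id()
      seqs <- ctg
      span <- c(orf_start, orf_start + 3L * m - 1L)
      clen <- nchar(ctg)
      completeness <- "three_prime_fragment"
      prot <- substr(precursor, 1, m)
    }

    if (strand == "-") {
      # each contig is emitted reverse-complemented; for split pairs the
      # reassembled transcript is then rc(transcript), so the planted span
      # flips on the merged length
      seqs <- reverse_complement(seqs)
      span <- .flip_span(clen, span[1], span[2])
    }

    accession <- sprintf("AP9%04d", i)
    name <- paste0(fam_display[[fam]], "-synthetic-", i)
    refs[[i]] <- tibble::tibble(accession = accession, name = name,
                                mature_sequence = prec$mature,
                                family_hint = fam)
    contigs[[length(contigs) + 1L]] <-
      tibble::tibble(id = ids, desc = sprintf("len=%d", nchar(seqs)),
                     seq = seqs)
    genes[[i]] <- tibble::tibble(
      truth_id = sprintf("gene%02d", i),
      family = sub("_like$", "", fam), generator_family = fam,
      accession = accession, name = name,
      signal_peptide = prec$signal_peptide, mature = prec$mature,
      precursor = precursor, strand = strand, contig_layout = layout,
      contig_ids = paste(ids, collapse = "+"),
      orf_start_nt = span[1], orf_end_nt = span[2],
      completeness = completeness, expected_protein = prot,
      tier = tiers[i]
    )
  }

  gene_refs <- if (length(refs)) dplyr::bind_rows(refs) else
    tibble::tibble(accession = character(), name = character(),
                   mature_sequence = character(), family_hint = character())

  decoy_ids <- character(n_decoys)
  scheme <- scoring_scheme()
  for (d in seq_len(n_decoys)) {
    id <- next_id()
    repeat {
      s <- .rand_nt(sample(250:1200, 1))
      if (nrow(gene_refs) == 0) break
      hits <- search_amps_vs_sixframe(
        gene_refs, tibble::tibble(id = id, seq = s),
        scheme = scheme, min_score = decoy_max_score)
      if (nrow(hits) == 0) break
    }
    decoy_ids[d] <- id
    contigs[[length(contigs) + 1L]] <-
      tibble::tibble(id = id, desc = sprintf("len=%d", nchar(s)), seq = s)
  }

  list(
    contigs = dplyr::bind_rows(contigs),
    amp_refs = gene_refs,
    truth = list(
      genes = if (length(genes)) dplyr::bind_rows(genes) else
        tibble::tibble(),
      decoy_ids = decoy_ids,
      seed = if (is.null(seed)) NA_integer_ else seed,
      parameters = list(n_planted = n_planted, n_decoys = n_decoys,
                        layout_mix = as.list(layout_mix),
                        decoy_max_score = decoy_max_score)
    )
  )
}

.TIER_NB <- list(high = c(mu = 8000, size = 20),
                 medium = c(mu = 1000, size = 15),
                 low = c(mu = 50, size = 10))

#' Generate tiered per-library read counts for a synthetic truth table
#'
#' Per-gene totals are drawn from negative binomials centred on the tier
#' anchors (high 8000, medium 1000, low 50) and split across libraries with
#' Dirichlet-style weights; decoy contigs get background totals below 100.
#' A TOTAL row with per-library mapped-read totals (column sums plus an
#' unassigned background) is included.
#'
#' @param truth Truth list from [generate_transcriptome()].
#' @param libraries Library names (default: the seven tissue libraries).
#' @param seed Optional integer seed.
#' @return A `counts_table` object keyed by contig id.
#' @export
generate_counts <- function(truth, libraries = .TABLE2_LIBS, seed = NULL) {
  stopifnot(length(libraries) > 0)
  if (!is.null(seed)) set.seed(seed)
  nl <- length(libraries)
  rows <- list()
  split_total <- function(total) {
    w <- rgamma(nl, shape = 2)
    as.vector(rmultinom(1, total, w / sum(w)))
  }
  genes <- truth$genes
  if (!is.null(genes) && nrow(genes)) {
    for (i in seq_len(nrow(genes))) {
      par <- .TIER_NB[[genes$tier[i]]]
      total <- rnbinom(1, mu = par[["mu"]], size = par[["size"]])
      per_lib <- split_total(total)
      ids <- strsplit(genes$contig_ids[i], "+", fixed = TRUE)[[1]]
      if (length(ids) == 1) {
        rows[[length(rows) + 1L]] <-
          tibble::tibble(id = ids, library_id = libraries, reads = per_lib)
      } else {
        first <- vapply(per_lib, function(r) stats::rbinom(1, r, 0.5), 0L)
        rows[[length(rows) + 1L]] <-
          tibble::tibble(id = rep(ids, each = nl),
                         library_id = rep(libraries, 2),
                         reads = c(first, per_lib - first))
      }
    }
  }
  for (id in truth$decoy_ids) {
    total <- min(rnbinom(1, mu = 20, size = 5), 99L)
    rows[[length(rows) + 1L]] <-
      tibble::tibble(id = id, library_id = libraries,
                     reads = split_total(total))
  }
  counts <- dplyr::bind_rows(rows)
  sums <- tapply(counts$reads, counts$library_id, sum)[libraries]
  totals <- sums + rnbinom(nl, mu = 5e4, size = 10)
  structure(list(counts = counts, library_ids = libraries,
                 library_totals = setNames(as.numeric(totals), libraries)),
            class = "counts_table")
}

#' Write / read a truth table as JSON
#'
#' @param truth Truth list from [generate_transcriptome()].
#' @param path Output path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @rdname write_truth
#' @return `read_truth()` returns the truth list with `genes` as a tibble.
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (length(x$genes)) x$genes <- tibble::as_tibble(x$genes)
  x
}
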