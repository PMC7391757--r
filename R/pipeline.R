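#' Pipeline configuration
#'
#' @param min_score Raw alignment-score threshold for reported hits
#'   (default 90).
#' @param min_orf_aa Minimum ORF protein length (default 25).
#' @param scheme A [scoring_scheme()].
#' @param join_min_overlap Minimum exact overlap for contig joining
#'   (default 30 nt).
#' @param max_mature_len Maximum mature-peptide length for the AMP screen
#'   (default 150 aa).
#' @param seed Integer seed recorded with the run (the mining pipeline
#'   itself is deterministic).
#' @return Object of class `amp_config`.
#' @export
amp_config <- function(min_score = 90, min_orf_aa = 25,
                       scheme = scoring_scheme(), join_min_overlap = 30,
                       max_mature_len = 150, seed = 1L) {
  stopifnot(min_score > 0, min_orf_aa > 0, join_min_overlap > 0,
            max_mature_len > 0, inherits(scheme, "scoring_scheme"))
  structure(list(min_score = min_score, min_orf_aa = min_orf_aa,
                 scheme = scheme, join_min_overlap = join_min_overlap,
                 max_mature_len = max_mature_len, seed = as.integer(seed)),
            class = "amp_config")
}

# hits from both search approaches, expressed in ORF coordinates.
# orfs must carry orf_key; returns one row per (query, orf) with the
# protein-space span relative to the ORF and the forward-strand nt span.
.orf_level_hits <- function(contigs, orfs, amps, config) {
  scheme <- config$scheme
  clen <- setNames(nchar(contigs$seq), contigs$id)

  # approach A: ORF proteins searched directly
  hits_a <- search_amps_vs_proteins(
    amps, tibble::tibble(id = orfs$orf_key, seq = orfs$protein),
    scheme = scheme, min_score = config$min_score)
  if (nrow(hits_a)) {
    ai <- match(hits_a$subject_id, orfs$orf_key)
    hits_a <- tibble::tibble(
      query_id = hits_a$query_id, query_name = hits_a$query_name,
      orf_key = hits_a$subject_id,
      score = hits_a$score, percent_identity = hits_a$percent_identity,
      percent_positive = hits_a$percent_positive,
      q_start = hits_a$q_start, q_end = hits_a$q_end,
      s_start = hits_a$s_start, s_end = hits_a$s_end
    )
  } else hits_a <- NULL

  # approach B: six-frame search, hits assigned to their containing ORF
  hits_b <- search_amps_vs_sixframe(amps, contigs, scheme = scheme,
                                    min_score = config$min_score)
  dropped <- 0L
  rows_b <- NULL
  if (nrow(hits_b)) {
    rows_b <- purrr::map_dfr(seq_len(nrow(hits_b)), function(i) {
      h <- hits_b[i, ]
      cand <- orfs[orfs$contig_id == h$subject_id & orfs$frame == h$frame &
                     orfs$aa_start <= h$s_start & orfs$aa_end >= h$s_end, ]
      if (nrow(cand) == 0) {
        dropped <<- dropped + 1L
        return(NULL)
      }
      o <- cand[1, ]
      tibble::tibble(
        query_id = h$query_id, query_name = h$query_name,
        orf_key = o$orf_key,
        score = h$score, percent_identity = h$percent_identity,
        percent_positive = h$percent_positive,
        q_start = h$q_start, q_end = h$q_end,
        s_start = h$s_start - o$aa_start + 1L,
        s_end = h$s_end - o$aa_start + 1L
      )
    })
    if (dropped > 0) {
      warning(dropped, " six-frame hit(s) not contained in any single ORF ",
              "dropped (possible frameshift)", call. = FALSE)
    }
  }

  all_hits <- dplyr::bind_rows(hits_a, rows_b)
  if (nrow(all_hits) == 0) return(all_hits)
  # union of the two approaches: best score per (query, ORF)
  all_hits |>
    dplyr::arrange(dplyr::desc(.data$score), .data$query_id,
                   .data$orf_key) |>
    dplyr::distinct(.data$query_id, .data$orf_key, .keep_all = TRUE)
}

.with_orf_keys <- function(orfs) {
  if (nrow(orfs) == 0) {
    orfs$orf_key <- character(0)
    return(orfs)
  }
  orfs$orf_key <- paste(orfs$contig_id, orfs$frame, orfs$aa_start, sep = ":")
  orfs
}

# nt span of a hit on the forward strand of its contig
.hit_nt_span <- function(hit, orf, contig_len) {
  map_protein_span_to_nt(contig_len, orf$frame,
                         orf$aa_start + hit$s_start - 1L,
                         orf$aa_start + hit$s_end - 1L)
}

#' Mine AMP candidates from assembled contigs
#'
#' Runs both search approaches (local alignment of references against ORF
#' proteins, and against all six frame translations), unions the hits,
#' assigns each hit to its containing ORF, joins overlapping contig pairs
#' whose hits for the same reference abut the contig ends, annotates
#' (signal peptide on ORFs that retain their 5' end, domain patterns,
#' physicochemical profile, embedded flag, family), deduplicates overlapping
#' loci and assigns crab-style gene IDs. The result is sorted by family then
#' descending score and is fully deterministic for fixed inputs and
#' configuration.
#'
#' @param contigs Tibble of nucleotide records (`id`, `seq`).
#' @param amps Tibble of AMP reference entries ([parse_amp_reference()]).
#' @param config An [amp_config()].
#' @return A tibble of class `amp_candidates`.
#' @export
mine_amps <- function(contigs, amps, config = amp_config()) {
  stopifnot(nrow(contigs) > 0, nrow(amps) > 0)
  contigs <- tibble::as_tibble(contigs[, c("id", "seq")])
  contigs$seq <- toupper(contigs$seq)

  orfs <- .with_orf_keys(find_orfs(contigs, config$min_orf_aa))
  hits <- .orf_level_hits(contigs, orfs, amps, config)
  if (nrow(hits) == 0) {
    message("no hits at score >= ", config$min_score)
    return(.empty_candidates(config))
  }

  joined <- .join_contig_pairs(contigs, orfs, hits, amps, config)
  contigs <- joined$contigs; orfs <- joined$orfs; hits <- joined$hits

  # one candidate per ORF: best hit by score, ties toward the
  # lexicographically smaller accession
  best <- hits |>
    dplyr::arrange(dplyr::desc(.data$score), .data$query_id) |>
    dplyr::distinct(.data$orf_key, .keep_all = TRUE)

  oi <- match(best$orf_key, orfs$orf_key)
  clen <- setNames(nchar(contigs$seq), contigs$id)
  rows <- purrr::map_dfr(seq_len(nrow(best)), function(i) {
    h <- best[i, ]
    o <- orfs[oi[i], ]
    len_nt <- unname(clen[o$contig_id])
    sp_nt <- .hit_nt_span(h, o, len_nt)
    protein <- o$protein
    sig <- NULL
    if (o$completeness %in% c("complete", "three_prime_fragment")) {
      sig <- predict_signal_peptide(protein)
    }
    mature <- if (!is.null(sig)) {
      substr(protein, sig$cleavage_after + 1L, nchar(protein))
    } else protein
    domains <- dplyr::bind_rows(detect_wap(protein), detect_kazal(protein),
                                detect_alf_loop(protein))
    pc <- physchem_profile(mature)
    cls <- classify_family(h$query_id, domains, h$query_name)
    tibble::tibble(
      family = cls$family, prefix = cls$prefix,
      contig_ids = o$contig_id, strand = o$strand,
      start_nt = o$start_nt, end_nt = o$end_nt,
      completeness = o$completeness,
      protein = protein, peptide_length_aa = nchar(protein),
      transcript_length_nt = len_nt,
      best_hit_accession = h$query_id, best_hit_name = h$query_name,
      score = h$score, percent_identity = h$percent_identity,
      frame = o$frame,
      q_start = h$q_start, q_end = h$q_end,
      s_start = h$s_start, s_end = h$s_end,
      hit_nt_start = sp_nt$start_nt, hit_nt_end = sp_nt$end_nt,
      signal_peptide_flag = !is.null(sig),
      signal_cleavage_after = if (!is.null(sig)) sig$cleavage_after else
        NA_integer_,
      mature_peptide = mature,
      domain_list = if (nrow(domains)) paste(domains$kind, collapse = ",")
        else "",
      mass_kDa = pc$mass_kDa, net_charge = pc$net_charge,
      hydrophobic_fraction = pc$hydrophobic_fraction,
      passes_amp_screen = pc$length_aa <= config$max_mature_len &&
        pc$mass_kDa >= 2 && pc$mass_kDa <= 9,
      embedded = flag_embedded(nchar(protein), h$s_start, h$s_end)
    )
  })

  rows <- deduplicate_candidates(rows)
  rows <- assign_gene_ids(rows)
  rows <- dplyr::arrange(rows, .data$family, dplyr::desc(.data$score),
                         .data$gene_id)
  rows <- dplyr::select(rows, -"prefix")
  attr(rows, "config") <- config
  class(rows) <- c("amp_candidates", class(rows))
  rows
}

.empty_candidates <- function(config) {
  out <- tibble::tibble(
    gene_id = character(), family = character(), contig_ids = character(),
    strand = character(), start_nt = integer(), end_nt = integer(),
    completeness = character(), protein = character(),
    peptide_length_aa = integer(), transcript_length_nt = integer(),
    best_hit_accession = character(), best_hit_name = character(),
    score = integer(), percent_identity = double(), frame = integer(),
    q_start = integer(), q_end = integer(), s_start = integer(),
    s_end = integer(), hit_nt_start = integer(), hit_nt_end = integer(),
    signal_peptide_flag = logical(), signal_cleavage_after = integer(),
    mature_peptide = character(), domain_list = character(),
    mass_kDa = double(), net_charge = double(),
    hydrophobic_fraction = double(), passes_amp_screen = logical(),
    embedded = logical()
  )
  attr(out, "config") <- config
  class(out) <- c("amp_candidates", class(out))
  out
}

# attempt to reconstruct genes split across two overlapping contigs: a pair
# is tried when the same reference hits both contigs and each hit terminates
# within 10 codons (30 nt) of a contig end; the join is accepted only when
# the reference still hits the merged contig
.join_contig_pairs <- function(contigs, orfs, hits, amps, config) {
  if (nrow(contigs) < 2) {
    return(list(contigs = contigs, orfs = orfs, hits = hits))
  }
  clen <- setNames(nchar(contigs$seq), contigs$id)
  orf_contig <- setNames(orfs$contig_id, orfs$orf_key)

  # forward-strand nt span of every hit, for end proximity
  near_end <- purrr::map_dfr(seq_len(nrow(hits)), function(i) {
    o <- orfs[match(hits$orf_key[i], orfs$orf_key), ]
    len <- unname(clen[o$contig_id])
    sp <- .hit_nt_span(hits[i, ], o, len)
    tibble::tibble(query_id = hits$query_id[i], contig_id = o$contig_id,
                   near = (sp$start_nt - 1L) <= 30L |
                     (len - sp$end_nt) <= 30L)
  })

  pairs <- near_end |>
    dplyr::filter(.data$near) |>
    dplyr::distinct(.data$query_id, .data$contig_id)
  pair_tab <- list()
  for (q in unique(pairs$query_id)) {
    cids <- pairs$contig_id[pairs$query_id == q]
    cids <- cids[order(match(cids, contigs$id))]
    if (length(cids) < 2) next
    for (cmb in utils::combn(cids, 2, simplify = FALSE)) {
      key <- paste(cmb, collapse = "|")
      if (is.null(pair_tab[[key]])) pair_tab[[key]] <- character(0)
      pair_tab[[key]] <- union(pair_tab[[key]], q)
    }
  }
  if (!length(pair_tab)) {
    return(list(contigs = contigs, orfs = orfs, hits = hits))
  }

  for (key in names(pair_tab)) {
    cids <- strsplit(key, "|", fixed = TRUE)[[1]]
    a <- contigs[contigs$id == cids[1], ]
    b <- contigs[contigs$id == cids[2], ]
    mg <- merge_overlapping_contigs(a, b, config$join_min_overlap)
    if (is.null(mg)) next
    merged <- tibble::tibble(id = mg$merged$id, seq = mg$merged$seq)
    m_orfs <- .with_orf_keys(find_orfs(merged, config$min_orf_aa))
    if (nrow(m_orfs) == 0) next
    trig <- amps[amps$accession %in% pair_tab[[key]], ]
    m_hits <- .orf_level_hits(merged, m_orfs, trig, config)
    if (nrow(m_hits) == 0) next   # join does not preserve the hits
    ok_amps <- unique(m_hits$query_id)
    contigs <- dplyr::bind_rows(contigs, merged)
    orfs <- dplyr::bind_rows(orfs, m_orfs)
    # suppress the fragment hits this join explains
    drop <- hits$query_id %in% ok_amps &
      orf_contig[hits$orf_key] %in% cids
    hits <- dplyr::bind_rows(hits[!drop, ], m_hits)
  }
  list(contigs = contigs, orfs = orfs, hits = hits)
}

#' Collapse redundant candidates at the same locus
#'
#' Candidates whose ORFs overlap by at least one nt on the same contig and
#' strand are grouped; only the highest-scoring candidate per group is kept
#' (ties: longer ORF, then lexicographically smaller accession).
#'
#' @param candidates Candidate tibble.
#' @return Filtered tibble, loci pairwise non-overlapping.
#' @export
deduplicate_candidates <- function(candidates) {
  if (nrow(candidates) < 2) return(candidates)
  candidates |>
    dplyr::group_by(.data$contig_ids, .data$strand) |>
    dplyr::arrange(.data$start_nt, .by_group = TRUE) |>
    dplyr::mutate(cluster = cumsum(
      .data$start_nt > dplyr::lag(cummax(as.numeric(.data$end_nt)),
                                  default = -Inf))) |>
    dplyr::group_by(.data$cluster, .add = TRUE) |>
    dplyr::arrange(dplyr::desc(.data$score),
                   dplyr::desc(.data$peptide_length_aa),
                   .data$best_hit_accession, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::select(-"cluster")
}

#' Assign crab-style gene identifiers
#'
#' Within each family, candidates are numbered by descending best score
#' starting at 1, using the family prefix (PcPar1, PcCrs1, PcALF1, ...).
#'
#' @param candidates Candidate tibble with `family` (and optionally
#'   `prefix`) columns.
#' @return The tibble with a `gene_id` column.
#' @export
assign_gene_ids <- function(candidates) {
  if (nrow(candidates) == 0) {
    candidates$gene_id <- character(0)
    return(candidates)
  }
  if (!"prefix" %in% names(candidates)) {
    candidates$prefix <- unname(.FAMILY_PREFIX[candidates$family])
  }
  candidates |>
    dplyr::group_by(.data$family) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$best_hit_accession,
                   .data$contig_ids, .by_group = TRUE) |>
    dplyr::mutate(gene_id = paste0(.data$prefix, dplyr::row_number())) |>
    dplyr::ungroup() |>
    dplyr::relocate("gene_id")
}

#' Write the candidate report (TSV + JSON summary)
#'
#' @param candidates An `amp_candidates` tibble.
#' @param path Output TSV path; the JSON summary (counts per family and per
#'   completeness class) is written next to it unless `json_path` is given.
#' @param json_path Optional JSON summary path.
#' @export
report_candidates <- function(candidates, path, json_path = NULL) {
  write_candidate_table(candidates, path)
  if (is.null(json_path)) json_path <- sub("\\.[^.]*$", "", path)
  if (!grepl("\\.json$", json_path)) json_path <- paste0(json_path, ".json")
  count_sorted <- function(x) {
    tb <- table(x)
    as.list(setNames(as.integer(tb), names(tb)))
  }
  summary <- list(
    n_candidates = nrow(candidates),
    by_family = count_sorted(candidates$family),
    by_completeness = count_sorted(candidates$completeness)
  )
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(path, json_path))
}
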