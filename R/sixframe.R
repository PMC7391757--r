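#' Reverse-complement nucleotide sequences
#'
#' @param seq Character vector of `A,C,G,T,N` sequences.
#' @return Character vector of the same length.
#' @export
reverse_complement <- function(seq) {
  bad <- regexpr("[^ACGTN]", seq)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop("illegal nucleotide '", substr(seq[i], bad[i], bad[i]),
         "' at position ", bad[i], call. = FALSE)
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

# translate from a 1-based offset within `seq`; codons containing anything
# outside ACGT (e.g. N) render "X"; trailing partial codon dropped
.translate_offset <- function(seq, offset) {
  n <- nchar(seq)
  if (n - offset + 1 < 3) return("")
  starts <- seq.int(offset, n - 2, by = 3)
  codons <- substring(seq, starts, starts + 2)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Translate one reading frame
#'
#' Standard genetic code; stop codons render `*`, codons containing `N`
#' render `X`, a trailing partial codon is dropped. Negative frames translate
#' the reverse complement at the corresponding offset.
#'
#' @param seq A nucleotide sequence (single string).
#' @param frame One of `+1, +2, +3, -1, -2, -3`.
#' @return The protein string (possibly empty).
#' @export
translate_frame <- function(seq, frame) {
  stopifnot(length(seq) == 1, frame %in% c(1, 2, 3, -1, -2, -3))
  if (frame > 0) .translate_offset(toupper(seq), frame)
  else .translate_offset(reverse_complement(toupper(seq)), -frame)
}

#' Six-frame translation of contigs
#'
#' @param contigs Tibble with columns `id`, `seq` (nucleotide).
#' @return Tibble with one row per contig and frame, frames in the fixed
#'   order `+1,+2,+3,-1,-2,-3`: columns `contig_id`, `frame`, `protein`,
#'   `contig_len`.
#' @export
six_frame_translate <- function(contigs) {
  frames <- c(1L, 2L, 3L, -1L, -2L, -3L)
  purrr::map_dfr(seq_len(nrow(contigs)), function(i) {
    s <- toupper(contigs$seq[i])
    rc <- if (nchar(s) >= 3) reverse_complement(s) else s
    tibble::tibble(
      contig_id = contigs$id[i],
      frame = frames,
      protein = vapply(frames, function(f) {
        if (f > 0) .translate_offset(s, f) else .translate_offset(rc, -f)
      }, ""),
      contig_len = nchar(s)
    )
  })
}

#' Map a protein span in a reading frame to forward-strand coordinates
#'
#' @param contig_len Contig length in nt.
#' @param frame Frame (`+1..+3`, `-1..-3`).
#' @param p_start,p_end 1-based inclusive protein positions within the frame
#'   translation.
#' @return List with `start_nt`, `end_nt` (1-based inclusive, forward
#'   strand; span is exactly `3 * (p_end - p_start + 1)` nt) and `strand`.
#' @export
map_protein_span_to_nt <- function(contig_len, frame, p_start, p_end) {
  stopifnot(frame %in% c(1, 2, 3, -1, -2, -3))
  off <- abs(frame)
  n_codon <- (contig_len - off + 1) %/% 3
  if (p_start < 1 || p_end < p_start || p_end > n_codon) {
    stop("protein span out of range for frame ", frame)
  }
  if (frame > 0) {
    list(start_nt = off + 3 * (p_start - 1),
         end_nt = off + 3 * p_end - 1,
         strand = "+")
  } else {
    list(start_nt = contig_len - off - 3 * p_end + 2,
         end_nt = contig_len - off - 3 * (p_start - 1) + 1,
         strand = "-")
  }
}

# classify one stop-free stretch of a frame translation;
# returns NULL or list(aa_start, aa_end, completeness)
.classify_stretch <- function(chars, a, b, bounded_right, min_aa) {
  m <- which(chars[a:b] == "M")
  m <- if (length(m)) a + m[1] - 1 else NA_integer_
  if (bounded_right) {           # an in-frame stop follows the stretch
    if (!is.na(m)) {
      list(aa_start = m, aa_end = b, completeness = "complete")
    } else if (a == 1L) {        # open end abuts the contig boundary
      list(aa_start = a, aa_end = b, completeness = "five_prime_fragment")
    } else NULL
  } else {                       # stretch runs into the contig end
    if (!is.na(m)) {
      list(aa_start = m, aa_end = b, completeness = "three_prime_fragment")
    } else if (a == 1L) {        # no stop anywhere: spans the whole frame
      list(aa_start = a, aa_end = b, completeness = "internal_fragment")
    } else NULL
  }
}

#' Find open reading frames in contigs
#'
#' Scans all six frames for maximal stop-free stretches. Complete ORFs run
#' from the first ATG of a stretch to the codon before the in-frame stop (the
#' stop codon is excluded from the span, so span = 3 x protein length).
#' Stretches truncated by the contig boundary are reported as
#' `three_prime_fragment` (no stop; from the first ATG when present),
#' `five_prime_fragment` (stop but no preceding ATG, open end at the
#' boundary) or `internal_fragment` (whole frame, neither). Coordinates are
#' 1-based inclusive on the forward strand with a strand flag.
#'
#' @param contigs Tibble with columns `id`, `seq`.
#' @param min_aa Minimum protein length to report (default 25).
#' @return Tibble: `contig_id`, `strand`, `frame`, `start_nt`, `end_nt`,
#'   `aa_start`, `aa_end` (positions within the frame translation),
#'   `protein`, `length_aa`, `completeness`.
#' @export
find_orfs <- function(contigs, min_aa = 25) {
  stopifnot(min_aa >= 1)
  fts <- six_frame_translate(contigs)
  out <- purrr::map_dfr(seq_len(nrow(fts)), function(i) {
    prot <- fts$protein[i]
    n_aa <- nchar(prot)
    if (n_aa == 0) return(NULL)
    chars <- .chars(prot)
    stops <- which(chars == "*")
    starts <- c(1L, stops + 1L)
    ends <- c(stops - 1L, n_aa)
    keep <- starts <= ends
    starts <- starts[keep]; ends <- ends[keep]
    if (!length(starts)) return(NULL)
    res <- purrr::map(seq_along(starts), function(k) {
      # bounded_right is TRUE iff position ends[k]+1 is a stop codon
      bounded <- (ends[k] + 1L) %in% stops
      o <- .classify_stretch(chars, starts[k], ends[k], bounded, min_aa)
      if (is.null(o) || (o$aa_end - o$aa_start + 1) < min_aa) return(NULL)
      sp <- map_protein_span_to_nt(fts$contig_len[i], fts$frame[i],
                                   o$aa_start, o$aa_end)
      tibble::tibble(
        contig_id = fts$contig_id[i], strand = sp$strand,
        frame = fts$frame[i], start_nt = sp$start_nt, end_nt = sp$end_nt,
        aa_start = o$aa_start, aa_end = o$aa_end,
        protein = substr(prot, o$aa_start, o$aa_end),
        length_aa = o$aa_end - o$aa_start + 1L,
        completeness = o$completeness
      )
    })
    dplyr::bind_rows(res)
  })
  if (nrow(out) == 0) {
    return(tibble::tibble(contig_id = character(), strand = character(),
                          frame = integer(), start_nt = integer(),
                          end_nt = integer(), aa_start = integer(),
                          aa_end = integer(), protein = character(),
                          length_aa = integer(), completeness = character()))
  }
  out
}

# longest exact overlap with suffix of `x` equal to prefix of `y`,
# at least min_overlap; 0 if none
.overlap_len <- function(x, y, min_overlap) {
  nx <- nchar(x); ny <- nchar(y)
  for (k in seq(min(nx, ny), min_overlap)) {
    if (substr(x, nx - k + 1, nx) == substr(y, 1, k)) return(k)
  }
  0L
}

#' Merge two contigs sharing an exact terminal overlap
#'
#' Tests suffix/prefix overlaps in both arrangements and both orientations of
#' `b`; the longest exact overlap of at least `min_overlap` nt wins, with
#' ties broken toward the orientation preserving `a`'s strand. The merged
#' identifier is always `a$id + "+" + b$id`.
#'
#' @param a,b One-row tibbles (or lists) with `id` and `seq`.
#' @param min_overlap Minimum exact overlap in nt (default 30).
#' @return `NULL` when no admissible overlap exists, else a list with
#'   `merged` (tibble: `id`, `desc`, `seq`), `left_id`, `right_id`,
#'   `overlap_len`, `b_orientation` (`"forward"` or `"revcomp"`).
#' @export
merge_overlapping_contigs <- function(a, b, min_overlap = 30) {
  stopifnot(min_overlap >= 1)
  sa <- toupper(a$seq[1]); sb <- toupper(b$seq[1])
  if (min(nchar(sa), nchar(sb)) < min_overlap) return(NULL)
  cands <- list(
    list(x = sa, y = sb, left = a$id[1], right = b$id[1], orient = "forward"),
    list(x = sb, y = sa, left = b$id[1], right = a$id[1], orient = "forward"),
    list(x = sa, y = reverse_complement(sb), left = a$id[1], right = b$id[1],
         orient = "revcomp"),
    list(x = reverse_complement(sb), y = sa, left = b$id[1], right = a$id[1],
         orient = "revcomp")
  )
  ov <- vapply(cands, function(cc) .overlap_len(cc$x, cc$y, min_overlap), 0L)
  if (max(ov) == 0L) return(NULL)
  best <- cands[[which.max(ov)]]   # first maximum: forward b preferred on ties
  k <- max(ov)
  merged_seq <- paste0(best$x, substr(best$y, k + 1, nchar(best$y)))
  list(
    merged = tibble::tibble(id = paste0(a$id[1], "+", b$id[1]),
                            desc = "", seq = merged_seq),
    left_id = best$left, right_id = best$right,
    overlap_len = k, b_orientation = best$orient
  )
}
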