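#' Construct an alignment scoring scheme
#'
#' Default: bundled BLOSUM62 with affine gap costs (a gap of length k costs
#' `gap_open + k * gap_extend`, BLAST-style). The `X` row and column are
#' forced to -1 so unknown residues score -1 against everything.
#'
#' @param matrix Integer substitution matrix with residue dimnames, or `NULL`
#'   for the bundled BLOSUM62 (see [read_score_matrix()]).
#' @param gap_open,gap_extend Positive integer gap costs,
#'   `gap_open >= gap_extend >= 1`.
#' @param matrix_name Label for reporting.
#' @return Object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(matrix = NULL, gap_open = 11, gap_extend = 1,
                           matrix_name = "BLOSUM62") {
  if (is.null(matrix)) {
    matrix <- read_score_matrix(system.file("extdata", "BLOSUM62.txt",
                                            package = "ampminer"))
  }
  stopifnot(gap_open >= gap_extend, gap_extend >= 1)
  if (!isTRUE(all.equal(matrix, t(matrix), check.attributes = FALSE))) {
    stop("substitution matrix must be symmetric")
  }
  if ("X" %in% rownames(matrix)) {
    matrix["X", ] <- -1L
    matrix[, "X"] <- -1L
  }
  structure(list(matrix_name = matrix_name, substitution = matrix,
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend)),
            class = "scoring_scheme")
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat("<scoring_scheme> ", x$matrix_name, ", gap open ", x$gap_open,
      ", extend ", x$gap_extend, "\n", sep = "")
  invisible(x)
}

#' Smith-Waterman local alignment of two peptides
#'
#' Exact affine-gap local alignment (Gotoh), deterministic traceback (ties:
#' diagonal > up > left; best cell = first maximum in row-major order).
#'
#' @param a,b Amino-acid sequences (single strings, non-empty).
#' @param scheme A [scoring_scheme()].
#' @return List: `score`, `a_start`, `a_end`, `b_start`, `b_end` (1-based
#'   inclusive), `a_aln`, `b_aln` (gapped aligned strings),
#'   `percent_identity`, `percent_positive`. A score of 0 means no alignment
#'   (spans are `NA`).
#' @export
smith_waterman <- function(a, b, scheme = scoring_scheme()) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  res <- .sw_align_cpp(a, b, scheme$substitution,
                       scheme$gap_open, scheme$gap_extend)
  if (res$score == 0) {
    res$percent_identity <- NA_real_
    res$percent_positive <- NA_real_
    return(res)
  }
  ca <- .chars(res$a_aln); cb <- .chars(res$b_aln)
  len <- length(ca)
  both <- ca != "-" & cb != "-"
  idn <- sum(ca == cb & both)
  pos <- idn
  mism <- which(both & ca != cb)
  if (length(mism)) {
    pos <- pos + sum(scheme$substitution[cbind(ca[mism], cb[mism])] > 0)
  }
  res$percent_identity <- 100 * idn / len
  res$percent_positive <- 100 * pos / len
  res
}

.empty_hits <- function() {
  tibble::tibble(query_id = character(), query_name = character(),
                 subject_id = character(), frame = integer(),
                 score = integer(), percent_identity = double(),
                 percent_positive = double(), q_start = integer(),
                 q_end = integer(), s_start = integer(), s_end = integer(),
                 nt_start = integer(), nt_end = integer(),
                 strand = character())
}

.sort_hits <- function(hits) {
  dplyr::arrange(hits, dplyr::desc(.data$score), .data$subject_id,
                 .data$query_id)
}

#' Search AMP reference peptides against a protein set
#'
#' Exhaustive all-vs-all local alignment; hits at or above `min_score` are
#' returned sorted by descending score then subject id. `frame` is `NA`
#' (protein-space search).
#'
#' @param amps Tibble of reference entries ([parse_amp_reference()]).
#' @param proteins Tibble with columns `id`, `seq` (amino-acid records).
#' @param scheme A [scoring_scheme()].
#' @param min_score Raw-score threshold (default 90).
#' @return Tibble of alignment hits.
#' @export
search_amps_vs_proteins <- function(amps, proteins,
                                    scheme = scoring_scheme(),
                                    min_score = 90) {
  if (nrow(proteins) == 0 || nrow(amps) == 0) return(.empty_hits())
  rows <- purrr::map_dfr(seq_len(nrow(amps)), function(i) {
    purrr::map_dfr(seq_len(nrow(proteins)), function(j) {
      r <- smith_waterman(amps$mature_sequence[i], proteins$seq[j], scheme)
      if (r$score < min_score) return(NULL)
      tibble::tibble(query_id = amps$accession[i],
                     query_name = amps$name[i],
                     subject_id = proteins$id[j], frame = NA_integer_,
                     score = r$score,
                     percent_identity = r$percent_identity,
                     percent_positive = r$percent_positive,
                     q_start = r$a_start, q_end = r$a_end,
                     s_start = r$b_start, s_end = r$b_end,
                     nt_start = NA_integer_, nt_end = NA_integer_,
                     strand = NA_character_)
    })
  })
  if (nrow(rows) == 0) return(.empty_hits())
  .sort_hits(rows)
}

#' Search AMP reference peptides against six-frame translated contigs
#'
#' Each reference is aligned against all six frame translations of each
#' contig (a tblastn-style search done exactly); hits carry the frame, the
#' protein-space subject span within that frame, and the forward-strand
#' nucleotide span.
#'
#' @inheritParams search_amps_vs_proteins
#' @param contigs Tibble with columns `id`, `seq` (nucleotide records).
#' @return Tibble of alignment hits (same schema as
#'   [search_amps_vs_proteins()], with `frame`, `nt_start`, `nt_end`,
#'   `strand` filled in).
#' @export
search_amps_vs_sixframe <- function(amps, contigs,
                                    scheme = scoring_scheme(),
                                    min_score = 90) {
  if (nrow(contigs) == 0 || nrow(amps) == 0) return(.empty_hits())
  fts <- six_frame_translate(contigs)
  fts <- fts[nchar(fts$protein) > 0, ]
  rows <- purrr::map_dfr(seq_len(nrow(amps)), function(i) {
    purrr::map_dfr(seq_len(nrow(fts)), function(j) {
      r <- smith_waterman(amps$mature_sequence[i], fts$protein[j], scheme)
      if (r$score < min_score) return(NULL)
      sp <- map_protein_span_to_nt(fts$contig_len[j], fts$frame[j],
                                   r$b_start, r$b_end)
      tibble::tibble(query_id = amps$accession[i],
                     query_name = amps$name[i],
                     subject_id = fts$contig_id[j], frame = fts$frame[j],
                     score = r$score,
                     percent_identity = r$percent_identity,
                     percent_positive = r$percent_positive,
                     q_start = r$a_start, q_end = r$a_end,
                     s_start = r$b_start, s_end = r$b_end,
                     nt_start = sp$start_nt, nt_end = sp$end_nt,
                     strand = sp$strand)
    })
  })
  if (nrow(rows) == 0) return(.empty_hits())
  .sort_hits(rows)
}
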