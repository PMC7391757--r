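#' Reads per kilobase of transcript per million mapped reads
#'
#' `rpkm = 1e9 * C / (L * N)` with C mapped reads, L transcript length in
#' nt, N total mapped reads in the library. Vectorised.
#'
#' @param reads Non-negative read counts.
#' @param length_nt Positive transcript lengths (nt).
#' @param library_total Positive library totals.
#' @return Numeric vector.
#' @export
rpkm <- function(reads, length_nt, library_total) {
  if (any(length_nt <= 0)) stop("transcript length must be positive")
  if (any(library_total <= 0)) stop("library total must be positive")
  if (any(reads < 0)) stop("reads must be non-negative")
  1e9 * as.numeric(reads) / (as.numeric(length_nt) *
                               as.numeric(library_total))
}

#' Expression tier from summed raw reads
#'
#' Tiers follow the printed read anchors: `high` above 3,000 reads, `low`
#' below 100, `medium` otherwise (the "around 1,000" class formalised as
#' the closed interval 100..3000).
#'
#' @param total_reads Non-negative summed read counts (vectorised).
#' @return Character vector of `"high"`, `"medium"`, `"low"`.
#' @export
expression_tier <- function(total_reads) {
  if (any(total_reads < 0)) stop("reads must be non-negative")
  dplyr::case_when(total_reads > 3000 ~ "high",
                   total_reads < 100 ~ "low",
                   TRUE ~ "medium")
}

#' Quantify candidate expression across libraries
#'
#' Joins a candidate table to a counts table: a candidate's reads in a
#' library are summed over its contigs, L is its transcript length, N the
#' library total. The tier is computed from reads summed over all libraries.
#'
#' @param candidates Candidate tibble ([mine_amps()]); needs `gene_id`,
#'   `contig_ids` (joined with `+`), `transcript_length_nt`.
#' @param counts A `counts_table` ([read_counts_table()]).
#' @return Tibble of class `amp_expression`: `gene_id`, `library_id`,
#'   `reads`, `length_nt`, `library_total`, `rpkm`, `tier`.
#' @export
quantify_expression <- function(candidates, counts) {
  stopifnot(inherits(counts, "counts_table"))
  libs <- counts$library_ids
  rows <- purrr::map_dfr(seq_len(nrow(candidates)), function(i) {
    ids <- strsplit(candidates$contig_ids[i], "+", fixed = TRUE)[[1]]
    sub <- counts$counts[counts$counts$id %in% ids, ]
    per_lib <- setNames(numeric(length(libs)), libs)
    if (nrow(sub)) {
      agg <- tapply(sub$reads, sub$library_id, sum)
      per_lib[names(agg)] <- agg
    }
    tibble::tibble(
      gene_id = candidates$gene_id[i],
      library_id = libs,
      reads = unname(per_lib),
      length_nt = candidates$transcript_length_nt[i],
      library_total = unname(counts$library_totals[libs])
    )
  })
  rows$rpkm <- rpkm(rows$reads, rows$length_nt, rows$library_total)
  totals <- tapply(rows$reads, rows$gene_id, sum)
  rows$tier <- unname(expression_tier(totals[rows$gene_id]))
  class(rows) <- c("amp_expression", class(rows))
  rows
}

#' Per-gene mean RPKM across libraries
#'
#' @param records An `amp_expression` tibble ([quantify_expression()]).
#' @return Tibble `gene_id`, `mean_rpkm`, `total_reads`, `tier`, sorted by
#'   descending mean.
#' @export
summarize_mean_rpkm <- function(records) {
  stopifnot(nrow(records) > 0)
  records |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(mean_rpkm = mean(.data$rpkm),
                     total_reads = sum(.data$reads),
                     tier = dplyr::first(.data$tier),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$mean_rpkm))
}
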