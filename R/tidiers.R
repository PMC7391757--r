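#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an AMP candidate table
#'
#' @param x An `amp_candidates` tibble.
#' @param ... Unused.
#' @return A plain tibble with the report columns (one row per candidate).
#' @export
tidy.amp_candidates <- function(x, ...) {
  tibble::as_tibble(x)[, c("gene_id", "family", "contig_ids", "strand",
                           "start_nt", "end_nt", "completeness",
                           "peptide_length_aa", "best_hit_accession",
                           "best_hit_name", "score", "signal_peptide_flag",
                           "domain_list", "passes_amp_screen", "embedded")]
}

#' One-row summary of a mining run
#'
#' @inheritParams tidy.amp_candidates
#' @return Tibble with candidate, family and completeness counts and score
#'   range.
#' @export
glance.amp_candidates <- function(x, ...) {
  tibble::tibble(
    n_candidates = nrow(x),
    n_families = dplyr::n_distinct(x$family),
    n_complete = sum(x$completeness == "complete"),
    n_fragments = sum(x$completeness != "complete"),
    n_signal_peptide = sum(x$signal_peptide_flag),
    min_score = if (nrow(x)) min(x$score) else NA_integer_,
    max_score = if (nrow(x)) max(x$score) else NA_integer_
  )
}

#' Plot candidate scores by family
#'
#' @param object An `amp_candidates` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.amp_candidates <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$gene_id <- factor(df$gene_id, levels = rev(df$gene_id))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = .data$gene_id,
                                   fill = .data$family)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = attr(object, "config")$min_score,
                        linetype = "dashed") +
    ggplot2::labs(x = "best local-alignment score", y = NULL,
                  fill = "family") +
    ggplot2::theme_minimal()
}

#' Tidy an expression table
#'
#' @param x An `amp_expression` tibble.
#' @param ... Unused.
#' @export
tidy.amp_expression <- function(x, ...) {
  tibble::as_tibble(x)
}

#' One-row summary of an expression table
#'
#' @inheritParams tidy.amp_expression
#' @export
glance.amp_expression <- function(x, ...) {
  s <- summarize_mean_rpkm(x)
  tibble::tibble(
    n_genes = nrow(s),
    n_libraries = dplyr::n_distinct(x$library_id),
    n_high = sum(s$tier == "high"),
    n_medium = sum(s$tier == "medium"),
    n_low = sum(s$tier == "low")
  )
}

#' Plot average RPKM per gene
#'
#' @param object An `amp_expression` tibble.
#' @param ... Unused.
#' @return A ggplot object (mean RPKM per gene, coloured by tier).
#' @export
autoplot.amp_expression <- function(object, ...) {
  s <- summarize_mean_rpkm(object)
  s$gene_id <- factor(s$gene_id, levels = rev(s$gene_id))
  ggplot2::ggplot(s, ggplot2::aes(x = .data$mean_rpkm, y = .data$gene_id,
                                  fill = .data$tier)) +
    ggplot2::geom_col() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "mean RPKM across libraries", y = NULL,
                  fill = "tier") +
    ggplot2::theme_minimal()
}

#' @export
print.amp_candidates <- function(x, ...) {
  cat("# AMP candidate table:", nrow(x), "candidate(s),",
      dplyr::n_distinct(x$family), "family(ies)\n")
  NextMethod()
}
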