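#' Read a FASTA file into a tibble of sequence records
#'
#' Headers are split at the first whitespace into `id` and `desc`; residues
#' are upper-cased and validated against the declared alphabet (nucleotide
#' `A,C,G,T,N` or the 20 amino acids plus `X` and `*`).
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"nucleotide"` or `"protein"`.
#' @return A tibble with columns `id`, `desc`, `seq`, `alphabet`, one row per
#'   record, in file order.
#' @export
read_fasta <- function(path, alphabet = c("nucleotide", "protein")) {
  alphabet <- match.arg(alphabet)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("no records in '", path, "'",
                                           call. = FALSE))
  if (length(set) == 0) stop("no records in '", path, "'", call. = FALSE)
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(as.character(set))
  recs <- tibble::tibble(id = unname(id), desc = unname(desc),
                         seq = unname(seqs), alphabet = alphabet)
  validate_records(recs)
  recs
}

validate_records <- function(recs) {
  allowed <- ifelse(recs$alphabet == "nucleotide",
                    "[^ACGTN]", "[^ACDEFGHIKLMNPQRSTVWYX*]")
  for (i in seq_len(nrow(recs))) {
    if (!nzchar(recs$id[i])) stop("record ", i, ": empty identifier")
    if (!nzchar(recs$seq[i])) stop("record '", recs$id[i], "': empty sequence")
    bad <- regexpr(allowed[i], recs$seq[i])
    if (bad > 0) {
      stop("record '", recs$id[i], "': illegal character '",
           substr(recs$seq[i], bad, bad), "' at position ", bad,
           " for ", recs$alphabet[i], " alphabet", call. = FALSE)
    }
  }
  invisible(recs)
}

#' Write sequence records to a FASTA file
#'
#' @param records Tibble with columns `id`, `seq` and optionally `desc`.
#' @param path Output path.
#' @param width Line-wrap width (positive integer).
#' @export
write_fasta <- function(records, path, width = 60) {
  stopifnot(nrow(records) > 0, width >= 1)
  desc <- if ("desc" %in% names(records)) records$desc else ""
  headers <- ifelse(nzchar(desc), paste(records$id, desc), records$id)
  set <- Biostrings::BStringSet(records$seq)
  names(set) <- headers
  Biostrings::writeXStringSet(set, filepath = path, width = as.integer(width))
  invisible(path)
}

#' Parse AMP reference entries from FASTA records
#'
#' Reference headers follow the APD convention `AP<digits>_<name>`, e.g.
#' `AP02959_Paralithocin 1`. Records whose header lacks the accession prefix
#' are skipped with a warning; the number of skips is attached as attribute
#' `n_skipped`.
#'
#' @param records Tibble of protein records as returned by [read_fasta()].
#' @return Tibble with columns `accession`, `name`, `mature_sequence`,
#'   `family_hint`.
#' @export
parse_amp_reference <- function(records) {
  header <- ifelse(nzchar(records$desc),
                   paste(records$id, records$desc), records$id)
  ok <- grepl("^AP[0-9]+_", header)
  n_skipped <- sum(!ok)
  if (n_skipped > 0) {
    warning(n_skipped, " record(s) without APD-style 'AP<digits>_' header ",
            "skipped: ", paste(head(header[!ok], 5), collapse = ", "),
            call. = FALSE)
  }
  header <- header[ok]
  entries <- tibble::tibble(
    accession = sub("_.*$", "", header),
    name = sub("^[^_]+_", "", header),
    mature_sequence = records$seq[ok],
    family_hint = NA_character_
  )
  short <- nchar(entries$mature_sequence) < 5
  if (any(short)) {
    stop("mature sequence shorter than 5 aa: ",
         paste(entries$accession[short], collapse = ", "))
  }
  attr(entries, "n_skipped") <- n_skipped
  entries
}

#' Read a per-library read-counts table
#'
#' Tab-separated; first column holds gene/contig identifiers, remaining
#' columns one per library. An optional final `TOTAL` row gives per-library
#' mapped-read totals; otherwise column sums are used.
#'
#' @param path Path to the TSV file.
#' @return An object of class `counts_table`: a list with `counts` (long
#'   tibble: `id`, `library_id`, `reads`), `library_ids`, and
#'   `library_totals` (named numeric).
#' @export
read_counts_table <- function(path) {
  raw <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  if (ncol(raw) < 2) stop("counts table needs an id column and >= 1 library")
  libs <- colnames(raw)[-1]
  ids <- raw[[1]]
  mat <- as.matrix(raw[, -1, drop = FALSE])
  for (j in seq_along(libs)) {
    for (i in seq_along(ids)) {
      v <- suppressWarnings(as.numeric(mat[i, j]))
      if (is.na(v) || v < 0 || v != round(v)) {
        stop("invalid count '", mat[i, j], "' at row ", i, " (", ids[i],
             "), column '", libs[j], "': counts must be non-negative integers")
      }
    }
  }
  num <- matrix(as.numeric(mat), nrow = nrow(mat),
                dimnames = list(NULL, libs))
  is_total <- ids == "TOTAL"
  if (sum(is_total) > 1) stop("multiple TOTAL rows")
  if (any(is_total)) {
    totals <- num[is_total, ]
    num <- num[!is_total, , drop = FALSE]
    ids <- ids[!is_total]
    if (any(totals < colSums(num))) {
      stop("TOTAL row smaller than column sums")
    }
  } else {
    totals <- colSums(num)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate id(s): ", paste(unique(ids[duplicated(ids)]),
                                    collapse = ", "))
  }
  counts <- tibble::tibble(
    id = rep(ids, times = length(libs)),
    library_id = rep(libs, each = length(ids)),
    reads = as.vector(num)
  )
  structure(list(counts = counts, library_ids = libs,
                 library_totals = setNames(as.numeric(totals), libs)),
            class = "counts_table")
}

#' Write a counts table to TSV (wide format, with TOTAL row)
#'
#' @param x A `counts_table` object.
#' @param path Output path.
#' @export
write_counts_table <- function(x, path) {
  stopifnot(inherits(x, "counts_table"))
  wide <- tidyr::pivot_wider(x$counts, names_from = "library_id",
                             values_from = "reads", values_fill = 0)
  wide <- wide[, c("id", x$library_ids)]
  total <- c(list(id = "TOTAL"), as.list(x$library_totals))
  out <- rbind(as.data.frame(wide), as.data.frame(total, check.names = FALSE))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# fixed column order of the candidate report
.REPORT_COLS <- c("gene_id", "contig_ids", "best_hit_accession",
                  "best_hit_name", "peptide_length_aa", "completeness",
                  "signal_peptide_flag", "domain_list", "family",
                  "embedded_flag", "score")

#' Write the candidate report table
#'
#' Tab-separated with a fixed column order so downstream diffs are stable:
#' gene_id, contig_ids (joined with `+`), best_hit_accession, best_hit_name,
#' peptide_length_aa, completeness, signal_peptide_flag, domain_list, family,
#' embedded_flag, score. An empty candidate set yields a header-only file.
#'
#' @param candidates Candidate tibble as returned by [mine_amps()].
#' @param path Output path.
#' @export
write_candidate_table <- function(candidates, path) {
  if (is.null(candidates) || nrow(candidates) == 0) {
    writeLines(paste(.REPORT_COLS, collapse = "\t"), path)
    return(invisible(path))
  }
  out <- tibble::tibble(
    gene_id = candidates$gene_id,
    contig_ids = candidates$contig_ids,
    best_hit_accession = candidates$best_hit_accession,
    best_hit_name = candidates$best_hit_name,
    peptide_length_aa = candidates$peptide_length_aa,
    completeness = candidates$completeness,
    signal_peptide_flag = candidates$signal_peptide_flag,
    domain_list = candidates$domain_list,
    family = candidates$family,
    embedded_flag = candidates$embedded,
    score = candidates$score
  )
  write.table(as.data.frame(out), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Load a substitution matrix from an NCBI-format text file
#'
#' @param path Path to a matrix file (`#` comment lines, a header row of
#'   residue letters, then one labelled row per residue).
#' @return Integer matrix with residue dimnames.
#' @export
read_score_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- strsplit(trimws(lines[-1]), "\\s+")
  labels <- vapply(rows, `[`, "", 1)
  vals <- lapply(rows, function(r) as.integer(r[-1]))
  mat <- do.call(rbind, vals)
  dimnames(mat) <- list(labels, header)
  if (!identical(rownames(mat), colnames(mat))) {
    stop("matrix rows and columns disagree")
  }
  mat
}
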