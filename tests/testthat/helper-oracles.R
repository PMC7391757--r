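# Independent oracles, deliberately coded without reusing the package's
# implementation paths.

# plain-R Gotoh affine local alignment, score only; a gap of length k costs
# open + k * ext
sw_oracle_score <- function(a, b, submat, open, ext) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)
  F <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(M[i, j - 1] - open - ext, E[i, j - 1] - ext)
      F[i, j] <- max(M[i - 1, j] - open - ext, F[i - 1, j] - ext)
      d <- max(M[i - 1, j - 1], E[i - 1, j - 1], F[i - 1, j - 1]) +
        submat[av[i - 1], bv[j - 1]]
      M[i, j] <- max(0, d)
      best <- max(best, M[i, j])
    }
  }
  best
}

# exhaustive ORF enumeration over every (frame, start, stop) combination;
# frame translations come from Biostrings, not from the package
orf_oracle <- function(seq, min_aa) {
  L <- nchar(seq)
  out <- list()
  for (frame in c(1L, 2L, 3L, -1L, -2L, -3L)) {
    off <- abs(frame)
    s <- if (frame > 0) seq else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    n_codon <- (nchar(s) - off + 1) %/% 3
    if (n_codon < 1) next
    sub <- substr(s, off, off + 3 * n_codon - 1)
    prot <- as.character(Biostrings::translate(Biostrings::DNAString(sub),
                                               if.fuzzy.codon = "X", no.init.codon = TRUE))
    aa <- strsplit(prot, "")[[1]]
    stops <- which(aa == "*")
    span_fwd <- function(m, b) {
      if (frame > 0) c(off + 3 * (m - 1), off + 3 * b - 1)
      else c(L - (off + 3 * b - 1) + 1, L - (off + 3 * (m - 1)) + 1)
    }
    emit <- function(m, b, cls) {
      if (b - m + 1 < min_aa) return()
      sp <- span_fwd(m, b)
      out[[length(out) + 1L]] <<- data.frame(
        frame = frame, start_nt = sp[1], end_nt = sp[2],
        protein = paste(aa[m:b], collapse = ""), completeness = cls,
        stringsAsFactors = FALSE)
    }
    # for every stop, the stretch since the previous stop
    prev <- 0L
    for (st in stops) {
      if (st > prev + 1L) {
        region <- (prev + 1L):(st - 1L)
        ms <- region[aa[region] == "M"]
        if (length(ms)) emit(ms[1], st - 1L, "complete")
        else if (prev == 0L) emit(1L, st - 1L, "five_prime_fragment")
      }
      prev <- st
    }
    if (prev < n_codon) {          # trailing stretch without a stop
      region <- (prev + 1L):n_codon
      ms <- region[aa[region] == "M"]
      if (length(ms)) emit(ms[1], n_codon, "three_prime_fragment")
      else if (prev == 0L) emit(1L, n_codon, "internal_fragment")
    }
  }
  if (!length(out)) {
    return(data.frame(frame = integer(), start_nt = integer(),
                      end_nt = integer(), protein = character(),
                      completeness = character()))
  }
  do.call(rbind, out)
}

random_nt <- function(n, with_n = FALSE) {
  pool <- if (with_n) c("A", "C", "G", "T", "N") else c("A", "C", "G", "T")
  prob <- if (with_n) c(rep(0.2425, 4), 0.03) else rep(0.25, 4)
  paste(sample(pool, n, replace = TRUE, prob = prob), collapse = "")
}

AA20 <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")

random_protein <- function(n, with_x = FALSE) {
  pool <- if (with_x) c(AA20, "X") else AA20
  paste(sample(pool, n, replace = TRUE), collapse = "")
}
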