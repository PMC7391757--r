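# max-mean hydrophobic window of length >= 7 within chars[from..to];
# NULL when no window reaches the cutoff, else list(start, end, mean)
.best_h_window <- function(kd, from, to, min_len = 7, cutoff = 1.5) {
  if (to - from + 1 < min_len) return(NULL)
  best <- NULL
  cs <- c(0, cumsum(kd))
  for (s in from:(to - min_len + 1)) {
    for (e in (s + min_len - 1):to) {
      m <- (cs[e + 1] - cs[s]) / (e - s + 1)
      if (m >= cutoff && (is.null(best) || m > best$mean)) {
        best <- list(start = s, end = e, mean = m)
      }
    }
  }
  best
}

#' Predict an N-terminal signal peptide and its cleavage site
#'
#' A deterministic von Heijne-style heuristic. Candidate cleavage points
#' `p` in 15..35 are valid when (i) the n-region (positions `1..max(2,p-15)`)
#' contains K or R, or the protein begins with M followed within five
#' residues by K or R; (ii) some window of at least seven consecutive
#' residues within `3..p-3` has mean Kyte-Doolittle hydropathy >= 1.5 (the
#' h-region); and (iii) the (-3,-1) rule holds: residue `p` is one of
#' A,G,S,C,T,Q and residue `p-2` one of A,G,S,C,T,V,L,I. Among valid
#' candidates the one maximising h-region mean hydropathy (+0.5 when residue
#' `p` is Ala) is returned; exact ties are resolved toward the candidate
#' closest to the canonical eukaryotic signal length of 23, then the smaller
#' index.
#'
#' @param protein Amino-acid sequence (single string).
#' @return `NULL` when no valid candidate (or protein shorter than 30 aa),
#'   else a one-row tibble: `cleavage_after`, `n_start`, `n_end`, `h_start`,
#'   `h_end`, `c_start`, `c_end`, `score`.
#' @export
predict_signal_peptide <- function(protein) {
  n <- nchar(protein)
  if (n < 30) return(NULL)
  chars <- .chars(protein)
  kd <- .KD[chars]
  kd[is.na(kd)] <- 0  # X and other unknowns treated as neutral
  has_m_start <- chars[1] == "M" &&
    any(chars[2:min(6, n)] %in% c("K", "R"))
  best <- NULL
  for (p in 15:min(35, n - 1)) {
    if (!(chars[p] %in% .SP_MINUS1)) next
    if (!(chars[p - 2] %in% .SP_MINUS3)) next
    nr_end <- max(2L, p - 15L)
    if (!(any(chars[1:nr_end] %in% c("K", "R")) || has_m_start)) next
    hw <- .best_h_window(kd, 3L, p - 3L)
    if (is.null(hw)) next
    score <- hw$mean + if (chars[p] == "A") 0.5 else 0
    # lexicographic preference: score, then closeness to 23, then smaller p
    key <- c(score, -abs(p - 23L), -p)
    better <- is.null(best) ||
      key[1] > best$key[1] ||
      (key[1] == best$key[1] && key[2] > best$key[2]) ||
      (key[1] == best$key[1] && key[2] == best$key[2] && key[3] > best$key[3])
    if (better) best <- list(p = p, hw = hw, score = score, key = key)
  }
  if (is.null(best)) return(NULL)
  tibble::tibble(
    cleavage_after = best$p,
    n_start = 1L, n_end = best$hw$start - 1L,
    h_start = best$hw$start, h_end = best$hw$end,
    c_start = best$hw$end + 1L, c_end = best$p,
    score = best$score
  )
}

.domain_hit <- function(kind, protein, start, end, detail = "") {
  span <- substr(protein, start, end)
  tibble::tibble(kind = kind, start = as.integer(start),
                 end = as.integer(end),
                 cysteine_count = stringr::str_count(span, stringr::fixed("C")),
                 detail = detail)
}

#' Detect a WAP (whey acidic protein) four-disulfide-core domain
#'
#' Bounded-gap eight-cysteine spacing pattern
#' `C x(3-10) C x(4-8) C x(4-8) C x(4-12) C x(4-10) C C x(3-6) C` with
#' cysteine-free gaps; the first match is reported.
#'
#' @param protein Amino-acid sequence.
#' @return `NULL` or a one-row tibble (`kind`, `start`, `end`,
#'   `cysteine_count`, `detail`).
#' @export
detect_wap <- function(protein) {
  pat <- "C[^C]{3,10}C[^C]{4,8}C[^C]{4,8}C[^C]{4,12}C[^C]{4,10}CC[^C]{3,6}C"
  m <- regexpr(pat, protein, perl = TRUE)
  if (m < 0) return(NULL)
  .domain_hit("WAP", protein, m, m + attr(m, "match.length") - 1L)
}

#' Detect a Kazal-type protease-inhibitor domain
#'
#' Spacing pattern `C x(7) C x(6) Y x(3) C x(2,3) C` with cysteine-free
#' gaps; the first match is reported.
#'
#' @inheritParams detect_wap
#' @return `NULL` or a one-row tibble.
#' @export
detect_kazal <- function(protein) {
  pat <- "C[^C]{7}C[^C]{6}Y[^C]{3}C[^C]{2,3}C"
  m <- regexpr(pat, protein, perl = TRUE)
  if (m < 0) return(NULL)
  .domain_hit("Kazal", protein, m, m + attr(m, "match.length") - 1L)
}

#' Detect an ALF-style cationic disulfide loop
#'
#' Looks for two cysteines 15-35 positions apart whose enclosed segment has
#' net charge >= +3 (K,R = +1, H = +0.5, D,E = -1); the highest-charge pair
#' is reported.
#'
#' @inheritParams detect_wap
#' @return `NULL` or a one-row tibble; `detail` carries the loop net charge.
#' @export
detect_alf_loop <- function(protein) {
  chars <- .chars(protein)
  cys <- which(chars == "C")
  if (length(cys) < 2) return(NULL)
  best <- NULL
  for (i in seq_along(cys)) {
    for (j in seq_along(cys)) {
      if (j <= i) next
      d <- cys[j] - cys[i]
      if (d < 15 || d > 35) next
      q <- .net_charge(chars[(cys[i] + 1):(cys[j] - 1)])
      if (q >= 3 && (is.null(best) || q > best$q)) {
        best <- list(i = cys[i], j = cys[j], q = q)
      }
    }
  }
  if (is.null(best)) return(NULL)
  .domain_hit("ALF_loop", protein, best$i, best$j,
              detail = sprintf("loop_net_charge=%+.1f", best$q))
}

#' Physicochemical profile and AMP screen
#'
#' Mass is the sum of average residue masses plus 18.02 Da (water), reported
#' in kDa; unknown residues (`X`) contribute 110 Da and are flagged in
#' `detail`. The screen passes iff length <= 150 aa and 2 <= mass <= 9 kDa
#' (the classical small-cationic-AMP window); hydrophobic fraction (residues
#' in A,I,L,M,F,V,W,C) is reported but not thresholded.
#'
#' @param peptide Amino-acid sequence without `*`.
#' @return One-row tibble: `length_aa`, `mass_kDa`, `net_charge`,
#'   `hydrophobic_fraction`, `passes_amp_screen`, `detail`.
#' @export
physchem_profile <- function(peptide) {
  if (!nzchar(peptide)) stop("empty peptide")
  if (grepl("*", peptide, fixed = TRUE)) stop("peptide contains '*'")
  chars <- .chars(peptide)
  unknown <- !(chars %in% .AA20)
  if (any(unknown & chars != "X")) {
    stop("illegal residue '", chars[unknown & chars != "X"][1], "'")
  }
  mass <- sum(.AA_MASS[chars[!unknown]]) + sum(unknown) * .MASS_X +
    .MASS_WATER
  len <- length(chars)
  mass_kda <- mass / 1000
  tibble::tibble(
    length_aa = len,
    mass_kDa = mass_kda,
    net_charge = .net_charge(chars),
    hydrophobic_fraction = mean(chars %in% .HYDROPHOBIC),
    passes_amp_screen = len <= 150 && mass_kda >= 2 && mass_kda <= 9,
    detail = if (any(unknown)) sprintf("%d unknown residue(s) at 110 Da",
                                       sum(unknown)) else ""
  )
}

.family_map_env <- new.env(parent = emptyenv())

.family_map <- function() {
  if (is.null(.family_map_env$map)) {
    tab <- read.delim(system.file("extdata", "amp_families.tsv",
                                  package = "ampminer"),
                      stringsAsFactors = FALSE)
    .family_map_env$map <- setNames(tab$family, tab$accession)
  }
  .family_map_env$map
}

.FAMILY_KEYWORDS <- c(
  paralithocin = "paralithocin",
  crustin = "crustin|carcinin",
  alf = "\\bALF\\b|anti-?lipopolysaccharide",
  kazal = "kazal|spink",
  buforin = "buforin|hipposin",
  acipensin = "acipensin",
  ubiquicidin = "ubiquicidin",
  lysozyme = "lysozyme",
  beta_thymosin = "thymosin"
)

#' Classify an AMP candidate into a family
#'
#' Family is taken from the bundled accession map; unmapped accessions fall
#' back to case-insensitive keywords in the reference name; domain evidence
#' upgrades a residual `other` call (WAP to crustin, Kazal to kazal,
#' ALF_loop to alf). Each family carries a crab gene-ID prefix (PcBuf,
#' PcCrs, PcPar, PcALF, ..., PcAMP for `other`).
#'
#' @param accession APD-style accession of the best hit.
#' @param domains `NULL` or tibble of domain hits (column `kind`).
#' @param name Free-text name of the best hit (optional).
#' @return List with `family` and `prefix`.
#' @export
classify_family <- function(accession, domains = NULL, name = "") {
  fam <- unname(.family_map()[accession])
  if (is.na(fam) || is.null(fam)) {
    fam <- "other"
    if (nzchar(name)) {
      hit <- vapply(.FAMILY_KEYWORDS, function(p) {
        grepl(p, name, ignore.case = TRUE, perl = TRUE)
      }, TRUE)
      if (any(hit)) fam <- names(.FAMILY_KEYWORDS)[which(hit)[1]]
    }
  }
  if (fam == "other" && !is.null(domains) && nrow(domains) > 0) {
    if ("WAP" %in% domains$kind) fam <- "crustin"
    else if ("Kazal" %in% domains$kind) fam <- "kazal"
    else if ("ALF_loop" %in% domains$kind) fam <- "alf"
  }
  list(family = fam, prefix = unname(.FAMILY_PREFIX[fam]))
}

#' Flag an AMP match embedded in a larger coding gene
#'
#' AMP-similar segments are often just part of a large ORF belonging to a
#' housekeeping gene. A candidate is flagged embedded iff the ORF protein is
#' longer than 150 aa and the hit covers less than half of it.
#'
#' @param protein_length_aa ORF protein length.
#' @param s_start,s_end Hit span within the ORF protein (1-based inclusive).
#' @return Logical.
#' @export
flag_embedded <- function(protein_length_aa, s_start, s_end) {
  protein_length_aa > 150 &
    (s_end - s_start + 1) / protein_length_aa < 0.5
}
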