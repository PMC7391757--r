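# The three paralithocin precursor N-termini as printed for the red king
# crab, each followed by the first two mature residues. Filler repeats "AKK"
# so that no filler position can itself satisfy the (-3,-1) cleavage rule.
SP_FILLER <- strrep("AKK", 10)
PARALITHOCIN_PRECURSORS <- c(
  par1 = paste0("MGPMKVLLVLLVVMVAAPHIADA", "WQ", SP_FILLER),
  par2 = paste0("MGAAKVLLVVLAVMVAVPNLAEG", "RS", SP_FILLER),
  par3 = paste0("MGPMKVLLVMLVVMVAAPHIADA", "RS", SP_FILLER)
)

# build a contig carrying `protein`'s ORF at forward positions
# orf_start .. orf_start + 3*nchar(protein) - 1, with an in-frame stop
# immediately upstream and a stop codon after the ORF
plant_orf_contig <- function(protein, orf_start, utr3 = 90, id = "ctg") {
  stopifnot(orf_start >= 4)
  u5 <- orf_start - 1L
  utr5 <- random_nt(u5)
  substr(utr5, u5 - 2L, u5) <- "TAA"
  tibble::tibble(
    id = id, desc = "",
    seq = paste0(utr5, reverse_translate(protein), "TAA", random_nt(utr3))
  )
}

# a protein guaranteed to start with M and contain no further M or
# problematic residues for ORF planting
random_orf_protein <- function(n_aa) {
  paste0("M", paste(sample(setdiff(AA20, c("M", "W")), n_aa - 1,
                           replace = TRUE), collapse = ""))
}
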