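---
title: "Mining antimicrobial peptides from transcriptome assemblies: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining antimicrobial peptides from transcriptome assemblies: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampminer)
```

## The problem

Antimicrobial peptides (AMPs) are short innate-immunity effectors —
typically up to 150 amino acids and 2–9 kDa — that many invertebrates,
including crustaceans, deploy as a first line of defence. In a de novo
transcriptome assembly (Trinity-style contigs, no genome), AMP genes are
found by similarity: known AMP mature peptides are compared against the
translated contigs, candidate open reading frames (ORFs) are delineated
around the matches, and the resulting precursors are vetted structurally
(signal peptide, family-specific cysteine scaffolds) and by expression.
`ampminer` implements that desk workflow end to end, deterministically, and
pairs it with a synthetic-transcriptome generator so that every step can be
validated against a known truth.

## Search model

Two complementary searches are run and their hits unioned, mirroring the
two ways practitioners use BLAST in this setting:

* ORF-space ("blastp-like"): ORFs are called in all six frames first and
  reference peptides are aligned against the ORF proteins.
* Frame-space ("tblastn-like"): references are aligned against the complete
  six-frame translations, and each hit is then assigned to the ORF whose
  protein span contains it. Hits crossing an ORF boundary (possible
  frameshifts) are dropped with a warning rather than patched — such cases
  need manual curation.

Alignment is exact Smith–Waterman with Gotoh affine gaps rather than a
seeded heuristic: at desk scale (hundreds of contigs, tens of references)
exactness is affordable, and it makes oracle testing meaningful. Scoring is
BLOSUM62 with gap open 11 and extend 1 (a gap of length $k$ costs
$11 + k$), the common protein-BLAST default. A hit is kept when its **raw
score is at least 90**. The filter in the original workflow was a CLC
"similarity score ≥ 90" whose exact semantics are not recoverable; the raw
score is the conservative, scale-free reading, and the threshold, matrix
and gap costs are all configurable (`amp_config()`, `scoring_scheme()`,
including loading any NCBI-format matrix) for users who prefer a different
calibration. No E-values are computed: the workflow filters on one number.
Unknown residues (`X`) score −1 against everything; stop characters in
frame translations score −4, so local alignments do not cross stops.

Determinism is part of the contract: the best alignment cell is the first
maximum in row-major order and traceback ties resolve diagonal > up >
left, so identical inputs give byte-identical reports.

## ORF model

Coordinates are 1-based, inclusive, reported on the forward strand with a
strand flag. A complete ORF runs from the first ATG of a stop-free stretch
to the codon before the in-frame stop; the stop codon is excluded, so the
span is exactly three times the protein length (the printed worked example
— a 72-aa protein at positions 148–363 — fixes this convention, since
(363 − 148 + 1)/3 = 72). Only ATG opens an ORF; codons containing `N`
translate to `X` and can be neither start nor stop. Stretches cut by the
contig edge are reported honestly instead of being promoted: a stretch with
a stop but no upstream ATG whose open end touches the boundary is a
5′ fragment; a stretch with an ATG but no stop before the contig end is a
3′ fragment; a whole frame with neither is an internal fragment. The
default minimum ORF length is 25 aa, safely below the shortest AMP regions
of interest (~29–34 aa) while bounding noise ORFs.

Genes split across two contigs are reconstructed by exact suffix/prefix
overlap (default minimum 30 nt, both orientations of the second contig,
longest overlap wins, ties toward the orientation preserving the first
contig's strand). A join is attempted only when the same reference hits two
contigs and each hit terminates within 10 codons of a contig end, and it is
accepted only when the reference still hits the merged contig — this
reproduces genuine fragment pairs without gluing unrelated isoforms.

## Signal peptides

No trained predictor is bundled; instead a fully documented von
Heijne-style heuristic makes the behaviour reproducible. A cleavage
candidate $p \in [15, 35]$ is valid when

1. the n-region (positions 1..max(2, p−15)) contains K or R, or the protein
   starts with Met followed within five residues by K or R;
2. some window of ≥ 7 consecutive residues within 3..p−3 has mean
   Kyte–Doolittle hydropathy ≥ 1.5 (the h-region);
3. the (−3,−1) rule holds: residue $p$ ∈ {A,G,S,C,T,Q} and residue $p−2$ ∈
   {A,G,S,C,T,V,L,I}.

Among valid candidates the caller maximises the h-region mean hydropathy,
plus 0.5 when the −1 residue is alanine (Ala is by far the most common −1
residue in eukaryotic signal peptides). Exact score ties do occur — several
cleavage points can share the same best hydrophobic window — and are
resolved toward the candidate closest to 23, the canonical eukaryotic
signal-peptide length, then toward the smaller index. Proteins shorter than
30 aa return no call, and ORFs lacking their 5′ end are never scanned: a
fragment without its N-terminus cannot contain a signal peptide.

```{r signal}
predict_signal_peptide(paste0("MGPMKVLLVLLVVMVAAPHIADA", "RS",
                              strrep("AKK", 10)))
```

## Domain detectors and the physicochemical screen

The domain calls are bounded-gap cysteine-spacing patterns, not profile
HMMs: WAP four-disulfide core
`C x(3-10) C x(4-8) C x(4-8) C x(4-12) C x(4-10) C C x(3-6) C`, Kazal
`C x(7) C x(6) Y x(3) C x(2,3) C`, and the ALF lipopolysaccharide-binding
loop (two cysteines 15–35 apart enclosing a segment of net charge ≥ +3,
with K/R = +1, H = +0.5, D/E = −1). Gap positions exclude cysteine so the
matched span contains exactly the pattern cysteines. These detectors are
validated constructively on planted fixtures; they are honest
approximations, not replacements for Pfam models, and loop-like patterns
can legitimately co-occur (a cationic inter-cysteine stretch in a crustin
will also satisfy the ALF loop geometry — all evidence is reported, and
family assignment does not depend on it when the accession or name already
identifies the family).

The AMP screen is exactly the classical definition and nothing more:
length ≤ 150 aa and average-mass 2–9 kDa (residue masses summed + 18.02 Da;
unknown residues contribute 110 Da and are flagged). The hydrophobic
fraction is reported but deliberately not thresholded — no published cutoff
exists for "a high portion of hydrophobic residues".

## Candidate bookkeeping

Redundant matches — different references explaining the same locus — are
collapsed: candidates whose ORFs overlap by ≥ 1 nt on the same contig and
strand form a group and only the best-scoring one survives (ties: longer
ORF, then lexicographically smaller accession). Matches embedded in large
housekeeping proteins are kept but flagged (`embedded`) when the ORF
exceeds 150 aa and the hit covers less than half of it. Families come from
a shipped accession→family table (editable TSV), then from name keywords
for accessions outside the table, then from domain evidence (WAP → crustin,
Kazal → kazal, ALF loop → alf); gene IDs are the family prefix plus a rank
by descending score (PcPar1, PcCrs1, ...; the β-thymosin prefix is
transliterated to ASCII `PcBThm`).

## Expression

RPKM $= 10^9 \, C / (L \, N)$ with $C$ the gene's mapped reads in a
library, $L$ its transcript length and $N$ the library's total mapped
reads (taken from the counts table's TOTAL row, or column sums). Tiers are
assigned on raw reads summed across libraries, anchored at the two sharp
printed boundaries: more than 3,000 reads is high, fewer than 100 is low,
and the "around 1,000" middle class is formalised as the closed interval
[100, 3000]. Counts are keyed by contig; a joined candidate's reads are
summed over its contigs.

## The synthetic transcriptome generator

`generate_transcriptome()` emulates the features of the real assembly the
pipeline must cope with: planted precursor ORFs (signal peptide +
family-patterned mature peptide) reverse-translated with uniform synonymous
codon choice, random UTRs with an in-frame stop immediately upstream of the
initiator (so the planted start is the ORF start), minus-strand placement,
genes split across two contigs with a 60-nt exact overlap, 5′/3′
truncations cut across the contig edge, and composition-matched decoys
re-drawn until no reference aligns at score ≥ 60 (a wide margin below the
90 filter). Defaults — 20 planted genes, 80 decoys, five families cycled,
roughly 70/20/10 % high/medium/low expression tiers with negative-binomial
totals around 8000/1000/50 reads — are the package's standing study
conditions for validation. Truncated and split layouts are only assigned to
signal-bearing families: a histone-derived (buforin-like) precursor is too
short to leave both fragments above the score filter, and truncation cuts
are placed inside the signal peptide so the remainder is Met-free —
otherwise an internal Met would legitimately make the fragment a complete
ORF and the planted completeness truth would be wrong, not the caller.

What the generator does **not** emulate: sequencing errors, coverage-driven
assembly artefacts, isoform families, codon bias, paralogous loci, or
references that only partially resemble the planted gene. Passing the
recovery tests therefore demonstrates the correctness of the machinery —
coordinates, strand handling, joining, classification — not the field
sensitivity of the workflow on real data, which depends on reference
coverage and assembly quality.

```{r recovery}
sim <- generate_transcriptome(n_planted = 6, n_decoys = 10, seed = 4)
cands <- mine_amps(sim$contigs, sim$amp_refs)
glance(cands)
```

## Numerical and testing choices

Validation sizes are chosen to keep the full suite within a few minutes on
one CPU while exercising every code path: alignment scores are checked
against an independently coded plain-R dynamic program on 200 random pairs
(≤ 30 aa), ORF calling against an exhaustive (frame, start, stop)
enumeration on 500 random contigs (≤ 1 kb, some containing `N`), and
end-to-end recovery on the default 20-gene / 80-decoy transcriptome, where
at least 95 % of complete planted genes must be recovered at exact
coordinates with zero decoys and correctly classed fragments. Degenerate
inputs follow fixed conventions: empty alignments (score 0) carry NA spans;
contigs shorter than one codon translate to six empty frames; an all-decoy
run returns an empty, typed candidate table rather than an error.

## Known limitations

* The score-90 filter is a raw-score reading of an unrecoverable
  vendor-specific "similarity score"; candidate counts on real data will
  differ from those of the original CLC-based analysis.
* The signal-peptide caller is a deterministic stand-in, tuned to the
  documented rules, not a reimplementation of SignalP; its h-region scoring
  can tie across nearby cleavage points and relies on the stated
  tie-breaks.
* Domain detectors are spacing patterns; divergent family members that
  violate the gap bounds will be missed, and the ALF loop pattern can fire
  on any sufficiently cationic inter-cysteine segment.
* Expression uses RPKM only, with totals as given in the counts table — no
  mapping-rate correction and no differential testing.
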