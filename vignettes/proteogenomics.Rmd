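---
title: "Proteogenomic gene-model assessment: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proteogenomic gene-model assessment: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protegap)
```

# The problem

Gene catalogs of ciliates and other non-model eukaryotes are built from
*ab initio* prediction and homology, and carry systematic errors: missed
short genes, wrong start or stop codons, and mis-drawn intron
boundaries. Shotgun proteomics offers direct evidence about what is
actually translated. Searching MS/MS spectra against a database built by
translating the *genome itself* (all six frames) and assembled
transcripts (three frames), alongside the annotated proteome, yields two
kinds of identifications: peptides explained by annotated proteins, and
**genome search-specific peptides (GSSPs)** that match only the
translated genome or transcripts. GSSPs are the evidence units for novel
genes and for annotation errors.

`protegap` implements this audit end to end, together with a
synthetic-data generator that produces a genome, an annotation with
known injected defects, hidden genes, spectra and RNA counts — plus a
ledger recording the truth behind every observable — so each stage can
be tested against ground truth.

# Translation and database construction

The organism modelled is a ciliate, so translation defaults to NCBI
table 6: TAA and TAG encode glutamine and TGA is the only stop. Getting
this wrong would shatter six-frame stretches at every in-frame TAA/TAG,
so the code is a first-class parameter (`genetic_code("standard")` is
available).

Six-frame entries are *maximal stop-free stretches*, not start-to-stop
ORFs: peptide evidence may legitimately lie upstream of any start codon
(that is exactly how start-codon errors are found), so start inference
is deferred to the novel-gene caller. Stretches shorter than 20 residues
are dropped. Codons containing N translate to X; X never splits a
stretch but makes the digestion peptides containing it non-matchable —
a conservative treatment of ambiguity.

All internal coordinates are 0-based half-open on the forward strand;
GFF3 input/output converts to and from 1-based inclusive coordinates in
one place (`read_gff3()`/`write_gff3()`), which removes off-by-one
ambiguity from the interval arithmetic everywhere else.

Decoys are full-sequence reversals, one per target entry — a
deterministic, reproducible construction. A peptide found in both a
target and a decoy entry counts as a target (target-decoy competition).

# Digestion and masses

Digestion is fully tryptic with the Keil rule (cleave after K/R except
before P), up to 2 missed cleavages, peptide length 6–60. The 60-residue
cap bounds the index; it is configurable. Carbamidomethylation of
cysteine (+57.02146 Da) is applied as a fixed modification by default,
reflecting standard iodoacetamide alkylation; it can be switched off in
`mass_constants()`. Protein N-terminal methionine is not removed and no
semi-tryptic peptides are generated: the modelled search is fully
tryptic.

A consequence worth spelling out: a protein's N-terminal tryptic peptide
exists in the *annotated-protein* database but is a tryptic peptide of a
*six-frame stretch* only when the upstream in-frame codon is a stop or
encodes K/R. Start-codon errors whose only crossing peptide is such an
unmappable N-terminal peptide are therefore invisible to a fully tryptic
genome search; the tests account for this when deciding which injected
errors count as evidence-covered.

# The open search

For each spectrum the neutral precursor mass is compared against the
peptide index; candidates are peptides whose unmodified mass lies within
the open window (default −500 to +500 Da) of the precursor, or within
20 ppm of it (the unmodified branch). The scorer is deliberately simple
and documented rather than a re-implementation of a commercial engine:

* score = (number of matched peaks) + (fraction of total intensity in
  matched peaks);
* a peak matches when it lies within 20 ppm of any theoretical singly
  charged b/y ion of the hypothesis;
* a non-zero delta is attributed to one residue position; the position
  is chosen by matched-ion count (computed for all positions in O(L)
  with prefix sums), and the chosen hypothesis is then scored on
  distinct peaks. On count ties the lowest position is taken.

Counting *distinct matched peaks* rather than matched ion hypotheses
matters: a longer peptide with a compensating negative delta can align
two ion series onto the same peaks and would out-score the true peptide
under ion counting, while under peak counting the two explanations tie
and the tie-break (smaller |delta|, then lexicographically smaller
peptide) selects the parsimonious one. Ties are total, so the search is
deterministic.

A PSM is reported only when its best candidate explains at least 4
distinct peaks (`min_matched_peaks`). A 2–3-peak "best match" of a
noise spectrum is not evidence, and reporting such matches loads the
ranked list with junk whose false-positive rate the decoy estimator can
only track approximately.

Known residual error mode: when a modified spectrum's shifted ladder is
equally well explained by a different peptide with a *smaller* |delta|,
the tie-break prefers the wrong peptide. This is rare (well under 1% of
accepted PSMs at the default noise level) and is controlled by the FDR
accounting below.

## FDR estimation

PSMs are ranked by score; the estimated FDR at a depth is the
decoy/target ratio above it, converted to q-values by a running minimum
from the bottom; the accepted set is q ≤ 0.01 with decoys removed after
estimation. The default uses the +1-corrected count
((#decoys + 1)/#targets): the running-minimum step otherwise selects
depths where the decoy count is momentarily lucky, which makes the plain
ratio anticonservative on lists of a few thousand PSMs — we measured
realized false-identification proportions of 1.2–1.6% at a nominal 1%
with the plain ratio on synthetic data, and ≈0.2–0.5% with the
correction. `plus_one = FALSE` restores the plain ratio. The same
estimator applies to protein groups scored by their best peptide.

# GSSP classification, grouping, genome mapping

Accepted peptides are matched to database entries through the
digestion-derived parent map, so matches always have tryptic termini;
I and L are distinct residues throughout (the simplest exact-match
contract, stated rather than hidden). A peptide is a GSSP when no parent
is a reference or contaminant entry. Contaminant-only peptides are kept
in the reference-matched class but flagged and excluded from genome
mapping.

Protein grouping is parsimony-based: identical peptide sets merge,
strict subsets are subsumed, and every peptide is assigned to exactly
one group (greedy, by descending peptide count then anchor id). Shared
peptides therefore count toward their anchor group only, which keeps
spectral-count totals conserved and NSAF denominators simple; fractional
splitting was considered and rejected for determinism. Grouping is run
over reference and contaminant entries; six-frame evidence belongs to
the novel-gene caller, not to protein groups.

Peptides map to the genome through their parents: six-frame parents by
offsetting the entry interval 3 nt per residue (strand-aware), reference
parents by splice-aware projection through the gene model's CDS
segments. Every mapping is required — and tested exhaustively — to
re-translate to its peptide exactly.

# Novel genes and the gene-model audit

GSSP mappings on the same contig, strand and frame within 300 nt of each
other cluster into loci (`max_gap = 300`; the value spans typical
inter-peptide gaps at modest coverage and is configurable). GSSPs
overlapping an annotated gene span on the same strand are routed to the
error audit instead — they contradict the annotation rather than
indicate a new locus.

A locus becomes a gene call only with ≥ 2 unique supporting GSSPs. The
ORF extends upstream in frame to the nearest stop, then forward to the
first ATG; if none, the first GTG/CTG/TTG (ATG is preferred even when an
alternative initiator lies further upstream, reflecting the observed
predominance of ATG among novel genes); if no candidate start exists
before the evidence begins, the codon immediately after the bounding
stop is reported with class `noncanonical` — an evidence-bounded choice
that does not guess an initiation mechanism. Downstream the ORF runs to
the first in-frame stop. Only single-exon ORFs are called. Calls report
GC content (N excluded) because novel coding sequence tends to run
slightly GC-richer than the annotated background, and the generator
reproduces that contrast so the comparison has signal.

The audit classifies contiguous (six-frame) peptide evidence against
each annotated model: crossing the 5' CDS boundary in frame →
`start_error`; crossing the 3' boundary in frame → `stop_error`;
translating contiguously across an annotated exon–intron boundary →
`intron_boundary_error`; lying wholly within an annotated intron in
frame with the flanking CDS → `intron_coding`. One record per (gene,
category). A single injected defect can legitimately produce two
categories — a peptide wholly inside a short fake intron and another
crossing its boundary are both genuine evidence against the same intron
— so the tests require the injected category to be present and clean
genes to produce no records, rather than exactly one record per gene.

# PTM annotation

The shipped catalog holds 30 common eukaryotic modifications with Unimod
monoisotopic masses, as a TSV config rather than hard-coded constants.
Matching a precursor delta to the catalog uses the same 20 ppm tolerance
as the search, applied on the precursor scale. When two catalog masses
fall inside one tolerance window the assignment is *ambiguous* and
deferred — reported, but excluded from confident counts. At 20 ppm this
is the unavoidable fate of phosphorylation (+79.9663) versus sulfation
(+79.9568) and of the ubiquitination remnant GlyGly (+114.0429) versus
glutarylation (+114.0317); the catalog flags such near-isobaric pairs.
Acetylation (+42.0106) and trimethylation (+42.0470) are 36 mDa apart
and resolve cleanly at 1,000 Da.

Site localization places the shift at every specificity-compatible
position and takes the argmax of the matched-ion count; the call is
confident only with a margin of at least one ion over the runner-up,
ties fall to the lowest position and are not confident. One modification
per PSM, consistent with the single-delta open search.

# Quantification and integration

NSAF, FPKM, row z-scores (sample SD, matching common spreadsheet and
clustering-tool behaviour), the strict z > 2 / z < 0 state-specificity
rule, and per-state Pearson correlation are implemented as plain matrix
operations with the degenerate cases (zero columns, constant rows)
flagged rather than silently divided. Correlations are computed on
log2-transformed values by default (offset 1 for FPKM, half the minimum
positive value for NSAF) because both measures are heavy-tailed;
`transform = "none"` is available. NSAF uses the group anchor's length,
matching the anchor-only count assignment.

# The synthetic study

The generator emulates the study design the pipeline targets, with
defaults fixed as the package's study conditions:

* ten states named G, S3, S15, C2, C12, C18, 3A1-27G/S, 3A1-80G/S;
* a 75% AT genome on two contigs; 50 annotated genes of 90–200 codons
  (eleven carrying one injected annotation error each: 3 start, 3 stop,
  3 intron-boundary, 2 intron-coding), real introns (GT..AG, 50–120 nt)
  in 40% of clean genes; 5 hidden genes of 40–90 codons with GC raised
  by 0.08, absent from the GFF3;
* 200 peptide spectra per state sampled proportional to protein
  abundance, plus 1,000 noise-only spectra; 5 ppm Gaussian mass error on
  every peak and precursor; 8 uniform noise peaks per spectrum; planted
  modification rates Phospho 0.04, Acetyl 0.04, Trimethyl 0.03,
  Oxidation 0.03, GlyGly 0.02; precursor charges 2–4;
* per-state true mRNA and protein log-levels constructed (by in-sample
  orthogonalization) to realize the target correlation of 0.5 exactly,
  so downstream deviations measure count noise only; negative-binomial
  counts with dispersion 0.1, at sequencing and spectral depths deep
  enough that count noise attenuates log-scale correlations by well
  under 0.1.

Hidden genes are planted with an in-frame stop immediately upstream of
their ATG. Without it, the upstream in-frame region of a hidden gene is
random sequence whose nearest stop and first ATG are arbitrary, so even
a perfect caller could not be scored against a unique true interval;
with it, the true ORF is the unique recoverable answer and recovery can
be tested exactly.

What the generator does **not** emulate: chromatography and retention
behaviour, isotope envelopes, co-isolated chimeric spectra, charge-state
dependent fragmentation, semi-tryptic or in-source fragments,
heteroscedastic library sizes, and batch effects. Passing tests on this
synthetic system therefore demonstrates the correctness of the
*inference machinery* — translation, indexing, scoring, FDR accounting,
coordinate arithmetic, the decision rules — not the expected
identification yield on real instrument data.

# Problem sizes used by the tests

The test suite runs the full pipeline on the 50-gene default study (one
standard and one noise-free instance), an FDR-calibration sweep of ten
15-gene studies, and a 550-gene quantification-only study for
correlation recovery; the acceptance script runs the 50-gene study over
ten seeds. These sizes keep complete ground-truth verification —
exhaustive round-trip checks of every mapping included — comfortably
within a laptop-scale budget.

# Known limitations

* The scorer ranks well on synthetic ladders but is not a calibrated
  spectral match score; absolute scores are not comparable across
  spectra of very different peak counts.
* Near-isobaric modification pairs cannot be resolved by precursor mass
  at 20 ppm; fragment-level disambiguation of such pairs is not
  attempted beyond site localization.
* Novel-gene calling emits single-exon ORFs only; a hidden gene with a
  real intron would be called as its longest exonic open stretch.
* Decoy reversal preserves amino-acid composition but not tryptic
  peptide boundaries exactly; at very small database sizes the decoy
  peptide space can be slightly smaller than the target space.
* The protein-level FDR is computed per run; a global option across runs
  is left to the caller (apply `protein_fdr()` to a concatenated group
  table).
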