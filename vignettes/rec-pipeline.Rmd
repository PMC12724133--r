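---
title: "Reconstructing HERV-K Rec ORFs: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing HERV-K Rec ORFs: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hervrec)
```

## The biological model

Type-2 HERV-K (HML-2) proviruses can encode Rec from a doubly spliced mRNA.
The first coding exon contributes 87 residues that coincide with the start
of the 95-residue Env signal peptide; the second coding exon overlaps *env*
in a different reading frame. Type-1 proviruses carry a 292-bp deletion at
the pol–env junction that removes most of exon 1; many also carry an A→T
substitution a few bases upstream that simultaneously introduces a stop
codon in the *env* frame and converts a GA dinucleotide into a GT donor (the
Np9 splice form). Whether a given locus can still express a functional Rec
is, at the sequence level, a chain of small decisions — is the locus type 1
or type 2, are the GT/AG splice sites intact, does the spliced ORF translate
to the consensus C-terminus without stops or frameshifts, and which residues
differ from the consensus Rec. This package makes each of those decisions
explicit, testable code.

## Alignment and annotation transfer

The pipeline's core is pairwise global alignment with affine gaps
(Needleman–Wunsch/Gotoh), one provirus against each annotated reference.
The published analysis performed annotation transfer inside a commercial
GUI via multiple alignment; a pairwise formulation computes exactly the
object liftover needs (a per-column coordinate map), is deterministic, and
can be validated against a brute-force oracle. Design choices that matter:

* **Scoring defaults** match 5, mismatch −4, gap open 10, gap extend 0.5,
  free end gaps on — common DNA scoring; a gap of length $L$ costs
  $g_{open} + (L-1)\,g_{ext}$. Scores are processed in integer half-units,
  so every score must be a multiple of 0.5 (BLOSUM62 and all common DNA
  schemes qualify); this keeps the kernel fast and exactly reproducible.
* **Determinism.** Ties are broken by a fixed source preference (diagonal,
  then query-consuming gap, then reference-consuming gap), and in ends-free
  mode the terminal cell is chosen by a fixed scan order. The same inputs
  always produce byte-identical alignments. Tests assert that the emitted
  alignment prices exactly at the reported score and that the score equals
  the optimum found by exhaustive enumeration of all alignments on short
  sequences.
* **Ends-free mode** lets boundary-truncated proviruses align without
  spurious terminal penalties; the all-gap corner cases (one sequence
  entirely leading gap, the other entirely trailing) are included in the
  terminal scan.
* **N handling.** `N` scores 0 against everything; sequences over 10%
  ambiguous bases flag the map and warn.

Liftover maps each reference feature to the smallest query interval
containing all query bases aligned to its reference bases; coverage is the
aligned fraction of reference feature bases, and a feature under 50%
coverage is flagged disrupted (configurable). Deletion calling reports
maximal reference-only runs, merging runs separated by fewer than 10
aligned columns — proviral decay often interrupts one ancestral deletion
with a few residual matches.

## Type calling

A locus is called type 1 iff a deletion of at least `min_del_len` (default
100 bp) overlaps rec exon 1 on the type-2 map. The diagnostic deletion is
292 bp, so the threshold tolerates decayed boundaries by a wide margin; the
A→T donor signature is recorded separately but deliberately not required,
because it is described for many, not all, type-1 proviruses. Loci whose
overall identity to the reference falls below 0.6 are reported `ambiguous`
rather than forced into a type. Orientation is decided by aligning both
strands and keeping the higher score (ties keep `+` with a warning); the
winning alignment is reused downstream, so orientation costs one extra
alignment, not two.

## Rec reconstruction

Splice sites are checked by reading the two intron-edge bases at the lifted
coordinate: GT for donors, AG for acceptors; a site within 2 bp of a contig
end or lost in a deletion is "not assessable" and treated as not intact for
the splicing decision. If both the exon-1 donor and the exon-2 acceptor are
intact, the two lifted exons are joined; otherwise exon 1 is kept contiguous
with *env*, ending at the provirus region aligned to the reference *env*
stop codon. Translation uses the standard code, renders stops as `*` and
continues past them, so a premature stop's position is always recoverable
from the protein string. A stop is *premature* when it falls strictly before
the last translated residue — an alignment-free definition that makes the
expected value computable directly from a mutation spec.

Classification against the consensus Rec uses a BLOSUM62 ends-free protein
alignment (gap open 11, extend 1). `full_length` requires:

* aligned consensus coverage ≥ 0.9 (the published partition is categorical,
  "incomplete or heavily truncated", without a printed cutoff; 0.9 is shipped
  as configuration and calibrated by the engineered panel's 25/29 split);
* the consensus C-terminal residue covered, with no stop before it;
* identity ≥ 0.5 over the exon-2-encoded consensus segment (residues
  88–105). This last criterion is needed because a global alignment will
  happily pair the consensus exon-2 tail with *env*-frame residues of a
  readthrough product; requiring the exon-2 segment to be recognisably
  present keeps acceptor/donor mutants out of the full-length class without
  penalising genuine variants, whose changes are rarely concentrated there.

`extended` marks proteins meeting the full-length criteria that continue
past the consensus C-terminus (a lost stop codon). `no_acceptor` marks loci
whose exon-2 acceptor check failed (the AG→GG case). Everything else is
`truncated`.

Frameshifts are detected at cDNA level by aligning the reconstructed cDNA to
the reference Rec cDNA and tracking the running frame offset (+1 per
query-only column, −1 per reference-only column). The naive rule — any indel
run with length ≢ 0 (mod 3) — false-positives: an affine-gap aligner may
represent a three-mismatch codon substitution as a balanced insertion +
deletion pair a few columns apart when that prices better than three
mismatches. A shift is therefore called only when the offset is non-zero
mod 3 at the end of the coding region or persists over ≥ 15 aligned columns
(5 codons). A genuinely shifted-then-restored stretch shorter than 5 codons
would be missed, which we accept as the cost of robustness.

Variant calling aligns the mature protein to the consensus with penalised
end gaps and reads the edit script off the columns: mismatches become
substitutions (`N2H`), consensus-only runs deletions (`E34del`,
`E34_K36del`), query-only runs insertions numbered by the consensus residue
they precede (`62insK`). Positions always refer to consensus coordinates, so
downstream shifts never renumber a variant. `apply_variants()` is the exact
inverse; the round trip (call, then apply) reconstructs every full-length
protein, which the tests exercise on 200 seeded mutants. Exact edit-*set*
recovery additionally requires the edits to be unambiguous: deleting one of
two identical adjacent residues, or an insertion/deletion pair close enough
to be rewritten as substitutions, have equivalent representations, and the
caller deterministically picks the leftmost.

## Reporter quantification

* **Gating** is a fixed sequential hierarchy — scatter window, singlet gate,
  mCherry⁺, eBFP2⁺ — with per-stage counts logged and an empty-stage flag
  rather than zero MFIs. The singlet gate keeps events with
  $|FSC_H - k\,FSC_A| \le tol \cdot k\,FSC_A$. The slope $k$ is fit once by
  least squares when the gate spec is constructed (`fit_singlet_slope()`),
  ideally on a doublet-poor control acquisition: fitting inside `gate()`
  would make gating non-idempotent, and a doublet-heavy table biases the
  FSC²-weighted fit. Positivity thresholds default to the 99.9th percentile
  of a negative-control (untransduced) table per channel.
* **Activity** is the arithmetic-mean GFP MFI divided by the arithmetic-mean
  eBFP2 MFI of the gated events ("mean fluorescence intensity" is taken at
  its word; a geometric-mean estimator is available but off by default).
  The ratio is invariant under common rescaling of both channels and
  equivariant under rescaling one.
* **Expression normalisation** divides MFI by the HA-tag band intensity
  relative to its β-tubulin loading control: `mfi / (ha / tubulin)`.
* **Trans-dominant series** subtract the empty-vector GFP background and
  scale so the control (100 ng functional Rec alone) is exactly 1.0, flooring
  at zero; doses follow the assay design (0, 200, 400, 800 ng competitor).
* **p24 standards** (12.5–1,600 pg/mL, two-fold series) are fit with a 4PL
  curve by Levenberg–Marquardt least squares; `a` is the zero-concentration
  asymptote and `d` the saturating one. Standards whose Spearman correlation
  with concentration falls below 0.8 are rejected as non-monotone.
  Interpolation inverts the fitted curve and flags out-of-range ODs as `NA`
  instead of extrapolating; duplicate sample ODs are interpolated
  individually and averaged.

## What the synthetic generator emulates — and what it does not

`make_reference()` builds a ~2.8-kb annotated provirus with the structural
logic the analysis assumes: LTRs, a major splice donor, an *env* ORF whose
first 261 nt form rec exon 1 (87 codons, mirroring the real exon-1 length),
an overlapping rec exon 2 in a shifted frame with its own GT/AG pair, and
the A→T/GA→GT context eight bases upstream of a 292-bp deletion interval.
The *env* frame is made stop-free by sampling non-stop codons and the
exon-2 frame is cleaned of cross-junction stops, so the spliced cDNA
translates to a 105-residue consensus with pinned residues (N at 2, E at 34,
non-K residues at 61–62) that make the engineered variant labels
unambiguous. The scale — 2.8 kb rather than the real 9.5 kb — keeps each
locus scan around a second and the brute-force alignment oracle feasible;
nothing in the pipeline depends on the toy length.

`degrade()` applies a mutation spec (type-1 deletion, point/splice edits,
premature stops, frameshifts, amino-acid substitutions/deletions/insertions,
synonymous changes, strand flips) and derives the expected downstream calls
*from the edit list alone*, never by running the pipeline — the truth table
is an independent oracle. `make_panel()` draws stratified class mixtures
(defaults: 30% type 1, 25% clean, 25% premature stop, 10% splice mutant,
10% strand-flipped, each locus plus a few neutral SNVs in the gag–pol
filler); `make_study_panel()` fixes a 55-locus composition that mirrors the
reported structure of the study's type-2 set — 25 full-length (five
consensus-identical via synonymous changes, one N2H+E34del locus, one
62insK locus, eighteen loci with 1–3 distinct substitutions), 29 truncated,
and one AG→GG acceptor mutant — so the downstream counts (25/29, 21
distinct, a group of 5) are engineered truth recovered by computation.

The generators do **not** emulate real flanking human genome, LTR–LTR
recombination, internal recombination between loci, sequencing error, or
realistic HERV-K codon usage and phylogenetic correlation between copies.
Passing the end-to-end tests therefore shows the pipeline's logic is sound
under the structural assumptions above, not that thresholds such as the 0.9
coverage cutoff are optimal for real GenBank proviruses. Flow simulations
use independent log-normal channels with closed-form means; real cytometry
adds spillover (assumed compensated upstream), autofluorescence correlation
and acquisition drift. The trans-dominant generator's competitive model
`a₀·c₀/(c₀ + k·d)` is an explicit stand-in used to test normalisation and
monotonicity handling — the source study reports, but does not model,
inhibition.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run, per invocation: one
enumeration-oracle battery (all DNA pairs up to length 2, seeded pairs to
length 8), five 60-locus panels plus one 55-locus panel through the full
pipeline (~355 locus scans, each three ~2.8-kb global alignments), 200
variant round-trip mutants, 30,000-event flow simulations, and noiseless
4PL recovery to machine precision (asserted at 1e-6). Alignment memory is
one byte of packed traceback per cell (~8 MB per scan) with rolling score
rows.

## Known limitations

* Np9 reconstruction from type-1 loci is out of scope; type-1 calls record
  the deletion and signature only.
* `full_length` tolerates N-terminal extensions implicitly (ends-free
  alignment); only C-terminal extension is reported as `extended`.
* The variant caller's labels follow the leftmost-alignment convention, not
  full HGVS 3′-shifting; for the repeat-free engineered consensus these
  coincide.
* Compensation/spillover correction and FCS binary ingestion are out of
  scope; event tables arrive as CSV/data frames, assumed compensated.
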