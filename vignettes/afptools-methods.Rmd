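---
title: "afptools: methods, parameters and design choices"
author: "afptools authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{afptools: methods, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afptools)
```

## The problem

Type I antifreeze proteins (AFPs) in righteye flounders are short,
alanine-rich α-helices whose genes occur in multigene loci with banks of
near-identical tandem repeats. Two analysis problems recur with such
loci. First, the repeats are too similar for assembly to count them, so
copy number must be inferred from raw long-read composition. Second, the
gene family's origin (here, from the antiviral *Gig2* gene) leaves its
trace almost entirely in *non-coding* sequence — flanks, the non-coding
first exon, introns, 3′ regions — while the coding sequence has been
overwritten; establishing provenance therefore requires mapping local
homology blocks and contrasting their coverage of coding vs non-coding
annotation. afptools implements both, plus the supporting stages
(isoform classification, microsynteny, virtual Southern blotting) and a
synthetic-data generator that makes each stage testable offline.

## Copy-number estimation from read categories

A sequenced BAC is a circular molecule: vector backbone + insert, the
insert being left flank + N tandem units + right flank. Reads are
assigned to components by error-tolerant k-mer voting: each 500-bp read
window is scored by the number of canonical k-mers (k = 15) it shares
with each reference component, and takes the argmax (ties or zero votes
→ *ambiguous*). Base counts accumulate per window, so a junction read
splits proportionally; in read mode a read goes to its majority
category. K-mers claimed by two components are discarded up front.

The estimator is

$$\hat N = \frac{C_\text{repeat}}{C_\text{vector}} \cdot
           \frac{L_\text{vector}}{L_\text{unit}}$$

with $C$ base counts by default. Under uniform coverage of the circle
the expected base-count ratio is exactly $N L_\text{unit} /
L_\text{vector}$, so $\hat N$ is consistent; base counting (rather than
read counting) is the default because it is unbiased under variable read
length. Ambiguous bases are excluded from numerator and denominator.

*Uncertainty.* The reported SE/CI is a nonparametric bootstrap over
reads (B = 1000 by default), resampling the per-read category
contributions after a canonical sort by read id — this makes the
estimate and its CI invariant to input order. An analytic
ratio-of-Poissons SE on read counts, $\hat N\sqrt{1/n_r + 1/n_v}$, is
emitted alongside for comparison; the small-B percentile CI is clamped
to contain the point estimate. The source analysis reports "±" values
without defining them; this package defines its own uncertainty as
above and documents it rather than guessing.

*Choices.* k = 15 keeps voting specific at BAC scale while a 500-bp
window still collects ~40 surviving k-mers at ~15% read error (an
error-free 15-mer survives with probability ≈ 0.85^15 ≈ 0.09). Both are
configurable.

*Anchored resolution of outer units.* Separately from counting, reads
containing a unique exact 31-mer from a flank are oriented and walked
unit-by-unit against the unit consensus by local alignment; substitution
variants are called at ≥ `min_support` agreeing anchored reads, and
resolution per side is the fractional number of consecutive units with
support everywhere. Interior units are deliberately never assembled:
counting and anchoring are separate deliverables, mirroring how such
arrays are analyzed in practice.

## Similarity scanning and the coding/non-coding contrast

`global_identity` is an optimal global (Needleman–Wunsch) alignment;
identity is **matches / alignment columns with gap columns in the
denominator**, and N never counts as a match. This convention is fixed
and conservative because the alignment settings behind published
identity figures are typically unstated; for that reason identity
comparisons against published values carry a ±1 percentage-point
tolerance. Defaults: DNA +1/−1, gap open 2 / extend 1; protein BLOSUM62,
gap open 10 / extend 1.

`local_blocks` finds homology blocks by exact-seed matching (seed length
12, both strands), greedy diagonal chaining (band 50 bp, gap 400 bp),
and re-scoring of each candidate region by optimal local alignment — so
every reported block identity is exact, whatever the seeding missed.
Blocks overlapping ≥ 50% on both axes collapse to the higher-scoring
one. Default thresholds (min identity 0.70, min length 100 bp)
correspond to the reported range of inter-locus block identities
(70–96%). On sequences ≤ 200 bp the best block score equals an
independent affine-gap Smith–Waterman oracle (tested).

`annotate_blocks` classifies each block by majority (≥ 60%) base overlap
with the a-side annotation (coding > intron > UTR/non-coding exon >
intergenic, per base) and aggregates per-class coverage; the
non-coding/coding coverage ratio is the quantitative form of the
provenance argument ("homology everywhere except the coding sequence").

`tandem_period` reads the repeat period off the dominant off-diagonal of
a seed self-comparison (spacings between successive occurrences of each
15-mer, 100-bp bins), then phases unit boundaries by maximizing
adjacent-unit identity on a coarse grid. Absence of a dominant
off-diagonal is a result (`tandem = FALSE`), not an error.

## Isoform classification

Classes are assigned by explicit, ordered rules over measured peptide
features; every fired rule is recorded as evidence:

1. **pseudogene** — missing exon 1, a frameshift, or a mature peptide
   shorter than the shortest functional isoform (37 aa) without Thr
   periodicity;
2. **gig2_like** — Ala fraction < 0.15 and length 100–200 aa;
3. among Ala-rich (≥ 0.40), Thr-periodic (period score ≥ 0.5) peptides:
   **maxi** (signal, no propeptide, ≥ 120 aa), **midi** (signal +
   propeptide, 60–119 aa), **liver** (signal + propeptide, < 60 aa),
   **skin** (no signal, 37–60 aa);
4. otherwise **unclassified**.

The length cutoffs (60, 120) sit in the wide gaps between the observed
classes (37–54 / 76 / 194–195 aa), and the Ala cutoffs (0.40, 0.15)
bracket the observed ~62% vs ~5% compositions; all are configurable.
The Thr period score is the fraction of consecutive Thr–Thr spacings
equal to 11. Signal/propeptide boundaries come from annotation, never
from de novo prediction — published cleavage sites are figure
annotations, not derivable rules. Mature-peptide derivation removes the
annotated signal, then propeptide, then a C-terminal Gly (amidation)
when present; N-terminal Met acetylation of skin isoforms is metadata
and never alters sequence. Classification is a pure function of the
gene model: permuting gene order permutes output identically, and the
rule table is tested against an independent brute-force
re-implementation on 200 random gene models.

## Microsynteny and relocation

Gene identity is by name string, case-insensitive (orthology inference
is out of scope). `flanks` reports the `depth` (default 2, enough to
capture double flanks like HDAC5 + ZG57) nearest non-focal genes per
side, with contiguous focal genes collapsed to one block so tandem
expansions don't change flank calls. `relocation_call` scores a pair of
rows: `same_context` if flank genes are shared on both sides,
`relocated` if both species carry the family but share no flank gene on
either side, `absent_in_one` if a row lacks the family. A pair sharing
exactly one side is scored `same_context`: calling it `absent_in_one`
would be semantically wrong, and one conserved flank is still shared
context. This was a genuinely open corner of the design; the choice is
recorded here.

## Virtual Southern blotting

`digest` cuts at every occurrence of the recognition sequence
(non-palindromes scanned on both strands; circular molecules checked
across the origin); a linear molecule with n cuts yields n + 1 fragments
summing exactly to its length, a circular one yields n. DraI is
modelled as TTTAAA with a blunt cut at offset 3 (standard enzymology;
overridable). A fragment is probe-positive when its best local
alignment to the probe on either strand reaches identity ≥ 0.80 over
≥ 50 columns — a documented stand-in for hybridization stringency,
which blots do not quantify. Positive fragments within 5% relative size
co-migrate as one band whose intensity is the fragment count (the gel
resolution proxy); fragments below 200 bp are unreportable by default.
Partial digestion and transfer efficiency are not modelled.
`match_alleles` greedily matches observed to predicted bands one-to-one
within a relative log-size tolerance and reports score, coverage and
unexplained bands.

## The synthetic generator: what it emulates, what it does not

`build_tandem_bac` emits a circular vector + flanks + N mutated copies
of one random 50%-GC unit template. Each unit carries a skin-type
cassette (non-coding 44-bp exon 1, intron, CDS for a 38-aa Ala-rich
peptide with Thr at 11-residue spacing) and a liver-type cassette
(23-aa signal split across the exon-1/2 junction with a phase-2 codon,
9-aa propeptide, 38-aa mature peptide, amide Gly) — mirroring the
skin + liver pair per repeat. Two DraI sites are embedded per unit and
spurious TTTAAA occurrences are scrubbed from generated random
segments, so the within-unit probe fragment is identical across units
and its band intensity equals the unit count by construction. Defaults:
vector 7,500 bp (a typical BAC backbone; the true vector length is
unpublished), flanks 6,000 bp, unit 11,200 bp, N = 12, per-unit SNV
rate 5 × 10⁻⁴.

`simulate_reads` draws uniform start positions on the circle and
truncated log-normal lengths (mean 8 kb, SD 4 kb, min 500 bp — plausible
for early single-molecule long-read chemistry), records truth intervals
that tile each read, then applies substitutions (0.08/bp), single-base
insertions (0.05/bp) and deletions (0.02/bp), uniform over the
alternatives. Not emulated: instrument-specific error profiles
(homopolymer bias), chimeric reads, quality strings, cloning artefacts.
A green copy-number test therefore establishes estimator correctness
under idealized uniform sampling with simple errors — not robustness to
library-specific coverage bias.

`build_allele_pair` derives a short allele by deleting whole units and
applying 2% substitutions elsewhere (the observed allelic flank
divergence is ~3%, concentrated in low-complexity regions which the
generator does not have). `build_provenance_pair` realizes the two
coding-origin hypotheses: scaffold (flank/exon-1/intron/3′) shared at a
configurable identity with the CDS either point-diverged or wholly
replaced by (GCC)ₙ — the latter translating to poly-Ala, the
GC-rich-replacement hypothesis in its purest form.

All generators restore the caller's RNG state and are byte-identical
under a fixed seed. Point mutations can legitimately demote a cassette
(an SNV through a Thr codon destroys periodicity), in which case the
classifier is right and the generator's truth label is stale; exact
truth-recovery tests therefore run at SNV rate 0.

## Numerical choices and degenerate inputs

- Internal coordinates are 0-based half-open everywhere; GFF3/GenBank
  (1-based inclusive) and BED (native) convert at the I/O boundary;
  user-facing reports echo 1-based inclusive positions.
- CDS lengths not divisible by three translate on ⌊n/3⌋ codons with a
  flag (and imply a frameshift for classification); codons containing N
  translate to X; internal stops are retained and flagged.
- All-ambiguous read sets warn and carry a `degenerate` flag into the
  estimate; zero vector support is an error, not a number.
- Alignment tie-breaking follows Biostrings' deterministic first-path
  convention; identity symmetry is tested property-style.
- Bootstrap replicates that lose all vector reads are dropped (and at
  B = 0 no interval is reported).

## Acceptance-scale choices

The copy-number acceptance runs the spec'd world exactly: default
12-unit configuration, 3,000 reads per replicate, 20 replicates. The
calibration criterion (true N ∈ {2, 6, 12}, 50 replicates each) fixes
replicate counts but not read depth; it runs at 800 reads per replicate
to stay inside the runtime budget, which widens per-replicate CIs but
leaves bias and coverage interpretable. Accession-based integration
checks are opt-in and require pre-downloaded records; nothing is
downloaded implicitly.

## Known limitations

- The block scanner re-scores candidate regions by full local DP; it is
  intended for locus-scale (≲ 30 kb) comparisons, not genomes.
- Copy-number truth is recovered for unit counts where vector coverage
  is adequate; with very few vector-spanning reads the ratio estimator's
  variance dominates (the bootstrap reports it honestly).
- Statistical significance (E-values) for similarity blocks is out of
  scope; thresholds are explicit instead.
- Orthology is by gene name in the synteny module; renamed orthologs
  will produce spurious `relocated` calls.
- The hybridization proxy is a similarity threshold; it does not model
  melting thermodynamics, partial digestion or probe length effects
  beyond the span minimum.
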