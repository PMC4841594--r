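---
title: "Phylogenetic and epigenetic footprinting of conserved regulatory elements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic and epigenetic footprinting of conserved regulatory elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecrfoot)
```

## The problem

Imprinted domains such as the ~500-kb *Peg3* region are thought to be
regulated by a set of short evolutionarily conserved regions (ECRs):
100–300-bp blocks that keep high human–mouse identity although they lie
outside any open reading frame. Characterising such blocks as candidate
enhancers combines four independent lines of evidence, and this package
implements each as a testable, reusable step:

1. **Conservation calling** — find the blocks themselves between two
   genomic intervals, with the field's operational criterion: a region is
   an ECR when it is *longer than* 50 bp and shows identity *strictly
   greater than* 75%.
2. **Cross-species presence** — use each block as a probe in a
   seed-and-extend search over other species' sequence (a BLAT-like
   strategy) and tabulate the species-by-probe presence matrix.
3. **Phylogenetic footprinting** — align each block's ortholog set,
   extract the sub-regions with *no* sequence variation across species,
   scan cis-regulatory motifs, and score per-block motif enrichment.
4. **Epigenetic profiling** — in-silico COBRA for DNA methylation, and
   H3K4me1/H3K27ac peak intersection for enhancer chromatin state and
   breadth (ubiquitous vs tissue-specific).

Every stage can run on synthetic inputs with planted ground truth, so the
whole pipeline is verifiable without any external download.

## Conservation calling

Two intervals are aligned globally under an affine gap model (defaults:
match +1, mismatch −1, gap open 2, gap extend 1 — a gap of length $k$
costs $2 + k$). Alignment is delegated to
`Biostrings::pairwiseAlignment()`; the test suite checks its scores
against an independently written Gotoh dynamic program on all inputs up
to 15 bp. **Identity is defined as matches divided by aligned columns,
with every gap column counting against identity**; `N` never matches.
This definition has to be fixed for the 75% criterion to be testable, and
it is the one used everywhere in the package.

Element calling works on the per-column match vector. Candidate segments
are the all-maximal positive-scoring subsequences (Ruzzo–Tompa) of the
score `match − baseline`. The baseline is placed 0.1 *below*
`min_identity` (0.65 at the default 0.75) rather than at the threshold
itself, for a reason worth recording: an optimal global alignment of two
*unrelated* sequences already produces ~0.55 per-column identity, because
the aligner is free to pair random matches. A baseline at or below that
level lets segments drift into flanking sequence and merge across it; a
baseline just under the reporting threshold keeps segment edges pinned to
the true edges of a conserved block. Each candidate segment is reported
only if its identity strictly exceeds `min_identity` and its span on the
reference strictly exceeds `min_length` — so a fully identical 50-bp
block is *not* called, by design. Reported elements never overlap on the
reference and are listed 5′→3′. Calling is made exactly symmetric in its
two inputs by aligning the pair in a canonical internal orientation.

## Ortholog search and the presence matrix

The search hashes every exact 11-mer of the probe over both strands of
the target (words containing `N` are skipped), clusters seed hits by
diagonal, and extends each cluster by local affine-gap alignment of the
probe against the surrounding window. Hits scoring below `min_hit_score`
(default 30) are dropped; overlapping hits keep only the best. The
presence matrix records, per species and probe, the **maximum** hit score
— one number per cell — plus per-probe species counts and their mean.
The reported score is this package's local-alignment score under its own
scoring scheme; it is deliberately *not* comparable to the absolute
values of any external search engine.

## Footprinting, motif scanning, enrichment

Ortholog sets are aligned by **reference anchoring**: each sequence is
aligned pairwise (global) to the reference species and the pairwise
alignments are merged on reference coordinates, with bases inserted
relative to the reference given their own flagged columns. This mirrors
the pairwise practice the field uses for these short elements and keeps
all coordinates on the reference; it is not a progressive multiple
alignment and makes no attempt at cross-species consistency of
insertions. Removing gaps from any row reproduces that species' input —
a property the tests enforce.

Footprints are maximal runs of columns in which every species has one
identical, unambiguous, non-gap residue, of length ≥
`min_footprint_length`. The default 6 is the length of the shortest
motif of interest (the E box, CAGCTG); "small regions" is otherwise
unquantified, so this is a configurable design choice. Output equals a
brute-force per-column scan on every tested alignment.

Motif scanning uses IUPAC patterns on both strands: the forward spelling
on the plus strand and the reverse-complement spelling against the same
forward sequence for the minus strand. A palindromic pattern (CAGCTG,
CCATGG) yields one hit per position, not two — with this rule the E-box
counts are identical whether or not one "deduplicates" strands, which is
why it is the default. All overlapping occurrences count; `N` never
matches. The shipped library holds the four motifs recurrently found in
these elements — E box CAGCTG, PITX2 GGGATTA/TAATCCC, NF-κB
GGAATTTT/AAAATTCC, RFX1 CCATGG — and users may add degenerate patterns
(e.g. CANNTG for a permissive E box, available via
`default_motif_library(degenerate_ebox = TRUE)`).

Per (element, motif), the enrichment statistic is
`ratio = total hits across species / number of species with a sequence`;
the ratio may exceed 1 (several sites per species), and the flag is set
only when the ratio is **strictly greater than 0.5**. Species with no
identified ortholog are excluded from the denominator.

## In-silico COBRA

Bisulfite conversion turns every unmethylated C into T on the strand
being read, retaining C at methylated CpGs. Conversion is top-strand by
default (one strand is what a primer set assays); the bottom strand is
available and converts on its own sense. Incomplete conversion can be
modelled as a per-C failure probability (default 0).

The key analytic step is **enzyme informativeness**, derived per
amplicon, never trusted from a label: the amplicon is converted under
both extremes (all CpGs unmethylated → TG everywhere; all methylated →
CG retained) and the enzyme's sites are compared. Sites existing only
under unmethylated conversion make the enzyme
*unmethylation-indicating* — the TG class, e.g. FokI (GGATG) and HphI
(GGTGA), whose post-conversion site is completed by a converted CpG.
Sites existing only under methylated conversion make it
*methylation-indicating* — the CG class, e.g. TaqI (TCGA), BstUI (CGCG),
HpyCH4IV (ACGT). Anything else is uninformative and refused by
`cobra_assay()`.

Digestion scans both strands of the converted (double-stranded after
PCR) amplicon; each site occurrence is one double-strand break at the
enzyme's cut offset, with palindromic sites counted once per locus.
Fragments always sum to the amplicon length; a cut falling outside the
amplicon is skipped with a warning.

Quantification treats band intensities as molecule counts per fragment
(the simulated gels are generated that way; ImageJ-style densitometry of
real gels approximates it). Bands are assigned to the fully methylated
or fully unmethylated allele's expected fragment set within a ±2-bp gel
tolerance; co-migrating bands pool and allele-shared lengths are
ignored. Each allele's molecule count is its specific intensity divided
by its number of specific fragments (a cut molecule contributes to every
fragment band it produces), and percent methylation is
$100 \cdot M/(M+U)$. For a CG-class enzyme the digested allele is M; for
a TG-class enzyme it is U — both reduce to the same arithmetic, and the
tests check the two classes agree on the same truth within noise.

Differential calls against a matched normal use replicate measurements
(≥2 per group, three in the analysis scripts): the verdict is
hyper-/hypomethylation only when the mean difference exceeds
`min_delta = 10` percentage points *and* a two-sided Welch test rejects
at `alpha = 0.05`. The original report lists three-replicate
significance without naming a test; Welch is the conservative default
and both knobs are configurable. With `min_delta = 0` the false-call
rate on noise-only data is the nominal alpha, which the acceptance suite
verifies over 1,000 trials.

## Enhancer states and breadth

Interval intersection is half-open throughout (`[0,10)` and `[10,20)` do
not overlap), any overlap ≥ 1 bp counts by default, and peaks are taken
as supplied — there is no peak calling. The two-mark grammar is: both
H3K4me1 and H3K27ac → ACTIVE; H3K4me1 only → POISED; H3K27ac only →
ACETYL_ONLY; neither → NONE, with DNA hypomethylation carried as an
independent flag. "Breadth" formalises *ubiquitous* as evidence in a
**strict majority** of tissues (5 of 10 is tissue-specific; 6 of 10 is
ubiquitous) — the qualitative wording "majority of tested tissues" needs
a sharp boundary to be testable, and strictness is that choice. The
evidence source is configurable (`marks`, `hypomethylation`, or the
default `either`, since both lines of evidence identify broadly active
elements).

## The synthetic-data generators

The generators define the conditions under which the pipeline is
validated; their defaults are fixed once and the tests are run against
them.

* **Ortholog sets** evolve independently from one random ancestor (a
  star phylogeny — no tree structure is used downstream, so none is
  simulated) with uniform per-site substitution to one of the three
  other bases (Jukes–Cantor-like), default 0.05 per site per lineage.
  No divergence estimates exist for the survey panel, so this is a
  calibration choice: low enough that the reference-anchored aligner
  stays gap-free in practice, high enough that flanking columns vary.
  Planted motifs are copied unmutated into every carrier species;
  non-carriers get one deterministic centre substitution. Indels are
  off by default; when enabled they are single-base and never fall
  inside planted motifs, keeping truth coordinates exact.
* **Genome pairs** embed blocks at exactly `round((1-identity)·length)`
  substituted positions inside independently random flanks, so the
  planted identity is exact rather than binomially noisy. Identity
  below 0.25 is rejected as indistinguishable from background.
* **The ortholog compendium** (`synthetic_s1_compendium()`) is a
  synthetic stand-in for a 45-genome survey supplement: 18 element sets
  over a 45-species panel, species counts fixed (mean exactly 20,
  reference species always present), ECR18 carried by 20 species with
  one invariant E box plus a second retained in 14 of them (34
  occurrences, 1.7 per species) and a PITX2 site. Chance occurrences
  of the library motifs are deterministically scrubbed from every
  generated sequence, so the planted sites are the *exact* motif
  content and parser/scanner results have a sharp expected value.
* **COBRA gels** simulate 10,000 molecules by default, methylating each
  CpG independently at its true fraction, digesting each molecule, and
  applying 2% multiplicative Gaussian noise per band. At 10,000
  molecules the binomial standard error of a 30% fraction is ~0.5
  points, so the ±3-point recovery check is dominated by densitometry
  noise, not sampling.
* **Tissue tracks** emit peaks only over elements whose assigned state
  requires them, with edge jitter up to 30 bp; elements must be spaced
  more than twice the jitter apart for truth to round-trip exactly,
  which the built-in layouts guarantee.

What the generators deliberately do *not* model: realistic phylogenies
(shared internal branches), CpG hypermutability or any
context-dependent mutation, PCR amplification bias, background peaks in
unrelated genomic positions. Passing the round-trip tests therefore
shows the pipeline's logic is correct under clean assumptions — it does
not certify performance on real genomes, where alignment error,
paralogy and incomplete assemblies add failure modes this benchmark
cannot exercise.

## Determinism and problem sizes

Every generator derives one seeded stream per operation call from the
master seed, so identical configuration and seed give byte-identical
outputs, including the pipeline's `summary.json`. The analysis scripts
use genome pairs of ~1.7 kb (three 150-bp blocks, 300-bp flanks),
18 × ~20 × 120–260-bp ortholog sets, 10,000-molecule gels and an
18-element × 8-tissue track panel; the acceptance script measures
element recovery over 200 genome-pair trials and the delta-call type-I
rate over 1,000 noise-only trials. These sizes were chosen so a full
verification run completes on a laptop in minutes while keeping
Monte-Carlo error well inside every tolerance used.

## Known limitations

* The reference-anchored merge can misplace columns at high divergence
  (noticeably above ~0.1 substitutions per site per lineage), where the
  global aligner may introduce spurious gaps; the planted-motif
  footprint guarantee holds below that regime.
* The element caller reports segment-level identity; it does not split
  a long segment whose two halves straddle the threshold.
* Ortholog search does not chain multiple local hits into one spliced
  hit and is not indexed for whole-genome-scale targets.
* COBRA quantification assumes the amplicon's informative sites for the
  chosen enzyme share the assayed CpG set; molecules cut at a strict
  subset of sites (possible with several independently methylated
  informative CpGs) would produce bands it refuses rather than
  misreads.
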