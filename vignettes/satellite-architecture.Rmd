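---
title: "Methods: satellite and acrocentric-arm architecture analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: satellite and acrocentric-arm architecture analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(satarch)
```

# Scope

`satarch` implements the computational core of a satellite-DNA and
acrocentric-chromosome analysis for a New World monkey genome:
tandem-repeat periodicity spectra, alpha-satellite monomer
classification and array annotation, dimer-haplotype and k-mer
signature calling, pseudo-homologous region (PHR) detection with its
sharing network, self-identity matrices, and rDNA array analysis (unit
detection, copy-number estimation and allocation, activity
classification, centromere-dip-region calling, and a sex comparison of
copy numbers). A first-class synthetic-genome generator plants all of
these structures with ground truth, so every stage is validated by
recovery tests rather than by external data.

The marmoset system this emulates has a characteristic architecture:
centromeres are compact *dimeric* alpha-satellite arrays built from two
~170 bp monomer types (S3 and S4) with older, inactive satellite layers
on the flanks; the X centromere exceptionally carries a higher-order
repeat whose unit spans 28 monomers; subterminal arrays are built from
a distinct ~171 bp monomer (MarmoSAT); acrocentric short arms share
>99%-identity segments (PHRs) across heterologous chromosomes and may
or may not carry tandem rDNA arrays (45S coding region plus intergenic
spacer, transcribed from the telomere toward the centromere), including
degraded units disrupted by retrotransposon-like insertions.

# Periodicity spectra

`ntr_spectrum()` tallies, for every k-mer occurring at least twice, the
distances between consecutive occurrences (up to `max_period`). A
tandem array of unit length *p* concentrates recurrence intervals at
*p* and its multiples; a dimer of two divergent monomers scores the
dimer length 2×170 = 340 most strongly because few k-mers survive in
both monomer types. Defaults are `k = 21` (long enough that random
recurrence is negligible at desk scales, short enough that ~2%
divergence leaves most k-mer copies exact) and `max_period = 3000`
(covers monomers through small HORs; large HORs are sought on the
class string instead, where the unit size is counted in monomers, so a
raw-spectrum ceiling of 3 kb suffices). K-mers containing N are
excluded. Scores are raw interval counts; spectra are comparable within
a run, and no cross-dataset normalization is attempted.

# Monomer segmentation and consensus

`segment_monomers()` places monomer boundaries on an in-phase lattice.
A rough pass anchors on the k-mer best supporting the detected period;
a provisional consensus built from interior rough monomers is then
aligned back to the array (exact k-mer matches at sampled offsets), and
the lattice is re-phased to the consensus start, shifted so tiling
begins at the array start. Gaps between anchor hits spanning *m*
periods are subdivided evenly (tolerating ±3 bp of net indel per
monomer, the cap the generator also enforces); the trailing partial
unit is dropped below period/2. Passing `phase_to =` a known consensus
instead phases boundaries to that consensus — used before
classification so monomers are in register with the profiles.

`build_consensus()` star-aligns monomers to the longest monomer and
takes the column-wise majority, ties to the alphabetically smaller
base; columns where the gap wins outright are removed, keeping the
consensus length near the median monomer length. Star alignment (not a
full MSA) is deliberate: at the divergences modeled (≤ ~5%), projection
onto a single reference loses almost nothing, and it keeps consensus
building linear in the number of monomers.

# Classification, arrays, dimhaps, signatures

Families are modeled as position-specific log-odds profiles over
ungapped monomer alignments (`train_profiles()`), not profile HMMs:
monomer lengths are near-constant here and the family scheme is defined
by substitution variants, not indel structure. Probabilities use a
pseudocount (default 0.01 of the column total) against a uniform
background; a pseudocount of 0 deliberately allows −∞ for unseen
bases. `classify_monomers()` scores both strands of each monomer
against every profile (summed log-odds; equal-length monomers score
directly, others are projected via banded alignment to the profile
consensus) and assigns the best family; assignments with a margin under
`min_margin = 2.0` log-odds over the runner-up are labeled
`ambiguous`. Classification is order-independent, with ties broken by
lexicographic family name.

`annotate_satellite_arrays()` merges runs of same-family monomers
(gap ≤ `max_gap` = 500 bp) into arrays, drops runs below
`min_array_monomers` = 10, and labels the largest array per centromere
window (or per sequence) `active`, the rest `inactive` — the layered
architecture in which an active array of one subfamily is flanked by
small relic arrays of another. Because a dimeric array alternates two
monomer families, `family_groups` maps monomer families to their
array-level (subSF-style) label before run-merging.

`call_dimhaps()` single-links array dimer consensuses at
`link_identity = 0.99` — the same identity scale used for PHR calling —
and reports per-cluster specificity as the fraction of member arrays on
the modal chromosome (specificity is computed per array, not per
monomer; the alternative was left open in the source material for this
design). `kmer_signatures()` returns, per active array, the canonical
k-mers with ≥ `min_copies` occurrences in that array and zero in every
other; the output sets are disjoint by construction and asserted so on
every call.

`build_tree()` computes distances as 1 − global-alignment identity and
runs neighbor joining (`ape::nj`), a standard minimum-evolution
heuristic; on additive matrices NJ provably recovers the topology,
which the tests exercise. `homogenization_test()` asks whether monomers
cluster by chromosome: the statistic is the fraction of taxa whose
nearest tree neighbor (patristic distance, ties averaged) shares their
chromosome label, with significance from label permutations
(`p = (1 + #permuted ≥ observed) / (1 + n)`). A non-significant result
on subterminal monomers is the signature of inter-chromosomal
homogenization.

# PHR detection

`windowed_identity()` slides windows (default 5 kb, step 2.5 kb — both
below the 10 kb span threshold so that threshold-length PHRs are always
covered by multiple windows) along sequence A, anchors each window in B
by exact 32-mer seeds (sampled every 200 bp; ≥ 3 seeds must agree on a
diagonal within 200 bp), and aligns the window to the anchored slice of
B with a banded Needleman–Wunsch (band 256). Identity is matches over
aligned columns *including gap columns* — the stricter, reproducible
definition. Each window alignment is trimmed to its best local
sub-segment (maximum-subarray on per-column scores of +1 match / −3
mismatch-or-gap; the asymmetric penalty stops the trim from drifting
into unrelated flanks), and hits below 300 columns or 80% identity are
discarded. Collinear same-orientation hits with gaps up to one window
are chained. Both orientations are searched; inverted sharing is
reported with orientation `-` on the original coordinates.

`call_phrs()` merges abutting/overlapping segments — only when they
overlap on *both* sequences, so distinct homologous copies are not
fused — and applies the two thresholds jointly: identity ≥ 0.99 over
≥ 10 kb on both sequences. The chained-then-filtered order is one
consistent reading of a rule whose original operational details
(aligner, chaining) are not public; raising either threshold can only
shrink total PHR bp, a monotonicity property the tests check across a
grid. `phr_network()` aggregates PHRs into one undirected edge per
chromosome pair with summed shared bp (the smaller span of each PHR)
and bp-weighted mean identity. `self_identity_matrix()` applies the
same alignment contract to all window pairs of one sequence, giving the
long-format matrix behind triangular self-identity heatmaps.

The pairwise aligner itself (`src/align.cpp`) is a compact banded
Needleman–Wunsch (match +1, mismatch −1, gap −2, linear) returning the
aligned strings; banding exploits the fact that every alignment the
package performs is pre-anchored, so the net diagonal drift is small.
An unbanded mode (band = 0) serves short monomer-scale alignments.

# rDNA analysis

`find_rdna_units()` seeds the coding (45S-like) consensus in the target
on both strands with exact 32-mers every 150 bp and clusters hit
diagonals — one cluster per unit copy. Insertions are read directly
from the anchor diagonals: a jump of ≥ `min_insertion` = 100 bp between
consecutive anchors marks a retrotransposon-like disruption at that
consensus position, flagging the unit degraded; this is robust where
gap placement in a linear-penalty alignment is not. Units extend to the
next unit's coding start, or one IGS length past the coding end.

`estimate_total_copies()` is the diploid depth ratio: copies = 2 ×
mean depth over the rDNA reference region / mean depth over a
single-copy region, the single-copy baseline being 2 copies per diploid
genome. Both regions must be covered by ≥ 50 bins. The estimate is
returned unrounded. `allocate_array_copies()` renormalizes per-array
fractional intensities (accepted when summing to 1 ± 0.02) and converts
them to integers by largest-remainder rounding — the standard rule that
conserves the total exactly; remainder ties break by array name for
determinism.

`classify_activity()` encodes the epigenetic dichotomy of rRNA genes:
the coding region of active genes is hypomethylated while the IGS stays
methylated in either state. An array is `active` when its mean coding
methylated fraction is below `threshold = 0.5` (the midpoint of a
binary dichotomy described without a cutoff); the IGS mean is reported
but never used for the call. `call_cdrs()` smooths methylation with an
11-bin moving mean and reports maximal runs below `dip_factor = 0.5` ×
the array mean spanning ≥ 10 kb — hypomethylated dips that mark
candidate kinetochore sites. `compare_sex_copy_number()` uses a
rank-sum statistic with a two-sided permutation null rather than a
t-test: copy numbers are skewed and the rank test is distribution-free.

# The synthetic generator

The generator is the package's study system, not a tuning knob. Its
defaults encode the architecture above: 170 bp alpha-satellite
monomers in S3/S4 dimers (150 dimers ≈ 51 kb active arrays) with
inactive flanking layers of a second dimer family, 20% inter-family
divergence and 2% per-copy substitution; a 171 bp subterminal monomer;
a 28-class unit for the X-style HOR; rDNA units with telomere-to-
centromere transcription and optional planted insertions; PHR donors
mutated at half the requested divergence per arm so the two planted
copies share the requested *pairwise* identity; and depth/methylation
tracks where a single-copy region sits at `mean_depth` (default 30×)
and rDNA bins scale by copies/2. Divergence between families and among
copies are free parameters of the simulation — the real values are not
published in the source material — chosen at levels a practitioner
would call realistic for recently homogenized satellites (intra-array
2%, inter-family 10–20%).

All randomness flows through one seed per operation (`with_seed`
restores the caller's RNG state), so outputs are byte-identical across
reruns. Indels are single-base with net drift capped at ±3 bp per
monomer, keeping segmentation testable. Coordinates are 0-based
half-open everywhere, matching the emitted BED.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: read-level sequencing error and mappability
structure (tracks are drawn around their expected values, not
simulated from reads), satellite homogenization gradients along arrays,
transposon families with internal structure (spacers are random DNA),
centromeric inversions, and the long-range haplotype diversity of real
assemblies. Recovery rates here are upper bounds on real-data
performance.

# Problem sizes and runtime choices

Test and acceptance workloads are sized for a single CPU: arrays of
50–350 monomers (≈ 8–60 kb), arms of 40–80 kb, PHR donors of 12–15 kb,
rDNA models of 2–3 kb coding + 0.8–1.5 kb IGS (scaled an order of
magnitude below real 45S units, preserving structure), 200-simulation
null calibrations with 99–199 permutations, and 10-seed recovery loops.
The full suite runs in a few minutes; the acceptance script in well
under one.

# Known limitations

- Profile classification assumes near-constant monomer length; grossly
  length-variant satellite families would need profile HMMs.
- The aligner's linear gap penalty is adequate for anchored,
  substitution-dominated comparisons but places large gaps poorly;
  rDNA insertion detection therefore reads diagonals, not gaps.
- `windowed_identity` requires an exact 32-mer seed match; sharing
  below ~95% identity can escape anchoring. This is safe for PHRs
  (≥ 99%) but the function is not a general homology search.
- Dimer-haplotype clustering is all-pairs and quadratic in the number
  of arrays; it is meant for tens of arrays, not thousands.
- The rDNA copy estimator inherits every bias of the depth tracks it is
  given (GC, mappability); on real data those corrections must happen
  upstream.
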