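---
title: "Structure, age, and rates: methods behind evostruct"
author: "evostruct authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure, age, and rates: methods behind evostruct}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evostruct)
```

## The question the package addresses

Protein evolutionary rates vary enormously, and both present-day structural
properties and evolutionary history have been proposed as determinants. Two
regularities motivate this package: the per-residue nonsynonymous rate
(dN) rises roughly linearly with relative solvent accessibility (RSA), and
proteins that arose more recently (assessed by phylostratigraphy — the
phylogenetic width over which homologs are detectable) evolve faster
overall. `evostruct` implements the joint analysis of these two effects:
residue-level structural classification, age assignment, rate estimation on
concatenated residue classes, a knowledge-based stability potential with a
mutational-robustness simulation, and the statistical comparisons that tie
them together. A synthetic-data generator supplies every input with the
statistical structure those analyses assume, so the entire chain is testable
without downloading structures, genomes or alignments.

## Residue features

RSA is the DSSP accessibility divided by the residue's reference area in an
extended Gly-X-Gly tripeptide (the Miller et al. reference values, shipped
as `inst/extdata/miller_asa.tsv`); ratios above 1 are clamped to 1. A
residue is *buried* below 25% accessibility and *exposed* otherwise; we
classify RSA exactly 0.25 as exposed so that "buried" stays strictly below
the threshold. RSA is also apportioned into 20 equal-width bins, half-open
`[lo, hi)` with bin 20 closed at 1 so the clamped maximum has a bin. A small
numeric tolerance (1e-9) keeps exact bin boundaries such as 0.15 in the
upper bin despite binary floating point. Secondary structure uses the
four-way mapping: helix (DSSP H), sheet (E), turn (S, T) and coil
(B, G, I, "."); other letters are an error rather than silently coerced.
Structures shorter than 50 residues, with gapped numbering, or with an
incomplete N/CA/C/O backbone are rejected before analysis, and multi-model
(NMR) files contribute their first model only. When the coordinate record
and the DSSP record disagree on a residue's identity the position is
dropped.

## Age assignment

Each query is assigned the oldest clade in which a homolog is detectable at
an e-value of 1e-4 or better, over four species groups (youngest to
oldest): mammals (mouse, rat), non-mammalian vertebrates (chicken, frog,
zebrafish, fugu), other metazoans (sea squirt, fly, mosquito, worm) and
other eukaryotes (two yeasts, rice, thale cress). Mammal-level assignments
are flagged and excluded from comparative analyses — at realistic corpus
sizes that class is too small to analyze. For structure-to-protein mapping,
hits below 99% identity are removed and overlapping hits are reduced to
one. "Closest to the query" is operationalized as highest percent identity,
ties broken by longer alignment and then lower e-value; the underlying
notion admits several readings (identity, coverage, genomic position) and
this choice is ours, recorded here rather than attributed to anyone.

## Rate estimation

Aligned ortholog pairs are back-translated to codon alignments, and codon
columns are concatenated by structural category (secondary structure,
exposure, or RSA bin, optionally crossed with age class); pairs below 50%
protein identity are excluded, and estimates from concatenations shorter
than 60 amino acids, or with dN > 0.5 or dS > 2, are discarded as likely
non-homology or saturation.

dN and dS are estimated by Nei–Gojobori (1986) counting with the
Jukes–Cantor correction `d = -(3/4) log(1 - (4/3) p)` — a deliberate,
self-contained substitution for maximum-likelihood codon models. For the
closely related pairs this analysis admits (dS ≤ 2) counting and ML agree
well in ordering, but absolute values can differ; the package's estimates
should not be compared numerically against ML output. Two conventions are
fixed and tested: single-nucleotide changes that would create a stop codon
count as nonsynonymous in the site tally, so synonymous plus nonsynonymous
sites equal three per codon exactly; and multi-hit codon differences are
averaged over all orderings of the changes, excluding orderings that pass
through a stop codon (with a fallback to all orderings when every one is
blocked). When a proportion of differences reaches 3/4 the correction is
undefined and the estimate carries a "saturated" flag; omega is flagged
undefined when dS is 0. The implementation is held to exact (1e-12)
agreement with an independently written brute-force oracle in the test
suite.

## The four-body potential

Stability is scored with a coarse-grained four-body knowledge-based
potential. Residues are reduced to their alpha-carbon positions (a
side-chain-center variant is a possible extension; the coarse single-point
representation is standard for this potential family). The Delaunay
tetrahedralization of those points defines quadruplets of spatially
neighboring residues; simplices with any edge longer than 8.5 Å are
discarded to suppress artifactual surface-spanning tetrahedra (the cutoff
is configurable; 8.5 Å is common practice for tessellation potentials).
Because no 3D Delaunay implementation was available in our R dependency
set, the tessellation is implemented in compiled code as an incremental
Bowyer–Watson construction with an infinite vertex for the hull facets;
it is validated against brute-force empty-circumsphere enumeration on
hundreds of small random point sets. Exactly degenerate inputs are retried
once after a deterministic 1e-6 Å jitter seeded from the structure id; in
double precision the jitter resolves flat configurations, so the remaining
degenerate-input error path is defensive.

The score of an unordered amino-acid quadruplet composition `q` is the
log-odds `ln(f_q / p_q)`: `f_q` is its frequency among all retained
simplices of a training corpus (add-one pseudocounts keep all 8,855
compositions finite) and `p_q` is the multinomial expectation from the
corpus amino-acid frequencies with the multiset multiplicity factor
`4!/prod(m_a!)`. Note that an unobserved composition's score is finite but
its sign depends on how small its expectation is — compositions of four
identical rare residues can score positive simply because `p_q` is tiny.
The stability of a (conformation, sequence) pair is
`ΔG = -Σ score(q)` over retained simplices, so lower ΔG means greater
stability; mutants are scored by swapping the sequence on the fixed native
conformation, as the potential assumes. ΔG is reported unnormalized by
length, so cross-group stability comparisons must use the length-binned
pairing described below.

## Mutational robustness

Two mutation rates are implemented: one random substitution per 50 residues
(2% of sites) and per 10 residues (10%), with `k = max(1, floor(L/d))`
distinct positions per mutant and a uniformly chosen different amino acid
at each. A population of 1000 mutants (default) yields the robustness
statistics: `Z = (ΔG_native - <ΔG_mutants>) / σ` (standard deviation with
the n−1 denominator) and the rank of the native score in the sorted mutant
list, lowest (most stable) first. Mutants scoring exactly the native value
count as above it (`rank = 1 + #{mutants strictly below}`), a deterministic
and conservative tie rule. Per-site scans mutate each position once to a
random different residue and record `|ΔΔG| = |ΔG_native - ΔG_mutant|`.

## The statistical layer

Rates are summarized per RSA bin, and the RSA–dN relationship is assessed
by Pearson correlation over the 20 binned points and by ordinary least
squares on those points (`dN ~ RSA` within an age class;
`dN ~ RSA + RSA*age + age` for every pair of age classes, with the
interaction coefficient testing slope differences). Fitting on bin-level
rather than residue-level observations matches how the binned relationship
is usually displayed; residue-level fits would weight bins by their codon
counts, and a count-weighted option exists but is off by default. The
standard error of each binned dN is estimated by codon bootstrap (200
resamples) — the error estimator is our choice, as none is prescribed for
binned concatenations. Group comparisons use Wilcoxon tests: exact
enumeration for small untied samples (minimum n ≤ 25), the tie-corrected
normal approximation with continuity correction otherwise. Raw p-values
are reported (no multiple-testing correction by default; a
Benjamini–Hochberg pass is a one-liner with `p.adjust` on the emitted
tables). For stability comparisons across age classes, structures are
binned by length (25-residue bins) and down-sampled (seeded) to equal
counts per group within each bin, so compared groups share a length
distribution at bin resolution; when no bin contains every group the
pairing is empty and the result reports which group's exclusion would
rescue it.

## What the synthetic generator emulates — and what it does not

The generator is the package's study-condition definition, not a tuning
knob. A structure is a collapsed self-avoiding walk (consecutive
alpha-carbon distance 3.8 ± 0.1 Å, steps biased toward the running
centroid) with idealized backbone atoms; it reproduces the two features the
downstream methods actually consume — realistic contact density and a
hydrophobic core — and nothing else. Residues nearest the centroid receive
hydrophobic amino acids; per-residue RSA is a piecewise-linear map of the
burial rank calibrated so the expected buried fraction equals
`core_fraction`, plus Gaussian noise (sd 0.05), emitted as integer
DSSP-style accessibilities. Secondary-structure letters are drawn in runs
with realistic class weights but carry no geometric meaning.

Ortholog pairs substitute codon `i` with probability
`min(1, base_rate + rsa_slope * RSA_i)`; a substitution is nonsynonymous
with probability 0.75 (about the random expectation) and synonymous
otherwise, always via a single-nucleotide non-stop neighbor. A synonymous
draw at a codon without a synonymous neighbor (Met, Trp) leaves the codon
unchanged, which keeps the nonsynonymous process exactly
`0.75 * p` at every site — diverting those draws would couple the planted
slope to local amino-acid composition. On the dN scale the planted slope
is therefore approximately `0.75 * rsa_slope / 2.2` (2.2 ≈ nonsynonymous
sites per codon).

Per-age defaults are set once: `core_fraction` 0.45/0.40/0.35 and
`base_rate` 0.01/0.02/0.04 for eukarya/metazoa/vertebrata (older proteins
more buried and slower), and `rsa_slope` 0.0075/0.009/0.018 — a 2.4-fold
eukarya-to-vertebrata ratio, chosen so the recovered dN-scale slopes land
near 0.0025 and 0.006. The per-age buried fractions are free parameters of
the generator (no empirical distribution exists to calibrate them against);
only their ordering is meaningful.

What the generator does *not* emulate: real folds and side chains, indels
(alignments are gap-free by construction), disordered or low-complexity
regions, compositional biases among age classes beyond the core fraction,
and any correlation between expression level and rate. Passing tests
therefore demonstrate that the pipeline recovers effects of the assumed
form from data of realistic size and noise — not that real proteomes
behave this way. In particular the generator plants no direct age effect
on mutational robustness; the Z-score and rank comparisons across
synthetic age classes inherit only the core-fraction differences and are
correspondingly weak.

## Problem sizes and numerical choices

The default pipeline (`pipeline_config()`) simulates 24 structures of
120–260 residues per age class, trains the potential on a disjoint
50-structure corpus, and uses 1000-mutant populations; it completes in
about half a minute. The parameter-recovery experiments use 90 structures
of 200 residues per age class with 13 replicate pairs each (about 230k
codons per age class), which gives the binned regression enough codons per
bin (~10k) for the interaction test to be reliably significant at the
planted 2.4-fold slope ratio. Null calibration uses 200 replicate datasets.
Seeds propagate from a single master seed through deterministic integer
maps, and every generator restores the caller's RNG state, so identical
configurations are bit-reproducible.

## Known limitations

Counting-based dN/dS saturates sooner than ML and the Jukes–Cantor
correction ignores transition/transversion bias; both matter only beyond
the dS ≤ 2 regime this analysis admits. The potential's absolute ΔG values
are corpus-dependent and dimensionless — only comparisons under one model
are meaningful. The tessellation uses floating-point predicates with a
conservative in-sphere slack rather than exact arithmetic; adversarially
cospherical inputs could in principle be mis-tessellated, which the
jitter rule mitigates for the package's use on (possibly jittered)
experimental coordinates. The CLI wrapper (`inst/exec/evostruct`) is a thin
convenience over the documented functions, which remain the primary
interface.
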