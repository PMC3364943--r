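# evostruct

Joint analysis of protein structure and evolutionary age as determinants of
protein evolutionary rate.

Two things are separately well established: residues with higher relative
solvent accessibility (RSA) accumulate nonsynonymous substitutions faster
(the binned dN–RSA relationship is close to linear), and evolutionarily
younger proteins — those whose homologs are detectable over a narrower
phylogenetic range — evolve faster than older ones. `evostruct` is for
researchers who want to study how these two effects interact: whether age
modulates the RSA–rate slope, whether structural differences among age
classes (buried-core fraction, secondary-structure composition, computed
stability, mutational robustness) can account for the age–rate
relationship, and how all of this behaves under a fully specified
generative model.

The package implements, end to end:

* **Residue features** — PDB/DSSP-style parsing with quality filters
  (≥ 50 residues, contiguous chain, complete N/CA/C/O backbone; first NMR
  model only), RSA normalization by Gly-X-Gly reference areas with clamping
  at 1, the 25% buried/exposed rule, 20 RSA bins, and the four-way
  helix/sheet/turn/coil mapping.
* **Age assignment** — phylostratigraphy over four species groups
  (mammals < vertebrates < metazoans < eukaryotes) with an e-value cutoff
  of 1e-4, plus the 99%-identity non-overlapping filter for mapping
  structures onto proteins.
* **Rates** — back-translation of protein alignments to codon alignments,
  concatenation by structural category / RSA bin / age class, and dN, dS,
  dN/dS by Nei–Gojobori counting with the Jukes–Cantor correction
  (`d = -(3/4)·ln(1 - (4/3)·p)`), with the ≥ 60-aa, dN ≤ 0.5, dS ≤ 2
  robustness filters.
* **Stability** — a coarse-grained four-body knowledge-based potential on
  the Delaunay tessellation of alpha carbons (8.5 Å edge cutoff), scoring
  each quadruplet composition `q` as `ln(f_q/p_q)` against a trained corpus
  and each structure as `ΔG = -Σ scores` (lower = more stable).
* **Robustness** — random mutagenesis at 1 substitution per 50 (or 10)
  residues, 1000-mutant populations, `Z = (ΔG - ⟨ΔG⟩)/σ` and the rank of
  the native among its mutants; per-site |ΔΔG| scans.
* **Statistics** — binned Pearson correlations, `dN ~ RSA` and
  `dN ~ RSA + RSA*age + age` fits, exact/tie-corrected Wilcoxon suites, and
  length-binned pairing for stability comparisons across age classes.
* **Synthetic data** — a generator producing compact structures with a
  planted hydrophobic core, ortholog codon pairs whose substitution
  probability is linear in RSA with age-dependent slope and rate, homolog
  hit tables of any planted age, and decoy sets; every downstream stage is
  testable against planted truth.

## Worked example

```r
library(evostruct)

cfg <- sim_config(chain_length = 120, age_class = "vertebrata", seed = 42)
s <- generate_toy_structure(cfg)
s
#> <protein_structure> SYN0042: 120 residues (xray, model 1)

feats <- residue_features(s)
fraction_exposed(feats)
#> [1] 65.8   # percent of residues with RSA >= 0.25

pair <- generate_ortholog_pair(s, feats, cfg)
estimate_dn_ds(codon_alignment(pair$codons_a, pair$codons_b))
#> <rate_estimate> 120 codons: dN = 0.0102, dS = 0.04853, dN/dS = 0.2101

hits <- generate_homolog_profile("vertebrata", seed = 42, query_id = s$id)
assign_age(hits)
#> <age_assignment> vertebrata (ok); hits per group: mammalia=0 vertebrata=3 metazoa=0 eukarya=0
```

The dN here is the nonsynonymous substitution rate per nonsynonymous site
recovered from the planted process (vertebrate defaults: 0.04 substitutions
per codon at RSA 0, rising with accessibility), and the age assignment
round-trips the planted phylogenetic width.

A full synthetic study — cohort, features, rates, potential, robustness,
statistics — is one call:

```r
report <- run_pipeline(pipeline_config(seed = 11))
report
#> <evostruct_report>
#>   cohort: 72 structures, 14084 residues
#>   stage rates      ok
#>   stage stats      ok
#>   stage stability  ok
#>   stage robustness ok
#>   binned RSA-dN Pearson r = 0.518 (p = 0.0193)
#>   dN~RSA slopes: eukarya 0.0018, metazoa 0.0023, vertebrata 0.0094
```

(Default desk scale is deliberately small; the correlation tightens toward
1 as codons per bin grow — see the vignette for the scales used in the
recovery experiments.) `run_pipeline(..., outdir = "out")` writes every
intermediate table as TSV plus a JSON run manifest, and
`plot(report)` draws the binned dN–RSA relationship per age class. A thin
CLI with `simulate`/`rates`/`report`/... subcommands is installed under
`inst/exec/evostruct`.

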