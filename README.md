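# dielortho

Cross-species day–night expression comparison and ortholog sign-flip
analysis.

## The problem

When two closely related species occupy opposite temporal niches — one
diurnal, one nocturnal — the genes behind the switch should betray
themselves in head transcriptomes sampled at midday and midnight: their
day–night direction *flips* between the species in register with each
species' activity phase (day-upregulated in the diurnal species,
night-upregulated in the nocturnal one). `dielortho` implements that
comparison as a reusable, fully tested pipeline for anyone analysing
paired diel RNA-seq designs across species, together with a synthetic-data
generator that plants known truth at every level so the whole chain can be
validated end to end without any sequencing data.

## What it computes

Starting from transcript × sample count matrices (one per species) with a
sample design (species, diel phase, activity niche, replicate):

* **Differential expression**, two flavours per species under the
  negative-binomial model Var = μ + φμ²: an exact conditional test
  (TMM-scaled counts; the two-sided p-value sums all splits of a gene's
  total between day and night no more likely than the observed one) and a
  Wald test from an IRLS-fitted NB log-linear model (median-of-ratios
  offsets; log₂FC = β₁/ln 2). Sign convention: positive = night
  overexpression. Significance: BH FDR < 0.05 and |log₂FC| ≥ 2; the
  per-species consensus of both flavours feeds the cross-species stage.
* **Orthology**: reciprocal best hits over proteomes (own C++
  Smith–Waterman, BLOSUM62, affine gaps 11 + k), anchored to a reference
  proteome; orthogroups, representative selection (similarity, then
  length), and reference-free cross-species pairs.
* **Cross-species classification**: collapse onto reference genes,
  patterns (concordant day/night, flipped, strong single-species),
  diel-coincidence (day-up in the diurnal AND night-up in the nocturnal
  species), and candidate ranking by three criteria — DE in both species,
  coincidence, and a sensory/circadian GO annotation.
* **GO over-representation**: hypergeometric upper tail with BH within
  namespace, including fold-change-stratified study sets (FC ≤ −5,
  FC ≥ 5, FC ≥ 2).
* **Co-expression networks**: unsigned |r|^β adjacency (β = 9),
  topological overlap TOMᵢⱼ = (Σᵤ aᵢᵤaᵤⱼ + aᵢⱼ)/(min(kᵢ,kⱼ) + 1 − aᵢⱼ),
  static-cut average-linkage modules, eigengenes, and module–trait
  (phase/species) correlations on the combined two-species matrix.
* **Conservation profiling**: per-column Shannon-entropy scores
  (1 − H/ln 20, gap-penalized, smoothed, graded 1–9), conserved-block
  detection, focal-pair mutation mapping with in-block counts, and
  shared-vs-lineage-specific block comparison between orthologs of
  different lengths.

## Worked example

```r
library(dielortho)

cfg <- sim_config(seed = 1, n_ref_genes = 500, n_flipped = 15,
                  n_concordant = 10, n_single_species = 10,
                  n_modules = 2, module_size = 20)
study <- simulate_study(cfg)
res <- run_study_analysis(study, orthology_source = "rbh")

head(res$candidates[, c("reference_gene", "pattern", "diel_coincident",
                        "categories", "score", "min_adj_p")], 3)
#>   reference_gene pattern diel_coincident        categories score    min_adj_p
#> 1       REF00183 flipped            TRUE         circadian     3 1.025448e-46
#> 2       REF00155 flipped            TRUE         circadian     3 5.112053e-17
#> 3       REF00341 flipped            TRUE circadian,hearing     3 2.938280e-16

evaluate_against_truth(res, study$truth, study$family)
#> evaluation against planted truth:
#>   flip_sensitivity           1
#>   flip_precision             1
#>   n_planted_flips            15
#>   n_detected_flips           15
#>   candidate_rank_key_gene    1
#>   module_ari                 0.9511323
#>   enrichment_detected        FALSE
#>   block_jaccard              0.9952607
#>   de_type1                   0.03694268
```

Reading the output: all 15 planted sign-flips were recovered with no
false flips; the planted key candidate (`REF00183` here — flipped,
diel-coincident, circadian-annotated, strongest cycler) ranks first; the
co-expression modules are recovered at adjusted Rand 0.95 and the planted
conserved blocks at Jaccard 0.995. Enrichment is undetected at this
reduced size (15 flipped genes give little power at a 0.02 annotation
base rate) — at the default 2000-gene configuration with 50 flips it is
detected at adjusted p ≈ 1e−7.

The `analysis/` directory holds the same workflow as numbered narrative
scripts (`01_simulate.R` … `08_evaluate.R`), each a thin driver over the
package that prints what it found and writes its tables under `results/`.
Run them in order from the repository root:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_differential_expression.R
# ... through
Rscript analysis/08_evaluate.R
```

## Documentation

The methods vignette (`vignettes/diel-ortho-methods.Rmd`) describes the
models, the generator's design and what it does and does not emulate, the
numerical choices (dispersion moment corrections, static-cut calibration,
entropy conservation scoring), and known limitations.
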