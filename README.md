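# digitid

Comparative transcriptomics of digit identity in amniote limbs.

`digitid` is an R package plus a set of analysis drivers for asking
whether the digits of a limb carry distinct, evolutionarily conserved
gene-regulatory programs. It works from gene × sample read-count
matrices of individual digits (with their posterior interdigital
mesenchyme), sampled across species, limbs, stages and replicates, and
implements the full analytic chain used to interrogate digit identity:

* **Normalization** — TPM from median transcript lengths, square-root
  variance stabilization, and per-gene mean-centering within declared
  bulks (all samples of a stage or of a limb) for cross-stage and
  cross-limb analyses.
* **Differential expression** — per-gene negative-binomial GLMs
  (`Var = μ + φμ²`, log link, library-size offsets) compared by
  likelihood-ratio tests between adjacent digits (1 df) or across all
  digits of a limb (ANOVA-style, digits − 1 df); Cox–Reid
  adjusted-profile-likelihood dispersion estimation with fixed-weight
  tagwise shrinkage; optional stage factors and PC1 artifact covariates;
  Benjamini–Hochberg and Storey q-value FDR control.
* **Multivariate structure** — average-linkage clustering on
  `1 − Pearson r` dissimilarities with gene-bootstrap support (BP, and
  optionally multiscale AU), centered PCA with deterministic sign
  conventions, supplementary projection of held-out samples, and
  nearest-centroid digit-correspondence calls in the PCA plane (the
  frame-shift evaluation).
* **Conservation statistics** — per-species DE sets restricted to the
  one-to-one ortholog universe (size *N*), their intersection
  ("conserved differentially expressed genes"), binomial overlap tests
  (per-gene chance probability `p = Π kᵢ/N`, expected overlap `N·p`,
  exact tail summation), single-gene recovery probabilities, and the
  threshold-free comparison of ortholog fold changes against
  expression-matched random genes (Pearson correlations compared by t
  and Mann–Whitney tests).
* **Diagnostics** — p-value-distribution uniformity (the signature of
  undifferentiated digits), replicate concordance with best-pair
  selection, and dispersion comparisons between sibling-derived and
  population-derived datasets.
* **Synthetic data** — a negative-binomial count simulator with
  one-to-one ortholog structure and planted digit-identity modules
  (including homogeneous limbs and a frame-shifted 4-digit limb), so the
  whole pipeline is testable end to end with known ground truth.

## Worked example

Three simulated pentadactyl species share a planted 30-gene module
upregulated 4-fold in digit 1; everything downstream is computed by the
package:

```r
library(digitid)

cfg <- sim_config(
  n_genes = 1000, ortholog_fraction = 1,
  species = list(species_spec("mouse_like"),
                 species_spec("alligator_like"),
                 species_spec("anolis_like")),
  modules = list(module_spec("conserved_D1", digit = 1, size = 30,
                             log2fc = 2)),
  seed = 1)
sim <- simulate_counts(cfg)

de   <- lapply(sim$counts, lrt_pairwise, digits = c(1, 2),
               lengths = sim$lengths)
sets <- de_sets_by_boundary(de, sim$ortholog_map, fdr = 0.05)
cons <- intersect_conserved(sets$sets, sets$direction, N = sets$N,
                            boundary = "D1_vs_D2")
print(cons)
#> ConservationResult [D1_vs_D2]: |intersection| = 30 of N = 1000 (k: 37/40/38)
#>   expected by chance 0.0562; P(>= observed) = 7.31e-71

score_recovery(sim$truth, cons$intersection, "conserved_D1")
#> sensitivity 1.00, false-discovery proportion 0.00

expr <- sqrt_transform(tpm_normalize(sim$counts$mouse_like, sim$lengths))
tree <- bootstrap_support(expr, n_boot = 1000, seed = 1)
d1 <- sim$counts$mouse_like$samples$sample_id[
  sim$counts$mouse_like$samples$digit == 1]
group_support(tree, d1)
#> D1 clade monophyletic: TRUE, BP = 100.0
```

Reading the numbers: each species calls 37–40 of the 1000 one-to-one
orthologs differentially expressed between digits 1 and 2 at BH-FDR
0.05 (the planted 30 plus a handful of false positives); the three-way
intersection recovers exactly the planted module, against an expected
chance overlap of 0.056 genes (binomial tail 7.3e-71); and in
clustering, the digit-1 replicates form a clade with 100% bootstrap
support. A homogeneous species run through the same code yields
near-uniform p-values, empty DE sets and no supported clades — the
signature of digits without distinct identities.

## The analysis workflow

Numbered drivers under `analysis/` run the study end to end on
simulated data and write tables under `results/`:

```sh
Rscript analysis/01_simulate.R                 # counts, orthologs, truth
Rscript analysis/02_differential_expression.R  # adjacent & any-digit tests
Rscript analysis/03_clustering_pca.R           # trees with BP, PCA scores
Rscript analysis/04_conservation.R             # CDEG-style intersections
Rscript analysis/05_frameshift.R               # wing-projection calls
Rscript analysis/06_diagnostics.R              # concordance, dispersion
```

A single-configuration orchestration of the same stages is available as
`run_digit_pipeline()` (see `inst/extdata/demo_config.yaml`), and the
methods vignette (`vignettes/digit-identity-methods.Rmd`) documents the
models, defaults and numerical choices.

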