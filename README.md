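# bsig — expression signatures and proliferation analysis of B cell subsets

`bsig` is an R package for case-control transcriptomic studies of sorted
B cell subsets (naive, memory, plasmablast) and the flow-cytometry
proliferation experiments that accompany them. It targets the analysis
pattern of lupus (SLE) B-cell studies: an interferon-stimulated gene
signature elevated across all subsets, a cell-cycle program switched on
only in patient plasmablasts, and a coexpression module organized around
the transcription factor FOXM1.

The package provides, as tested reusable components:

* **Differential expression** — per-array 75th-percentile
  normalization of log2 intensities; an empirical-Bayes **moderated
  t-test** written from first principles (scaled-inverse-chi-square
  variance prior, moment matching on log variances with Newton trigamma
  inversion; posterior variance
  `s~² = (d0·s0² + df·s²)/(d0 + df)`, Student-t reference with
  `df + d0` degrees of freedom); signed fold changes (`-1/r` for
  `r < 1`); DEG calling at `p < 0.05` and two-fold change; one-sided
  Fisher's exact over-representation.
* **Signature scoring** — the max-normalize-and-sum score: each gene
  row is scaled so its maximum across samples is exactly 1 (on the
  linear scale), and a sample's score is the sum over the set; plus
  ANOVA/Tukey and per-subset contrasts on the scores.
* **Coexpression screening** — "similar entities": Pearson correlation
  of candidate profiles to an anchor gene, selected inside the closed
  band `[0.6, 1.0]`.
* **Proliferation & apoptosis** — dye-dilution generation assignment
  (log-spaced peaks, geometric-mean boundaries), the proliferation
  index `PI = ΣN_i / Σ(N_i/2^i)` (total cells over inferred founders),
  and annexin/viability apoptosis gating fractions.
* **Synthetic data** — a seeded generator for the full
  3-subset × 2-group × 4-donor study (with planted IFN, cell-cycle and
  anchor-module effects and complete ground truth) and for dye-dilution
  experiments, so every stage is testable without external data.
* **Pipeline** — `run_pipeline()` drives
  simulate → normalize → DEG → ORA → score → similar → proliferation
  from one seeded YAML/list config, writing TSV outputs and a JSON run
  manifest with checksums. A thin CLI lives at `inst/cli/bsig.R`.

## Worked example

```r
library(bsig)

study <- simulate_expression_study(simulation_config(seed = 1))
norm  <- normalize_percentile(study$matrix, percentile = 75)
stats <- moderated_t_test(norm, study$annotation, subset = "plasmablast")
degs  <- call_degs(stats, p_thresh = 0.05, fc_thresh = 2)
degs
#> <deg_result> 5000 genes tested: 228 up, 89 down (p < 0.05, |fc| >= 2)
attr(stats, "prior")
#> <variance_prior> d0 = 4.04362, s0_sq = 0.246093
```

The fitted prior recovers the generator's variance hyperparameters
(`d0 = 4`, scale `0.5² = 0.25`). The IFN signature score separates
SLE from HC in every subset:

```r
sets <- truth_gene_sets(study$truth)
sc <- signature_score(study$matrix, sets$IFN_SIGNATURE, study$annotation)
compare_scores(sc)$subset_contrasts
#>        subset mean_HC mean_SLE     t        p
#> 1       naive    5.66     10.5  9.05 1.02e-04
#> 2      memory    6.31     12.1 10.94 3.47e-05
#> 3 plasmablast    6.85     12.9 10.26 5.01e-05
```

Scores are sums of per-gene values normalized to a maximum of 1, so with
23 usable genes the score lies in [0, 23]; SLE samples roughly double
the HC score in each subset, and the per-subset t contrasts are all
significant. Screening the plasmablast up-regulated DEGs for profiles
similar to the FOXM1 anchor, and testing set over-representation:

```r
sim <- find_similar_entities(study$matrix, "FOXM1",
                             c("FOXM1", setdiff(degs$up_genes, "FOXM1")))
sim
#> <similarity_result> anchor FOXM1: 136/228 candidates in [0.6, 1] (pearson)
ora <- ora_fisher(c(degs$up_genes, degs$down_genes), stats$gene_id, sets)
ora[, c("set_name", "set_size_bg", "overlap", "p", "significant")]
#>        set_name set_size_bg overlap         p significant
#> 1 IFN_SIGNATURE          23       5  1.29e-02       FALSE
#> 2    CELL_CYCLE         231      79  8.29e-40        TRUE
#> 3  FOXM1_MODULE         100      98 2.34e-121        TRUE
```

The similar-entities list is dominated by the planted module and
correlated cell-cycle genes — the pattern the screen is designed to
expose — and at the `p < 0.01` ORA threshold the plasmablast DEGs
over-represent the cell-cycle and module sets but not the IFN set
(which is up in *all* subsets, so it contributes proportionally fewer
plasmablast-specific DEGs). Finally, the flow readouts:

```r
div  <- simulate_division_experiment(division_sim_config(seed = 2))
dist <- assign_generations(div$events, gen0_mean = 10000, i_max = 5)
proliferation_index(dist)
#> <pi_result> PI = 8.4303 (founder-equivalents 11.8619)
apoptosis_fractions(div$events, apoptosis_gate(600, 600))
#>  live early  late
#> 0.695 0.204 0.101
```

A PI of 8.43 means the culture holds 8.43 cells per inferred founder —
an average of about three divisions — and the gated apoptosis fractions
recover the simulator's configured 0.7/0.2/0.1 class mix.

## Repository layout

```
R/                  implementation (data model & IO, simulators,
                    differential expression, signatures, coexpression,
                    proliferation, pipeline)
tests/testthat/     unit, property and acceptance tests (fixtures are
                    generated in code)
vignettes/          methods vignette: models, conventions, design choices
scripts/            acceptance script
inst/cli/bsig.R     command-line wrapper
inst/extdata/       small illustrative GMT file
```
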