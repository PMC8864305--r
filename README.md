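# cortiscore

Cell-type-resolved scoring of microRNA perturbations in the developing
cortex, from single-cell RNA-seq counts and live-imaging migration tracks.

## The problem

In utero electroporation introduces a microRNA-overexpression construct
(condition `miR`) or a scrambled control (`scram`) into embryonic cortical
progenitors; single-cell RNA-seq of the electroporated cells follows the
differentiation trajectory from apical progenitors (AP) through basal
progenitors (BP) to newborn (N0) and differentiating (N1) neurons. The
analytical questions — and the tools this package provides for them — are:

* **Which cell type responds?** A regularized hinge-loss classifier of
  `scram` vs `miR` cells per type, evaluated by cross-validated AUC:

  $$\min_{w,b}\; \tfrac1n \sum_i \max(0,\, 1 - y_i (w\cdot x_i + b)) +
  \tfrac{\lambda}{2}\lVert w\rVert^2 .$$

  Genes are ranked by signed weight and the model is re-optimized on the
  best 100 genes (top 50 + bottom 50); gene selection runs inside every
  cross-validation fold so held-out AUCs are leakage-free. The top
  positive/negative weights name the induced and repressed genes.
* **Is maturation shifted?** An all-threshold ordinal regression (same
  hinge machinery plus K−1 ordered thresholds) trained on control cells
  yields a per-cell pseudo-maturation score $w \cdot x$; perturbed or
  cross-species cells are projected onto the model and compared to the
  controls' cross-validation scores by a rank-sum test.
* **Which identity do perturbed neurons adopt?** Binary identity models
  (L4 vs L2/3, P3 vs P7, superficial vs deep layers) classify projected
  query cells; proportions come with exact binomial intervals and a
  chi-square / Fisher exact contingency test.
* **How do the cells migrate?** Track metrics with the strict pause rule
  (step < 12 µm per 10 min), average vs movement speed, directionality,
  the multipolar-to-bipolar transition fraction within a 300 × 150 µm ROI,
  and equal-per-slice subsampling; laminar 10-bin position analysis and
  marker ratios for histology.

A ground-truth-annotated synthetic generator (four-state trajectory,
negative-binomial counts, marker programs, mitochondrial fractions,
injected effects, migration tracks) makes every stage testable end to end
without any downloads.

## Worked example

```r
library(cortiscore)

ds <- generate_trajectory_dataset(sim_config(seed = 42))
#> <expr_dataset> 1200 genes x 414 cells
#>   conditions: miR=222, scram=192

qc    <- qc_filter(ds, qc_thresholds(min_genes_detected = 500))
norm  <- normalize_rpm_log(qc$dataset)          # log10(1 + RPM)
types <- assign_cell_types(norm, default_marker_sets(qc$dataset))

res <- score_cell_types(norm, types$cell_type,
                        qc$dataset$cell_meta$condition, seed = 42)
dplyr::select(res, cell_type, n_control, n_perturbed, auc)
#>   cell_type n_control n_perturbed   auc
#> 1 AP               47          44 0.431
#> 2 BP               54          39 0.963
#> 3 N0               45          48 0.449
#> 4 N1               62          51 0.627
```

The simulation injected 50 induced + 50 repressed genes (2-fold) only in
BP cells of the `miR` condition: the BP classifier separates conditions
almost perfectly (cross-validated AUC 0.963) while the unaffected types
hover near chance — the perturbation is localized to BPs. The affected
genes fall out of the winning model's weights:

```r
top_regulated_genes(res$cv[[which(res$cell_type == "BP")]]$model, n = 5)
#>    gene_id  weight direction
#>  1 g0503    0.0851 induced
#>  2 g1081    0.0842 induced
#>  ...
#>  6 g0754   -0.0508 repressed
```

Pseudotime, identity and migration follow the same pattern; see
`?fit_pseudotime`, `?fit_identity_model`, `?track_set_metrics` and the
methods vignette (`vignettes/cortiscore-methods.Rmd`). `run_pipeline()`
drives whole scenarios from a YAML config and writes a reproducibility
manifest; a thin CLI wrapper lives in `exec/cortiscore`.

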