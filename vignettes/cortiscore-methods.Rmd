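---
title: "Scoring microRNA perturbations in cortical development: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring microRNA perturbations in cortical development: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortiscore)
```

## The analysis problem

In utero electroporation delivers a microRNA-overexpression construct (or a
scrambled control, "scram") to apical progenitors of the embryonic cortex;
single-cell RNA-seq of the electroporated cells then asks three questions:

1. **Which cell type responds transcriptionally?** The differentiation
   trajectory spans apical progenitors (AP), basal progenitors (BP),
   newborn neurons (N0) and differentiating neurons (N1). A per-cell-type
   classifier of scram vs miR cells, evaluated by cross-validated AUC,
   localizes the response: a type whose cells are separable from controls
   at AUC well above 0.5 carries a transcriptional effect.
2. **Is maturation shifted?** An ordinal-regression "pseudo-maturation"
   model trained on control cells orders cells along differentiation; the
   perturbed cells' scores are compared to the controls' cross-validation
   scores.
3. **Which identity do the perturbed neurons adopt?** Binary identity
   models (L4 vs L2/3, P3 vs P7, superficial vs deep layers) trained on
   reference populations classify perturbed cells, and contingency tests
   compare the called proportions.

Around the transcriptomic core, live-imaging migration statistics (speeds,
directionality, pause detection, the multipolar-to-bipolar transition) and
laminar-position binning quantify the anatomical phenotype.

## Models

### Regularized hinge-loss classification

Binary models minimize

$$\frac{1}{n}\sum_i \max\bigl(0,\; 1 - y_i\,(w \cdot x_i + b)\bigr) \;+\;
\frac{\lambda}{2}\lVert w\rVert^2,$$

with $y_i \in \{-1, +1\}$, an unregularized bias $b$, and per-gene
standardization (mean 0, sd 1 on the training cells) so that $\lambda$
means the same thing across datasets. The per-cell *prediction score* is
the linear combination $w \cdot x + b$.

### All-threshold ordinal regression

For $K$ ordered categories the model fits weights $w$ and $K-1$ increasing
thresholds $\theta_k$, minimizing

$$\frac{1}{n}\sum_i \sum_{k=1}^{K-1}
\max\bigl(0,\; 1 - s_{ik}(w \cdot x_i - \theta_k)\bigr) +
\frac{\lambda}{2}\lVert w\rVert^2,
\qquad s_{ik} = \begin{cases} +1 & \text{category}(i) > k\\ -1 &
\text{otherwise,}\end{cases}$$

the *all-threshold* variant: every cell is penalized against every
threshold it sits on the wrong side of, which makes the optimum thresholds
ordered automatically. The pseudo-maturation score of a cell is $w \cdot x$.
Several ordinal-hinge variants exist (immediate-threshold,
one-vs-next, ...); the all-threshold form is used because it exploits the
full ordering and reduces exactly to the binary hinge at $K = 2$.

### Solver

Both objectives are convex but non-smooth. The package smooths the hinge
kink by Huber rounding over a width $\delta$ (bias at most $\delta/2$ per
term) and minimizes with L-BFGS-B under $\delta$-continuation
($10^{-3} \to 10^{-6}$) from a zero start, which is deterministic: the
contract is the objective value (relative tolerance $10^{-6}$, iteration cap
10,000 with a convergence error), not a particular algorithm. The test
suite checks the achieved objective against exhaustive grid search on small
instances, for both losses.

### Gene ranking, the best-100 panel, and cross-validation

Genes are ranked by signed weight (ties broken by gene id, so rankings are
reproducible); the model is then re-trained on the 50 most positive plus 50
most negative genes. Model performance is assessed by stratified 20-fold or
leave-one-out cross-validation in which *the entire pipeline — full-gene
training, ranking, re-training — runs inside each training fold*, so gene
selection never sees held-out cells (`cross_validate(select_in_fold =
TRUE)`, the default). AUC is the tie-corrected pairwise concordance of the
held-out scores.

One deliberate exception: `fit_pseudotime()` defaults to
`select_in_fold = FALSE`, i.e. the gene panel is chosen once on all control
cells and only the 100-gene model is re-fitted per fold. Its
cross-validation scores are not a leakage-free accuracy estimate — they are
the *reference distribution* that perturbed cells' projections are compared
against, and those projections are computed on the final panel. Comparing
distributions across per-fold-different gene panels would be an
inconsistent contrast. Users wanting the conservative accuracy estimate can
set the flag.

### Regularization default

$\lambda$ defaults to 1 (unit ridge on standardized genes). With far more
genes than cells — the operating regime of every analysis here — small
penalties such as $1/n$ leave the hinge in a near-separable regime where
fold-to-fold models are dominated by noise directions; unit ridge pulls the
solution toward the stable class-centroid direction. $\lambda$ is exposed
on every trainer for users who want to tune it.

## The synthetic-data generator

`generate_trajectory_dataset()` emulates the statistical structure the
analyses rely on, with ground truth recorded in the metadata:

* a latent maturation $m \in [0,1]$ per cell (Beta(1.2, 1.2)), cut at
  (0.25, 0.5, 0.75) into AP/BP/N0/N1;
* marker programs that follow smooth logistic windows in $m$ (peak
  fold-change 8), so pseudotime recovery is a meaningful test, not a
  lookup;
* negative-binomial (gamma–Poisson) counts, dispersion 0.15, log-normal
  library sizes around 20,000;
* per-cell mitochondrial fractions from a Beta mixture with ~7% "damaged"
  cells exceeding 15%, so QC filters have work to do;
* induced/repressed genes (50 + 50 at 2-fold) applied *only* in the
  perturbed cell type × perturbed condition, drawn from the upper half of
  baseline expression — a 2-fold change on a near-zero-count gene is not
  observable at these library sizes;
* optional maturation delay (shift on $m$, truncated) and BP/AP
  composition multiplier (cells moved between the AP and BP intervals until
  the perturbed-condition ratio is the stated multiple of the realized
  control ratio);
* default cell numbers 192 control / 222 perturbed, matching post-QC
  embryonic experiments, and 1,200 genes — large enough that gene selection
  is a real problem, small enough that the full suite runs on a laptop.

What it does **not** emulate: doublets, batch effects, ambient RNA,
dropout beyond NB sampling, spatial structure, or raw reads/UMIs. Passing
tests on this generator demonstrates that the pipeline recovers the
structure it models; they say nothing about robustness to artifacts the
generator omits.

`generate_layer_dataset()` produces two reference populations with disjoint
marker programs plus a mixed query population; `generate_tracks()` produces
10-min-interval, 12-h migration tracks (73 frames) with an irreversible
multipolar-to-bipolar switch (per-frame transition probability), directed
bipolar steps toward the pial side, and pauses.

## Conventions and edge rules

* **QC boundaries are strict exclusions**: a cell is dropped when it
  expresses *fewer than* `min_genes_detected` genes (2,000 embryonic,
  1,000 postnatal) or *more than* 15% mitochondrial counts; cells exactly
  at a boundary stay. "Genes detected" means count > 0. Filtering is
  idempotent. An optional `picture_qc` column (single healthy cell seen in
  the well) is honored when present.
* **Normalization** is $\log_{10}(1 + \text{RPM})$; the pseudocount is
  configurable and the RPM values sum to $10^6$ per cell before the log.
* **Pauses** are steps of *strictly less than* 12 µm per 10-min frame;
  exactly 12 µm counts as movement. `average_speed` uses total path length
  over total time; `movement_speed` excludes pausing steps (0 with a flag
  when all steps pause); `directionality` is net displacement over path
  length.
* **MBT fraction**: denominator = tracks multipolar at $t=0$ starting
  inside the 300 × 150 µm ROI whose upper border sits on the IZ/deep-layer
  boundary; numerator = those turning bipolar within 12 h.
* **Laminar bins** are half-open $[0,10), [10,20), \ldots$ with the last
  bin closed at 100 (percent distance from the white matter); frequencies
  are computed per brain, then averaged with SEM across brains.
* **"Fisher's chi-square"** is ambiguous, so `proportion_test()` reports
  the Pearson chi-square (no continuity correction by default) for any
  table and adds the two-sided Fisher exact p for 2 × 2 tables.
* **Classification threshold** for projected binary scores is 0, the
  decision boundary; `classify_query()` exposes it.
* **Missing model genes** at projection time contribute 0 after
  standardization and trigger a coverage warning; below 50% coverage the
  projection errors. Cross-species projection maps symbols
  case-insensitively unless an explicit ortholog map is supplied.
* **Pseudotime scores** are reported raw and min-max scaled to the control
  cross-validation range for plotting.

## Problem sizes used in the tests

Unit tests run on scaled-down simulations (300 genes, 60 cells per
condition); the end-to-end checks run at the generator defaults
(1,200 genes, 192/222 cells, 20-fold or leave-one-out cross-validation),
sizes chosen so the full suite completes in minutes while keeping the
p ≫ n regime that makes gene selection and regularization meaningful.

## Known limitations

* Cross-validated AUCs from pooled held-out scores at these cell numbers
  are noisy (sd ≈ 0.06–0.10 under the null) and carry a small pessimistic
  bias (mean ≈ 0.46 under the null) — the finite-dataset exclusion effect
  of cross-validating centroid-like classifiers. Per-type null AUCs should
  be read with a band of roughly ±0.15, not treated as precise chance
  levels; an identical spread is obtained with an independent
  ridge-logistic implementation, so this is a property of the estimator,
  not of the solver.
* Ordinal pseudo-maturation scores resolve order *between* categories
  better than gradation *within* them (the hinge saturates); shift tests
  inherit this, and at 100 cells per arm a 0.2 latent shift is detected at
  p < 0.01 in most but not all datasets — close to the information ceiling
  of the latent truth itself.
* The marker-score cell typer replaces graph clustering deliberately: the
  downstream models need labels, not embeddings. It assumes marker sets
  are informative for all four states; on real data these must be supplied
  (e.g. from the developmental-atlas literature), and the shipped sets are
  synthetic-data defaults.
* `select_variable_genes()` (vst-style standardized variance) recovers
  marker programs reliably but is nearly blind to condition-restricted
  effects confined to a minority of cells — which is why differential
  expression goes through the classifier ranking instead.
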