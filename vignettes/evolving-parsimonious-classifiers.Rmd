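---
title: "Evolving parsimonious neural classifiers for treatment-uptake modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolving parsimonious neural classifiers for treatment-uptake modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evonnet)
```

## The problem

Chronic hepatitis C in people co-infected with HIV is curable with
direct-acting antivirals, but when treatment capacity is rationed, national
prioritisation criteria decide who is treated first. The clinical question
behind this package is which patient characteristics actually drive
treatment uptake — including characteristics, such as recent injection drug
use, that may suppress uptake even when the formal criteria are met.

`evonnet` frames this as imbalanced binary classification over a cohort
table of 17 indicator/ordinal/continuous patient variables (prioritisation
status, people-who-inject-drugs category, psychiatric comorbidity,
incarceration, HCV treatment history, liver-fibrosis stage, gender, age and
HCV genotype) with a treated/untreated outcome at roughly a 2:1 imbalance.
Rather than fitting one fixed architecture, it evolves *sparse* feedforward
networks — the search prunes inputs as well as weights — so that the final
model is small enough to read off which variables matter.

## Model families

Three hidden-unit (basis) families are supported, each feeding a logistic
output unit so the network output is `p(treated | x) = plogis(beta_0 +
sum_j beta_j B_j(x))`:

* **Product units (PU)**: `B_j(x) = prod_i x_i^{w_ji}` over connected
  inputs. Multiplicative units capture high-order interactions with very
  few nodes, but are scale-sensitive, so inputs are mapped to [1, 2] —
  bounded away from zero because negative exponents blow up near zero.
* **Sigmoid units (SU)**: `B_j(x) = plogis(w_j0 + sum_i w_ji x_i)`, the
  classical multilayer-perceptron unit; inputs are mapped to [0.1, 0.9] to
  keep the unit off its saturated tails at initialisation.
* **Gaussian radial basis functions (RBF)**: `B_j(x) =
  exp(-||x - c_j||^2 / (2 r_j^2))` over connected inputs, one shared radius
  per node (the classical RBF network; it also minimises parameter count,
  in keeping with the parsimony goal); inputs are mapped to the
  origin-symmetric [-1, 1].

The output activation is not dictated by the problem statement; a logistic
unit was chosen so that the network emits a probability (needed for ROC and
precision-recall analysis) and hard labels fall out at the 0.5 threshold.
Scalers are fitted on training data only and reused unchanged on
generalisation data, without clipping, to avoid information leakage.

## Evolutionary training

Both the architecture and the weights are learned by evolutionary
programming: mutation and rank-based survival only, no crossover, in the
Angeline-style lineage of evolutionary neural networks. The defaults follow
the reference regime wherever it states one:

| parameter | default | why |
|---|---|---|
| generations | 600 | stated budget; no early stopping |
| hidden nodes | min 1, init max 2, overall max 4 | stated bounds |
| structural counts | uniform {1, 2} | stated add/delete range |
| input-layer init | PU [-1, 1]; SU/RBF [-5, 5] | stated ranges |
| output-layer init | [-5, 5] | stated range |
| population | 500 | free parameter; the source text's "population size was 2940" describes the dataset, so a value typical of this algorithm family is used |
| elitism | 10% | free parameter of this implementation |
| mutation scale | sd 0.5 decaying linearly to 10% | free parameter; adaptive Gaussian perturbation per the lineage |

Each generation: fitness is evaluated (`1 / (1 + E)` with `E` the mean
binary cross-entropy — bounded, monotone in the error, standard for this
algorithm family, since the reference regime never states its fitness);
the top 10% are copied unchanged (displacing the worst); the surviving
ranks are refilled with mutated copies — parametric Gaussian perturbation
for the better half, structural mutation (add/delete nodes or connections)
for the rest. Structural repair is truncation-based: node counts clamp to
[1, 4] and a deletion never leaves a node without input connections.
Every genome at every generation is validated against these invariants on
construction.

Connection counting — the parsimony measure — counts input-to-hidden links,
hidden-to-output weights and the output bias; sigmoid node biases and RBF
radii are node parameters, not connections. This is the only convention
under which a one-node Gaussian model reading six inputs has 8 connections,
matching the published best model.

## Experimental protocol

`run_protocol()` mirrors the published design: one holdout split —
2193 training / 747 generalisation at the reference cohort size of 2940
(the printed counts are 74.6%, not the stated 75%; the counts win) —
shared across all repeated runs and all methods, with only the
evolutionary seed varying between the 30 runs. Splits are stratified by
default (the reference is silent; stratification protects the minimum
sensitivity metric on imbalanced data, and a flag restores plain
splitting). Per-run generalisation metrics are the correct classification
rate (CCR), the minimum per-class sensitivity (MS), the trapezoidal
tie-grouped ROC AUC (algebraically the Mann–Whitney statistic with
half-weight ties) and the connection count; all are reported as fractions
in [0, 1] even where the source defines sensitivity with a factor of 100,
because its own reported values are fractions. The best run is selected by
training fitness with a fewer-connections tie-break — generalisation data
never influence selection.

`compare_methods()` reproduces the statistical harness: per-metric
Kolmogorov–Smirnov normality screens per method (against a normal with
sample-estimated mean and sd — strictly a Lilliefors situation, so these
p-values are approximate and conservative), one-way ANOVA across methods,
Levene's variance-homogeneity test and Tukey HSD pairwise comparisons with
a ranking of means. No multiple-testing correction is applied across the
four metrics, matching the per-metric presentation of the source.
`ablation_study()` reruns the protocol with one variable's column removed
under identical split membership and identical per-run seeds, so metric
deltas are attributable to the missing variable alone.

## The synthetic cohort generator

The real cohort is not public, so `default_schema()` +
`sample_cohort()` generate cohorts with the published *marginal* structure:
every indicator frequency, the four-stage fibrosis distribution, the
treated prevalence of 1952/2940, and age on [18, 76] with mean 48.95. What
the source does not state is invented once and exposed as configuration:

* Age uses a truncated normal with sd 8 years — the source gives only
  min/max/mean, and sd 8 keeps essentially all mass inside the bounds
  while matching the mean.
* Variables outside the three one-hot blocks are independent Bernoullis;
  the source gives no joint distribution, and independence is the neutral
  default (the outcome model, below, is where dependence is planted).
* The fibrosis stage is encoded as a single ordinal 1–4 column, taking the
  17-column layout at face value.
* The outcome is logistic in min–max unit-scaled features, so coefficients
  are comparable across indicators, the ordinal stage and age. The default
  planted model puts nonzero effects exactly on the variables the published
  best sparse model selected — OST PWID, recent PWID, therapy-naive status,
  fibrosis stage, age and genotype 3 — with recent PWID carrying the
  dominant negative coefficient (-6 on the unit scale), so ablation
  experiments can reproduce the qualitative direction of the published
  leave-one-out finding. The intercept is calibrated by Monte Carlo +
  bisection (`calibrate_intercept()`; the expected prevalence is strictly
  monotone in the intercept, so bisection on a fixed Monte Carlo draw is
  deterministic and converges to machine tolerance on that draw).

What synthetic cohorts deliberately do **not** emulate: the unknown real
joint dependence between predictors, site/geography effects, and the true
(unpublished) outcome mechanism. Tests passing on synthetic cohorts
therefore validate the machinery — sampling fidelity, scaling, search,
metrics, statistics — not clinical performance on the real cohort, whose
headline values (generalisation AUC 0.802 for the best Gaussian model)
require the non-public records.

## Numerical choices and edge cases

* Fibrosis staging: the published kPa bands leave [8.9, 9.0) and
  [14.5, 14.6) uncovered; both gaps resolve to the lower stage
  (conservative staging), making the stages a partition of the axis.
* Constant feature columns scale to the midpoint of the target range;
  scaling is otherwise invertible to 1e-10.
* Forward probabilities are clamped to [1e-12, 1 - 1e-12] inside the
  cross-entropy only, never in reported predictions.
* ROC/PR curves group tied scores into a single threshold step and
  integrate trapezoidally; AUC is checked against an O(n²) pairwise oracle.
* RBF radii are initialised as |uniform draw| floored at 1e-3 and kept
  positive under mutation by reflection.
* Genomes serialise to JSON at 17 significant digits, which round-trips
  IEEE doubles bit-exactly.
* Single-class training data trains (degenerately) but flags a warning in
  the trace; single-run protocols report a dispersion of 0 by convention.

## A small worked example

The scale used throughout the tests keeps runtimes in seconds; a faithful
rerun of the full regime (population 500, 600 generations, 30 runs) is the
same code with the default `ea_config()`.

```{r example, eval = FALSE}
sch <- default_schema()
mod <- calibrate_intercept(default_outcome_model(), sch, 0.664)
coh <- sample_cohort(sch, mod, n = 2940, seed = 1)

cfg <- ea_config("RBF", pop_size = 200, generations = 150)
rs <- run_protocol(coh, "RBF", cfg, n_runs = 10, master_seed = 1)
rs
rs$best_report

ab <- ablation_study(coh, "RBF", cfg, "X4", n_runs = 10, master_seed = 1)
ab
```

The repository's acceptance script (`scripts/acceptance.R`) runs exactly
this kind of pipeline at fixed scaled-down sizes — a 50-point separable toy
problem over 30 short runs (population 100, 200 generations) for the
search-behaviour checks, and a 2000-patient synthetic cohort with 10
matched runs per arm (population 200, 150 generations) for the ablation
direction — sizes chosen to make the full recomputation a matter of
minutes while leaving every qualitative conclusion intact.

## Known limitations

* The exact selection/replacement scheme and mutation adaptation of the
  original implementation are unpublished; this package's choices are
  documented defaults, all configurable, not a reconstruction.
* The synthetic generator cannot reproduce real-cohort performance values;
  it exists to make the pipeline testable and to support qualitative
  (direction) findings such as the recent-PWID ablation collapse.
* Product-unit networks require strictly positive inputs by construction;
  feeding unscaled data is an error, not a silent misbehaviour.
* The Kolmogorov–Smirnov normality screen with estimated parameters
  under-rejects normality (the Lilliefors caveat); it is kept
  because it mirrors the published harness, and it is a screen, not an
  inferential endpoint.
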