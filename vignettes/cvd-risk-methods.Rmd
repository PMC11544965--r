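---
title: "Methods: a discrete Bayesian network for 5-year cardiovascular risk in young breast-cancer survivors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a discrete Bayesian network for 5-year cardiovascular risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvdbn)
```

## The problem

Cardiovascular disease (CVD) is a rare but serious long-term sequela in
adolescent and young-adult (AYA) women surviving breast cancer, driven
largely by cardiotoxic treatment (anthracycline chemotherapy,
chest radiotherapy, HER2-targeted drugs) and by hormone-therapy-related
ischemic risk. Real-world evidence on this question typically lives in
two incompatible silos:

* a **population-based cohort (PBC)**: registry records linked to
  administrative data, so treatments, cardiovascular risk factors and
  CVD outcomes are observed, but tumour prognostic detail (grade,
  receptor status, stage) is absent;
* a **clinic-based cohort (CBC)**: hospital charts with full tumour and
  treatment detail but no administrative linkage, hence no CVD
  follow-up at all.

Missingness is therefore *block-wise and missing-not-at-random* (MNAR):
which variables are missing is a deterministic function of the cohort a
patient came from. `cvdbn` implements the modelling strategy suited to
this situation: a discrete Bayesian network whose **root context node
is the cohort indicator**. Because the missingness mechanism is then
part of the model, Expectation-Maximization over the pooled data is
valid even though the data are MNAR marginally.

## The model

A discrete Bayesian network over variables $X_1,\dots,X_n$ is a DAG $G$
plus one conditional probability table (CPT) per node, factorizing

$$P(x_1,\dots,x_n) \;=\; \prod_{i=1}^{n} P(x_i \mid \mathrm{pa}_G(x_i)).$$

The 25 model variables (see `cvd_dictionary()`) are organised in
temporal tiers that encode the flow of causation: cohort context →
tumour prognostic factors → neoadjuvant treatments → surgery → adjuvant
treatments → cardiovascular risk factors and treatment toxicities →
the CVD target and 5-year vital status. `knowledge_dag()` is the
prior-knowledge structure over those tiers; `model_tiers()` exposes the
tier partition used to constrain structure search.

Individual prediction is a posterior query: given partial evidence $e$
on a patient's observed covariates, the model reports
$P(\texttt{cvds}=\text{Yes}\mid e)$ and classifies the patient as
at-risk when the posterior reaches a threshold.

## Learning under block-MNAR missingness

`structural_em()` alternates:

1. **parameter EM** on the current structure (`em_parameters()`): the
   E-step computes expected family counts by *exact* marginalization of
   each record's missing block under the current model, the M-step
   refits the CPTs with a small pseudo-count;
2. **expected sufficient statistics** under the fitted model;
3. **constrained hill-climbing** (`hill_climb()`) on the decomposable
   BIC score computed from those expected counts, under
   `knowledge_constraints()`: required arcs (the prior DAG) are never
   removed, forbidden arcs never added, arcs never point into the
   context node or backwards across tiers, and the graph stays acyclic.

The loop stops when the structure is stable. Arcs discovered beyond the
prior DAG are returned in `added_arcs`, deliberately *not* auto-merged
into the required set: vetting discovered arcs against the literature
is a human step, and re-running with an extended constraints file is
the explicit, auditable way to accept them.

Implementation notes:

* The E-step exploits the block structure: the posterior of a missing
  block depends only on the CPT factors touching it, so records are
  grouped by the relevant observed sub-vector and one block posterior
  is computed per group. This makes expected counts for *arbitrary*
  candidate families (as needed by the structure search) cheap exact
  tallies, with a guard (default $10^5$ joint completions per missing
  block) against pathological missingness patterns.
* EM initialization is a deterministic available-case Laplace fit, so
  learning is reproducible without a random restart policy.
* Convergence uses the relative change in observed-data log-likelihood
  (`rel_tol`, default `1e-4`; cap `max_iterations = 100`); the outer
  structural loop is capped at `sem_max_outer = 20`.
* With `smoothing_alpha = 0` the observed log-likelihood trace is
  provably non-decreasing; with a positive pseudo-count EM ascends the
  *penalized* likelihood instead, so the monotonicity checks in the
  test suite run at `alpha = 0`.
* **Why `smoothing_alpha = 0.1` and not 1.** The outcome is rare
  (~2%) and some families have dozens of parent configurations. A full
  Laplace count of 1 per cell then dominates the handful of real
  events — in a configuration with ten patients and no event,
  Laplace-1 asserts an 8% event rate — which flattens the fitted risk
  surface and destroys ranking. A pseudo-count of 0.1 keeps every CPT
  strictly positive (required for inference) while letting observed
  events dominate. This is the package's own calibration of a design
  trade-off; both settings are available.
* BIC is the default score (decomposable, prior-free); the score of a
  family with expected counts $N_{jk}$ is
  $\sum_{jk} N_{jk}\log\hat\theta_{jk} - \tfrac{\log N}{2}\,(r-1)q$
  with $r$ child states and $q$ parent configurations.

## Inference engines

* `enumerate_posterior()` — brute-force summation; exponential, guarded
  at $2^{22}$ completions; kept as the oracle all other engines are
  tested against.
* `eliminate_posterior()` — exact variable elimination with min-fill
  ordering (lexicographic tie-break); the default engine, since the
  study-scale networks are small.
* `likelihood_weighting()` — ancestral sampling with evidence clamped
  and weighted; reports per-state ratio-estimator Monte-Carlo standard
  errors; retained for approximate-inference workflows and stress
  tests. Zero total weight raises an inconsistent-evidence error, the
  same condition class the exact engines use for zero-probability
  evidence.

`predict_risk()` leaves the cohort node unevidenced by default: the
context node describes where a record was collected, not patient
biology, and a new patient belongs to neither cohort. Whether 5-year
vital status should be evidence at prediction time is genuinely open
(death competes with CVD); the default marginalizes it, and
`pipeline_evaluate(evidence_death = TRUE)` conditions on it instead.
The default classification threshold is the model's marginal outcome
prevalence — the standard operating point under heavy class imbalance,
where a 0.5 threshold would classify everyone as not-at-risk.

## Evaluation under class imbalance

With a ~2% outcome, accuracy and TNR are dominated by the majority
class. `classification_metrics()` therefore reports balanced accuracy
$(\mathrm{TPR}+\mathrm{TNR})/2$ and the Matthews correlation
coefficient alongside the usual proportions, with normal-approximation
95% intervals $p \pm z\sqrt{p(1-p)/n}$ on each proportion. Metrics with
an empty denominator are reported as explicitly undefined (`NA`), never
coerced to 0, because rare-event confusion tables routinely have empty
cells; MCC is set to 0 when one of its marginal factors vanishes. AUC
is the midrank Mann-Whitney statistic; an AUC confidence interval is
deliberately out of scope (proportion CIs only — a documented
limitation). `lift_curve()` ranks patients by predicted risk (stable
ties by default, pooled-tie averaging by flag) and
`gain_at_fraction()` reads the cumulative gain at a screening budget,
e.g. the fraction of true cases captured among the top 25% of patients
by predicted risk.

## The synthetic two-cohort generator

The study cohorts are not public, so `simulate_cohorts()` reproduces
their *structural* properties — not their covariate joint distribution,
which is unpublished and out of scope:

* default sizes 1036 (PBC) + 339 (CBC), mirroring the study design;
* a rare binary outcome: the outcome is described as rare but no rate
  is printed, so the default 2% marginal prevalence is a documented
  stand-in (configurable);
* exact block missingness: PBC records lose the tumour prognostic
  factors except age; CBC records lose the whole CVD follow-up block
  (`default_cohort_mask()`); pre-mask truth is retained for recovery
  testing;
* the clinic cohort never reaches the validation set
  (`train_validation_split()` holds out PBC records only).

CPTs are seeded-random with structure: treatment nodes escalate with
the number of adverse prognostic features (logit shift
$0.4\,s$ per feature, with `effect_strength` $s$); cardiotoxicity and
ischemic heart disease are logistic in a weighted count of cardiotoxic
exposures (weights drawn once per parent in $[0.6, 1.4]$, shift
$0.8\,s$ per weighted exposure); the CVD target is a leaky noisy-OR of
its two toxicity parents; remaining nodes get Dirichlet baselines with
seeded logit perturbations scaled by $s$. Setting $s=0$ severs every
parent-child dependence, which the tests exploit as a degenerate case.

A single shared baseline parameter is calibrated by bisection (cap 50
iterations) so that the exact marginal $P(\texttt{cvds}=\text{Yes})$,
computed by variable elimination, hits the target prevalence; forward
sampling serves as the independent check. Exact calibration was chosen
over a forward-sampling search because it is deterministic and removes
Monte-Carlo noise from the generator contract.

The default `effect_strength = 3` encodes *strong* treatment-toxicity
effects (odds ratio $\approx e^{2.4} \approx 11$ per unit weighted
exposure). The value was fixed by requiring the *generating* model
itself to discriminate well: at $s=3$ the true model's held-out AUC is
about 0.85 under the default design, i.e. the synthetic condition
genuinely is a strong-signal regime; much larger values make the 2%
prevalence unattainable for some seeds (the exposure ladder saturates
the calibration floor).

What passing tests on these cohorts shows — and what it does not: the
pipeline recovers structure and parameters it generated under the
stated missingness design, and its evaluation stack is exact. It says
nothing about the covariate distribution, treatment-guideline
correlations, or measurement error of any real registry.

## Problem sizes used in the test suite

Module tests run on the 10-variable reduced network
(`reduced_dictionary()`), where enumeration oracles are feasible;
learning checks use 5,000-record cohorts (3,600 + 1,400) and 20-seed
replications; the end-to-end check runs the full 25-variable model at
the default 1,036 + 339 design over 10 seeds with held-out evaluation
on 413 population-cohort patients, matching the study's split
(339 CBC + 623 PBC train / 413 PBC validation).

## Known limitations

* Inference is exact-by-elimination; no junction-tree engine, no
  most-probable-explanation over multiple variables.
* Structure search is score-based only (no PC/FCI-style
  constraint-based discovery) and does not model latent confounders.
* Continuous or conditional-Gaussian nodes are unsupported; every
  variable is discrete with a fixed printed state set.
* The AUC is reported without a confidence interval.
* The generator emulates missingness structure and effect direction,
  not real-world covariate distributions; absolute metric values on
  synthetic cohorts are not estimates of any clinical quantity.
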