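---
title: "Conditional-Gaussian network analysis of drug response: models and design"
author: "lipidBN"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conditional-Gaussian network analysis of drug response: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidBN)
```

# The problem

Association scans relate one marker at a time to a trait; they say
nothing about which of several correlated variables acts on which.
Bayesian networks offer an exploratory middle ground: a directed acyclic
graph (DAG) over all measured variables whose structure encodes
conditional dependencies, fitted by score-based search, with bootstrap
model averaging quantifying how confident the data are about each edge
and its orientation. `lipidBN` implements this workflow for cohorts that
mix SNP genotypes, CpG methylation beta-values, covariates and blood
triglyceride (TG) measurements taken before and after treatment with a
lipid-lowering drug, together with the regression scans (EWAS/GWAS) that
usually precede the network stage and a synthetic-cohort generator with
a known causal truth for calibration.

# The network model

## Conditional-Gaussian score

Nodes are typed: continuous (TG levels, age, methylation, optionally
dosage) or discrete (sex, center, genotype as a three-level factor).
The joint model is conditional-Gaussian (CG): discrete nodes may not
have continuous parents, discrete children given their discrete parents
are multinomial, and a continuous child given its parents follows a
separate Gaussian linear regression on its continuous parents within
each configuration of its discrete parents.

The network score is the BIC on the convention

$$\mathrm{score} = \log \hat L - \tfrac{k}{2}\,\log n,$$

higher being better, which decomposes into per-node local scores. For a
continuous child, `k` counts an intercept, one slope per continuous
parent and a variance for every configuration in the full cross-product
of the discrete parents' levels; the likelihood is evaluated at the
maximum-likelihood (not df-corrected) variance, which is what makes
Markov-equivalent all-continuous structures score identically (a
property the test suite checks to `1e-8`). For a discrete child, `k` is
`(levels - 1)` per parent configuration.

Degenerate cells — a parent configuration observed fewer than twice, or
with zero residual variance — cannot support a variance estimate. They
contribute zero log-likelihood, keep their parameter count, and raise a
classed warning (`lipidBN_degenerateConfig`); the search muffles the
warning because probing such parent sets is routine and the untouched
penalty already disfavours them. No prior smoothing is applied.
Missing data are handled complete-case per local score.

## Constraints

Three rule types restrict the search space ([bnConstraints()]):
whitelist edges (always present, fixed direction), blacklist edges
(never present) and no-parent nodes. The drug-response scheme
([gaw20Constraints()]) encodes the temporal logic of a two-visit trial:
the pre-treatment level TG2 is forced to be a parent of the
post-treatment level TG4 (so the TG4 regression on TG2 models the
*change* in TG), SNPs and the categorical covariates have no parents,
and post-treatment methylation cannot be a parent of pre-treatment TG.

## Search

`hillClimb()` starts from the whitelist-only graph and greedily applies
the best strictly score-improving single-edge move (add, delete,
reverse) that keeps the graph acyclic, CG-consistent and
constraint-consistent. Moves tied within `1e-9` are broken uniformly at
random: without randomised tie-breaking, score-equivalent orientations
would be resolved by enumeration order and bootstrap direction
probabilities would collapse to 0 or 1 instead of hovering near 0.5
where the data are genuinely uninformative about direction. After a
local optimum, each of `restarts` (default 10) random restarts perturbs
the optimum by `perturb` (default twice the node count) random valid
additions/deletions and re-climbs; the best network seen is returned.
`exhaustiveBest()` provides the exact optimum for up to five nodes by
enumerating the three states of every node pair and filtering invalid
graphs; the suite requires hill climbing to match it on at least 95 of
100 random four-node problems.

## Bootstrap averaging

`bootstrapNetworks()` refits the search on `B` (conventionally 1000)
resamples of individuals; `edgeStatistics()` turns the fitted DAGs into
per-pair *strength* (presence in either direction) and per-orientation
*direction* probability (conditional on presence, so the two
orientations sum to 1). Pairs never seen are reported missing rather
than direction 0.5. A whitelisted edge necessarily has strength 1 and
direction 1. Replicates reuse the restart schedule but default to a
single restart — inside the bootstrap the start graph is already the
constraint core and variability across resamples dominates; the full
schedule is available via the `restarts` argument.

`strengthThreshold()` estimates a significance cutoff as the value
whose induced two-level CDF (noise edges at 0, significant edges at 1)
is L1-closest to the empirical CDF of the observed strengths, by brute
force over the observed strengths plus 0. The candidate 0 is needed so
that, under the strict-greater retention convention, a unanimous set of
strength-1 edges is retained in full; ties take the smallest candidate.
`filterAverage()` retains pairs with strength *strictly greater* than
the cutoff — an edge whose strength equals the cutoff is dropped, the
behaviour documented for the published 0.441 example, where the
weakest of five SNP-to-TG-change edges (strength exactly 0.441) leaves
the plot.

# Regression stages

`runEWAS()` regresses log TG (TGs are approximately log-normal) on each
CpG with age, sex, center and the leading principal components of the
CpG matrix (default 4) as covariates; PCs absorb shared technical and
biological structure such as batch effects or a per-individual
methylation propensity. PCs are recomputed from the CpG matrix entering
each scan. With `changeModel = TRUE` the outcome is log TG4 and log TG2
joins the covariates; conditioning on the baseline makes the marker
coefficient a test of association with the change in log TG. The
baseline enters on the log scale — the generator's data-generating model
is additive in log TG, and a raw-scale baseline would test change only
approximately. `runGWASChange()` does the same per SNP dosage (MAF
strictly above 0.01, monomorphic markers skipped with a warning),
without methylation PCs. Both report the genomic-control inflation
factor (median implied 1-df chi-square over 0.4549) and the Bonferroni
threshold `alpha/m`, with significance declared by strict less-than.
Relatedness is deliberately not modelled: the scans are ordinary least
squares and the simulator emits unrelated individuals; mixed-model
corrections are out of scope.

# The synthetic cohort generator

`simulateCohort()` emulates a two-visit lipid-lowering drug trial with
genotype-by-methylation response modification:

* **Genotypes** — Hardy–Weinberg dosages at configurable MAF; the five
  default causal SNPs use MAF 0.3, a common-variant regime that keeps
  effect-size calibration stable at moderate n.
* **Methylation** — beta-values `plogis(mu_j + a_i + e_ij)` with
  per-CpG baselines `mu_j ~ U(-2, 2)`, unit site noise and a shared
  per-individual propensity `a_i ~ N(0, 1)` by default, reproducing the
  observation that individuals tend to be globally hyper- or
  hypo-methylated; propensity 0 gives independent CpGs.
* **TG** — `log TG2 ~ N(log 110, 0.5^2)` (a typical adult TG of ~110
  mg/dL with geometric SD ~1.65), and

  $$\log TG4 = \log TG2 + \delta + \textstyle\sum_k \beta_k G_k
  m(M_k) + \gamma'z + \varepsilon,\qquad
  \varepsilon \sim N(0, 0.25^2),$$

  with mean drug effect `delta = -0.2` (a TG-lowering drug) and
  covariate effects `gamma` defaulting to 0 (the covariates exist so
  the network has discrete nodes; their effect sizes are user-set).
* **Modification** — `m(M) = M` (`proportional`, default: the SNP acts
  only when its paired CpG is methylated), `1 - M` (`complement`), or
  `m = 1` (`none`: no epigenetic modification). Under `none` the model
  is purely additive, and per-allele effects are calibrated as
  `beta = sqrt(h2 * totalVar / (2 maf (1 - maf)))` against
  `totalVar`, the response variance implied by the configuration in
  that regime, `totalVar = (residualSd^2 + var(covariate terms)) /
  (1 - sum h2)` — with the defaults, 0.1. Each SNP then explains
  exactly its configured heritability of the log-TG change, which the
  acceptance suite verifies at n = 1e5 within three Monte-Carlo
  standard errors for all five default values (0.125, 0.075, 0.100,
  0.025, 0.050). Under `proportional`/`complement` the same `beta_k`
  is attenuated by the methylation factor, so realized marginal
  heritabilities fall below nominal — that is the point of the design:
  main-effect scans lose power when the effect acts through an
  interaction.

The truth record (`SimTruth`) stores realized betas, nominal h2, the
causal edge list (including TG2 to TG4 and, under modification, CpG to
TG4) and all generator parameters, so parameter-recovery tests never
reverse-engineer the generator. The cohort defaults to n = 680
individuals, the order of magnitude of a methylation-subsample of a
family lipid study once reduced to unrelated individuals.

What the generator does **not** emulate: pedigree/family structure
(individuals are exchangeable), linkage disequilibrium between SNPs,
epigenome-scale CpG counts, genomic position, cell-type composition, or
visit-to-visit methylation dynamics (one CpG matrix stands for the
post-treatment measurement). Tests passing on these cohorts therefore
show correctness of the machinery and calibration under the stated
model, not robustness to relatedness, LD or cellular heterogeneity.

# Numerical and design choices

* BIC convention `logLik - (k/2) log n`; ML variance estimates;
  parameter counts over the full discrete-parent cross-product so that
  unobserved cells still cost parameters.
* Tie tolerance `1e-9` on score deltas; strictly-improving moves only,
  which with score equivalence prevents add/reverse cycling.
* Exhaustive enumeration is capped at 5 nodes (59,049 pair-state
  combinations before filtering).
* All randomness flows through R's global RNG: `set.seed()` before a
  search or bootstrap reproduces it exactly, and `simulateCohort()`
  seeds itself from its config for byte-identical output. The
  command-line layer derives fixed per-stage seeds from one top-level
  `--seed` and logs them.
* Problem sizes in the test suite (n = 1e5 for heritability
  calibration, 100 four-node problems for oracle equivalence, B = 200
  bootstrap replicates at n = 500 and 12 nodes for constraint
  soundness, B = 500 at n = 1000 for direction calibration) were
  chosen to keep Monte-Carlo error well inside the asserted tolerances
  while completing in minutes on one core.

# Known limitations

* Hill climbing with restarts is a heuristic; outside the enumerable
  regime optimality is only probabilistic (the oracle-equivalence rate
  is itself one of the tested properties).
* The ECDF/L1 threshold is one defensible estimator of a strength
  cutoff; the command-line layer therefore also accepts a fixed
  user-supplied cutoff.
* No inter-causal queries, parameter estimation beyond scoring, MCMC
  structure sampling or tabu search.
* Scans are OLS: cohorts with family structure need an external
  mixed-model stage before trusting p-values.
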