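---
title: "Ranking and profiling first-line myeloma regimens: the models behind mmnma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking and profiling first-line myeloma regimens: the models behind mmnma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmnma)
```

## The problem

Transplant-ineligible newly diagnosed multiple myeloma (NEMM) is treated
first-line with doublet, triplet or quadruplet regimens built from
proteasome inhibitors, immunomodulatory drugs, steroids, alkylators and
the anti-CD38 antibody daratumumab. Almost none of these regimens have
been compared head to head. Network meta-analysis (NMA) joins the
randomized evidence across a connected network of treatments: where two
regimens were never co-randomized, their relative effect is inferred
through chains of shared comparators under the consistency assumption
$d_{BC} = d_{AC} - d_{AB}$.

`mmnma` implements the full chain for five endpoints — progression-free
survival (PFS) and overall survival (OS) on the hazard-ratio scale,
overall response (ORR) and complete response (CR) on the odds-ratio
scale, and safety (risk of the most frequent grade 3–4 adverse event) on
the risk-ratio scale — followed by SUCRA ranking and an unsupervised
grouping of regimens by their SUCRA profiles.

## Effect measures

Arm-level summaries are converted to log-scale contrasts against each
trial's baseline arm:

* binary endpoints: log OR (efficacy) or log RR (safety) from 2×2
  counts, with variance by the delta method; when a cell is zero, 0.5 is
  added to all four cells first (Gart correction; the constant is a
  parameter),
* survival endpoints: the reported log HR and SE; where a trial reports
  only a log-rank p-value with total events $E$, the Tierney
  reconstruction is used ($V = ER/(1+R)^2$ for allocation ratio $R$,
  $\log HR = z\sqrt{V}/V$, $\mathrm{var} = 1/V$, the sign supplied by the
  caller since a p-value carries none), and where only an HR with a 95%
  CI is given, $SE = (\log hi - \log lo)/(2 \cdot 1.96)$.

## The Bayesian random-effects consistency model

Per endpoint the contrast-level (Lu–Ades) model is fitted:
$y_i \sim N(\delta_i, S_i)$ for each trial's vector of observed
contrasts, $\delta_i \sim N(X_i d, \tau^2 C_i)$ with
$C_i = (I + J)/2$ so contrasts sharing a baseline arm have heterogeneity
correlation 1/2, basic parameters $d$ relative to a reference treatment
(MP by default, the classical melphalan–prednisone comparator), and
vague priors $d \sim N(0, 10^2)$, $\tau \sim U(0, 5)$ — both exposed in
`nma_config()`. Multi-arm trials contribute the baseline arm's variance
share as the off-diagonal of $S_i$ (computable from counts; for
reported HRs it must be supplied, default 0, since a published HR+SE
does not reveal it).

The sampler is Metropolis-within-Gibbs in compiled code: $d$ and
$\delta$ have conjugate normal full conditionals; $\tau$ is updated by a
stepping-out/shrinkage slice sampler on its bounded full conditional,
chosen over a random-walk update because it needs no tuning constant.
Defaults are 4 chains × 30,000 iterations with the first 10,000
discarded; convergence is monitored by split-$\hat R$ with a warning at
1.05. A contrast-level normal likelihood is used rather than an
arm-level binomial one: the survival endpoints only exist as contrasts
(HR + SE), and converting the binary endpoints keeps one likelihood for
all five endpoints. This is an approximation for small trials with few
events.

The model nests classical pairwise meta-analysis: on a single-edge
network the posterior mean of $d$ agrees with the REML random-effects
pooled estimate, which the test suite checks against an independent
implementation.

## Ranking: rankograms, cumulative curves, SUCRA

Each retained draw ranks all treatments (the reference included at 0)
after orienting the scale so rank 1 is best: lower is better for PFS/OS
hazard ratios and for the safety risk ratio — so the safety SUCRA
rewards *safer* regimens — and higher is better for ORR/CR odds ratios.
Exact ties (measure zero) are broken by stable input order for
determinism. Tallying gives the rank-probability matrix, whose rows and
columns each sum to 1; row-wise prefix sums give the cumulative curves,
and $\mathrm{SUCRA}_i$ is the mean of the first $a-1$ cumulative
entries. Consequences used as test invariants: $\sum_i \mathrm{SUCRA}_i
= a/2$, invariance to the reference used for the draws, and
monotonicity under a uniform improvement of one treatment.

The five per-endpoint SUCRAs are averaged unweighted into the ranking
chart; weighting is deliberately left to the user, since any weighting
is a clinical judgement.

## Loop inconsistency and heterogeneity

For every triangular loop whose three edges carry direct evidence, the
Bucher comparison is computed: the inconsistency factor is the absolute
difference between one edge's pooled direct estimate and the indirect
estimate implied by the other two, with variance the sum of the three
variances, a z statistic, and a 95% CI truncated at zero on the
absolute-value scale. Heterogeneity enters through a loop-level
$\tau^2$, estimated by REML on the union of the loop's pairwise
estimates with a common $\tau^2$ and per-comparison means (the
restricted log-likelihood is maximized by bounded 1-D optimization on
$[0, \tau^2_{max}]$), then plugged into the pooling weights
$1/(v_i+\tau^2)$. Only triangles are assessed; quadrilateral loops are
out of scope. Under a consistent simulation truth the 95% CI excludes
zero at the nominal 5% rate, which the acceptance checks verify with
2,000 simulated loops.

## SUCRA-profile clustering

The treatments × endpoints SUCRA matrix is reduced by PCA (via
`prcomp`). Defaults are center and scale on — the five columns share
the $[0,1]$ scale but their variances differ by endpoint, so
correlation PCA keeps one endpoint from dominating; both are flags. PC
signs are fixed by making each component's largest-magnitude loading
positive, so results are deterministic. Clustering runs on the smallest
set of leading PCs explaining ≥ 80% of variance (configurable): the
published analysis clusters in a 2-D plot plane but does not state the
clustering space, and the retained-variance rule adapts to how much
structure the profile actually has.

Grouping uses partitioning around medoids (PAM): BUILD greedily seeds
$k$ medoids, SWAP repeatedly applies the best improving
(medoid, non-medoid) exchange until none reduces the total Euclidean
dissimilarity. PAM is a local search: its objective is non-increasing
and terminates 2-swap stable, but 2-swap-stable configurations that are
not the global medoid-subset optimum exist even for $n \le 8$ — the
reference implementation in the `cluster` package lands on the same
ones — so global optimality is not asserted, only measured. The number
of groups is chosen by maximizing the mean silhouette width over
$k \in 2..6$ by default (singleton clusters contribute 0), with a fixed
`k = 3` override reproducing a three-group structure.

## The synthetic-trial generator

Because no per-trial effect estimates are published, validation rests
on simulation with known truth. `simulate_profiled_network()` builds a
truth with planted regimen groups: group centers spaced by a
`separation` gap on the log scale in the efficacy endpoints (group 1
best), a non-monotone toxicity pattern so profiles differ in more than
one direction, and within-group jitter (SD 0.05 by default) drawn with
exchangeable correlation 0.5 across endpoints. `simulate_trialset()`
then draws trials: a random spanning tree guarantees a connected
network, trial random effects have SD $\tau$ (0.1 by default — a
moderate between-trial heterogeneity on the log scale) with correlation
1/2 between contrasts sharing a baseline, binary endpoints produce
binomial counts from baseline risks (ORR 0.5, CR 0.15, safety 0.3 —
typical of this population), and survival endpoints produce observed
log HRs with variance $4/E$, the equal-allocation log-rank noise,
$E$ set by event fractions 0.7 (PFS) and 0.5 (OS). Defaults of 30
trials with 100–400 patients per arm and 20% three-arm trials mirror
the scale of the real 27-trial network.

What the generator does *not* emulate: publication bias, endpoint
definitions drifting across two decades of trials, non-proportional
hazards, and the fact that the real safety endpoint pools *different*
adverse events across trials. Passing tests therefore show the chain is
correct for data generated under its own assumptions, not that those
assumptions hold in any given literature.

The packaged roster fixture (`table1_fixture()`,
`inst/extdata/table1_synthetic.csv`) reproduces the real 27-trial
structure — study labels, years, arm labels, per-trial totals (split
equally across arms, remainder to the first arm) and most frequent
grade 3–4 adverse event — and fills endpoint summaries synthetically
from a seeded three-group truth, since the published table prints no
effect data. Its structural counts (27 trials, 12,935 patients, 23
regimens after the VTP→VTD merge, 9 triangular loops) are exact; its
effect values are not data.

## Numerical choices and problem sizes

* Continuity correction 0.5 applied to all four cells only when a cell
  is zero.
* REML optimization on $[0, 100]$ with `optimize()` at tolerance 1e-9;
  $\hat\tau^2 = 0$ returned when the boundary beats the interior
  optimum.
* Slice sampler width adapts to the current conditional mode; proposals
  are clamped to $(0, \tau_{max})$.
* Funnel plots center on the fixed-effect pooled estimate; the
  comparison-adjusted variant across the whole network is not
  implemented.
* Tests and the acceptance script run scaled-down MCMC (2 chains,
  2,500–10,000 iterations) and moderate replicate counts (100–200
  recovery replicates, 20 end-to-end seeds, 2,000 simulated loops);
  these sizes give Monte Carlo error well inside every asserted
  tolerance.

## Known limitations

* Contrast-level normal likelihood (no exact binomial arm model).
* The baseline variance share of multi-arm trials reporting only HRs is
  not identifiable from published summaries; the default of 0
  understates within-trial correlation slightly.
* Only triangular loops are assessed for inconsistency; no
  design-by-treatment interaction model and no node splitting.
* No P-scores, median ranks, meta-regression, or consensus clustering.
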