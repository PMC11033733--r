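---
title: "Quantifying deterministic and stochastic gut microbiome assembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying deterministic and stochastic gut microbiome assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(assemblage)
```

## The problem

Early-life gut communities assemble under two kinds of forces. *Deterministic*
processes (selection: host health, diet, habitat filtering) push communities
toward particular compositions; *stochastic* processes (drift, dispersal,
priority effects) make composition a lottery over the regional species pool.
`assemblage` implements the null-model toolkit used to separate the two in
longitudinal cohort designs — here modeled on a veal-calf trial with two
treatment arms (placebo vs a probiotic yeast), healthy and diarrheic
subgroups, and fecal sampling at weeks 1, 2, 3, 6 and 8 — together with a
synthetic cohort generator that plants known assembly regimes so that every
statistic can be validated against ground truth.

## Statistics

**C-score SES.** For taxa $i, j$ with row totals $R_i, R_j$ and $S_{ij}$
joint occurrences in a presence/absence matrix, the checkerboard unit count
is $CU_{ij} = (R_i - S_{ij})(R_j - S_{ij})$ and the C-score is the mean over
all pairs. The standardized effect size is
$\mathrm{SES} = (C_{obs} - \overline{C}_{null}) / \mathrm{SD}(C_{null})$
against a fixed-fixed null (sequential swap, 10 000 matrices by default).
$|\mathrm{SES}| > 2$ flags non-random co-occurrence; the sign distinguishes
segregation (overdispersion) from aggregation.

**Modified Raup–Crick ($\beta_{RC}$).** Each sample pair's observed shared-taxon
count is ranked within its distribution under a richness-preserving,
occupancy-weighted null; $\beta_{RC} = 2 \cdot \mathrm{frac} - 1 \in [-1, 1]$
with ties at half weight. $+1$: deterministically dissimilar; $-1$:
deterministically similar; $\approx 0$: indistinguishable from stochastic
assembly.

**Modified stochasticity ratio (MST).** With observed dissimilarity $D$ and
null expectation $\bar E$, $\mathrm{MST} = D/\bar E$ when $D \le \bar E$ and
$(1-D)/(1-\bar E)$ otherwise. MST is 1 at the null expectation and falls
toward 0 under determinism of either sign; 0.5 is the conventional boundary
between determinism- and stochasticity-dominated strata. This is a
self-contained reformulation honouring that contract; numerical parity with
any particular stochasticity-ratio package (which offer many metric/null
combinations) is deliberately not claimed.

**PERMDISP.** Actual samples are pooled with an equal-sized batch of
null-simulated communities; $\beta_{RC}$ distances over the pool are embedded
by principal coordinates and the two groups' distances to their own spatial
centroid are compared by a permutation F test. $P < .05$ is the stratum-level
determinism call.

**Ecotypes.** Levins breadth $B_j = 1/\sum_i P_{ij}^2$ is compared with its
distribution under 1000 abundance-quasiswap randomizations; above the 97.5th
percentile: generalist, below the 2.5th: specialist, inside: neutralist.

**Networks.** Spearman co-occurrence ($r > 0.6$, $P < .05$, strict, positive
only) on relative abundances; modularity (Louvain, best of 10 seeded
restarts), average degree $2E/N$, mean local clustering; two-sample KS tests
compare degree and clustering distributions across strata; the Integrated
Value of Influence composite (hubness $\times$ spreading over six centrality
components) ranks taxa, of which the top 10% are reported.

**Two-state Markov model.** Per-sample MST is thresholded at 0.5 into
stochastic (1) / deterministic (2) states; per calf, the state sequence over
weeks 1–8 is modeled as a continuous-time Markov chain observed at irregular
times, with covariates acting proportionally on both intensities,
$q_{rs}(x) = q_{rs,0} e^{\beta_{rs} x}$. Forward = stochastic→deterministic.
Hazard ratios are $e^{\beta}$ with Wald 95% intervals from the inverse
observed information.

## The occupancy pool: local vs regional

The single most consequential design choice in the package. The
occupancy-weighted null can draw from the *stratum-local* pool (taxa weighted
by their occupancy within the group × week being analyzed) or from the
*regional* pool (occupancy over the whole cohort). Both are exposed via the
`pool_occupancy` argument of `beta_rc()`, `mst()`, `permdisp_vs_null()` and
`simulate_null_communities()`.

The pipeline default is the regional pool, and the stratum matrices keep
their all-zero taxon rows so the pool is not truncated. The reason is
structural, not cosmetic: samples that are independent draws from one shared
(filtered) distribution are *distributionally identical* to their own
stratum-local null, so no local-pool statistic can see the filtering. What
habitat filtering actually does is restrict a community to a narrow slice of
the regional pool — and only a regional reference exposes that. In our
calibration experiments, filtered strata sat at mean MST ≈ 0.57 (local pool)
versus ≈ 0.33 (regional pool, filter strength 10), while neutral strata
stayed near 0.67 under both. SES keeps stratum-local matrices (all-zero rows
dropped) since its null randomizes the within-stratum co-occurrence
structure itself.

## PERMDISP calibration and the self-conditioned null

The occupancy-weighted draw is not *occupancy-stationary*: resimulating from
a simulated matrix's own occupancy yields systematically flatter occupancy
and more dispersed communities. Consequently the everyday construction —
null batch simulated from the observed matrix — is mildly anti-conservative,
and increasingly so with stratum size. `permdisp_vs_null()` therefore takes a
`null_from` argument: in calibration studies where the generating base
matrix is known, passing it makes the two groups exchangeable (measured
type-I error 4.75% at $\alpha = .05$ over 400 runs). Applied analyses, where
only the observed matrix exists, use the default and should read borderline
P-values with that caveat.

A stronger version of the same phenomenon concerns deeply sequenced neutral
communities. An iid multinomial draw from a fixed metacommunity is *not* the
same stochastic process as the occupancy-weighted fixed-richness draw: near
presence saturation the null compresses the inclusion probability of
always-present taxa and therefore disperses more than the data do, so the
self-conditioned PERMDISP flags even neutral strata as "deterministic" most
of the time on synthetic cohorts at depth 5000. Interpret the pipeline's
PERMDISP column as "the data deviate from this particular null", and prefer
the MST-based stratum call (group mean above/below 0.5, which is calibrated
for both regimes) when an automatic stochastic/deterministic label is
needed — the assembly-state panel feeding the Markov model is built from
per-sample MST for exactly this reason.

## The synthetic cohort: what it emulates, and what it does not

`cohort_config()` defaults state the emulated world: 84 calves (42 per arm;
placebo split 14 healthy / 28 unhealthy, probiotic 21 / 21), weeks
1, 2, 3, 6, 8, ~21 of 420 samples lost to attrition (independent dropout),
120 genus-like taxa from a lognormal metacommunity (meanlog 0, sdlog 1.5 — a
realistically steep rank-abundance curve), 5000 reads per sample. Stochastic
samples are multinomial draws from the pool; deterministic samples reweight
the pool by a Gaussian fitness kernel
$e^{-s\,(\mathrm{optimum} - \mathrm{environment})^2}$ (shared environment ⇒
convergence; opposed environments ⇒ divergence). Latent assembly states
evolve per calf by the two-state CTMC ($q_{12} = 0.3$, $q_{21} = 0.2$ per
week, week-1 state stochastic with probability 0.9) with poor health
multiplying the forward intensity by $e^{\beta}$, $\beta = \log 1.34$ — the
effect size the emulated study design motivates.

Two strength conventions are used deliberately: the generator default
`filter_strength = 5` is sufficient for the PERMDISP determinism call
(measured power 1.0 at 20 samples/stratum), while the "strongly filtered"
condition used for MST calibration is strength 10, because the Jaccard-MST
contrast needs the filtered community to occupy a distinctly narrower slice
of the regional pool (at strength 5 filtered strata average MST ≈ 0.53; at
10, ≈ 0.33).

What the generator does **not** emulate: compositional sequencing artefacts,
overdispersion beyond multinomial, phylogenetic structure among taxa,
mortality-linked (non-random) attrition, or time-varying health status. A
green calibration test therefore establishes that the statistics behave as
designed under their own model of the world — not that they are robust to
every failure mode of real amplicon data.

## Numerical choices

- Presence threshold: count ≥ 1; no prevalence filter by default.
- Shannon uses natural log; Chao1 is the bias-corrected form.
- Sequential swap: burn-in $10 \times$ fill, thin = fill (standard mixing
  heuristic). Matrices without any 2×2 checkerboard yield a degenerate
  ensemble of identical copies with a warning, and SES propagates NaN
  rather than erroring so grouped pipelines survive degenerate strata.
- $\beta_{RC}$ ties at half weight; 999 replicates by default.
- MST pairs with $\bar E \in \{0, 1\}$ are masked. Per-observation states:
  MST exactly 0.5 is called stochastic (strict `<` for deterministic).
- $\beta_{RC} \in [-1,1]$ is rescaled to $[0,1]$ before embedding; negative
  squared distances from imaginary principal-coordinate axes are truncated
  to zero (the classical correction).
- Network edge P-values use the large-sample t approximation; no multiplicity
  correction by default (raw $P < .05$), matching field practice for these
  exploratory graphs.
- IVI components are min–max scaled to [1, 100]; an all-equal component or
  composite maps every node to the scale's floor (or, for the final score,
  to 1), so complete graphs score all nodes 1.
- Markov likelihood is maximized by BFGS on log-intensities (positivity by
  construction) from crude count-based initial values; zero transitions in a
  direction pin that intensity near the boundary with a warning rather than
  failing.
- Every stage seed is derived by a stable polynomial hash of
  (global seed, stage, stratum), so serial and re-entrant runs agree.

## Known limitations

- The MST implementation targets the stated contract (range, boundary,
  direction), not numerical parity with any released stochasticity-ratio
  package; published MST ranges are not comparable numbers.
- The per-observation assembly state is an operationalization (per-sample
  MST at 0.5); group-level determinism calls cannot drive a per-calf panel,
  and other bridges (e.g. $\beta_{RC}$-based states) can be swapped in via
  `assign_states()`.
- Ecotype nulls require count tables with genuine zeros; saturated tables
  have no shuffleable incidence structure and raise an informative error.
- The quasiswap family samples the fixed-fixed space approximately
  uniformly; exact uniformity is not guaranteed for pathological marginals.
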