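# assemblage

Null-model analysis of gut microbial community assembly in longitudinal
cohorts.

## What problem this solves, and for whom

Microbiome researchers studying early-life gut colonization — here modeled
on neonatal calves sampled at weeks 1, 2, 3, 6 and 8 across two treatment
arms (placebo vs probiotic yeast) and two health groups (healthy vs
diarrheic) — need to say *how* communities assemble, not just what they
contain: is composition driven by deterministic selection (host health,
diet, habitat filtering) or by stochastic drift and dispersal? `assemblage`
packages the null-model toolkit for that question, end to end:

- **C-score SES** — standardized effect size of the checkerboard score
  against fixed-fixed (sequential-swap) null matrices:
  `SES = (C_obs − mean C_null) / sd C_null`, with |SES| > 2 flagging
  non-random co-occurrence.
- **Modified Raup–Crick (βRC)** — per sample pair, observed shared-taxon
  count ranked within a richness-preserving, occupancy-weighted null;
  βRC ∈ [−1, 1], with −1/+1 = deterministically similar/dissimilar and 0 =
  indistinguishable from stochastic assembly.
- **Modified stochasticity ratio (MST)** — MST = D/Ē for D ≤ Ē else
  (1−D)/(1−Ē); 1 at the null expectation, below 0.5 read as
  determinism-dominated.
- **PERMDISP** — permutation test of dispersion (distance to group centroid
  in a principal-coordinate embedding of βRC) of actual vs null-simulated
  communities: the stratum-level determinism call.
- **Ecotypes** — Levins niche breadth `B = 1/Σp²` against 1000
  abundance-quasiswap nulls: generalist / specialist / neutralist by the
  95% null interval.
- **Co-occurrence networks** — Spearman r > 0.6, P < .05 edges; modularity,
  average degree, clustering; KS comparisons across ages; Integrated Value
  of Influence (IVI ∈ [0, 1]) with the top 10% reported as influential taxa.
- **Two-state Markov model** — per-calf stochastic/deterministic state
  sequences as a continuous-time Markov chain observed at irregular weeks,
  covariates acting proportionally on the intensities; hazard ratios
  (forward = stochastic→deterministic) with Wald 95% CIs.
- **Synthetic cohorts** — a generator that plants known assembly regimes,
  ecotypes and Markov dynamics (84 calves, 42 per arm, subgroups 14/28 and
  21/21, ~21 of 420 samples lost to attrition), so every statistic is
  validated against ground truth.

See `vignettes/assembly-methods.Rmd` for the models, assumptions, and the
design choices (notably the regional-vs-local occupancy pool and PERMDISP
calibration).

## Worked example

Simulate a half-size cohort and run the full pipeline per health × week
stratum:

```r
library(assemblage)

cfg <- cohort_config(n_calves_per_arm = 21L, n_healthy_con = 7L,
                     n_healthy_scb = 10L, seed = 42)
sim <- simulate_cohort(cfg)
sim$table
#> feature_table: 190 samples x 120 taxa (total count 950000)

res <- run_pipeline(sim$table, sim$metadata, "out/",
                    group_by = c("health", "week"),
                    n_sim_ses = 500L, n_reps_rc = 199L, n_reps_mst = 199L,
                    n_reps_ecotypes = 500L, n_perm = 199L, seed = 7L)

res$ses[, c("stratum", "n_samples", "c_obs", "ses", "classification")]
#>  stratum n_samples c_obs  ses classification
#>      H.1        15 0.341 8.33  overdispersed
#>      H.2        17 0.504 9.77  overdispersed
#>     ...
#>     UH.6        24 1.577 4.53  overdispersed
#>     UH.8        22 1.561 4.69  overdispersed

aggregate(mst ~ stratum, res$mst, mean)
#>  stratum   mst
#>      H.1 0.622
#>      H.3 0.721
#>     UH.6 0.665   # etc.
```

Reading the output: every stratum's SES exceeds 2 because each stratum mixes
calves in latent stochastic and deterministic states *and* contains the
planted generalist/specialist taxa — genuine non-random co-occurrence
structure. Stratum-mean MST stays above 0.5 (stochasticity-dominated on
average) because deterministic-state samples are diluted by their
neutral-state partners; per-sample values, written to `mst.tsv`, feed the
assembly-state panel.

The Markov layer, on a panel with a planted forward hazard of 1.34 for the
covariate (e.g. diarrhea making the stochastic→deterministic transition more
likely):

```r
panel <- simulate_panel(800, times = c(1, 2, 3, 6, 8), q12 = 0.3, q21 = 0.2,
                        beta12 = log(1.34), beta21 = 0, seed = 1)
fit <- fit_two_state(panel, covariates = "x")
fit
#> two-state Markov fit: q12=0.2914 q21=0.1988 /week, loglik=-1786.53
#>   transition covariate       hr     ci_lo    ci_hi
#> 1    forward         x 1.418755 1.1536293 1.744813
#> 2   backward         x 1.025642 0.8142192 1.291965
```

The baseline intensities (true 0.3 and 0.2/week) and the forward hazard
ratio (true 1.34, estimated 1.42 with CI 1.15–1.74; mean over 10 replicate
panels 1.35) are recovered; the backward ratio correctly spans 1.

## Command line

```sh
Rscript inst/cli/assemblage.R simulate --seed 42 --out data/
Rscript inst/cli/assemblage.R run --table data/feature_table.tsv \
    --metadata data/metadata.tsv --group-by treatment,health,week \
    --seed 17 --out results/
```

Subcommands: `simulate`, `ses`, `rc`, `mst`, `permdisp`, `ecotypes`,
`network`, `markov`, `run`.

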