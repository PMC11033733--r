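test_that("metacommunity is normalized, decreasing and seed-stable", {
  pool <- simulate_metacommunity(50, seed = 3)
  expect_equal(sum(pool), 1, tolerance = 1e-12)
  expect_true(all(diff(pool) <= 0))
  expect_identical(pool, simulate_metacommunity(50, seed = 3))
  expect_error(simulate_metacommunity(5), ">= 10")
})

test_that("neutral and filtered samples honour depth and the zero limit", {
  pool <- simulate_metacommunity(60, seed = 4)
  s <- simulate_neutral_sample(pool, 1234, seed = 1)
  expect_equal(sum(s), 1234)
  optima <- seq(-1, 1, length.out = 60)
  f <- simulate_filtered_sample(pool, 0, optima, 5, 1234, seed = 1)
  expect_equal(sum(f), 1234)
  # strength 0 reduces exactly to the neutral draw (same RNG stream)
  f0 <- simulate_filtered_sample(pool, 0, optima, 0, 1234, seed = 9)
  n0 <- simulate_neutral_sample(pool, 1234, seed = 9)
  expect_identical(f0, n0)
  expect_warning(simulate_filtered_sample(pool, 5, optima, 200, 100, seed = 1),
                 "fewer than 5")
})

test_that("filtering shifts sampling toward taxa near the optimum", {
  pool <- simulate_metacommunity(60, seed = 5)
  optima <- seq(-1, 1, length.out = 60)
  set.seed(5)
  f <- simulate_filtered_sample(pool, -1, optima, 8, 20000)
  n <- simulate_neutral_sample(pool, 20000)
  near <- optima < -0.5
  expect_gt(sum(f[near]) / sum(f), sum(n[near]) / sum(n))
})

test_that("divergent environments push beta_rc up, convergent down", {
  pool <- simulate_metacommunity(100, seed = 6)
  set.seed(6)
  optima <- runif(100, -1, 1)
  conv <- t(sapply(1:8, function(i)
    simulate_filtered_sample(pool, 0, optima, 6, 4000)))
  div <- t(sapply(1:8, function(i)
    simulate_filtered_sample(pool, c(-1, 1)[1 + i %% 2], optima, 6, 4000)))
  neut <- t(sapply(1:8, function(i) simulate_neutral_sample(pool, 4000)))
  occ <- colSums(rbind(conv, div, neut) > 0)
  rc_c <- beta_rc(t((conv > 0) * 1), n_reps = 199, seed = 2,
                  pool_occupancy = occ)
  rc_d <- beta_rc(t((div > 0) * 1), n_reps = 199, seed = 2,
                  pool_occupancy = occ)
  # divergent pairs with opposite environments share fewer taxa than null
  opp <- outer(1:8, 1:8, function(i, j) (i %% 2) != (j %% 2))
  expect_gt(mean(rc_d$values[upper.tri(rc_d$values) & opp]), 0.5)
  expect_lt(mean(rc_c$values[upper.tri(rc_c$values)]),
            mean(rc_d$values[upper.tri(rc_d$values) & opp]))
})

test_that("plant_ecotypes plants verifiable breadth and errors on excess", {
  tab <- neutral_table(20, 30, 2000, seed = 7)
  planted <- plant_ecotypes(feature_table(tab), 4, 4, seed = 1)
  expect_identical(nrow(planted$truth), 8L)
  b <- niche_breadth(planted$table)
  gen <- planted$truth$taxon_id[planted$truth$label == "generalist"]
  expect_true(all(b[gen] > 0.9 * 20))
  expect_error(plant_ecotypes(feature_table(tab), 20, 20), "exceeds")
})

test_that("simulate_cohort reproduces the trial design", {
  cfg <- cohort_config(seed = 11)
  sim <- simulate_cohort(cfg)
  md <- sim$metadata
  # 84 calves in two arms of 42; subgroup sizes 14/28 and 21/21
  calves <- unique(md[, c("calf_id", "treatment", "health")])
  expect_identical(nrow(calves), 84L)
  tb <- table(calves$treatment, calves$health)
  expect_identical(unname(tb["CON", "H"]), 14L)
  expect_identical(unname(tb["CON", "UH"]), 28L)
  expect_identical(unname(tb["SCB", "H"]), 21L)
  expect_identical(unname(tb["SCB", "UH"]), 21L)
  # attrition: <= 420 scheduled, about 21 lost in expectation
  expect_lte(nrow(md), 420L)
  expect_gt(nrow(md), 370L)
  expect_identical(rownames(sim$table$counts), md$sample_id)
  # truth bundle is coherent
  expect_identical(dim(sim$truth$states), c(84L, 5L))
  expect_identical(nrow(sim$truth$regimes), nrow(md))
  expect_identical(nrow(sim$truth$ecotypes), 10L)
  # pure function of the seed
  sim2 <- simulate_cohort(cohort_config(seed = 11))
  expect_identical(sim$table$counts, sim2$table$counts)
  expect_identical(sim$metadata, sim2$metadata)
})

test_that("latent states follow the configured Markov dynamics", {
  # with a strong health effect, unhealthy calves spend more time
  # deterministic
  cfg <- cohort_config(n_taxa = 20, depth = 200, beta_health = log(3),
                       n_generalists = 0, n_specialists = 0, seed = 12)
  sim <- simulate_cohort(cfg)
  calves <- unique(sim$metadata[, c("calf_id", "health")])
  det_frac <- rowMeans(sim$truth$states == 2L)
  uh <- calves$calf_id[calves$health == "UH"]
  h <- calves$calf_id[calves$health == "H"]
  expect_gt(mean(det_frac[uh]), mean(det_frac[h]))
})
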