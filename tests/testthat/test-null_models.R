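test_that("c_score matches hand-enumerated pairs", {
  expect_equal(c_score(matrix(c(1, 0, 0, 1), 2, 2)), 1.0)
  expect_equal(c_score(matrix(1, 2, 2)), 0.0)
  # [[1,1,0],[0,1,1]]: R=(2,2), S=1 -> (2-1)(2-1) = 1
  expect_equal(c_score(matrix(c(1, 0, 1, 1, 0, 1), 2, 3)), 1.0)
  expect_error(c_score(matrix(1, 1, 3)), "2 taxa")
})

test_that("c_score equals the brute-force oracle on random matrices", {
  set.seed(42)
  for (i in 1:300) {
    m <- random_binary(sample(2:5, 1), sample(2:5, 1),
                       density = runif(1, .2, .8))
    expect_identical(c_score(m), c_score_oracle(m))
  }
})

test_that("randomizations preserve marginals exactly", {
  set.seed(9)
  for (i in 1:5) {
    m <- random_binary(sample(5:12, 1), sample(5:12, 1))
    for (ens in list(sequential_swap(m, n_sim = 30, seed = i),
                     quasiswap(m, n_sim = 30, seed = i))) {
      ok <- vapply(seq_len(ens$n_sim), function(k) {
        s <- ens$matrices[, , k]
        all(rowSums(s) == rowSums(m)) && all(colSums(s) == colSums(m)) &&
          all(s %in% c(0, 1))
      }, logical(1))
      expect_true(all(ok))
    }
  }
})

test_that("sequential swap on a 2x2 checkerboard only visits its two states", {
  m <- matrix(c(1, 0, 0, 1), 2, 2)
  ens <- sequential_swap(m, n_sim = 50, burn_in = 10, thin = 1, seed = 4)
  states <- apply(ens$matrices, 3, paste, collapse = "")
  expect_true(all(states %in% c("1001", "0110")))
  expect_length(unique(states), 2L)  # the chain mixes between both
})

test_that("randomizations are reproducible by seed", {
  m <- random_binary(6, 8)
  expect_identical(sequential_swap(m, 10, seed = 11)$matrices,
                   sequential_swap(m, 10, seed = 11)$matrices)
  expect_identical(quasiswap(m, 10, seed = 11)$matrices,
                   quasiswap(m, 10, seed = 11)$matrices)
  cm <- matrix(rpois(48, 2), 6, 8)
  expect_identical(quasiswap_count(cm, 5, seed = 3)$matrices,
                   quasiswap_count(cm, 5, seed = 3)$matrices)
})

test_that("quasiswap samples attainable configurations near-uniformly", {
  # with row sums (1,1,2) and col sums (1,1,2) the fixed-fixed space
  # restricted to matrices distinct from each other is enumerable; check the
  # two configurations that differ in the placement of the two singleton 1s
  m <- matrix(c(1, 0, 0,
                0, 1, 0,
                0, 0, 1), 3, 3, byrow = TRUE)
  ens <- quasiswap(m, n_sim = 2000, seed = 8)
  keys <- apply(ens$matrices, 3, paste, collapse = "")
  tab <- table(keys)
  # all permutation matrices of size 3 are attainable (6 of them)
  expect_length(tab, 6L)
  expect_gt(suppressWarnings(chisq.test(tab)$p.value), 0.01)
})

test_that("ses computes the standardized effect size and classifies", {
  set.seed(10)
  m <- random_binary(12, 10)
  ens <- sequential_swap(m, n_sim = 300, seed = 2)
  r <- ses(m, ens)
  cs <- vapply(1:300, function(i) c_score(ens$matrices[, , i]), numeric(1))
  expect_equal(r$ses, (c_score(m) - mean(cs)) / sd(cs), tolerance = 1e-12)
  expect_true(r$classification %in%
                c("overdispersed", "underdispersed", "indeterminate"))

  # perfect checkerboard is strongly segregated
  cb <- (outer(1:10, 1:10, "+") %% 2)
  ens_cb <- sequential_swap(cb, n_sim = 300, seed = 5)
  r_cb <- ses(cb, ens_cb)
  expect_gt(r_cb$ses, 2)
  expect_identical(r_cb$classification, "overdispersed")

  # degenerate matrix: NaN SES, no error
  ones <- matrix(1, 4, 4)
  expect_warning(ens1 <- sequential_swap(ones, n_sim = 20, seed = 1),
                 "degenerate")
  r1 <- ses(ones, ens1)
  expect_true(is.nan(r1$ses))
  expect_identical(r1$classification, "undefined")
})

test_that("SES is invariant to simultaneous row/column permutation", {
  set.seed(21)
  m <- random_binary(8, 9)
  p <- m[sample(nrow(m)), sample(ncol(m))]
  r1 <- ses(m, sequential_swap(m, n_sim = 400, seed = 6))
  r2 <- ses(p, sequential_swap(p, n_sim = 400, seed = 6))
  expect_equal(r1$c_obs, r2$c_obs, tolerance = 1e-12)
  # null distribution identical up to Monte Carlo noise
  expect_equal(r1$ses, r2$ses, tolerance = 0.35)
})
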