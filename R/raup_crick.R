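# One occupancy-weighted, richness-preserving null draw of the whole
# community matrix: each sample is replaced by a random set of taxa of the
# same richness, drawn without replacement with probability proportional to
# taxon occupancy across the matrix. Uses the session RNG.
occ_weights <- function(m, pool_occupancy) {
  if (is.null(pool_occupancy)) return(rowSums(m))
  stopifnot(length(pool_occupancy) == nrow(m), all(pool_occupancy >= 0))
  w <- as.numeric(pool_occupancy)
  # taxa present in m must be drawable even if absent from the wider pool
  w[w == 0 & rowSums(m) > 0] <- min(w[w > 0])
  w
}

null_draw <- function(n_taxa, richness, occ_prob) {
  z <- matrix(0, n_taxa, length(richness))
  for (s in seq_along(richness)) {
    k <- richness[s]
    if (k > 0) z[sample.int(n_taxa, k, prob = occ_prob), s] <- 1
  }
  z
}

#' Occupancy-weighted null community simulation
#'
#' Generates stochastic-assembly reference communities: every sample of the
#' input is replaced by a random draw of equal richness from the taxon pool,
#' with per-taxon inclusion probability proportional to its occupancy
#' (number of samples occupied) in the input matrix. This is the shared null
#' behind the modified Raup-Crick dissimilarity ([beta_rc()]), the modified
#' stochasticity ratio ([mst()]), and the PERMDISP null group
#' ([permdisp_vs_null()]).
#'
#' @param m 0/1 taxa x samples matrix ([to_binary()]).
#' @param n_sets number of simulated community matrices.
#' @param seed integer seed.
#' @param pool_occupancy optional per-taxon occupancy weights for the draw
#'   (length `nrow(m)`). Defaults to the occupancy of `m` itself
#'   (stratum-local pool); pass occupancy computed over the whole cohort for
#'   a regional (gamma-scale) pool, which is what lets habitat filtering --
#'   communities restricted to a narrow slice of the regional pool -- stand
#'   out from the null.
#' @return List of `n_sets` 0/1 taxa x samples matrices with the input's
#'   dimnames; per-sample richness is conserved in every set.
#' @export
simulate_null_communities <- function(m, n_sets, seed = 1L,
                                      pool_occupancy = NULL) {
  m <- unclass(as.matrix(m))
  occ <- occ_weights(m, pool_occupancy)
  richness <- colSums(m)
  set.seed(seed)
  lapply(seq_len(n_sets), function(i) {
    z <- null_draw(nrow(m), richness, occ)
    dimnames(z) <- dimnames(m)
    z
  })
}

#' Modified Raup-Crick dissimilarity
#'
#' For each sample pair, compares the observed number of shared taxa with
#' its distribution under the occupancy-weighted, richness-preserving null
#' (the "pure stochastic" reference). With `frac` the fraction of null
#' replicates sharing more taxa than observed (ties at half weight),
#' \deqn{\beta_{RC} = 2 \cdot frac - 1 \in [-1, 1].}
#' Values near +1 mean the pair shares fewer taxa than expected by chance
#' (deterministically dissimilar); values near -1 mean it shares more
#' (deterministically similar); values near 0 are indistinguishable from
#' stochastic assembly.
#'
#' @param m 0/1 taxa x samples matrix; occupancy frequencies default to
#'   this matrix (i.e. the analysis stratum).
#' @param n_reps number of null replicates (default 999).
#' @param seed integer seed.
#' @inheritParams simulate_null_communities
#' @return An `rc_matrix`: list with `values` (symmetric samples x samples
#'   matrix, diagonal `NA`), `n_reps`, `seed`.
#' @export
beta_rc <- function(m, n_reps = 999L, seed = 1L, pool_occupancy = NULL) {
  m <- unclass(as.matrix(m))
  if (ncol(m) < 2L) stop("beta_rc needs at least 2 samples")
  richness <- colSums(m)
  empty <- richness == 0
  if (any(empty)) warning(sum(empty), " sample(s) with richness 0 are masked")
  occ <- occ_weights(m, pool_occupancy)
  obs_shared <- crossprod(m)  # samples x samples
  n_s <- ncol(m)
  gt <- matrix(0, n_s, n_s)
  ties <- matrix(0, n_s, n_s)
  set.seed(seed)
  for (r in seq_len(n_reps)) {
    z <- null_draw(nrow(m), richness, occ)
    null_shared <- crossprod(z)
    gt <- gt + (null_shared > obs_shared)
    ties <- ties + (null_shared == obs_shared)
  }
  frac <- (gt + 0.5 * ties) / n_reps
  rc <- 2 * frac - 1
  diag(rc) <- NA_real_
  rc[empty, ] <- NA_real_
  rc[, empty] <- NA_real_
  dimnames(rc) <- list(colnames(m), colnames(m))
  structure(list(values = rc, n_reps = n_reps, seed = seed),
            class = "rc_matrix")
}

#' @export
print.rc_matrix <- function(x, ...) {
  v <- x$values[upper.tri(x$values)]
  cat(sprintf("rc_matrix: %d samples, n_reps=%d, mean betaRC=%.3f\n",
              nrow(x$values), x$n_reps, mean(v, na.rm = TRUE)))
  invisible(x)
}
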