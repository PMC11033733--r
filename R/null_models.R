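#' Checkerboard C-score
#'
#' Mean number of checkerboard units per taxon pair in a presence/absence
#' matrix. For taxa i and j with row totals \eqn{R_i}, \eqn{R_j} and
#' \eqn{S_{ij}} joint occurrences, the pair contributes
#' \eqn{CU_{ij} = (R_i - S_{ij})(R_j - S_{ij})}; the C-score is the mean of
#' \eqn{CU_{ij}} over all unordered pairs (pairs with zero units included).
#' High values indicate taxon segregation.
#'
#' @param m a 0/1 taxa x samples matrix (see [to_binary()]).
#' @return The C-score, a single non-negative number.
#' @export
c_score <- function(m) {
  m <- unclass(as.matrix(m))
  if (nrow(m) < 2L) stop("C-score needs at least 2 taxa")
  S <- tcrossprod(m)
  R <- rowSums(m)
  CU <- (R - S) * t(R - t(S))  # (R_i - S_ij)(R_j - S_ij)
  mean(CU[upper.tri(CU)])
}

# checkerboard unit matrix for all pairs; used by the brute-force tests too
checkerboard_exists <- function(m) {
  m <- unclass(as.matrix(m))
  if (nrow(m) < 2L) return(FALSE)
  cross <- m %*% t(1 - m)  # cross[i,j] = # samples with i present, j absent
  any(cross > 0 & t(cross) > 0)
}

new_null_ensemble <- function(perm, algorithm, n_sim, seed,
                              burn_in = NA_integer_, thin = NA_integer_,
                              source_dim, dimnames) {
  structure(list(matrices = perm, algorithm = algorithm,
                 n_sim = n_sim, seed = seed, burn_in = burn_in, thin = thin,
                 source_dim = source_dim, dimnames = dimnames),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("null_ensemble: %d matrices (%d x %d), algorithm=%s, seed=%s\n",
              x$n_sim, x$source_dim[1], x$source_dim[2], x$algorithm,
              format(x$seed)))
  invisible(x)
}

#' Extract the i-th randomized matrix from an ensemble
#' @param ensemble a `null_ensemble`.
#' @param i index in `1:n_sim`.
#' @return 0/1 matrix with the source dimnames.
#' @export
ensemble_member <- function(ensemble, i) {
  out <- ensemble$matrices[, , i]
  dimnames(out) <- ensemble$dimnames
  out
}

#' Fixed-fixed binary matrix randomization
#'
#' Both algorithms preserve row and column sums of the source matrix exactly
#' ("fixed-fixed" null models) and are backed by the corresponding
#' \pkg{vegan} null models. `sequential_swap` is a Markov chain of 2x2
#' checkerboard flips ([[1,0],[0,1]] <-> [[0,1],[1,0]]): `burn_in` initial
#' swap attempts are discarded and one matrix is emitted every `thin`
#' attempts. `quasiswap` generates each member independently (random fill
#' respecting marginals, then checkerboard repair to exact marginals),
#' giving approximately uniform sampling of the fixed-fixed configuration
#' space.
#'
#' If the matrix contains no swappable 2x2 checkerboard submatrix the
#' ensemble degenerates to identical copies of the input and a warning is
#' issued (downstream SES will be undefined).
#'
#' @param m a 0/1 taxa x samples matrix.
#' @param n_sim number of randomized matrices (default 10000 for
#'   `sequential_swap` to match the SES protocol; 1000 for `quasiswap`).
#' @param burn_in swaps discarded before sampling; default `10 * fill` where
#'   fill is the number of 1s (standard mixing heuristic).
#' @param thin swap attempts between emitted matrices; default `fill`.
#' @param seed integer seed; the ensemble is a pure function of (m, seed).
#' @return A `null_ensemble`: 3-d array of matrices plus algorithm metadata.
#' @export
sequential_swap <- function(m, n_sim = 10000L, burn_in = NULL, thin = NULL,
                            seed = 1L) {
  m <- unclass(as.matrix(m))
  fill <- sum(m)
  if (is.null(burn_in)) burn_in <- 10L * fill
  if (is.null(thin)) thin <- fill
  if (!checkerboard_exists(m)) {
    warning("no swappable 2x2 checkerboard submatrix; ensemble is degenerate")
    return(new_null_ensemble(array(as.numeric(m),
                                   dim = c(nrow(m), ncol(m), n_sim)),
                             "sequential_swap", n_sim, seed, burn_in, thin,
                             dim(m), dimnames(m)))
  }
  nm <- vegan::nullmodel(m, "swap")
  perm <- stats::simulate(nm, nsim = n_sim, seed = seed,
                          burnin = burn_in, thin = thin)
  new_null_ensemble(array(as.numeric(perm), dim = c(nrow(m), ncol(m), n_sim)),
                    "sequential_swap", n_sim, seed, burn_in, thin,
                    dim(m), dimnames(m))
}

#' @rdname sequential_swap
#' @export
quasiswap <- function(m, n_sim = 1000L, seed = 1L) {
  m <- unclass(as.matrix(m))
  if (!checkerboard_exists(m)) {
    warning("no swappable 2x2 checkerboard submatrix; ensemble is degenerate")
    return(new_null_ensemble(array(as.numeric(m),
                                   dim = c(nrow(m), ncol(m), n_sim)),
                             "quasiswap", n_sim, seed, NA_integer_,
                             NA_integer_, dim(m), dimnames(m)))
  }
  nm <- vegan::nullmodel(m, "quasiswap")
  perm <- stats::simulate(nm, nsim = n_sim, seed = seed)
  new_null_ensemble(array(as.numeric(perm), dim = c(nrow(m), ncol(m), n_sim)),
                    "quasiswap", n_sim, seed, NA_integer_, NA_integer_,
                    dim(m), dimnames(m))
}

#' Integer-preserving count-matrix randomization
#'
#' Abundance quasiswap: shuffles a count matrix while preserving row sums,
#' column sums and matrix fill exactly (vegan null model `quasiswap_count`).
#' Used for the niche-breadth ecotype null, where an abundance-based index
#' must remain well defined on randomized tables.
#'
#' @param counts non-negative integer matrix (any orientation; marginals of
#'   the given orientation are preserved).
#' @inheritParams sequential_swap
#' @return A `null_ensemble` with algorithm `"quasiswap_count"`.
#' @export
quasiswap_count <- function(counts, n_sim = 1000L, seed = 1L) {
  counts <- as.matrix(counts)
  nm <- vegan::nullmodel(counts, "quasiswap_count")
  perm <- stats::simulate(nm, nsim = n_sim, seed = seed)
  new_null_ensemble(array(as.numeric(perm),
                          dim = c(nrow(counts), ncol(counts), n_sim)),
                    "quasiswap_count", n_sim, seed, NA_integer_, NA_integer_,
                    dim(counts), dimnames(counts))
}

#' Standardized effect size of the C-score
#'
#' \deqn{SES = (Cscore_{obs} - mean(Cscore_{null})) / sd(Cscore_{null})}
#' computed against a fixed-fixed null ensemble. SES > 2 is classified as
#' overdispersed (taxon segregation beyond null expectation), SES < -2 as
#' underdispersed, anything between as indeterminate; the magnitude reads as
#' the strength of the deterministic imprint on co-occurrence. If the null
#' standard deviation is zero (degenerate ensemble) the SES is NaN and the
#' classification `"undefined"`; no error is thrown so that grouped
#' pipelines survive degenerate strata.
#'
#' @param m the observed 0/1 taxa x samples matrix.
#' @param ensemble a `null_ensemble` derived from `m` (see
#'   [sequential_swap()]).
#' @return A list of class `ses_result`: `c_obs`, `null_mean`, `null_sd`,
#'   `ses`, `n_sim`, `classification`.
#' @export
ses <- function(m, ensemble) {
  stopifnot(inherits(ensemble, "null_ensemble"))
  m <- unclass(as.matrix(m))
  if (!all(dim(m) == ensemble$source_dim))
    stop("ensemble does not match matrix dimensions")
  c_obs <- c_score(m)
  c_null <- vapply(seq_len(ensemble$n_sim),
                   function(i) c_score(ensemble$matrices[, , i]), numeric(1))
  null_mean <- mean(c_null)
  null_sd <- stats::sd(c_null)
  if (!is.finite(null_sd) || null_sd == 0) {
    s <- NaN
    cls <- "undefined"
  } else {
    s <- (c_obs - null_mean) / null_sd
    cls <- if (s > 2) "overdispersed" else if (s < -2) "underdispersed"
           else "indeterminate"
  }
  structure(list(c_obs = c_obs, null_mean = null_mean, null_sd = null_sd,
                 ses = s, n_sim = ensemble$n_sim, classification = cls),
            class = "ses_result")
}

#' @export
print.ses_result <- function(x, ...) {
  cat(sprintf("C-score SES: obs=%.4f null=%.4f (sd %.4f) SES=%.3f [%s]\n",
              x$c_obs, x$null_mean, x$null_sd, x$ses, x$classification))
  invisible(x)
}
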