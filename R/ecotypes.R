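#' Levins niche breadth
#'
#' For taxon j observed over N samples with \eqn{P_{ij}} the proportion of
#' taxon j's total count found in sample i,
#' \deqn{B_j = 1 / \sum_i P_{ij}^2.}
#' B ranges from 1 (all abundance in a single sample: narrowest niche) to N
#' (abundance spread evenly over all samples: widest niche) and reads as the
#' effective number of samples a taxon uses.
#'
#' @param table a [feature_table()] or samples x taxa count matrix.
#' @return Named numeric vector of B values; zero-total taxa are dropped
#'   with a warning.
#' @export
niche_breadth <- function(table) {
  counts <- if (inherits(table, "feature_table")) table$counts else as.matrix(table)
  tot <- colSums(counts)
  if (any(tot == 0)) {
    warning(sum(tot == 0), " zero-total taxa dropped")
    counts <- counts[, tot > 0, drop = FALSE]
    tot <- tot[tot > 0]
  }
  p <- sweep(counts, 2, tot, "/")
  1 / colSums(p^2)
}

#' Classify taxa into generalists, specialists and neutralists
#'
#' Compares each taxon's empirical niche breadth with its null distribution
#' under `n_reps` abundance-quasiswap randomizations of the count table
#' ([quasiswap_count()]; row sums, column sums and fill preserved, so B
#' remains an abundance-based index on null tables). A taxon whose breadth
#' exceeds the 97.5th percentile of its null is a generalist; below the
#' 2.5th percentile, a specialist; within the central 95% interval, a
#' neutralist.
#'
#' @param table a [feature_table()] or samples x taxa count matrix;
#'   zero-total taxa are excluded.
#' @param n_reps null randomizations (default 1000).
#' @param seed integer seed.
#' @return A data.frame of class `ecotype_calls`: `taxon_id`, `breadth`,
#'   `null_lo`, `null_hi`, `label`.
#' @export
classify_ecotypes <- function(table, n_reps = 1000L, seed = 1L) {
  counts <- if (inherits(table, "feature_table")) table$counts else as.matrix(table)
  tot <- colSums(counts)
  if (any(tot == 0)) counts <- counts[, tot > 0, drop = FALSE]
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("t", seq_len(ncol(counts)))
  b_obs <- niche_breadth(counts)
  ens <- tryCatch(quasiswap_count(counts, n_sim = n_reps, seed = seed),
                  error = function(e)
                    stop("count table has no shuffleable incidence ",
                         "structure (no zeros form a checkerboard): ",
                         conditionMessage(e)))
  null_b <- matrix(NA_real_, n_reps, ncol(counts))
  for (r in seq_len(n_reps))
    null_b[r, ] <- niche_breadth(ens$matrices[, , r])
  qs <- apply(null_b, 2, stats::quantile, probs = c(0.025, 0.975),
              names = FALSE)
  label <- ifelse(b_obs > qs[2, ], "generalist",
                  ifelse(b_obs < qs[1, ], "specialist", "neutralist"))
  structure(data.frame(taxon_id = colnames(counts), breadth = unname(b_obs),
                       null_lo = qs[1, ], null_hi = qs[2, ], label = label,
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("ecotype_calls", "data.frame"),
            n_reps = n_reps, seed = seed)
}
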