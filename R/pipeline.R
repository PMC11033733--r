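#' Stable per-stage seed derivation
#'
#' Hashes (seed, stage, stratum) into a 31-bit integer with a polynomial
#' string hash, so stage seeds are reproducible regardless of execution
#' order.
#'
#' @param seed global integer seed.
#' @param ... stage/stratum labels (coerced to character).
#' @return Integer in \[1, 2^31 - 2\].
#' @export
derive_seed <- function(seed, ...) {
  key <- paste(c(format(seed), vapply(list(...), as.character, character(1))),
               collapse = "/")
  h <- 7
  m <- 2147483647
  for (cp in utf8ToInt(key)) h <- (h * 31 + cp) %% m
  as.integer(h %% (m - 2L) + 1L)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

stratum_key <- function(metadata, group_by) {
  if (!length(group_by)) return(rep("all", nrow(metadata)))
  do.call(paste, c(metadata[group_by], sep = "."))
}

#' Run the full assembly analysis pipeline
#'
#' Orchestrates, per stratum of `group_by`: C-score SES against a
#' sequential-swap null, modified Raup-Crick distance matrices, MST per
#' sample, the PERMDISP determinism call, ecotype classification, and a
#' co-occurrence network with topology and top-fraction IVI taxa. Per-sample
#' MST is then thresholded into a two-state assembly panel and the Markov
#' model is fitted per treatment arm with health as the covariate. All
#' outputs are written as TSV plus a machine-readable JSON report; the run
#' is a pure function of the inputs and `seed` (per-stage seeds are derived
#' with [derive_seed()]).
#'
#' Strata with fewer than `min_samples` samples are skipped and logged.
#'
#' @param table a [feature_table()].
#' @param metadata metadata data.frame (see [read_metadata()]).
#' @param out_dir output directory (created if needed).
#' @param group_by metadata columns defining strata (default treatment,
#'   health, week).
#' @param n_sim_ses sequential-swap null matrices for SES (default 10000).
#' @param n_reps_rc Raup-Crick replicates (default 999).
#' @param n_reps_mst MST null replicates (default 1000).
#' @param n_reps_ecotypes ecotype null randomizations (default 1000).
#' @param n_perm permutations for PERMDISP (default 999).
#' @param r_min,p_max network edge thresholds.
#' @param ivi_fraction fraction of top influential nodes reported.
#' @param mst_threshold assembly-state boundary (default 0.5).
#' @param min_samples minimum stratum size (default 4).
#' @param seed global seed.
#' @return Invisibly, a list with all result tables plus `skipped`; also
#'   written under `out_dir` (ses.tsv, mst.tsv, permdisp.tsv, ecotypes.tsv,
#'   network_summary.tsv, influential.tsv, panel.tsv, markov_hr.tsv,
#'   rc/<stratum>.tsv, report.json, run.log).
#' @export
run_pipeline <- function(table, metadata, out_dir,
                         group_by = c("treatment", "health", "week"),
                         n_sim_ses = 10000L, n_reps_rc = 999L,
                         n_reps_mst = 1000L, n_reps_ecotypes = 1000L,
                         n_perm = 999L, r_min = 0.6, p_max = 0.05,
                         ivi_fraction = 0.10, mst_threshold = 0.5,
                         min_samples = 4L, seed = 1L) {
  stopifnot(inherits(table, "feature_table"))
  metadata <- validate_metadata(metadata, table)
  miss <- setdiff(group_by, names(metadata))
  if (length(miss)) stop("grouping column(s) not in metadata: ",
                         paste(miss, collapse = ", "))
  dir.create(file.path(out_dir, "rc"), recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  log_add <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  log_add("pipeline start: %d samples, %d taxa, seed=%d",
          nrow(table$counts), ncol(table$counts), seed)

  # regional (gamma-scale) occupancy pool: presence counts over the whole
  # cohort; strata are analyzed against this pool so habitat-filtered
  # strata, which occupy a narrow slice of it, register as deterministic
  global_occ <- colSums(table$counts[metadata$sample_id, , drop = FALSE] > 0)

  key <- stratum_key(metadata, group_by)
  strata <- split(metadata$sample_id, key)
  ses_rows <- list(); pd_rows <- list(); mst_rows <- list()
  eco_rows <- list(); net_rows <- list(); inf_rows <- list()
  skipped <- character(0)
  mst_all <- numeric(0)

  for (st in names(strata)) {
    ids <- strata[[st]]
    if (length(ids) < min_samples) {
      skipped <- c(skipped, st)
      log_add("stratum %s skipped (%d samples < %d)", st, length(ids),
              min_samples)
      next
    }
    sub_full <- table$counts[ids, , drop = FALSE]
    sub <- sub_full[, colSums(sub_full) > 0, drop = FALSE]
    # SES randomizes within the stratum: all-zero taxa dropped
    bm <- suppressWarnings(to_binary(feature_table(sub)))
    # the null-expectation statistics keep the full taxon set so the
    # regional occupancy pool is not truncated to the stratum
    bm_reg <- t((sub_full > 0) * 1)
    t0 <- proc.time()[3]

    ens <- suppressWarnings(
      sequential_swap(bm, n_sim = n_sim_ses,
                      seed = derive_seed(seed, "ses", st)))
    sr <- ses(bm, ens)
    ses_rows[[st]] <- data.frame(stratum = st, n_samples = length(ids),
                                 c_obs = sr$c_obs, null_mean = sr$null_mean,
                                 null_sd = sr$null_sd, ses = sr$ses,
                                 classification = sr$classification)

    rc <- beta_rc(bm_reg, n_reps = n_reps_rc,
                  seed = derive_seed(seed, "rc", st),
                  pool_occupancy = global_occ)
    write_tsv(data.frame(sample_id = rownames(rc$values), rc$values,
                         check.names = FALSE),
              file.path(out_dir, "rc", paste0(st, ".tsv")))

    ms <- mst(bm_reg, n_reps = n_reps_mst, metric = "jaccard",
              seed = derive_seed(seed, "mst", st),
              pool_occupancy = global_occ)
    per <- mst_per_sample(ms)
    mst_all <- c(mst_all, per)
    mst_rows[[st]] <- data.frame(stratum = st, sample_id = names(per),
                                 mst = unname(per),
                                 group_mean = ms$group_mean)

    pd <- permdisp_vs_null(bm_reg, n_reps_rc = n_reps_rc, n_perm = n_perm,
                           seed = derive_seed(seed, "permdisp", st),
                           pool_occupancy = global_occ)
    pd_rows[[st]] <- data.frame(stratum = st,
                                centroid_actual = pd$centroid_dist_actual,
                                centroid_null = pd$centroid_dist_null,
                                f_stat = pd$f_stat, p_value = pd$p_value)

    eco <- classify_ecotypes(feature_table(sub),
                             n_reps = n_reps_ecotypes,
                             seed = derive_seed(seed, "ecotypes", st))
    eco_rows[[st]] <- cbind(stratum = st, as.data.frame(eco))

    net <- suppressWarnings(
      build_network(feature_table(sub), r_min = r_min, p_max = p_max))
    if (igraph::vcount(net$graph) >= 2L) {
      topo <- topology(net, seed = derive_seed(seed, "topology", st))
      net_rows[[st]] <- data.frame(stratum = st, n_nodes = topo$n_nodes,
                                   n_edges = topo$n_edges,
                                   modularity = topo$modularity,
                                   average_degree = topo$average_degree,
                                   clustering = topo$clustering_coefficient)
      scores <- ivi(net)
      top <- top_influential(scores, ivi_fraction)
      inf_rows[[st]] <- data.frame(stratum = st, rank = seq_along(top),
                                   taxon_id = top,
                                   ivi = scores$ivi[match(top, scores$node)])
    } else {
      log_add("stratum %s: network too small, topology skipped", st)
    }
    log_add("stratum %s done (%d samples, %.1fs)", st, length(ids),
            proc.time()[3] - t0)
  }

  res <- list(ses = do.call(rbind, ses_rows),
              permdisp = do.call(rbind, pd_rows),
              mst = do.call(rbind, mst_rows),
              ecotypes = do.call(rbind, eco_rows),
              network = do.call(rbind, net_rows),
              influential = do.call(rbind, inf_rows))

  panel <- assign_states(mst_all, metadata[metadata$sample_id %in%
                                             names(mst_all), , drop = FALSE],
                         threshold = mst_threshold)
  res$panel <- panel
  hr_rows <- list()
  for (arm in sort(unique(panel$treatment))) {
    sub_panel <- panel[panel$treatment == arm, , drop = FALSE]
    fit <- tryCatch(
      suppressMessages(fit_two_state(sub_panel, covariates = "health")),
      error = function(e) {
        log_add("markov fit failed for arm %s: %s", arm, conditionMessage(e))
        NULL
      })
    if (!is.null(fit))
      hr_rows[[arm]] <- cbind(arm = arm, fit$hr,
                              q12 = fit$q12_0, q21 = fit$q21_0,
                              converged = fit$converged)
  }
  res$markov_hr <- do.call(rbind, hr_rows)
  res$skipped <- skipped

  for (nm in c("ses", "permdisp", "mst", "ecotypes", "network",
               "influential", "panel", "markov_hr")) {
    if (!is.null(res[[nm]])) {
      rownames(res[[nm]]) <- NULL
      write_tsv(res[[nm]], file.path(out_dir, paste0(nm, ".tsv")))
    }
  }
  report <- c(list(seed = seed, group_by = group_by,
                   n_samples = nrow(table$counts),
                   n_taxa = ncol(table$counts), skipped = skipped),
              lapply(res[c("ses", "permdisp", "network", "markov_hr")],
                     function(x) x))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows", pretty = TRUE)
  writeLines(log_lines, file.path(out_dir, "run.log"))
  log_add("pipeline complete")
  invisible(res)
}
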