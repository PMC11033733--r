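#' Configuration for the synthetic longitudinal cohort
#'
#' Defaults emulate the design of an 84-calf, two-arm probiotic trial:
#' 42 calves per arm (placebo arm split 14 healthy / 28 unhealthy, probiotic
#' arm 21 / 21), fecal sampling at weeks 1, 2, 3, 6 and 8, with about 21 of
#' the 420 scheduled samples lost to attrition. Communities are genus-like
#' count vectors drawn from a lognormal metacommunity at a sequencing depth
#' of 5000 reads; deterministic assembly is produced by Gaussian
#' environmental filtering of the sampling weights, stochastic assembly by
#' plain multinomial sampling. Each calf's latent assembly state follows a
#' two-state CTMC whose forward (stochastic to deterministic) intensity is
#' multiplied by `exp(beta_health)` for unhealthy calves.
#'
#' @param n_calves_per_arm calves per treatment arm (default 42).
#' @param n_healthy_con,n_healthy_scb healthy calves in the placebo and
#'   probiotic arms (defaults 14 and 21).
#' @param weeks sampling weeks (default 1, 2, 3, 6, 8).
#' @param n_taxa metacommunity size (default 120 genera).
#' @param meanlog,sdlog lognormal metacommunity parameters (defaults 0 and
#'   1.5, a realistic steep rank-abundance curve).
#' @param depth reads per sample (default 5000).
#' @param filter_strength Gaussian filtering strength for deterministic
#'   samples (default 5; 0 reduces exactly to neutral sampling).
#' @param q12,q21 baseline CTMC intensities per week (defaults 0.3, 0.2).
#' @param beta_health log hazard effect of poor health on the forward
#'   transition (default log(1.34)).
#' @param p_init_stochastic probability the week-1 state is stochastic
#'   (default 0.9; early-life assembly is stochastic-leaning).
#' @param attrition expected number of missing samples over the whole
#'   design (default 21; applied as an independent per-sample dropout
#'   probability).
#' @param n_generalists,n_specialists taxa to re-plant as known ecotypes
#'   (defaults 5 and 5; set to 0 to leave the assembly regimes untouched).
#' @param seed integer seed; every generator is a pure function of
#'   (config, seed).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_calves_per_arm = 42L, n_healthy_con = 14L,
                          n_healthy_scb = 21L, weeks = c(1L, 2L, 3L, 6L, 8L),
                          n_taxa = 120L, meanlog = 0, sdlog = 1.5,
                          depth = 5000L, filter_strength = 5,
                          q12 = 0.3, q21 = 0.2, beta_health = log(1.34),
                          p_init_stochastic = 0.9, attrition = 21L,
                          n_generalists = 5L, n_specialists = 5L,
                          seed = 1L) {
  stopifnot(n_taxa >= 10L, all(diff(weeks) > 0), filter_strength >= 0,
            n_healthy_con <= n_calves_per_arm,
            n_healthy_scb <= n_calves_per_arm)
  structure(as.list(environment()), class = "cohort_config")
}

#' Simulate a metacommunity
#'
#' Lognormal relative abundances, sorted decreasing and normalized to 1.
#'
#' @param n_taxa number of taxa (>= 10).
#' @param meanlog,sdlog lognormal parameters.
#' @param seed integer seed.
#' @return Named numeric vector of relative abundances summing to 1.
#' @export
simulate_metacommunity <- function(n_taxa, meanlog = 0, sdlog = 1.5,
                                   seed = 1L) {
  stopifnot(n_taxa >= 10L)
  set.seed(seed)
  ab <- sort(stats::rlnorm(n_taxa, meanlog, sdlog), decreasing = TRUE)
  ab <- ab / sum(ab)
  names(ab) <- sprintf("genus_%03d", seq_len(n_taxa))
  ab
}

#' Neutral (stochastic) community sample
#'
#' A multinomial draw of `depth` reads from the metacommunity pool: the pure
#' drift/dispersal reference with no fitness differences.
#'
#' @param pool named relative-abundance vector ([simulate_metacommunity()]).
#' @param depth reads to draw.
#' @param seed optional seed; if `NULL` the current RNG stream is used.
#' @return Named integer count vector summing to `depth`.
#' @export
simulate_neutral_sample <- function(pool, depth, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  counts <- as.vector(stats::rmultinom(1, depth, pool))
  names(counts) <- names(pool)
  counts
}

#' Habitat-filtered (deterministic) community sample
#'
#' Deterministic selection: sampling weights are the pool abundances
#' multiplied by a Gaussian fitness kernel
#' \eqn{\exp(-strength (optimum - environment)^2)} and renormalized. A
#' shared environment across a stratum produces convergent communities
#' (Raup-Crick toward -1); opposed environments produce divergence (toward
#' +1). `filter_strength = 0` reduces exactly to
#' [simulate_neutral_sample()].
#'
#' @param pool named relative-abundance vector.
#' @param environment environment value of the sample.
#' @param optima per-taxon environmental optima (same length as pool).
#' @param filter_strength Gaussian kernel strength (>= 0).
#' @param depth reads to draw.
#' @param seed optional seed; if `NULL` the current RNG stream is used.
#' @return Named integer count vector summing to `depth`.
#' @export
simulate_filtered_sample <- function(pool, environment, optima,
                                     filter_strength, depth, seed = NULL) {
  stopifnot(length(optima) == length(pool), filter_strength >= 0)
  if (!is.null(seed)) set.seed(seed)
  # log-space renormalization: immune to kernel underflow at high strength
  # (strength 0 short-circuits so the neutral limit is bit-identical)
  if (filter_strength == 0) {
    w <- pool / sum(pool)
  } else {
    lw <- log(pool) - filter_strength * (optima - environment)^2
    w <- exp(lw - max(lw))
    w <- w / sum(w)
  }
  if (sum(w > 1e-12) < 5L)
    warning("filter so strong that fewer than 5 taxa retain weight")
  counts <- as.vector(stats::rmultinom(1, depth, w))
  names(counts) <- names(pool)
  counts
}

#' Plant known generalist and specialist taxa
#'
#' Rewrites selected taxa of a count table so their niche breadth is known:
#' planted generalists get their column total redistributed near-uniformly
#' over all N samples (empirical B close to N); planted specialists get the
#' total concentrated in `k_specialist` samples (B <= k). The
#' highest-total taxa are planted first so the redistribution is stable.
#'
#' @param table a [feature_table()] or samples x taxa count matrix.
#' @param n_generalists,n_specialists how many taxa of each kind to plant.
#' @param k_specialist samples carrying a specialist (default 2, split
#'   60/40).
#' @param seed integer seed.
#' @return List: `table` (modified [feature_table()]) and `truth`
#'   (data.frame taxon_id, label).
#' @export
plant_ecotypes <- function(table, n_generalists, n_specialists,
                           k_specialist = 2L, seed = 1L) {
  counts <- if (inherits(table, "feature_table")) table$counts else as.matrix(table)
  n <- nrow(counts)
  if (n_generalists + n_specialists > ncol(counts))
    stop("ecotype plan exceeds taxon count")
  set.seed(seed)
  ord <- order(colSums(counts), decreasing = TRUE)
  gen_idx <- ord[seq_len(n_generalists)]
  spec_idx <- ord[n_generalists + seq_len(n_specialists)]
  min_total <- 20L * n  # keep multinomial noise on B below ~10%
  for (j in gen_idx) {
    tot <- max(sum(counts[, j]), min_total)
    counts[, j] <- as.vector(stats::rmultinom(1, tot, rep(1 / n, n)))
  }
  for (j in spec_idx) {
    tot <- max(sum(counts[, j]), min_total)
    counts[, j] <- 0
    hosts <- sample.int(n, k_specialist)
    share <- round(tot * 0.6)
    counts[hosts[1], j] <- share
    if (k_specialist > 1L)
      counts[hosts[-1], j] <- round((tot - share) / (k_specialist - 1L))
  }
  truth <- data.frame(
    taxon_id = colnames(counts)[c(gen_idx, spec_idx)],
    label = rep(c("generalist", "specialist"),
                c(n_generalists, n_specialists)),
    stringsAsFactors = FALSE)
  list(table = feature_table(counts), truth = truth)
}

#' Simulate a full longitudinal cohort
#'
#' Generates the complete stated world: per calf, a latent assembly state
#' evolving by the two-state CTMC (forward intensity scaled by
#' `exp(beta_health)` for unhealthy calves) selects, week by week, the
#' neutral or the habitat-filtered community generator (shared environment
#' 0, i.e. convergent filtering). Attrition then removes samples
#' independently at the configured expected rate, and, if requested, known
#' generalists/specialists are planted into the final table.
#'
#' @param config a [cohort_config()].
#' @return List: `table` ([feature_table()]), `metadata` (data.frame:
#'   sample_id, calf_id, week, treatment, health), `truth` (list with
#'   `states` per calf-week, `regimes` per retained sample, `markov`
#'   parameters, `ecotypes` data.frame or NULL, `pool`, `optima`).
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  set.seed(cfg$seed)
  pool <- {
    ab <- sort(stats::rlnorm(cfg$n_taxa, cfg$meanlog, cfg$sdlog),
               decreasing = TRUE)
    ab <- ab / sum(ab)
    names(ab) <- sprintf("genus_%03d", seq_len(cfg$n_taxa))
    ab
  }
  optima <- stats::runif(cfg$n_taxa, -1, 1)

  arm <- rep(c("CON", "SCB"), each = cfg$n_calves_per_arm)
  health <- c(rep(c("H", "UH"),
                  c(cfg$n_healthy_con, cfg$n_calves_per_arm - cfg$n_healthy_con)),
              rep(c("H", "UH"),
                  c(cfg$n_healthy_scb, cfg$n_calves_per_arm - cfg$n_healthy_scb)))
  n_calves <- length(arm)
  calf_id <- sprintf("calf%03d", seq_len(n_calves))
  weeks <- cfg$weeks

  states <- matrix(NA_integer_, n_calves, length(weeks),
                   dimnames = list(calf_id, paste0("w", weeks)))
  for (i in seq_len(n_calves)) {
    x <- as.integer(health[i] == "UH")
    q12 <- cfg$q12 * exp(cfg$beta_health * x)
    q21 <- cfg$q21
    st <- integer(length(weeks))
    st[1] <- if (stats::runif(1) < cfg$p_init_stochastic) 1L else 2L
    for (j in seq_along(weeks)[-1]) {
      P <- transition_matrix(q12, q21, weeks[j] - weeks[j - 1])
      st[j] <- sample.int(2L, 1L, prob = P[st[j - 1], ])
    }
    states[i, ] <- st
  }

  n_sched <- n_calves * length(weeks)
  counts <- matrix(0L, n_sched, cfg$n_taxa)
  meta <- data.frame(sample_id = character(n_sched),
                     calf_id = character(n_sched), week = integer(n_sched),
                     treatment = character(n_sched),
                     health = character(n_sched),
                     stringsAsFactors = FALSE)
  regime <- character(n_sched)
  r <- 0L
  for (i in seq_len(n_calves)) {
    for (j in seq_along(weeks)) {
      r <- r + 1L
      if (states[i, j] == 1L) {
        counts[r, ] <- simulate_neutral_sample(pool, cfg$depth)
        regime[r] <- "neutral"
      } else {
        counts[r, ] <- simulate_filtered_sample(pool, 0, optima,
                                                cfg$filter_strength,
                                                cfg$depth)
        regime[r] <- "filtered_convergent"
      }
      meta[r, ] <- list(sprintf("%s_w%d", calf_id[i], weeks[j]),
                        calf_id[i], weeks[j], arm[i], health[i])
    }
  }
  keep <- stats::runif(n_sched) >= cfg$attrition / n_sched
  counts <- counts[keep, , drop = FALSE]
  meta <- meta[keep, , drop = FALSE]
  regime <- regime[keep]
  rownames(meta) <- NULL
  colnames(counts) <- names(pool)
  rownames(counts) <- meta$sample_id
  table <- feature_table(counts)

  ecotruth <- NULL
  if (cfg$n_generalists + cfg$n_specialists > 0L) {
    planted <- plant_ecotypes(table, cfg$n_generalists, cfg$n_specialists,
                              seed = cfg$seed + 1L)
    table <- planted$table
    ecotruth <- planted$truth
  }
  list(table = table, metadata = meta,
       truth = list(states = states,
                    regimes = data.frame(sample_id = meta$sample_id,
                                         regime = regime,
                                         stringsAsFactors = FALSE),
                    markov = list(q12 = cfg$q12, q21 = cfg$q21,
                                  beta_health = cfg$beta_health),
                    ecotypes = ecotruth, pool = pool, optima = optima,
                    config = cfg))
}
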