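# Shared fixtures and independent oracles used across test files.

# random binary taxa x samples matrix guaranteed to have no empty rows/cols
random_binary <- function(n_taxa, n_samples, density = 0.4) {
  repeat {
    m <- matrix(rbinom(n_taxa * n_samples, 1, density), n_taxa, n_samples)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) return(m)
  }
}

# brute-force C-score oracle: explicit double loop over taxon pairs
c_score_oracle <- function(m) {
  n <- nrow(m)
  total <- 0
  npair <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ri <- sum(m[i, ]); rj <- sum(m[j, ])
      sij <- sum(m[i, ] == 1 & m[j, ] == 1)
      total <- total + (ri - sij) * (rj - sij)
      npair <- npair + 1
    }
  }
  total / npair
}

# a small realistic neutral count table (samples x taxa)
neutral_table <- function(n_samples, n_taxa, depth, seed) {
  pool <- simulate_metacommunity(n_taxa, seed = seed)
  set.seed(seed + 1)
  tab <- t(replicate(n_samples, simulate_neutral_sample(pool, depth)))
  rownames(tab) <- sprintf("s%02d", seq_len(n_samples))
  tab
}

# hand-built BIOM-JSON v1 (sparse) matching tsv_fixture_counts below,
# including one all-zero taxon row
biom_json_fixture <- function(path) {
  counts <- tsv_fixture_counts()  # taxa x samples
  idx <- which(counts != 0, arr.ind = TRUE)
  data <- lapply(seq_len(nrow(idx)), function(k)
    c(idx[k, 1] - 1L, idx[k, 2] - 1L, counts[idx[k, 1], idx[k, 2]]))
  obj <- list(
    id = "fixture", format = "Biological Observation Matrix 1.0.0",
    format_url = "http://biom-format.org",
    type = "OTU table", generated_by = "assemblage tests",
    date = "2026-01-01T00:00:00",
    matrix_type = "sparse", matrix_element_type = "int",
    shape = dim(counts),
    rows = lapply(rownames(counts), function(r)
      list(id = r, metadata = NULL)),
    columns = lapply(colnames(counts), function(s)
      list(id = s, metadata = NULL)),
    data = data)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null"), path)
  path
}

tsv_fixture_counts <- function() {
  m <- matrix(c(5L, 0L, 3L, 2L,
                0L, 0L, 0L, 0L,
                1L, 4L, 0L, 7L,
                2L, 2L, 2L, 2L), 4, 4, byrow = TRUE)
  dimnames(m) <- list(paste0("taxon", 1:4), paste0("sample", 1:4))
  m
}

write_tsv_fixture <- function(path) {
  counts <- tsv_fixture_counts()
  df <- data.frame(`#OTU ID` = rownames(counts), counts, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# metadata for a toy cohort
toy_metadata <- function(sample_ids, n_calves, weeks) {
  grid <- expand.grid(week = weeks, calf = seq_len(n_calves))
  data.frame(sample_id = sample_ids,
             calf_id = sprintf("calf%02d", grid$calf[seq_along(sample_ids)]),
             week = grid$week[seq_along(sample_ids)],
             treatment = rep(c("CON", "SCB"), length.out = length(sample_ids)),
             health = rep(c("H", "UH"), length.out = length(sample_ids)),
             stringsAsFactors = FALSE)
}
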