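#' Construct a feature table
#'
#' The universal input container of the package: a samples x taxa matrix of
#' non-negative integer counts with unique sample and taxon identifiers, and
#' an optional per-taxon lineage string (semicolon-delimited, kingdom to
#' genus) used by [aggregate_taxonomy()].
#'
#' @param counts integer matrix, samples in rows, taxa in columns.
#' @param sample_ids character vector of unique sample identifiers; defaults
#'   to `rownames(counts)`.
#' @param taxon_ids character vector of unique taxon identifiers; defaults to
#'   `colnames(counts)`.
#' @param taxonomy optional character vector of lineage strings, one per
#'   taxon, e.g. `"k__Bacteria;p__Firmicutes;...;g__Blautia"`.
#' @return An object of class `feature_table` with elements `counts`
#'   (samples x taxa integer matrix with dimnames), and `taxonomy` (or NULL).
#' @export
feature_table <- function(counts, sample_ids = rownames(counts),
                          taxon_ids = colnames(counts), taxonomy = NULL) {
  counts <- as.matrix(counts)
  if (length(counts) == 0L || nrow(counts) == 0L || ncol(counts) == 0L)
    stop("feature table is empty")
  if (is.null(sample_ids))
    sample_ids <- sprintf("sample_%03d", seq_len(nrow(counts)))
  if (is.null(taxon_ids))
    taxon_ids <- sprintf("taxon_%03d", seq_len(ncol(counts)))
  sample_ids <- as.character(sample_ids)
  taxon_ids <- as.character(taxon_ids)
  if (length(sample_ids) != nrow(counts) || length(taxon_ids) != ncol(counts))
    stop("identifier lengths do not match matrix dimensions")
  if (anyDuplicated(sample_ids)) stop("duplicate sample identifiers")
  if (anyDuplicated(taxon_ids)) stop("duplicate taxon identifiers")
  if (anyNA(counts)) stop("missing values in counts")
  if (any(counts < 0)) stop("negative counts are not allowed")
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be integers")
  storage.mode(counts) <- "double"
  counts <- round(counts)
  dimnames(counts) <- list(sample_ids, taxon_ids)
  if (!is.null(taxonomy)) {
    taxonomy <- as.character(taxonomy)
    if (length(taxonomy) != ncol(counts))
      stop("taxonomy length does not match number of taxa")
    names(taxonomy) <- taxon_ids
  }
  structure(list(counts = counts, taxonomy = taxonomy),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d samples x %d taxa (total count %g)%s\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts),
              if (is.null(x$taxonomy)) "" else ", with taxonomy"))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$counts)

#' Read a feature table from TSV or BIOM-JSON
#'
#' The TSV dialect is the common QIIME-style export: taxa as rows, samples as
#' columns, first column holding the taxon identifier. An optional trailing
#' `taxonomy` column is kept as the lineage. Tables are transposed on load to
#' the canonical samples x taxa orientation. BIOM-JSON v1.0 (dense or sparse)
#' is parsed with the biomformat package.
#'
#' @param path path to the file.
#' @param format `"tsv"` or `"biom-json"`; default guesses from the file
#'   extension (`.biom`/`.json` vs anything else).
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path, format = c("auto", "tsv", "biom-json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(biom|json)$", path, ignore.case = TRUE))
      "biom-json" else "tsv"
  }
  if (format == "tsv") {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE,
                            comment.char = "", quote = "")
    if (nrow(df) == 0L || ncol(df) < 2L) stop("empty table: ", path)
    taxon_ids <- as.character(df[[1L]])
    df <- df[, -1L, drop = FALSE]
    taxonomy <- NULL
    if (tolower(names(df)[ncol(df)]) == "taxonomy") {
      taxonomy <- as.character(df[[ncol(df)]])
      df <- df[, -ncol(df), drop = FALSE]
    }
    m <- as.matrix(df)
    if (!is.numeric(m)) stop("non-numeric cells in feature table")
    if (any(abs(m - round(m)) > 1e-8)) stop("non-integer counts in ", path)
    ft <- feature_table(t(m), sample_ids = colnames(df),
                        taxon_ids = taxon_ids, taxonomy = taxonomy)
  } else {
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")  # taxa x samples
    tax <- tryCatch(biomformat::observation_metadata(b),
                    error = function(e) NULL)
    taxonomy <- NULL
    if (!is.null(tax) && length(tax)) {
      taxonomy <- vapply(seq_len(nrow(m)), function(i) {
        row <- if (is.data.frame(tax)) unlist(tax[i, ]) else tax[[i]]
        paste(unlist(row), collapse = ";")
      }, character(1))
    }
    ft <- feature_table(t(m), sample_ids = colnames(m),
                        taxon_ids = rownames(m), taxonomy = taxonomy)
  }
  ft
}

#' Write a feature table as TSV
#'
#' Inverse of [read_feature_table()] for the TSV dialect (taxa rows, samples
#' columns, first column `#OTU ID`, optional trailing `taxonomy` column).
#'
#' @param table a [feature_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  m <- t(table$counts)  # taxa x samples
  df <- data.frame(`#OTU ID` = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!is.null(table$taxonomy)) df$taxonomy <- unname(table$taxonomy)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' Metadata TSV with required columns `sample_id`, `calf_id`, `week`,
#' `treatment`, `health`. At most one sample per calf and week is allowed.
#'
#' @param path path to the metadata TSV.
#' @param table optional [feature_table()]; if given, `sample_id` must be a
#'   subset of its sample identifiers.
#' @return A data.frame with validated columns.
#' @export
read_metadata <- function(path, table = NULL) {
  md <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  validate_metadata(md, table)
}

#' @rdname read_metadata
#' @param metadata a metadata data.frame to validate in place.
#' @export
validate_metadata <- function(metadata, table = NULL) {
  need <- c("sample_id", "calf_id", "week", "treatment", "health")
  miss <- setdiff(need, names(metadata))
  if (length(miss)) stop("missing metadata column(s): ",
                         paste(miss, collapse = ", "))
  metadata$sample_id <- as.character(metadata$sample_id)
  metadata$calf_id <- as.character(metadata$calf_id)
  metadata$week <- as.integer(metadata$week)
  if (anyDuplicated(metadata$sample_id)) stop("duplicate sample_id in metadata")
  if (anyDuplicated(metadata[, c("calf_id", "week")]))
    stop("more than one sample per calf x week")
  if (!is.null(table)) {
    unknown <- setdiff(metadata$sample_id, rownames(table$counts))
    if (length(unknown))
      stop("metadata sample_id not in feature table: ",
           paste(utils::head(unknown, 5), collapse = ", "))
  }
  metadata
}

#' Presence/absence matrix from counts
#'
#' Converts a feature table into a binary taxa x samples matrix: the
#' substrate for all co-occurrence randomizations. Orientation is taxa x
#' samples because checkerboard pairs are taxon pairs. Taxa or samples that
#' are all-zero after thresholding are dropped with a warning.
#'
#' @param table a [feature_table()] or a samples x taxa numeric matrix.
#' @param detection_threshold minimum count for presence (default 1).
#' @return A `binary_matrix`: 0/1 matrix, taxa in rows, samples in columns.
#' @export
to_binary <- function(table, detection_threshold = 1L) {
  if (detection_threshold < 1) stop("detection_threshold must be >= 1")
  counts <- if (inherits(table, "feature_table")) table$counts else as.matrix(table)
  b <- t((counts >= detection_threshold) * 1)  # taxa x samples
  as_binary_matrix(b)
}

#' @rdname to_binary
#' @param m a 0/1 taxa x samples matrix to validate/clean.
#' @export
as_binary_matrix <- function(m) {
  m <- as.matrix(m)
  if (!all(m %in% c(0, 1))) stop("entries must be 0/1")
  drop_r <- rowSums(m) == 0
  drop_c <- colSums(m) == 0
  if (any(drop_r) || any(drop_c)) {
    warning(sprintf("dropping %d all-zero taxa and %d all-zero samples",
                    sum(drop_r), sum(drop_c)))
    m <- m[!drop_r, !drop_c, drop = FALSE]
  }
  if (nrow(m) == 0L || ncol(m) == 0L) stop("binary matrix is empty")
  class(m) <- c("binary_matrix", class(m))
  m
}

#' Relative abundance matrix
#'
#' @param table a [feature_table()].
#' @return samples x taxa matrix of proportions; each row sums to 1.
#' @export
relative_abundance <- function(table) {
  counts <- if (inherits(table, "feature_table")) table$counts else as.matrix(table)
  tot <- rowSums(counts)
  zero <- tot == 0
  if (any(zero))
    stop("sample(s) with zero total count: ",
         paste(rownames(counts)[zero], collapse = ", "))
  counts / tot
}

#' Aggregate counts to a higher taxonomic rank
#'
#' Sums counts of taxa sharing the same label at the requested rank.
#' Lineages are parsed as semicolon-delimited fields, optionally with
#' `k__`/`p__`/... prefixes; taxa whose lineage does not resolve at the rank
#' are pooled under `"unclassified"`.
#'
#' @param table a [feature_table()] with taxonomy.
#' @param rank one of `"kingdom"`, `"phylum"`, `"class"`, `"order"`,
#'   `"family"`, `"genus"`.
#' @return A [feature_table()] of aggregated counts (no taxonomy).
#' @export
aggregate_taxonomy <- function(table,
                               rank = c("genus", "phylum", "kingdom",
                                        "class", "order", "family")) {
  stopifnot(inherits(table, "feature_table"))
  rank <- match.arg(rank)
  if (is.null(table$taxonomy)) stop("feature table has no taxonomy")
  idx <- match(rank, c("kingdom", "phylum", "class", "order", "family",
                       "genus"))
  labels <- vapply(strsplit(table$taxonomy, ";"), function(parts) {
    parts <- trimws(parts)
    if (length(parts) < idx) return("unclassified")
    lab <- sub("^[a-z]__", "", parts[idx])
    if (!nzchar(lab)) "unclassified" else lab
  }, character(1))
  groups <- unique(labels)
  agg <- vapply(groups, function(g)
    rowSums(table$counts[, labels == g, drop = FALSE]), numeric(nrow(table$counts)))
  if (nrow(table$counts) == 1L) agg <- matrix(agg, nrow = 1)
  feature_table(agg, sample_ids = rownames(table$counts), taxon_ids = groups)
}

#' Per-sample alpha diversity
#'
#' Shannon index uses the natural logarithm, \eqn{H = -\sum p \ln p}.
#' Chao1 is the bias-corrected form
#' \eqn{S_{obs} + F_1 (F_1 - 1) / (2 (F_2 + 1))} where \eqn{F_1} and
#' \eqn{F_2} are the numbers of singleton and doubleton taxa.
#'
#' @param table a [feature_table()].
#' @param metric `"chao1"` or `"shannon"`.
#' @return Named numeric vector, one value per sample.
#' @export
alpha_diversity <- function(table, metric = c("chao1", "shannon")) {
  metric <- match.arg(metric)
  counts <- if (inherits(table, "feature_table")) table$counts else as.matrix(table)
  tot <- rowSums(counts)
  if (any(tot == 0))
    stop("empty sample(s): ",
         paste(rownames(counts)[tot == 0], collapse = ", "))
  if (metric == "shannon") {
    p <- counts / tot
    return(apply(p, 1, function(pi) {
      pi <- pi[pi > 0]
      -sum(pi * log(pi))
    }))
  }
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("chao1 requires integer counts")
  apply(counts, 1, function(x) {
    s <- sum(x > 0)
    f1 <- sum(x == 1)
    f2 <- sum(x == 2)
    s + f1 * (f1 - 1) / (2 * (f2 + 1))
  })
}
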