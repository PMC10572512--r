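#' Construct a feature matrix with aligned labels and column origins
#'
#' @param values R x d numeric matrix (rows = samples, columns = features).
#' @param labels optional length-R integer vector of class labels in
#'   `0..C-1`; required for selection and evaluation, optional for fusion.
#' @param column_ids optional character vector of column identifiers
#'   recording origin (source tag + original column index).
#' @param source tag used to build default column ids (e.g. `"A"`).
#' @return a list of class `feature_matrix` with fields `values`, `labels`,
#'   `column_ids`.
#' @export
feature_matrix <- function(values, labels = NULL, column_ids = NULL,
                           source = "A") {
  values <- as.matrix(values)
  if (nrow(values) < 2L) stop("need at least two samples")
  if (ncol(values) < 1L) stop("need at least one feature")
  if (any(!is.finite(values))) stop("feature values must be finite")
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != nrow(values))
      stop("labels must align with rows")
    if (any(labels < 0)) stop("labels must be nonnegative integers 0..C-1")
  }
  if (is.null(column_ids))
    column_ids <- paste0(source, seq_len(ncol(values)) - 1L)
  if (length(column_ids) != ncol(values))
    stop("column_ids must align with columns")
  structure(list(values = values, labels = labels,
                 column_ids = as.character(column_ids)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix: %d samples x %d features%s>\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$labels)) "" else
                sprintf(", %d classes", length(unique(x$labels)))))
  invisible(x)
}

#' Serial concatenation of two feature matrices
#'
#' Column-wise concatenation of two per-sample feature sources over the same
#' samples; column identifiers keep track of each column's origin.
#'
#' @param Fa,Fb `feature_matrix` objects with equal row counts and identical
#'   labels (when both carry labels).
#' @return a `feature_matrix` with `ncol(Fa) + ncol(Fb)` columns.
#' @export
serial_concat <- function(Fa, Fb) {
  if (nrow(Fa$values) != nrow(Fb$values))
    stop("row counts differ between the two feature sources")
  if (!is.null(Fa$labels) && !is.null(Fb$labels) &&
      !identical(Fa$labels, Fb$labels))
    stop("labels differ between the two feature sources")
  feature_matrix(cbind(Fa$values, Fb$values),
                 labels = if (is.null(Fa$labels)) Fb$labels else Fa$labels,
                 column_ids = c(Fa$column_ids, Fb$column_ids))
}

#' Maximum cross-source rank-correlation score per column
#'
#' For every column of the concatenated matrix, the score is the maximum
#' absolute Spearman rank correlation against all columns of the *other*
#' source. This is the supremum of correlation over monotone transforms, a
#' tractable surrogate for the maximal-correlation supremum over all Borel
#' functions. Constant columns score 0 by convention.
#'
#' @param Fa,Fb `feature_matrix` objects with equal row counts, R >= 3.
#' @param max_pairs optional cap on the number of companion columns scanned
#'   per source (seeded subsample); default exhaustive.
#' @param seed seed used only when `max_pairs` subsampling is active.
#' @return list with `scores` (length `ncol(Fa)+ncol(Fb)` vector in \[0,1\])
#'   and `method = "rank_max_abs"`.
#' @export
correlation_scores <- function(Fa, Fb, max_pairs = NULL, seed = 1L) {
  R <- nrow(Fa$values)
  if (nrow(Fb$values) != R) stop("row counts differ")
  if (R < 3L) stop("need at least 3 samples for rank correlation")
  A <- Fa$values; B <- Fb$values
  cols_a <- seq_len(ncol(A)); cols_b <- seq_len(ncol(B))
  if (!is.null(max_pairs)) {
    old <- .Random.seed_save()
    set.seed(seed)
    if (ncol(A) > max_pairs) cols_a <- sort(sample(ncol(A), max_pairs))
    if (ncol(B) > max_pairs) cols_b <- sort(sample(ncol(B), max_pairs))
    .Random.seed_restore(old)
  }
  ra <- apply(A, 2L, rank)
  rb <- apply(B, 2L, rank)
  const_a <- apply(A, 2L, function(x) max(x) == min(x))
  const_b <- apply(B, 2L, function(x) max(x) == min(x))
  # Spearman = Pearson on ranks; suppress sd-zero warnings, patch NAs to 0
  cc <- suppressWarnings(stats::cor(ra, rb[, cols_b, drop = FALSE]))
  cc[is.na(cc)] <- 0
  score_a <- apply(abs(cc), 1L, max)
  cc2 <- suppressWarnings(stats::cor(rb, ra[, cols_a, drop = FALSE]))
  cc2[is.na(cc2)] <- 0
  score_b <- apply(abs(cc2), 1L, max)
  score_a[const_a] <- 0
  score_b[const_b] <- 0
  scores <- pmin(c(score_a, score_b), 1)
  list(scores = scores, method = "rank_max_abs")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Harmonic mean
#'
#' `H = n / sum(1/f_i)` over a positive vector. The harmonic mean weights
#' small values more heavily than the arithmetic mean (H <= AM always), so a
#' threshold at H retains at least as many features as one at the arithmetic
#' mean.
#'
#' @param scores positive numeric vector (callers floor zeros at 1e-6).
#' @return a positive scalar.
#' @export
harmonic_mean <- function(scores) {
  if (length(scores) == 0L) stop("empty score vector")
  if (any(scores <= 0)) stop("harmonic mean requires positive entries")
  length(scores) / sum(1 / scores)
}

#' Serial--harmonic-mean fusion of two feature sources
#'
#' Concatenates the two sources, scores every column by its maximum absolute
#' cross-source rank correlation, computes the harmonic mean H of the
#' (epsilon-floored) scores, and keeps exactly the columns scoring >= H.
#'
#' @inheritParams correlation_scores
#' @return list of class `fused_features` with `matrix` (a `feature_matrix`
#'   of the kept columns), `kept_indices` (strictly increasing indices into
#'   the concatenated matrix), `scores` (all scores) and `threshold` (H).
#' @examples
#' spec <- feature_dataset_spec(n_samples = 30, d1 = 8, d2 = 8, seed = 1)
#' ds <- make_feature_dataset(spec)
#' fu <- fuse(ds$Fa, ds$Fb)
#' length(fu$kept_indices)
#' @export
fuse <- function(Fa, Fb, max_pairs = NULL, seed = 1L) {
  concat <- serial_concat(Fa, Fb)
  cs <- correlation_scores(Fa, Fb, max_pairs = max_pairs, seed = seed)
  scores <- pmax(cs$scores, 1e-6)
  H <- harmonic_mean(scores)
  keep <- which(scores >= H)
  if (length(keep) == 0L) {
    warning("harmonic threshold discarded every column; keeping the best one")
    keep <- which.max(scores)
  }
  out <- feature_matrix(concat$values[, keep, drop = FALSE],
                        labels = concat$labels,
                        column_ids = concat$column_ids[keep])
  structure(list(matrix = out, kept_indices = keep,
                 scores = cs$scores, threshold = H),
            class = "fused_features")
}

#' @export
print.fused_features <- function(x, ...) {
  cat(sprintf(
    "<fused_features: kept %d of %d columns (harmonic threshold %.4f)>\n",
    length(x$kept_indices), length(x$scores), x$threshold))
  invisible(x)
}

#' Read a feature matrix from CSV
#'
#' Expected layout: header row; first column `sample_id`; optional `label`
#' column; remaining columns are features.
#'
#' @param path CSV file path.
#' @param source origin tag for column ids.
#' @return a `feature_matrix`.
#' @export
read_features_csv <- function(path, source = "A") {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"sample_id" %in% names(df)[1])
    stop("first column must be 'sample_id'")
  labels <- NULL
  if ("label" %in% names(df)) {
    labels <- as.integer(df$label)
    df$label <- NULL
  }
  ids <- df$sample_id
  df$sample_id <- NULL
  m <- as.matrix(df)
  rownames(m) <- ids
  feature_matrix(m, labels = labels, column_ids = colnames(m), source = source)
}

#' Write a feature matrix to CSV
#'
#' Inverse of [read_features_csv()].
#'
#' @param fm a `feature_matrix`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(fm, path) {
  df <- as.data.frame(fm$values)
  names(df) <- fm$column_ids
  ids <- rownames(fm$values)
  if (is.null(ids)) ids <- paste0("s", seq_len(nrow(fm$values)))
  out <- cbind(data.frame(sample_id = ids), df)
  if (!is.null(fm$labels)) out <- cbind(out[1], label = fm$labels, df)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
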