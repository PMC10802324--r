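# Sample-mode PCA via thin SVD of the centered matrix, plus group centroids.
#
# Samples are the observations: each sample is a point in feature space,
# centering subtracts each feature's mean across samples. The covariance
# denominator is 1/(D-1); explained fractions are denominator-independent.

#' Center a feature matrix
#'
#' Subtracts each feature's mean across samples, so every feature row has
#' zero mean. Idempotent.
#'
#' @param m feature matrix (features x samples), finite.
#' @return list with `matrix` (centered) and `means` (the per-feature row
#'   means that were removed).
#' @export
center_matrix <- function(m) {
  validate_feature_matrix(m, require_finite = TRUE)
  mu <- rowMeans(m)
  list(matrix = m - mu, means = mu)
}

#' Principal component analysis of samples
#'
#' Computes the top `n_components` variance-maximizing orthogonal directions
#' of the sample cloud via thin SVD of the centered matrix (numerically
#' stable for many more features than samples; the explicit covariance
#' eigendecomposition is used only as a test oracle). The matrix is centered
#' internally regardless of input state.
#'
#' Each component's sign is fixed so that its largest-magnitude feature
#' loading is positive (ties broken by lowest feature index), making scores
#' reproducible across platforms.
#'
#' @param m feature matrix (N features x D samples), finite.
#' @param n_components number of components L, `1 <= L <= min(N, D)`.
#' @return object of class `pca_result`: list with
#'   \describe{
#'     \item{scores}{D x L matrix of sample coordinates (rownames = sample
#'       IDs, colnames = PC1..PCL); columns have zero mean and are mutually
#'       uncorrelated.}
#'     \item{loadings}{N x L matrix of feature loadings (orthonormal
#'       columns).}
#'     \item{eigenvalues}{variances of the score columns (1/(D-1)
#'       denominator), non-increasing.}
#'     \item{explained_fraction}{eigenvalues / total variance; sums to 1
#'       over all `min(N, D-1)` possible components.}
#'     \item{center}{the removed per-feature means.}
#'     \item{n_components}{L.}
#'   }
#' @export
compute_pca <- function(m, n_components = 2L) {
  validate_feature_matrix(m, require_finite = TRUE)
  n_features <- nrow(m)
  n_samples <- ncol(m)
  L <- as.integer(n_components)
  if (L < 1L || L > min(n_features, n_samples)) {
    stop("n_components must be between 1 and min(N features, D samples) = ",
         min(n_features, n_samples), call. = FALSE)
  }
  centered <- m - rowMeans(m)
  # samples as rows: D x N
  X <- t(centered)
  sv <- svd(X)
  total_var <- sum(sv$d^2) / (n_samples - 1L)
  if (total_var <= .Machine$double.eps * n_features) {
    stop("degenerate input: total variance is zero", call. = FALSE)
  }
  eig_all <- sv$d^2 / (n_samples - 1L)
  u <- sv$u[, seq_len(L), drop = FALSE]
  v <- sv$v[, seq_len(L), drop = FALSE]
  # sign convention: dominant loading positive, ties -> lowest feature index
  for (l in seq_len(L)) {
    j <- which.max(abs(v[, l]))
    if (v[j, l] < 0) {
      v[, l] <- -v[, l]
      u[, l] <- -u[, l]
    }
  }
  scores <- u * rep(sv$d[seq_len(L)], each = n_samples)
  dimnames(scores) <- list(colnames(m), paste0("PC", seq_len(L)))
  dimnames(v) <- list(rownames(m), paste0("PC", seq_len(L)))
  structure(list(scores = scores,
                 loadings = v,
                 eigenvalues = eig_all[seq_len(L)],
                 explained_fraction = eig_all[seq_len(L)] / total_var,
                 total_variance = total_var,
                 center = rowMeans(m),
                 n_components = L),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("pca_result:", nrow(x$scores), "samples,", x$n_components,
      "component(s)\n")
  cat("explained variance:",
      paste0(sprintf("%.1f", 100 * x$explained_fraction), "%",
             collapse = ", "), "\n")
  invisible(x)
}

#' Per-group centroids of PCA scores
#'
#' The centroid of group k is the arithmetic mean of the score rows of its
#' members. Because scores are centered, the size-weighted mean of the
#' centroids is the origin. Levels declared in the annotation's
#' `level_order` but absent among analyzed samples are omitted with a
#' warning.
#'
#' @param pca a `pca_result`.
#' @param annotation a `sample_annotation` labeling (at least) the analyzed
#'   samples.
#' @param variable grouping variable name.
#' @return object of class `group_centroids`: list with `centroids`
#'   (K x L matrix, rownames = group labels, in level order), `group_labels`,
#'   `group_sizes`, `variable`.
#' @export
compute_centroids <- function(pca, annotation, variable) {
  stopifnot(inherits(pca, "pca_result"))
  labels <- annotation_labels(annotation, variable,
                              samples = rownames(pca$scores))
  if (anyNA(labels)) {
    stop(sum(is.na(labels)), " analyzed sample(s) lack a '", variable,
         "' label; align samples before PCA", call. = FALSE)
  }
  level_order <- annotation_level_order(annotation, variable)
  missing_levels <- setdiff(level_order, labels)
  if (length(missing_levels)) {
    warning("group(s) with no analyzed member omitted: ",
            paste(missing_levels, collapse = ", "), call. = FALSE)
    level_order <- setdiff(level_order, missing_levels)
  }
  f <- factor(labels, levels = level_order)
  sizes <- as.integer(table(f))
  centroids <- rowsum(pca$scores, f) / sizes
  structure(list(centroids = centroids,
                 group_labels = level_order,
                 group_sizes = sizes,
                 variable = variable),
            class = "group_centroids")
}

#' @export
print.group_centroids <- function(x, ...) {
  cat("group_centroids for '", x$variable, "': ", length(x$group_labels),
      " group(s)\n", sep = "")
  print(cbind(size = x$group_sizes, x$centroids))
  invisible(x)
}

#' Write PCA scores to TSV
#'
#' Columns: `sample_id`, `PC1`..`PCL`.
#' @param pca a `pca_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(pca, path) {
  df <- data.frame(sample_id = rownames(pca$scores), pca$scores,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write group centroids to TSV
#'
#' Columns: `group`, `size`, `PC1`..`PCL`.
#' @param centroids a `group_centroids`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_centroids <- function(centroids, path) {
  df <- data.frame(group = centroids$group_labels,
                   size = centroids$group_sizes,
                   centroids$centroids, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
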