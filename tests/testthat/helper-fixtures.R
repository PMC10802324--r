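# Shared fixture builders: everything is generated in code at test time.

# small labeled feature matrix with dimnames
random_feature_matrix <- function(n_features, n_samples) {
  m <- matrix(rnorm(n_features * n_samples), nrow = n_features,
              dimnames = list(sprintf("g%03d", seq_len(n_features)),
                              sprintf("s%03d", seq_len(n_samples))))
  m
}

# random (data, labels) instance in sample-rows orientation for DSC tests;
# guarantees >= 2 groups with >= 2 members each (avoids the size-1 warning)
random_dsc_instance <- function(n_samples, n_dims, n_groups) {
  data <- matrix(rnorm(n_samples * n_dims), nrow = n_samples)
  k <- max(2L, min(n_groups, n_samples %/% 2L))
  labels <- sample(rep_len(paste0("grp", seq_len(k)), n_samples))
  list(data = data, labels = labels)
}

# brute-force PCA oracle: eigendecomposition of the explicit sample-space
# covariance matrix (independent of the SVD path under test)
pca_covariance_oracle <- function(m, L) {
  X <- t(m - rowMeans(m))              # samples x features
  S <- stats::cov(X)                   # 1/(D-1) denominator
  e <- eigen(S, symmetric = TRUE)
  eigenvalues <- pmax(e$values, 0)
  scores <- X %*% e$vectors[, seq_len(L), drop = FALSE]
  list(eigenvalues = eigenvalues[seq_len(L)], scores = scores,
       total = sum(eigenvalues))
}

# annotation wrapper around a label vector
labels_annotation <- function(sample_ids, labels, variable = "batch",
                              level_order = NULL) {
  vars <- data.frame(labels, stringsAsFactors = FALSE)
  names(vars) <- variable
  lo <- if (is.null(level_order)) list() else
    stats::setNames(list(level_order), variable)
  sample_annotation(sample_ids, vars, level_order = lo)
}

write_tsv_matrix_file <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
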