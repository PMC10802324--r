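# Synthetic grouped Gaussian data emulating batch-effect scenarios in
# molecular profiling matrices: between-batch mean shifts, temporal drift
# of batch means, and a hidden binary variable (e.g. sex-linked probes)
# cutting across batches.

#' Specification for synthetic grouped data
#'
#' Defines a grouped spherical-Gaussian scenario. Defaults describe a
#' moderate three-batch experiment: 20 samples per batch, 200 features,
#' unit within-group standard deviation.
#'
#' @param n_groups number of groups/batches K (>= 1).
#' @param samples_per_group integer vector of group sizes (recycled to K).
#' @param n_features number of features d.
#' @param group_mean_shift per-feature mean shift delta between consecutive
#'   groups (group j mean = (j-1) * delta along the shift subspace).
#' @param within_sd within-group standard deviation sigma (> 0), identical
#'   for every feature.
#' @param shift_subspace where the shift lives: `"all-features"` (every
#'   feature shifted by the same amount), `"first-axis"` (only feature 1),
#'   or `"random-direction"` (a random unit vector; delta is the shift in
#'   Euclidean norm).
#' @param drift_per_step per-step displacement for [generate_trend()].
#' @param dichotomy_fraction fraction of features carrying the hidden
#'   binary effect in [generate_dichotomy()].
#' @param dichotomy_effect half-separation of the hidden dichotomy: affected
#'   features are shifted by +effect for one level and -effect for the
#'   other.
#' @param seed integer seed; generation is exactly reproducible from
#'   (spec, seed).
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_groups = 3L, samples_per_group = 20L,
                           n_features = 200L, group_mean_shift = 1,
                           within_sd = 1,
                           shift_subspace = c("all-features", "first-axis",
                                              "random-direction"),
                           drift_per_step = 0, dichotomy_fraction = 0.1,
                           dichotomy_effect = 0, seed = 1L) {
  shift_subspace <- match.arg(shift_subspace)
  n_groups <- as.integer(n_groups)
  samples_per_group <- rep_len(as.integer(samples_per_group), n_groups)
  n_features <- as.integer(n_features)
  if (n_groups < 1L || any(samples_per_group < 1L) || n_features < 1L) {
    stop("counts must be positive", call. = FALSE)
  }
  if (within_sd <= 0) stop("within_sd must be > 0", call. = FALSE)
  if (dichotomy_fraction < 0 || dichotomy_fraction > 1) {
    stop("dichotomy_fraction must be in [0, 1]", call. = FALSE)
  }
  structure(list(n_groups = n_groups, samples_per_group = samples_per_group,
                 n_features = n_features, group_mean_shift = group_mean_shift,
                 within_sd = within_sd, shift_subspace = shift_subspace,
                 drift_per_step = drift_per_step,
                 dichotomy_fraction = dichotomy_fraction,
                 dichotomy_effect = dichotomy_effect,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

.shift_direction <- function(spec) {
  # drawn first from the seeded stream so group structure is reproducible
  switch(spec$shift_subspace,
    "all-features" = rep(1, spec$n_features),
    "first-axis" = c(1, rep(0, spec$n_features - 1L)),
    "random-direction" = {
      u <- stats::rnorm(spec$n_features)
      u / sqrt(sum(u^2))
    })
}

.generate_core <- function(spec, step) {
  k <- spec$n_groups
  sizes <- spec$samples_per_group
  n <- sum(sizes)
  d <- spec$n_features
  direction <- .shift_direction(spec)
  batch <- rep(paste0("b", seq_len(k)), times = sizes)
  # features x samples noise, then add group means feature-wise
  values <- matrix(stats::rnorm(d * n, sd = spec$within_sd), nrow = d)
  offsets <- outer(direction, (match(batch, unique(batch)) - 1L) * step)
  values <- values + offsets
  dimnames(values) <- list(sprintf("f%04d", seq_len(d)),
                           sprintf("s%03d", seq_len(n)))
  list(values = values, batch = batch, direction = direction)
}

#' Generate grouped Gaussian data with batch mean shifts
#'
#' Samples are drawn from spherical Gaussians; the mean of batch j is
#' displaced by `(j - 1) * group_mean_shift` along the chosen shift
#' subspace. The annotation carries a `"batch"` variable with explicit
#' level order `b1 < b2 < ...`.
#'
#' @param spec a `synthetic_spec`.
#' @return list with `matrix` (features x samples), `annotation`
#'   (a `sample_annotation`), `direction` (the shift direction vector) and
#'   `spec`.
#' @export
generate_grouped <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  core <- withr::with_seed(spec$seed,
                           .generate_core(spec, spec$group_mean_shift))
  ann <- sample_annotation(
    colnames(core$values),
    data.frame(batch = core$batch, stringsAsFactors = FALSE),
    level_order = list(batch = unique(core$batch)))
  list(matrix = core$values, annotation = ann, direction = core$direction,
       spec = spec)
}

#' Generate temporally drifting batches
#'
#' Ordered batches whose means advance by `drift_per_step` per batch along
#' a fixed direction, emulating slow drift of an assay over time. The
#' `"batch"` variable is ordinal with explicit level order. With
#' `drift_per_step = 0` this reduces to [generate_grouped()] with no shift.
#'
#' @param spec a `synthetic_spec` (the drift magnitude comes from
#'   `drift_per_step`; `group_mean_shift` is ignored).
#' @return as [generate_grouped()].
#' @export
generate_trend <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  core <- withr::with_seed(spec$seed,
                           .generate_core(spec, spec$drift_per_step))
  ann <- sample_annotation(
    colnames(core$values),
    data.frame(batch = core$batch, stringsAsFactors = FALSE),
    level_order = list(batch = unique(core$batch)))
  list(matrix = core$values, annotation = ann, direction = core$direction,
       spec = spec)
}

#' Generate data with a hidden binary dichotomy
#'
#' On top of the batch structure of [generate_grouped()], every sample is
#' assigned a hidden binary variable `"sex"`; a designated fraction of the
#' features (IDs prefixed `sexlinked_`) is shifted by `+dichotomy_effect`
#' for level `M` and `-dichotomy_effect` for level `F`. Sex is balanced
#' within each batch, so the two variables are unassociated by design and
#' the dichotomy cannot be explained by any batch. Removing the
#' `sexlinked_` features with [exclude_features()] eliminates the
#' dichotomy.
#'
#' @param spec a `synthetic_spec` with `dichotomy_fraction > 0`.
#' @return list with `matrix`, `annotation` (variables `batch` and `sex`),
#'   `affected_features` (the prefixed IDs), `direction`, `spec`.
#' @export
generate_dichotomy <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$dichotomy_fraction <= 0) {
    stop("dichotomy_fraction must be > 0", call. = FALSE)
  }
  res <- withr::with_seed(spec$seed, {
    core <- .generate_core(spec, spec$group_mean_shift)
    sizes <- spec$samples_per_group
    sex <- unlist(lapply(sizes, function(s) {
      sample(rep_len(c("F", "M"), s))
    }), use.names = FALSE)
    n_affected <- max(1L, round(spec$dichotomy_fraction * spec$n_features))
    affected <- seq_len(n_affected)
    signs <- ifelse(sex == "M", 1, -1)
    core$values[affected, ] <- core$values[affected, , drop = FALSE] +
      spec$dichotomy_effect * rep(signs, each = n_affected)
    rownames(core$values)[affected] <-
      paste0("sexlinked_", rownames(core$values)[affected])
    list(core = core, sex = sex,
         affected = rownames(core$values)[affected])
  })
  core <- res$core
  ann <- sample_annotation(
    colnames(core$values),
    data.frame(batch = core$batch, sex = res$sex, stringsAsFactors = FALSE),
    level_order = list(batch = unique(core$batch)))
  list(matrix = core$values, annotation = ann,
       affected_features = res$affected, direction = core$direction,
       spec = spec)
}

#' Per-batch mean-centering correction
#'
#' A deliberately simple location correction for before/after DSC
#' quantitation: for each feature, the batch mean is subtracted and the
#' global feature mean restored. A pure mean-shift batch effect is removed
#' exactly (post-correction between-batch dispersion is zero); effects of
#' an independent, within-batch-balanced variable are left in place.
#' Distribution-level corrections (e.g. empirical-Bayes shrinkage of both
#' location and scale) are intentionally out of scope.
#'
#' @param m feature matrix (features x samples), finite.
#' @param annotation a `sample_annotation`.
#' @param variable batch variable name.
#' @return corrected matrix with the same dimnames.
#' @export
mean_center_by_batch <- function(m, annotation, variable = "batch") {
  aligned <- align_samples(m, annotation, variable)
  m <- aligned$matrix
  f <- factor(aligned$labels)
  sizes <- tabulate(f)
  # batch means per feature: features x K
  batch_means <- t(rowsum(t(m), f) / sizes)
  corrected <- m - batch_means[, as.integer(f), drop = FALSE] + rowMeans(m)
  dimnames(corrected) <- dimnames(m)
  corrected
}

#' Write synthetic data to disk
#'
#' Emits the matrix TSV, annotation TSV and the generating spec as JSON.
#'
#' @param data result of a `generate_*()` function.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return named character vector of written paths, invisibly.
#' @export
write_synthetic <- function(data, dir, prefix = "synthetic") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(matrix = file.path(dir, paste0(prefix, "_matrix.tsv")),
             annotation = file.path(dir, paste0(prefix, "_annotation.tsv")),
             spec = file.path(dir, paste0(prefix, "_spec.json")))
  write_matrix(data$matrix, paths[["matrix"]])
  ann_df <- data.frame(sample = data$annotation$sample_ids,
                       data$annotation$variables,
                       check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(ann_df, paths[["annotation"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(unclass(data$spec), paths[["spec"]],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
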