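# Dispersion Separability Criterion (DSC).
#
# DSC = D_b / D_w, where D_b^2 = trace(S_b) and D_w^2 = trace(S_w) with
# between-group scatter S_b = sum_j pi_j (mu_j - M_o)(mu_j - M_o)^T and
# within-group scatter S_w = sum_j pi_j Sigma_j, pi_j = s_j / N estimated
# from group sizes. The trace identities collapse both to streaming sums of
# squared deviations (no matrix products), which is how dsc_fast computes
# them; dsc_naive builds the scatter matrices explicitly and serves as the
# independent oracle for the equivalence.

# Shared computational core; no validation, never errors on degenerate
# dispersion. Returns db, dw and a dsc that is Inf when dw = 0 < db and 0
# when both vanish (callers decide how to surface those cases).
.dsc_core <- function(data, f) {
  n <- nrow(data)
  gi <- as.integer(f)
  sizes <- tabulate(gi, nbins = nlevels(f))
  group_means <- rowsum(data, gi) / sizes  # rows sorted by group index 1..K
  global_mean <- colMeans(data)
  # Db^2 = (1/N) sum_j s_j sum_i (mu_ij - M_i)^2
  db2 <- sum(sizes * rowSums(sweep(group_means, 2L, global_mean)^2)) / n
  # Dw^2 = (1/N) sum_j sum_h sum_i (x_hij - mu_ij)^2
  dev <- data - group_means[gi, , drop = FALSE]
  dw2 <- sum(dev * dev) / n
  db <- sqrt(db2)
  dw <- sqrt(dw2)
  dsc <- if (dw > 0) db / dw else if (db > 0) Inf else 0
  list(db = db, dw = dw, dsc = dsc)
}

.check_grouping <- function(data, labels) {
  if (!is.matrix(data)) data <- as.matrix(data)
  if (!is.numeric(data) || !all(is.finite(data))) {
    stop("data must be a finite numeric matrix (samples x dimensions)",
         call. = FALSE)
  }
  if (length(labels) != nrow(data)) {
    stop("labels must have one entry per sample (matrix row)", call. = FALSE)
  }
  f <- droplevels(factor(labels))
  if (nlevels(f) < 2L) {
    stop("need at least 2 groups, got ", nlevels(f), call. = FALSE)
  }
  if (any(tabulate(f) == 1L)) {
    warning("group(s) of size 1 present; they contribute nothing to the ",
            "within-group dispersion, and a single outlier sample can ",
            "inflate the DSC while its p-value stays non-significant",
            call. = FALSE)
  }
  list(data = data, f = f)
}

.dsc_result <- function(core, n_samples, n_groups, space_tag) {
  if (core$dw == 0) {
    if (core$db > 0) {
      stop("zero within-group dispersion (Dw = 0) with Db = ", core$db,
           "; DSC is undefined", call. = FALSE)
    }
    warning("degenerate data: zero between- and within-group dispersion; ",
            "DSC defined as 0", call. = FALSE)
  }
  structure(list(dsc = core$dsc, db = core$db, dw = core$dw,
                 n_samples = n_samples, n_groups = n_groups,
                 space_tag = space_tag),
            class = "dsc_result")
}

#' Dispersion Separability Criterion (fast trace form)
#'
#' Quantifies how dispersed group centroids are relative to the dispersion
#' of samples within their groups: `DSC = Db / Dw`, where `Db^2` is the
#' size-weighted mean squared distance of group means from the global mean
#' and `Dw^2` is the mean squared distance of samples from their group
#' mean. Computed via streaming sums of squared deviations — no scatter
#' matrix is ever formed — so it scales to many thousands of dimensions.
#'
#' Rule of thumb (see [interpret_dsc()]): below 0.3 the groups are
#' reasonably consistent, 0.3–0.6 indicates moderate differences, above
#' 0.6 strong differences.
#'
#' @param data numeric matrix, samples in rows, dimensions (features or PC
#'   scores) in columns; finite.
#' @param labels group assignment, one per sample (>= 2 groups, each with
#'   >= 1 member).
#' @param space_tag label recording which space `data` lives in
#'   (`"overall"` for the full feature space, `"pca-L"` for L score
#'   columns).
#' @return object of class `dsc_result`: list with `dsc`, `db`, `dw`,
#'   `n_samples`, `n_groups`, `space_tag`. `db^2 + dw^2` equals the total
#'   mean squared deviation about the global mean (law of total variance).
#' @export
#' @examples
#' x <- matrix(c(0, 1, 3, 4), ncol = 1)
#' dsc_fast(x, c("A", "A", "B", "B"))  # Db = 1.5, Dw = 0.5, DSC = 3
dsc_fast <- function(data, labels, space_tag = "overall") {
  g <- .check_grouping(data, labels)
  core <- .dsc_core(g$data, g$f)
  .dsc_result(core, nrow(g$data), nlevels(g$f), space_tag)
}

#' Dispersion Separability Criterion (explicit scatter matrices)
#'
#' Reference implementation that forms the within-group scatter matrix
#' `S_w = sum_j pi_j Sigma_j` and between-group scatter matrix
#' `S_b = sum_j pi_j (mu_j - M_o)(mu_j - M_o)^T` explicitly
#' (`pi_j = s_j / N`; `Sigma_j` the mean squared-deviation matrix about the
#' group mean) and returns `Db = sqrt(trace(S_b))`, `Dw = sqrt(trace(S_w))`.
#' Algebraically identical to [dsc_fast()] but quadratic in the number of
#' dimensions; retained as the independent test oracle for the trace-form
#' computation.
#'
#' @inheritParams dsc_fast
#' @return a `dsc_result` (see [dsc_fast()]).
#' @export
dsc_naive <- function(data, labels, space_tag = "overall") {
  g <- .check_grouping(data, labels)
  data <- g$data
  f <- g$f
  n <- nrow(data)
  d <- ncol(data)
  sizes <- tabulate(f)
  pi_j <- sizes / n
  global_mean <- colMeans(data)
  s_w <- matrix(0, d, d)
  s_b <- matrix(0, d, d)
  for (j in seq_len(nlevels(f))) {
    xj <- data[as.integer(f) == j, , drop = FALSE]
    mu_j <- colMeans(xj)
    dev <- sweep(xj, 2L, mu_j)
    s_w <- s_w + pi_j[j] * crossprod(dev) / sizes[j]
    diff <- mu_j - global_mean
    s_b <- s_b + pi_j[j] * tcrossprod(diff)
  }
  core <- list(db = sqrt(sum(diag(s_b))), dw = sqrt(sum(diag(s_w))))
  core$dsc <- if (core$dw > 0) core$db / core$dw else if (core$db > 0) Inf else 0
  .dsc_result(core, n, nlevels(f), space_tag)
}

#' @export
print.dsc_result <- function(x, ...) {
  cat(sprintf("DSC = %.4g (Db = %.4g, Dw = %.4g) [%s] %d samples, %d groups -> %s\n",
              x$dsc, x$db, x$dw, x$space_tag, x$n_samples, x$n_groups,
              interpret_dsc(min(x$dsc, .Machine$double.xmax))))
  invisible(x)
}

#' Permutation-test p-value for the DSC
#'
#' Shuffles the group labels uniformly at random `n_perm` times, keeping
#' the group sizes identical to the observed assignment, and recomputes the
#' DSC each time. The one-tailed p-value is the fraction of permuted DSC
#' values greater than or equal to the observed DSC (ties count toward the
#' null), under the null hypothesis that samples are exchangeable with
#' respect to group. Permutations are sampled with replacement from the
#' assignment space; duplicates are permitted.
#'
#' A permutation in which the within-group dispersion vanishes while group
#' means differ yields an infinite DSC and counts toward the null; fully
#' degenerate permutations (both dispersions zero) yield DSC 0.
#'
#' @inheritParams dsc_fast
#' @param n_perm number of permutations (default 2000, resolving p-values
#'   down to 0.0005).
#' @param seed integer seed making the null reproducible; the caller's RNG
#'   state is left untouched. `NULL` uses (and advances) the current RNG
#'   stream.
#' @param smooth if TRUE, use the add-one estimate
#'   `(count + 1) / (n_perm + 1)` instead of the plain fraction
#'   `count / n_perm` (default FALSE).
#' @return object of class `dsc_permutation`: list with `observed_dsc`,
#'   `null_dsc` (length `n_perm`), `n_perm`, `p_value`, `seed`, `smooth`.
#' @export
permutation_test <- function(data, labels, n_perm = 2000L, seed = NULL,
                             smooth = FALSE) {
  n_perm <- as.integer(n_perm)
  if (n_perm < 1L) stop("n_perm must be >= 1", call. = FALSE)
  g <- .check_grouping(data, labels)
  observed <- .dsc_core(g$data, g$f)$dsc
  run <- function() {
    null_dsc <- numeric(n_perm)
    for (b in seq_len(n_perm)) {
      null_dsc[b] <- .dsc_core(g$data, sample(g$f))$dsc
    }
    null_dsc
  }
  null_dsc <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  count <- sum(null_dsc >= observed)
  p <- if (smooth) (count + 1) / (n_perm + 1) else count / n_perm
  structure(list(observed_dsc = observed, null_dsc = null_dsc,
                 n_perm = n_perm, p_value = p,
                 seed = if (is.null(seed)) NA_integer_ else seed,
                 smooth = smooth),
            class = "dsc_permutation")
}

#' @export
print.dsc_permutation <- function(x, ...) {
  cat(sprintf("permutation test: observed DSC = %.4g, p = %.4g (%d permutations)\n",
              x$observed_dsc, x$p_value, x$n_perm))
  invisible(x)
}

#' Qualitative interpretation of a DSC value
#'
#' Rule of thumb for group separation: values below 0.3 indicate reasonable
#' consistency among groups (`"low"`, e.g. low batch effects), values in
#' the closed interval \[0.3, 0.6\] moderate differences (`"moderate"`),
#' and values above 0.6 strong differences (`"strong"`, e.g. batch effects
#' that likely require correction). Always weigh the interpretation
#' together with the permutation p-value: an outlier-driven DSC can be
#' large yet non-significant with few samples per group, and a tiny DSC
#' can be significant with many.
#'
#' @param dsc numeric vector of non-negative DSC values.
#' @return character vector: `"low"`, `"moderate"` or `"strong"`.
#' @export
#' @examples
#' interpret_dsc(c(0.2, 0.45, 0.7))
interpret_dsc <- function(dsc) {
  if (!is.numeric(dsc) || any(is.na(dsc)) || any(dsc < 0)) {
    stop("dsc must be non-negative", call. = FALSE)
  }
  ifelse(dsc < 0.3, "low", ifelse(dsc <= 0.6, "moderate", "strong"))
}

#' Paired DSC report: full feature space and plotted components
#'
#' Computes the DSC twice for one grouping variable — on the full filtered
#' feature space ("overall") and on the L retained PCA score columns
#' ("pca-L", the space shown in the plots) — each with its own permutation
#' p-value. Both permutation runs draw from a single seeded stream, so the
#' whole report is reproducible from `seed`.
#'
#' @param m feature matrix (features x samples), filtered/finite.
#' @param pca a `pca_result` computed from `m` (same samples).
#' @param annotation a `sample_annotation`.
#' @param variable grouping variable name.
#' @param n_perm permutations per space (default 2000).
#' @param seed integer seed (default 20231).
#' @param smooth passed to [permutation_test()].
#' @return object of class `dsc_report`: list with `table` (a data.frame
#'   with columns variable, space, n_samples, n_groups, Db, Dw, DSC,
#'   p_value, n_perm, interpretation) and the underlying `overall` /
#'   `pca` result pairs.
#' @export
dsc_report <- function(m, pca, annotation, variable, n_perm = 2000L,
                       seed = 20231L, smooth = FALSE) {
  stopifnot(inherits(pca, "pca_result"))
  validate_feature_matrix(m, require_finite = TRUE)
  samples <- rownames(pca$scores)
  if (!all(samples %in% colnames(m))) {
    stop("PCA scores contain samples absent from the matrix", call. = FALSE)
  }
  labels <- annotation_labels(annotation, variable, samples = samples)
  if (anyNA(labels)) {
    stop(sum(is.na(labels)), " analyzed sample(s) lack a '", variable,
         "' label", call. = FALSE)
  }
  overall_data <- t(m[, samples, drop = FALSE])
  pca_tag <- paste0("pca-", pca$n_components)
  run_all <- function() {
    list(overall = list(
           dsc = dsc_fast(overall_data, labels, space_tag = "overall"),
           perm = permutation_test(overall_data, labels, n_perm = n_perm)),
         pca = list(
           dsc = dsc_fast(pca$scores, labels, space_tag = pca_tag),
           perm = permutation_test(pca$scores, labels, n_perm = n_perm)))
  }
  res <- if (is.null(seed)) run_all() else withr::with_seed(seed, run_all())
  if (smooth) {
    for (nm in c("overall", "pca")) {
      pr <- res[[nm]]$perm
      res[[nm]]$perm$p_value <- (sum(pr$null_dsc >= pr$observed_dsc) + 1) /
        (pr$n_perm + 1)
      res[[nm]]$perm$smooth <- TRUE
    }
  }
  row_of <- function(x) {
    data.frame(variable = variable, space = x$dsc$space_tag,
               n_samples = x$dsc$n_samples, n_groups = x$dsc$n_groups,
               Db = x$dsc$db, Dw = x$dsc$dw, DSC = x$dsc$dsc,
               p_value = x$perm$p_value, n_perm = x$perm$n_perm,
               interpretation = interpret_dsc(x$dsc$dsc),
               stringsAsFactors = FALSE)
  }
  structure(list(table = rbind(row_of(res$overall), row_of(res$pca)),
                 overall = res$overall, pca = res$pca,
                 variable = variable, seed = seed),
            class = "dsc_report")
}

#' @export
print.dsc_report <- function(x, ...) {
  cat("DSC report for '", x$variable, "':\n", sep = "")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write a DSC report table to TSV
#'
#' @param report a `dsc_report` (or a list of them; tables are stacked).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dsc_report <- function(report, path) {
  tab <- if (inherits(report, "dsc_report")) report$table
         else do.call(rbind, lapply(report, function(r) r$table))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
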