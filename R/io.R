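# Matrix and annotation I/O, sample alignment, feature filtering.
#
# A feature matrix is a plain numeric matrix: features in rows (rownames =
# feature IDs), samples in columns (colnames = sample IDs). Delimited files
# follow the dominant omics convention: first column = feature IDs, header
# row = sample IDs, tab-delimited by default.

#' Validate a feature matrix
#'
#' Checks the structural invariants of a feature-by-sample matrix: numeric,
#' at least 1 feature and 2 samples, unique row and column identifiers.
#' Non-finite values are permitted unless `require_finite = TRUE` (analysis
#' functions require finite input; use [filter_features()] first).
#'
#' @param m numeric matrix, features in rows, samples in columns, with
#'   rownames and colnames set.
#' @param require_finite error if any value is `NA`/`NaN`/`Inf`.
#' @return `m`, invisibly.
#' @export
validate_feature_matrix <- function(m, require_finite = FALSE) {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop("feature matrix must be a numeric matrix", call. = FALSE)
  }
  if (nrow(m) < 1L) stop("feature matrix has no features", call. = FALSE)
  if (ncol(m) < 2L) {
    stop("feature matrix needs at least 2 samples, got ", ncol(m),
         call. = FALSE)
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("feature matrix must carry feature IDs (rownames) and sample IDs (colnames)",
         call. = FALSE)
  }
  dup_f <- rownames(m)[duplicated(rownames(m))]
  if (length(dup_f)) {
    stop("duplicate feature ID(s): ", paste(unique(dup_f), collapse = ", "),
         call. = FALSE)
  }
  dup_s <- colnames(m)[duplicated(colnames(m))]
  if (length(dup_s)) {
    stop("duplicate sample ID(s): ", paste(unique(dup_s), collapse = ", "),
         call. = FALSE)
  }
  if (require_finite && !all(is.finite(m))) {
    stop("feature matrix contains non-finite values; run filter_features() first",
         call. = FALSE)
  }
  invisible(m)
}

#' Read a feature-by-sample matrix
#'
#' Delimited files (`tsv`, `csv`) must have a header row of sample IDs and a
#' first column of feature IDs. MatrixMarket (`mtx`) files must be
#' accompanied by sidecar ID files `<path>.rows` (feature IDs, one per line)
#' and `<path>.cols` (sample IDs).
#'
#' @param path file path.
#' @param format one of `"tsv"`, `"csv"`, `"mtx"`; default guessed from the
#'   file extension, falling back to `"tsv"`.
#' @return numeric matrix with feature IDs as rownames and sample IDs as
#'   colnames, in file order.
#' @export
read_matrix <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("tsv", "csv", "mtx")) ext else "tsv"
  }
  format <- match.arg(format, c("tsv", "csv", "mtx"))
  if (format == "mtx") {
    return(.read_matrix_mtx(path))
  }
  sep <- if (format == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          comment.char = "", check.names = FALSE,
                          stringsAsFactors = FALSE,
                          colClasses = NA)
  if (ncol(df) < 2L) {
    stop("malformed header in ", path,
         ": expected a feature-ID column plus at least one sample column",
         call. = FALSE)
  }
  feature_ids <- as.character(df[[1L]])
  sample_ids <- colnames(df)[-1L]
  for (j in seq_along(sample_ids)) {
    col <- df[[j + 1L]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))) & !is.na(col))[1L]
      stop("non-numeric value in column '", sample_ids[j], "'",
           if (!is.na(bad)) paste0(", row '", feature_ids[bad], "'"),
           call. = FALSE)
    }
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  dimnames(m) <- list(feature_ids, sample_ids)
  validate_feature_matrix(m)
  m
}

.read_matrix_mtx <- function(path) {
  rows_path <- paste0(path, ".rows")
  cols_path <- paste0(path, ".cols")
  if (!file.exists(rows_path) || !file.exists(cols_path)) {
    stop("MTX sidecar ID files missing: expected ", rows_path, " and ",
         cols_path, call. = FALSE)
  }
  mm <- Matrix::readMM(path)
  feature_ids <- readLines(rows_path)
  sample_ids <- readLines(cols_path)
  if (length(feature_ids) != nrow(mm)) {
    stop("row ID file has ", length(feature_ids), " IDs but matrix has ",
         nrow(mm), " rows", call. = FALSE)
  }
  if (length(sample_ids) != ncol(mm)) {
    stop("column ID file has ", length(sample_ids), " IDs but matrix has ",
         ncol(mm), " columns", call. = FALSE)
  }
  m <- as.matrix(mm)
  dimnames(m) <- list(feature_ids, sample_ids)
  validate_feature_matrix(m)
  m
}

#' Write a feature-by-sample matrix
#'
#' Inverse of [read_matrix()] for delimited formats: first column `id` holds
#' feature IDs, header row holds sample IDs. `mtx` writes a MatrixMarket
#' file plus `<path>.rows` / `<path>.cols` sidecar ID files.
#'
#' @param m numeric matrix with dimnames (see [validate_feature_matrix()]).
#' @param path output file path.
#' @param format `"tsv"` (default), `"csv"` or `"mtx"`.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, format = c("tsv", "csv", "mtx")) {
  format <- match.arg(format)
  validate_feature_matrix(m)
  if (format == "mtx") {
    Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), path)
    writeLines(rownames(m), paste0(path, ".rows"))
    writeLines(colnames(m), paste0(path, ".cols"))
    return(invisible(path))
  }
  sep <- if (format == "tsv") "\t" else ","
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a sample annotation object
#'
#' Holds one or more categorical/ordinal variables per sample (batch ID,
#' ship date, sex, subtype, ...), with optional explicit level orderings
#' used by trend trajectories.
#'
#' @param sample_ids character vector of unique sample IDs.
#' @param variables data.frame (one row per sample) of character label
#'   columns, or a named list coercible to one.
#' @param level_order optional named list: variable name -> ordered
#'   character vector containing every observed level of that variable
#'   exactly once.
#' @return object of class `sample_annotation`.
#' @export
sample_annotation <- function(sample_ids, variables, level_order = list()) {
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ID(s): ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  variables <- as.data.frame(variables, stringsAsFactors = FALSE)
  if (nrow(variables) != length(sample_ids)) {
    stop("variables must have one row per sample", call. = FALSE)
  }
  variables[] <- lapply(variables, as.character)
  rownames(variables) <- sample_ids
  for (v in names(level_order)) {
    if (!v %in% names(variables)) {
      stop("level_order refers to unknown variable '", v, "'", call. = FALSE)
    }
    obs <- unique(stats::na.omit(variables[[v]]))
    lo <- level_order[[v]]
    if (anyDuplicated(lo) || !setequal(lo, obs)) {
      stop("level_order for '", v,
           "' must contain every observed level exactly once", call. = FALSE)
    }
  }
  structure(list(sample_ids = sample_ids, variables = variables,
                 level_order = level_order),
            class = "sample_annotation")
}

#' @export
print.sample_annotation <- function(x, ...) {
  cat("sample_annotation:", length(x$sample_ids), "samples,",
      ncol(x$variables), "variable(s):",
      paste(names(x$variables), collapse = ", "), "\n")
  invisible(x)
}

#' Read a sample annotation table
#'
#' Expects a TSV with a sample-ID column (named `sample`, `sample_id` or
#' `id`, case-insensitive; otherwise the first column is used with a
#' message) and one column per annotation variable.
#'
#' @param path TSV file path.
#' @param variables optional character vector restricting to these
#'   variables; an absent variable is an error listing the available ones.
#' @param level_order optional named list of explicit level orderings,
#'   passed to [sample_annotation()].
#' @return a `sample_annotation`.
#' @export
read_annotations <- function(path, variables = NULL, level_order = list()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "\"",
                          comment.char = "", check.names = FALSE,
                          stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(df) < 2L) {
    stop("annotation table needs a sample-ID column plus at least one variable",
         call. = FALSE)
  }
  id_idx <- which(tolower(colnames(df)) %in% c("sample", "sample_id", "id"))[1L]
  if (is.na(id_idx)) {
    id_idx <- 1L
    message("no column named sample/sample_id/id; using first column '",
            colnames(df)[1L], "' as sample IDs")
  }
  ids <- df[[id_idx]]
  vars <- df[, -id_idx, drop = FALSE]
  if (!is.null(variables)) {
    missing_v <- setdiff(variables, colnames(vars))
    if (length(missing_v)) {
      stop("variable(s) not found: ", paste(missing_v, collapse = ", "),
           "; available: ", paste(colnames(vars), collapse = ", "),
           call. = FALSE)
    }
    vars <- vars[, variables, drop = FALSE]
  }
  n_missing <- sum(!stats::complete.cases(vars))
  if (n_missing > 0L) {
    message(n_missing, " sample(s) lack a label for at least one variable")
  }
  sample_annotation(ids, vars, level_order = level_order)
}

#' Extract per-sample labels for one variable
#'
#' @param annotation a `sample_annotation`.
#' @param variable variable name.
#' @param samples optional character vector of sample IDs; labels are
#'   returned in this order (`NA` where unknown).
#' @return named character vector of labels.
#' @export
annotation_labels <- function(annotation, variable, samples = NULL) {
  stopifnot(inherits(annotation, "sample_annotation"))
  if (!variable %in% names(annotation$variables)) {
    stop("variable '", variable, "' not found; available: ",
         paste(names(annotation$variables), collapse = ", "), call. = FALSE)
  }
  labels <- annotation$variables[[variable]]
  names(labels) <- annotation$sample_ids
  if (is.null(samples)) labels else labels[samples]
}

#' Ordered levels of an annotation variable
#'
#' Uses the explicit `level_order` when present; otherwise levels are
#' sorted numerically when all parse as numbers, else lexicographically.
#'
#' @inheritParams annotation_labels
#' @param observed optional character vector restricting to these levels.
#' @return character vector of ordered levels.
#' @export
annotation_level_order <- function(annotation, variable, observed = NULL) {
  labels <- annotation_labels(annotation, variable)
  levels <- unique(stats::na.omit(labels))
  if (!is.null(observed)) levels <- intersect(levels, observed)
  lo <- annotation$level_order[[variable]]
  if (!is.null(lo)) {
    return(lo[lo %in% levels])
  }
  num <- suppressWarnings(as.numeric(levels))
  if (!anyNA(num)) levels[order(num)] else sort(levels)
}

#' Align a feature matrix with annotation labels
#'
#' Restricts the matrix to the samples that carry a label for `variable`
#' (exact set intersection; matrix column order preserved, no silent
#' reordering) and returns index-aligned labels. Dropped samples are
#' reported with a warning.
#'
#' @param m feature matrix (features x samples).
#' @param annotation a `sample_annotation`.
#' @param variable variable name.
#' @return list with `matrix` (possibly fewer columns) and `labels`
#'   (character vector aligned with its columns).
#' @export
align_samples <- function(m, annotation, variable) {
  validate_feature_matrix(m)
  labels <- annotation_labels(annotation, variable, samples = colnames(m))
  keep <- !is.na(labels)
  if (!any(keep)) {
    stop("no sample in the matrix carries a '", variable, "' label",
         call. = FALSE)
  }
  if (!all(keep)) {
    warning(sum(!keep), " sample(s) without a '", variable,
            "' label dropped: ",
            paste(utils::head(colnames(m)[!keep], 5L), collapse = ", "),
            if (sum(!keep) > 5L) ", ...", call. = FALSE)
  }
  list(matrix = m[, keep, drop = FALSE],
       labels = unname(labels[keep]))
}

#' Filter non-finite and constant feature rows
#'
#' @param m feature matrix.
#' @param drop_na drop rows containing any `NA`/`NaN`/`Inf` (default TRUE).
#' @param drop_constant drop zero-variance rows (default FALSE).
#' @return list with `matrix` (filtered) and `report`
#'   (`list(na_removed, constant_removed)`). Idempotent: filtering twice
#'   equals filtering once.
#' @export
filter_features <- function(m, drop_na = TRUE, drop_constant = FALSE) {
  validate_feature_matrix(m)
  report <- list(na_removed = 0L, constant_removed = 0L)
  if (drop_na) {
    bad <- rowSums(!is.finite(m)) > 0L
    report$na_removed <- sum(bad)
    m <- m[!bad, , drop = FALSE]
  }
  if (nrow(m) == 0L) {
    stop("all features removed by filtering", call. = FALSE)
  }
  if (drop_constant) {
    finite_rows <- rowSums(!is.finite(m)) == 0L
    v <- rep(NA_real_, nrow(m))
    if (any(finite_rows)) {
      mf <- m[finite_rows, , drop = FALSE]
      v[finite_rows] <- rowSums((mf - rowMeans(mf))^2)
    }
    const <- !is.na(v) & v == 0
    report$constant_removed <- sum(const)
    m <- m[!const, , drop = FALSE]
  }
  if (nrow(m) == 0L) {
    stop("all features removed by filtering", call. = FALSE)
  }
  if (report$na_removed + report$constant_removed > 0L) {
    message("filter_features: removed ", report$na_removed,
            " row(s) with non-finite values, ", report$constant_removed,
            " constant row(s)")
  }
  list(matrix = m, report = report)
}

#' Remove named features from a matrix
#'
#' Used e.g. to drop sex-chromosome probes when investigating a hidden
#' dichotomy. IDs not present are ignored with a message; removing every
#' feature is an error. Order of the remaining features is preserved.
#'
#' @param m feature matrix.
#' @param ids character vector of feature IDs to remove.
#' @return the reduced matrix.
#' @export
exclude_features <- function(m, ids) {
  validate_feature_matrix(m)
  ids <- as.character(ids)
  absent <- setdiff(ids, rownames(m))
  if (length(absent)) {
    message("exclude_features: ", length(absent),
            " ID(s) not present in the matrix, ignored")
  }
  keep <- !(rownames(m) %in% ids)
  if (!any(keep)) stop("all features excluded; empty matrix", call. = FALSE)
  n_removed <- sum(!keep)
  if (n_removed > 0L) {
    message("exclude_features: removed ", n_removed, " feature(s)")
  }
  m[keep, , drop = FALSE]
}
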