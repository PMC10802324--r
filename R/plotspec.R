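# Declarative plot specifications for centroid/ray/trend PCA plots.
#
# All geometry (points, centroids, rays, trend arrows) lives in a plain
# plot_spec object that tests can interrogate without rendering pixels;
# render_plot_spec() turns one into a ggplot and writes PNG/SVG/PDF.

# Fixed 20-color categorical cycle (a pure function of the sorted level
# list, stable across runs and platforms). Levels beyond the cycle reuse
# colors with distinct point shapes.
.palette20 <- c(
  "#1F77B4", "#FF7F0E", "#2CA02C", "#D62728", "#9467BD",
  "#8C564B", "#E377C2", "#7F7F7F", "#BCBD22", "#17BECF",
  "#AEC7E8", "#FFBB78", "#98DF8A", "#FF9896", "#C5B0D5",
  "#C49C94", "#F7B6D2", "#C7C7C7", "#DBDB8D", "#9EDAE5")

.shapes <- c(16, 17, 15, 18, 3, 4, 8, 1, 2, 0, 5, 6)

#' Deterministic categorical palette
#'
#' Maps an ordered set of levels to colors from a fixed 20-color cycle.
#' More than 20 levels wrap around with a message (pair with shapes to
#' keep them distinguishable).
#'
#' @param levels character vector of level names (order defines the
#'   assignment).
#' @return named character vector of hex colors.
#' @export
spec_palette <- function(levels) {
  n <- length(levels)
  if (n > length(.palette20)) {
    message("more than ", length(.palette20),
            " levels; colors recycled, distinguish by shape")
  }
  stats::setNames(.palette20[(seq_len(n) - 1L) %% length(.palette20) + 1L],
                  levels)
}

.spec_shapes <- function(levels) {
  n <- length(levels)
  stats::setNames(.shapes[(seq_len(n) - 1L) %% length(.shapes) + 1L], levels)
}

.axis_label <- function(component, fraction) {
  sprintf("PC%d (%.1f%% of variance)", component, 100 * fraction)
}

.new_plot_spec <- function(points, centroids, rays, axis_labels, legend,
                           subtitle = NULL) {
  structure(list(points = points, centroids = centroids, rays = rays,
                 arrows = data.frame(from = character(), to = character(),
                                     x0 = numeric(), y0 = numeric(),
                                     x1 = numeric(), y1 = numeric(),
                                     stringsAsFactors = FALSE),
                 axis_labels = axis_labels, legend = legend,
                 subtitle = subtitle),
            class = "plot_spec")
}

#' Build a centroid-and-rays plot specification
#'
#' One point per sample, one centroid per group, and one ray per
#' (group, member) pair running from the group centroid to the member's
#' point — the rays visualize within-group dispersion. Colors are assigned
#' per group from a deterministic palette; axis labels carry the
#' explained-variance percentages.
#'
#' @param pca a `pca_result`.
#' @param centroids a `group_centroids` computed on the same scores.
#' @param annotation a `sample_annotation`.
#' @param variable grouping variable (must match `centroids$variable`).
#' @param components pair of component indices to plot (default `c(1, 2)`),
#'   each within `1..L`.
#' @param subtitle optional subtitle string (see [dsc_subtitle()] for the
#'   conventional DSC annotation).
#' @return object of class `plot_spec`: list with data.frames `points`
#'   (sample_id, x, y, color_key, shape_key), `centroids`
#'   (group, x, y, color_key), `rays` (group, x0, y0, x1, y1, color_key),
#'   `arrows` (empty until [add_trend()]), plus `axis_labels`, `legend`
#'   and `subtitle`.
#' @export
build_plot_spec <- function(pca, centroids, annotation, variable,
                            components = c(1L, 2L), subtitle = NULL) {
  stopifnot(inherits(pca, "pca_result"), inherits(centroids, "group_centroids"))
  if (!identical(centroids$variable, variable)) {
    stop("centroids were computed for variable '", centroids$variable,
         "', not '", variable, "'", call. = FALSE)
  }
  components <- as.integer(components)
  if (length(components) != 2L || any(components < 1L) ||
      any(components > pca$n_components)) {
    stop("components must be two indices within 1..", pca$n_components,
         call. = FALSE)
  }
  labels <- annotation_labels(annotation, variable,
                              samples = rownames(pca$scores))
  if (anyNA(labels)) {
    stop("every analyzed sample needs a '", variable, "' label",
         call. = FALSE)
  }
  pal <- spec_palette(centroids$group_labels)
  points <- data.frame(
    sample_id = rownames(pca$scores),
    x = pca$scores[, components[1L]],
    y = pca$scores[, components[2L]],
    color_key = unname(labels),
    shape_key = unname(labels),
    stringsAsFactors = FALSE, row.names = NULL)
  cents <- data.frame(
    group = centroids$group_labels,
    x = centroids$centroids[, components[1L]],
    y = centroids$centroids[, components[2L]],
    color_key = centroids$group_labels,
    stringsAsFactors = FALSE, row.names = NULL)
  gi <- match(points$color_key, cents$group)
  rays <- data.frame(
    group = cents$group[gi],
    x0 = cents$x[gi], y0 = cents$y[gi],
    x1 = points$x, y1 = points$y,
    color_key = cents$group[gi],
    stringsAsFactors = FALSE, row.names = NULL)
  .new_plot_spec(
    points = points, centroids = cents, rays = rays,
    axis_labels = c(
      x = .axis_label(components[1L], pca$explained_fraction[components[1L]]),
      y = .axis_label(components[2L], pca$explained_fraction[components[2L]])),
    legend = list(color = pal, shape = .spec_shapes(centroids$group_labels)),
    subtitle = subtitle)
}

#' Append trend arrows to a plot specification
#'
#' Connects the group centroids with K-1 directed arrows in the declared
#' ordinal order (ascending batch number, ship date, ...), revealing drift
#' over the ordering.
#'
#' @param spec a `plot_spec` built from the same centroids.
#' @param centroids the `group_centroids` used for `spec`.
#' @param order character vector: a permutation of the group labels.
#' @return the `plot_spec` with `arrows` filled in (row i: centroid of
#'   `order[i]` -> centroid of `order[i + 1]`).
#' @export
add_trend <- function(spec, centroids, order = centroids$group_labels) {
  stopifnot(inherits(spec, "plot_spec"), inherits(centroids, "group_centroids"))
  order <- as.character(order)
  if (anyDuplicated(order) || !setequal(order, centroids$group_labels)) {
    stop("order must be a permutation of the group labels: ",
         paste(centroids$group_labels, collapse = ", "), call. = FALSE)
  }
  k <- length(order)
  if (k < 2L) {
    spec$arrows <- spec$arrows[0L, ]
    return(spec)
  }
  ci <- match(order, spec$centroids$group)
  spec$arrows <- data.frame(
    from = order[-k], to = order[-1L],
    x0 = spec$centroids$x[ci[-k]], y0 = spec$centroids$y[ci[-k]],
    x1 = spec$centroids$x[ci[-1L]], y1 = spec$centroids$y[ci[-1L]],
    stringsAsFactors = FALSE, row.names = NULL)
  spec
}

#' Dual-variable plot specification
#'
#' Centroids and rays are grouped and colored by one variable (typically
#' the batch) while the sample points are colored and shaped by a second
#' variable (sex, subtype, ...). This is the "detective work" view: a
#' dichotomy that does not follow any batch shows up as a split of point
#' colors that the ray structure cannot explain.
#'
#' @param pca a `pca_result`.
#' @param annotation a `sample_annotation` labeling all analyzed samples
#'   for both variables.
#' @param ray_variable variable driving centroids and rays.
#' @param point_variable variable driving point color and shape.
#' @param components pair of component indices (default `c(1, 2)`).
#' @param subtitle optional subtitle.
#' @return a `plot_spec`; `legend$color` covers the union of both
#'   variables' levels (ray levels first), `legend$shape` the point
#'   variable's levels.
#' @export
dual_variable_spec <- function(pca, annotation, ray_variable, point_variable,
                               components = c(1L, 2L), subtitle = NULL) {
  cents <- compute_centroids(pca, annotation, ray_variable)
  spec <- build_plot_spec(pca, cents, annotation, ray_variable,
                          components = components, subtitle = subtitle)
  point_labels <- annotation_labels(annotation, point_variable,
                                    samples = spec$points$sample_id)
  if (anyNA(point_labels)) {
    stop("every analyzed sample needs a '", point_variable, "' label",
         call. = FALSE)
  }
  spec$points$color_key <- unname(point_labels)
  spec$points$shape_key <- unname(point_labels)
  point_levels <- annotation_level_order(annotation, point_variable,
                                         observed = unique(point_labels))
  extra <- setdiff(point_levels, names(spec$legend$color))
  if (length(extra)) {
    spec$legend$color <- spec_palette(c(cents$group_labels, extra))
  }
  spec$legend$shape <- .spec_shapes(point_levels)
  spec
}

#' Conventional DSC subtitle for a plot
#'
#' Formats the figure-caption convention, e.g.
#' `"DSC for PCA=0.60, p-value < 0.0005; Overall DSC=0.357, p-value < 0.0005"`.
#' p-values of zero are printed as `< 1/n_perm`.
#'
#' @param report a `dsc_report`.
#' @return a string.
#' @export
dsc_subtitle <- function(report) {
  stopifnot(inherits(report, "dsc_report"))
  fmt_p <- function(p, n_perm) {
    if (p == 0) sprintf("p-value < %.4g", 1 / n_perm)
    else sprintf("p-value = %.4g", p)
  }
  sprintf("DSC for PCA=%.3g, %s; Overall DSC=%.3g, %s",
          report$pca$dsc$dsc, fmt_p(report$pca$perm$p_value,
                                    report$pca$perm$n_perm),
          report$overall$dsc$dsc, fmt_p(report$overall$perm$p_value,
                                        report$overall$perm$n_perm))
}

#' @export
print.plot_spec <- function(x, ...) {
  cat("plot_spec:", nrow(x$points), "points,", nrow(x$centroids),
      "centroids,", nrow(x$rays), "rays,", nrow(x$arrows), "arrows\n")
  invisible(x)
}

#' Serialize a plot specification to JSON
#'
#' @param spec a `plot_spec`.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
plot_spec_to_json <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "plot_spec"))
  json <- jsonlite::toJSON(unclass(spec), dataframe = "rows",
                           auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

#' Render a plot specification to an image file
#'
#' Draws rays (thin, semi-transparent), sample points, enlarged centroid
#' markers and trend arrows with ggplot2, honoring the spec's legends and
#' axis labels, and writes the result. Output is deterministic given the
#' spec and format.
#'
#' @param spec a `plot_spec`.
#' @param path output file path.
#' @param format `"png"`, `"svg"` or `"pdf"`; default guessed from the
#'   extension of `path`.
#' @param width,height device size in inches.
#' @param dpi resolution for PNG.
#' @return `path`, invisibly.
#' @export
render_plot_spec <- function(spec, path, format = NULL, width = 7,
                             height = 5.5, dpi = 150) {
  stopifnot(inherits(spec, "plot_spec"))
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  format <- match.arg(format, c("png", "svg", "pdf"))
  p <- plot_spec_gg(spec)
  device <- switch(format,
    png = function(file, ...) grDevices::png(file, width = width,
                                             height = height, units = "in",
                                             res = dpi),
    svg = function(file, ...) grDevices::svg(file, width = width,
                                             height = height),
    pdf = function(file, ...) grDevices::pdf(file, width = width,
                                             height = height))
  device(path)
  on.exit(grDevices::dev.off(), add = TRUE)
  print(p)
  invisible(path)
}

#' Turn a plot specification into a ggplot object
#'
#' @param spec a `plot_spec`.
#' @return a ggplot.
#' @export
plot_spec_gg <- function(spec) {
  stopifnot(inherits(spec, "plot_spec"))
  p <- ggplot2::ggplot()
  if (nrow(spec$rays)) {
    p <- p + ggplot2::geom_segment(
      data = spec$rays,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1,
                   yend = .data$y1, color = .data$color_key),
      linewidth = 0.3, alpha = 0.45, show.legend = FALSE)
  }
  p <- p + ggplot2::geom_point(
    data = spec$points,
    ggplot2::aes(x = .data$x, y = .data$y, color = .data$color_key,
                 shape = .data$shape_key),
    size = 1.8)
  if (nrow(spec$centroids)) {
    p <- p + ggplot2::geom_point(
      data = spec$centroids,
      ggplot2::aes(x = .data$x, y = .data$y, color = .data$color_key),
      size = 4, shape = 18, show.legend = FALSE)
  }
  if (nrow(spec$arrows)) {
    p <- p + ggplot2::geom_segment(
      data = spec$arrows,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1,
                   yend = .data$y1),
      color = "black", linewidth = 0.5,
      arrow = ggplot2::arrow(length = ggplot2::unit(0.12, "in"),
                             type = "closed"))
  }
  p +
    ggplot2::scale_color_manual(values = spec$legend$color, name = NULL) +
    ggplot2::scale_shape_manual(values = spec$legend$shape, name = NULL) +
    ggplot2::labs(x = spec$axis_labels[["x"]], y = spec$axis_labels[["y"]],
                  subtitle = spec$subtitle) +
    ggplot2::theme_bw()
}
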