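# ggplot2 graphics for each result type.

#' PCA score plot with 95% class ellipses
#'
#' @param object a [fit_pca()] model.
#' @param data tibble to project (defaults to none: training scores are
#'   plotted without classes).
#' @param class_col class column for coloring and ellipses.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.kin_pca <- function(object, data = NULL, class_col = NULL, ...) {
  if (is.null(data)) {
    scores <- tibble::as_tibble(object$scores)
    p <- ggplot2::ggplot(scores, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
      ggplot2::geom_point(alpha = 0.6)
    ell <- NULL
  } else {
    proj <- project_pca(object, data, class_col = class_col)
    scores <- proj$scores
    ell <- proj$ellipses
    p <- ggplot2::ggplot(scores,
                         ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                      color = .data$class)) +
      ggplot2::geom_point(alpha = 0.6)
  }
  if (!is.null(ell) && nrow(ell) > 0) {
    circ <- tibble::tibble(theta = seq(0, 2 * pi, length.out = 181))
    ell_pts <- purrr::pmap_dfr(ell, function(class, center_x, center_y,
                                             var_x, var_y, cov_xy, level) {
      s <- matrix(c(var_x, cov_xy, cov_xy, var_y), 2, 2)
      e <- eigen(s, symmetric = TRUE)
      rad <- sqrt(stats::qchisq(level, 2))
      pts <- cbind(cos(circ$theta), sin(circ$theta)) %*%
        diag(rad * sqrt(pmax(e$values, 0))) %*% t(e$vectors)
      tibble::tibble(class = class, PC1 = pts[, 1] + center_x,
                     PC2 = pts[, 2] + center_y)
    })
    p <- p + ggplot2::geom_path(
      data = ell_pts,
      ggplot2::aes(x = .data$PC1, y = .data$PC2, color = .data$class),
      inherit.aes = FALSE)
  }
  pct <- round(100 * object$explained_ratio[1:2], 1)
  p + ggplot2::labs(x = paste0("PC1 (", pct[1], "%)"),
                    y = paste0("PC2 (", pct[2], "%)")) +
    ggplot2::theme_minimal()
}

#' Correlation circle plot
#'
#' @param model a [fit_pca()] model.
#' @param components two component indices.
#' @return a ggplot object.
#' @export
plot_correlation_circle <- function(model, components = c(1, 2)) {
  cc <- correlation_circle(model, components)
  circ <- tibble::tibble(theta = seq(0, 2 * pi, length.out = 181))
  ggplot2::ggplot(cc) +
    ggplot2::geom_path(
      data = tibble::tibble(x = cos(circ$theta), y = sin(circ$theta)),
      ggplot2::aes(x = .data$x, y = .data$y), color = "grey60") +
    ggplot2::geom_segment(
      ggplot2::aes(x = 0, y = 0, xend = .data$x, yend = .data$y),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))) +
    ggplot2::geom_text(
      ggplot2::aes(x = .data$x * 1.08, y = .data$y * 1.08,
                   label = .data$variable), size = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = paste0("PC", components[1]),
                  y = paste0("PC", components[2])) +
    ggplot2::theme_minimal()
}

#' PMI triangle plot
#'
#' Plots NPR1/NPR2 points inside the rod-disc-sphere triangle.
#'
#' @param pmi output of [pmi_table()].
#' @return a ggplot object.
#' @export
plot_pmi_triangle <- function(pmi) {
  tri <- tibble::tibble(NPR1 = c(0, 0.5, 1, 0), NPR2 = c(1, 0.5, 1, 1))
  ggplot2::ggplot(pmi, ggplot2::aes(x = .data$NPR1, y = .data$NPR2)) +
    ggplot2::geom_path(data = tri, color = "grey40") +
    ggplot2::geom_point(ggplot2::aes(color = .data$dataset_label),
                        alpha = 0.7) +
    ggplot2::annotate("text", x = c(0, 0.5, 1), y = c(1.03, 0.47, 1.03),
                      label = c("rod", "disc", "sphere"), size = 3) +
    ggplot2::labs(x = "NPR1 (I1/I3)", y = "NPR2 (I2/I3)") +
    ggplot2::theme_minimal()
}

#' Descriptor distribution grid
#'
#' Histograms of each descriptor with the guideline range shaded out.
#'
#' @param descriptors output of [compute_descriptors()].
#' @param guidelines optional output of [derive_guidelines()].
#' @return a ggplot object.
#' @export
plot_descriptor_distributions <- function(descriptors, guidelines = NULL) {
  vars <- intersect(descriptor_names, names(descriptors))
  long <- tidyr::pivot_longer(descriptors[, vars], dplyr::all_of(vars),
                              names_to = "descriptor")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue") +
    ggplot2::facet_wrap(~descriptor, scales = "free") +
    ggplot2::theme_minimal()
  if (!is.null(guidelines)) {
    g <- guidelines[guidelines$descriptor %in% vars, ]
    p <- p +
      ggplot2::geom_vline(data = g, ggplot2::aes(xintercept = .data$lower),
                          linetype = 2, color = "red") +
      ggplot2::geom_vline(data = g, ggplot2::aes(xintercept = .data$upper),
                          linetype = 2, color = "red")
  }
  p
}

#' Bicycle frequency bar chart
#'
#' @param freq output of [bicycle_frequency()].
#' @param top number of top-ranked ring systems to show.
#' @return a ggplot object.
#' @export
plot_bicycle_frequency <- function(freq, top = 10) {
  d <- utils::head(freq, top)
  d$key <- factor(d$key, levels = rev(d$key))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$count, y = .data$key)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%d (%.1f%%)", .data$count, 100 * .data$frequency)),
      hjust = -0.1, size = 3) +
    ggplot2::scale_x_continuous(expand = ggplot2::expansion(mult = c(0, 0.2))) +
    ggplot2::labs(y = NULL, x = "occurrences") +
    ggplot2::theme_minimal()
}
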