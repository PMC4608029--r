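# ggplot2 visualization helpers.

#' Plot a closed curve in three orthogonal projections
#'
#' @inheritParams as_curve_matrix
#' @param reference Optional second curve drawn underneath (e.g. the
#'   ground-truth backbone of a phantom).
#' @return A ggplot object faceted by projection plane.
#' @export
plot_curve <- function(curve, reference = NULL) {
  proj_tbl <- function(cv, which) {
    m <- as_curve_matrix(cv)
    m <- rbind(m, m[1, ])  # close the loop visually
    dplyr::bind_rows(
      tibble::tibble(plane = "xy", h = m[, 1], v = m[, 2], set = which),
      tibble::tibble(plane = "xz", h = m[, 1], v = m[, 3], set = which),
      tibble::tibble(plane = "yz", h = m[, 2], v = m[, 3], set = which))
  }
  dat <- proj_tbl(curve, "trace")
  if (!is.null(reference)) dat <- dplyr::bind_rows(proj_tbl(reference, "reference"), dat)
  ggplot2::ggplot(dat, ggplot2::aes(.data$h, .data$v, colour = .data$set)) +
    ggplot2::geom_path(linewidth = 0.6) +
    ggplot2::facet_wrap(~plane) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, colour = NULL,
                  title = "Closed-curve orthogonal projections (Å)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.trace_result <- function(object, ...) plot_curve(object$curve)

#' Shape frequency distribution plot
#'
#' Bar chart of class fractions with the weighted-compactness average
#' marked, mirroring the per-topoisomer distribution plots.
#'
#' @param object A [shape_distribution()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.shape_distribution <- function(object, ...) {
  dat <- dplyr::filter(object, .data$shape_class != "other" |
                         .data$count > 0)
  dat$shape_class <- factor(dat$shape_class,
                            levels = c(SHAPE_CLASSES, "other"))
  wc <- attr(object, "weighted_compactness")
  p <- ggplot2::ggplot(dat,
                       ggplot2::aes(.data$shape_class,
                                    .data$count / max(1, sum(dat$count)))) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = NULL, y = "fraction",
                  title = "Minicircle shape frequency distribution") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 35, hjust = 1))
  if (!is.na(wc)) {
    p <- p + ggplot2::annotate("point", x = wc, y = 0, shape = 17, size = 3) +
      ggplot2::labs(subtitle = sprintf("weighted compactness = %.2f", wc))
  }
  p
}

#' Plot per-group radius of gyration with error bars
#'
#' @param summary A [population_summary()] tibble.
#' @return A ggplot object (mean +- sd per group).
#' @export
plot_rg_summary <- function(summary) {
  ggplot2::ggplot(summary, ggplot2::aes(.data$group, .data$rg_mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$rg_mean - .data$rg_sd,
                                          ymax = .data$rg_mean + .data$rg_sd)) +
    ggplot2::labs(x = NULL, y = "radius of gyration (Å)",
                  title = "Density radius of gyration by group") +
    ggplot2::theme_minimal()
}
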