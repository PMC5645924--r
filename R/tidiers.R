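#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a swallow analysis
#'
#' @param x A `swallow_analysis`.
#' @param ... Unused.
#' @return The peak-summary tibble (`structure`, `parameter`, `value`,
#'   `units`, `frame`).
#' @export
tidy.swallow_analysis <- function(x, ...) x$summary

#' One-row overview of a swallow analysis
#'
#' @param x A `swallow_analysis`.
#' @param ... Unused.
#' @return One-row tibble: structures analyzed, frame count, fps, duration,
#'   scale factor, smoothing method.
#' @export
glance.swallow_analysis <- function(x, ...) {
  nf <- dplyr::n_distinct(x$series$frame)
  tibble::tibble(
    n_structures = length(x$structures),
    structures = paste(x$structures, collapse = ","),
    n_frames = nf,
    fps = x$fps,
    duration_s = (nf - 1) / x$fps,
    scale_mm_per_px = x$scale,
    smoothing = x$config$smoothing$method
  )
}

#' Tidy an ICC result
#'
#' @param x An `icc_result`.
#' @param ... Unused.
#' @return One-row tibble: `icc`, `ci_low`, `ci_high`, `model`, `category`.
#' @export
tidy.icc_result <- function(x, ...) {
  tibble::tibble(icc = x$icc, ci_low = x$ci_low, ci_high = x$ci_high,
                 model = x$model, category = x$category)
}

#' Mean-square components of an ICC fit
#'
#' @param x An `icc_result`.
#' @param ... Unused.
#' @return One-row tibble with the ANOVA mean squares and dimensions.
#' @export
glance.icc_result <- function(x, ...) {
  tibble::tibble(msr = x$msr, msc = x$msc, mse = x$mse,
                 n = x$n, k = x$k, conf_level = x$conf_level)
}

#' Tidy a Bland-Altman result
#'
#' @param x A `bland_altman_result`.
#' @param ... Unused.
#' @return One-row tibble: `bias`, `loa_low`, `loa_high`, `sd_diff`, `n`.
#' @export
tidy.bland_altman_result <- function(x, ...) {
  tibble::tibble(bias = x$bias, loa_low = x$loa_low, loa_high = x$loa_high,
                 sd_diff = x$sd_diff, n = x$n)
}

#' Displacement and velocity panels for an analysis
#'
#' One facet per structure parameter, displacement-type series and
#' velocity-type series distinguishable by the units in the facet label.
#'
#' @param object A `swallow_analysis`.
#' @param parameters Optional character vector restricting which parameters
#'   are drawn (e.g. `c("disp_vert", "vel_vert")`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.swallow_analysis <- function(object, parameters = NULL, ...) {
  d <- object$series
  if (!is.null(parameters)) d <- d[d$parameter %in% parameters, ]
  d$panel <- paste0(d$structure, ": ", d$parameter, " (", d$units, ")")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Superimposed vertical displacements
#'
#' All structures' vertical displacement on the common time base, the
#' at-a-glance view of swallow-pattern timing.
#'
#' @param analysis A `swallow_analysis`.
#' @return A ggplot object.
#' @export
plot_superimposed <- function(analysis) {
  long <- tidyr::pivot_longer(analysis$superimposed, -c("frame", "time_s"),
                              names_to = "structure", values_to = "mm")
  long$structure <- sub("_disp_vert_mm$", "", long$structure)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$mm,
                                     colour = .data$structure)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = "time (s)", y = "vertical displacement (mm)") +
    ggplot2::theme_minimal()
}

#' Bland-Altman agreement plot
#'
#' @param object A `bland_altman_result`.
#' @param ... Unused.
#' @return A ggplot object: per-pair differences against means with the
#'   bias and the 95% limits of agreement.
#' @export
autoplot.bland_altman_result <- function(object, ...) {
  ggplot2::ggplot(object$pairs, ggplot2::aes(x = .data$mean, y = .data$difference)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$bias) +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed") +
    ggplot2::labs(x = "mean of measurement and reference", y = "difference") +
    ggplot2::theme_minimal()
}

#' Animated-trajectory table plot
#'
#' Static rendering of the animation table: each marker's smoothed
#' anatomical path, coloured by time.
#'
#' @param analysis A `swallow_analysis`.
#' @return A ggplot object.
#' @export
plot_trajectories <- function(analysis) {
  ggplot2::ggplot(analysis$animation,
                  ggplot2::aes(x = .data$x_mm, y = .data$y_mm,
                               colour = .data$time_s, group = .data$marker)) +
    ggplot2::geom_path(na.rm = TRUE) +
    ggplot2::facet_wrap(~marker) +
    ggplot2::labs(x = "x (mm, anterior positive)", y = "y (mm, toward C2)") +
    ggplot2::theme_minimal()
}
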