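#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a calibration result
#'
#' @param x A `pa_calibration` from [calibrate()].
#' @param ... Unused.
#' @return A tibble with one row per confidence level: `mode`,
#'   `confidence`, `level`, `c_lod`.
#' @method tidy pa_calibration
#' @export
tidy.pa_calibration <- function(x, ...) {
  tibble::tibble(
    mode = x$mode,
    confidence = c("relaxed", "strict"),
    level = c(x$params$confidence_relaxed, x$params$confidence_strict),
    c_lod = c(x$c_lod_relaxed, x$c_lod_strict)
  )
}

#' One-row summary of a calibration result
#'
#' @param x A `pa_calibration` from [calibrate()].
#' @param ... Unused.
#' @return A one-row tibble: mode, panel size, simulated offspring, valid
#'   offspring, unthresholded accuracy, both C-LOD values and the seed.
#' @method glance pa_calibration
#' @export
glance.pa_calibration <- function(x, ...) {
  tibble::tibble(
    mode = x$mode, n_loci = x$n_loci, n_offspring = x$n_offspring,
    n_valid = x$n_valid, accuracy = x$accuracy,
    c_lod_relaxed = x$c_lod_relaxed, c_lod_strict = x$c_lod_strict,
    seed = x$seed
  )
}

#' Plot the simulated LOD distributions behind a calibration
#'
#' Requires `calibrate(..., keep_draws = TRUE)`. Shows the A-LOD
#' distribution of most-likely candidates split by whether they are the
#' true parent, with finite critical thresholds as vertical lines.
#'
#' @param object A `pa_calibration` with draws.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pa_calibration
#' @export
autoplot.pa_calibration <- function(object, ...) {
  if (is.null(object$draws)) {
    stop("re-run calibrate() with keep_draws = TRUE to plot", call. = FALSE)
  }
  df <- dplyr::mutate(
    object$draws,
    status = ifelse(.data$is_true, "true parent", "false candidate")
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$a_lod, fill = .data$status)) +
    ggplot2::geom_histogram(bins = 60, alpha = 0.7, position = "identity") +
    ggplot2::labs(
      x = "A-LOD of most likely candidate", y = "simulated offspring",
      fill = NULL,
      title = sprintf("LOD calibration, %s mode, %d loci", object$mode, object$n_loci)
    )
  for (th in c(object$c_lod_relaxed, object$c_lod_strict)) {
    if (abs(th) < 999) p <- p + ggplot2::geom_vline(xintercept = th, linetype = 2)
  }
  p
}

#' A-LOD distributions by panel and mode
#'
#' @param assignments Tibble from [batch_assign()].
#' @return A ggplot object (boxplots of A-LOD per panel, faceted by mode).
#' @export
plot_alod <- function(assignments) {
  ggplot2::ggplot(
    assignments,
    ggplot2::aes(x = .data$panel, y = .data$a_lod)
  ) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(ggplot2::vars(.data$mode)) +
    ggplot2::labs(x = NULL, y = "A-LOD", title = "Assignment LOD scores by marker panel")
}

#' Stacked confidence-class composition
#'
#' @param conf Tibble from [summarize_confidence()].
#' @return A ggplot object.
#' @export
plot_confidence <- function(conf) {
  x <- if ("panel" %in% names(conf)) "panel" else "mode"
  p <- ggplot2::ggplot(
    conf,
    ggplot2::aes(x = .data[[x]], y = .data$pct, fill = .data$class)
  ) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "% of assignments", fill = "confidence class")
  if ("mode" %in% names(conf) && x == "panel") {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$mode))
  }
  p
}
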