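#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a registration result
#'
#' One row per pose parameter with its estimate, in broom style.
#'
#' @param x a `noa_registration`.
#' @param ... unused.
#' @return tibble with columns `term`, `estimate`, `unit`.
#' @export
tidy.noa_registration <- function(x, ...) {
  p <- pose_params(x$pose)
  tibble::tibble(term = names(p), estimate = unname(p),
                 unit = rep(c("degree", "mm"), each = 3L))
}

#' One-row summary of a registration result
#'
#' @param x a `noa_registration`.
#' @param ... unused.
#' @return one-row tibble: residual NOA, relative NOA (%), iteration count,
#'   stage count, convergence flag, wall time.
#' @export
glance.noa_registration <- function(x, ...) {
  tibble::tibble(noa = x$noa,
                 relative_noa_pct = 100 * x$relative_noa,
                 iterations = x$total_iterations,
                 stages = nrow(x$stages),
                 converged = x$converged,
                 mode = x$mode,
                 wall_time = x$wall_time)
}

#' Plot per-stage residual decrease of a registration
#'
#' @param object a `noa_registration`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.noa_registration <- function(object, ...) {
  d <- dplyr::mutate(object$stages, stage = dplyr::row_number())
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$stage),
                                  y = .data$residual_ss)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "stage (coarse to fine)",
                  y = "residual sum of squares (NOA)",
                  title = "Residual NOA per optimization stage") +
    ggplot2::theme_minimal()
}

#' Plot absolute pose errors against pixel spacing
#'
#' Box plots of the per-axis absolute registration errors for each pixel
#' spacing, on a logarithmic scale — the standard accuracy-versus-resolution
#' view of the in silico evaluation.
#'
#' @param object an `insilico_experiment` tibble.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.insilico_experiment <- function(object, ...) {
  d <- tidyr::pivot_longer(tibble::as_tibble(object),
                           dplyr::starts_with("err_"),
                           names_to = "axis", values_to = "abs_error")
  d$kind <- ifelse(d$axis %in% c("err_rx", "err_ry", "err_rz"),
                   "rotation (degrees)", "translation (mm)")
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$pixel_spacing),
                                  y = pmax(.data$abs_error, 1e-8),
                                  fill = .data$axis)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~kind, scales = "free_y") +
    ggplot2::labs(x = "pixel spacing (mm)", y = "absolute error",
                  title = "Registration accuracy vs radiograph resolution") +
    ggplot2::theme_minimal()
}

#' Tidy an in silico experiment into long per-axis errors
#' @param x an `insilico_experiment` tibble.
#' @param ... unused.
#' @return long tibble with `axis` and `abs_error` columns.
#' @export
tidy.insilico_experiment <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x), dplyr::starts_with("err_"),
                      names_to = "axis", values_to = "abs_error")
}

#' One-row-per-cell summary of an in silico experiment
#' @param x an `insilico_experiment` tibble.
#' @param ... unused.
#' @return the [summarize_insilico()] tibble.
#' @export
glance.insilico_experiment <- function(x, ...) summarize_insilico(x)
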