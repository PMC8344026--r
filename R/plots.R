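# ggplot2 graphics for the distribution, fitted cumulative incidence and
# screening results.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a three-parameter Gompertz distribution
#'
#' Shows the distribution function with its plateau, next to the density
#' and the sub-distribution hazard.
#'
#' @param object A [gomp_params()].
#' @param times Time grid (years).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gomp_params
#' @export
autoplot.gomp_params <- function(object, times = seq(0, 10, by = 0.05), ...) {
  df <- tibble::tibble(
    time = times,
    value = c(gomp_cdf(times, object), gomp_pdf(times, object),
              gomp_subhazard(times, object)),
    fn = rep(c("cumulative incidence", "density", "sub-hazard"),
             each = length(times))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(
      data = tibble::tibble(fn = "cumulative incidence",
                            pl = gomp_plateau(object)),
      ggplot2::aes(yintercept = .data$pl), linetype = "dashed") +
    ggplot2::facet_wrap(~fn, scales = "free_y") +
    ggplot2::labs(x = "time (years)", y = NULL)
}

.df_wrap <- function(times, values, fn) {
  tibble::tibble(time = times, value = values, fn = fn)
}

#' Cumulative incidence curves of a fitted model
#'
#' @param object A converged [crisk_fit()].
#' @param newdata Optional one-row covariate profile (see [cif_curve()]).
#' @param times Time grid (years).
#' @param ... Unused.
#' @return A ggplot object with one curve per cause.
#' @method autoplot crisk_fit
#' @export
autoplot.crisk_fit <- function(object, newdata = NULL,
                               times = seq(0, 4, by = 0.05), ...) {
  cc <- cif_curve(object, newdata = newdata, times = times)
  ggplot2::ggplot(cc, ggplot2::aes(x = .data$time, y = .data$cif,
                                   colour = .data$cause)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "years since start of dialysis",
                  y = "cumulative incidence", colour = NULL) +
    ggplot2::ylim(0, 1)
}

#' @rdname autoplot.crisk_fit
#' @param fit A converged [crisk_fit()].
#' @export
plot_cif <- function(fit, newdata = NULL, times = seq(0, 4, by = 0.05)) {
  autoplot(fit, newdata = newdata, times = times)
}

#' Forest plot of a screening report
#'
#' Sub-hazard ratios with their screening-level intervals, per cause,
#' from the univariate stage of [run_screening()].
#'
#' @param object A `screen_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot screen_report
#' @export
autoplot.screen_report <- function(object, ...) {
  uni <- dplyr::bind_rows(object$univariate, .id = "cause")
  uni <- uni[!uni$reference & uni$status == "ok", , drop = FALSE]
  uni$label <- ifelse(is.na(uni$level), uni$variable,
                      paste0(uni$variable, " [", uni$level, "]"))
  ggplot2::ggplot(uni, ggplot2::aes(x = .data$shr, y = .data$label,
                                    colour = .data$retained)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high),
      height = 0.2) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~cause) +
    ggplot2::labs(x = "sub-hazard ratio (log scale)", y = NULL,
                  colour = "retained")
}

#' @importFrom rlang .data
NULL
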