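# ggplot2 display methods for the result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bland-Altman plot
#'
#' Differences against pair means with the mean difference (solid) and the
#' limits of agreement (dashed).
#'
#' @param object a [bland_altman()] result.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.bland_altman <- function(object, ...) {
  s <- object$stats
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = s$mean_diff, linewidth = 0.6) +
    ggplot2::geom_hline(yintercept = c(s$loa_lower, s$loa_upper),
                        linetype = "dashed") +
    ggplot2::labs(x = "mean of paired measurements",
                  y = "difference",
                  title = "Bland-Altman agreement",
                  subtitle = sprintf(
                    "mean difference %.2f; limits of agreement [%.2f, %.2f]",
                    s$mean_diff, s$loa_lower, s$loa_upper)) +
    ggplot2::theme_minimal()
}

#' Training history plot for a fitted U-Net
#'
#' Loss curves (training and validation) and validation IoU per epoch.
#'
#' @param object a trained `unet`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.unet <- function(object, ...) {
  if (is.null(object$history)) stop("network has no training history",
                                    call. = FALSE)
  h <- tidyr::pivot_longer(object$history, -"epoch",
                           names_to = "metric", values_to = "value")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$value,
                                  colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~ metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, title = "U-Net training history") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Compartment enhancement curves of a phantom
#'
#' Noiseless concentration (or signal) time-courses of cortex, medulla and
#' pelvis, with the early cortical uptake, delayed medullary rise and late
#' pelvic accumulation visible.
#'
#' @param object a `phantom`.
#' @param what `"conc"` or `"signal"`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.phantom <- function(object, what = c("conc", "signal"), ...) {
  what <- match.arg(what)
  ggplot2::ggplot(object$curves,
                  ggplot2::aes(x = .data$time, y = .data[[what]],
                               colour = .data$compartment)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "time (s)",
                  y = if (what == "conc") "concentration (mmol/L)"
                      else "signal (a.u.)",
                  title = "Phantom compartment enhancement") +
    ggplot2::theme_minimal()
}
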