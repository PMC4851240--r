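#' Plot a case-study result
#'
#' Maximum type I error rate against the endpoint correlation, one line
#' per second-stage restriction, with the nominal level as a dashed
#' reference.
#'
#' @param object A `blindsr_case_study` tibble from [run_case_study()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot blindsr_case_study
#' @export
autoplot.blindsr_case_study <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = rlang::.data$rho,
                                       y = rlang::.data$estimate,
                                       colour = rlang::.data$restriction)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = 0.025, linetype = "dashed") +
    ggplot2::labs(
      x = expression(rho), y = expression(alpha[max]),
      colour = NULL,
      title = sprintf("Worst-case inflation, %s endpoint",
                      object$endpoint[1])
    ) +
    ggplot2::theme_minimal()
}

#' Plot an effect-size sweep
#'
#' Maximum type I error rate against the secondary endpoint effect size,
#' one line per correlation.
#'
#' @param object A `blindsr_sweep` tibble from [run_effectsize_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot blindsr_sweep
#' @export
autoplot.blindsr_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = rlang::.data$effect,
                                       y = rlang::.data$estimate,
                                       colour = factor(rlang::.data$rho))) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0.025, linetype = "dashed") +
    ggplot2::labs(x = "secondary endpoint effect size",
                  y = expression(alpha[max]),
                  colour = expression(rho)) +
    ggplot2::theme_minimal()
}

#' Plot an unblinding-correlation sweep
#'
#' @param object A `blindsr_unblinding` tibble from
#'   [run_unblinding_study()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot blindsr_unblinding
#' @export
autoplot.blindsr_unblinding <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = rlang::.data$rho,
                                       y = rlang::.data$r)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = expression(rho), y = "unblinding correlation r",
                  title = sprintf("%s endpoint", object$endpoint[1])) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
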