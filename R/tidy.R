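#' Tidy a maximum type I error estimate
#'
#' @param x An `alpha_max` object from [estimate_max_type1()].
#' @param ... Unused.
#' @return A one-row tibble with the estimate, its Monte Carlo standard
#'   error, and the run settings.
#' @method tidy alpha_max
#' @export
tidy.alpha_max <- function(x, ...) {
  tibble::tibble(
    estimate = x$estimate,
    mc_se = x$mc_se,
    n_runs = x$n_runs,
    seed = x$seed,
    method = x$method,
    test = if (x$method == "montecarlo") x$test else NA_character_,
    rule = x$rule
  )
}

#' Glance at a maximum type I error estimate
#'
#' @inheritParams tidy.alpha_max
#' @return A one-row tibble summarising the fit and the design it was
#'   computed under.
#' @method glance alpha_max
#' @export
glance.alpha_max <- function(x, ...) {
  tibble::tibble(
    estimate = x$estimate,
    mc_se = x$mc_se,
    n_runs = x$n_runs,
    alpha = x$design$alpha,
    n1 = x$design$n1,
    n2min = x$design$n2min,
    n2max = x$design$n2max,
    scheme = x$design$scheme,
    secondary_effect = abs(x$params$nu1 - x$params$nu0),
    rho = x$params$rho
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
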