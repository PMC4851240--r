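#' Endpoint model parameters
#'
#' Parameters of the bivariate-normal two-endpoint model: each subject
#' contributes a primary response \eqn{X} and a secondary response \eqn{Y},
#' with \eqn{(X, Y) \mid G = g \sim N((\mu_g, \nu_g), \sigma^2
#' \left(\begin{smallmatrix}1 & \rho\\ \rho & 1\end{smallmatrix}\right))},
#' where \eqn{G \in \{0, 1\}} is the (hidden) treatment allocation.
#'
#' @param mu0,mu1 Primary endpoint means under control and treatment
#'   (response units). Under the null hypothesis of interest `mu0 == mu1`.
#' @param nu0,nu1 Secondary endpoint means under control and treatment.
#' @param sigma Common standard deviation of both endpoints, `> 0`.
#' @param rho Correlation between primary and secondary endpoint, in
#'   `[-1, 1]`.
#'
#' @return An object of class `endpoint_params`.
#' @examples
#' endpoint_params(nu0 = 1.8, nu1 = 0.55, sigma = 0.31)
#' @export
endpoint_params <- function(mu0 = 0, mu1 = 0, nu0 = 0, nu1 = 0,
                            sigma = 1, rho = 0) {
  stopifnot(
    is.numeric(mu0), is.numeric(mu1), is.numeric(nu0), is.numeric(nu1),
    length(sigma) == 1, is.finite(sigma), sigma > 0,
    length(rho) == 1, is.finite(rho), abs(rho) <= 1
  )
  structure(
    list(mu0 = mu0, mu1 = mu1, nu0 = nu0, nu1 = nu1,
         sigma = sigma, rho = rho),
    class = "endpoint_params"
  )
}

#' @export
print.endpoint_params <- function(x, ...) {
  cat("<endpoint_params>\n")
  cat(sprintf("  primary   means: mu0 = %g, mu1 = %g\n", x$mu0, x$mu1))
  cat(sprintf("  secondary means: nu0 = %g, nu1 = %g\n", x$nu0, x$nu1))
  cat(sprintf("  sigma = %g, rho = %g\n", x$sigma, x$rho))
  invisible(x)
}

#' Two-stage trial design
#'
#' Describes a two-arm, two-stage superiority trial with a blinded interim
#' analysis after `n1` subjects and a second-stage sample size `n2` chosen
#' inside `[n2min, n2max]`. `n2max = Inf` encodes an unrestricted second
#' stage.
#'
#' @param n1 First-stage total sample size; a positive even integer.
#' @param n2min,n2max Bounds for the second-stage sample size;
#'   `0 <= n2min < n2max`, `n2max` may be `Inf`.
#' @param alpha One-sided significance level in `(0, 1)`.
#' @param scheme Randomization scheme for stage 1: `"random_allocation"`
#'   (exactly `n1/2` treated), `"simple"` (iid fair coin), or `"block"`
#'   (balanced blocks of length `tau`).
#' @param tau Block length; required when `scheme = "block"`, even and a
#'   divisor of `n1`.
#'
#' @return An object of class `trial_design`.
#' @examples
#' trial_design(n1 = 144, n2min = 72, n2max = 576)
#' trial_design(n1 = 144, scheme = "block", tau = 4)
#' @export
trial_design <- function(n1, n2min = 0, n2max = Inf, alpha = 0.025,
                         scheme = c("random_allocation", "simple", "block"),
                         tau = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(
    length(n1) == 1, is.finite(n1), n1 > 0, n1 %% 2 == 0,
    length(n2min) == 1, n2min >= 0, is.finite(n2min),
    length(n2max) == 1, n2max > n2min,
    length(alpha) == 1, alpha > 0, alpha < 1
  )
  if (scheme == "block") {
    if (is.null(tau)) {
      stop("`tau` is required when scheme = \"block\"", call. = FALSE)
    }
    stopifnot(length(tau) == 1, is.finite(tau), tau >= 2,
              tau %% 2 == 0, n1 %% tau == 0)
  } else if (!is.null(tau)) {
    stop("`tau` is only meaningful when scheme = \"block\"", call. = FALSE)
  }
  structure(
    list(n1 = as.numeric(n1), n2min = as.numeric(n2min),
         n2max = as.numeric(n2max), alpha = alpha, scheme = scheme,
         tau = if (is.null(tau)) NA_real_ else as.numeric(tau)),
    class = "trial_design"
  )
}

#' @export
print.trial_design <- function(x, ...) {
  cat("<trial_design>\n")
  cat(sprintf("  n1 = %g, n2 in [%g, %g], one-sided alpha = %g\n",
              x$n1, x$n2min, x$n2max, x$alpha))
  cat(sprintf("  randomization: %s%s\n", x$scheme,
              if (x$scheme == "block") sprintf(" (tau = %g)", x$tau) else ""))
  invisible(x)
}

#' Fingolimod case-study parameterizations
#'
#' Endpoint parameters for a two-arm phase III trial comparing high-dose
#' Fingolimod with placebo in relapsing-remitting multiple sclerosis, where
#' the blinded interim data include a laboratory parameter that is strongly
#' affected by treatment. The primary endpoint is modelled as normal under
#' the null (`mu0 = mu1 = 0`) with the same standard deviation as the
#' secondary endpoint; the correlation `rho` is unknown and scanned over a
#' grid in practice.
#'
#' * `"lymphocyte"`: mean lymphocyte count, `nu0 = 1.8`, `nu1 = 0.55`
#'   (`\\u00d7 10^9` cells/L), common SD `0.31` — an almost fully unblinding
#'   secondary endpoint (standardised effect about 4).
#' * `"wbc"`: mean total white blood cell count, `nu0 = 6.5`, `nu1 = 3.8`,
#'   pooled SD `1.57` — a partially unblinding secondary endpoint.
#'
#' @param endpoint `"lymphocyte"` or `"wbc"`.
#' @param rho Correlation between primary and secondary endpoint.
#' @return An `endpoint_params` object.
#' @examples
#' fingolimod_params("wbc", rho = 0.5)
#' @export
fingolimod_params <- function(endpoint = c("lymphocyte", "wbc"), rho = 0) {
  endpoint <- match.arg(endpoint)
  if (endpoint == "lymphocyte") {
    endpoint_params(nu0 = 1.8, nu1 = 0.55, sigma = 0.31, rho = rho)
  } else {
    endpoint_params(nu0 = 6.5, nu1 = 3.8, sigma = 1.57, rho = rho)
  }
}

# internal: validate a stage-1 data frame (columns x, y, optional g, block_id)
check_stage1 <- function(data, design = NULL, require_g = FALSE) {
  stopifnot(is.data.frame(data))
  for (col in c("x", "y")) {
    if (!col %in% names(data)) {
      stop(sprintf("stage-1 data must contain column `%s`", col),
           call. = FALSE)
    }
    if (!is.numeric(data[[col]])) {
      stop(sprintf("column `%s` must be numeric", col), call. = FALSE)
    }
  }
  if (require_g && !"g" %in% names(data)) {
    stop("true allocations `g` are required but absent", call. = FALSE)
  }
  if ("g" %in% names(data)) {
    if (!all(data$g %in% c(0, 1))) {
      stop("column `g` must contain only 0/1", call. = FALSE)
    }
  }
  if (!is.null(design)) {
    if (nrow(data) != design$n1) {
      stop(sprintf("stage-1 data has %d rows but design$n1 = %g",
                   nrow(data), design$n1), call. = FALSE)
    }
    if (design$scheme == "random_allocation" && "g" %in% names(data) &&
        sum(data$g) != design$n1 / 2) {
      stop("under random allocation `g` must contain exactly n1/2 ones",
           call. = FALSE)
    }
  }
  invisible(data)
}
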