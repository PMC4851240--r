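#' Posterior probability of treatment allocation from blinded data
#'
#' Under simple randomization each subject is treated independently with
#' probability 1/2, so by Bayes' theorem the posterior probability that
#' subject \eqn{j} is in the treatment arm given its blinded pair
#' \eqn{(x_j, y_j)} is
#' \deqn{q_j = \frac{\varphi_1(x_j, y_j)}{\varphi_0(x_j, y_j) +
#'   \varphi_1(x_j, y_j)},}
#' where \eqn{\varphi_g} is the bivariate normal density with mean vector
#' \eqn{(\mu_g, \nu_g)}, common variance \eqn{\sigma^2} and correlation
#' \eqn{\rho}. When the arms are indistinguishable (`nu0 == nu1` and
#' `mu0 == mu1`) every `q_j` is 1/2: the blinded data carry no allocation
#' information.
#'
#' At `|rho| = 1` the joint density is singular; the residual
#' \eqn{y - \rho x} is then deterministic given the allocation and the
#' posterior collapses to the 0/1 indicator of whichever arm's offset is
#' nearer to the observed residual (exact ties give 1/2).
#'
#' @param data A data frame with numeric columns `x` (primary) and `y`
#'   (secondary), one row per subject.
#' @param params An [endpoint_params()] object.
#' @return The input data as a tibble with an added column `q`, the
#'   posterior treatment probability of each subject, in `[0, 1]`.
#' @examples
#' d <- tibble::tibble(x = c(0.2, -0.1), y = c(1.9, 0.6))
#' allocation_posterior(d, fingolimod_params("lymphocyte"))
#' @export
allocation_posterior <- function(data, params) {
  check_stage1(data)
  stopifnot(inherits(params, "endpoint_params"))
  out <- tibble::as_tibble(data)
  out$q <- posterior_prob(out$x, out$y, params)
  out
}

#' Vectorised posterior allocation probability
#'
#' The computational core of [allocation_posterior()]: accepts plain numeric
#' vectors (or matrices) of primary and secondary responses and returns the
#' posterior treatment probabilities elementwise.
#'
#' @param x,y Numeric vectors or matrices of equal shape.
#' @param params An [endpoint_params()] object.
#' @return Posterior probabilities with the shape of `x`.
#' @export
posterior_prob <- function(x, y, params) {
  stopifnot(inherits(params, "endpoint_params"), length(x) == length(y))
  p <- params
  if (abs(p$rho) >= 1) {
    # singular case: y - rho*x is deterministic given the arm
    resid <- y - p$rho * x
    d0 <- abs(resid - (p$nu0 - p$rho * p$mu0))
    d1 <- abs(resid - (p$nu1 - p$rho * p$mu1))
    q <- ifelse(abs(d0 - d1) < 1e-12, 0.5, as.numeric(d1 < d0))
    if (is.matrix(x)) dim(q) <- dim(x)
    return(q)
  }
  # exact factorisation f(x, y | g) = f(x | g) f(y | x, g)
  sy <- p$sigma * sqrt(1 - p$rho^2)
  l0 <- stats::dnorm(x, p$mu0, p$sigma, log = TRUE) +
    stats::dnorm(y, p$nu0 + p$rho * (x - p$mu0), sy, log = TRUE)
  l1 <- stats::dnorm(x, p$mu1, p$sigma, log = TRUE) +
    stats::dnorm(y, p$nu1 + p$rho * (x - p$mu1), sy, log = TRUE)
  q <- stats::plogis(l1 - l0)
  if (is.matrix(x)) dim(q) <- dim(x)
  q
}

# internal: per-subject log density under each arm, as a list(l0, l1);
# inputs may be matrices (runs x subjects)
arm_logdens <- function(x, y, params) {
  p <- params
  if (abs(p$rho) >= 1) {
    # represent the singular density by a sharp surrogate consistent with
    # posterior_prob(): the arm whose deterministic residual matches wins
    resid <- y - p$rho * x
    pen <- 1e8
    l0 <- -pen * abs(resid - (p$nu0 - p$rho * p$mu0)) +
      stats::dnorm(x, p$mu0, p$sigma, log = TRUE)
    l1 <- -pen * abs(resid - (p$nu1 - p$rho * p$mu1)) +
      stats::dnorm(x, p$mu1, p$sigma, log = TRUE)
    return(list(l0 = l0, l1 = l1))
  }
  sy <- p$sigma * sqrt(1 - p$rho^2)
  list(
    l0 = stats::dnorm(x, p$mu0, p$sigma, log = TRUE) +
      stats::dnorm(y, p$nu0 + p$rho * (x - p$mu0), sy, log = TRUE),
    l1 = stats::dnorm(x, p$mu1, p$sigma, log = TRUE) +
      stats::dnorm(y, p$nu1 + p$rho * (x - p$mu1), sy, log = TRUE)
  )
}
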