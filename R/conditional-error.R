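#' First-stage z-statistic
#'
#' The standardised treatment-control contrast
#' \deqn{Z = \frac{1}{\sigma\sqrt{N}} \sum_i (2 g_i - 1) x_i,}
#' the usual z-test statistic for a balanced two-arm comparison with known
#' standard deviation. With `data` a stage-1 data frame carrying the true
#' allocations it is the unblinded first-stage test statistic \eqn{Z_1}.
#'
#' @param data A data frame with numeric column `x` and 0/1 column `g`.
#' @param sigma Known common standard deviation, `> 0`.
#' @return A single number.
#' @examples
#' z_statistic(tibble::tibble(x = c(1, -1), g = c(1, 0)), sigma = 1)
#' @export
z_statistic <- function(data, sigma) {
  check_stage1_xg(data)
  stopifnot(length(sigma) == 1, is.finite(sigma), sigma > 0)
  sum((2 * data$g - 1) * data$x) / (sigma * sqrt(nrow(data)))
}

check_stage1_xg <- function(data) {
  stopifnot(is.data.frame(data), nrow(data) > 0)
  if (!all(c("x", "g") %in% names(data))) {
    stop("data must contain columns `x` and `g`", call. = FALSE)
  }
  if (!all(data$g %in% c(0, 1))) stop("`g` must be 0/1", call. = FALSE)
  invisible(data)
}

#' Conditional law of the first-stage z-statistic given blinded data
#'
#' Given posterior allocation probabilities \eqn{q_i} for the `n1` stage-1
#' subjects, the conditional distribution of the unblinded first-stage
#' statistic \eqn{Z_1} given the blinded data is asymptotically normal with
#' \deqn{m_1 = \sum_i (2 q_i - 1) x_i / (\sigma \sqrt{n_1}), \qquad
#'       V_1 = \frac{4}{\sigma^2 n_1} \sum_i x_i^2 q_i (1 - q_i).}
#' When all \eqn{q_i \in \{0, 1\}} the data are fully unblinded: the
#' variance is zero and the mean equals the z-statistic of the implied
#' allocation. When all \eqn{q_i = 1/2} the mean is zero and the variance is
#' the lumped second moment \eqn{\sum x_i^2 / (\sigma^2 n_1)}.
#'
#' @param data A data frame with columns `x` and `q` (as produced by
#'   [allocation_posterior()]), or columns `x` plus a separate `q` argument.
#' @param sigma Known common standard deviation.
#' @param q Optional vector of posterior probabilities overriding `data$q`.
#' @return A `conditional_law` object: a list with elements `mean` and
#'   `variance`.
#' @seealso [block_conditional_moments()] for the block-randomization
#'   analogue.
#' @export
conditional_moments <- function(data, sigma, q = NULL) {
  stopifnot(is.data.frame(data), nrow(data) > 0, "x" %in% names(data))
  if (is.null(q)) {
    if (!"q" %in% names(data)) {
      stop("supply `q` or a data frame with a `q` column", call. = FALSE)
    }
    q <- data$q
  }
  stopifnot(length(q) == nrow(data), all(q >= 0 & q <= 1),
            length(sigma) == 1, sigma > 0)
  n1 <- nrow(data)
  conditional_law(
    mean = sum((2 * q - 1) * data$x) / (sigma * sqrt(n1)),
    variance = 4 * sum(data$x^2 * q * (1 - q)) / (sigma^2 * n1)
  )
}

#' @rdname conditional_moments
#' @param mean,variance Components of the law; `variance >= 0`.
#' @export
conditional_law <- function(mean, variance) {
  stopifnot(length(mean) == 1, is.finite(mean),
            length(variance) == 1, is.finite(variance))
  # clip tiny negative round-off
  if (variance < 0 && variance > -1e-12) variance <- 0
  stopifnot(variance >= 0)
  structure(list(mean = mean, variance = variance),
            class = "conditional_law")
}

#' @export
print.conditional_law <- function(x, ...) {
  cat(sprintf("<conditional_law>  mean = %.6g, variance = %.6g\n",
              x$mean, x$variance))
  invisible(x)
}

#' Conditional type I error rate given unblinded first-stage data
#'
#' Probability of rejecting at the final analysis given the observed
#' first-stage z-statistic `z1`, when the trial continues with `n2` further
#' subjects and the final z-test is performed at one-sided level `alpha`
#' without any adjustment for the adaptation:
#' \deqn{1 - \Phi\!\left(\sqrt{N/n_2}\, z_{1-\alpha} -
#'   \sqrt{n_1/n_2}\, z_1\right), \quad N = n_1 + n_2.}
#' Strictly increasing in `z1`. The degenerate boundary cases are the
#' limits: `n2 = 0` gives the indicator of `z1 > z_{1-alpha}` and
#' `n2 = Inf` gives `alpha`.
#'
#' @param z1 Observed first-stage z-statistic (vectorised).
#' @param n1 First-stage sample size, `> 0`.
#' @param n2 Second-stage sample size, `>= 0`, may be `Inf` (vectorised).
#' @param alpha One-sided significance level.
#' @return Conditional rejection probabilities in `[0, 1]`.
#' @export
conditional_error_unblinded <- function(z1, n1, n2, alpha = 0.025) {
  stopifnot(n1 > 0, all(n2 >= 0), alpha > 0, alpha < 1)
  zc <- stats::qnorm(1 - alpha)
  k <- max(length(z1), length(n2))
  z1 <- rep_len(z1, k); n2 <- rep_len(n2, k)
  out <- numeric(k)
  inf <- is.infinite(n2)
  out[inf] <- alpha
  zero <- !inf & n2 == 0
  out[zero] <- as.numeric(z1[zero] > zc)
  f <- !inf & !zero
  if (any(f)) {
    N <- n1 + n2[f]
    out[f] <- 1 - stats::pnorm(sqrt(N / n2[f]) * zc -
                                 sqrt(n1 / n2[f]) * z1[f])
  }
  out
}

#' Conditional type I error rate given blinded first-stage data
#'
#' Approximates the conditional rejection probability given only blinded
#' first-stage data by integrating the unblinded conditional error over a
#' normal approximation \eqn{N(m_1, V_1)} to the conditional law of
#' \eqn{Z_1}:
#' \deqn{1 - \Phi\!\left(\frac{z_{1-\alpha} - \sqrt{n_1/N}\, m_1}
#'   {\sqrt{(n_1 V_1 + n_2)/N}}\right), \quad N = n_1 + n_2.}
#' With `v1 = 1, m1 = 0` (the null reference law) this equals `alpha` for
#' every `n2`; with `v1 = 0` it reduces to
#' [conditional_error_unblinded()] at `z1 = m1`.
#'
#' @param m1,v1 Mean and variance of the conditional law of `Z1`
#'   (vectorised); alternatively pass a `conditional_law` as `m1`.
#' @param n1 First-stage sample size.
#' @param n2 Second-stage sample size, may be `Inf` (vectorised).
#' @param alpha One-sided significance level.
#' @return Conditional rejection probabilities in `[0, 1]`.
#' @export
conditional_error_blinded <- function(m1, v1 = NULL, n1, n2, alpha = 0.025) {
  if (inherits(m1, "conditional_law")) {
    v1 <- m1$variance
    m1 <- m1$mean
  }
  stopifnot(!is.null(v1), n1 > 0, all(n2 >= 0), all(v1 >= 0),
            alpha > 0, alpha < 1)
  zc <- stats::qnorm(1 - alpha)
  k <- max(length(m1), length(v1), length(n2))
  m1 <- rep_len(m1, k); v1 <- rep_len(v1, k); n2 <- rep_len(n2, k)
  out <- numeric(k)
  inf <- is.infinite(n2)
  out[inf] <- alpha
  degen <- !inf & v1 == 0 & n2 == 0
  out[degen] <- as.numeric(m1[degen] > zc)
  f <- !inf & !degen
  if (any(f)) {
    N <- n1 + n2[f]
    out[f] <- 1 - stats::pnorm((zc - sqrt(n1 / N) * m1[f]) /
                                 sqrt((n1 * v1[f] + n2[f]) / N))
  }
  out
}

# internal fully-vectorised worst-case rule over (m1, v1) vectors.
# Returns list(n2, error). Exact argmax of the blinded conditional error:
# as a function of u = sqrt(n1/N) the objective has at most one interior
# stationary point, a maximum only when v1 < 1 and m1 > 0, so the argmax
# lies in {n2min, clamped interior point, n2max}.
wc_rule <- function(m1, v1, n1, n2min, n2max, alpha) {
  zc <- stats::qnorm(1 - alpha)
  k <- length(m1)
  interior <- rep(n2max, k)
  ok <- v1 < 1 & m1 > 0
  if (any(ok)) {
    nt <- ((zc * (1 - v1[ok]) / m1[ok])^2 - 1) * n1
    interior[ok] <- pmin(pmax(nt, n2min), n2max)
  }
  cand <- cbind(rep(n2min, k), interior, rep(n2max, k))
  err <- cbind(
    conditional_error_blinded(m1, v1, n1, cand[, 1], alpha),
    conditional_error_blinded(m1, v1, n1, cand[, 2], alpha),
    conditional_error_blinded(m1, v1, n1, cand[, 3], alpha)
  )
  j <- max.col(err, ties.method = "first")
  idx <- cbind(seq_len(k), j)
  list(n2 = cand[idx], error = err[idx])
}

#' Worst-case second-stage sample size
#'
#' The second-stage sample size in `[n2min, n2max]` that maximizes the
#' blinded conditional type I error rate [conditional_error_blinded()], in
#' closed form. Treating \eqn{n_2} as continuous and writing
#' \eqn{u = \sqrt{n_1/N}}, the objective has at most one interior stationary
#' point \eqn{\tilde n_2 = \{(z_{1-\alpha}(1 - V_1)/m_1)^2 - 1\}\, n_1},
#' which is a maximum precisely when \eqn{V_1 < 1} and \eqn{m_1 > 0}; with
#' thresholds \eqn{z_* = z_{1-\alpha}(1 - V_1)/\sqrt{1 + n_{2max}/n_1}} and
#' \eqn{z^* = z_{1-\alpha}(1 - V_1)/\sqrt{1 + n_{2min}/n_1}} the rule for
#' \eqn{V_1 \le 1} selects `n2max` when \eqn{m_1 < z_*}, the clamped
#' interior point for \eqn{m_1 \in [z_*, z^*]} and `n2min` when
#' \eqn{m_1 > z^*}; for \eqn{V_1 > 1} the maximizer is an endpoint. The
#' implementation evaluates the candidate set exactly, so the returned `n2`
#' attains the maximum for every input. An unbounded design
#' (`n2max = Inf`) reports the sentinel `Inf` with conditional error equal
#' to its limit `alpha` whenever the unbounded branch wins.
#'
#' @param law A `conditional_law` (from [conditional_moments()] or
#'   [block_conditional_moments()]).
#' @param design A [trial_design()].
#' @return A one-row tibble with columns `n2` and `conditional_error`.
#' @examples
#' law <- conditional_law(mean = 0.8, variance = 0.4)
#' worst_case_n2(law, trial_design(n1 = 144, n2min = 72, n2max = 576))
#' @export
worst_case_n2 <- function(law, design) {
  stopifnot(inherits(law, "conditional_law"),
            inherits(design, "trial_design"))
  r <- wc_rule(law$mean, law$variance, design$n1, design$n2min,
               design$n2max, design$alpha)
  tibble::tibble(n2 = r$n2, conditional_error = r$error)
}

#' Blinded and unblinded first-stage effect estimates
#'
#' The unblinded first-stage effect estimate is
#' \eqn{\bar X = \sum_i 2 (2 g_i - 1) x_i / n_1} (the treatment-control
#' mean difference); substituting the posterior allocation probabilities
#' \eqn{q_i} for the unknown \eqn{g_i} gives its blinded reconstruction
#' \eqn{\bar X_b = \sum_i 2 (2 q_i - 1) x_i / n_1}. The correlation between
#' the two across trials measures how much the secondary endpoint unblinds
#' the primary effect estimate; see [unblinding_correlation()].
#'
#' @param data A data frame with column `x`, a 0/1 column `g` (for the
#'   unblinded estimate) and/or a probability column `q` (for the blinded
#'   one).
#' @return A one-row tibble with columns `xbar` and `xbar_blinded`
#'   (`NA` for whichever input column is absent).
#' @export
effect_estimates <- function(data) {
  stopifnot(is.data.frame(data), nrow(data) > 0, "x" %in% names(data))
  n1 <- nrow(data)
  xbar <- if ("g" %in% names(data)) {
    stopifnot(all(data$g %in% c(0, 1)))
    sum(2 * (2 * data$g - 1) * data$x) / n1
  } else NA_real_
  xbar_b <- if ("q" %in% names(data)) {
    stopifnot(all(data$q >= 0 & data$q <= 1))
    sum(2 * (2 * data$q - 1) * data$x) / n1
  } else NA_real_
  tibble::tibble(xbar = xbar, xbar_blinded = xbar_b)
}
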