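#' Exact posterior over balanced allocations by enumeration
#'
#' Under random allocation all \eqn{\binom{n_1}{n_1/2}} balanced sequences
#' are a priori equally likely, so the posterior probability of a sequence
#' \eqn{g} given the blinded data is proportional to
#' \eqn{\prod_i f(x_i, y_i \mid g_i)}. Enumeration is exponential in `n1`
#' and is guarded to `n1 <= 14`; it serves as the brute-force reference for
#' the MCMC sampler.
#'
#' @param data A stage-1 data frame with columns `x` and `y`; `nrow(data)`
#'   even and at most 14.
#' @param params An [endpoint_params()] object.
#' @return A tibble with a list-column `g` (0/1 allocation vectors) and a
#'   column `probability` summing to 1.
#' @export
exact_allocation_posterior <- function(data, params) {
  check_stage1(data)
  n1 <- nrow(data)
  stopifnot(n1 %% 2 == 0)
  if (n1 > 14) {
    stop("enumeration is limited to n1 <= 14 (use mcmc_sample_allocations)",
         call. = FALSE)
  }
  ld <- arm_logdens(data$x, data$y, params)
  d <- ld$l1 - ld$l0
  idx <- utils::combn(n1, n1 / 2)
  G <- matrix(0L, ncol(idx), n1)
  for (k in seq_len(ncol(idx))) G[k, idx[, k]] <- 1L
  loglik <- as.vector(G %*% d)
  loglik <- loglik - max(loglik)
  p <- exp(loglik) / sum(exp(loglik))
  tibble::tibble(
    g = lapply(seq_len(nrow(G)), function(k) G[k, ]),
    probability = p
  )
}

#' Metropolis sampler over balanced allocations
#'
#' Samples from the posterior distribution of the balanced stage-1
#' allocation vector given the blinded data (the target of
#' [exact_allocation_posterior()]) with a Metropolis chain whose proposal
#' swaps the labels of one uniformly chosen treated and one untreated
#' subject — every state visited is balanced. The acceptance ratio involves
#' only the two swapped subjects' likelihood ratios, so each proposal is
#' O(1).
#'
#' @param data A stage-1 data frame with columns `x` and `y`, even row
#'   count.
#' @param params An [endpoint_params()] object.
#' @param n_draws Number of retained draws.
#' @param burn_in Number of burn-in sweeps (one sweep = `n1` proposals).
#' @param thin Proposals between retained draws; defaults to `n1` (one
#'   sweep).
#' @param seed Integer seed; the chain is reproducible given the seed.
#' @return An object of class `allocation_sample`: list with `draws`
#'   (an `n_draws x n1` 0/1 matrix), `n1` and `seed`.
#' @export
mcmc_sample_allocations <- function(data, params, n_draws = 2000,
                                    burn_in = 1000, thin = NULL,
                                    seed = 1) {
  check_stage1(data)
  n1 <- nrow(data)
  stopifnot(n1 %% 2 == 0, n_draws >= 1, burn_in >= 0)
  if (is.null(thin)) thin <- n1
  stopifnot(thin >= 1)
  set.seed(seed)
  ld <- arm_logdens(data$x, data$y, params)
  d <- ld$l1 - ld$l0
  g <- integer(n1)
  g[sample.int(n1, n1 / 2)] <- 1L
  treated <- which(g == 1L)
  control <- which(g == 0L)
  half <- n1 / 2L
  n_prop <- burn_in * n1 + n_draws * thin
  # pregenerate randomness in one vectorised pass
  pick_t <- sample.int(half, n_prop, replace = TRUE)
  pick_c <- sample.int(half, n_prop, replace = TRUE)
  logu <- log(stats::runif(n_prop))
  draws <- matrix(0L, n_draws, n1)
  keep_at <- burn_in * n1 + seq_len(n_draws) * thin
  ki <- 1L
  for (s in seq_len(n_prop)) {
    j <- treated[pick_t[s]]
    k <- control[pick_c[s]]
    if (logu[s] < d[k] - d[j]) {
      treated[pick_t[s]] <- k
      control[pick_c[s]] <- j
    }
    if (ki <= n_draws && s == keep_at[ki]) {
      gi <- integer(n1)
      gi[treated] <- 1L
      draws[ki, ] <- gi
      ki <- ki + 1L
    }
  }
  structure(list(draws = draws, n1 = n1, seed = seed),
            class = "allocation_sample")
}

#' Export retained MCMC allocation draws as CSV
#'
#' One row per retained draw, columns `g1..g<n1>`.
#'
#' @param sample An `allocation_sample` from [mcmc_sample_allocations()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_allocation_draws <- function(sample, path) {
  stopifnot(inherits(sample, "allocation_sample"))
  d <- as.data.frame(sample$draws)
  names(d) <- paste0("g", seq_len(ncol(d)))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.allocation_sample <- function(x, ...) {
  cat(sprintf("<allocation_sample>  %d draws over %d subjects (seed %s)\n",
              nrow(x$draws), x$n1, format(x$seed)))
  invisible(x)
}

#' Conditional type I error by Monte Carlo over allocations
#'
#' Integrates the unblinded conditional error over the posterior of the
#' allocation vector given the blinded data: for each sampled allocation
#' \eqn{g} the first-stage z-statistic \eqn{Z_1(g)} is computed and
#' [conditional_error_unblinded()] averaged across draws. This is the
#' computational (sampling-based) counterpart of the normal approximation
#' in [conditional_error_blinded()].
#'
#' @param data A stage-1 data frame with columns `x` and `y`.
#' @param params An [endpoint_params()] object (supplies `sigma`).
#' @param n2 Second-stage sample size (scalar, may be `Inf`).
#' @param alpha One-sided level.
#' @param sample An `allocation_sample` from [mcmc_sample_allocations()],
#'   or a posterior tibble from [exact_allocation_posterior()] (then the
#'   average is the exact weighted one).
#' @return A single probability.
#' @export
conditional_error_mcmc <- function(data, params, n2, alpha = 0.025,
                                   sample) {
  check_stage1(data)
  n1 <- nrow(data)
  z1 <- allocation_z1(sample, data$x, params$sigma)
  w <- attr(z1, "weights")
  err <- conditional_error_unblinded(as.numeric(z1), n1, n2, alpha)
  sum(w * err)
}

# internal: Z1 per draw/sequence plus normalized weights
allocation_z1 <- function(sample, x, sigma) {
  n1 <- length(x)
  if (inherits(sample, "allocation_sample")) {
    stopifnot(ncol(sample$draws) == n1, nrow(sample$draws) >= 1)
    G <- sample$draws
    w <- rep(1 / nrow(G), nrow(G))
  } else if (is.data.frame(sample) &&
             all(c("g", "probability") %in% names(sample))) {
    G <- do.call(rbind, sample$g)
    w <- sample$probability
  } else {
    stop("`sample` must be an allocation_sample or an exact posterior tibble",
         call. = FALSE)
  }
  z1 <- as.vector(G %*% x)
  z1 <- (2 * z1 - sum(x)) / (sigma * sqrt(n1))
  attr(z1, "weights") <- w
  z1
}

#' Maximize the sampled conditional error over a sample-size grid
#'
#' Evaluates [conditional_error_mcmc()] on a grid of candidate second-stage
#' sample sizes and returns the maximizing `n2` (ties resolved toward the
#' smallest). The default grid is geometric over
#' `[max(n2min, 1), n2max]` with the closed-form candidate of
#' [worst_case_n2()] (under the normal approximation) and the bounds
#' appended.
#'
#' @inheritParams conditional_error_mcmc
#' @param design A [trial_design()].
#' @param n2_grid Optional explicit grid of candidate `n2` values within
#'   the design bounds.
#' @param grid_size Number of geometric grid points when `n2_grid` is
#'   omitted.
#' @return A one-row tibble with columns `n2` and `conditional_error`.
#' @export
maximize_conditional_error_mcmc <- function(data, params, design,
                                            sample, n2_grid = NULL,
                                            grid_size = 200) {
  stopifnot(inherits(design, "trial_design"))
  if (is.null(n2_grid)) {
    hi <- if (is.finite(design$n2max)) design$n2max else 100 * design$n1
    lo <- max(design$n2min, 1)
    n2_grid <- exp(seq(log(lo), log(hi), length.out = grid_size))
    q <- allocation_posterior(data, params)
    law <- conditional_moments(q, params$sigma)
    cf <- worst_case_n2(law, design)$n2
    n2_grid <- c(design$n2min, n2_grid, cf, design$n2max)
    n2_grid <- n2_grid[n2_grid >= design$n2min & n2_grid <= design$n2max]
    n2_grid <- sort(unique(n2_grid))
  }
  stopifnot(length(n2_grid) >= 1)
  err <- vapply(n2_grid, function(n2) {
    conditional_error_mcmc(data, params, n2, design$alpha, sample)
  }, numeric(1))
  j <- which.max(err)   # which.max takes the first (smallest n2) on ties
  tibble::tibble(n2 = n2_grid[j], conditional_error = err[j])
}
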