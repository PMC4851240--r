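#' Simulate blinded first-stage trial data
#'
#' Draws one stage-1 dataset from the bivariate-normal two-endpoint model:
#' allocations `g` according to the design's randomization scheme, then
#' responses \eqn{(x, y) \mid g} bivariate normal with means
#' \eqn{(\mu_g, \nu_g)}, common variance \eqn{\sigma^2} and correlation
#' \eqn{\rho}.
#'
#' Schemes: `"simple"` draws each `g_i` as an independent fair coin;
#' `"random_allocation"` draws a uniformly random balanced sequence
#' (exactly `n1/2` treated); `"block"` draws an independent uniform
#' balanced sequence within each consecutive block of length `tau`.
#'
#' @param params An [endpoint_params()] object.
#' @param design A [trial_design()]; supplies `n1`, the scheme and `tau`.
#' @param seed Integer seed; the dataset is reproducible given the seed.
#' @return A tibble with columns `subject` (0-based), `x`, `y`, `g` and,
#'   for the block scheme, `block_id`.
#' @examples
#' simulate_stage1(fingolimod_params("wbc"), trial_design(n1 = 8), seed = 7)
#' @export
simulate_stage1 <- function(params, design, seed = 1) {
  stopifnot(inherits(params, "endpoint_params"),
            inherits(design, "trial_design"))
  set.seed(seed)
  n1 <- design$n1
  g <- switch(design$scheme,
    simple = stats::rbinom(n1, 1, 0.5),
    random_allocation = {
      gg <- integer(n1)
      gg[sample.int(n1, n1 / 2)] <- 1L
      gg
    },
    block = {
      tau <- design$tau
      as.vector(vapply(seq_len(n1 / tau), function(b) {
        gg <- integer(tau)
        gg[sample.int(tau, tau / 2)] <- 1L
        gg
      }, integer(tau)))
    }
  )
  xy <- draw_responses(g, params)
  out <- tibble::tibble(subject = seq_len(n1) - 1L, x = xy$x, y = xy$y,
                        g = as.integer(g))
  if (design$scheme == "block") {
    out$block_id <- rep(seq_len(n1 / design$tau), each = design$tau)
  }
  out
}

#' Simulate unblinded second-stage trial data
#'
#' Second-stage responses under the same endpoint model, with random
#' allocation (exactly `n2/2` treated). Only the primary responses enter
#' the final test statistic; the secondary responses are generated for
#' completeness.
#'
#' @param params An [endpoint_params()] object.
#' @param n2 Even second-stage sample size, `>= 2`.
#' @param seed Integer seed.
#' @return A tibble with columns `subject` (0-based, continuing no
#'   particular stage-1 numbering), `x`, `y`, `g`.
#' @export
simulate_stage2 <- function(params, n2, seed = 1) {
  stopifnot(inherits(params, "endpoint_params"),
            length(n2) == 1, is.finite(n2), n2 >= 2, n2 %% 2 == 0)
  set.seed(seed)
  g <- integer(n2)
  g[sample.int(n2, n2 / 2)] <- 1L
  xy <- draw_responses(g, params)
  tibble::tibble(subject = seq_len(n2) - 1L, x = xy$x, y = xy$y,
                 g = as.integer(g))
}

# internal: responses given allocations; g may be a vector or matrix
draw_responses <- function(g, params) {
  p <- params
  mu <- ifelse(g == 1, p$mu1, p$mu0)
  nu <- ifelse(g == 1, p$nu1, p$nu0)
  x <- mu + p$sigma * stats::rnorm(length(g))
  y <- nu + p$rho * (x - mu) +
    p$sigma * sqrt(max(0, 1 - p$rho^2)) * stats::rnorm(length(g))
  if (is.matrix(g)) { dim(x) <- dim(g); dim(y) <- dim(g) }
  list(x = x, y = y)
}

# internal: allocation matrix (runs x n1) for the vectorised engines.
# Under random_allocation a fixed balanced vector is used: all statistics
# computed downstream are exchangeable in the subject index, so the joint
# law equals that of a uniformly permuted balanced allocation.
allocation_matrix <- function(runs, design) {
  n1 <- design$n1
  switch(design$scheme,
    simple = matrix(stats::rbinom(runs * n1, 1, 0.5), runs, n1),
    random_allocation = matrix(rep(c(1, 0), each = n1 / 2),
                               runs, n1, byrow = TRUE),
    block = {
      tau <- design$tau
      W <- enumerate_block_allocations(tau)
      nb <- n1 / tau
      ks <- sample.int(nrow(W), runs * nb, replace = TRUE)
      # rows of W indexed per (run, block); lay out block-major then bind
      g <- W[ks, , drop = FALSE]            # (runs*nb) x tau, run-major
      matrix(t(g), runs, n1, byrow = TRUE)
    }
  )
}
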