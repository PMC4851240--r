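# independent oracles used across test files

# dense-grid argmax of the blinded conditional error over n2 (log-spaced),
# independent of the closed-form rule in worst_case_n2()
grid_oracle_n2 <- function(m1, v1, n1, n2min, n2max, alpha = 0.025,
                           points = 1e4) {
  hi <- if (is.finite(n2max)) n2max else 1e6 * n1
  grid <- exp(seq(log(max(n2min, 1e-8)), log(hi), length.out = points))
  grid <- c(n2min, grid, if (is.finite(n2max)) n2max else Inf)
  err <- conditional_error_blinded(m1, v1, n1, grid, alpha)
  list(n2 = grid[which.max(err)], error = max(err))
}

# brute-force conditional moments of Z1 by enumerating all balanced
# within-block sequences jointly (only for a single block tau = n1)
enum_block_moments <- function(x, y, params) {
  n1 <- length(x)
  W <- enumerate_block_allocations(n1)
  ld <- blindsr:::arm_logdens(x, y, params)
  loglik <- as.vector(W %*% (ld$l1 - ld$l0))
  p <- exp(loglik - max(loglik))
  p <- p / sum(p)
  z <- as.vector((2 * W - 1) %*% x) / (params$sigma * sqrt(n1))
  list(mean = sum(p * z), variance = sum(p * z^2) - sum(p * z)^2)
}

rand_stage1 <- function(n1, params, seed) {
  simulate_stage1(params, trial_design(n1 = n1), seed = seed)
}
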