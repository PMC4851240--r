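#' Enumerate balanced within-block allocation sequences
#'
#' Under block randomization with block length `tau`, each block realises
#' one of \eqn{K = \binom{\tau}{\tau/2}} equally likely balanced allocation
#' sequences. The indicator convention is `1` = treatment, `0` = control.
#'
#' @param tau Even block length, between 2 and 12 (the enumeration grows
#'   combinatorially).
#' @return A `K x tau` 0/1 matrix, rows in lexicographic order of the
#'   treated index sets, each row summing to `tau/2`.
#' @examples
#' enumerate_block_allocations(4)
#' @export
enumerate_block_allocations <- function(tau) {
  stopifnot(length(tau) == 1, is.finite(tau), tau %% 2 == 0,
            tau >= 2, tau <= 12)
  idx <- utils::combn(tau, tau / 2)
  W <- matrix(0L, ncol(idx), tau)
  for (k in seq_len(ncol(idx))) W[k, idx[, k]] <- 1L
  W
}

#' Posterior over allocation sequences of one block
#'
#' Given the blinded responses of one block of length `tau`, the posterior
#' probability of the k-th balanced allocation sequence \eqn{\omega_k} is
#' \deqn{P(\omega_k \mid b) = \frac{f(b \mid \omega_k)}
#'   {\sum_{k'} f(b \mid \omega_{k'})},}
#' with \eqn{f(b \mid \omega)} the product over block members of the
#' bivariate normal density under the arm assigned by \eqn{\omega}
#' (all sequences having equal prior probability \eqn{1/K}). Densities are
#' accumulated on the log scale with a max-shift normalization, so large
#' secondary-endpoint effects do not underflow. The per-sequence block
#' score is \eqn{m_\tau(k) = \sum_l (2 \omega_{k,l} - 1) x_l}, the block's
#' contribution to the unblinded treatment-control contrast if the true
#' sequence were \eqn{\omega_k}.
#'
#' @param block A data frame with columns `x` and `y`; `nrow(block)` is the
#'   block length.
#' @param params An [endpoint_params()] object.
#' @param allocs Optional matrix from [enumerate_block_allocations()];
#'   enumerated from `nrow(block)` when omitted.
#' @return A tibble with one row per sequence: `k`, `probability` (sums to
#'   1) and `score`.
#' @export
block_posterior <- function(block, params, allocs = NULL) {
  check_stage1(block)
  stopifnot(inherits(params, "endpoint_params"))
  tau <- nrow(block)
  if (is.null(allocs)) allocs <- enumerate_block_allocations(tau)
  stopifnot(is.matrix(allocs), ncol(allocs) == tau)
  ld <- arm_logdens(block$x, block$y, params)
  d <- ld$l1 - ld$l0                       # per-subject log likelihood ratio
  loglik <- as.vector(allocs %*% d)        # + constant sum(l0)
  loglik <- loglik - max(loglik)
  prob <- exp(loglik) / sum(exp(loglik))
  score <- as.vector((2 * allocs - 1) %*% block$x)
  tibble::tibble(k = seq_len(nrow(allocs)), probability = prob,
                 score = score)
}

#' Conditional law of the z-statistic under block randomization
#'
#' With balanced blocks of length `tau`, blocks contribute independent
#' information and the conditional mean and variance of the first-stage
#' z-statistic given the blinded data are
#' \deqn{m_{Z_1} = \frac{1}{\sigma\sqrt{n_1}} \sum_{i \in T} \sum_k
#'   P(\omega_k \mid b_i)\, m_{\tau,i}(k),}
#' \deqn{v_{Z_1} = \frac{1}{\sigma^2 n_1} \sum_{i \in T} \left\{ \sum_k
#'   P(\omega_k \mid b_i)\, m_{\tau,i}(k)^2 - \Big(\sum_k
#'   P(\omega_k \mid b_i)\, m_{\tau,i}(k)\Big)^2 \right\},}
#' where \eqn{T} are the block start indices and \eqn{m_{\tau,i}(k)} the
#' per-sequence block scores of [block_posterior()]. Because every
#' sequence's complement is equally likely a priori, identical arms give
#' mean zero exactly; a very large secondary effect drives the variance to
#' zero and the mean to the true-allocation z-statistic (full unblinding).
#'
#' Blocks are fixed consecutive index ranges: rows `1..tau`,
#' `tau+1..2*tau`, and so on; when `data` has a `block_id` column it must
#' agree with that layout. Partial blocks are rejected.
#'
#' @param data A stage-1 data frame with columns `x`, `y` (and optionally
#'   `block_id`).
#' @param tau Block length; must divide `nrow(data)`.
#' @param params An [endpoint_params()] object.
#' @return A `conditional_law` object.
#' @export
block_conditional_moments <- function(data, tau, params) {
  check_stage1(data)
  n1 <- nrow(data)
  stopifnot(tau >= 2, tau %% 2 == 0)
  if (n1 %% tau != 0) {
    stop("`tau` must divide the number of stage-1 subjects (full blocks only)",
         call. = FALSE)
  }
  if ("block_id" %in% names(data)) {
    expect_id <- rep(seq_len(n1 / tau), each = tau)
    if (length(unique(data$block_id)) != n1 / tau ||
        any(as.integer(factor(data$block_id, unique(data$block_id))) !=
            expect_id)) {
      stop("`block_id` must mark consecutive full blocks of length tau",
           call. = FALSE)
    }
  }
  W <- enumerate_block_allocations(tau)
  ld <- arm_logdens(data$x, data$y, params)
  mo <- block_moment_engine(
    d = matrix(ld$l1 - ld$l0, nrow = 1),
    x = matrix(data$x, nrow = 1), W = W
  )
  conditional_law(mean = mo$sum_m[1] / (params$sigma * sqrt(n1)),
                  variance = max(mo$sum_v[1], 0) / (params$sigma^2 * n1))
}

# internal: vectorised block moments across many runs.
# d, x: (runs x n1) matrices of per-subject log-LRs and primary responses;
# W: K x tau allocation matrix. Returns per-run sums over blocks of the
# posterior mean block score (sum_m) and posterior score variance (sum_v),
# both unnormalised by sigma/n1.
block_moment_engine <- function(d, x, W) {
  runs <- nrow(d); n1 <- ncol(d); tau <- ncol(W)
  nb <- n1 %/% tau
  # each block of tau consecutive subjects becomes one column (run-major)
  Db <- matrix(t(d), nrow = tau)          # tau x (nb*runs)
  Xb <- matrix(t(x), nrow = tau)
  S <- crossprod(Db, t(W))                # (nb*runs) x K log-lik (up to const)
  M <- crossprod(Xb, 2 * t(W)) - colSums(Xb)  # block scores m_tau(k)
  S <- S - apply(S, 1, max)
  P <- exp(S)
  P <- P / rowSums(P)
  m_mean <- rowSums(P * M)
  m_var <- rowSums(P * M^2) - m_mean^2
  # fold blocks back onto runs: blocks of run r occupy columns r of the
  # tau-major layout -> rows (seq) with run index recycled fastest? The
  # t(D) layout stacks run-1 row first, so block rows are grouped by run.
  run_id <- rep(seq_len(runs), each = nb)
  list(sum_m = as.vector(tapply(m_mean, run_id, sum)),
       sum_v = as.vector(tapply(m_var, run_id, sum)))
}

#' Worst-case second-stage sample size under block randomization
#'
#' Computes the blocked conditional law via [block_conditional_moments()]
#' and applies the same closed-form worst-case rule as [worst_case_n2()]
#' with \eqn{(m_1, V_1)} replaced by \eqn{(m_{Z_1}, v_{Z_1})}; the attained
#' conditional error uses the same normal-approximation formula.
#'
#' @inheritParams block_conditional_moments
#' @param design A [trial_design()] (its `scheme`/`tau` need not be set to
#'   block; only the bounds, `n1` and `alpha` enter the rule).
#' @return A one-row tibble with columns `n2` and `conditional_error`.
#' @export
worst_case_n2_block <- function(data, tau, params, design) {
  law <- block_conditional_moments(data, tau, params)
  worst_case_n2(law, design)
}
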