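#' Maximum type I error rate under worst-case blinded reassessment
#'
#' Estimates by Monte Carlo the maximum attainable type I error rate of a
#' two-stage z-test (or t-test) when, after a blinded interim analysis, the
#' second-stage sample size is chosen adversarially — i.e. to maximize the
#' conditional rejection probability under the primary-endpoint null —
#' using the information that the secondary endpoint leaks about the
#' treatment allocation.
#'
#' Each simulation run draws a stage-1 dataset under the null
#' (`mu0 == mu1`), computes the conditional law of the first-stage
#' z-statistic given the blinded data (per-subject posteriors for the
#' unblocked rule, block posteriors for the block rule), and applies the
#' closed-form worst-case rule of [worst_case_n2()]. Two estimators are
#' available:
#'
#' * `method = "analytic"`: averages the attained blinded conditional
#'   error across runs (the normal-approximation evaluation). `mc_se` is
#'   the standard deviation of the per-run conditional errors divided by
#'   `sqrt(n_runs)`.
#' * `method = "montecarlo"`: completes each trial and records actual
#'   rejections. The chosen `n2` is rounded to the nearest even integer
#'   and clamped to the design bounds. For `test = "z"` the final
#'   statistic is \eqn{Z_N = \sqrt{n_1/N} Z_1 + \sqrt{n_2/N} Z_2} with
#'   \eqn{Z_2} the (exactly standard normal) second-stage statistic; for
#'   `test = "t"` a pooled-variance two-sample t-test with `N - 2` degrees
#'   of freedom is performed, simulated exactly through the group
#'   sufficient statistics (means and within-group sums of squares) of
#'   both stages. `mc_se` is the binomial standard error. The t-test
#'   requires a finite `n2max`.
#'
#' `rule = "auto"` uses the block rule when the design's scheme is
#' `"block"` and the unblocked rule otherwise; forcing
#' `rule = "random_allocation"` on a block design reproduces the
#' mismatched-rule setting where the adversary ignores the blocking.
#' Setting `n2_fixed` disables the adaptation (the trial always continues
#' with that second-stage size) — the null calibration check.
#'
#' @param params An [endpoint_params()] with `mu0 == mu1` (primary null).
#' @param design A [trial_design()].
#' @param n_runs Number of simulation runs.
#' @param seed Integer seed.
#' @param method `"analytic"` or `"montecarlo"`.
#' @param test Final-analysis test for `method = "montecarlo"`: `"z"` or
#'   `"t"`.
#' @param rule Reassessment rule: `"auto"`, `"random_allocation"`
#'   (unblocked) or `"block"`.
#' @param n2_fixed Optional fixed second-stage size disabling adaptation.
#' @param chunk Runs per vectorised chunk (memory/speed trade-off).
#' @return An object of class `alpha_max`; see [tidy.alpha_max()].
#' @examples
#' p <- endpoint_params(nu1 = 1, rho = 0.8)
#' d <- trial_design(n1 = 144)
#' estimate_max_type1(p, d, n_runs = 2000, seed = 1)
#' @export
estimate_max_type1 <- function(params, design, n_runs = 2e5, seed = 1,
                               method = c("analytic", "montecarlo"),
                               test = c("z", "t"),
                               rule = c("auto", "random_allocation",
                                        "block"),
                               n2_fixed = NULL, chunk = 2e4) {
  method <- match.arg(method)
  test <- match.arg(test)
  rule <- match.arg(rule)
  stopifnot(inherits(params, "endpoint_params"),
            inherits(design, "trial_design"), n_runs >= 1)
  if (params$mu0 != params$mu1) {
    warning("type I error is defined under mu0 == mu1; ",
            "simulating at the supplied (non-null) primary means")
  }
  if (rule == "auto") {
    rule <- if (design$scheme == "block") "block" else "random_allocation"
  }
  if (rule == "block" && !is.finite(design$tau)) {
    stop("block rule requires a design with scheme = \"block\"",
         call. = FALSE)
  }
  if (method == "montecarlo" && test == "t" &&
      !is.finite(design$n2max) && is.null(n2_fixed)) {
    stop("the t-test estimator requires a finite n2max", call. = FALSE)
  }
  res <- mc_engine(params, design, n_runs, seed, method, test, rule,
                   n2_fixed, chunk)
  structure(
    list(estimate = res$estimate, mc_se = res$mc_se, n_runs = n_runs,
         seed = seed, method = method, test = test, rule = rule,
         n2_fixed = n2_fixed, params = params, design = design),
    class = "alpha_max"
  )
}

#' @export
print.alpha_max <- function(x, ...) {
  lab <- if (!is.null(x$n2_fixed)) {
    sprintf("fixed n2 = %g (no adaptation)", x$n2_fixed)
  } else "worst-case reassessment"
  cat(sprintf("<alpha_max>  %s, %s\n", lab,
              if (x$method == "analytic") "analytic conditional error"
              else sprintf("full trial simulation (%s-test)", x$test)))
  cat(sprintf("  estimate = %.5f  (mc_se = %.5f, %s runs, seed %s)\n",
              x$estimate, x$mc_se, format(x$n_runs, big.mark = ","),
              format(x$seed)))
  invisible(x)
}

# ---- internal vectorised engine ------------------------------------------

# one pass over n_runs in chunks; accumulates either conditional errors
# (analytic) or rejection indicators (montecarlo)
mc_engine <- function(params, design, n_runs, seed, method, test, rule,
                      n2_fixed, chunk) {
  set.seed(seed)
  acc <- c(s = 0, s2 = 0, n = 0)
  W <- if (rule == "block") enumerate_block_allocations(design$tau)
  zc <- stats::qnorm(1 - design$alpha)
  n1 <- design$n1
  done <- 0
  while (done < n_runs) {
    m <- min(chunk, n_runs - done)
    st <- chunk_stats(params, design, m, rule, W,
                      need_x = (method == "montecarlo" && test == "t"))
    if (is.null(n2_fixed)) {
      wc <- wc_rule(st$m1, st$v1, n1, design$n2min, design$n2max,
                    design$alpha)
      n2 <- wc$n2
      err <- wc$error
    } else {
      n2 <- rep(n2_fixed, m)
      err <- conditional_error_blinded(st$m1, st$v1, n1, n2, design$alpha)
    }
    if (method == "analytic") {
      acc <- acc + c(sum(err), sum(err^2), m)
    } else {
      n2r <- ifelse(is.finite(n2),
                    pmin(pmax(2 * round(n2 / 2), design$n2min),
                         design$n2max), Inf)
      rej <- if (test == "z") reject_z(st$z1, n1, n2r, zc)
             else reject_t(st, n1, n2r, params$sigma, design$alpha)
      acc <- acc + c(sum(rej), sum(rej), m)
    }
    done <- done + m
  }
  est <- acc[["s"]] / acc[["n"]]
  mc_se <- if (method == "analytic") {
    sqrt(max(acc[["s2"]] / acc[["n"]] - est^2, 0) / acc[["n"]])
  } else {
    sqrt(est * (1 - est) / acc[["n"]])
  }
  list(estimate = est, mc_se = mc_se)
}

# per-chunk blinded statistics: m1, v1 (conditional law), z1 (true) and,
# when needed for the t-test, stage-1 group sufficient statistics
chunk_stats <- function(params, design, m, rule, W, need_x = FALSE) {
  g <- allocation_matrix(m, design)
  xy <- draw_responses(g, params)
  n1 <- design$n1
  z1 <- rowSums((2 * g - 1) * xy$x) / (params$sigma * sqrt(n1))
  if (rule == "block") {
    ld <- arm_logdens(xy$x, xy$y, params)
    mo <- block_moment_engine(ld$l1 - ld$l0, xy$x, W)
    m1 <- mo$sum_m / (params$sigma * sqrt(n1))
    v1 <- pmax(mo$sum_v, 0) / (params$sigma^2 * n1)
  } else {
    q <- posterior_prob(xy$x, xy$y, params)
    m1 <- rowSums((2 * q - 1) * xy$x) / (params$sigma * sqrt(n1))
    v1 <- 4 * rowSums(xy$x^2 * q * (1 - q)) / (params$sigma^2 * n1)
  }
  out <- list(m1 = m1, v1 = v1, z1 = z1)
  if (need_x) {
    tx <- g == 1
    nt <- rowSums(tx)                      # treated count (n1/2 if balanced)
    sxt <- rowSums(xy$x * tx)
    sxt2 <- rowSums(xy$x^2 * tx)
    out$grp1 <- list(n = nt, mean = sxt / nt,
                     ss = sxt2 - sxt^2 / nt)
    nc <- n1 - nt
    sxc <- rowSums(xy$x) - sxt
    sxc2 <- rowSums(xy$x^2) - sxt2
    out$grp0 <- list(n = nc, mean = sxc / nc,
                     ss = sxc2 - sxc^2 / nc)
  }
  out
}

# z-test rejection: Z2 is exactly N(0,1) under the null for any balanced
# second stage, so it is drawn directly; n2 = Inf is the limit ZN = Z2
reject_z <- function(z1, n1, n2, zc) {
  z2 <- stats::rnorm(length(z1))
  N <- n1 + n2
  w1 <- ifelse(is.finite(n2), sqrt(n1 / N), 0)
  w2 <- ifelse(is.finite(n2), sqrt(n2 / N), 1)
  zn <- w1 * z1 + w2 * z2
  zero <- n2 == 0
  zn[zero] <- z1[zero]
  zn > zc
}

# pooled-variance t-test via exact group sufficient statistics:
# second-stage group means ~ N(mu, sigma^2/(n2/2)) and sums of squares
# ~ sigma^2 * chisq(n2/2 - 1), combined with the simulated stage-1 groups
reject_t <- function(st, n1, n2, sigma, alpha) {
  m <- length(n2)
  h2 <- n2 / 2
  comb <- function(grp) {
    mean2 <- stats::rnorm(m, 0, ifelse(h2 > 0, sigma / sqrt(pmax(h2, 1)), 0))
    ss2 <- sigma^2 * stats::rchisq(m, df = pmax(h2 - 1, 0))
    mean2[h2 == 0] <- 0
    ss2[h2 == 0] <- 0
    ntot <- grp$n + h2
    mtot <- (grp$n * grp$mean + h2 * mean2) / ntot
    ss <- grp$ss + ss2 + grp$n * (grp$mean - mtot)^2 +
      h2 * (mean2 - mtot)^2
    list(n = ntot, mean = mtot, ss = ss)
  }
  g1 <- comb(st$grp1)
  g0 <- comb(st$grp0)
  df <- g1$n + g0$n - 2
  sp <- sqrt((g1$ss + g0$ss) / df)
  tstat <- (g1$mean - g0$mean) / (sp * sqrt(1 / g1$n + 1 / g0$n))
  tstat > stats::qt(1 - alpha, df)
}

# shared engine for the case study: one pass over the draws, several
# second-stage restrictions evaluated on the same (m1, v1)
analytic_multi_bounds <- function(params, design, bounds, n_runs, seed,
                                  chunk = 2e4) {
  set.seed(seed)
  nb <- length(bounds)
  s <- numeric(nb); s2 <- numeric(nb)
  done <- 0
  while (done < n_runs) {
    m <- min(chunk, n_runs - done)
    st <- chunk_stats(params, design, m, "random_allocation", NULL)
    for (j in seq_len(nb)) {
      err <- wc_rule(st$m1, st$v1, design$n1, bounds[[j]][1],
                     bounds[[j]][2], design$alpha)$error
      s[j] <- s[j] + sum(err)
      s2[j] <- s2[j] + sum(err^2)
    }
    done <- done + m
  }
  est <- s / n_runs
  tibble::tibble(
    restriction = names(bounds),
    n2min = vapply(bounds, `[`, numeric(1), 1),
    n2max = vapply(bounds, `[`, numeric(1), 2),
    estimate = est,
    mc_se = sqrt(pmax(s2 / n_runs - est^2, 0) / n_runs)
  )
}

# ---- study drivers -------------------------------------------------------

#' Case study: maximum inflation for the Fingolimod parameterizations
#'
#' Scans the correlation `rho` over a grid and estimates, for each value,
#' the maximum type I error rate attainable by worst-case blinded
#' reassessment for a phase III trial with an interim analysis after
#' `n1 = 400` subjects and a strongly treatment-affected laboratory
#' secondary endpoint ([fingolimod_params()]). Both an unrestricted second
#' stage and a restriction `n2 in [200, 1600]` are evaluated on the same
#' simulated draws.
#'
#' @param endpoint `"lymphocyte"` or `"wbc"`.
#' @param rho_grid Correlation grid; default 10 equispaced points over
#'   `[0, 0.9]`.
#' @param n_runs Simulation runs per grid point.
#' @param seed Integer master seed; each grid point uses an offset
#'   sub-seed.
#' @param n1 First-stage sample size.
#' @param alpha One-sided level.
#' @param restrictions Named list of `c(n2min, n2max)` pairs.
#' @param chunk Runs per vectorised chunk.
#' @return A tibble of class `blindsr_case_study`: one row per
#'   (`rho`, `restriction`) with `estimate` and `mc_se`.
#' @seealso [autoplot.blindsr_case_study()]
#' @export
run_case_study <- function(endpoint = c("lymphocyte", "wbc"),
                           rho_grid = seq(0, 0.9, length.out = 10),
                           n_runs = 2e5, seed = 1, n1 = 400,
                           alpha = 0.025,
                           restrictions = list(
                             unrestricted = c(0, Inf),
                             restricted = c(200, 1600)
                           ),
                           chunk = 2e4) {
  endpoint <- match.arg(endpoint)
  design <- trial_design(n1 = n1, alpha = alpha)
  out <- purrr::imap(rho_grid, function(rho, i) {
    params <- fingolimod_params(endpoint, rho = rho)
    res <- analytic_multi_bounds(params, design, restrictions, n_runs,
                                 seed = seed + 1000L * (i - 1L),
                                 chunk = chunk)
    res$rho <- rho
    res
  })
  out <- dplyr::bind_rows(out)
  out$endpoint <- endpoint
  out$n_runs <- n_runs
  out$seed <- seed
  out <- dplyr::relocate(out, "endpoint", "rho", "restriction")
  class(out) <- c("blindsr_case_study", class(out))
  out
}

#' Sweep of the maximum inflation over secondary effect sizes
#'
#' Estimates the maximum type I error rate as a function of the secondary
#' endpoint effect size for several correlations, under the study
#' conditions of the unblocked setting: `n1 = 144`, `sigma = 1`, one-sided
#' 2.5% z-test. Both the unrestricted and a restricted
#' (`n2 in [n1/2, 4 n1]`) second stage can be requested.
#'
#' @param effect_grid Secondary effect sizes `nu1 - nu0` (with `nu0 = 0`).
#' @param rho_list Correlations to sweep.
#' @param design A [trial_design()]; its bounds define the restriction.
#' @param n_runs Simulation runs per grid point.
#' @param seed Master seed (per-point offsets derived from it).
#' @param method,test Passed to [estimate_max_type1()].
#' @param chunk Runs per vectorised chunk.
#' @return A tibble of class `blindsr_sweep`: one row per
#'   (`rho`, `effect`) with `estimate` and `mc_se`.
#' @export
run_effectsize_sweep <- function(effect_grid = seq(0, 2, by = 0.25),
                                 rho_list = c(0, 0.5, 0.8, 0.9, 1),
                                 design = trial_design(n1 = 144),
                                 n_runs = 2e4, seed = 1,
                                 method = c("analytic", "montecarlo"),
                                 test = c("z", "t"), chunk = 2e4) {
  method <- match.arg(method)
  test <- match.arg(test)
  grid <- expand.grid(effect = effect_grid, rho = rho_list,
                      KEEP.OUT.ATTRS = FALSE)
  out <- purrr::pmap(grid, function(effect, rho) {
    params <- endpoint_params(nu0 = 0, nu1 = effect, sigma = 1, rho = rho)
    i <- which(grid$effect == effect & grid$rho == rho)[1]
    fit <- estimate_max_type1(params, design, n_runs = n_runs,
                              seed = seed + 1000L * (i - 1L),
                              method = method, test = test, chunk = chunk)
    tibble::tibble(rho = rho, effect = effect, estimate = fit$estimate,
                   mc_se = fit$mc_se)
  })
  out <- dplyr::bind_rows(out)
  out$n_runs <- n_runs
  out$seed <- seed
  class(out) <- c("blindsr_sweep", class(out))
  out
}

#' Block-randomization study of the maximum inflation
#'
#' Estimates the maximum type I error rate when randomization is blocked
#' and the adversary uses the block structure in the reassessment rule,
#' across block lengths. Smaller blocks reveal more about the allocation
#' and give larger inflation.
#'
#' @param taus Block lengths to compare.
#' @param params An [endpoint_params()] (null primary means).
#' @param n1 First-stage sample size (divisible by every `tau`).
#' @param n2min,n2max Second-stage bounds.
#' @param alpha One-sided level.
#' @param n_runs,seed,chunk Simulation controls.
#' @return A tibble of class `blindsr_block_study`: one row per `tau`.
#' @export
run_block_study <- function(taus = c(2, 4, 6), params, n1 = 144,
                            n2min = 0, n2max = Inf, alpha = 0.025,
                            n_runs = 2e4, seed = 1, chunk = 2e4) {
  out <- purrr::imap(taus, function(tau, i) {
    design <- trial_design(n1 = n1, n2min = n2min, n2max = n2max,
                           alpha = alpha, scheme = "block", tau = tau)
    fit <- estimate_max_type1(params, design, n_runs = n_runs,
                              seed = seed + 1000L * (i - 1L),
                              rule = "block", chunk = chunk)
    tibble::tibble(tau = tau, estimate = fit$estimate, mc_se = fit$mc_se)
  })
  out <- dplyr::bind_rows(out)
  out$n_runs <- n_runs
  out$seed <- seed
  class(out) <- c("blindsr_block_study", class(out))
  out
}

#' Mismatched-rule study: block randomization, unblocked rule
#'
#' Estimates the maximum type I error rate when the trial uses block
#' randomization but the adversarial reassessment applies the unblocked
#' rule (block sizes unknown to the analyst), and compares it against the
#' same rule under genuine random allocation at identical parameters and
#' seed. The two agree closely: ignoring the block structure removes the
#' extra unblinding that blocking would otherwise provide.
#'
#' @param params An [endpoint_params()] (null primary means).
#' @param tau Block length of the data-generating design.
#' @param n1,n2min,n2max,alpha Design settings.
#' @param n_runs,seed,chunk Simulation controls.
#' @return A tibble with rows `block_data` and `random_allocation`, their
#'   estimates, and the difference.
#' @export
run_mismatch_study <- function(params, tau = 2, n1 = 144, n2min = 0,
                               n2max = Inf, alpha = 0.025, n_runs = 2e4,
                               seed = 1, chunk = 2e4) {
  d_block <- trial_design(n1 = n1, n2min = n2min, n2max = n2max,
                          alpha = alpha, scheme = "block", tau = tau)
  d_rand <- trial_design(n1 = n1, n2min = n2min, n2max = n2max,
                         alpha = alpha)
  f_block <- estimate_max_type1(params, d_block, n_runs = n_runs,
                                seed = seed, rule = "random_allocation",
                                chunk = chunk)
  f_rand <- estimate_max_type1(params, d_rand, n_runs = n_runs,
                               seed = seed, chunk = chunk)
  tibble::tibble(
    data_scheme = c("block_data", "random_allocation"),
    tau = c(tau, NA_real_),
    estimate = c(f_block$estimate, f_rand$estimate),
    mc_se = c(f_block$mc_se, f_rand$mc_se),
    n_runs = n_runs, seed = seed
  )
}

#' Unblinding correlation between blinded and unblinded effect estimates
#'
#' Across simulated null stage-1 datasets under random allocation, computes
#' the Pearson correlation `r` between the unblinded first-stage effect
#' estimate \eqn{\bar X} and its blinded reconstruction \eqn{\bar X_b}
#' (see [effect_estimates()]). `r` measures how much the secondary
#' endpoint unblinds the primary effect estimate: it approaches 1 as the
#' standardised secondary effect grows, and is degenerate (reported as
#' `NA`) when the arms are indistinguishable and `rho = 0`, since
#' \eqn{\bar X_b} is then identically 0.
#'
#' @param params An [endpoint_params()] (null primary means).
#' @param n1 First-stage sample size.
#' @param n_runs Simulated datasets.
#' @param seed Integer seed.
#' @param chunk Runs per vectorised chunk.
#' @return A one-row tibble with `r`, `n_runs`, `seed`.
#' @export
unblinding_correlation <- function(params, n1 = 400, n_runs = 5e4,
                                   seed = 1, chunk = 2e4) {
  stopifnot(inherits(params, "endpoint_params"), n1 %% 2 == 0)
  design <- trial_design(n1 = n1)
  set.seed(seed)
  xb <- numeric(n_runs); xbb <- numeric(n_runs)
  done <- 0
  while (done < n_runs) {
    m <- min(chunk, n_runs - done)
    g <- allocation_matrix(m, design)
    xy <- draw_responses(g, params)
    q <- posterior_prob(xy$x, xy$y, params)
    ii <- done + seq_len(m)
    xb[ii] <- rowSums(2 * (2 * g - 1) * xy$x) / n1
    xbb[ii] <- rowSums(2 * (2 * q - 1) * xy$x) / n1
    done <- done + m
  }
  r <- if (stats::sd(xbb) == 0) NA_real_ else stats::cor(xb, xbb)
  tibble::tibble(r = r, n_runs = n_runs, seed = seed)
}

#' Unblinding correlation over a correlation grid
#'
#' Convenience sweep of [unblinding_correlation()] over a grid of
#' endpoint correlations `rho` for a case-study parameterization.
#'
#' @inheritParams run_case_study
#' @return A tibble of class `blindsr_unblinding`: one row per `rho` with
#'   the correlation `r`.
#' @export
run_unblinding_study <- function(endpoint = c("lymphocyte", "wbc"),
                                 rho_grid = seq(0, 0.9, length.out = 10),
                                 n1 = 400, n_runs = 5e4, seed = 1,
                                 chunk = 2e4) {
  endpoint <- match.arg(endpoint)
  out <- purrr::imap(rho_grid, function(rho, i) {
    params <- fingolimod_params(endpoint, rho = rho)
    res <- unblinding_correlation(params, n1 = n1, n_runs = n_runs,
                                  seed = seed + 1000L * (i - 1L),
                                  chunk = chunk)
    tibble::tibble(rho = rho, r = res$r)
  })
  out <- dplyr::bind_rows(out)
  out$endpoint <- endpoint
  out$n_runs <- n_runs
  out$seed <- seed
  class(out) <- c("blindsr_unblinding", class(out))
  out
}
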