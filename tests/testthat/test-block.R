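test_that("block allocation enumeration is complete and balanced", {
  expect_equal(nrow(enumerate_block_allocations(2)), 2)
  expect_equal(nrow(enumerate_block_allocations(6)), 20)
  W4 <- enumerate_block_allocations(4)
  expect_equal(nrow(W4), 6)
  expect_true(all(rowSums(W4) == 2))
  expect_equal(nrow(unique(W4)), 6)
  # with 1 = treatment (B), the six length-4 sequences as a set
  lab <- apply(W4, 1, function(w) paste(c("A", "B")[w + 1], collapse = ""))
  expect_setequal(lab, c("AABB", "ABAB", "ABBA", "BABA", "BBAA", "BAAB"))
  expect_error(enumerate_block_allocations(3))
  expect_error(enumerate_block_allocations(14))
})

test_that("block posterior normalizes and matches two-hypothesis Bayes", {
  p <- endpoint_params(nu0 = 0, nu1 = 2, sigma = 1, rho = 0)
  # identical arms: uniform over sequences
  p0 <- endpoint_params(nu0 = 1, nu1 = 1, sigma = 1, rho = 0.5)
  blk <- tibble::tibble(x = c(0.3, -1, 2, 0), y = c(1, 0, -0.5, 2))
  bp0 <- block_posterior(blk, p0)
  expect_equal(bp0$probability, rep(1 / 6, 6))

  # tau = 2: direct two-hypothesis computation (AB vs BA)
  blk2 <- tibble::tibble(x = c(0.4, -0.2), y = c(0, 2))
  f <- function(x, y, nu) dnorm(x) * dnorm(y, nu)
  lAB <- f(0.4, 0, 0) * f(-0.2, 2, 2)   # first control, second treated
  lBA <- f(0.4, 0, 2) * f(-0.2, 2, 0)
  bp2 <- block_posterior(blk2, p)
  w <- enumerate_block_allocations(2)
  iAB <- which(w[, 1] == 0)
  expect_equal(bp2$probability[iAB], lAB / (lAB + lBA), tolerance = 1e-12)
  expect_equal(sum(bp2$probability), 1)
  # scores follow the 2g-1 contrast
  expect_equal(sort(bp2$score), sort(c(-0.2 - 0.4, 0.4 + 0.2)))

  # random blocks normalize exactly
  set.seed(8)
  for (tau in c(2, 4, 6)) {
    blkr <- tibble::tibble(x = rnorm(tau), y = rnorm(tau))
    expect_equal(sum(block_posterior(blkr, p)$probability), 1)
  }
})

test_that("per-subject marginals from block posteriors are probabilities", {
  p0 <- endpoint_params(nu0 = 1, nu1 = 1, sigma = 1, rho = 0)
  p <- endpoint_params(nu0 = 0, nu1 = 1, sigma = 1, rho = 0.3)
  W <- enumerate_block_allocations(4)
  set.seed(21)
  marg <- replicate(300, {
    blk <- tibble::tibble(x = rnorm(4), y = rnorm(4) + rep(0:1, 2))
    colSums(block_posterior(blk, p, W)$probability * W)
  })
  expect_true(all(marg >= 0 & marg <= 1))
  # identical arms: marginal treated probability is exactly 1/2
  blk <- tibble::tibble(x = rnorm(4), y = rnorm(4))
  m0 <- colSums(block_posterior(blk, p0, W)$probability * W)
  expect_equal(m0, rep(0.5, 4))
})

test_that("tau = 2 block marginal equals the two-hypothesis Bayes marginal", {
  p <- endpoint_params(nu0 = 0.5, nu1 = 1.7, sigma = 0.9, rho = 0.4)
  W <- enumerate_block_allocations(2)
  set.seed(9)
  for (i in 1:20) {
    blk <- simulate_stage1(p, trial_design(n1 = 2, scheme = "block",
                                           tau = 2), seed = 100 + i)
    post <- block_posterior(blk, p, W)
    marg1 <- sum(post$probability * W[, 1])
    # direct Bayes over the two sequences using per-subject densities
    ld <- blindsr:::arm_logdens(blk$x, blk$y, p)
    l_ab <- ld$l0[1] + ld$l1[2]
    l_ba <- ld$l1[1] + ld$l0[2]
    expect_equal(marg1, 1 / (1 + exp(l_ab - l_ba)), tolerance = 1e-10)
  }
})

test_that("block conditional moments match exhaustive enumeration", {
  p <- endpoint_params(nu0 = 0, nu1 = 1.5, sigma = 1.2, rho = 0.3)
  for (seed in 1:10) {
    d <- simulate_stage1(p, trial_design(n1 = 4, scheme = "block",
                                         tau = 4), seed = seed)
    law <- block_conditional_moments(d, 4, p)
    ref <- enum_block_moments(d$x, d$y, p)
    expect_equal(law$mean, ref$mean, tolerance = 1e-10)
    expect_equal(law$variance, ref$variance, tolerance = 1e-10)
  }
})

test_that("block moments behave at the information extremes", {
  # identical arms: mean is exactly zero (complement sequences cancel)
  p0 <- endpoint_params(nu0 = 1, nu1 = 1, sigma = 1, rho = 0.2)
  d <- simulate_stage1(p0, trial_design(n1 = 24, scheme = "block",
                                        tau = 4), seed = 3)
  law0 <- block_conditional_moments(d, 4, p0)
  expect_equal(law0$mean, 0, tolerance = 1e-12)

  # huge secondary effect: variance -> 0, mean -> true-allocation z
  pbig <- endpoint_params(nu0 = 0, nu1 = 40, sigma = 1, rho = 0)
  db <- simulate_stage1(pbig, trial_design(n1 = 24, scheme = "block",
                                           tau = 4), seed = 4)
  lawb <- block_conditional_moments(db, 4, pbig)
  expect_lt(lawb$variance, 1e-8)
  expect_equal(lawb$mean, z_statistic(db, 1), tolerance = 1e-6)

  # swapping the arm labels negates the conditional mean
  p <- endpoint_params(nu0 = 0, nu1 = 1, sigma = 1, rho = 0.3)
  pswap <- endpoint_params(nu0 = 1, nu1 = 0, sigma = 1, rho = 0.3)
  dd <- simulate_stage1(p, trial_design(n1 = 12, scheme = "block",
                                        tau = 4), seed = 5)
  expect_equal(block_conditional_moments(dd, 4, pswap)$mean,
               -block_conditional_moments(dd, 4, p)$mean,
               tolerance = 1e-10)
  expect_equal(block_conditional_moments(dd, 4, pswap)$variance,
               block_conditional_moments(dd, 4, p)$variance,
               tolerance = 1e-10)
})

test_that("blocking adds allocation information relative to the unblocked law", {
  # on average the blocked conditional variance is no larger
  p <- endpoint_params(nu0 = 0, nu1 = 1, sigma = 1, rho = 0)
  dsg <- trial_design(n1 = 16, scheme = "block", tau = 2)
  set.seed(6)
  diffs <- vapply(1:400, function(i) {
    d <- simulate_stage1(p, dsg, seed = 2000 + i)
    vb <- block_conditional_moments(d, 2, p)$variance
    q <- allocation_posterior(d, p)
    vu <- conditional_moments(q, p$sigma)$variance
    vu - vb
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("blocked worst-case decision agrees with a grid search", {
  p <- endpoint_params(nu0 = 0, nu1 = 1.2, sigma = 1, rho = 0.4)
  d <- trial_design(n1 = 24, n2min = 10, n2max = 300, scheme = "block",
                    tau = 4)
  for (seed in 1:8) {
    dat <- simulate_stage1(p, d, seed = 300 + seed)
    wc <- worst_case_n2_block(dat, 4, p, d)
    law <- block_conditional_moments(dat, 4, p)
    oracle <- grid_oracle_n2(law$mean, law$variance, 24, 10, 300)
    expect_gte(wc$conditional_error, oracle$error - 1e-9)
  }
  # identical arms, tau = 2: uniform over {AB, BA}, so each block's score
  # is +/-(x1 - x2) with mean zero and variance (x1 - x2)^2
  p0 <- endpoint_params(nu0 = 1, nu1 = 1, sigma = 1.4, rho = 0)
  d2 <- trial_design(n1 = 24, n2min = 10, n2max = 300, scheme = "block",
                     tau = 2)
  dat0 <- simulate_stage1(p0, d2, seed = 77)
  law0 <- block_conditional_moments(dat0, 2, p0)
  diffs <- dat0$x[seq(1, 23, 2)] - dat0$x[seq(2, 24, 2)]
  expect_equal(law0$mean, 0, tolerance = 1e-12)
  expect_equal(law0$variance, sum(diffs^2) / (1.4^2 * 24),
               tolerance = 1e-10)
  expect_equal(worst_case_n2_block(dat0, 2, p0, d2),
               worst_case_n2(law0, d2))
})

test_that("partial blocks and inconsistent block ids are rejected", {
  p <- endpoint_params(nu0 = 0, nu1 = 1)
  d <- tibble::tibble(x = rnorm(6), y = rnorm(6))
  expect_error(block_conditional_moments(d, 4, p), "divide")
  d$block_id <- c(1, 1, 2, 2, 3, 3)
  expect_error(block_conditional_moments(d, 2, p), NA)
  d$block_id <- c(1, 2, 1, 2, 3, 3)
  expect_error(block_conditional_moments(d, 2, p), "consecutive")
})
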