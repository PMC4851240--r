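test_that("analytic and full-simulation estimators of the inflation agree", {
  p <- endpoint_params(nu0 = 0, nu1 = 1, rho = 0.8)
  d <- trial_design(n1 = 144, n2min = 72, n2max = 576)
  a <- estimate_max_type1(p, d, n_runs = 3e4, seed = 1)
  m <- estimate_max_type1(p, d, n_runs = 3e4, seed = 2,
                          method = "montecarlo", test = "z")
  expect_lt(abs(a$estimate - m$estimate),
            3 * sqrt(a$mc_se^2 + m$mc_se^2))
  expect_gt(a$estimate, 0.025)   # genuine inflation at this effect size
})

test_that("known-variance z-test is inflated even with no secondary effect", {
  # the rule still exploits excess blinded variance when sigma is known
  p0 <- endpoint_params(nu0 = 0, nu1 = 0)
  d <- trial_design(n1 = 144)
  z0 <- estimate_max_type1(p0, d, n_runs = 1.2e5, seed = 3,
                           method = "montecarlo", test = "z")
  expect_gt(z0$estimate - 0.025, 3 * z0$mc_se)
})

test_that("t-test at zero secondary effect is not anticonservative", {
  p0 <- endpoint_params(nu0 = 0, nu1 = 0)
  d <- trial_design(n1 = 144, n2min = 72, n2max = 576)
  t0 <- estimate_max_type1(p0, d, n_runs = 3e4, seed = 4,
                           method = "montecarlo", test = "t")
  expect_lte(t0$estimate, 0.025 + 3 * t0$mc_se)
  # and the t machinery stays consistent with z at a configuration where
  # the variance artifact is dominated by real unblinding
  p <- endpoint_params(nu0 = 0, nu1 = 2, rho = 0.8)
  tz <- estimate_max_type1(p, d, n_runs = 2e4, seed = 5,
                           method = "montecarlo", test = "t")
  zz <- estimate_max_type1(p, d, n_runs = 2e4, seed = 6,
                           method = "montecarlo", test = "z")
  expect_lt(abs(tz$estimate - zz$estimate),
            0.004 + 3 * sqrt(tz$mc_se^2 + zz$mc_se^2))
})

test_that("restricting the second stage can only lower the maximum", {
  p <- endpoint_params(nu0 = 0, nu1 = 1, rho = 0.5)
  du <- trial_design(n1 = 144)
  dr <- trial_design(n1 = 144, n2min = 72, n2max = 576)
  u <- estimate_max_type1(p, du, n_runs = 2e4, seed = 7)
  r <- estimate_max_type1(p, dr, n_runs = 2e4, seed = 7)
  # same seed: identical draws, pointwise constrained <= unconstrained
  expect_lte(r$estimate, u$estimate)
})

test_that("inflation grows with correlation and effect size and stays bounded", {
  sw <- run_effectsize_sweep(effect_grid = c(0, 1, 2), rho_list = c(0, 0.9),
                             n_runs = 8000, seed = 8)
  for (rh in c(0, 0.9)) {
    est <- sw$estimate[sw$rho == rh][order(sw$effect[sw$rho == rh])]
    expect_true(all(diff(est) > -3 * 0.003))
  }
  e1 <- sw$estimate[sw$effect == 1]
  expect_gt(e1[sw$rho[sw$effect == 1] == 0.9],
            e1[sw$rho[sw$effect == 1] == 0])
  expect_true(all(sw$estimate <= 0.065))
})

test_that("smaller blocks unblind more and raise the maximum inflation", {
  p <- endpoint_params(nu0 = 0, nu1 = 1)
  bs <- run_block_study(taus = c(2, 6), params = p, n1 = 144,
                        n_runs = 1.5e4, seed = 9)
  expect_gt(bs$estimate[bs$tau == 2],
            bs$estimate[bs$tau == 6] - 3 * sqrt(sum(bs$mc_se^2)))
  # block rule beats the unblocked rule on block data at tau = 2
  d_bl <- trial_design(n1 = 144, scheme = "block", tau = 2)
  blocked <- estimate_max_type1(p, d_bl, n_runs = 1.5e4, seed = 10,
                                rule = "block")
  unblocked <- estimate_max_type1(p, d_bl, n_runs = 1.5e4, seed = 10,
                                  rule = "random_allocation")
  expect_gt(blocked$estimate,
            unblocked$estimate - 3 * sqrt(blocked$mc_se^2 +
                                          unblocked$mc_se^2))
})

test_that("ignoring the block structure reproduces the unblocked inflation", {
  p <- endpoint_params(nu0 = 0, nu1 = 1)
  for (tau in c(2, 4)) {
    ms <- run_mismatch_study(p, tau = tau, n1 = 144, n_runs = 2e4,
                             seed = 11)
    diff <- abs(ms$estimate[1] - ms$estimate[2])
    expect_lt(diff, 0.003 + 3 * sqrt(sum(ms$mc_se^2)))
  }
})

test_that("unblinding correlation rises from 0 toward 1 with information", {
  # enormous secondary effect: near-perfect reconstruction
  pbig <- endpoint_params(nu0 = 0, nu1 = 20)
  rbig <- unblinding_correlation(pbig, n1 = 100, n_runs = 2000, seed = 12)
  expect_gt(rbig$r, 0.99)
  # no secondary effect and rho = 0: blinded estimate degenerate
  p0 <- endpoint_params(nu0 = 0, nu1 = 0, rho = 0)
  r0 <- unblinding_correlation(p0, n1 = 100, n_runs = 500, seed = 13)
  expect_true(is.na(r0$r))
  # monotone in rho for a partially unblinding endpoint
  ru <- run_unblinding_study("wbc", rho_grid = c(0, 0.5, 0.9), n1 = 200,
                             n_runs = 4000, seed = 14)
  expect_true(all(diff(ru$r) > 0))
  expect_true(all(ru$r > 0.5 & ru$r < 1))
})

test_that("case-study driver returns a tidy grid with both restrictions", {
  cs <- run_case_study("wbc", rho_grid = c(0, 0.9), n_runs = 4000,
                       seed = 15)
  expect_s3_class(cs, "blindsr_case_study")
  expect_equal(nrow(cs), 4)
  expect_setequal(unique(cs$restriction), c("unrestricted", "restricted"))
  wide <- split(cs$estimate, cs$restriction)
  expect_true(all(wide$restricted <= wide$unrestricted))
  # reproducibility under the same seed
  cs2 <- run_case_study("wbc", rho_grid = c(0, 0.9), n_runs = 4000,
                        seed = 15)
  expect_equal(cs$estimate, cs2$estimate)
})

test_that("tidy, glance and autoplot expose the fitted results", {
  p <- endpoint_params(nu0 = 0, nu1 = 1, rho = 0.5)
  fit <- estimate_max_type1(p, trial_design(n1 = 40), n_runs = 500,
                            seed = 16)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("estimate", "mc_se", "n_runs", "seed", "method",
                     "test", "rule"))
  gl <- glance(fit)
  expect_equal(gl$rho, 0.5)
  expect_equal(gl$secondary_effect, 1)
  cs <- run_case_study("wbc", rho_grid = c(0, 0.5), n_runs = 500,
                       seed = 17)
  expect_s3_class(autoplot(cs), "ggplot")
  sw <- run_effectsize_sweep(effect_grid = c(0, 1), rho_list = 0,
                             n_runs = 500, seed = 18)
  expect_s3_class(autoplot(sw), "ggplot")
  ru <- run_unblinding_study("wbc", rho_grid = c(0, 0.5), n1 = 50,
                             n_runs = 500, seed = 19)
  expect_s3_class(autoplot(ru), "ggplot")
})
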