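test_that("scenario presets encode the canonical arm parameters", {
  s1 <- scenario_preset(1)
  expect_equal(unclass(s1$control_arm), list(tau = 0, gamma = 0, sigma_t = 1.22))
  expect_equal(unclass(s1$case_arm), list(tau = 0.34, gamma = 0.02, sigma_t = 1.1 * 1.22))

  s2 <- scenario_preset(2)
  expect_equal(s2$case_arm$sigma_t / s2$control_arm$sigma_t, 1.1)
  expect_equal(s2$case_arm$tau, s2$control_arm$tau)
  expect_equal(s2$case_arm$gamma, s2$control_arm$gamma)

  s3 <- scenario_preset(3)
  expect_equal(s3$case_arm$tau, 0.34)
  expect_equal(s3$case_arm$gamma, 0.02)
  expect_equal(s3$control_arm$sigma_t, 1.28)
  expect_equal(s3$case_arm$sigma_t, 1.28)

  s4 <- scenario_preset(4)
  expect_identical(unclass(s4$control_arm), unclass(s4$case_arm))
  expect_equal(s4$control_arm$sigma_t, 1.22)

  # variance reading of the SD inflation
  s2v <- scenario_preset(2, sd_ratio_applies_to = "variance")
  expect_equal(s2v$case_arm$sigma_t^2 / s2v$control_arm$sigma_t^2, 1.1)

  expect_error(scenario_preset(5), class = "invalid_scenario")
})

test_that("scenario constructor enforces the per-scenario structure", {
  expect_error(error_scenario(4, arm_error(0, 0, 1), arm_error(0, 0, 2)),
               class = "invalid_scenario")
  expect_error(error_scenario(2, arm_error(0, 0, 2), arm_error(0, 0, 1)),
               class = "invalid_scenario")
  expect_error(error_scenario(2, arm_error(0.1, 0, 1), arm_error(0, 0, 2)),
               class = "invalid_scenario")
  expect_error(error_scenario(3, arm_error(0, 0, 1), arm_error(0.3, 0, 1.2)),
               class = "invalid_scenario")
})

test_that("apply_error follows the per-arm error law pointwise", {
  ds <- make_dataset(case = c(0, 0, 1, 1), regular = c(1, 0, 1, 0),
                     x_true = c(1.5, 0, 1.0, 0))

  # identity law
  ident <- error_scenario(4, arm_error(0, 0, 0), arm_error(0, 0, 0))
  out <- apply_error(ds, ident, centering_mean = 0.7)
  expect_equal(out$y_observed, c(1.5, 0, 1.0, 0))

  # case-arm mean shift only: Y = X + 0.34 for a case with x = 1.0
  shift <- error_scenario(3, arm_error(0, 0, 0), arm_error(0.34, 0, 0))
  out <- apply_error(ds, shift, centering_mean = 0.7)
  expect_equal(out$y_observed[3], 1.34)
  expect_equal(out$y_observed[1], 1.5) # control untouched

  # centered slope vanishes at the centering mean
  slope <- error_scenario(3, arm_error(0, 0.02, 0), arm_error(0, 0.02, 0))
  ds2 <- make_dataset(case = c(0, 1), regular = c(1, 1), x_true = c(0.7, 0.7))
  out2 <- apply_error(ds2, slope, centering_mean = 0.7)
  expect_equal(out2$y_observed, c(0.7, 0.7))

  # never-regular records always keep zero
  noisy <- apply_error(ds, scenario_preset(1), centering_mean = 0.7, seed = 1)
  expect_identical(noisy$y_observed[ds$regular == 0L], c(0, 0))
})

test_that("empirical error moments match the arm parameters", {
  n <- 40000
  mu <- 0.7
  set.seed(21)
  x <- rnorm(n, mu, 1.5)
  ds <- make_dataset(case = rep(c(0, 1), each = n / 2), regular = rep(1L, n), x_true = x)
  spec <- scenario_preset(1)
  out <- apply_error(ds, spec, centering_mean = mu, seed = 22)
  t_err <- out$y_observed - out$x_true
  ctrl <- out$case == 0L

  # mean among controls -> tau_ctrl; among cases -> tau + gamma*(mean(X)-mu)
  expect_lt(abs(mean(t_err[ctrl]) - 0), 4 * 1.22 / sqrt(n / 2))
  case_target <- 0.34 + 0.02 * (mean(x[!ctrl]) - mu)
  expect_lt(abs(mean(t_err[!ctrl]) - case_target), 4 * (1.1 * 1.22) / sqrt(n / 2))

  # SD of (Y - X | X) after regressing out the slope term
  resid_ctrl <- t_err[ctrl]
  resid_case <- t_err[!ctrl] - 0.34 - 0.02 * (x[!ctrl] - mu)
  expect_lt(abs(sd(resid_ctrl) - 1.22), 4 * 1.22 / sqrt(n))
  expect_lt(abs(sd(resid_case) - 1.1 * 1.22), 4 * 1.1 * 1.22 / sqrt(n))
})

test_that("scenario 4 errors are exchangeable between arms", {
  n <- 20000
  set.seed(31)
  x <- rnorm(n, 0.7, 1.5)
  ds <- make_dataset(case = rep(c(0, 1), each = n / 2), regular = rep(1L, n), x_true = x)
  out <- apply_error(ds, scenario_preset(4), centering_mean = 0.7, seed = 32)
  t_err <- out$y_observed - out$x_true
  ks <- ks.test(t_err[out$case == 0L], t_err[out$case == 1L])
  expect_gt(ks$p.value, 0.001)
})
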