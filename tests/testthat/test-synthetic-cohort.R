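test_that("regular-status generation honors degenerate and stochastic Bernoulli laws", {
  expect_false(any(generate_regular_status(100, 0, seed = 1)))
  expect_true(all(generate_regular_status(100, 1, seed = 1)))
  expect_error(generate_regular_status(0, 0.5), class = "invalid_design")

  # oracle: central 99.9% binomial interval from qbinom
  n <- 30000; p <- 0.6
  bounds <- qbinom(c(5e-4, 1 - 5e-4), n, p)
  count <- sum(generate_regular_status(n, p, seed = 11))
  expect_gte(count, bounds[1])
  expect_lte(count, bounds[2])
})

test_that("true exposure is zero for never-regular users and normal otherwise", {
  expect_identical(generate_true_exposure(rep(FALSE, 50), exposure_distribution(), seed = 1),
                   rep(0, 50))
  degen <- generate_true_exposure(rep(TRUE, 20), exposure_distribution(2.5, 0), seed = 1)
  expect_identical(degen, rep(2.5, 20))

  n <- 50000
  x <- generate_true_exposure(rep(TRUE, n), exposure_distribution(0.7, 1.5), seed = 2)
  expect_lt(abs(mean(x) - 0.7), 4 * 1.5 / sqrt(n)) # CLT bound
  expect_lt(abs(sd(x) - 1.5), 4 * 1.5 / sqrt(2 * n))
})

test_that("alpha calibration inverts the expected case fraction", {
  d <- study_design(1000, 2000)
  dist <- exposure_distribution()
  expect_equal(calibrate_alpha(d, dist, true_effect(1)), qlogis(1 / 3))
  expect_equal(calibrate_alpha(study_design(500, 500), dist, true_effect(1)), 0)

  # brute-force Monte Carlo oracle for the alternative
  eff <- true_effect(1.3, dist)
  alpha <- calibrate_alpha(d, dist, eff)
  set.seed(33)
  n <- 1e6
  reg <- runif(n) < d$p_regular
  x <- ifelse(reg, rnorm(n, dist$mu_x, dist$sigma_x), 0)
  mc_frac <- mean(plogis(alpha + eff$beta_star * x))
  expect_equal(mc_frac, 1 / 3, tolerance = 1e-3)
})

test_that("outcome generation follows the logistic law including saturation", {
  eff0 <- true_effect(1); eff0$alpha_star <- qlogis(1 / 3)
  n <- 30000
  d <- generate_outcome(rnorm(n), eff0, seed = 5)
  expect_lt(abs(mean(d) - 1 / 3), 4 * sqrt((1 / 3) * (2 / 3) / n))

  efflo <- true_effect(1); efflo$alpha_star <- -50
  expect_false(any(generate_outcome(rnorm(100), efflo, seed = 1)))
  effhi <- true_effect(1); effhi$alpha_star <- 50
  expect_true(all(generate_outcome(rnorm(100), effhi, seed = 1)))
  expect_error(generate_outcome(rnorm(5), true_effect(1)), class = "invalid_effect")
})

test_that("true_effect enforces beta* = log(OR*)/delta", {
  dist <- exposure_distribution(0.7, 1.5)
  eff <- true_effect(1.3, dist)
  expect_equal(eff$beta_star, log(1.3) / eff$delta)
  expect_equal(eff$delta, decile_delta(dist))
  expect_identical(true_effect(1, dist)$beta_star, 0)

  # delta oracle: truncated-tail means of the normal law by simulation
  set.seed(7)
  x <- rnorm(2e6, 0.7, 1.5)
  q <- quantile(x, c(0.1, 0.9))
  mc_delta <- mean(x[x > q[2]]) - mean(x[x < q[1]])
  expect_equal(eff$delta, mc_delta, tolerance = 0.01)
})

test_that("generate_dataset respects both sampling modes", {
  design <- study_design(1000, 2000)
  dist <- exposure_distribution()

  # p_regular = 0, null: all exposure zero, case fraction ~ design
  ds0 <- generate_dataset(study_design(1000, 2000, p_regular = 0), dist,
                          true_effect(1), mode = "expected-count", seed = 3)
  expect_true(all(ds0$x_true == 0))
  expect_lt(abs(mean(ds0$case) - 1 / 3), 4 * sqrt((1 / 3) * (2 / 3) / 3000))

  # exact-count null: case count pinned in every replicate
  for (s in 1:5) {
    ds <- generate_dataset(design, dist, true_effect(1), mode = "exact-count", seed = s)
    expect_identical(sum(ds$case), 1000L)
  }

  # exact-count under the alternative: rejection sampling still pins counts
  dsa <- generate_dataset(study_design(30, 60), dist, true_effect(1.3, dist),
                          mode = "exact-count", seed = 9)
  expect_identical(sum(dsa$case), 30L)
  expect_error(
    generate_dataset(design, dist, true_effect(1.3, dist),
                     mode = "exact-count", max_redraws = 1, seed = 1),
    class = "resampling_budget"
  )

  # expected-count: mean realized case count matches the binomial mean
  reps <- 500
  counts <- vapply(seq_len(reps), function(i) {
    sum(generate_dataset(design, dist, true_effect(1),
                         mode = "expected-count", seed = 1000 + i)$case)
  }, numeric(1))
  expect_lt(abs(mean(counts) - 1000), 4 * sqrt(1000 * (2 / 3)) / sqrt(reps))
})

test_that("under the null (D, X) factorize and only never-regular users carry zero", {
  design <- study_design(1000, 2000)
  dist <- exposure_distribution()
  pooled <- do.call(rbind, lapply(1:12, function(s)
    as.data.frame(generate_dataset(design, dist, true_effect(1),
                                   mode = "exact-count", seed = 100 + s))))
  reg <- pooled$regular == 1L
  expect_identical(pooled$x_true == 0, !reg)
  ks <- suppressWarnings(
    ks.test(pooled$x_true[reg & pooled$case == 1L],
            pooled$x_true[reg & pooled$case == 0L]))
  expect_gt(ks$p.value, 0.001)

  # calibration round trip: regenerate with the returned alpha*
  eff <- true_effect(1.3, dist)
  eff$alpha_star <- calibrate_alpha(design, dist, eff)
  n <- 30000
  with_frac <- mean(vapply(1:10, function(s) {
    set.seed(200 + s)
    reg <- runif(n) < design$p_regular
    x <- ifelse(reg, rnorm(n, dist$mu_x, dist$sigma_x), 0)
    mean(generate_outcome(x, eff))
  }, numeric(1)))
  expect_lt(abs(with_frac - 1 / 3), 4 * sqrt((1 / 3) * (2 / 3) / (10 * n)))
})

test_that("dataset CSV round trip preserves records", {
  ds <- generate_dataset(study_design(30, 60), exposure_distribution(),
                         true_effect(1), seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_datasets_csv(list(ds, ds), path)
  back <- read_datasets_csv(path)
  expect_identical(nrow(back), 180L)
  expect_equal(back$x_true[back$replicate_id == 1], ds$x_true)
})
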