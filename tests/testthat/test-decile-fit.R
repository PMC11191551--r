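test_that("cutpoints are the empirical 10th-90th percentiles of the source stratum", {
  ds <- make_dataset(case = rep(0L, 100), regular = rep(1L, 100), x_true = 1:100)
  cp <- compute_cutpoints(ds, "x_true", "controls-only")
  # sort-based oracle under the fixed percentile rule
  expect_equal(cp$cutpoints,
               unname(quantile(1:100, seq(0.1, 0.9, 0.1), type = 7)))

  expect_error(compute_cutpoints(make_dataset(0L, 1L, 1), "x_true"),
               class = "insufficient_data")

  # controls-only ignores cases
  ds2 <- make_dataset(case = c(rep(0L, 100), rep(1L, 50)),
                      regular = rep(1L, 150), x_true = c(1:100, rep(1000, 50)))
  expect_equal(compute_cutpoints(ds2, "x_true", "controls-only")$cutpoints,
               cp$cutpoints)
  expect_false(identical(compute_cutpoints(ds2, "x_true", "all-regular")$cutpoints,
                         cp$cutpoints))
})

test_that("categorization uses right-closed decile bins with reference 0", {
  ds <- make_dataset(case = rep(0L, 100), regular = rep(1L, 100), x_true = 1:100)
  cp <- compute_cutpoints(ds, "x_true")

  mixed <- make_dataset(case = rep(0L, 4), regular = c(0L, 1L, 1L, 1L),
                        x_true = c(0, cp$cutpoints[1], cp$cutpoints[9] + 1, -5))
  codes <- categorize(mixed, cp, "x_true")
  expect_identical(codes, c(0L, 1L, 10L, 1L)) # nonregular; tie -> lower; overflow -> 10

  # degenerate cutpoints refuse to categorize
  const <- make_dataset(case = rep(0L, 20), regular = rep(1L, 20), x_true = rep(3, 20))
  cp_const <- compute_cutpoints(const, "x_true")
  expect_true(all(cp_const$cutpoints == 3))
  expect_error(categorize(const, cp_const, "x_true"), class = "degenerate_cutpoints")

  # empirical deciles partition the source controls into tenths (+/- 1)
  set.seed(41)
  big <- make_dataset(case = rep(0L, 1200), regular = rep(1L, 1200),
                      x_true = rnorm(1200, 0.7, 1.5))
  cpb <- compute_cutpoints(big, "x_true")
  tab <- table(categorize(big, cpb, "x_true"))
  expect_true(all(abs(tab - 120) <= 1))
})

test_that("the saturated logistic fit matches the 2x2 cross-product oracle", {
  # spec-style single-exposure-category table: 30/70 cases, 20/80 controls
  case <- c(rep(1L, 100), rep(0L, 100))
  cats <- c(rep(1L, 30), rep(0L, 70), rep(1L, 20), rep(0L, 80))
  fit <- fit_categorical_logistic(case, cats)
  expect_equal(unname(fit$estimates["D1"]), log((30 * 80) / (70 * 20)), tolerance = 1e-7)
  expect_equal(unname(fit$estimates["D1"]), 0.5390, tolerance = 1e-4)
  expect_equal(unname(fit$se["D1"]), sqrt(1 / 30 + 1 / 70 + 1 / 20 + 1 / 80),
               tolerance = 1e-7)
  expect_equal(fit$cell_counts["cat1", ], c(control = 20L, case = 30L))

  # 100 random full tables: equivalence with the closed form to 1e-6
  set.seed(42)
  for (i in 1:100) {
    counts <- matrix(sample(1:40, 22, replace = TRUE), ncol = 2,
                     dimnames = list(paste0("cat", 0:10), c("control", "case")))
    dat <- expand_counts(counts)
    fit <- fit_categorical_logistic(dat$case, dat$categories)
    oracle <- woolf_oracle(counts)
    expect_equal(unname(fit$estimates), oracle$est, tolerance = 1e-6)
    expect_equal(unname(fit$se), oracle$se, tolerance = 1e-6)
    expect_true(fit$converged)
    expect_true(all(fit$ci_low <= fit$estimates & fit$estimates <= fit$ci_high))
  }
})

test_that("no-association tables give zero estimates and fits ignore record order", {
  # identical case fraction in every category
  counts <- matrix(c(rep(30L, 11), rep(15L, 11)), ncol = 2,
                   dimnames = list(paste0("cat", 0:10), c("control", "case")))
  dat <- expand_counts(counts)
  fit <- fit_categorical_logistic(dat$case, dat$categories)
  expect_true(all(abs(fit$estimates) < 1e-8))

  set.seed(43)
  perm <- sample(length(dat$case))
  fit_perm <- fit_categorical_logistic(dat$case[perm], dat$categories[perm])
  expect_equal(fit_perm$estimates, fit$estimates)
  expect_equal(fit_perm$se, fit$se)
})

test_that("separation and empty reference are handled without crashing", {
  counts <- matrix(c(rep(20L, 11), 10L, 0L, rep(10L, 9)), ncol = 2,
                   dimnames = list(paste0("cat", 0:10), c("control", "case")))
  dat <- expand_counts(counts)
  fit <- fit_categorical_logistic(dat$case, dat$categories) # zero cases in D1
  expect_false(fit$converged)
  expect_false(fit$identifiable[["D1"]])
  expect_true(all(fit$identifiable[paste0("D", 2:10)]))
  expect_identical(fit$cell_counts["cat1", "case"], 0L)

  expect_error(fit_categorical_logistic(rep(1L, 20), rep(0:9, 2)),
               class = "invalid_fit_input")
  expect_error(fit_categorical_logistic(c(0L, 1L), c(0L, 11L)),
               class = "invalid_fit_input")
})

test_that("fits serialize to long-format CSV", {
  counts <- matrix(rep(10L, 22), ncol = 2,
                   dimnames = list(paste0("cat", 0:10), c("control", "case")))
  dat <- expand_counts(counts)
  fit <- fit_categorical_logistic(dat$case, dat$categories)
  path <- withr::local_tempfile(fileext = ".csv")
  write_fits_csv(list(fit, fit), path)
  df <- read.csv(path)
  expect_identical(nrow(df), 20L)
  expect_identical(unique(df$replicate), c(1L, 2L))
  expect_equal(df$estimate[df$replicate == 2], unname(fit$estimates))
})
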