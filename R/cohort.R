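#' Case-control study design
#'
#' Describes the sampling frame of the simulated case-control study: the
#' target numbers of cases and controls and the population probability of
#' being a regular user of the exposure source (at least one call per week
#' over six months or more, in the motivating studies). Never-regular users
#' carry exactly zero exposure and form the reference category throughout.
#'
#' @param n_cases Number of cases (default 1000).
#' @param n_controls Number of controls (default 2000).
#' @param p_regular Probability that a subject is a regular user, in \[0, 1\].
#' @param metric_label Free-text label of the exposure metric, e.g.
#'   `"duration"` or `"number"` of calls. Informational only.
#' @return An object of class `study_design`.
#' @examples
#' study_design(1000, 2000, p_regular = 0.6)
#' @export
study_design <- function(n_cases = 1000, n_controls = 2000,
                         p_regular = 0.6, metric_label = "duration") {
  if (!is_count(n_cases) || !is_count(n_controls) || n_cases + n_controls <= 0)
    stop_invalid("invalid_design", "n_cases and n_controls must be nonnegative integers with a positive sum")
  if (!is_prob(p_regular))
    stop_invalid("invalid_design", "p_regular must be a probability in [0, 1]")
  structure(
    list(n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
         p_regular = p_regular, metric_label = as.character(metric_label)),
    class = "study_design"
  )
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("Case-control design: %d cases / %d controls, P(regular use) = %g [%s]\n",
              x$n_cases, x$n_controls, x$p_regular, x$metric_label))
  invisible(x)
}

#' True exposure distribution among regular users
#'
#' Log-scale normal law of the true exposure X among regular users;
#' equivalently, monthly cumulative use is log-normal. The defaults are
#' documented placeholders for the population parameters (which in the
#' motivating analysis come from a posterior predictive distribution not
#' reproduced here) and should be overridden when better values are known.
#'
#' @param mu_x Mean of log exposure among regular users.
#' @param sigma_x Standard deviation of log exposure, `>= 0`.
#' @return An object of class `exposure_dist`.
#' @export
exposure_distribution <- function(mu_x = 0.7, sigma_x = 1.5) {
  if (!is_scalar_num(mu_x) || !is_scalar_num(sigma_x) || sigma_x < 0)
    stop_invalid("invalid_distribution", "mu_x must be finite and sigma_x >= 0")
  structure(list(mu_x = mu_x, sigma_x = sigma_x), class = "exposure_dist")
}

#' Exposure gap between the top and bottom decile
#'
#' The unit "delta" in which the true odds ratio is expressed: the expected
#' exposure difference between the highest and the lowest decile of the
#' regular-user exposure law, `E[X | X in decile 10] - E[X | X in decile 1]`,
#' computed in closed form from truncated-normal means. Decile cutpoints
#' alone do not pin down "the exposure of a decile"; the conditional mean is
#' this package's definition.
#'
#' @param dist An [exposure_distribution()].
#' @return Positive scalar (0 when `sigma_x = 0`).
#' @export
decile_delta <- function(dist) {
  stopifnot(inherits(dist, "exposure_dist"))
  z <- stats::qnorm(0.9)
  # E[X | X > q90] - E[X | X < q10] = 2 * sigma * phi(z) / 0.1
  2 * dist$sigma_x * stats::dnorm(z) / 0.1
}

#' True exposure effect on disease risk
#'
#' Bundles the true odds ratio `OR*` (expressed per `delta` increase in
#' exposure, where `delta` is the top-vs-bottom-decile exposure gap of
#' [decile_delta()]), the implied log-scale slope
#' `beta* = log(OR*) / delta`, and the baseline log-odds `alpha*` of disease
#' among never-regular (zero-exposure) users. `alpha*` is usually left `NA`
#' and filled by [calibrate_alpha()] so that the expected case count matches
#' the design.
#'
#' @param or_star True odds ratio per delta (1 under the null; e.g. 1.3
#'   under the alternative).
#' @param dist An [exposure_distribution()]; used to compute `delta`.
#' @param delta Optional explicit delta, overriding the closed form.
#' @param alpha_star Optional baseline log-odds; `NA` until calibrated.
#' @return An object of class `true_effect` with fields `or_star`, `delta`,
#'   `beta_star`, `alpha_star`.
#' @export
true_effect <- function(or_star = 1, dist = exposure_distribution(),
                        delta = NULL, alpha_star = NA_real_) {
  if (!is_scalar_num(or_star) || or_star <= 0)
    stop_invalid("invalid_effect", "or_star must be a positive number")
  delta <- delta %||% decile_delta(dist)
  if (!is_scalar_num(delta) || delta < 0)
    stop_invalid("invalid_effect", "delta must be a nonnegative number")
  beta_star <- if (or_star == 1) 0 else {
    if (delta == 0)
      stop_invalid("invalid_effect", "delta = 0 is incompatible with or_star != 1")
    log(or_star) / delta
  }
  structure(
    list(or_star = or_star, delta = delta, beta_star = beta_star,
         alpha_star = alpha_star),
    class = "true_effect"
  )
}

expit <- function(x) stats::plogis(x)
logit <- function(p) stats::qlogis(p)

#' Calibrate the baseline log-odds to the design's case fraction
#'
#' Solves for `alpha*` such that the expected case fraction under
#' `P(D = 1 | X) = expit(alpha* + beta* X)` equals
#' `n_cases / (n_cases + n_controls)`, integrating over the exposure
#' mixture: a point mass at zero with weight `1 - p_regular` and the
#' regular-user normal law otherwise. Monotone root finding; the returned
#' root satisfies `|E[cases] - n_cases| < 1e-6 * n_total`.
#'
#' @param design A [study_design()].
#' @param dist An [exposure_distribution()].
#' @param effect A [true_effect()] (its `alpha_star` is ignored).
#' @return The calibrated `alpha*` (scalar). Combine with
#'   `effect$alpha_star <- calibrate_alpha(...)` or use
#'   [generate_dataset()], which calibrates on the fly.
#' @examples
#' d <- study_design(1000, 2000)
#' calibrate_alpha(d, exposure_distribution(), true_effect(1)) # logit(1/3)
#' @export
calibrate_alpha <- function(design, dist, effect) {
  stopifnot(inherits(design, "study_design"), inherits(dist, "exposure_dist"),
            inherits(effect, "true_effect"))
  n_total <- design$n_cases + design$n_controls
  target <- design$n_cases / n_total
  if (target <= 0 || target >= 1)
    stop_invalid("calibration_failure", "target case fraction must lie strictly in (0, 1)")
  if (effect$beta_star == 0) return(logit(target))

  p_case <- function(alpha) {
    p0 <- (1 - design$p_regular) * expit(alpha)
    if (design$p_regular == 0) return(p0)
    if (dist$sigma_x == 0) {
      p1 <- expit(alpha + effect$beta_star * dist$mu_x)
    } else {
      p1 <- stats::integrate(
        function(x) expit(alpha + effect$beta_star * x) *
          stats::dnorm(x, dist$mu_x, dist$sigma_x),
        lower = -Inf, upper = Inf, rel.tol = 1e-10
      )$value
    }
    p0 + design$p_regular * p1
  }

  f <- function(alpha) p_case(alpha) - target
  lo <- -50; hi <- 50
  if (f(lo) > 0 || f(hi) < 0)
    stop_invalid("calibration_failure", "could not bracket the calibration root in [-50, 50]")
  root <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
  if (abs(p_case(root) - target) * n_total >= 1e-6 * n_total)
    stop_invalid("calibration_failure", "root finding did not reach the required tolerance")
  root
}

#' Draw regular-user status
#'
#' Independent Bernoulli draws of regular-user status with probability
#' `p_regular`.
#'
#' @param n Number of subjects (positive integer).
#' @param p_regular Probability of regular use.
#' @param seed Optional seed for a local, restored RNG state.
#' @return Logical vector of length `n`.
#' @export
generate_regular_status <- function(n, p_regular, seed = NULL) {
  if (!is_count(n) || n <= 0)
    stop_invalid("invalid_design", "n must be a positive integer")
  if (!is_prob(p_regular))
    stop_invalid("invalid_design", "p_regular must be a probability")
  with_seed(seed, stats::runif(n) < p_regular)
}

#' Draw true exposure given regular-user status
#'
#' Regular users receive i.i.d. Normal(`mu_x`, `sigma_x^2`) log-scale
#' exposure; never-regular users receive exactly zero.
#'
#' @param regular_flags Logical vector of regular-user status.
#' @param dist An [exposure_distribution()].
#' @param seed Optional seed.
#' @return Numeric vector, zero wherever `regular_flags` is `FALSE`.
#' @export
generate_true_exposure <- function(regular_flags, dist, seed = NULL) {
  stopifnot(is.logical(regular_flags), inherits(dist, "exposure_dist"))
  x <- numeric(length(regular_flags))
  n_reg <- sum(regular_flags)
  if (n_reg > 0)
    x[regular_flags] <- with_seed(seed, stats::rnorm(n_reg, dist$mu_x, dist$sigma_x))
  x
}

#' Draw case-control outcome status given true exposure
#'
#' Independent Bernoulli draws with `P(D = 1 | X) = expit(alpha* + beta* X)`.
#' `effect$alpha_star` must already be calibrated (non-`NA`).
#'
#' @param x_true Numeric vector of true log exposure (0 for never-regular).
#' @param effect A [true_effect()] with `alpha_star` set.
#' @param seed Optional seed.
#' @return Logical vector: `TRUE` = case.
#' @export
generate_outcome <- function(x_true, effect, seed = NULL) {
  stopifnot(inherits(effect, "true_effect"))
  if (is.na(effect$alpha_star))
    stop_invalid("invalid_effect", "alpha_star must be calibrated before generating outcomes")
  p <- expit(effect$alpha_star + effect$beta_star * x_true)
  with_seed(seed, stats::runif(length(x_true)) < p)
}

#' Generate one synthetic case-control dataset
#'
#' Executes the generating model: (1) regular status ~ Bernoulli(P); (2)
#' among regular users, true log exposure X ~ Normal(mu_x, sigma_x^2), zero
#' otherwise; (3) disease status D | X ~ Bernoulli(expit(alpha* + beta* X)).
#' The observed exposure column `y_observed` is left `NA` for regular users
#' (zero for never-regular users) until an error law is applied with
#' [apply_error()].
#'
#' Two sampling modes reconcile the fixed case/control totals of a
#' case-control design with the Bernoulli outcome law:
#' * `"exact-count"` (default): exactly `n_cases` cases. Under the null
#'   (`beta* = 0`, where D is independent of X) case labels are assigned to
#'   a simple random sample of subjects; under an alternative, whole
#'   datasets are redrawn until the realized case count hits `n_cases`.
#' * `"expected-count"`: one Bernoulli pass; the case count is random with
#'   expectation `n_cases`.
#'
#' @param design A [study_design()].
#' @param dist An [exposure_distribution()].
#' @param effect A [true_effect()]; if `alpha_star` is `NA` it is
#'   calibrated internally.
#' @param mode `"exact-count"` or `"expected-count"`.
#' @param max_redraws Redraw budget for exact-count rejection under the
#'   alternative (default 10000).
#' @param seed Optional seed.
#' @return A `cc_dataset`: a data frame with columns `case` (0/1),
#'   `regular` (0/1), `x_true`, `y_observed`, carrying the design and
#'   generation metadata as attributes.
#' @examples
#' ds <- generate_dataset(study_design(50, 100), exposure_distribution(),
#'                        true_effect(1), seed = 1)
#' table(ds$case)
#' @export
generate_dataset <- function(design, dist, effect,
                             mode = c("exact-count", "expected-count"),
                             max_redraws = 10000, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(design, "study_design"))
  if (is.na(effect$alpha_star))
    effect$alpha_star <- calibrate_alpha(design, dist, effect)
  n_total <- design$n_cases + design$n_controls

  build <- function() {
    reg <- generate_regular_status(n_total, design$p_regular)
    x <- generate_true_exposure(reg, dist)
    d <- generate_outcome(x, effect)
    list(reg = reg, x = x, d = d)
  }

  with_seed(seed, {
    if (mode == "exact-count" && effect$beta_star == 0) {
      reg <- generate_regular_status(n_total, design$p_regular)
      x <- generate_true_exposure(reg, dist)
      d <- logical(n_total)
      d[sample.int(n_total, design$n_cases)] <- TRUE # valid: D independent of X under the null
      draw <- list(reg = reg, x = x, d = d); n_draws <- 1L
    } else if (mode == "exact-count") {
      n_draws <- 0L
      repeat {
        n_draws <- n_draws + 1L
        if (n_draws > max_redraws)
          stop_invalid("resampling_budget",
                       sprintf("exact-count rejection exceeded the budget of %d redraws", max_redraws))
        draw <- build()
        if (sum(draw$d) == design$n_cases) break
      }
    } else {
      draw <- build(); n_draws <- 1L
    }
    new_cc_dataset(draw, design, mode, n_draws, seed)
  })
}

new_cc_dataset <- function(draw, design, mode, n_draws, seed) {
  y <- ifelse(draw$reg, NA_real_, 0)
  df <- data.frame(
    case = as.integer(draw$d),
    regular = as.integer(draw$reg),
    x_true = draw$x,
    y_observed = y
  )
  structure(df,
            class = c("cc_dataset", "data.frame"),
            design = design, mode = mode, n_draws = n_draws,
            seed = seed %||% NA_integer_)
}

#' @export
print.cc_dataset <- function(x, ...) {
  cat(sprintf("Synthetic case-control dataset: %d subjects (%d cases, %d regular users)\n",
              nrow(x), sum(x$case), sum(x$regular)))
  cat(sprintf("  mode = %s; y_observed %s\n", attr(x, "mode"),
              if (anyNA(x$y_observed)) "not yet generated" else "populated"))
  invisible(x)
}

#' Write / read simulated datasets as plain CSV
#'
#' Columns: `case` (0/1), `regular` (0/1), `x_true`, `y_observed`,
#' `replicate_id`.
#'
#' @param datasets A `cc_dataset` or list of them.
#' @param path Output CSV path.
#' @return `write_datasets_csv` returns `path` invisibly;
#'   `read_datasets_csv` returns a data frame with the columns above.
#' @export
write_datasets_csv <- function(datasets, path) {
  if (inherits(datasets, "cc_dataset")) datasets <- list(datasets)
  rows <- lapply(seq_along(datasets), function(i) {
    d <- as.data.frame(datasets[[i]])
    d$replicate_id <- i
    d
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_datasets_csv
#' @export
read_datasets_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("case", "regular", "x_true", "y_observed", "replicate_id")
  if (!all(need %in% names(df)))
    stop_invalid("invalid_file", paste("dataset CSV must have columns:", paste(need, collapse = ", ")))
  df
}
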