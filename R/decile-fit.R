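#' Decile cutpoints of exposure among regular users
#'
#' The 10th-90th percentiles of the chosen exposure among regular users,
#' computed by default among regular *controls* only (mirroring risk
#' analyses that build deciles from the control distribution), optionally
#' among all regular users. Percentiles use linear interpolation between
#' order statistics (`quantile` type 7); any standard rule differs
#' negligibly at realistic sample sizes but one must be fixed for
#' reproducibility.
#'
#' @param dataset A `cc_dataset` (or data frame with `case`, `regular` and
#'   the exposure column).
#' @param exposure `"x_true"` or `"y_observed"`.
#' @param source `"controls-only"` (default) or `"all-regular"`.
#' @return An object of class `decile_cutpoints`: the 9 ordered cutpoints
#'   plus the source stratum.
#' @export
compute_cutpoints <- function(dataset,
                              exposure = c("x_true", "y_observed"),
                              source = c("controls-only", "all-regular")) {
  exposure <- match.arg(exposure)
  source <- match.arg(source)
  reg <- dataset$regular == 1L
  keep <- if (source == "controls-only") reg & dataset$case == 0L else reg
  vals <- dataset[[exposure]][keep]
  if (anyNA(vals))
    stop_invalid("insufficient_data", sprintf("%s contains NA in the source stratum", exposure))
  if (length(vals) < 10)
    stop_invalid("insufficient_data",
                 sprintf("need at least 10 regular users in stratum '%s'; got %d", source, length(vals)))
  cp <- unname(stats::quantile(vals, probs = seq(0.1, 0.9, by = 0.1), type = 7))
  structure(list(cutpoints = cp, source = source, exposure = exposure),
            class = "decile_cutpoints")
}

#' @export
print.decile_cutpoints <- function(x, ...) {
  cat(sprintf("Decile cutpoints (%s, %s):\n", x$exposure, x$source))
  print(round(x$cutpoints, 4))
  invisible(x)
}

#' Categorize exposure into never-regular + 10 deciles
#'
#' Never-regular users get category 0 (the reference); regular users get
#' the decile `k` whose right-closed bin `(c[k-1], c[k]]` contains their
#' exposure, with `(-Inf, c[1]]` mapping to 1 and `(c[9], Inf)` to 10. A
#' value exactly on a cutpoint falls in the lower decile.
#'
#' @param dataset A `cc_dataset` (or compatible data frame).
#' @param cutpoints A [compute_cutpoints()] result (must be strictly
#'   increasing; ties raise a degenerate-cutpoint error).
#' @param exposure `"x_true"` or `"y_observed"`; defaults to the field the
#'   cutpoints were built from.
#' @return Integer vector of category codes 0-10.
#' @export
categorize <- function(dataset, cutpoints, exposure = NULL) {
  stopifnot(inherits(cutpoints, "decile_cutpoints"))
  exposure <- exposure %||% cutpoints$exposure
  cp <- cutpoints$cutpoints
  if (any(diff(cp) <= 0))
    stop_invalid("degenerate_cutpoints", "cutpoints must be strictly increasing")
  vals <- dataset[[exposure]]
  if (anyNA(vals))
    stop_invalid("insufficient_data", sprintf("%s contains NA", exposure))
  cat <- 1L + findInterval(vals, cp, left.open = TRUE)
  cat[dataset$regular == 0L] <- 0L
  cat
}

#' Fit the never-regular-reference decile logistic model
#'
#' Maximum-likelihood logistic regression of case status on the categorical
#' exposure with indicator coding for categories 1-10 and category 0
#' (never-regular) as the reference. Wald 95% CIs are
#' `estimate +/- 1.96 * SE`. A replicate never crashes on separation: any
#' decile cell with zero cases or zero controls is flagged non-identifiable
#' and the fit is marked `converged = FALSE`, with the cell counts recorded.
#'
#' Because the model is saturated, the ML estimate for each decile equals
#' the 2x2 cross-product log odds ratio against the reference cells and the
#' SE equals the Woolf standard error; tests exploit this closed form as an
#' independent oracle.
#'
#' @param case_flags Logical (or 0/1) vector of case status.
#' @param categories Integer vector of codes 0-10 from [categorize()].
#' @return An object of class `decile_fit` with fields `estimates`, `se`,
#'   `ci_low`, `ci_high` (length-10, names `D1`-`D10`), `identifiable`
#'   (length-10 logical), `converged`, and `cell_counts` (11x2 matrix,
#'   categories x control/case).
#' @export
fit_categorical_logistic <- function(case_flags, categories) {
  case <- as.integer(as.logical(case_flags))
  categories <- as.integer(categories)
  if (length(case) != length(categories))
    stop_invalid("invalid_fit_input", "case_flags and categories must have equal length")
  if (!all(categories %in% 0:10))
    stop_invalid("invalid_fit_input", "categories must be codes 0..10")

  counts <- matrix(0L, nrow = 11, ncol = 2,
                   dimnames = list(paste0("cat", 0:10), c("control", "case")))
  tab <- table(factor(categories, levels = 0:10), factor(case, levels = 0:1))
  counts[, ] <- as.integer(tab)

  if (any(counts["cat0", ] == 0))
    stop_invalid("invalid_fit_input",
                 "reference category (never-regular) must contain both cases and controls")

  identifiable <- counts[2:11, "control"] > 0 & counts[2:11, "case"] > 0
  present <- rowSums(counts[2:11, , drop = FALSE]) > 0

  # saturated model: fit by IRLS on the indicator design matrix
  X <- cbind(`(Intercept)` = 1,
             outer(categories, 1:10, `==`) * 1)
  colnames(X)[2:11] <- paste0("D", 1:10)
  fit <- suppressWarnings(
    stats::glm.fit(X, case, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-12, maxit = 100))
  )
  ok <- !is.na(fit$coefficients)
  beta <- fit$coefficients
  se <- rep(NA_real_, 10)
  if (any(ok)) {
    # Newton polish on identifiable coordinates: IRLS's deviance-based stop
    # can leave O(1e-6) coefficient error, visible in the Wald SEs
    Xok <- X[, ok, drop = FALSE]
    b <- beta[ok]
    cov_ok <- NULL
    for (iter in 1:25) {
      eta <- drop(Xok %*% b)
      p <- expit(eta)
      g <- drop(crossprod(Xok, case - p))
      w <- p * (1 - p)
      XtWX <- crossprod(Xok * sqrt(w))
      cov_try <- tryCatch(chol2inv(chol(XtWX)), error = function(e) NULL)
      if (is.null(cov_try)) break
      cov_ok <- cov_try
      step <- drop(cov_ok %*% g)
      if (max(abs(g)) < 1e-10 || max(abs(step)) > 10) break
      b <- b + step
    }
    beta[ok] <- b
    if (!is.null(cov_ok)) {
      se_all <- rep(NA_real_, ncol(X))
      se_all[ok] <- sqrt(diag(cov_ok))
      names(se_all) <- colnames(X)
      se <- se_all[paste0("D", 1:10)]
    }
  }
  est <- beta[paste0("D", 1:10)]
  est <- unname(est); se <- unname(se)
  est[!present] <- NA_real_
  se[!present] <- NA_real_
  converged <- isTRUE(fit$converged) && all(identifiable)

  structure(
    list(
      estimates = stats::setNames(est, paste0("D", 1:10)),
      se = stats::setNames(se, paste0("D", 1:10)),
      ci_low = stats::setNames(est - 1.96 * se, paste0("D", 1:10)),
      ci_high = stats::setNames(est + 1.96 * se, paste0("D", 1:10)),
      identifiable = stats::setNames(identifiable, paste0("D", 1:10)),
      converged = converged,
      cell_counts = counts,
      n = length(case)
    ),
    class = "decile_fit"
  )
}

#' @export
print.decile_fit <- function(x, ...) {
  cat(sprintf("Decile logistic fit (n = %d, %s)\n", x$n,
              if (x$converged) "converged" else "NON-IDENTIFIABLE cells present"))
  print(round(data.frame(logOR = x$estimates, SE = x$se,
                         lo = x$ci_low, hi = x$ci_high), 4))
  invisible(x)
}

#' Write a list of decile fits as long-format CSV
#'
#' One row per (replicate, decile) with estimate, SE, Wald CI bounds and
#' identifiability/convergence flags.
#'
#' @param fits List of `decile_fit` objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_fits_csv <- function(fits, path) {
  rows <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    data.frame(replicate = i, decile = 1:10,
               estimate = unname(f$estimates), se = unname(f$se),
               ci_low = unname(f$ci_low), ci_high = unname(f$ci_high),
               identifiable = unname(f$identifiable),
               converged = f$converged)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
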