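# shared fixture builders -- everything is generated in code at test time

# a dataset built directly from vectors, bypassing the generators
make_dataset <- function(case, regular, x_true, y_observed = NULL) {
  y <- y_observed %||% ifelse(regular == 1L, NA_real_, 0)
  structure(
    data.frame(case = as.integer(case), regular = as.integer(regular),
               x_true = x_true, y_observed = y),
    class = c("cc_dataset", "data.frame"),
    design = study_design(max(sum(case), 1), max(sum(1 - case), 1)),
    mode = "fixture", n_draws = 1L, seed = NA_integer_
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent closed-form oracle: 2x2 cross-product log-OR and Woolf SE
# against the reference cells, from an 11x2 cell-count matrix
woolf_oracle <- function(counts) {
  a0 <- counts[1, "case"]; b0 <- counts[1, "control"]
  est <- se <- numeric(10)
  for (k in 1:10) {
    a <- counts[k + 1, "case"]; b <- counts[k + 1, "control"]
    est[k] <- log((a * b0) / (a0 * b))
    se[k] <- sqrt(1 / a + 1 / b + 1 / a0 + 1 / b0)
  }
  list(est = est, se = se)
}

# expand an 11x2 count matrix into (case, category) vectors
expand_counts <- function(counts) {
  cat <- rep(rep(0:10, 2), times = c(counts[, "control"], counts[, "case"]))
  case <- rep(c(0L, 1L), times = c(sum(counts[, "control"]), sum(counts[, "case"])))
  list(case = case, categories = cat)
}

# minimal decile_fit stand-in for summarize_fits unit tests
make_fake_fit <- function(est, se, identifiable = rep(TRUE, 10), converged = TRUE) {
  structure(list(
    estimates = stats::setNames(est, paste0("D", 1:10)),
    se = stats::setNames(se, paste0("D", 1:10)),
    ci_low = stats::setNames(est - 1.96 * se, paste0("D", 1:10)),
    ci_high = stats::setNames(est + 1.96 * se, paste0("D", 1:10)),
    identifiable = stats::setNames(identifiable, paste0("D", 1:10)),
    converged = converged,
    cell_counts = matrix(1L, 11, 2, dimnames = list(paste0("cat", 0:10),
                                                    c("control", "case"))),
    n = 0L
  ), class = "decile_fit")
}

# participation table with arbitrary probabilities, packaged-label layout
make_prob_table <- function(control, case) {
  data.frame(exposure = c("nonregular", rep("regular", 4)),
             level = start_year_levels(),
             control = control, case = case)
}
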