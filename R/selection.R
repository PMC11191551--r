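#' Start-year exposure categories
#'
#' The five exposure categories used in the nonresponse-questionnaire
#' selection analysis: never-regular users (the reference) plus four
#' year-of-first-regular-use bands.
#'
#' @return Character vector of the five labels, reference first.
#' @export
start_year_levels <- function() {
  c("nonregular", ">=2001", "1998-2000", "1993-1997", "<=1992")
}

#' W ratio: exposure proportion among participants vs NRQ responders
#'
#' The ratio of the proportion exposed (in a start-year category) among
#' interviewed participants to that among responders of the nonresponse
#' questionnaire. `W > 1` means that exposure category is overrepresented
#' among participants.
#'
#' @param p_exposed_interviewed,p_exposed_nrq Exposure proportions in the
#'   two groups.
#' @return Positive scalar.
#' @export
w_ratio <- function(p_exposed_interviewed, p_exposed_nrq) {
  if (!is_prob(p_exposed_interviewed) || !is.numeric(p_exposed_nrq))
    stop_invalid("invalid_input", "inputs must be proportions")
  if (length(p_exposed_nrq) != 1L || !is.finite(p_exposed_nrq) || p_exposed_nrq <= 0)
    stop_invalid("undefined_ratio", "NRQ exposure proportion must be positive")
  p_exposed_interviewed / p_exposed_nrq
}

#' Case-to-control ratio of W ratios
#'
#' `w_case / w_control`; tabular outputs print it to 2 decimals.
#'
#' @param w_case,w_control Per-arm W ratios.
#' @return Positive scalar.
#' @export
case_control_w_ratio <- function(w_case, w_control) {
  stopifnot(is_scalar_num(w_case), is_scalar_num(w_control), w_case > 0)
  if (w_control <= 0)
    stop_invalid("undefined_ratio", "w_control must be positive")
  w_case / w_control
}

#' Participation probability from a W ratio and the overall rate
#'
#' Bayes inversion of the W ratio: reading `W` as the ratio of the
#' exposure probability among participants to that among nonparticipants,
#' the participation probability in the exposure category is
#' `r / (r + (1 - r) / W)` where `r` is the overall participation rate of
#' the arm. `W = 1` returns `r` (selection unrelated to exposure).
#'
#' @param w W ratio, `> 0`.
#' @param overall_rate Overall participation rate of the arm, in (0, 1).
#' @return Probability in (0, 1).
#' @examples
#' participation_probability(0.71, 0.95) # never-regular cases
#' @export
participation_probability <- function(w, overall_rate) {
  if (!is_scalar_num(w) || w <= 0)
    stop_invalid("invalid_input", "w must be a positive number")
  if (!is_scalar_num(overall_rate) || overall_rate <= 0 || overall_rate >= 1)
    stop_invalid("invalid_input", "overall_rate must lie strictly in (0, 1)")
  overall_rate / (overall_rate + (1 - overall_rate) / w)
}

#' Greenland's selection-bias factor
#'
#' Cross-ratio of arm- and exposure-specific selection (participation)
#' probabilities:
#' `B = (s_case_e * s_ctrl_ref) / (s_case_ref * s_ctrl_e)`.
#' The observed odds ratio equals the true odds ratio times `B`, so the
#' bias-corrected estimate is `OR_observed / B`. `B` is invariant to
#' rescaling all four probabilities by a common factor.
#'
#' @param s_case_e,s_case_ref Selection probabilities of exposed and
#'   reference-category cases.
#' @param s_ctrl_e,s_ctrl_ref Same for controls.
#' @return Positive scalar bias factor.
#' @examples
#' greenland_bias_factor(0.97, 0.93, 0.84, 0.67) # start years 1993-1997
#' @export
greenland_bias_factor <- function(s_case_e, s_case_ref, s_ctrl_e, s_ctrl_ref) {
  p <- c(s_case_e, s_case_ref, s_ctrl_e, s_ctrl_ref)
  if (!all(vapply(p, is_scalar_num, logical(1))) || any(p <= 0) || any(p > 1))
    stop_invalid("undefined_correction", "all selection probabilities must lie in (0, 1]")
  (s_case_e * s_ctrl_ref) / (s_case_ref * s_ctrl_e)
}

#' Packaged selection tables
#'
#' `read_w_table()` returns the per-arm W ratios by start-year category;
#' `read_participation_table()` returns the derived participation
#' probabilities by category and arm. Both ship as plain CSV under
#' `extdata` exactly as printed in the source tables; readers validate the
#' category labels. `overall_participation_rates()` returns the printed
#' overall rates per arm (controls 75.8%, cases 95%).
#'
#' @param path CSV path; defaults to the packaged fixture.
#' @return A data frame with a `level` column using [start_year_levels()]
#'   labels.
#' @export
read_w_table <- function(path = system.file("extdata", "interphone_w_ratios.csv",
                                            package = "recallsim")) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("level", "w_control", "w_case")
  if (!all(need %in% names(df)))
    stop_invalid("invalid_file", paste("W table must have columns:", paste(need, collapse = ", ")))
  validate_levels(df$level)
  df
}

#' @rdname read_w_table
#' @export
read_participation_table <- function(path = system.file("extdata",
                                                        "interphone_participation.csv",
                                                        package = "recallsim")) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("level", "control", "case")
  if (!all(need %in% names(df)))
    stop_invalid("invalid_file", paste("participation table must have columns:",
                                       paste(need, collapse = ", ")))
  validate_levels(df$level)
  if (!all(df$control > 0 & df$control <= 1 & df$case > 0 & df$case <= 1))
    stop_invalid("invalid_file", "participation probabilities must lie in (0, 1]")
  df
}

validate_levels <- function(levels) {
  expected <- start_year_levels()
  if (!setequal(levels, expected) || anyDuplicated(levels))
    stop_invalid("invalid_file",
                 paste("category labels must be exactly:", paste(expected, collapse = ", ")))
  invisible(levels)
}

#' @rdname read_w_table
#' @export
overall_participation_rates <- function() {
  c(control = 0.758, case = 0.95)
}

#' Assign start-year categories to a simulated cohort
#'
#' Never-regular users get `"nonregular"`; regular users draw one of the
#' four start-year bands from a multinomial. The source tables do not link
#' start year to the continuous exposure metric, so the default is uniform
#' over the four bands and independent of exposure.
#'
#' @param dataset A `cc_dataset`.
#' @param weights Length-4 positive weights over the regular-user bands,
#'   in [start_year_levels()] order (positions 2-5).
#' @param seed Optional seed.
#' @return Factor of category labels, levels [start_year_levels()].
#' @export
assign_start_category <- function(dataset, weights = rep(0.25, 4), seed = NULL) {
  stopifnot(length(weights) == 4, all(weights > 0))
  lv <- start_year_levels()
  out <- rep(lv[1], nrow(dataset))
  reg <- dataset$regular == 1L
  out[reg] <- with_seed(seed,
    sample(lv[-1], sum(reg), replace = TRUE, prob = weights / sum(weights)))
  factor(out, levels = lv)
}

#' Thin a cohort by participation probabilities
#'
#' Each record is retained independently with the participation probability
#' of its arm and start-year category, emulating differential nonresponse.
#' The retained dataset keeps the `cc_dataset` class; case/control counts
#' are no longer fixed.
#'
#' @param dataset A `cc_dataset`.
#' @param categories Factor from [assign_start_category()] (one per record).
#' @param probs A participation table as from [read_participation_table()].
#' @param seed Optional seed.
#' @return The thinned `cc_dataset`, with the retained `categories` as
#'   attribute `"categories"`.
#' @export
apply_selection <- function(dataset, categories, probs, seed = NULL) {
  stopifnot(inherits(dataset, "cc_dataset"), nrow(dataset) == length(categories))
  validate_levels(probs$level)
  idx <- match(as.character(categories), probs$level)
  if (anyNA(idx))
    stop_invalid("configuration_error", "every record needs a category present in the probability table")
  p <- ifelse(dataset$case == 1L, probs$case[idx], probs$control[idx])
  if (anyNA(p))
    stop_invalid("configuration_error", "missing participation probability")
  keep <- with_seed(seed, stats::runif(nrow(dataset)) < p)
  out <- dataset[keep, , drop = FALSE]
  attr(out, "categories") <- factor(as.character(categories)[keep],
                                    levels = start_year_levels())
  class(out) <- c("cc_dataset", "data.frame")
  out
}

#' Crude odds ratio of case status for a binary exposure
#'
#' `(cases_exposed * controls_unexposed) / (cases_unexposed * controls_exposed)`.
#'
#' @param case_flags Logical/0-1 case status.
#' @param exposed_flags Logical/0-1 exposure indicator.
#' @return Scalar OR (`NaN`/`Inf` if a cell is empty).
#' @export
crude_or <- function(case_flags, exposed_flags) {
  d <- as.logical(case_flags); e <- as.logical(exposed_flags)
  (sum(d & e) * sum(!d & !e)) / (sum(d & !e) * sum(!d & e))
}

#' Selection-bias null experiment
#'
#' Generates case-control cohorts under the null, thins them with a
#' participation table, and reports per start-year category the crude odds
#' ratio of case status (category vs never-regular), the Greenland bias
#' factor implied by the table, and the bias-corrected odds ratio
#' (crude / B). Under the null the crude ORs are biased away from 1 by
#' selection alone and the corrected ORs return to 1 in expectation.
#'
#' @param probs Participation table (default the packaged one).
#' @param n_replicates Number of simulated cohorts to pool (default 20).
#' @param design A [study_design()]; defaults to 1000 cases / 2000 controls.
#' @param weights Start-year band weights for [assign_start_category()].
#' @param master_seed Integer seed.
#' @return Data frame: one row per regular-user category plus a pooled
#'   `regular (all)` row, with columns `crude_or`, `bias_factor`,
#'   `corrected_or`.
#' @export
selection_experiment <- function(probs = read_participation_table(),
                                 n_replicates = 20,
                                 design = study_design(),
                                 weights = rep(0.25, 4),
                                 master_seed = 1L) {
  dist <- exposure_distribution()
  effect <- true_effect(1)
  lv <- start_year_levels()
  cells <- array(0, dim = c(5, 2), dimnames = list(lv, c("control", "case")))
  for (i in seq_len(n_replicates)) {
    seed <- replicate_seed(master_seed, i)
    with_seed(seed, {
      ds <- generate_dataset(design, dist, effect, mode = "exact-count")
      cats <- assign_start_category(ds, weights)
      thinned <- apply_selection(ds, cats, probs)
      tc <- attr(thinned, "categories")
      tab <- table(tc, factor(thinned$case, levels = 0:1))
      cells <- cells + as.matrix(tab)
    })
  }
  ref <- cells["nonregular", ]
  s_case_ref <- probs$case[probs$level == "nonregular"]
  s_ctrl_ref <- probs$control[probs$level == "nonregular"]
  rows <- lapply(lv[-1], function(cat) {
    b <- greenland_bias_factor(probs$case[probs$level == cat], s_case_ref,
                               probs$control[probs$level == cat], s_ctrl_ref)
    or <- (cells[cat, "case"] * ref["control"]) / (ref["case"] * cells[cat, "control"])
    data.frame(level = cat, crude_or = unname(or), bias_factor = b,
               corrected_or = unname(or / b))
  })
  # pooled regular-vs-nonregular contrast with the aggregate bias factor
  reg_cells <- colSums(cells[lv[-1], ])
  w <- weights / sum(weights)
  b_all <- greenland_bias_factor(sum(w * probs$case[match(lv[-1], probs$level)]),
                                 s_case_ref,
                                 sum(w * probs$control[match(lv[-1], probs$level)]),
                                 s_ctrl_ref)
  or_all <- (reg_cells["case"] * ref["control"]) / (ref["case"] * reg_cells["control"])
  out <- rbind(do.call(rbind, rows),
               data.frame(level = "regular (all)", crude_or = unname(or_all),
                          bias_factor = b_all, corrected_or = unname(or_all / b_all)))
  rownames(out) <- NULL
  out
}
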