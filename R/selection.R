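#' -2 SD lower bound of the cross-validation capture rate
#'
#' The gatekeeper statistic of the clinical acceptance rules: the mean
#' capture rate across cross-validation folds minus two sample standard
#' deviations. Works on fractions or percentages alike.
#'
#' @param mean_capture,sd_capture Numeric vectors.
#' @return `mean_capture - 2 * sd_capture`.
#' @examples
#' lower_bound(99.76, 0.18) # 99.40
#' lower_bound(99.94, 0.14) # 99.66
#' @export
lower_bound <- function(mean_capture, sd_capture) {
  stopifnot(all(sd_capture >= 0 | is.na(sd_capture)))
  mean_capture - 2 * sd_capture
}

#' Clinical acceptance criteria
#'
#' A model passes for clinical use only if (1) the -2 SD lower bound of its
#' cross-validation capture rate is at least the minimum acceptable capture
#' rate, and (2) its final testing capture rate is at least that lower
#' bound (a consistency check against over/underfitting). The defaults
#' (minimum 99%, target 99.5%) suit routine confirmation triage; the
#' stringent preset (minimum 99.9%, target 100%) suits settings where
#' essentially no false positive call may escape.
#'
#' @param minimum_capture Minimum acceptable capture rate, in `(0, 1]`.
#' @param target_capture Desired capture rate, `>= minimum_capture`.
#' @return An `acceptance_criteria` list.
#' @export
acceptance_criteria <- function(minimum_capture = 0.99, target_capture = 0.995) {
  stopifnot(
    minimum_capture > 0, minimum_capture <= target_capture,
    target_capture <= 1
  )
  structure(
    list(minimum_capture = minimum_capture, target_capture = target_capture),
    class = "acceptance_criteria"
  )
}

#' @rdname acceptance_criteria
#' @export
stringent_criteria <- function() {
  acceptance_criteria(minimum_capture = 0.999, target_capture = 1.0)
}

#' Apply the two clinical pass rules to candidate models
#'
#' @param cv_mean,cv_sd Cross-validation capture-rate mean and SD
#'   (fractions).
#' @param final_capture Final testing capture rate (fraction).
#' @param criteria An [acceptance_criteria()].
#' @return Tibble with `lower_bound`, `passed_rule1`, `passed_rule2`,
#'   `passed`.
#' @export
acceptance_check <- function(cv_mean, cv_sd, final_capture,
                             criteria = acceptance_criteria()) {
  lb <- lower_bound(cv_mean, cv_sd)
  r1 <- lb >= criteria$minimum_capture
  r2 <- final_capture >= lb
  tibble(
    lower_bound = lb,
    passed_rule1 = r1,
    passed_rule2 = r2,
    passed = r1 & r2
  )
}

#' Modified F1 score for model tie-breaking
#'
#' Harmonic mean of the capture rate and the specificity
#' (`1 - tp_flag_rate`): high only when nearly all false positive calls are
#' captured *and* few true positive calls are needlessly confirmed. Defined
#' as its own named function so a laboratory can swap in a different
#' tie-break statistic.
#'
#' @param capture_rate,tp_flag_rate Rates in `[0, 1]`.
#' @return The modified F1 in `[0, 1]`; 0 when both terms are 0.
#' @examples
#' modified_f1(0.995, 0.122) # 0.93273
#' @export
modified_f1 <- function(capture_rate, tp_flag_rate) {
  spec <- 1 - tp_flag_rate
  denom <- capture_rate + spec
  if_else(denom == 0, 0, 2 * capture_rate * spec / denom)
}

#' Select one model per stratum from evaluated candidates
#'
#' Applies [acceptance_check()] to every candidate (one row per algorithm
#' and evaluation capture rate), computes the [modified_f1()] tie-break from
#' the final testing metrics, and marks at most one selected candidate per
#' stratum: the passing candidate with the highest modified F1, ties broken
#' by lower TP flag rate, then lower evaluation target, then algorithm name.
#' A stratum with no passing candidate gets no model and is always sent for
#' confirmation downstream.
#'
#' @param candidates Tibble with columns `stratum`, `algorithm`, `target`,
#'   `cv_mean_capture`, `cv_sd_capture`, `final_capture`, `final_tp_flag`
#'   (rates as fractions).
#' @param criteria An [acceptance_criteria()].
#' @return `candidates` plus `lower_bound`, `passed_rule1`, `passed_rule2`,
#'   `passed`, `modified_f1`, `selected`; row order preserved.
#' @export
select_models <- function(candidates, criteria = acceptance_criteria()) {
  candidates <- as_tibble(candidates)
  need <- c(
    "stratum", "algorithm", "target", "cv_mean_capture", "cv_sd_capture",
    "final_capture", "final_tp_flag"
  )
  missing <- setdiff(need, names(candidates))
  if (length(missing) > 0) {
    abort(paste0("select_models: missing columns ", paste(missing, collapse = ", ")))
  }
  out <- candidates |>
    mutate(
      acceptance_check(
        .data$cv_mean_capture, .data$cv_sd_capture, .data$final_capture,
        criteria
      ),
      modified_f1 = modified_f1(.data$final_capture, .data$final_tp_flag),
      .row = row_number()
    )
  winners <- out |>
    filter(.data$passed) |>
    group_by(.data$stratum) |>
    arrange(
      dplyr::desc(.data$modified_f1), .data$final_tp_flag, .data$target,
      .data$algorithm,
      .by_group = TRUE
    ) |>
    slice(1) |>
    ungroup() |>
    pull(".row")
  out$selected <- out$.row %in% winners
  out$.row <- NULL
  out
}
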