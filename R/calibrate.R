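#' Default evaluation capture rates
#'
#' Eight target capture rates in the 99-100% range at which every model is
#' calibrated and evaluated. 99% is a practical floor (1 in 100 false
#' positive calls escapes review); 100% flags every false positive call
#' seen in training. Override per run in the configuration.
#'
#' @return Strictly increasing numeric vector in `[0.99, 1]`.
#' @export
default_capture_rates <- function() {
  c(0.990, 0.995, 0.996, 0.997, 0.998, 0.999, 0.9995, 1.000)
}

#' Calibrate a score threshold at a target capture rate
#'
#' Given the classifier scores of the false positive calls in a calibration
#' set, returns the largest threshold such that flagging all calls with
#' `score >= threshold` captures at least `target` of those false positive
#' calls. The threshold is the appropriate order statistic of the FP
#' scores, so the capture guarantee on the calibration data is exact by
#' construction; ties at the threshold are flagged (resolved toward
#' confirmation). For `target = 1` the threshold is the minimum FP score.
#'
#' @param fp_scores Scores of false positive calls (higher = more FP-like).
#' @param target Capture rate in `(0, 1]`.
#' @return The score threshold.
#' @examples
#' calibrate_threshold(1:100 / 100, 0.99) # 0.02: 99 of 100 flagged
#' @export
calibrate_threshold <- function(fp_scores, target) {
  if (length(fp_scores) == 0 || anyNA(fp_scores)) {
    abort("calibrate_threshold: no false positive scores to calibrate on.")
  }
  stopifnot(target > 0, target <= 1)
  n <- length(fp_scores)
  s <- sort(fp_scores)
  m <- ceiling(n * target - 1e-9) # required number of flagged FPs
  k <- n - m + 1L
  s[k]
}

#' @rdname calibrate_threshold
#' @param targets Vector of target capture rates.
#' @return For `calibrate_thresholds()`: tibble with `target`, `threshold`;
#'   thresholds are non-increasing in `target`.
#' @export
calibrate_thresholds <- function(fp_scores, targets = default_capture_rates()) {
  tibble(
    target = targets,
    threshold = vapply(targets, function(t) calibrate_threshold(fp_scores, t), numeric(1))
  )
}

#' Capture rate and TP flag rate at a threshold
#'
#' The two operating characteristics of a triage model: the capture rate is
#' the fraction of false positive calls flagged (sensitivity for the FP
#' class); the TP flag rate is the fraction of true positive calls
#' needlessly flagged for confirmation.
#'
#' @param scores Numeric scores.
#' @param labels `"TP"`/`"FP"` character (or 0/1 with 1 = FP).
#' @param threshold Flag calls with `score >= threshold`.
#' @return One-row tibble with `capture_rate`, `tp_flag_rate`, `n_fp`,
#'   `n_tp`.
#' @export
evaluate_at_threshold <- function(scores, labels, threshold) {
  is_fp <- labels_to_fp(labels)
  if (!any(is_fp) || all(is_fp)) {
    abort("evaluate_at_threshold: both TP and FP calls must be present.")
  }
  flagged <- scores >= threshold
  tibble(
    capture_rate = mean(flagged[is_fp]),
    tp_flag_rate = mean(flagged[!is_fp]),
    n_fp = sum(is_fp),
    n_tp = sum(!is_fp)
  )
}

labels_to_fp <- function(labels) {
  if (is.numeric(labels)) {
    return(labels == 1)
  }
  labels == "FP"
}
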