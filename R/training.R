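#' Split labeled calls into balanced training and testing halves
#'
#' Per sample and per label class, half the calls (rounded up for the
#' training side) go to training and half to testing, so both halves keep
#' the sample mixture and the TP/FP balance of the input. The split is
#' deterministic for a fixed seed.
#'
#' @param calls Labeled calls tibble (needs `label`; `sample_id` used when
#'   present).
#' @param seed Integer seed.
#' @return List with elements `train` and `test`.
#' @export
split_train_test <- function(calls, seed = 1L) {
  calls <- as_tibble(calls)
  if (!"label" %in% names(calls)) abort("split_train_test needs a label column.")
  for (lab in c("TP", "FP")) {
    if (!any(calls$label == lab)) {
      warn(sprintf("split_train_test: no %s calls present; models cannot be trained on this stratum.", lab))
    }
  }
  grp <- if ("sample_id" %in% names(calls)) {
    paste(calls$sample_id, calls$label)
  } else {
    calls$label
  }
  take_train <- logical(nrow(calls))
  with_local_seed(seed, {
    for (g in unique(grp)) {
      idx <- which(grp == g)
      n_train <- ceiling(length(idx) / 2)
      take_train[sample(idx, n_train)] <- TRUE
    }
  })
  list(
    train = calls[take_train, , drop = FALSE],
    test = calls[!take_train, , drop = FALSE]
  )
}

#' Leave-one-sample-out cross-validation over a hyperparameter grid
#'
#' For each grid point and each fold, a classifier is fitted on all samples
#' but one, score thresholds are calibrated on the training portion's false
#' positive scores at every target capture rate, and the left-out sample is
#' scored — simulating the arrival of a new sample. Hyperparameters are
#' chosen per algorithm by highest mean ROC AUC across folds; the
#' cross-validation summary (per-target mean, SD and `mean - 2*SD` lower
#' bound of the capture rate, plus TP flag rate moments) is computed from
#' the winning grid point's folds.
#'
#' @param labeled Labeled calls for one stratum, with `sample_id`, `label`
#'   and feature columns.
#' @param grid Learner grid (see [default_learner_grid()]).
#' @param targets Evaluation capture rates.
#' @param seed Integer seed.
#' @param features Feature column names; default: every numeric non-metadata
#'   column.
#' @return A `loso_cv` object with elements `fold_metrics`, `best`,
#'   `cv_summary`. [tidy()] returns the summary, [glance()] the per-algorithm
#'   winners.
#' @export
loso_cv <- function(labeled, grid = default_learner_grid(),
                    targets = default_capture_rates(), seed = 1L,
                    features = NULL) {
  labeled <- as_tibble(labeled)
  stopifnot("sample_id" %in% names(labeled), "label" %in% names(labeled))
  check_targets(targets)
  samples <- sort(unique(labeled$sample_id))
  if (length(samples) < 2) abort("loso_cv needs at least 2 samples.")
  feats <- feature_cols(labeled, features)
  y_all <- as.integer(labeled$label == "FP")

  fold_rows <- list()
  skipped_folds <- 0L
  for (g in seq_len(nrow(grid))) {
    alg <- grid$algorithm[g]
    params <- grid$params[[g]]
    for (f in seq_along(samples)) {
      left_out <- samples[f]
      tr <- labeled$sample_id != left_out
      y_tr <- y_all[tr]
      y_te <- y_all[!tr]
      if (length(unique(y_tr)) < 2) {
        warn(sprintf("loso_cv: fold %s has a single class in training; skipped.", left_out))
        next
      }
      fit <- fit_learner(alg, params, labeled[tr, feats], y_tr,
        seed = seed + 1000L * g + f
      )
      thr <- calibrate_thresholds(predict_scores(fit, labeled[tr & y_all == 1L, feats]), targets)
      te_scores <- predict_scores(fit, labeled[!tr, feats])
      auc <- roc_auc(te_scores, y_te)
      has_fp <- any(y_te == 1L)
      has_tp <- any(y_te == 0L)
      if (!has_fp) skipped_folds <- skipped_folds + 1L
      fold_rows[[length(fold_rows) + 1]] <- tibble(
        algorithm = alg, grid_id = grid$grid_id[g], left_out = left_out,
        target = thr$target, threshold = thr$threshold,
        capture_rate = if (has_fp) {
          vapply(thr$threshold, function(t) mean(te_scores[y_te == 1L] >= t), numeric(1))
        } else {
          NA_real_
        },
        tp_flag_rate = if (has_tp) {
          vapply(thr$threshold, function(t) mean(te_scores[y_te == 0L] >= t), numeric(1))
        } else {
          NA_real_
        },
        roc_auc = auc
      )
    }
  }
  fold_metrics <- bind_rows(fold_rows)
  if (skipped_folds > 0) {
    warn(sprintf(
      "loso_cv: %d fold(s) had no false positive calls in the left-out sample; capture rate excluded from the summary there.",
      as.integer(round(skipped_folds / nrow(grid)))
    ))
  }

  best <- fold_metrics |>
    distinct(.data$algorithm, .data$grid_id, .data$left_out, .data$roc_auc) |>
    group_by(.data$algorithm, .data$grid_id) |>
    summarise(mean_auc = mean(.data$roc_auc, na.rm = TRUE), .groups = "drop") |>
    group_by(.data$algorithm) |>
    arrange(dplyr::desc(.data$mean_auc), .data$grid_id, .by_group = TRUE) |>
    slice(1) |>
    ungroup()
  best$params <- lapply(best$grid_id, function(id) grid$params[[match(id, grid$grid_id)]])

  cv_summary <- fold_metrics |>
    inner_join(best[c("algorithm", "grid_id")], by = c("algorithm", "grid_id")) |>
    group_by(.data$algorithm, .data$target) |>
    summarise(
      mean_capture = mean(.data$capture_rate, na.rm = TRUE),
      sd_capture = sd(.data$capture_rate, na.rm = TRUE),
      mean_tp_flag = mean(.data$tp_flag_rate, na.rm = TRUE),
      sd_tp_flag = sd(.data$tp_flag_rate, na.rm = TRUE),
      n_folds = sum(!is.na(.data$capture_rate)),
      .groups = "drop"
    ) |>
    mutate(lower_bound = lower_bound(.data$mean_capture, .data$sd_capture)) |>
    relocate("lower_bound", .after = "sd_capture")

  structure(
    list(
      fold_metrics = fold_metrics, best = best, cv_summary = cv_summary,
      targets = targets, seed = seed, features = feats,
      n_samples = length(samples)
    ),
    class = "loso_cv"
  )
}

check_targets <- function(targets) {
  if (length(targets) == 0 || any(diff(targets) <= 0) ||
    any(targets < 0.99 - 1e-12) || any(targets > 1)) {
    abort("Evaluation capture rates must be strictly increasing within [0.99, 1].")
  }
  invisible(targets)
}

#' @export
tidy.loso_cv <- function(x, ...) x$cv_summary

#' @export
glance.loso_cv <- function(x, ...) {
  x$best |> select("algorithm", "grid_id", "mean_auc")
}

#' @exportS3Method base::print
print.loso_cv <- function(x, ...) {
  cat(sprintf(
    "<loso_cv> %d samples, %d grid points, %d targets\n",
    x$n_samples, length(unique(x$fold_metrics$grid_id)), length(x$targets)
  ))
  print(x$cv_summary)
  invisible(x)
}

#' Train and calibrate the final model for one stratum
#'
#' Fits the chosen algorithm on the full training half, recalibrates the
#' score thresholds on the training half's false positive scores at every
#' target capture rate, and evaluates capture and TP flag rates on the
#' untouched testing half.
#'
#' @param train,test Labeled call tibbles from [split_train_test()].
#' @param algorithm,params Winning learner and hyperparameters (e.g. from
#'   [loso_cv()]'s `best`).
#' @param targets Evaluation capture rates.
#' @param seed Integer seed.
#' @param stratum,schema_id Optional metadata recorded on the model.
#' @param cv_summary Optional CV summary (from [loso_cv()]) stored for the
#'   selection step.
#' @param features Feature columns (default inferred).
#' @return A `calibrated_model`; [tidy()] gives per-target thresholds and
#'   held-out metrics.
#' @export
train_final <- function(train, test, algorithm, params,
                        targets = default_capture_rates(), seed = 1L,
                        stratum = NULL, schema_id = NULL, cv_summary = NULL,
                        features = NULL) {
  check_targets(targets)
  feats <- feature_cols(train, features)
  y_tr <- as.integer(train$label == "FP")
  y_te <- as.integer(test$label == "FP")
  if (length(unique(y_tr)) < 2) {
    abort("train_final: training data must contain both TP and FP calls.")
  }
  fit <- fit_learner(algorithm, params, train[, feats], y_tr, seed = seed)
  thresholds <- calibrate_thresholds(
    predict_scores(fit, train[y_tr == 1L, feats]), targets
  )
  te_scores <- predict_scores(fit, test[, feats])
  final_metrics <- thresholds |>
    mutate(purrr::map_dfr(
      .data$threshold,
      function(t) evaluate_at_threshold(te_scores, y_te, t)
    ))
  structure(
    list(
      stratum = stratum, algorithm = algorithm, params = params,
      fit = fit, thresholds = thresholds, final_metrics = final_metrics,
      cv_summary = cv_summary, features = feats, schema_id = schema_id,
      seed = seed
    ),
    class = "calibrated_model"
  )
}

#' @exportS3Method base::print
print.calibrated_model <- function(x, ...) {
  cat(sprintf(
    "<calibrated_model> %s (%s), %d thresholds\n",
    x$algorithm, x$stratum %||% "unspecified stratum", nrow(x$thresholds)
  ))
  print(x$final_metrics)
  invisible(x)
}

#' @export
tidy.calibrated_model <- function(x, ...) x$final_metrics

#' @export
glance.calibrated_model <- function(x, ...) {
  tibble(
    stratum = x$stratum %||% NA_character_,
    algorithm = x$algorithm,
    n_features = length(x$features),
    n_targets = nrow(x$thresholds),
    schema_id = x$schema_id %||% NA_character_
  )
}

#' Score or flag calls with a calibrated model
#'
#' @param object A `calibrated_model`.
#' @param calls Calls tibble containing the model's feature columns. If the
#'   tibble carries a `schema_id` attribute (as [read_vcf()] output does) it
#'   must match the model's.
#' @param target Target capture rate selecting the threshold (required for
#'   `type = "flag"`); must be one of the model's calibrated targets.
#' @param type `"score"` for raw scores, `"flag"` for logical flags.
#' @param ... Unused.
#' @return Numeric scores or logical flags.
#' @export
predict.calibrated_model <- function(object, calls, target = NULL,
                                     type = c("score", "flag"), ...) {
  type <- match.arg(type)
  in_schema <- attr(calls, "schema_id")
  if (!is.null(in_schema) && !is.null(object$schema_id) &&
    !identical(in_schema, object$schema_id)) {
    abort(sprintf(
      "Schema mismatch: calls were extracted under '%s' but the model was trained under '%s'.",
      in_schema, object$schema_id
    ))
  }
  scores <- predict_scores(object$fit, calls[, object$features, drop = FALSE])
  if (type == "score") {
    return(scores)
  }
  if (is.null(target)) abort("predict(type = 'flag') needs a target capture rate.")
  row <- which(abs(object$thresholds$target - target) < 1e-12)
  if (length(row) != 1) {
    abort("target is not one of the model's calibrated capture rates.")
  }
  scores >= object$thresholds$threshold[row]
}

#' @export
autoplot.calibrated_model <- function(object, ...) {
  dat <- object$final_metrics |>
    tidyr::pivot_longer(c("capture_rate", "tp_flag_rate"),
      names_to = "metric", values_to = "rate"
    )
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$target, y = .data$rate, colour = .data$metric
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "target capture rate", y = "held-out rate",
      title = paste0(
        object$algorithm,
        if (!is.null(object$stratum)) paste0(" / ", object$stratum)
      )
    ) +
    ggplot2::theme_minimal()
}
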