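#' Train, cross-validate, and select triage models for every stratum
#'
#' The full modeling workflow for a labeled multi-sample cohort: calls are
#' partitioned into the six variant-type by genotype strata; within each
#' stratum the calls are split into balanced training/testing halves,
#' leave-one-sample-out cross-validation chooses hyperparameters per
#' algorithm, final models are retrained and calibrated at every evaluation
#' capture rate, and the clinical acceptance rules pick at most one model
#' per stratum. Strata without both call labels (or failing every
#' criterion) end up with no model and are always confirmed downstream.
#'
#' @param labeled Labeled calls across samples (columns `sample_id`,
#'   `label`, features; stratum columns added if absent).
#' @param grid Learner grid; [default_learner_grid()] has 45 points,
#'   [small_learner_grid()] one per algorithm.
#' @param targets Evaluation capture rates.
#' @param criteria [acceptance_criteria()].
#' @param seed Integer seed.
#' @param features Feature columns (default inferred).
#' @param schema_id Recorded on every model; predictions refuse calls
#'   extracted under a different schema.
#' @return A `model_set`: `models` (per-stratum list with the selected
#'   `calibrated_model`, its `target` and `threshold`, or `NULL`), `report`
#'   (all candidates with pass/selection columns, mirroring a selection
#'   table), `cv` (per-stratum `loso_cv` objects). [tidy()] returns the
#'   report.
#' @export
train_stratum_models <- function(labeled,
                                 grid = default_learner_grid(),
                                 targets = default_capture_rates(),
                                 criteria = acceptance_criteria(),
                                 seed = 1L, features = NULL,
                                 schema_id = NULL) {
  labeled <- as_tibble(labeled)
  if (!"stratum" %in% names(labeled)) {
    labeled <- suppressWarnings(classify_stratum(labeled, on_unclassifiable = "drop"))
  }
  strata <- partition_by_stratum(labeled)
  models <- setNames(vector("list", length(strata)), names(strata))
  cvs <- list()
  report_rows <- list()
  no_model <- function(stratum, reason) {
    inform(sprintf("stratum %s: no model (%s)", stratum, reason))
  }

  for (s in names(strata)) {
    dat <- strata[[s]]
    if (nrow(dat) == 0) {
      no_model(s, "no calls")
      next
    }
    n_fp <- sum(dat$label == "FP")
    n_tp <- sum(dat$label == "TP")
    if (n_fp < 2 || n_tp < 2) {
      no_model(s, sprintf("insufficient labeled calls (%d FP, %d TP)", n_fp, n_tp))
      next
    }
    halves <- suppressWarnings(split_train_test(dat, seed = seed))
    cv <- tryCatch(
      suppressWarnings(loso_cv(halves$train,
        grid = grid, targets = targets,
        seed = seed, features = features
      )),
      error = function(e) {
        no_model(s, conditionMessage(e))
        NULL
      }
    )
    if (is.null(cv)) next
    cvs[[s]] <- cv

    cand_rows <- list()
    finals <- list()
    for (a in seq_len(nrow(cv$best))) {
      alg <- cv$best$algorithm[a]
      fm <- tryCatch(
        train_final(halves$train, halves$test, alg, cv$best$params[[a]],
          targets = targets, seed = seed, stratum = s,
          schema_id = schema_id,
          cv_summary = cv$cv_summary[cv$cv_summary$algorithm == alg, ],
          features = features
        ),
        error = function(e) NULL
      )
      if (is.null(fm)) next
      finals[[alg]] <- fm
      cvs_a <- cv$cv_summary[cv$cv_summary$algorithm == alg, ]
      cand_rows[[alg]] <- tibble(
        stratum = s, algorithm = alg, target = cvs_a$target,
        cv_mean_capture = cvs_a$mean_capture, cv_sd_capture = cvs_a$sd_capture,
        cv_mean_tp_flag = cvs_a$mean_tp_flag, cv_sd_tp_flag = cvs_a$sd_tp_flag,
        final_capture = fm$final_metrics$capture_rate,
        final_tp_flag = fm$final_metrics$tp_flag_rate
      )
    }
    if (length(cand_rows) == 0) {
      no_model(s, "no trainable candidate")
      next
    }
    decisions <- select_models(bind_rows(cand_rows), criteria)
    report_rows[[s]] <- decisions
    sel <- decisions[decisions$selected, , drop = FALSE]
    if (nrow(sel) == 1) {
      model <- finals[[sel$algorithm]]
      thr_row <- which(abs(model$thresholds$target - sel$target) < 1e-12)
      models[[s]] <- list(
        model = model,
        target = sel$target,
        threshold = model$thresholds$threshold[thr_row]
      )
    } else {
      no_model(s, "no candidate passed the acceptance criteria")
    }
  }

  structure(
    list(
      models = models,
      report = bind_rows(report_rows),
      cv = cvs,
      criteria = criteria, targets = targets, seed = seed,
      schema_id = schema_id
    ),
    class = "model_set"
  )
}

#' @exportS3Method base::print
print.model_set <- function(x, ...) {
  passing <- names(x$models)[!vapply(x$models, is.null, logical(1))]
  cat(sprintf(
    "<model_set> %d/%d strata with a selected model (minimum %.4g, target %.4g)\n",
    length(passing), length(x$models),
    x$criteria$minimum_capture, x$criteria$target_capture
  ))
  for (s in names(x$models)) {
    m <- x$models[[s]]
    if (is.null(m)) {
      cat(sprintf("  %-18s (none — always confirmed)\n", s))
    } else {
      cat(sprintf(
        "  %-18s %s @ capture target %.4g (threshold %.4g)\n",
        s, m$model$algorithm, m$target, m$threshold
      ))
    }
  }
  invisible(x)
}

#' @export
tidy.model_set <- function(x, ...) x$report

#' @export
glance.model_set <- function(x, ...) {
  tibble(
    stratum = names(x$models),
    has_model = !vapply(x$models, is.null, logical(1)),
    algorithm = vapply(x$models, function(m) {
      if (is.null(m)) NA_character_ else m$model$algorithm
    }, character(1)),
    target = vapply(x$models, function(m) {
      if (is.null(m)) NA_real_ else m$target
    }, numeric(1))
  )
}

#' @export
autoplot.model_set <- function(object, ...) {
  rep <- object$report
  ggplot2::ggplot(rep, ggplot2::aes(
    x = .data$target, y = .data$final_capture,
    colour = .data$algorithm, shape = .data$passed
  )) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(
      yintercept = object$criteria$minimum_capture, linetype = "dashed"
    ) +
    ggplot2::facet_wrap(~stratum) +
    ggplot2::labs(
      x = "evaluation capture rate target", y = "final testing capture rate"
    ) +
    ggplot2::theme_minimal()
}

bundle_version <- "1"

#' Save / load a model set bundle
#'
#' The bundle records the fitted models, thresholds, selection report,
#' schema identifier, seed, and a configuration hash, and is versioned so
#' stale bundles are refused on read.
#'
#' @param model_set A `model_set`.
#' @param path File path for the bundle (an RDS file).
#' @return `path` (write) or the restored `model_set` (read).
#' @export
write_model_bundle <- function(model_set, path) {
  stopifnot(inherits(model_set, "model_set"))
  payload <- list(
    bundle_version = bundle_version,
    config_hash = hash(list(
      model_set$criteria, model_set$targets, model_set$seed,
      model_set$schema_id
    )),
    model_set = model_set
  )
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname write_model_bundle
#' @export
read_model_bundle <- function(path) {
  payload <- readRDS(path)
  if (!identical(payload$bundle_version, bundle_version)) {
    abort(sprintf(
      "Bundle version '%s' is not supported by this package version.",
      payload$bundle_version %||% "unknown"
    ))
  }
  payload$model_set
}
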