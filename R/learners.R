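# Learner layer: four algorithms behind one fit/score interface. The
# classifier's score is the probability-like evidence that a call is a
# false positive (FP = class 1); thresholds are calibrated on this score.

# Run code with a locally-seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Supported learning algorithms
#' @return Character vector of algorithm identifiers.
#' @export
learner_algorithms <- function() {
  c("adaboost", "easyensemble", "gradientboosting", "randomforest")
}

#' Default hyperparameter grid
#'
#' A 45-point grid across the four algorithms (12 AdaBoost, 5 EasyEnsemble,
#' 16 GradientBoosting, 12 RandomForest). The grid is plain data and fully
#' configurable; [small_learner_grid()] gives one point per algorithm for
#' quick runs.
#'
#' @return Tibble with columns `algorithm`, `grid_id`, `params`
#'   (list-column of named lists).
#' @export
default_learner_grid <- function() {
  ada <- tidyr::expand_grid(
    n_estimators = c(25L, 50L, 100L),
    learning_rate = c(0.5, 1.0),
    max_depth = c(1L, 2L)
  )
  easy <- tibble(
    n_subsets = c(5L, 5L, 10L, 10L, 15L),
    n_estimators = c(25L, 50L, 25L, 50L, 25L),
    max_depth = 1L, learning_rate = 1.0
  )
  gb <- tidyr::expand_grid(
    nrounds = c(50L, 100L),
    max_depth = c(2L, 4L),
    eta = c(0.1, 0.3),
    subsample = c(0.8, 1.0)
  )
  rf <- tidyr::expand_grid(
    num_trees = c(100L, 300L),
    min_node_size = c(1L, 5L, 10L),
    mtry_frac = c(0.4, 0.8)
  )
  pack <- function(algorithm, tbl) {
    tibble(
      algorithm = algorithm,
      grid_id = paste0(algorithm, "-", seq_len(nrow(tbl))),
      params = lapply(seq_len(nrow(tbl)), function(i) as.list(tbl[i, ]))
    )
  }
  bind_rows(
    pack("adaboost", ada),
    pack("easyensemble", easy),
    pack("gradientboosting", gb),
    pack("randomforest", rf)
  )
}

#' @rdname default_learner_grid
#' @export
small_learner_grid <- function() {
  grid <- default_learner_grid()
  picks <- c(
    "adaboost-7", # 50 estimators, lr 1.0, stumps
    "easyensemble-3", # 10 subsets x 25 stumps
    "gradientboosting-8", # 50 rounds, depth 4, eta 0.3
    "randomforest-3" # 100 trees, node size 5
  )
  grid[grid$grid_id %in% picks, , drop = FALSE]
}

#' Fit one classifier
#'
#' @param algorithm One of [learner_algorithms()].
#' @param params Named list of hyperparameters (see
#'   [default_learner_grid()] for the names each algorithm understands).
#' @param data Data frame of numeric features.
#' @param y Integer vector of labels, 1 = false positive call, 0 = true
#'   positive call.
#' @param seed Integer seed; fits are deterministic given it.
#' @return An `fp_learner` object for [predict_scores()].
#' @export
fit_learner <- function(algorithm, params, data, y, seed = 1L) {
  algorithm <- match.arg(algorithm, learner_algorithms())
  stopifnot(nrow(data) == length(y), all(y %in% c(0L, 1L)))
  if (length(unique(y)) < 2) {
    abort("fit_learner needs both classes present.")
  }
  fit <- with_local_seed(seed, switch(algorithm,
    adaboost = do.call(ada_fit, c(list(x = data, y = y), params)),
    easyensemble = do.call(easy_fit, c(list(x = data, y = y), params)),
    gradientboosting = xgb_fit(data, y, params),
    randomforest = rf_fit(data, y, params, seed)
  ))
  structure(
    list(algorithm = algorithm, params = params, fit = fit, features = names(data)),
    class = "fp_learner"
  )
}

#' Score calls with a fitted classifier
#'
#' @param object An `fp_learner` from [fit_learner()].
#' @param data Data frame containing the learner's feature columns.
#' @return Numeric vector in `[0, 1]`; higher means more likely a false
#'   positive call.
#' @export
predict_scores <- function(object, data) {
  stopifnot(inherits(object, "fp_learner"))
  data <- as.data.frame(data)[object$features]
  switch(object$algorithm,
    adaboost = ada_score(object$fit, data),
    easyensemble = easy_score(object$fit, data),
    gradientboosting = as.numeric(
      predict(object$fit, xgboost::xgb.DMatrix(as.matrix(data)))
    ),
    randomforest = as.numeric(
      predict(object$fit, data = data, num.threads = 1L)$predictions[, "1"]
    )
  )
}

# ---- AdaBoost (SAMME with rpart base learners) -------------------------
# No installed package provides AdaBoost, so the classic discrete SAMME
# boosting scheme is implemented here over rpart classification trees.

ada_fit <- function(x, y, n_estimators = 50L, learning_rate = 1.0,
                    max_depth = 1L, ...) {
  df <- as.data.frame(x)
  df$.y <- factor(y, levels = c(0L, 1L))
  n <- nrow(df)
  w <- rep(1 / n, n)
  trees <- list()
  alphas <- numeric(0)
  ctrl <- rpart::rpart.control(
    maxdepth = max_depth, cp = 0, xval = 0, minsplit = 10, maxcompete = 0,
    maxsurrogate = 0
  )
  for (m in seq_len(n_estimators)) {
    wt <- w * n
    tree <- rpart::rpart(.y ~ ., data = df, weights = wt,
      method = "class", control = ctrl)
    pred <- predict(tree, type = "class")
    miss <- pred != df$.y
    err <- sum(w[miss])
    err <- min(max(err, 1e-10), 1 - 1e-10)
    alpha <- learning_rate * log((1 - err) / err)
    if (alpha <= 0) {
      if (length(trees) == 0) {
        trees <- list(tree)
        alphas <- 1e-6
      }
      break
    }
    trees[[length(trees) + 1]] <- tree
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * miss)
    w <- w / sum(w)
  }
  list(trees = trees, alphas = alphas)
}

ada_score <- function(fit, data) {
  if (length(fit$trees) == 0) {
    return(rep(0.5, nrow(data)))
  }
  votes <- vapply(fit$trees, function(tree) {
    predict(tree, newdata = data, type = "class") == "1"
  }, logical(nrow(data)))
  votes <- matrix(votes, nrow = nrow(data))
  as.numeric(votes %*% fit$alphas) / sum(fit$alphas)
}

# ---- EasyEnsemble (balanced bagging of AdaBoost learners) --------------
# Ensemble of AdaBoost models, each trained on all minority-class calls
# plus an equal-sized random subsample of the majority class; scores are
# averaged. This is the standard remedy when false positive calls are rare.

easy_fit <- function(x, y, n_subsets = 10L, n_estimators = 25L,
                     max_depth = 1L, learning_rate = 1.0, ...) {
  minority <- if (sum(y == 1L) <= sum(y == 0L)) 1L else 0L
  idx_min <- which(y == minority)
  idx_maj <- which(y != minority)
  bags <- lapply(seq_len(n_subsets), function(b) {
    take <- sample(idx_maj, size = min(length(idx_min), length(idx_maj)))
    idx <- c(idx_min, take)
    ada_fit(x[idx, , drop = FALSE], y[idx],
      n_estimators = n_estimators,
      learning_rate = learning_rate, max_depth = max_depth
    )
  })
  list(bags = bags)
}

easy_score <- function(fit, data) {
  scores <- vapply(
    fit$bags, function(b) ada_score(b, data),
    numeric(nrow(data))
  )
  rowMeans(matrix(scores, nrow = nrow(data)))
}

# ---- GradientBoosting (xgboost) / RandomForest (ranger) ----------------

xgb_fit <- function(x, y, params) {
  p <- modifyList(
    list(nrounds = 50L, max_depth = 3L, eta = 0.3, subsample = 1.0),
    params[names(params) %in% c("nrounds", "max_depth", "eta", "subsample")]
  )
  dtrain <- xgboost::xgb.DMatrix(as.matrix(x), label = y)
  xgboost::xgb.train(
    params = list(
      objective = "binary:logistic", max_depth = p$max_depth, eta = p$eta,
      subsample = p$subsample, nthread = 1L
    ),
    data = dtrain, nrounds = p$nrounds, verbose = 0
  )
}

rf_fit <- function(x, y, params, seed) {
  p <- modifyList(
    list(num_trees = 100L, min_node_size = 5L, mtry_frac = NULL),
    params[names(params) %in% c("num_trees", "min_node_size", "mtry_frac")]
  )
  mtry <- if (is.null(p$mtry_frac)) {
    max(1L, floor(sqrt(ncol(x))))
  } else {
    max(1L, floor(p$mtry_frac * ncol(x)))
  }
  ranger::ranger(
    x = as.data.frame(x), y = factor(y, levels = c(0L, 1L)),
    probability = TRUE, num.trees = p$num_trees,
    min.node.size = p$min_node_size, mtry = mtry,
    seed = seed, num.threads = 1L
  )
}

#' Area under the ROC curve for false-positive-call scores
#'
#' @param scores Numeric scores (higher = more likely FP).
#' @param y Labels, 1 = FP call, 0 = TP call.
#' @return AUC in `[0, 1]`; `NA` if only one class is present.
#' @export
roc_auc <- function(scores, y) {
  if (length(unique(y)) < 2) {
    return(NA_real_)
  }
  as.numeric(pROC::auc(pROC::roc(
    response = y, predictor = scores,
    levels = c("0", "1"), direction = "<", quiet = TRUE
  )))
}
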