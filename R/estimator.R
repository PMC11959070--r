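#' The default hyperparameter grid for the stroke-volume regressor
#'
#' Number of boosting rounds \{60, 80, 100, 120\}, learning rate
#' \{0.2, 0.4, 0.6\}, maximum tree depth \{3, 5, 8, 10\}, per-split feature
#' subsampling `"sqrt"`, and minimum samples per leaf \{1, 3, 5\}.
#'
#' @param n_estimators,learning_rate,max_depth,max_features,min_samples_leaf
#'   grid values; each must be non-empty.
#' @return a list of class `sv_grid`.
#' @export
sv_grid <- function(n_estimators = c(60, 80, 100, 120),
                    learning_rate = c(0.2, 0.4, 0.6),
                    max_depth = c(3, 5, 8, 10),
                    max_features = "sqrt",
                    min_samples_leaf = c(1, 3, 5)) {
  g <- list(n_estimators = n_estimators, learning_rate = learning_rate,
            max_depth = max_depth, max_features = max_features,
            min_samples_leaf = min_samples_leaf)
  if (any(lengths(g) == 0)) abort("all grid dimensions must be non-empty")
  if (!all(max_features %in% c("sqrt", "all"))) {
    abort("`max_features` must be 'sqrt' or 'all'")
  }
  structure(g, class = "sv_grid")
}

SV_FEATURES <- c("age", "gender", "weight", "height", "sbp", "dbp", "pp",
                 "map", "cfpwv")

# numeric feature matrix in fixed schema order; gender encoded M -> 0, F -> 1
build_feature_matrix <- function(data, schema = SV_FEATURES) {
  miss <- setdiff(schema, names(data))
  if (length(miss) > 0) {
    abort(paste0("feature table lacks column(s): ", paste(miss, collapse = ", ")))
  }
  x <- data[schema]
  if (is.character(x$gender) || is.factor(x$gender)) {
    g <- as.character(x$gender)
    if (!all(g %in% c("M", "F"))) abort("`gender` must be 'M' or 'F'")
    x$gender <- ifelse(g == "F", 1, 0)
  }
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  if (anyNA(m) || any(!is.finite(m))) {
    bad <- which(!is.finite(m), arr.ind = TRUE)[1, ]
    abort(paste0("missing/non-finite feature: record ", bad[1], ", field '",
                 schema[bad[2]], "'"))
  }
  m
}

xgb_params <- function(learning_rate, max_depth, max_features,
                       min_samples_leaf, n_features, seed) {
  list(
    objective = "reg:squarederror",
    eta = learning_rate,
    max_depth = as.integer(max_depth),
    min_child_weight = min_samples_leaf,
    colsample_bynode = if (max_features == "sqrt") {
      sqrt(n_features) / n_features
    } else 1,
    nthread = 1,
    seed = as.integer(seed)
  )
}

#' Train the gradient-boosting stroke-volume estimator with grid search
#'
#' Exhaustively evaluates every grid combination by K-fold cross-validation
#' scored with R^2 (coefficient of determination on the held-out fold),
#' selects the combination with the highest mean CV score, and refits it on
#' the full dataset. The feature schema (nine ordered inputs, gender coded
#' M = 0 / F = 1) is frozen at training time and enforced at prediction.
#' Training is deterministic given the seed (single-threaded boosting,
#' seeded fold assignment and per-node feature subsampling).
#'
#' @param data feature table with columns `age`, `gender`, `weight`,
#'   `height`, `sbp`, `dbp`, `pp`, `map`, `cfpwv` and the target `sv`;
#'   at least 100 rows.
#' @param grid an [sv_grid()].
#' @param folds number of cross-validation folds.
#' @param seed integer seed (required).
#' @return an object of class `sv_estimator` with the fitted booster, the
#'   selected hyperparameters, the full CV table, the winning CV score, the
#'   feature schema and a training-config hash.
#' @export
train_sv_estimator <- function(data, grid = sv_grid(), folds = 5, seed) {
  if (missing(seed) || !is.numeric(seed)) abort("`seed` is required")
  if (!inherits(grid, "sv_grid")) abort("`grid` must be an `sv_grid`")
  if (nrow(data) < 100) abort("training requires at least 100 records")
  if (!"sv" %in% names(data)) abort("feature table lacks the target column `sv`")
  y <- data$sv
  if (anyNA(y) || any(!is.finite(y))) abort("missing/non-finite target `sv`")
  if (stats::var(y) == 0) abort("degenerate target: `sv` has zero variance")
  x <- build_feature_matrix(data)
  n <- nrow(x)
  p <- ncol(x)

  set.seed(as.integer(seed))
  fold_id <- sample(rep(seq_len(folds), length.out = n))

  combos <- expand.grid(
    n_estimators = grid$n_estimators,
    learning_rate = grid$learning_rate,
    max_depth = grid$max_depth,
    max_features = grid$max_features,
    min_samples_leaf = grid$min_samples_leaf,
    stringsAsFactors = FALSE,
    KEEP.OUT.ATTRS = FALSE
  )

  cv_r2 <- matrix(NA_real_, nrow(combos), folds)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    dtr <- xgboost::xgb.DMatrix(x[tr, , drop = FALSE], label = y[tr])
    xte <- x[!tr, , drop = FALSE]
    yte <- y[!tr]
    ss_tot <- sum((yte - mean(yte))^2)
    for (ci in seq_len(nrow(combos))) {
      cmb <- combos[ci, ]
      params <- xgb_params(cmb$learning_rate, cmb$max_depth, cmb$max_features,
                           cmb$min_samples_leaf, p, seed)
      bst <- xgboost::xgb.train(params = params, data = dtr,
                                nrounds = cmb$n_estimators, verbose = 0)
      pred <- predict(bst, xte)
      cv_r2[ci, f] <- 1 - sum((yte - pred)^2) / ss_tot
    }
  }
  mean_r2 <- rowMeans(cv_r2)
  best <- which.max(mean_r2)  # ties resolved by grid order

  sel <- combos[best, ]
  params <- xgb_params(sel$learning_rate, sel$max_depth, sel$max_features,
                       sel$min_samples_leaf, p, seed)
  dall <- xgboost::xgb.DMatrix(x, label = y)
  booster <- xgboost::xgb.train(params = params, data = dall,
                                nrounds = sel$n_estimators, verbose = 0)

  cv_results <- as_tibble(combos)
  cv_results$mean_cv_r2 <- mean_r2
  config_hash <- rlang::hash(list(grid = unclass(grid), folds = folds,
                                  seed = as.integer(seed),
                                  schema = SV_FEATURES, n = n))
  structure(
    list(
      booster = booster,
      selected = as.list(sel),
      cv_score = mean_r2[best],
      cv_results = cv_results,
      schema = SV_FEATURES,
      gender_encoding = c(M = 0, F = 1),
      folds = folds,
      seed = as.integer(seed),
      config_hash = config_hash
    ),
    class = "sv_estimator"
  )
}

#' @export
print.sv_estimator <- function(x, ...) {
  cat("<sv_estimator> gradient boosting, CV R^2 =", signif(x$cv_score, 4), "\n")
  cat("  selected:", paste(names(x$selected), unlist(x$selected),
                           sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Predict stroke volume for new records
#'
#' Applies the frozen feature schema to `newdata` and returns one predicted
#' stroke volume per record; the input is not modified and no retraining
#' occurs.
#'
#' @param object an `sv_estimator`.
#' @param newdata feature table containing the schema columns.
#' @return tibble with column `sv_pred` (mL); attribute `model_hash`
#'   identifies the model.
#' @export
predict_sv <- function(object, newdata) {
  if (!inherits(object, "sv_estimator")) abort("`object` must be an `sv_estimator`")
  x <- build_feature_matrix(newdata, object$schema)
  out <- tibble(sv_pred = as.numeric(predict(object$booster, x)))
  attr(out, "model_hash") <- object$config_hash
  out
}

#' @export
predict.sv_estimator <- function(object, newdata, ...) {
  predict_sv(object, newdata)$sv_pred
}

MODEL_BUNDLE_VERSION <- 1L

#' Persist / restore a trained estimator
#'
#' The bundle stores the serialized booster together with its metadata
#' (schema and a schema checksum, selected hyperparameters, CV score, seed
#' and training-config hash); `load_sv_model()` verifies the checksum so a
#' tampered or corrupt bundle fails loudly. Round-tripping preserves
#' predictions bit-for-bit.
#'
#' @param object an `sv_estimator`.
#' @param path bundle file path.
#' @return `save_sv_model()` returns `path` invisibly; `load_sv_model()`
#'   returns the restored `sv_estimator`.
#' @export
save_sv_model <- function(object, path) {
  if (!inherits(object, "sv_estimator")) abort("`object` must be an `sv_estimator`")
  bundle <- list(
    version = MODEL_BUNDLE_VERSION,
    raw = xgboost::xgb.save.raw(object$booster),
    selected = object$selected,
    cv_score = object$cv_score,
    cv_results = object$cv_results,
    schema = object$schema,
    schema_hash = rlang::hash(object$schema),
    gender_encoding = object$gender_encoding,
    folds = object$folds,
    seed = object$seed,
    config_hash = object$config_hash
  )
  saveRDS(bundle, path)
  invisible(path)
}

#' @rdname save_sv_model
#' @export
load_sv_model <- function(path) {
  bundle <- tryCatch(readRDS(path), error = function(e) {
    abort(paste0("cannot read model bundle: ", conditionMessage(e)))
  })
  need <- c("version", "raw", "selected", "schema", "schema_hash", "config_hash")
  if (!is.list(bundle) || !all(need %in% names(bundle))) {
    abort("corrupt model bundle: missing fields")
  }
  if (bundle$version != MODEL_BUNDLE_VERSION) {
    abort(paste0("unsupported model bundle version: ", bundle$version))
  }
  if (!identical(rlang::hash(bundle$schema), bundle$schema_hash)) {
    abort("model bundle schema checksum mismatch (tampered or corrupt)")
  }
  booster <- xgboost::xgb.load.raw(bundle$raw)
  structure(
    list(
      booster = booster,
      selected = bundle$selected,
      cv_score = bundle$cv_score,
      cv_results = bundle$cv_results,
      schema = bundle$schema,
      gender_encoding = bundle$gender_encoding,
      folds = bundle$folds,
      seed = bundle$seed,
      config_hash = bundle$config_hash
    ),
    class = "sv_estimator"
  )
}
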