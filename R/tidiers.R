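#' @importFrom generics tidy glance augment
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an agreement report into a long metric table
#'
#' @param x an `sv_agreement`.
#' @param ... unused.
#' @return tibble with columns `metric`, `value`.
#' @export
tidy.sv_agreement <- function(x, ...) {
  metrics <- c("pearson_r", "p_value_r", "mae", "rmse", "nrmse", "bias",
               "sd_diff", "loa_low", "loa_high", "wilcoxon_p",
               "mean_reference", "sd_reference", "mean_predicted",
               "sd_predicted")
  tibble(metric = metrics,
         value = vapply(metrics, function(m) x[[m]], numeric(1)))
}

#' One-row summary of an agreement report
#'
#' @param x an `sv_agreement`.
#' @param ... unused.
#' @return one-row tibble.
#' @export
glance.sv_agreement <- function(x, ...) {
  tibble(n = x$n, pearson_r = x$pearson_r, p_value_r = x$p_value_r,
         mae = x$mae, rmse = x$rmse, nrmse = x$nrmse, bias = x$bias,
         loa_low = x$loa_low, loa_high = x$loa_high,
         wilcoxon_p = x$wilcoxon_p)
}

#' Cross-validation table of a trained estimator
#'
#' @param x an `sv_estimator`.
#' @param ... unused.
#' @return tibble with one row per grid point and its mean CV R^2.
#' @export
tidy.sv_estimator <- function(x, ...) {
  x$cv_results
}

#' One-row summary of a trained estimator
#'
#' @param x an `sv_estimator`.
#' @param ... unused.
#' @return one-row tibble with the selected hyperparameters and CV score.
#' @export
glance.sv_estimator <- function(x, ...) {
  tibble(
    n_estimators = x$selected$n_estimators,
    learning_rate = x$selected$learning_rate,
    max_depth = x$selected$max_depth,
    max_features = x$selected$max_features,
    min_samples_leaf = x$selected$min_samples_leaf,
    cv_r2 = x$cv_score,
    seed = x$seed
  )
}

#' One-row summary of a simulation run
#'
#' @param x an `sv_simulation`.
#' @param ... unused.
#' @return one-row tibble with convergence and cycle-volume diagnostics.
#' @export
glance.sv_simulation <- function(x, ...) {
  tibble(
    converged = x$converged, cycles_used = x$cycles_used, dt_s = x$dt_s,
    period_s = x$period_s,
    root_volume_ml = x$mass$root_volume_ml,
    terminal_volume_ml = sum(x$mass$terminal_volume_ml),
    storage_change_ml = x$mass$storage_change_ml,
    junction_imbalance_ml_s = x$junction_imbalance_ml_s
  )
}
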