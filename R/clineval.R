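PWV_REPEAT_COLS <- c("sbp_pwv", "dbp_pwv", "hr_pwv")
CATH_REPEAT_COLS <- c("sbp_cath", "dbp_cath", "hr_cath")

repeat_mean <- function(df, stem, id) {
  cols <- grep(paste0("^", stem, "_[0-9]+$"), names(df), value = TRUE)
  if (length(cols) == 0) abort(paste0("patient table lacks repeats for ", stem))
  m <- as.matrix(df[cols])
  n_avail <- rowSums(!is.na(m))
  if (any(n_avail == 0)) {
    abort(paste0("patient ", id[which(n_avail == 0)[1]],
                 ": no available repeat for ", stem))
  }
  list(mean = rowMeans(m, na.rm = TRUE), n = n_avail)
}

#' Average repeated clinical measurements per patient
#'
#' Arithmetic means over the available repeats of SBP, DBP and HR at each
#' setting (a single available repeat is tolerated and flagged), the mean of
#' the two PWV readings, cuff mean arterial pressure `MAP = DBP + PP/3` per
#' setting, and the thermodilution reference stroke volume
#' `SV = CO * 1000 / HR_cath` (CO in L/min).
#'
#' @param patients patient table, one row per patient, with columns `id`,
#'   `age_group`, `gender`, `height`, `weight`, repeats `sbp_pwv_1..3`,
#'   `dbp_pwv_1..3`, `hr_pwv_1..3`, `sbp_cath_1..3`, `dbp_cath_1..3`,
#'   `hr_cath_1..3`, readings `pwv_1`, `pwv_2`, and `co_thermo_lmin`.
#' @return tibble with per-setting means, `pp_*`, `map_*`, `cfpwv` and
#'   `sv_reference` (mL).
#' @export
average_repeats <- function(patients) {
  df <- as_tibble(patients)
  if (!"id" %in% names(df)) abort("patient table lacks `id`")
  out <- tibble(id = df$id)
  for (col in c("age_group", "gender", "height", "weight")) {
    if (col %in% names(df)) out[[col]] <- df[[col]]
  }
  singles <- 0L
  for (stem in c(PWV_REPEAT_COLS, CATH_REPEAT_COLS)) {
    r <- repeat_mean(df, stem, df$id)
    out[[stem]] <- r$mean
    singles <- singles + sum(r$n == 1)
  }
  if (singles > 0) {
    inform(paste0("average_repeats: ", singles,
                  " quantity(ies) averaged from a single repeat"))
  }
  pwv_cols <- grep("^pwv_[0-9]+$", names(df), value = TRUE)
  if (length(pwv_cols) == 0) abort("patient table lacks PWV readings (pwv_1, pwv_2)")
  pwvm <- as.matrix(df[pwv_cols])
  if (any(rowSums(!is.na(pwvm)) == 0)) abort("a patient has no PWV reading")
  if (any(pwvm <= 0, na.rm = TRUE)) abort("PWV readings must be > 0")
  out$cfpwv <- rowMeans(pwvm, na.rm = TRUE)
  out$pp_pwv <- out$sbp_pwv - out$dbp_pwv
  out$map_pwv <- out$dbp_pwv + out$pp_pwv / 3
  out$pp_cath <- out$sbp_cath - out$dbp_cath
  out$map_cath <- out$dbp_cath + out$pp_cath / 3
  if (!"co_thermo_lmin" %in% names(df)) abort("patient table lacks `co_thermo_lmin`")
  if (any(!is.finite(df$co_thermo_lmin)) || any(df$co_thermo_lmin <= 0)) {
    abort("`co_thermo_lmin` must be > 0")
  }
  out$sv_reference <- df$co_thermo_lmin * 1000 / out$hr_cath
  out
}

#' Hemodynamic-coherence filter
#'
#' A patient is excluded when the relative difference of MAP or of HR
#' between the PWV-assessment and catheterization settings exceeds the
#' threshold (default 25%). The relative difference is
#' `|x_pwv - x_cath| / x_cath` by default (the catheterization setting
#' anchors the reference stroke volume); `denominator = "mean"` uses the
#' symmetric mean instead.
#'
#' @param patients averaged patient table (see [average_repeats()]).
#' @param threshold exclusion threshold as a fraction (> 0; `Inf` keeps
#'   everyone).
#' @param denominator `"cath"` or `"mean"`.
#' @return a list with disjoint, exhaustive tibbles `kept` and `excluded`
#'   plus `diagnostics` (`id`, `rel_map`, `rel_hr`, `kept`).
#' @export
coherence_filter <- function(patients, threshold = 0.25,
                             denominator = c("cath", "mean")) {
  denominator <- match.arg(denominator)
  if (!is.numeric(threshold) || is.na(threshold) || threshold <= 0) {
    abort("`threshold` must be > 0")
  }
  need <- c("map_pwv", "map_cath", "hr_pwv", "hr_cath")
  miss <- setdiff(need, names(patients))
  if (length(miss) > 0) {
    abort(paste0("both settings required; missing: ", paste(miss, collapse = ", ")))
  }
  den_map <- if (denominator == "cath") patients$map_cath else
    (patients$map_pwv + patients$map_cath) / 2
  den_hr <- if (denominator == "cath") patients$hr_cath else
    (patients$hr_pwv + patients$hr_cath) / 2
  rel_map <- abs(patients$map_pwv - patients$map_cath) / den_map
  rel_hr <- abs(patients$hr_pwv - patients$hr_cath) / den_hr
  keep <- rel_map <= threshold & rel_hr <= threshold
  list(
    kept = patients[keep, , drop = FALSE],
    excluded = patients[!keep, , drop = FALSE],
    diagnostics = tibble(id = patients$id, rel_map = rel_map,
                         rel_hr = rel_hr, kept = keep)
  )
}

#' Agreement statistics between predicted and reference stroke volume
#'
#' Pearson correlation (p-value from the t distribution on n - 2 df), mean
#' absolute error, RMSE, normalized RMSE (RMSE over the reference range
#' `max - min`), Bland-Altman bias `mean(predicted - reference)` with limits
#' of agreement `bias +/- 1.96 SD(differences)`, a Wilcoxon signed-rank test
#' of the paired difference (exact distribution for n < 25, normal
#' approximation with continuity correction otherwise), and means +/- SD of
#' both series. With this sign convention an underestimating predictor
#' yields a negative bias.
#'
#' @param reference reference stroke volumes (mL), length >= 3.
#' @param predicted predicted stroke volumes (mL), same length.
#' @return an object of class `sv_agreement`.
#' @export
sv_agreement <- function(reference, predicted) {
  if (length(reference) != length(predicted)) {
    abort("`reference` and `predicted` must have equal length")
  }
  n <- length(reference)
  if (n < 3) abort("agreement requires at least 3 pairs")
  if (any(!is.finite(reference)) || any(!is.finite(predicted))) {
    abort("non-finite values in input series")
  }
  rng <- max(reference) - min(reference)
  if (rng == 0) abort("zero reference range: normalized RMSE undefined")
  d <- predicted - reference
  rmse <- sqrt(mean(d^2))
  ct <- suppressWarnings(cor.test(reference, predicted, method = "pearson"))
  if (all(d == 0)) {
    wp <- NA_real_
  } else {
    wp <- suppressWarnings(
      wilcox.test(predicted, reference, paired = TRUE,
                  exact = n < 25, correct = TRUE)$p.value
    )
  }
  # population SD (denominator n) throughout the descriptive report
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  sd_diff <- pop_sd(d)
  bias <- mean(d)
  structure(
    list(
      n = n,
      pearson_r = unname(ct$estimate),
      p_value_r = ct$p.value,
      mae = mean(abs(d)),
      rmse = rmse,
      nrmse = rmse / rng,
      bias = bias,
      sd_diff = sd_diff,
      loa_low = bias - 1.96 * sd_diff,
      loa_high = bias + 1.96 * sd_diff,
      wilcoxon_p = wp,
      mean_reference = mean(reference), sd_reference = pop_sd(reference),
      mean_predicted = mean(predicted), sd_predicted = pop_sd(predicted),
      reference = reference, predicted = predicted
    ),
    class = "sv_agreement"
  )
}

#' @export
print.sv_agreement <- function(x, ...) {
  cat("<sv_agreement> n =", x$n, "\n")
  cat(sprintf("  r = %.3f (p = %.3g), MAE = %.2f mL, RMSE = %.2f mL, nRMSE = %.1f%%\n",
              x$pearson_r, x$p_value_r, x$mae, x$rmse, 100 * x$nrmse))
  cat(sprintf("  bias = %.2f mL, LoA [%.2f, %.2f] mL, Wilcoxon p = %.3g\n",
              x$bias, x$loa_low, x$loa_high, x$wilcoxon_p))
  cat(sprintf("  reference %.1f +/- %.1f mL, predicted %.1f +/- %.1f mL\n",
              x$mean_reference, x$sd_reference, x$mean_predicted, x$sd_predicted))
  invisible(x)
}

#' Paired comparison of the two measurement settings
#'
#' For SBP, DBP, MAP and HR: paired t-test p-value (NaN when the two
#' settings are identical, by convention), mean and SD of the absolute
#' between-setting differences, and their range.
#'
#' @param patients averaged patient table (>= 3 rows).
#' @return tibble with one row per quantity.
#' @export
compare_settings <- function(patients) {
  if (nrow(patients) < 3) abort("paired comparison requires at least 3 patients")
  quantities <- list(
    sbp = c("sbp_pwv", "sbp_cath"), dbp = c("dbp_pwv", "dbp_cath"),
    map = c("map_pwv", "map_cath"), hr = c("hr_pwv", "hr_cath")
  )
  purrr::map_dfr(names(quantities), function(q) {
    a <- patients[[quantities[[q]][1]]]
    b <- patients[[quantities[[q]][2]]]
    # constant differences have zero variance: NaN for identical settings,
    # p = 0 for a constant non-zero offset (infinite t), documented convention
    pt <- if (sd(a - b) == 0) {
      if (all(a == b)) NaN else 0
    } else {
      suppressWarnings(t.test(a, b, paired = TRUE)$p.value)
    }
    ad <- abs(a - b)
    tibble(quantity = q, paired_t_p = pt,
           mean_abs_diff = mean(ad), sd_abs_diff = sd(ad),
           min_abs_diff = min(ad), max_abs_diff = max(ad))
  })
}

#' Welch's unequal-variance t-test between cohort and patient features
#'
#' Accounts for the very different sizes of the synthetic cohort and a
#' clinical cohort when comparing a feature distribution.
#'
#' @param cohort_feature numeric vector (synthetic cohort values).
#' @param patient_feature numeric vector (patient values).
#' @return one-row tibble `statistic`, `df`, `p_value`, `mean_cohort`,
#'   `mean_patients`.
#' @export
welch_cohort_test <- function(cohort_feature, patient_feature) {
  x <- cohort_feature[is.finite(cohort_feature)]
  y <- patient_feature[is.finite(patient_feature)]
  if (length(x) < 2 || length(y) < 2) abort("both series need >= 2 finite values")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    abort("zero variance in both series: Welch test undefined")
  }
  tt <- t.test(x, y, var.equal = FALSE)
  tibble(statistic = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value, mean_cohort = mean(x), mean_patients = mean(y))
}

#' Assemble estimator inputs from an averaged patient table
#'
#' Uses the PWV-assessment setting's pressures (the non-invasive protocol):
#' `sbp/dbp/pp/map = *_pwv`, the averaged cfPWV, and the demographic
#' columns, with `age` the stratum midpoint.
#'
#' @param patients averaged patient table (see [average_repeats()]).
#' @return tibble in the estimator feature schema.
#' @export
patient_features <- function(patients) {
  need <- c("age_group", "gender", "weight", "height", "sbp_pwv", "dbp_pwv",
            "pp_pwv", "map_pwv", "cfpwv")
  miss <- setdiff(need, names(patients))
  if (length(miss) > 0) {
    abort(paste0("averaged table lacks column(s): ", paste(miss, collapse = ", ")))
  }
  tibble(
    age = age_group_midpoint(patients$age_group),
    gender = patients$gender,
    weight = patients$weight, height = patients$height,
    sbp = patients$sbp_pwv, dbp = patients$dbp_pwv,
    pp = patients$pp_pwv, map = patients$map_pwv,
    cfpwv = patients$cfpwv
  )
}
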