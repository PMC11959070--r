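#' Configuration for synthetic clinical patient tables
#'
#' Controls the statistical structure of generated patient tables: cohort
#' size and age/gender composition (the default strata counts mirror a
#' catheterization cohort dominated by the >70 groups: 8 M and 8 F of >70
#' among 27), repeat-measurement noise, systematic between-setting
#' discrepancies (relative shifts of the catheterization values against the
#' PWV-assessment values), the fraction of patients with large (> 25%)
#' MAP/HR discrepancies, device noise on cfPWV, thermodilution noise and
#' the probability of a missing repeat.
#'
#' @param n_patients number of patients.
#' @param strata_weights length-12 non-negative weights over the strata in
#'   the order M/F within each age group (20-29 M, 20-29 F, ..., >70 F).
#' @param repeat_sd named vector: additive SD of repeat noise for `sbp`,
#'   `dbp` (mmHg) and `hr` (bpm).
#' @param shift_mean,shift_sd named vectors (`sbp`, `dbp`, `hr`): mean and
#'   SD of the relative between-setting shift (catheterization relative to
#'   PWV assessment).
#' @param large_discrepancy_fraction fraction of patients whose MAP and HR
#'   shifts are drawn uniformly in +/-\[0.28, 0.40\] (incoherent patients).
#' @param pwv_noise_sd additive SD (m/s) of each of the two PWV readings.
#' @param sv_noise_sd additive SD (mL) of the thermodilution reference.
#' @param missing_repeat_prob probability that each of repeats 2 and 3 is
#'   missing.
#' @param seed integer seed (required at generation time).
#' @return a list of class `clinical_sim_config`.
#' @export
clinical_sim_config <- function(n_patients = 27,
                                strata_weights = c(0, 1, 0, 1, 2, 0, 1, 2, 1, 3, 8, 8),
                                repeat_sd = c(sbp = 3, dbp = 2, hr = 2),
                                shift_mean = c(sbp = 0.03, dbp = 0.04, hr = -0.04),
                                shift_sd = c(sbp = 0.05, dbp = 0.05, hr = 0.05),
                                large_discrepancy_fraction = 0,
                                pwv_noise_sd = 0.5,
                                sv_noise_sd = 5,
                                missing_repeat_prob = 0.05,
                                seed = NULL) {
  if (n_patients < 1) abort("`n_patients` must be >= 1")
  if (length(strata_weights) != 12 || any(strata_weights < 0)) {
    abort("`strata_weights` must be 12 non-negative values")
  }
  if (sum(strata_weights) == 0) abort("`strata_weights` must not all be zero")
  for (v in list(repeat_sd, shift_sd)) {
    if (any(v < 0)) abort("noise SDs must be >= 0")
  }
  if (large_discrepancy_fraction < 0 || large_discrepancy_fraction > 1 ||
      missing_repeat_prob < 0 || missing_repeat_prob > 1) {
    abort("probabilities must lie in [0, 1]")
  }
  structure(
    list(n_patients = as.integer(n_patients), strata_weights = strata_weights,
         repeat_sd = repeat_sd, shift_mean = shift_mean, shift_sd = shift_sd,
         large_discrepancy_fraction = large_discrepancy_fraction,
         pwv_noise_sd = pwv_noise_sd, sv_noise_sd = sv_noise_sd,
         missing_repeat_prob = missing_repeat_prob, seed = seed),
    class = "clinical_sim_config"
  )
}

# strata in the weight order used by clinical_sim_config
strata_table <- function() {
  tibble(
    age_group = rep(AGE_GROUPS, each = 2),
    gender = rep(c("M", "F"), times = 6)
  )
}

#' Generate a synthetic clinical patient table
#'
#' Draws a ground-truth hemodynamic profile per patient (with
#' `source = "cohort"` the profile is pushed through the 1-D simulator so
#' BP, cfPWV and stroke volume are mutually consistent; `"parametric"`
#' skips the solver and synthesizes plausible values directly), then emits
#' noisy repeated cuff/HR measurements for the PWV-assessment and
#' catheterization settings with the configured between-setting shifts, two
#' noisy PWV readings, and a noisy thermodilution cardiac output. The
#' ground truth is returned separately for truth-known testing.
#'
#' @param config a [clinical_sim_config()].
#' @param source `"cohort"` (simulator-consistent, default) or
#'   `"parametric"`.
#' @param spec population spec for the ground-truth draws.
#' @param tree,blood,control simulator settings for `source = "cohort"`.
#' @param seed integer seed; overrides `config$seed`.
#' @return list with `patients` (the clinical-dialect table, one row per
#'   patient) and `truth` (`id`, `sv_true_ml` and the ground-truth
#'   features).
#' @export
generate_patient_table <- function(config = clinical_sim_config(),
                                   source = c("cohort", "parametric"),
                                   spec = population_spec(),
                                   tree = default_arterial_tree(),
                                   blood = blood_properties(),
                                   control = solver_control(),
                                   seed = NULL) {
  source <- match.arg(source)
  seed <- seed %||% config$seed
  if (is.null(seed)) abort("a seed is required (config$seed or `seed`)")
  set.seed(as.integer(seed))

  strata <- strata_table()
  idx <- sample(seq_len(12), config$n_patients, replace = TRUE,
                prob = config$strata_weights / sum(config$strata_weights))

  path_m <- if (source == "cohort") {
    tree_path_length(tree, "carotid", "femoral", units = "m")
  } else NA_real_

  make_truth <- function(pr) {
    if (source == "cohort") {
      rec <- simulate_record(pr, tree, blood, control, path_m)
      if (is.null(rec)) return(NULL)
      rec
    } else {
      # parametric stand-in: plausible physiology without the solver
      pp <- max(20, pr$sv_ml / (2.1 * pr$distensibility / 7.8 + 0.25))
      dbp <- max(35, pr$map_target - pp / 3)
      c0 <- sqrt(1 / (1050 * pr$distensibility * 1e-3 / MMHG_PA))
      tibble(
        age_group = pr$age_group, age = pr$age, gender = pr$gender,
        weight = pr$weight, height = pr$height,
        sbp = dbp + pp, dbp = dbp, pp = pp, map = pr$map_target,
        cfpwv = 1.8 * c0, sv = pr$sv_ml
      )
    }
  }

  truth_rows <- vector("list", config$n_patients)
  for (i in seq_len(config$n_patients)) {
    st <- strata[idx[i], ]
    rec <- NULL
    attempt <- 0
    while (is.null(rec) && attempt < 5) {
      # deterministic sub-seed per patient and attempt
      sub_seed <- (as.integer(seed) + 7919L * i + 104729L * attempt) %%
        .Machine$integer.max
      prof <- sample_profiles(spec, n_per_group = 1, seed = sub_seed)
      pr <- prof[prof$age_group == st$age_group & prof$gender == st$gender, ]
      rec <- make_truth(pr)
      attempt <- attempt + 1
    }
    if (is.null(rec)) {
      abort(paste0("patient ", i, ": no convergent hemodynamic profile in ",
                   attempt, " attempts"))
    }
    rec$id <- sprintf("P%02d", i)
    rec$hr <- pr$heart_rate
    truth_rows[[i]] <- rec
  }
  # restore the main RNG stream position after the sub-seeded draws
  set.seed(as.integer(seed) + 1L)
  truth <- dplyr::bind_rows(truth_rows)

  n <- nrow(truth)
  rs <- config$repeat_sd
  big <- stats::runif(n) < config$large_discrepancy_fraction
  shift_of <- function(q) {
    s <- rnorm(n, config$shift_mean[[q]], config$shift_sd[[q]])
    if (any(big) && q %in% c("sbp", "dbp", "hr")) {
      # magnitudes on the cath-relative scale the coherence filter uses
      mag <- stats::runif(sum(big), 0.28, 0.40)
      sgn <- sample(c(-1, 1), sum(big), replace = TRUE)
      s[big] <- ifelse(sgn > 0, 1 / (1 - mag) - 1, -mag)
    }
    # a shifted quantity must stay positive (shifts are multiplicative)
    pmax(s, -0.9)
  }
  sh_sbp <- shift_of("sbp"); sh_dbp <- shift_of("dbp"); sh_hr <- shift_of("hr")

  reps <- function(truth_val, sd) {
    m <- sapply(1:3, function(k) truth_val + rnorm(n, 0, sd))
    if (config$missing_repeat_prob > 0) {
      for (k in 2:3) {
        gone <- stats::runif(n) < config$missing_repeat_prob
        m[gone, k] <- NA_real_
      }
    }
    m
  }
  sbp_p <- reps(truth$sbp, rs[["sbp"]])
  dbp_p <- reps(truth$dbp, rs[["dbp"]])
  hr_p <- reps(truth$hr, rs[["hr"]])
  sbp_c <- reps(truth$sbp * (1 + sh_sbp), rs[["sbp"]])
  dbp_c <- reps(truth$dbp * (1 + sh_dbp), rs[["dbp"]])
  hr_cath_true <- truth$hr * (1 + sh_hr)
  hr_c <- reps(hr_cath_true, rs[["hr"]])

  pwv1 <- truth$cfpwv + rnorm(n, 0, config$pwv_noise_sd)
  pwv2 <- truth$cfpwv + rnorm(n, 0, config$pwv_noise_sd)
  co_thermo <- pmax(0.2, (truth$sv + rnorm(n, 0, config$sv_noise_sd)) *
                      hr_cath_true / 1000)

  patients <- tibble(
    id = truth$id, age_group = truth$age_group, gender = truth$gender,
    height = truth$height, weight = truth$weight,
    sbp_pwv_1 = sbp_p[, 1], sbp_pwv_2 = sbp_p[, 2], sbp_pwv_3 = sbp_p[, 3],
    dbp_pwv_1 = dbp_p[, 1], dbp_pwv_2 = dbp_p[, 2], dbp_pwv_3 = dbp_p[, 3],
    hr_pwv_1 = hr_p[, 1], hr_pwv_2 = hr_p[, 2], hr_pwv_3 = hr_p[, 3],
    pwv_1 = pwv1, pwv_2 = pwv2,
    sbp_cath_1 = sbp_c[, 1], sbp_cath_2 = sbp_c[, 2], sbp_cath_3 = sbp_c[, 3],
    dbp_cath_1 = dbp_c[, 1], dbp_cath_2 = dbp_c[, 2], dbp_cath_3 = dbp_c[, 3],
    hr_cath_1 = hr_c[, 1], hr_cath_2 = hr_c[, 2], hr_cath_3 = hr_c[, 3],
    co_thermo_lmin = co_thermo
  )
  list(
    patients = patients,
    truth = truth |> select("id", sv_true_ml = "sv", dplyr::everything())
  )
}

#' Write a synthetic patient table and its ground-truth sidecar
#'
#' @param tbl list from [generate_patient_table()].
#' @param path CSV path for the patient table; the ground truth goes to
#'   `<path base>_truth.csv`.
#' @return `path`, invisibly.
#' @export
write_patient_table <- function(tbl, path) {
  readr::write_csv(tbl$patients, path)
  truth_path <- sub("\\.csv$", "_truth.csv", path)
  if (identical(truth_path, path)) truth_path <- paste0(path, "_truth.csv")
  readr::write_csv(tbl$truth, truth_path)
  invisible(path)
}
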