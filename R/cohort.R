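#' Generate the synthetic training cohort
#'
#' For each subject profile: rescales the tree, builds the aortic inflow
#' wave from the subject's stroke volume, heart rate and ejection time,
#' solves the 1-D network, and extracts the nine estimator inputs — age,
#' gender, weight, height, brachial SBP/DBP/PP/MAP (from the simulated
#' left-brachial waveform; MAP is its time average) and carotid-femoral
#' pulse wave velocity (anatomical carotid-femoral path length over the
#' foot-to-foot delay of the converged cycle). The regression target
#' `sv` is the imposed inflow stroke volume, fixed before simulation.
#' Non-converged or failed simulations are dropped with a recorded count;
#' a stratum losing more than `max_drop_fraction` of its cases aborts.
#'
#' @param profiles tibble from [sample_profiles()].
#' @param tree an `arterial_tree`; defaults to the packaged reduced tree.
#' @param blood a `blood_properties`.
#' @param control a `solver_control`.
#' @param max_drop_fraction per-stratum failure fraction that aborts the run.
#' @param progress print a line every `progress` subjects (0 = quiet).
#' @return tibble with columns `age_group`, `age`, `gender`, `weight`,
#'   `height`, `sbp`, `dbp`, `pp`, `map`, `cfpwv`, `sv`; attribute
#'   `n_dropped` records discarded simulations.
#' @export
generate_cohort <- function(profiles, tree = default_arterial_tree(),
                            blood = blood_properties(),
                            control = solver_control(),
                            max_drop_fraction = 0.2, progress = 0) {
  path_m <- tree_path_length(tree, "carotid", "femoral", units = "m")
  n <- nrow(profiles)
  rows <- vector("list", n)
  ok <- logical(n)
  for (i in seq_len(n)) {
    pr <- profiles[i, ]
    rec <- tryCatch(
      simulate_record(pr, tree, blood, control, path_m),
      error = function(e) NULL
    )
    if (!is.null(rec)) {
      rows[[i]] <- rec
      ok[i] <- TRUE
    }
    if (progress > 0 && i %% progress == 0) {
      inform(paste0("cohort: ", i, "/", n, " simulated"))
    }
  }
  drop_by_stratum <- profiles |>
    mutate(ok = ok) |>
    group_by(.data$age_group, .data$gender) |>
    summarise(dropped = sum(!.data$ok), n = dplyr::n(), .groups = "drop")
  worst <- drop_by_stratum |> filter(.data$dropped / .data$n > max_drop_fraction)
  if (nrow(worst) > 0) {
    abort(paste0(
      "stratum ", worst$age_group[1], "/", worst$gender[1], " lost ",
      worst$dropped[1], "/", worst$n[1],
      " simulations (> ", 100 * max_drop_fraction, "%); check solver settings"
    ))
  }
  out <- dplyr::bind_rows(rows[ok])
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    inform(paste0("generate_cohort: dropped ", n_dropped,
                  " non-converged/failed simulation(s)"))
  }
  attr(out, "n_dropped") <- n_dropped
  attr(out, "seed") <- attr(profiles, "seed")
  attr(out, "n_per_group") <- attr(profiles, "n_per_group")
  out
}

simulate_record <- function(pr, tree, blood, control, path_m) {
  st <- scale_tree(tree, pr)
  inflow <- inflow_wave(pr$sv_ml, pr$heart_rate, pr$ejection_time_s)
  sim <- simulate_pulse(st, inflow, blood, control)
  if (!sim$converged) return(NULL)
  wf <- sim$waveforms
  brach <- wf[wf$site == "left_brachial", ]
  bp <- bp_features(brach)
  car <- wf[wf$site == "carotid", ]
  fem <- wf[wf$site == "femoral", ]
  f_car <- pulse_foot(car, period_s = sim$period_s)
  f_fem <- pulse_foot(fem, period_s = sim$period_s)
  dtt <- (f_fem - f_car) %% sim$period_s
  if (dtt <= 0 || dtt >= sim$period_s) return(NULL)
  # scaled tree path (lengths scale with the subject)
  pwv <- cfpwv(path_m * pr$length_scale, dtt)
  tibble(
    age_group = pr$age_group, age = pr$age, gender = pr$gender,
    weight = pr$weight, height = pr$height,
    sbp = bp$sbp, dbp = bp$dbp, pp = bp$pp, map = bp$map,
    cfpwv = pwv, sv = pr$sv_ml
  )
}

#' Write a cohort dataset with a metadata sidecar
#'
#' Writes `age,gender,weight,height,sbp,dbp,pp,map,cfpwv,sv` CSV (plus
#' `age_group`) and a `<path>.meta.json` sidecar recording the seed, the
#' per-stratum size, the number of dropped simulations and a content hash.
#'
#' @param cohort tibble from [generate_cohort()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path)
  meta <- list(
    seed = attr(cohort, "seed"),
    n_per_group = attr(cohort, "n_per_group"),
    n_rows = nrow(cohort),
    n_dropped = attr(cohort, "n_dropped") %||% 0L,
    hash = rlang::hash(as.data.frame(cohort))
  )
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a cohort dataset written by [write_cohort()]
#'
#' @param path CSV path.
#' @return tibble.
#' @export
read_cohort <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
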