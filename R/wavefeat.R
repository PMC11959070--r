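#' Blood-pressure landmarks of a pressure waveform
#'
#' Systolic pressure is the maximum, diastolic the minimum, pulse pressure
#' their difference and mean pressure the time average, all over the final
#' full cycle if `period_s` is supplied, otherwise over the whole series.
#'
#' @param wave data frame with uniformly sampled `time_s` and
#'   `pressure_mmhg` columns.
#' @param period_s optional cycle length (s) used to restrict to the final
#'   full cycle.
#' @return one-row tibble `sbp`, `dbp`, `pp`, `map` (mmHg).
#' @export
bp_features <- function(wave, period_s = NULL) {
  check_uniform(wave$time_s)
  p <- wave$pressure_mmhg
  t <- wave$time_s
  if (!is.null(period_s)) {
    keep <- t > max(t) - period_s + 1e-12
    if (sum(keep) < 3) abort("waveform shorter than one cycle")
    p <- p[keep]
  }
  if (any(!is.finite(p))) abort("non-finite pressure values")
  tibble(sbp = max(p), dbp = min(p), pp = max(p) - min(p), map = mean(p))
}

check_uniform <- function(t) {
  if (length(t) < 3) abort("waveform needs at least 3 samples")
  dt <- diff(t)
  if (max(dt) - min(dt) > 1e-6 * stats::median(dt)) {
    abort("waveform sampling must be uniform")
  }
  invisible(stats::median(dt))
}

# least-squares slope of y on x over a window (closed form)
ls_slope <- function(x, y) {
  xm <- x - mean(x)
  sum(xm * (y - mean(y))) / sum(xm^2)
}

#' Waveform foot by the intersecting-tangent method
#'
#' The foot of a pressure upstroke is located at the intersection of (a) the
#' tangent at the point of maximum upstroke slope (`dP/dt` max on the rising
#' limb between the cycle's diastolic minimum and its systolic maximum) and
#' (b) the horizontal line through the diastolic minimum. The slope is
#' estimated by a local least-squares fit over `window` samples, which makes
#' the construction exact on piecewise-linear upstrokes and robust to noise.
#'
#' @param wave data frame with uniformly sampled `time_s`, `pressure_mmhg`
#'   covering one cycle.
#' @param period_s optional cycle length; when given, a cycle whose minimum
#'   follows its maximum (periodic steady-state recordings) is rotated so
#'   the rising limb is contiguous, and the returned foot time is reported
#'   modulo the period within the original time window.
#' @param window odd number of samples for the local slope fit.
#' @return foot time (s), scalar.
#' @export
pulse_foot <- function(wave, period_s = NULL, window = 5) {
  dt <- check_uniform(wave$time_s)
  t <- wave$time_s
  p <- wave$pressure_mmhg
  n <- length(p)
  if (window < 3) abort("`window` must be >= 3")
  i_min <- which.min(p)
  i_max <- which.max(p)
  rotated <- 0
  if (i_max <= i_min) {
    if (is.null(period_s)) {
      abort("no upstroke after the diastolic minimum (supply `period_s` for periodic cycles)")
    }
    # rotate so the cycle starts at the diastolic minimum
    rot <- c(i_min:n, seq_len(i_min - 1))
    rotated <- i_min - 1
    p <- p[rot]
    i_min <- 1
    i_max <- which.max(p)
    if (i_max <= i_min) abort("no upstroke after the diastolic minimum")
  }
  # windowed slopes on the rising limb only (excludes dicrotic region)
  half <- floor(window / 2)
  idx <- seq(max(i_min, 1 + half), min(i_max, n - half))
  if (length(idx) == 0) abort("rising limb too short for the slope window")
  slopes <- vapply(idx, function(i) {
    w <- (i - half):(i + half)
    ls_slope(t[w], p[w])
  }, numeric(1))
  k <- which.max(slopes)
  s <- slopes[k]
  if (!is.finite(s) || s <= 0) abort("non-positive maximum upstroke slope")
  i_star <- idx[k]
  p_min <- min(p[i_min:i_max])
  foot_rel <- t[i_star] - (p[i_star] - p_min) / s
  if (rotated > 0) {
    # map back onto the original (unrotated) time axis, modulo the period
    foot_rel <- foot_rel + rotated * dt
    t_end <- t[1] + n * dt
    if (foot_rel >= t_end) foot_rel <- foot_rel - period_s
  }
  foot_rel
}

#' Foot-to-foot pulse transit time between two waveforms
#'
#' Segments both recordings into cardiac cycles of length `period_s`,
#' detects the foot of each cycle at both sites by the intersecting-tangent
#' method, and averages the per-cycle delay `foot(distal) - foot(proximal)`.
#' Delays are wrapped into `(0, period)`; cycles whose delay cannot be
#' resolved are flagged and excluded from the mean.
#'
#' @param proximal,distal data frames with uniformly sampled `time_s`,
#'   `pressure_mmhg` on a common grid.
#' @param period_s cycle length (s).
#' @param min_cycles minimum number of complete cycles required (10 for
#'   clinical-grade transit times; simulated single converged cycles may use
#'   1).
#' @param window slope window for [pulse_foot()].
#' @return an object of class `sv_transit`: tibble `cycles` (`cycle`,
#'   `foot_proximal_s`, `foot_distal_s`, `delta_t_s`, `valid`),
#'   `mean_delta_t_s`, `n_cycles_used`.
#' @export
transit_time <- function(proximal, distal, period_s, min_cycles = 10,
                         window = 5) {
  check_uniform(proximal$time_s)
  check_uniform(distal$time_s)
  if (nrow(proximal) != nrow(distal) ||
      max(abs(proximal$time_s - distal$time_s)) > 1e-9) {
    abort("proximal and distal waveforms must share the same sampling grid")
  }
  t <- proximal$time_s
  t0 <- t[1]
  n_cyc <- floor((t[length(t)] - t0 + diff(t)[1] / 2) / period_s)
  if (n_cyc < min_cycles) {
    abort(paste0("need at least ", min_cycles, " complete cycles, found ", n_cyc))
  }
  rows <- purrr::map_dfr(seq_len(n_cyc), function(k) {
    lo <- t0 + (k - 1) * period_s
    hi <- lo + period_s
    sel <- t >= lo - 1e-12 & t < hi - 1e-12
    fp <- tryCatch(pulse_foot(proximal[sel, ], period_s, window), error = function(e) NA_real_)
    fd <- tryCatch(pulse_foot(distal[sel, ], period_s, window), error = function(e) NA_real_)
    d <- fd - fp
    if (is.finite(d)) d <- d %% period_s
    valid <- is.finite(d) && d > 0 && d < period_s
    tibble(cycle = k, foot_proximal_s = fp, foot_distal_s = fd,
           delta_t_s = d, valid = valid)
  })
  used <- rows[rows$valid, ]
  if (nrow(used) == 0) {
    abort("no cycle yielded a resolvable transit time (zero or undetectable delay)")
  }
  structure(
    list(cycles = rows, mean_delta_t_s = mean(used$delta_t_s),
         n_cycles_used = nrow(used)),
    class = "sv_transit"
  )
}

#' @export
print.sv_transit <- function(x, ...) {
  cat("<sv_transit> mean delta-t", signif(x$mean_delta_t_s * 1e3, 4), "ms over",
      x$n_cycles_used, "cycles\n")
  invisible(x)
}

#' Pulse wave velocity from path length and transit time
#'
#' `PWV = L / delta_t`.
#'
#' @param path_length_m transit path length (m), > 0.
#' @param delta_t_s foot-to-foot transit time (s), > 0.
#' @return velocity (m/s), vectorized.
#' @export
cfpwv <- function(path_length_m, delta_t_s) {
  if (any(!is.finite(path_length_m)) || any(path_length_m <= 0)) {
    abort("`path_length_m` must be > 0")
  }
  if (any(!is.finite(delta_t_s)) || any(delta_t_s <= 0)) {
    abort("`delta_t_s` must be > 0")
  }
  path_length_m / delta_t_s
}

#' Corrected carotid-femoral path length from a surface measurement
#'
#' Clinically the straight surface distance between the carotid and femoral
#' sites overestimates the arterial path; it is multiplied by a correction
#' factor, conventionally 0.8.
#'
#' @param surface_distance_m measured surface distance (m), > 0.
#' @param correction dimensionless factor.
#' @return corrected path length (m), vectorized.
#' @export
clinical_path_length <- function(surface_distance_m, correction = 0.8) {
  if (any(!is.finite(surface_distance_m)) || any(surface_distance_m <= 0)) {
    abort("`surface_distance_m` must be > 0")
  }
  surface_distance_m * correction
}
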