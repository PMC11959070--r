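#' Synthesize an aortic inflow wave
#'
#' Builds the prescribed root boundary flow: a systolic ejection wave of
#' duration `et_s` whose integral over one cardiac period equals the stroke
#' volume, followed by zero flow in diastole (no regurgitation). The default
#' `half_sine` shape has peak flow `sv * pi / (2 * et)`; `triangular` is a
#' symmetric ramp; `constant` holds `sv * hr / 60` over the whole period and
#' is intended for steady-state checks.
#'
#' @param sv_ml stroke volume (mL), > 0.
#' @param hr_bpm heart rate (bpm), in \[20, 220\].
#' @param et_s ejection time (s), 0 < et < period (ignored for `constant`).
#' @param shape waveform family.
#' @param n_samples number of stored samples over one period.
#' @return an object of class `inflow_wave` with fields `sv_ml`, `hr_bpm`,
#'   `et_s`, `period_s`, `shape`, `fun` (vectorized flow in mL/s as a
#'   function of time in s) and `samples` (tibble `time_s`, `flow_ml_s`).
#' @export
#' @examples
#' w <- inflow_wave(73.3, 75, 0.23)
#' # period integral recovers the stroke volume
#' sum(w$samples$flow_ml_s) * diff(w$samples$time_s[1:2])
inflow_wave <- function(sv_ml, hr_bpm, et_s = NULL,
                        shape = c("half_sine", "triangular", "constant"),
                        n_samples = 2048) {
  shape <- match.arg(shape)
  if (!is.finite(sv_ml) || sv_ml <= 0) abort("`sv_ml` must be > 0")
  if (!is.finite(hr_bpm) || hr_bpm < 20 || hr_bpm > 220) {
    abort("`hr_bpm` must lie in [20, 220]")
  }
  period <- 60 / hr_bpm
  if (shape == "constant") {
    et_s <- period
  } else {
    if (is.null(et_s)) abort("`et_s` is required for pulsatile shapes")
    if (!is.finite(et_s) || et_s <= 0) abort("`et_s` must be > 0")
    if (et_s >= period) {
      abort(paste0("ejection time (", et_s, " s) must be shorter than the ",
                   "cardiac period (", signif(period, 4), " s)"))
    }
  }
  fun <- switch(shape,
    half_sine = function(t) {
      tt <- t %% period
      ifelse(tt < et_s, sv_ml * pi / (2 * et_s) * sin(pi * tt / et_s), 0)
    },
    triangular = function(t) {
      tt <- t %% period
      peak <- 2 * sv_ml / et_s
      ifelse(tt < et_s, peak * (1 - abs(2 * tt / et_s - 1)), 0)
    },
    constant = function(t) rep(sv_ml / period, length(t))
  )
  ts <- seq(0, period, length.out = n_samples + 1)[-(n_samples + 1)]
  structure(
    list(sv_ml = sv_ml, hr_bpm = hr_bpm, et_s = et_s, period_s = period,
         shape = shape, fun = fun,
         samples = tibble(time_s = ts, flow_ml_s = fun(ts))),
    class = "inflow_wave"
  )
}

#' @export
print.inflow_wave <- function(x, ...) {
  cat("<inflow_wave>", x$shape, "| SV", signif(x$sv_ml, 4), "mL | HR",
      x$hr_bpm, "bpm | ET", signif(x$et_s, 4), "s\n")
  invisible(x)
}
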