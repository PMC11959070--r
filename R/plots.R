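#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_hline
#'   geom_abline facet_wrap labs theme_minimal
#' @export
ggplot2::autoplot

#' Plot simulated pressure and flow waveforms
#'
#' One panel per named site, pressure on the left axis; set
#' `what = "flow"` for flow waveforms.
#'
#' @param sim an `sv_simulation`.
#' @param what `"pressure"` or `"flow"`.
#' @return a ggplot object.
#' @export
plot_waveforms <- function(sim, what = c("pressure", "flow")) {
  what <- match.arg(what)
  wf <- sim$waveforms
  if (what == "pressure") {
    ggplot(wf, aes(x = .data$time_s, y = .data$pressure_mmhg)) +
      geom_line(colour = "#8B0000") +
      facet_wrap(~site, scales = "free_y") +
      labs(x = "time (s)", y = "pressure (mmHg)") +
      theme_minimal()
  } else {
    ggplot(wf, aes(x = .data$time_s, y = .data$flow_ml_s)) +
      geom_line(colour = "#00468B") +
      facet_wrap(~site, scales = "free_y") +
      labs(x = "time (s)", y = "flow (mL/s)") +
      theme_minimal()
  }
}

#' @export
autoplot.sv_simulation <- function(object, ...) plot_waveforms(object, ...)

#' Bland-Altman and scatter views of an agreement report
#'
#' `type = "bland_altman"` plots the paired differences against the paired
#' means with the bias and limits of agreement; `type = "scatter"` plots
#' predicted against reference with the identity line.
#'
#' @param object an `sv_agreement`.
#' @param type plot type.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.sv_agreement <- function(object, type = c("bland_altman", "scatter"),
                                  ...) {
  type <- match.arg(type)
  df <- tibble(
    reference = object$reference, predicted = object$predicted,
    mean_pair = (object$reference + object$predicted) / 2,
    difference = object$predicted - object$reference
  )
  if (type == "bland_altman") {
    ggplot(df, aes(x = .data$mean_pair, y = .data$difference)) +
      geom_point() +
      geom_hline(yintercept = object$bias, linetype = "dashed") +
      geom_hline(yintercept = object$loa_low, linetype = "dotted") +
      geom_hline(yintercept = object$loa_high, linetype = "dotted") +
      labs(x = "mean of predicted and reference SV (mL)",
           y = "predicted - reference SV (mL)") +
      theme_minimal()
  } else {
    ggplot(df, aes(x = .data$reference, y = .data$predicted)) +
      geom_point() +
      geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
      labs(x = "reference SV (mL)", y = "predicted SV (mL)") +
      theme_minimal()
  }
}

#' @rdname autoplot.sv_agreement
#' @param reference,predicted stroke-volume series (mL), used when calling
#'   without a prebuilt agreement object.
#' @export
plot_bland_altman <- function(reference, predicted) {
  autoplot(sv_agreement(reference, predicted), type = "bland_altman")
}
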