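#' Logarithmic-amplifier transfer model
#'
#' The photomultiplier current is converted to voltage by a logarithmic
#' amplifier; the decade-log model used throughout is
#' `V = gain * log10(I / i_ref) + v_offset`, so reconstruction of the
#' current from the recorded voltage is `I = i_ref * 10^((V - v_offset) / gain)`.
#'
#' @param gain volts per decade of current, strictly positive. Default 1.
#' @param v_offset output voltage at the reference current, in volts.
#'   Default 0.
#' @param i_ref reference current (sets the unit of the reconstructed
#'   current), strictly positive. Default 1.
#' @return A `log_amp_model` object.
#' @export
log_amp_model <- function(gain = 1, v_offset = 0, i_ref = 1) {
  if (!is.finite(gain) || gain <= 0) {
    stop("log_amp_model: gain must be a positive finite number", call. = FALSE)
  }
  if (!is.finite(i_ref) || i_ref <= 0) {
    stop("log_amp_model: i_ref must be a positive finite number",
         call. = FALSE)
  }
  if (!is.finite(v_offset)) {
    stop("log_amp_model: v_offset must be finite", call. = FALSE)
  }
  structure(list(gain = gain, v_offset = v_offset, i_ref = i_ref),
            class = "log_amp_model")
}

#' Uniformly sampled voltage trace
#'
#' The raw voltage-time response curve recorded from the log amplifier.
#' Sampling must be uniform within 1 ppm of the mean interval.
#'
#' @param times strictly increasing sample times in seconds, at least 2.
#' @param voltages finite voltages in volts, same length as `times`.
#' @return A `voltage_trace` object with fields `times`, `voltages`, `dt`.
#' @export
voltage_trace <- function(times, voltages) {
  if (length(times) < 2 || length(times) != length(voltages)) {
    stop("voltage_trace: need >= 2 samples with matching lengths",
         call. = FALSE)
  }
  if (anyNA(times) || anyNA(voltages) || any(!is.finite(voltages))) {
    stop("voltage_trace: non-finite sample encountered", call. = FALSE)
  }
  dt <- diff(times)
  if (any(dt <= 0)) {
    stop("voltage_trace: times must be strictly increasing", call. = FALSE)
  }
  mdt <- mean(dt)
  if (max(abs(dt - mdt)) > 1e-6 * mdt) {
    stop("voltage_trace: sampling not uniform within 1 ppm", call. = FALSE)
  }
  structure(list(times = as.numeric(times), voltages = as.numeric(voltages),
                 dt = mdt),
            class = "voltage_trace")
}

#' Reconstruct the current trace from the log-amplifier voltage
#'
#' Applies the inverse-logarithmic transformation pointwise:
#' `I(t) = i_ref * 10^((V(t) - v_offset) / gain)`. The sample times are
#' preserved; the reconstructed currents are strictly positive (the range of
#' the inverse-log map).
#'
#' @param trace a [voltage_trace].
#' @param model a [log_amp_model].
#' @return A `current_trace` object with fields `times`, `currents`, `dt`.
#' @examples
#' tr <- voltage_trace(seq(0, 1, by = 0.1), rep(3, 11))
#' invert_log_amp(tr, log_amp_model())$currents[1]  # 1000
#' @export
invert_log_amp <- function(trace, model) {
  if (!inherits(trace, "voltage_trace")) {
    stop("invert_log_amp: trace must be a voltage_trace", call. = FALSE)
  }
  if (!inherits(model, "log_amp_model")) {
    stop("invert_log_amp: model must be a log_amp_model", call. = FALSE)
  }
  currents <- model$i_ref * 10^((trace$voltages - model$v_offset) / model$gain)
  structure(list(times = trace$times, currents = currents, dt = trace$dt),
            class = "current_trace")
}

#' Forward log-amplifier transform of a current trace
#'
#' Maps a strictly positive current trace to the voltage the amplifier would
#' output; the exact inverse of [invert_log_amp()]. Used by the synthetic
#' trace generator and by round-trip checks.
#'
#' @param trace a `current_trace` (or list with `times` and `currents`).
#' @param model a [log_amp_model].
#' @return A [voltage_trace].
#' @export
forward_log_amp <- function(trace, model) {
  if (!inherits(model, "log_amp_model")) {
    stop("forward_log_amp: model must be a log_amp_model", call. = FALSE)
  }
  if (any(trace$currents <= 0)) {
    stop("forward_log_amp: currents must be strictly positive", call. = FALSE)
  }
  voltage_trace(trace$times,
                model$gain * log10(trace$currents / model$i_ref) +
                  model$v_offset)
}

#' Locate the electrochemical reaction onset in a voltage trace
#'
#' Baseline statistics (mean and SD) are computed over the first
#' `baseline_len` seconds; the onset candidate is the first sample exceeding
#' `mu + k * sigma`. Because a finite rise can cross that threshold a few
#' samples late, the estimate is anchored to the rising edge: it walks back
#' over any immediately preceding samples still above `mu + sigma` and
#' returns the first sample of that rising run. An explicit
#' `t_onset_override` bypasses detection entirely (for scripted experiments
#' with a known excitation time).
#'
#' @param trace a [voltage_trace] spanning at least `baseline_len + 0.4` s.
#' @param k noise multiplier for the crossing threshold. Default 5.
#' @param baseline_len seconds of leading baseline used for the statistics.
#'   Default 0.4.
#' @param t_onset_override if supplied, returned as-is.
#' @return Onset time in seconds.
#' @export
detect_onset <- function(trace, k = 5, baseline_len = 0.4,
                         t_onset_override = NULL) {
  if (!is.null(t_onset_override)) return(as.numeric(t_onset_override))
  if (!inherits(trace, "voltage_trace")) {
    stop("detect_onset: trace must be a voltage_trace", call. = FALSE)
  }
  span <- trace$times[length(trace$times)] - trace$times[1]
  if (span < baseline_len + 0.4) {
    stop("detect_onset: trace shorter than baseline_len + 0.4 s",
         call. = FALSE)
  }
  base <- trace$voltages[trace$times < trace$times[1] + baseline_len]
  if (length(base) < 2) {
    stop("detect_onset: too few baseline samples", call. = FALSE)
  }
  mu <- mean(base)
  sigma <- stats::sd(base)
  i <- which(trace$voltages > mu + k * sigma)[1]
  if (is.na(i)) {
    stop("detect_onset: no sample exceeds the baseline threshold (no onset)",
         call. = FALSE)
  }
  while (i > 1 && trace$voltages[i - 1] > mu + sigma) i <- i - 1
  trace$times[i]
}

#' Adjacent integration windows around the reaction onset
#'
#' The background window covers the `window_len` seconds immediately before
#' onset and the target window the `window_len` seconds immediately after;
#' both are half-open `[t0, t0 + window_len)`. The 0.4-s default is the
#' window length that keeps the charge integral linear in the luminescence.
#'
#' @param t_onset reaction onset time, seconds.
#' @param window_len window length in seconds, positive. Default 0.4.
#' @return An `integration_windows` object with `noise_window` and
#'   `target_window`, each `c(start, end)`.
#' @export
integration_windows <- function(t_onset, window_len = 0.4) {
  if (!is.finite(window_len) || window_len <= 0) {
    stop("integration_windows: window_len must be positive", call. = FALSE)
  }
  structure(
    list(t_onset = t_onset, window_len = window_len,
         noise_window = c(t_onset - window_len, t_onset),
         target_window = c(t_onset, t_onset + window_len)),
    class = "integration_windows"
  )
}

#' Trapezoidal integral of a current trace over a time window
#'
#' Integrates the (reconstructed) current over the half-open window
#' `[window[1], window[2])` by the trapezoid rule, with the window endpoints
#' obtained by linear interpolation when they fall between samples. Exact
#' for constant and linear currents.
#'
#' @param trace a `current_trace` (fields `times`, `currents`).
#' @param window numeric `c(start, end)`, `start < end`, inside the trace
#'   time span.
#' @return The integral (charge, in units of current times seconds).
#' @export
window_integral <- function(trace, window) {
  if (length(window) != 2 || anyNA(window) || window[1] >= window[2]) {
    stop("window_integral: window must be c(start, end) with start < end",
         call. = FALSE)
  }
  tt <- trace$times
  if (window[1] < tt[1] || window[2] > tt[length(tt)]) {
    stop("window_integral: window outside the trace time span", call. = FALSE)
  }
  inside <- tt > window[1] & tt < window[2]
  xs <- c(window[1], tt[inside], window[2])
  ys <- c(stats::approx(tt, trace$currents, xout = window[1])$y,
          trace$currents[inside],
          stats::approx(tt, trace$currents, xout = window[2])$y)
  sum(diff(xs) * (ys[-1] + ys[-length(ys)]) / 2)
}

#' Background-corrected photon charge
#'
#' The luminescence charge is the target-window integral minus the
#' background (noise) window integral: `Q_photon = S_target - S_noise`.
#' Because the background is stationary over the reaction, the subtraction
#' cancels it exactly. Negative results (possible under noise fluctuation
#' when the true signal is near zero) are returned as-is with
#' `negative = TRUE` in the quality flags, never clamped.
#'
#' @param s_target integral over the target window (signal plus background).
#' @param s_noise integral over the background window.
#' @return A `photon_charge` object with `s_target`, `s_noise`, `q_photon`
#'   and a `flags` list.
#' @export
photon_charge <- function(s_target, s_noise) {
  if (!is.finite(s_target) || !is.finite(s_noise)) {
    stop("photon_charge: inputs must be finite", call. = FALSE)
  }
  q <- s_target - s_noise
  structure(
    list(s_target = s_target, s_noise = s_noise, q_photon = q,
         flags = list(negative = q < 0)),
    class = "photon_charge"
  )
}

#' Full voltage-trace processing chain
#'
#' Composition of the signal-processing stages: reconstruct the current by
#' [invert_log_amp()], locate the onset by [detect_onset()] (or the
#' override), form the adjacent 0.4-s windows, integrate each with
#' [window_integral()], and subtract via [photon_charge()]. All
#' intermediates are attached for audit.
#'
#' By default the charge is integrated on the reconstructed current (charge
#' semantics); `integrate = "voltage"` integrates the raw voltage instead,
#' for comparison.
#'
#' @param trace a [voltage_trace].
#' @param model a [log_amp_model].
#' @param k,baseline_len,t_onset_override onset options, see
#'   [detect_onset()].
#' @param window_len integration window length, seconds. Default 0.4.
#' @param integrate `"current"` (default) or `"voltage"`.
#' @return A `photon_charge` object, with the additional fields `t_onset`,
#'   `windows`, `current_trace` and `params`.
#' @export
process_trace <- function(trace, model = log_amp_model(), k = 5,
                          baseline_len = 0.4, t_onset_override = NULL,
                          window_len = 0.4,
                          integrate = c("current", "voltage")) {
  integrate <- match.arg(integrate)
  ct <- invert_log_amp(trace, model)
  t_onset <- detect_onset(trace, k = k, baseline_len = baseline_len,
                          t_onset_override = t_onset_override)
  w <- integration_windows(t_onset, window_len)
  tt <- trace$times
  if (w$noise_window[1] < tt[1] || w$target_window[2] > tt[length(tt)]) {
    stop("process_trace: integration windows fall outside the trace span",
         call. = FALSE)
  }
  itrace <- if (integrate == "current") ct else {
    list(times = trace$times, currents = trace$voltages)
  }
  s_noise <- window_integral(itrace, w$noise_window)
  s_target <- window_integral(itrace, w$target_window)
  out <- photon_charge(s_target, s_noise)
  out$t_onset <- t_onset
  out$windows <- w
  out$current_trace <- ct
  out$params <- list(model = unclass(model), k = k,
                     baseline_len = baseline_len, window_len = window_len,
                     integrate = integrate,
                     onset_overridden = !is.null(t_onset_override))
  out
}
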