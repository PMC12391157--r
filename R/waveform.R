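#' Periodic flow waveform for one cardiac cycle
#'
#' @param times sample times in s, uniformly spaced within `[0, period)`.
#' @param flows signed flow in cm^3/s (forward positive).
#' @param heart_rate beats/min; the period is `60 / heart_rate` s. If omitted
#'   it is inferred from the sample spacing (`period = n * dt`).
#' @return An object of class `flow_waveform` with elements `times`, `flows`,
#'   `period` (s) and `heart_rate` (beats/min).
#' @export
flow_waveform <- function(times, flows, heart_rate = NULL) {
  times <- as.numeric(times); flows <- as.numeric(flows)
  if (length(times) != length(flows)) stop("times/flows length mismatch")
  if (length(times) < 2L) stop("need at least 2 samples")
  dt <- diff(times)
  if (any(dt <= 0)) stop("times must be strictly increasing")
  if (diff(range(dt)) > 1e-9 * mean(dt)) stop("times must be uniformly spaced")
  if (!all(is.finite(flows))) stop("flows must be finite")
  period <- if (is.null(heart_rate)) length(times) * mean(dt) else 60 / heart_rate
  if (times[length(times)] >= period + 1e-12)
    stop("times must lie within one period [0, period)")
  structure(list(times = times, flows = flows, period = period,
                 heart_rate = 60 / period),
            class = "flow_waveform")
}

#' @export
print.flow_waveform <- function(x, ...) {
  cat(sprintf(paste0("<flow_waveform> %d samples, period %.3f s ",
                     "(HR %.1f bpm), flow range [%.1f, %.1f] cm^3/s\n"),
              length(x$times), x$period, x$heart_rate,
              min(x$flows), max(x$flows)))
  invisible(x)
}

#' @export
plot.flow_waveform <- function(x, ...) {
  plot(x$times, x$flows, type = "l", xlab = "time (s)",
       ylab = expression(flow ~ (cm^3 / s)), ...)
  abline(h = 0, lty = 3)
  invisible(x)
}

# Periodic trapezoidal integral of f over one cycle: the closure sample at
# t = period (equal to the first sample) is appended internally. With uniform
# sampling this equals mean(f) * period.
periodic_integral <- function(wf, f = wf$flows) {
  dt <- wf$period / length(wf$times)
  sum(f) * dt
}

#' Specification of a synthetic biphasic flow waveform
#'
#' The default shape is two raised-cosine lobes: a systolic forward lobe
#' integrating to `forward_volume` and a diastolic reverse lobe integrating
#' to `regurgitant_fraction * forward_volume`, emulating the pulmonary
#' regurgitation typical of repaired tetralogy of Fallot (cohort-scale
#' default RF 0.40).
#'
#' @param heart_rate beats/min (> 0).
#' @param forward_volume forward stroke volume in mL/beat (> 0).
#' @param regurgitant_fraction reverse/forward volume ratio in `[0, 1)`.
#' @param n_samples samples per cycle (>= 16).
#' @param systolic_fraction fraction of the cycle occupied by the forward
#'   lobe.
#' @param shape `"biphasic"` (raised-cosine lobes) or `"table"` (use
#'   `times`/`flows` as given).
#' @param times,flows waveform table for `shape = "table"`.
#' @return An object of class `waveform_spec`.
#' @export
waveform_spec <- function(heart_rate = 75, forward_volume = 153.3,
                          regurgitant_fraction = 0.40, n_samples = 200L,
                          systolic_fraction = 0.4,
                          shape = c("biphasic", "table"),
                          times = NULL, flows = NULL) {
  shape <- match.arg(shape)
  if (heart_rate <= 0) stop("heart_rate must be positive")
  if (forward_volume <= 0) stop("forward_volume must be positive")
  if (regurgitant_fraction < 0 || regurgitant_fraction >= 1)
    stop("regurgitant_fraction must be in [0, 1)")
  if (n_samples < 16L) stop("n_samples must be >= 16")
  if (systolic_fraction <= 0 || systolic_fraction >= 1)
    stop("systolic_fraction must be in (0, 1)")
  structure(list(heart_rate = heart_rate, forward_volume = forward_volume,
                 regurgitant_fraction = regurgitant_fraction,
                 n_samples = as.integer(n_samples),
                 systolic_fraction = systolic_fraction, shape = shape,
                 times = times, flows = flows),
            class = "waveform_spec")
}

#' Generate a pulsatile flow waveform with controlled regurgitation
#'
#' @param spec a [waveform_spec()].
#' @return a `flow_waveform` covering one full cycle at uniform sample times
#'   in `[0, period)`; the forward (positive) lobe integrates to
#'   `forward_volume` and the reverse lobe to
#'   `regurgitant_fraction * forward_volume`.
#' @examples
#' wf <- make_flow_waveform(waveform_spec(heart_rate = 75,
#'   forward_volume = 100, regurgitant_fraction = 0.4))
#' regurgitant_fraction(wf)  # ~ 0.400
#' @export
make_flow_waveform <- function(spec) {
  stopifnot(inherits(spec, "waveform_spec"))
  period <- 60 / spec$heart_rate
  if (spec$shape == "table") {
    if (is.null(spec$times) || is.null(spec$flows))
      stop("shape = 'table' requires times and flows")
    return(flow_waveform(spec$times, spec$flows, spec$heart_rate))
  }
  n <- spec$n_samples
  t <- (seq_len(n) - 1L) * period / n
  ts <- spec$systolic_fraction * period
  fv_cm3 <- spec$forward_volume            # mL == cm^3
  rv_cm3 <- spec$regurgitant_fraction * fv_cm3
  amp_f <- 2 * fv_cm3 / ts
  amp_r <- 2 * rv_cm3 / (period - ts)
  q <- ifelse(t < ts,
              amp_f * 0.5 * (1 - cos(2 * pi * t / ts)),
              -amp_r * 0.5 * (1 - cos(2 * pi * (t - ts) / (period - ts))))
  flow_waveform(t, q, spec$heart_rate)
}
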