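#' Blood fluid properties (CGS)
#'
#' Newtonian blood defaults: density 1.06 g/cm^3, dynamic viscosity
#' 0.04 g/(cm s).
#'
#' @param density g/cm^3.
#' @param viscosity g/(cm s) (poise).
#' @return An object of class `fluid_properties`.
#' @export
fluid_properties <- function(density = 1.06, viscosity = 0.04) {
  if (density <= 0 || viscosity <= 0)
    stop("density and viscosity must be positive")
  structure(list(density = density, viscosity = viscosity),
            class = "fluid_properties")
}

#' Steady inflow from stroke volume and heart rate
#'
#' The steady-simulation inlet flow is stroke volume times heart rate,
#' converted to cm^3/s. By convention the stroke volume here is the NET
#' forward volume (forward minus regurgitant), which is what an indexed RV
#' stroke volume measures; pass the forward volume instead if that is the
#' intended convention.
#'
#' @param stroke_volume mL/beat (> 0).
#' @param heart_rate beats/min (> 0).
#' @return steady flow in cm^3/s.
#' @examples
#' steady_inflow(80, 75)  # 100 cm^3/s
#' @export
steady_inflow <- function(stroke_volume, heart_rate) {
  if (!is.numeric(stroke_volume) || stroke_volume <= 0)
    stop("stroke_volume must be positive")
  if (!is.numeric(heart_rate) || heart_rate <= 0)
    stop("heart_rate must be positive")
  stroke_volume * heart_rate / 60
}

#' Fourier decomposition of a periodic flow waveform
#'
#' Projects one uniformly-sampled cycle onto its lowest `n_modes` harmonics
#' (default 10, the standard number of frequency-domain nodes used to map a
#' periodic inlet waveform). Mode 0 is the cycle-mean flow.
#'
#' @param waveform a `flow_waveform` with uniform sampling.
#' @param n_modes number of harmonics 0..n_modes-1 to retain
#'   (`n_modes <= n_samples / 2`).
#' @return An object of class `fourier_flow`: `modes` (complex, harmonics
#'   0..n_modes-1; one-sided convention, so harmonic k >= 1 contributes
#'   `2 Re(modes[k+1] exp(i k w t))`), `omega` (fundamental angular
#'   frequency, rad/s) and `period` (s).
#' @export
fourier_decompose <- function(waveform, n_modes = 10L) {
  stopifnot(inherits(waveform, "flow_waveform"))
  n <- length(waveform$times)
  dt <- diff(waveform$times)
  if (diff(range(dt)) > 1e-9 * mean(dt))
    stop("non-uniform sampling: Fourier decomposition requires uniform times")
  if (n_modes > n / 2) stop("n_modes must be <= n_samples / 2")
  coefs <- fft(waveform$flows) / n
  modes <- coefs[seq_len(n_modes)]
  modes[1L] <- complex(real = Re(modes[1L]), imaginary = 0)
  structure(list(modes = modes, omega = 2 * pi / waveform$period,
                 period = waveform$period),
            class = "fourier_flow")
}

#' @export
print.fourier_flow <- function(x, ...) {
  cat(sprintf(paste0("<fourier_flow> %d harmonics, fundamental %.3f rad/s, ",
                     "mean flow %.2f cm^3/s\n"),
              length(x$modes), x$omega, Re(x$modes[1L])))
  invisible(x)
}

#' Reconstruct a flow waveform from its Fourier modes
#'
#' @param ff a `fourier_flow`.
#' @param times evaluation times in s (any finite values; the series is
#'   periodic).
#' @return flows in cm^3/s (real part of the truncated Fourier series).
#' @export
reconstruct_waveform <- function(ff, times) {
  stopifnot(inherits(ff, "fourier_flow"))
  if (!all(is.finite(times))) stop("times must be finite")
  q <- rep(Re(ff$modes[1L]), length(times))
  if (length(ff$modes) > 1L) {
    for (k in seq_len(length(ff$modes) - 1L)) {
      q <- q + 2 * Re(ff$modes[k + 1L] * exp(1i * k * ff$omega * times))
    }
  }
  q
}

#' Parabolic (Poiseuille) inlet velocity profile
#'
#' Maps an instantaneous flow onto a no-slip parabolic axial velocity
#' profile: `u(r) = 2 Q / (pi R^2) (1 - r^2 / R^2)`.
#'
#' @param Q flow in cm^3/s.
#' @param radius inlet radius R in cm.
#' @param radial_position radius r in cm, `0 <= r <= R` (vectorized).
#' @return axial velocity in cm/s.
#' @examples
#' parabolic_profile(100, 1, 0)  # centerline velocity 63.66 cm/s
#' @export
parabolic_profile <- function(Q, radius, radial_position) {
  if (radius <= 0) stop("radius must be positive")
  if (any(radial_position < 0) || any(radial_position > radius))
    stop("radial_position must lie in [0, radius]")
  2 * Q / (pi * radius^2) * (1 - radial_position^2 / radius^2)
}

#' Parallel resistance outlet network
#'
#' Outlet resistances combine in parallel (`1/R_tot = sum 1/R_i`) and flow
#' splits in proportion to conductance. Two 2-iWU branch outlets give a total
#' lung resistance of 1 iWU with an even split.
#'
#' @param resistances per-outlet resistances (indexed Wood units), > 0,
#'   optionally named.
#' @param bsa body surface area in m^2 (carried as metadata for unit
#'   conversion).
#' @return An object of class `resistance_network`: `total` (iWU),
#'   `fractions` (per-outlet flow fractions summing to 1), `resistances`,
#'   `bsa`.
#' @examples
#' resistance_network(c(LPA = 2, RPA = 2))$total  # 1 iWU
#' @export
resistance_network <- function(resistances, bsa = 1) {
  resistances <- unlist(resistances)
  if (length(resistances) < 1L) stop("need at least one outlet")
  if (any(!is.finite(resistances)) || any(resistances <= 0))
    stop("resistances must be positive")
  if (bsa <= 0) stop("bsa must be positive")
  cond <- 1 / resistances
  structure(list(total = 1 / sum(cond), fractions = cond / sum(cond),
                 resistances = resistances, bsa = bsa),
            class = "resistance_network")
}

#' @export
print.resistance_network <- function(x, ...) {
  cat(sprintf("<resistance_network> total %.3f iWU; fractions: %s\n",
              x$total,
              paste(sprintf("%.3f", x$fractions), collapse = ", ")))
  invisible(x)
}

#' Convert indexed Wood units to CGS resistance
#'
#' Indexing convention: iWU = WU x BSA, so the absolute resistance is
#' `R / bsa` Wood units; 1 WU = 1 mmHg min/L = 1333.22 / 16.6667
#' dyn s/cm^5. This BSA-indexing direction is the conventional one for
#' pediatric pulmonary resistance.
#'
#' @param R resistance in indexed Wood units (> 0).
#' @param bsa body surface area in m^2 (> 0).
#' @return resistance in dyn s/cm^5.
#' @examples
#' iwu_to_cgs(1, 1)  # ~ 79.99 dyn s/cm^5
#' @export
iwu_to_cgs <- function(R, bsa) {
  if (any(R <= 0)) stop("R must be positive")
  if (bsa <= 0) stop("bsa must be positive")
  (R / bsa) * .MMHG_TO_DYN_CM2 / .LMIN_TO_CM3_S
}

#' Locate the systolic and diastolic timepoints
#'
#' Systole is the maximum-flow output timepoint and diastole the minimum;
#' ties break to the earliest index. Indices are 1-based.
#'
#' @param flows inflow values at the output timepoints (>= 2).
#' @return list with `systole_index` and `diastole_index`.
#' @export
find_systole_diastole <- function(flows) {
  if (length(flows) < 2L) stop("need at least 2 timepoints")
  if (diff(range(flows)) == 0) {
    warning("constant flow: systole and diastole are degenerate")
    return(list(systole_index = 1L, diastole_index = 1L))
  }
  list(systole_index = which.max(flows), diastole_index = which.min(flows))
}

#' Regurgitant fraction of a flow waveform
#'
#' Reverse volume over forward volume per cycle, by periodic trapezoidal
#' quadrature: `RF = int |Q^-| dt / int Q^+ dt`.
#'
#' @param waveform a `flow_waveform` with a positive (forward) lobe.
#' @return RF, dimensionless in `[0, Inf)`.
#' @export
regurgitant_fraction <- function(waveform) {
  stopifnot(inherits(waveform, "flow_waveform"))
  fwd <- periodic_integral(waveform, pmax(waveform$flows, 0))
  rev <- periodic_integral(waveform, pmax(-waveform$flows, 0))
  if (fwd <= 0) stop("waveform has no forward flow")
  rev / fwd
}

#' Net stroke volume of a flow waveform
#'
#' Periodic trapezoidal integral of the signed flow over one cycle
#' (forward minus regurgitant volume), in mL.
#'
#' @param waveform a `flow_waveform`.
#' @return net volume per cycle in mL.
#' @export
net_stroke_volume <- function(waveform) {
  stopifnot(inherits(waveform, "flow_waveform"))
  periodic_integral(waveform)
}
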