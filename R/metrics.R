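# Uniform-sampling check for cycle quadrature; periodic trapezoid on a
# uniform grid reduces to the plain sample mean (closure sample implied).
.check_uniform_cycle <- function(field) {
  nt <- length(field$times)
  if (nt < 2L) stop("need at least 2 timepoints spanning one full cycle")
  dt <- diff(field$times)
  if (diff(range(dt)) > 1e-9 * mean(dt))
    stop("field timepoints must be uniformly spaced across the cycle")
  invisible(nt)
}

#' Oscillatory shear index field
#'
#' `OSI(x) = 1/2 (1 - |int_0^T WSS(x,t) dt| / int_0^T |WSS(x,t)| dt)`:
#' the vector integral in the numerator, the magnitude integral in the
#' denominator, both by periodic trapezoidal quadrature over the cycle. An
#' OSI of 0 means the shear never changes direction; 0.5 (the maximum) means
#' fully reversing shear with zero mean.
#'
#' @param field a `wss_field` with >= 2 uniform timepoints over one cycle.
#' @return numeric vector of per-point OSI values in `[0, 0.5]`. Points with
#'   identically zero shear get OSI 0 by convention (with a warning).
#' @export
osi_field <- function(field) {
  stopifnot(inherits(field, "wss_field"))
  .check_uniform_cycle(field)
  mean_vec <- apply(field$vectors, c(1L, 2L), mean)       # n x 3
  num <- sqrt(rowSums(mean_vec^2))
  den <- rowMeans(.wss_magnitude(field))
  osi <- numeric(length(den))
  zero <- den <= 0
  if (any(zero)) warning("points with identically zero shear: OSI set to 0")
  osi[!zero] <- 0.5 * (1 - num[!zero] / den[!zero])
  pmin(pmax(osi, 0), 0.5)
}

#' Time-averaged wall shear stress field
#'
#' `taWSS(x) = (1/T) int_0^T |WSS(x,t)| dt`: the cycle average of the shear
#' magnitude (periodic trapezoidal quadrature). This is the standard taWSS
#' convention; the magnitude-of-the-mean alternative is already captured by
#' the OSI numerator.
#'
#' @param field a `wss_field`.
#' @return numeric vector of per-point taWSS (dynes/cm^2).
#' @export
tawss_field <- function(field) {
  stopifnot(inherits(field, "wss_field"))
  .check_uniform_cycle(field)
  rowMeans(.wss_magnitude(field))
}

# |WSS| as an n x nt matrix regardless of degenerate dimensions
.wss_magnitude <- function(field) {
  v <- field$vectors
  matrix(sqrt(v[, 1L, ]^2 + v[, 2L, ]^2 + v[, 3L, ]^2),
         dim(v)[1L], dim(v)[3L])
}

#' Wall shear magnitude at a single output timepoint
#'
#' @param field a `wss_field`.
#' @param index 1-based timepoint index (e.g. the systolic or diastolic index
#'   from [find_systole_diastole()]).
#' @return numeric vector of |WSS| (dynes/cm^2) per wall point.
#' @export
wss_at_timepoint <- function(field, index) {
  stopifnot(inherits(field, "wss_field"))
  if (index < 1L || index > length(field$times))
    stop("timepoint index out of range")
  v <- field$vectors[, , index, drop = FALSE]
  sqrt(v[, 1L, 1L]^2 + v[, 2L, 1L]^2 + v[, 3L, 1L]^2)
}

#' Per-segment average and peak of a wall scalar field
#'
#' Averages are area-weighted (mesh-resolution invariant); peaks are maxima
#' over wall points (optionally a quantile, to probe outlier sensitivity).
#' The whole-vessel row is computed over the union of the MPA/LPA/RPA points.
#' Extension points must already be trimmed. Empty regions are omitted.
#'
#' @param scalars per-point values.
#' @param labeling a `segment_labeling` covering the points.
#' @param peak_quantile peak definition: 1 (default) for the maximum, or a
#'   quantile in (0, 1) such as 0.99.
#' @return data.frame with columns `region` ("whole", "MPA", "LPA", "RPA"),
#'   `avg`, `peak`, `area`.
#' @export
segment_summary <- function(scalars, labeling, peak_quantile = 1) {
  stopifnot(inherits(labeling, "segment_labeling"))
  if (length(scalars) != length(labeling$labels))
    stop("scalars must cover all labeled points")
  if (any(labeling$labels == "extension"))
    stop("trim extensions before summarizing")
  pk <- function(x) if (peak_quantile >= 1) max(x)
    else as.numeric(quantile(x, peak_quantile, names = FALSE))
  rows <- list()
  seg_idx <- lapply(c(MPA = "MPA", LPA = "LPA", RPA = "RPA"),
                    function(r) which(labeling$labels == r))
  present <- names(seg_idx)[vapply(seg_idx, length, integer(1)) > 0]
  whole <- sort(unlist(seg_idx[present]))
  w <- labeling$areas
  rows[["whole"]] <- data.frame(
    region = "whole",
    avg = sum(scalars[whole] * w[whole]) / sum(w[whole]),
    peak = pk(scalars[whole]), area = sum(w[whole]))
  for (r in present) {
    i <- seg_idx[[r]]
    rows[[r]] <- data.frame(
      region = r, avg = sum(scalars[i] * w[i]) / sum(w[i]),
      peak = pk(scalars[i]), area = sum(w[i]))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Hemodynamic summary of one case
#'
#' Assembles the per-region metric set for one vessel: steady WSS (avg/peak),
#' and — when a pulsatile field is supplied — taWSS (avg/peak), systolic and
#' diastolic WSS (avg/peak at the max/min inflow output timepoints), and
#' average OSI. Steady-only input yields a steady-only summary (no error).
#'
#' @param steady a `wss_steady_field` (extensions trimmed).
#' @param pulsatile optional `wss_field` with consistent labeling.
#' @param waveform optional `flow_waveform` (the inlet flow) used to locate
#'   the systolic/diastolic output timepoints; required with `pulsatile`.
#' @param peak_quantile see [segment_summary()].
#' @return An object of class `hemo_summary`: a data.frame (one row per
#'   region: whole, MPA, LPA, RPA) with metric columns `wss_steady_avg`,
#'   `wss_steady_peak`, and, if pulsatile input was given, `tawss_avg`,
#'   `tawss_peak`, `wss_systole_avg`, `wss_systole_peak`,
#'   `wss_diastole_avg`, `wss_diastole_peak`, `osi_avg` (dynes/cm^2 except
#'   the dimensionless OSI). Attributes `systole_index`/`diastole_index`
#'   record the timepoints used.
#' @export
summarize_case <- function(steady, pulsatile = NULL, waveform = NULL,
                           peak_quantile = 1) {
  stopifnot(inherits(steady, "wss_steady_field"))
  base <- segment_summary(steady$scalars, steady$labeling, peak_quantile)
  out <- data.frame(region = base$region, area = base$area,
                    wss_steady_avg = base$avg, wss_steady_peak = base$peak)
  sys_idx <- dia_idx <- NA_integer_
  if (!is.null(pulsatile)) {
    stopifnot(inherits(pulsatile, "wss_field"))
    if (nrow(pulsatile$wall_points) != nrow(steady$wall_points))
      stop("steady and pulsatile fields must share wall points")
    if (is.null(waveform))
      stop("a waveform is required to locate systole/diastole")
    lab <- pulsatile$labeling
    inflow <- approx(c(waveform$times, waveform$period),
                     c(waveform$flows, waveform$flows[1L]),
                     xout = pulsatile$times %% waveform$period)$y
    sd_idx <- find_systole_diastole(inflow)
    sys_idx <- sd_idx$systole_index
    dia_idx <- sd_idx$diastole_index
    add <- function(scalars) segment_summary(scalars, lab, peak_quantile)
    ta <- add(tawss_field(pulsatile))
    sy <- add(wss_at_timepoint(pulsatile, sys_idx))
    di <- add(wss_at_timepoint(pulsatile, dia_idx))
    os <- add(osi_field(pulsatile))
    stopifnot(identical(ta$region, out$region))
    out$tawss_avg <- ta$avg; out$tawss_peak <- ta$peak
    out$wss_systole_avg <- sy$avg; out$wss_systole_peak <- sy$peak
    out$wss_diastole_avg <- di$avg; out$wss_diastole_peak <- di$peak
    out$osi_avg <- os$avg
  }
  structure(out, class = c("hemo_summary", "data.frame"),
            systole_index = sys_idx, diastole_index = dia_idx)
}

#' @export
print.hemo_summary <- function(x, digits = 4, ...) {
  cat("Hemodynamic summary (dynes/cm^2; OSI dimensionless)\n")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = digits)
  print(df, row.names = FALSE)
  if (!is.na(attr(x, "systole_index")))
    cat(sprintf("systole at output timepoint %d, diastole at %d\n",
                attr(x, "systole_index"), attr(x, "diastole_index")))
  invisible(x)
}
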