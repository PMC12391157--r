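#' Time-resolved wall shear stress field
#'
#' Per-wall-point 3D shear vectors at the output timepoints of one cardiac
#' cycle (20 evenly-spaced timepoints by default in the pipeline).
#'
#' @param wall_points n x 3 matrix of wall coordinates (cm).
#' @param areas per-point areas (cm^2, > 0).
#' @param times output times in s within one cycle.
#' @param vectors numeric array n x 3 x length(times) of shear vectors
#'   (dynes/cm^2).
#' @param labeling a `segment_labeling` for the wall points.
#' @param period cycle length in s (defaults to the implied uniform period).
#' @return An object of class `wss_field`.
#' @export
wss_field <- function(wall_points, areas, times, vectors, labeling,
                      period = NULL) {
  wall_points <- as.matrix(wall_points)
  vectors <- as.array(vectors)
  n <- nrow(wall_points)
  nt <- length(times)
  if (nt < 1L) stop("need at least one timepoint")
  if (!all(dim(vectors) == c(n, 3L, nt))) stop("vectors must be n x 3 x nt")
  if (!all(is.finite(vectors))) stop("shear vectors must be finite")
  if (any(areas <= 0)) stop("areas must be positive")
  stopifnot(inherits(labeling, "segment_labeling"),
            length(labeling$labels) == n)
  if (is.null(period)) {
    period <- if (nt > 1L) nt * (times[2L] - times[1L]) else 1
  }
  structure(list(wall_points = wall_points, areas = as.numeric(areas),
                 times = as.numeric(times), vectors = vectors,
                 labeling = labeling, period = period),
            class = "wss_field")
}

#' @export
print.wss_field <- function(x, ...) {
  mag <- sqrt(x$vectors[, 1, , drop = FALSE]^2 +
                x$vectors[, 2, , drop = FALSE]^2 +
                x$vectors[, 3, , drop = FALSE]^2)
  cat(sprintf(paste0("<wss_field> %d wall points x %d timepoints ",
                     "(period %.3f s), |WSS| range [%.2f, %.2f] dynes/cm^2\n"),
              nrow(x$wall_points), length(x$times), x$period,
              min(mag), max(mag)))
  invisible(x)
}

#' Steady wall shear stress field
#'
#' @param wall_points n x 3 matrix (cm).
#' @param areas per-point areas (cm^2, > 0).
#' @param scalars non-negative WSS magnitudes (dynes/cm^2).
#' @param labeling a `segment_labeling`.
#' @return An object of class `wss_steady_field`.
#' @export
wss_steady_field <- function(wall_points, areas, scalars, labeling) {
  wall_points <- as.matrix(wall_points)
  n <- nrow(wall_points)
  if (length(scalars) != n) stop("scalars must have one value per wall point")
  if (any(scalars < 0)) stop("steady WSS scalars must be non-negative")
  if (any(areas <= 0)) stop("areas must be positive")
  stopifnot(inherits(labeling, "segment_labeling"),
            length(labeling$labels) == n)
  structure(list(wall_points = wall_points, areas = as.numeric(areas),
                 scalars = as.numeric(scalars), labeling = labeling),
            class = "wss_steady_field")
}

#' @export
print.wss_steady_field <- function(x, ...) {
  cat(sprintf("<wss_steady_field> %d wall points, WSS range [%.2f, %.2f] dynes/cm^2\n",
              nrow(x$wall_points), min(x$scalars), max(x$scalars)))
  invisible(x)
}

#' @export
trim_extensions.wss_field <- function(x, labeling = NULL, ...) {
  lab <- if (is.null(labeling)) x$labeling else labeling
  keep <- .keep_mask(lab, nrow(x$wall_points))
  wss_field(x$wall_points[keep, , drop = FALSE], x$areas[keep], x$times,
            x$vectors[keep, , , drop = FALSE],
            segment_labeling(lab$labels[keep], x$areas[keep]),
            period = x$period)
}

#' @export
trim_extensions.wss_steady_field <- function(x, labeling = NULL, ...) {
  lab <- if (is.null(labeling)) x$labeling else labeling
  keep <- .keep_mask(lab, nrow(x$wall_points))
  wss_steady_field(x$wall_points[keep, , drop = FALSE], x$areas[keep],
                   x$scalars[keep],
                   segment_labeling(lab$labels[keep], x$areas[keep]))
}
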