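#' Construct a vessel centerline polyline
#'
#' A centerline is an ordered set of 3D points (cm) with cumulative arclength.
#' It is the geometric substrate for curvature and tortuosity metrics and for
#' the locally-cylindrical wall-shear engine.
#'
#' @param points numeric matrix (n x 3) of ordered 3D coordinates in cm, or a
#'   data.frame with columns x, y, z.
#' @return An object of class `centerline` with elements `points` (n x 3
#'   matrix) and `arclength` (cumulative distance, cm, starting at 0).
#' @examples
#' cl <- centerline(cbind(0, 0, seq(0, 5, by = 0.5)))
#' total_length(cl)
#' @export
centerline <- function(points) {
  if (is.data.frame(points)) points <- as.matrix(points[, c("x", "y", "z")])
  points <- as.matrix(points)
  dimnames(points) <- NULL
  storage.mode(points) <- "double"
  if (ncol(points) != 3L) stop("centerline points must be n x 3")
  if (nrow(points) < 2L) stop("centerline needs at least 2 points")
  if (!all(is.finite(points))) stop("centerline coordinates must be finite")
  seg <- sqrt(rowSums((points[-1L, , drop = FALSE] -
                         points[-nrow(points), , drop = FALSE])^2))
  if (any(seg <= 0)) stop("centerline contains coincident consecutive points")
  structure(list(points = points, arclength = c(0, cumsum(seg))),
            class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("<centerline> %d points, length %.3f cm\n",
              nrow(x$points), total_length(x)))
  invisible(x)
}

#' Total arclength of a centerline
#' @param line a `centerline`.
#' @return length in cm.
#' @export
total_length <- function(line) {
  stopifnot(inherits(line, "centerline"))
  line$arclength[length(line$arclength)]
}

#' Concatenate two centerlines end-to-start
#'
#' Used to build inlet-to-outlet branch paths (main trunk followed by a
#' branch); the duplicated junction point is dropped.
#'
#' @param a,b `centerline` objects; the end of `a` must coincide with the
#'   start of `b` (within `tol` cm).
#' @param tol junction coincidence tolerance in cm.
#' @return a `centerline`.
#' @export
join_centerlines <- function(a, b, tol = 1e-6) {
  stopifnot(inherits(a, "centerline"), inherits(b, "centerline"))
  gap <- sqrt(sum((a$points[nrow(a$points), ] - b$points[1L, ])^2))
  if (gap > tol) stop(sprintf("centerlines do not join (gap %.3g cm)", gap))
  centerline(rbind(a$points, b$points[-1L, , drop = FALSE]))
}

#' Resample a centerline at uniform arclength increments
#'
#' Linear interpolation along the polyline; the default 0.1 cm step matches
#' the analysis protocol used for the curvature/tortuosity metrics. First and
#' last points are preserved; the final gap may be shorter than `step`.
#'
#' @param line a `centerline`.
#' @param step arclength increment in cm (default 0.1).
#' @return a resampled `centerline`.
#' @export
resample_centerline <- function(line, step = 0.1) {
  stopifnot(inherits(line, "centerline"))
  if (!is.numeric(step) || length(step) != 1L || step <= 0)
    stop("step must be a positive scalar (cm)")
  L <- total_length(line)
  if (step >= L) {
    warning("step >= centerline length; returning endpoints only")
    return(centerline(line$points[c(1L, nrow(line$points)), ]))
  }
  s_new <- seq(0, L, by = step)
  if (s_new[length(s_new)] < L) s_new <- c(s_new, L)
  pts <- vapply(1:3, function(j)
    approx(line$arclength, line$points[, j], xout = s_new)$y,
    numeric(length(s_new)))
  # guarantee exact endpoint preservation against interpolation round-off
  pts[1L, ] <- line$points[1L, ]
  pts[nrow(pts), ] <- line$points[nrow(line$points), ]
  centerline(pts)
}

#' Curvature profile of a centerline
#'
#' Curvature is the inverse radius of the local osculating circle,
#' kappa(s) = |c'(s) x c''(s)| / |c'(s)|^3, evaluated from cubic smoothing
#' splines fitted per coordinate against arclength (analytic first and second
#' derivatives). Spline derivatives are unreliable at the path ends, so the
#' two endpoints are excluded from the reported mean.
#'
#' @param line a `centerline` (resample first; at least 5 points required).
#' @param lambda smoothing-spline penalty passed to
#'   [stats::smooth.spline()]. The default `1e-8` is near-interpolating,
#'   appropriate for clean (synthetic or already-smoothed) centerlines; raise
#'   it for noisy extracted centerlines.
#' @return An object of class `curvature_profile`: `s` (arclength, cm),
#'   `kappa` (cm^-1, >= 0), and `mean_kappa` (endpoint-excluded mean).
#' @examples
#' th <- seq(0, pi, length.out = 200)
#' arc <- centerline(cbind(2 * cos(th), 2 * sin(th), 0))
#' curvature_profile(resample_centerline(arc, 0.1))$mean_kappa  # ~ 0.5
#' @export
curvature_profile <- function(line, lambda = 1e-8) {
  stopifnot(inherits(line, "centerline"))
  n <- nrow(line$points)
  if (n < 5L) stop("need at least 5 points for curvature estimation")
  s <- line$arclength
  d1 <- matrix(0, n, 3L)
  d2 <- matrix(0, n, 3L)
  for (j in 1:3) {
    fit <- smooth.spline(s, line$points[, j], lambda = lambda,
                         all.knots = TRUE, keep.data = FALSE)
    d1[, j] <- predict(fit, s, deriv = 1L)$y
    d2[, j] <- predict(fit, s, deriv = 2L)$y
  }
  cross <- cbind(d1[, 2] * d2[, 3] - d1[, 3] * d2[, 2],
                 d1[, 3] * d2[, 1] - d1[, 1] * d2[, 3],
                 d1[, 1] * d2[, 2] - d1[, 2] * d2[, 1])
  speed <- sqrt(rowSums(d1^2))
  kappa <- sqrt(rowSums(cross^2)) / pmax(speed, .Machine$double.eps)^3
  # collinear/degenerate stretches: spline round-off, not real curvature
  kappa[kappa < 1e-8] <- 0
  structure(list(s = s, kappa = kappa,
                 mean_kappa = mean(kappa[-c(1L, n)])),
            class = "curvature_profile")
}

#' @export
print.curvature_profile <- function(x, ...) {
  cat(sprintf("<curvature_profile> %d points, mean curvature %.4f cm^-1\n",
              length(x$s), x$mean_kappa))
  invisible(x)
}

#' Centerline tortuosity
#'
#' Tortuosity is the arclength of the path divided by the Euclidean distance
#' between its endpoints, minus one: a straight vessel scores 0.
#'
#' @param line a `centerline` with distinct endpoints.
#' @return An object of class `geometry_metrics`: `tortuosity`
#'   (dimensionless), `path_length` (cm), `endpoint_distance` (cm).
#' @examples
#' th <- seq(0, pi, length.out = 100)
#' tortuosity(centerline(cbind(2 * cos(th), 2 * sin(th), 0)))  # ~ pi/2 - 1
#' @export
tortuosity <- function(line) {
  stopifnot(inherits(line, "centerline"))
  L <- total_length(line)
  D <- sqrt(sum((line$points[nrow(line$points), ] - line$points[1L, ])^2))
  if (D < 1e-9) stop("endpoints coincide (closed loop): tortuosity undefined")
  structure(list(tortuosity = L / D - 1, path_length = L,
                 endpoint_distance = D),
            class = "geometry_metrics")
}

#' @export
print.geometry_metrics <- function(x, ...) {
  cat(sprintf("<geometry_metrics> tortuosity %.4f (L = %.3f cm, D = %.3f cm)\n",
              x$tortuosity, x$path_length, x$endpoint_distance))
  invisible(x)
}
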