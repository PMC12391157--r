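#' Segment labeling of wall points
#'
#' Assignment of wall points to vessel regions (MPA/LPA/RPA/extension) with
#' per-point areas. The labels partition the wall and the areas sum to the
#' total wall area.
#'
#' @param labels character or factor, one of "MPA", "LPA", "RPA",
#'   "extension" per wall point.
#' @param areas numeric vector of per-point areas (cm^2), positive.
#' @return An object of class `segment_labeling`.
#' @export
segment_labeling <- function(labels, areas) {
  labels <- factor(as.character(labels),
                   levels = c("MPA", "LPA", "RPA", "extension"))
  if (anyNA(labels)) stop("labels must be MPA/LPA/RPA/extension")
  areas <- as.numeric(areas)
  if (length(areas) != length(labels)) stop("labels/areas length mismatch")
  if (any(!is.finite(areas)) || any(areas <= 0))
    stop("per-point areas must be positive")
  structure(list(labels = labels, areas = areas), class = "segment_labeling")
}

#' @export
print.segment_labeling <- function(x, ...) {
  tab <- table(droplevels(x$labels))
  cat("<segment_labeling>",
      paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
      sprintf("| total area %.3f cm^2\n", sum(x$areas)))
  invisible(x)
}

#' Specification of a synthetic tubular vessel
#'
#' @param centerline_fn either a function `f(t)` mapping t in \[0, 1\] to a
#'   3-vector/n x 3 matrix of coordinates (cm), or an n x 3 matrix of points
#'   sampled along the curve.
#' @param radius tube radius in cm: a positive scalar or a function of the
#'   normalized arclength fraction in \[0, 1\].
#' @param axial_samples number of rings along the axis (>= 4).
#' @param circumferential_samples vertices per ring (>= 8).
#' @return An object of class `tube_spec`.
#' @export
tube_spec <- function(centerline_fn, radius, axial_samples = 50L,
                      circumferential_samples = 24L) {
  if (axial_samples < 4L) stop("axial_samples must be >= 4")
  if (circumferential_samples < 8L) stop("circumferential_samples must be >= 8")
  if (!is.function(radius)) {
    r0 <- as.numeric(radius)
    if (length(r0) != 1L || !is.finite(r0) || r0 <= 0)
      stop("radius must be positive")
  }
  structure(list(centerline_fn = centerline_fn, radius = radius,
                 axial_samples = as.integer(axial_samples),
                 circumferential_samples = as.integer(circumferential_samples)),
            class = "tube_spec")
}

# Sample the spec curve at n points; returns an n x 3 matrix.
sample_spec_curve <- function(fn, n) {
  t <- seq(0, 1, length.out = n)
  if (is.function(fn)) {
    out <- fn(t)
    if (is.null(dim(out))) out <- t(vapply(t, fn, numeric(3)))
    out <- as.matrix(out)
  } else {
    pts <- as.matrix(fn)
    cl <- centerline(pts)
    out <- resample_centerline(cl, total_length(cl) / (n - 1))$points
    out <- out[seq_len(min(n, nrow(out))), , drop = FALSE]
  }
  out
}

# Parallel-transport orthonormal frames (normal, binormal) along tangents.
transport_frames <- function(tangents) {
  n <- nrow(tangents)
  tangents <- tangents / sqrt(rowSums(tangents^2))
  nrm <- matrix(0, n, 3)
  bin <- matrix(0, n, 3)
  t0 <- tangents[1L, ]
  ref <- if (abs(t0[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  v <- ref - sum(ref * t0) * t0
  nrm[1L, ] <- v / sqrt(sum(v^2))
  bin[1L, ] <- c(t0[2] * nrm[1, 3] - t0[3] * nrm[1, 2],
                 t0[3] * nrm[1, 1] - t0[1] * nrm[1, 3],
                 t0[1] * nrm[1, 2] - t0[2] * nrm[1, 1])
  for (i in 2:n) {
    ta <- tangents[i - 1L, ]; tb <- tangents[i, ]
    axis <- c(ta[2] * tb[3] - ta[3] * tb[2],
              ta[3] * tb[1] - ta[1] * tb[3],
              ta[1] * tb[2] - ta[2] * tb[1])
    s <- sqrt(sum(axis^2)); cth <- sum(ta * tb)
    if (s < 1e-12) {
      nrm[i, ] <- nrm[i - 1L, ]
    } else {
      axis <- axis / s
      v <- nrm[i - 1L, ]
      nrm[i, ] <- v * cth + c(axis[2] * v[3] - axis[3] * v[2],
                              axis[3] * v[1] - axis[1] * v[3],
                              axis[1] * v[2] - axis[2] * v[1]) * s +
        axis * sum(axis * v) * (1 - cth)
    }
    # re-orthogonalize against accumulated drift
    nrm[i, ] <- nrm[i, ] - sum(nrm[i, ] * tb) * tb
    nrm[i, ] <- nrm[i, ] / sqrt(sum(nrm[i, ]^2))
    bin[i, ] <- c(tb[2] * nrm[i, 3] - tb[3] * nrm[i, 2],
                  tb[3] * nrm[i, 1] - tb[1] * nrm[i, 3],
                  tb[1] * nrm[i, 2] - tb[2] * nrm[i, 1])
  }
  list(normal = nrm, binormal = bin)
}

# Discrete curvature via circumscribed-circle radius of consecutive triples.
discrete_curvature <- function(pts) {
  n <- nrow(pts)
  k <- numeric(n)
  if (n < 3L) return(k)
  for (i in 2:(n - 1L)) {
    a <- pts[i - 1L, ]; b <- pts[i, ]; c <- pts[i + 1L, ]
    ab <- b - a; ac <- c - a; bc <- c - b
    cr <- c(ab[2] * ac[3] - ab[3] * ac[2],
            ab[3] * ac[1] - ab[1] * ac[3],
            ab[1] * ac[2] - ab[2] * ac[1])
    num <- 2 * sqrt(sum(cr^2))
    den <- sqrt(sum(ab^2)) * sqrt(sum(ac^2)) * sqrt(sum(bc^2))
    k[i] <- if (den > 0) num / den else 0
  }
  k
}

#' Generate a triangulated tube with ground-truth centerline
#'
#' Builds a watertight-except-caps tube around the spec curve using
#' parallel-transport frames, so every surface vertex lies exactly at the
#' local radius from its centerline ring point.
#'
#' @param spec a [tube_spec()].
#' @return list with `mesh` (`surface_mesh`) and `centerline` (`centerline`,
#'   the exact sampled spec curve).
#' @examples
#' tg <- make_tube_geometry(tube_spec(function(t) cbind(0, 0, 5 * t), 1))
#' tortuosity(tg$centerline)$tortuosity  # 0: straight tube
#' @export
make_tube_geometry <- function(spec) {
  stopifnot(inherits(spec, "tube_spec"))
  na <- spec$axial_samples; nc <- spec$circumferential_samples
  pts <- sample_spec_curve(spec$centerline_fn, na)
  cl <- centerline(pts)
  sfrac <- cl$arclength / total_length(cl)
  r <- if (is.function(spec$radius)) {
    vapply(sfrac, spec$radius, numeric(1))
  } else rep(spec$radius, na)
  if (any(!is.finite(r)) || any(r <= 0)) stop("radius must be positive everywhere")
  kap <- discrete_curvature(pts)
  if (any(r * kap >= 1))
    stop("geometry error: tube radius exceeds local centerline curvature radius")
  # tangents by central differences
  tg <- rbind(pts[2L, ] - pts[1L, ],
              pts[3:na, , drop = FALSE] - pts[1:(na - 2L), , drop = FALSE],
              pts[na, ] - pts[na - 1L, ])
  fr <- transport_frames(tg)
  phi <- 2 * pi * (0:(nc - 1L)) / nc
  verts <- matrix(0, na * nc, 3)
  for (i in seq_len(na)) {
    ring <- outer(cos(phi), fr$normal[i, ]) + outer(sin(phi), fr$binormal[i, ])
    verts[((i - 1L) * nc + 1L):(i * nc), ] <-
      matrix(pts[i, ], nc, 3, byrow = TRUE) + r[i] * ring
  }
  tris <- matrix(0L, 2L * (na - 1L) * nc, 3L)
  row <- 1L
  for (i in seq_len(na - 1L)) {
    for (j in seq_len(nc)) {
      jn <- if (j == nc) 1L else j + 1L
      a <- (i - 1L) * nc + j; b <- (i - 1L) * nc + jn
      c2 <- i * nc + j; d <- i * nc + jn
      tris[row, ] <- c(a, b, c2); tris[row + 1L, ] <- c(b, d, c2)
      row <- row + 2L
    }
  }
  list(mesh = surface_mesh(verts, tris), centerline = cl)
}

#' Specification of a three-branch pulmonary artery bifurcation
#'
#' The main pulmonary artery (MPA) runs from the inlet to the junction point;
#' the left and right branches (LPA, RPA) originate at the junction.
#'
#' @param mpa,lpa,rpa [tube_spec()] objects. The MPA curve must end at
#'   `junction_point` and the branch curves must start there.
#' @param junction_point 3-vector (cm).
#' @return An object of class `pa_bifurcation_spec`.
#' @export
pa_bifurcation_spec <- function(mpa, lpa, rpa, junction_point) {
  stopifnot(inherits(mpa, "tube_spec"), inherits(lpa, "tube_spec"),
            inherits(rpa, "tube_spec"))
  junction_point <- as.numeric(junction_point)
  stopifnot(length(junction_point) == 3L)
  ends <- list(
    mpa_end = sample_spec_curve(mpa$centerline_fn, mpa$axial_samples)[mpa$axial_samples, ],
    lpa_start = sample_spec_curve(lpa$centerline_fn, lpa$axial_samples)[1L, ],
    rpa_start = sample_spec_curve(rpa$centerline_fn, rpa$axial_samples)[1L, ])
  for (nm in names(ends)) {
    if (sqrt(sum((ends[[nm]] - junction_point)^2)) > 1e-6)
      stop(sprintf("%s does not meet the junction point", nm))
  }
  structure(list(mpa = mpa, lpa = lpa, rpa = rpa,
                 junction_point = junction_point),
            class = "pa_bifurcation_spec")
}

# radius at a given arclength fraction for a tube_spec
.spec_radius <- function(spec, sfrac) {
  if (is.function(spec$radius)) spec$radius(sfrac) else spec$radius
}

#' Generate a synthetic pulmonary artery bifurcation
#'
#' Builds the three tubes and merges them into a single wall mesh with one
#' inlet (MPA) and two outlets (LPA, RPA), returning the ground-truth
#' centerlines and wall-point labeling. The branch walls start a short
#' distance (`wall_offset` times the MPA junction radius) past the junction
#' point: inside the trunk there is no branch wall, exactly as in a
#' segmented anatomy. The returned branch centerlines still originate at
#' the junction.
#'
#' @param spec a [pa_bifurcation_spec()], e.g. from [default_pa_spec()].
#' @param wall_offset branch wall start, as a fraction of the MPA junction
#'   radius.
#' @return list with `mesh` (`surface_mesh`), `centerlines` (named list of
#'   `centerline`: MPA, LPA, RPA), and `labeling` (`segment_labeling`,
#'   ground-truth construction labels).
#' @export
make_pa_bifurcation <- function(spec, wall_offset = 0.75) {
  stopifnot(inherits(spec, "pa_bifurcation_spec"))
  r_mpa_end <- .spec_radius(spec$mpa, 1)
  if (.spec_radius(spec$lpa, 0) > r_mpa_end ||
      .spec_radius(spec$rpa, 0) > r_mpa_end)
    stop("geometry error: branch radius exceeds MPA radius at the junction")
  parts <- lapply(list(MPA = spec$mpa, LPA = spec$lpa, RPA = spec$rpa),
                  make_tube_geometry)
  walls <- parts
  for (br in c("LPA", "RPA")) {
    ts <- spec[[tolower(br)]]
    s0 <- wall_offset * r_mpa_end
    len <- total_length(parts[[br]]$centerline)
    if (s0 > 0 && s0 < 0.5 * len) {
      t0 <- s0 / len
      fn <- ts$centerline_fn
      shifted <- if (is.function(fn)) {
        function(t) fn(t0 + t * (1 - t0))
      } else {
        resample_centerline(parts[[br]]$centerline, 0.02)$points
      }
      shifted_spec <- ts
      if (is.function(fn)) {
        shifted_spec$centerline_fn <- shifted
      } else {
        keep <- centerline(shifted)
        shifted_spec$centerline_fn <-
          keep$points[keep$arclength >= s0, , drop = FALSE]
      }
      walls[[br]] <- make_tube_geometry(shifted_spec)
    }
  }
  mesh <- merge_meshes(lapply(walls, function(p) p$mesh))
  labels <- rep(names(walls),
                vapply(walls, function(p) nrow(p$mesh$vertices), integer(1)))
  labeling <- segment_labeling(labels, vertex_areas(mesh))
  list(mesh = mesh,
       centerlines = lapply(parts, `[[`, "centerline"),
       labeling = labeling)
}

# circular-arc curve factory: starts at `origin` with tangent `dir0` (unit),
# turning toward `turn` (unit, orthogonal to dir0), arc radius rho, angle theta
.arc_curve <- function(origin, dir0, turn, rho, theta) {
  force(origin); force(dir0); force(turn); force(rho); force(theta)
  function(t) {
    a <- theta * t
    sweep(outer(sin(a), rho * dir0) + outer(1 - cos(a), rho * turn),
          2, origin, "+")
  }
}

#' Default synthetic pulmonary artery bifurcation spec
#'
#' A canonical three-branch geometry: a gently bowed MPA trunk and two
#' circular-arc branches. Default arc radii and sweep angles put the branch
#' curvature and tortuosity near typical repaired-tetralogy values (LPA
#' curvier than RPA), and default tube radii order LPA < RPA < MPA, which is
#' the size ordering that drives the characteristic wall-shear ordering
#' LPA > RPA > MPA.
#'
#' @param mpa_radius,lpa_radius,rpa_radius tube radii in cm.
#' @param mpa_length MPA trunk length in cm.
#' @param lpa_arc_radius,rpa_arc_radius branch arc radii in cm (curvature is
#'   their inverse).
#' @param lpa_sweep,rpa_sweep branch arc sweep angles in radians.
#' @param branch_angle opening half-angle in radians between the trunk axis
#'   and each branch's take-off direction (the branches leave the junction
#'   tilted left/right, as anatomical branches do, rather than tangent to
#'   the trunk).
#' @param axial_samples,circumferential_samples mesh resolution per tube.
#' @return a `pa_bifurcation_spec`.
#' @export
default_pa_spec <- function(mpa_radius = 1.2, lpa_radius = 0.8,
                            rpa_radius = 0.9, mpa_length = 4,
                            lpa_arc_radius = 2.2, rpa_arc_radius = 2.6,
                            lpa_sweep = 1.4, rpa_sweep = 1.2,
                            branch_angle = 0.7,
                            axial_samples = 40L,
                            circumferential_samples = 20L) {
  junction <- c(0, 0, mpa_length)
  mpa_fn <- function(t) cbind(0.15 * sin(pi * t), 0, mpa_length * t)
  ca <- cos(branch_angle); sa <- sin(branch_angle)
  lpa_fn <- .arc_curve(junction, c(sa, 0, ca), c(ca, 0, -sa),
                       lpa_arc_radius, lpa_sweep)
  rpa_fn <- .arc_curve(junction, c(-sa, 0, ca), c(-ca, 0, -sa),
                       rpa_arc_radius, rpa_sweep)
  pa_bifurcation_spec(
    mpa = tube_spec(mpa_fn, mpa_radius, axial_samples, circumferential_samples),
    lpa = tube_spec(lpa_fn, lpa_radius, axial_samples, circumferential_samples),
    rpa = tube_spec(rpa_fn, rpa_radius, axial_samples, circumferential_samples),
    junction_point = junction)
}
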