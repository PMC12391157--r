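# Distance from each query point to the nearest vertex of a (densely
# resampled) polyline; returns list(dist, index) with index into the
# resampled polyline.
nearest_centerline_point <- function(points, cl, step = 0.05) {
  cl_fine <- if (total_length(cl) > 2 * step) resample_centerline(cl, step) else cl
  cp <- cl_fine$points
  # squared distances via (|p|^2 + |c|^2 - 2 p.c), n_pts x n_cl
  pp <- rowSums(points^2)
  cc <- rowSums(cp^2)
  d2 <- outer(pp, cc, "+") - 2 * points %*% t(cp)
  d2[d2 < 0] <- 0
  idx <- max.col(-d2, ties.method = "first")
  list(dist = sqrt(d2[cbind(seq_len(nrow(points)), idx)]),
       index = idx, polyline = cl_fine)
}

# Detect whether lpa/rpa centerlines are full inlet-to-outlet paths sharing
# the MPA prefix, and if so truncate them where they diverge beyond
# junction_scale x local MPA radius.
.truncate_full_paths <- function(mesh, centerlines, junction_scale) {
  lpa <- centerlines$LPA; rpa <- centerlines$RPA; mpa <- centerlines$MPA
  if (is.null(lpa) || is.null(rpa)) return(centerlines)
  shared_start <- sqrt(sum((lpa$points[1L, ] - mpa$points[1L, ])^2)) < 1e-3 &&
    sqrt(sum((rpa$points[1L, ] - mpa$points[1L, ])^2)) < 1e-3
  if (!shared_start) return(centerlines)
  # local MPA radius: median distance from MPA centerline to its nearest wall
  r_mpa <- median(apply(mpa$points, 1L, function(p)
    min(sqrt(rowSums(sweep(mesh$vertices, 2, p)^2)))))
  step <- 0.05
  l_f <- resample_centerline(lpa, step)
  r_f <- resample_centerline(rpa, step)
  n <- min(nrow(l_f$points), nrow(r_f$points))
  sep <- sqrt(rowSums((l_f$points[1:n, ] - r_f$points[1:n, ])^2))
  div <- which(sep > junction_scale * r_mpa)[1L]
  if (is.na(div)) stop("LPA/RPA paths never diverge beyond the junction threshold")
  centerlines$LPA <- centerline(l_f$points[div:nrow(l_f$points), ])
  centerlines$RPA <- centerline(r_f$points[div:nrow(r_f$points), ])
  centerlines$MPA <- centerline(l_f$points[1:div, ])
  centerlines
}

#' Split a vessel wall into MPA/LPA/RPA segments
#'
#' Each wall point is assigned to the branch whose centerline is nearest.
#' If the LPA/RPA centerlines are supplied as full inlet-to-outlet paths
#' (sharing the MPA prefix), they are truncated where they diverge beyond
#' `junction_scale` times the local MPA radius. Ties are broken
#' deterministically in the order MPA < LPA < RPA. Per-point areas are one
#' third of the incident triangle areas.
#'
#' @param mesh a `surface_mesh`.
#' @param centerlines named list of `centerline` objects; `MPA` is required,
#'   `LPA`/`RPA` optional.
#' @param junction_scale radius-scaled divergence threshold (default 1.0).
#' @return a `segment_labeling`.
#' @export
split_branches <- function(mesh, centerlines, junction_scale = 1.0) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (is.null(centerlines$MPA)) stop("an MPA centerline is required")
  branch_names <- intersect(c("MPA", "LPA", "RPA"), names(centerlines))
  centerlines <- .truncate_full_paths(mesh, centerlines, junction_scale)
  d <- vapply(branch_names, function(nm)
    nearest_centerline_point(mesh$vertices, centerlines[[nm]])$dist,
    numeric(nrow(mesh$vertices)))
  # column order MPA, LPA, RPA => ties resolve to the lower enum order
  which_br <- max.col(-d, ties.method = "first")
  segment_labeling(branch_names[which_br], vertex_areas(mesh))
}

#' Add flow extensions to open inlet/outlet boundaries
#'
#' Each open boundary loop is extruded along its outward best-fit normal as a
#' constant cross-section sleeve of length `length_factor` times the local
#' diameter (default 5x, the standard rule for developing the flow field
#' before it reaches the analysis region). Extension points are labeled
#' `"extension"`.
#'
#' @param mesh a `surface_mesh` with open boundaries.
#' @param labeling optional `segment_labeling` for the input mesh points; if
#'   omitted, all original points keep label `"MPA"`.
#' @param diameters optional numeric vector overriding the measured diameter
#'   of each boundary loop (cm), recycled.
#' @param length_factor extension length as a multiple of diameter.
#' @param n_rings rings per extension sleeve.
#' @return list with `mesh` (extended `surface_mesh`), `labeling`
#'   (`segment_labeling` covering old + extension points) and `extensions`
#'   (data.frame: loop id, diameter, length).
#' @export
add_flow_extensions <- function(mesh, labeling = NULL, diameters = NULL,
                                length_factor = 5, n_rings = 10L) {
  stopifnot(inherits(mesh, "surface_mesh"))
  loops <- boundary_loops(mesh)
  if (length(loops) == 0L) stop("mesh has no open boundaries to extend")
  base_labels <- if (is.null(labeling)) rep("MPA", nrow(mesh$vertices))
    else as.character(labeling$labels)
  verts <- mesh$vertices
  tris <- mesh$triangles
  mesh_center <- colMeans(mesh$vertices)
  info <- data.frame(loop = integer(0), diameter = numeric(0),
                     length = numeric(0))
  new_labels <- character(0)
  for (li in seq_along(loops)) {
    loop <- loops[[li]]
    lp <- mesh$vertices[loop, , drop = FALSE]
    ctr <- colMeans(lp)
    cen <- sweep(lp, 2, ctr)
    sv <- svd(cen)
    normal <- sv$v[, 3]
    planarity <- sv$d[3] / max(sv$d[1], .Machine$double.eps)
    if (planarity > 0.05)
      warning("non-planar boundary loop; extruding along best-fit normal")
    if (sum(normal * (ctr - mesh_center)) < 0) normal <- -normal
    diam <- if (!is.null(diameters))
      diameters[(li - 1L) %% length(diameters) + 1L]
    else 2 * mean(sqrt(rowSums(cen^2)))
    ext_len <- length_factor * diam
    m <- length(loop)
    prev_ring <- loop
    for (k in seq_len(n_rings)) {
      ring_pts <- sweep(lp, 2, normal * (ext_len * k / n_rings), "+")
      idx0 <- nrow(verts)
      verts <- rbind(verts, ring_pts)
      new_labels <- c(new_labels, rep("extension", m))
      ring <- idx0 + seq_len(m)
      for (j in seq_len(m)) {
        jn <- if (j == m) 1L else j + 1L
        tris <- rbind(tris,
                      c(prev_ring[j], prev_ring[jn], ring[j]),
                      c(prev_ring[jn], ring[jn], ring[j]))
      }
      prev_ring <- ring
    }
    info <- rbind(info, data.frame(loop = li, diameter = diam,
                                   length = ext_len))
  }
  out <- surface_mesh(verts, tris)
  list(mesh = out,
       labeling = segment_labeling(c(base_labels, new_labels),
                                   vertex_areas(out)),
       extensions = info)
}

#' Trim flow extensions from per-point data
#'
#' Removes points labeled `"extension"`, leaving the analysis region
#' (MPA + LPA + RPA) unchanged. Works on per-point vectors/matrices, on
#' meshes, and on wall-shear fields (which carry their own labeling).
#'
#' @param x per-point numeric vector or matrix (rows = points), a
#'   `surface_mesh`, a `wss_field`, or a `wss_steady_field`.
#' @param labeling a `segment_labeling` covering the points of `x` (not
#'   needed for field objects, which carry one).
#' @param ... unused.
#' @return object of the same kind restricted to non-extension points. Field
#'   and mesh results carry the trimmed labeling.
#' @export
trim_extensions <- function(x, labeling = NULL, ...) UseMethod("trim_extensions")

.keep_mask <- function(labeling, n) {
  stopifnot(inherits(labeling, "segment_labeling"))
  if (length(labeling$labels) != n) stop("labeling does not cover the points")
  keep <- labeling$labels != "extension"
  if (!any(keep)) stop("empty analysis region after trimming")
  keep
}

#' @export
trim_extensions.default <- function(x, labeling = NULL, ...) {
  if (is.matrix(x)) {
    keep <- .keep_mask(labeling, nrow(x))
    x[keep, , drop = FALSE]
  } else {
    keep <- .keep_mask(labeling, length(x))
    x[keep]
  }
}

#' @export
trim_extensions.surface_mesh <- function(x, labeling = NULL, ...) {
  keep <- .keep_mask(labeling, nrow(x$vertices))
  new_id <- cumsum(keep)
  tri_keep <- apply(matrix(keep[x$triangles], ncol = 3L), 1L, all)
  tris <- matrix(new_id[x$triangles[tri_keep, , drop = FALSE]], ncol = 3L)
  mesh <- surface_mesh(x$vertices[keep, , drop = FALSE], tris)
  lab <- segment_labeling(labeling$labels[keep], vertex_areas(mesh))
  list(mesh = mesh, labeling = lab)
}
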