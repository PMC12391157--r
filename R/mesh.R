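#' Triangulated surface mesh
#'
#' Minimal container for a vessel-wall triangle mesh in cm.
#'
#' @param vertices numeric matrix (n x 3), coordinates in cm.
#' @param triangles integer matrix (m x 3), 1-based vertex indices.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, triangles) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  stopifnot(ncol(vertices) == 3L, ncol(triangles) == 3L)
  if (!all(is.finite(vertices))) stop("mesh vertices must be finite")
  if (min(triangles) < 1L || max(triangles) > nrow(vertices))
    stop("triangle indices out of range")
  structure(list(vertices = vertices, triangles = triangles),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d triangles, area %.3f cm^2\n",
              nrow(x$vertices), nrow(x$triangles), sum(triangle_areas(x))))
  invisible(x)
}

#' Per-triangle areas of a surface mesh
#' @param mesh a `surface_mesh`.
#' @return numeric vector of areas (cm^2), one per triangle.
#' @export
triangle_areas <- function(mesh) {
  v <- mesh$vertices
  tr <- mesh$triangles
  a <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Per-vertex areas (one third of incident triangle areas)
#' @param mesh a `surface_mesh`.
#' @return numeric vector of areas (cm^2), one per vertex; sums to the total
#'   wall area.
#' @export
vertex_areas <- function(mesh) {
  ta <- triangle_areas(mesh) / 3
  va <- numeric(nrow(mesh$vertices))
  for (k in 1:3) {
    acc <- tapply(ta, mesh$triangles[, k], sum)
    idx <- as.integer(names(acc))
    va[idx] <- va[idx] + as.numeric(acc)
  }
  va
}

# Open boundary loops of a mesh: edges used by exactly one triangle, grouped
# into ordered closed loops. Returns a list of integer vertex-index vectors.
boundary_loops <- function(mesh) {
  tr <- mesh$triangles
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key)
  open_keys <- names(cnt)[cnt == 1L]
  if (length(open_keys) == 0L) return(list())
  open <- e[key %in% open_keys, , drop = FALSE]
  # walk loops: adjacency from boundary edges (each boundary vertex has 2)
  adj <- split(c(open[, 2], open[, 1]), c(open[, 1], open[, 2]))
  loops <- list()
  visited <- character(0)
  for (start in unique(as.vector(open))) {
    if (as.character(start) %in% visited) next
    loop <- start
    prev <- NA_integer_
    cur <- start
    repeat {
      nb <- adj[[as.character(cur)]]
      nxt <- nb[is.na(prev) | nb != prev][1L]
      if (is.na(nxt) || nxt == start) break
      loop <- c(loop, nxt)
      prev <- cur
      cur <- nxt
      if (length(loop) > nrow(open) + 1L) stop("non-manifold boundary loop")
    }
    visited <- c(visited, as.character(loop))
    loops[[length(loops) + 1L]] <- loop
  }
  loops
}

# Merge a list of surface meshes into one (vertex indices offset).
merge_meshes <- function(meshes) {
  offs <- cumsum(c(0L, vapply(meshes, function(m) nrow(m$vertices),
                              integer(1))))
  verts <- do.call(rbind, lapply(meshes, `[[`, "vertices"))
  tris <- do.call(rbind, Map(function(m, o) m$triangles + o,
                             meshes, offs[-length(offs)]))
  surface_mesh(verts, tris)
}
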