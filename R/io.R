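#' Write a surface mesh as ASCII STL
#'
#' @param mesh a `surface_mesh`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  v <- mesh$vertices; tr <- mesh$triangles
  a <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  nx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  ny <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  nz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  nn <- pmax(sqrt(nx^2 + ny^2 + nz^2), .Machine$double.eps)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid vessel", con)
  for (i in seq_len(nrow(tr))) {
    writeLines(c(
      sprintf("  facet normal %.9g %.9g %.9g",
              nx[i] / nn[i], ny[i] / nn[i], nz[i] / nn[i]),
      "    outer loop",
      sprintf("      vertex %.9g %.9g %.9g",
              v[tr[i, ], 1], v[tr[i, ], 2], v[tr[i, ], 3]),
      "    endloop", "  endfacet"), con)
  }
  writeLines("endsolid vessel", con)
  invisible(path)
}

.xml_num <- function(x) paste(format(x, digits = 12, trim = TRUE,
                                     scientific = FALSE), collapse = " ")

#' Write a surface mesh (with optional point data) as VTK XML PolyData
#'
#' Minimal ASCII `.vtp` writer: points, triangle connectivity, optional
#' named per-point scalar or 3-vector arrays, and an optional `TimeValue`
#' field-data annotation.
#'
#' @param mesh a `surface_mesh` (or NULL to write a point cloud given
#'   `points`).
#' @param path output `.vtp` path.
#' @param point_data named list of per-point numeric vectors (scalars) or
#'   n x 3 matrices (vectors).
#' @param time_value optional time annotation in s.
#' @param points used when `mesh` is NULL: n x 3 matrix.
#' @return `path`, invisibly.
#' @export
write_vtp <- function(mesh, path, point_data = list(), time_value = NULL,
                      points = NULL) {
  if (is.null(mesh)) {
    v <- as.matrix(points)
    tr <- matrix(integer(0), 0L, 3L)
  } else {
    v <- mesh$vertices
    tr <- mesh$triangles
  }
  lines <- c(
    '<?xml version="1.0"?>',
    '<VTKFile type="PolyData" version="0.1" byte_order="LittleEndian">',
    "<PolyData>")
  if (!is.null(time_value)) {
    lines <- c(lines, "<FieldData>",
      paste0('<DataArray type="Float64" Name="TimeValue" ',
             'NumberOfTuples="1" format="ascii">'),
      .xml_num(time_value), "</DataArray>", "</FieldData>")
  }
  lines <- c(lines, sprintf(
    '<Piece NumberOfPoints="%d" NumberOfVerts="0" NumberOfLines="0" NumberOfStrips="0" NumberOfPolys="%d">',
    nrow(v), nrow(tr)),
    "<Points>",
    '<DataArray type="Float64" NumberOfComponents="3" format="ascii">',
    .xml_num(t(v)), "</DataArray>", "</Points>")
  if (length(point_data)) {
    lines <- c(lines, "<PointData>")
    for (nm in names(point_data)) {
      arr <- point_data[[nm]]
      ncomp <- if (is.matrix(arr)) ncol(arr) else 1L
      dat <- if (is.matrix(arr)) .xml_num(t(arr)) else .xml_num(arr)
      lines <- c(lines, sprintf(
        '<DataArray type="Float64" Name="%s" NumberOfComponents="%d" format="ascii">',
        nm, ncomp), dat, "</DataArray>")
    }
    lines <- c(lines, "</PointData>")
  }
  lines <- c(lines, "<Polys>",
    '<DataArray type="Int64" Name="connectivity" format="ascii">',
    if (nrow(tr)) .xml_num(as.vector(t(tr)) - 1L) else "",
    "</DataArray>",
    '<DataArray type="Int64" Name="offsets" format="ascii">',
    if (nrow(tr)) .xml_num(3L * seq_len(nrow(tr))) else "",
    "</DataArray>", "</Polys>", "</Piece>", "</PolyData>", "</VTKFile>")
  writeLines(lines, path)
  invisible(path)
}

#' Read a VTK XML PolyData file
#'
#' Counterpart of [write_vtp()]; reads points, triangle connectivity,
#' per-point data arrays and the `TimeValue` annotation.
#'
#' @param path `.vtp` file path.
#' @return list: `mesh` (`surface_mesh`, or NULL if no polys), `points`,
#'   `point_data` (named list), `time_value` (or NA).
#' @export
read_vtp <- function(path) {
  doc <- xml2::read_xml(path)
  num <- function(node) {
    if (length(node) == 0) return(numeric(0))
    as.numeric(strsplit(trimws(xml2::xml_text(node)), "\\s+")[[1]])
  }
  pts_node <- xml2::xml_find_first(doc, ".//Points/DataArray")
  pts <- matrix(num(pts_node), ncol = 3L, byrow = TRUE)
  conn <- num(xml2::xml_find_first(doc,
    ".//Polys/DataArray[@Name='connectivity']"))
  mesh <- if (length(conn)) {
    surface_mesh(pts, matrix(conn + 1L, ncol = 3L, byrow = TRUE))
  } else NULL
  pd <- list()
  for (node in xml2::xml_find_all(doc, ".//PointData/DataArray")) {
    nm <- xml2::xml_attr(node, "Name")
    ncomp <- as.integer(xml2::xml_attr(node, "NumberOfComponents"))
    if (is.na(ncomp)) ncomp <- 1L
    vals <- num(node)
    pd[[nm]] <- if (ncomp > 1L) matrix(vals, ncol = ncomp, byrow = TRUE)
      else vals
  }
  tv_node <- xml2::xml_find_first(doc,
    ".//FieldData/DataArray[@Name='TimeValue']")
  tv <- if (inherits(tv_node, "xml_missing")) NA_real_ else num(tv_node)
  list(mesh = mesh, points = pts, point_data = pd, time_value = tv)
}

#' Write a wall-shear time series to disk
#'
#' `format = "vtp"` writes one PolyData file per timepoint (point
#' coordinates, a 3-component `WSS` array, per-point `area` and `label`
#' codes, and the `TimeValue` annotation). `format = "csv"` writes a single
#' long table `point_id, x, y, z, area, label, t, wx, wy, wz`.
#'
#' @param field a `wss_field`.
#' @param dir output directory (created if needed).
#' @param format `"vtp"` or `"csv"`.
#' @param prefix file-name prefix.
#' @return character vector of written file paths, invisibly.
#' @export
write_wss_series <- function(field, dir, format = c("vtp", "csv"),
                             prefix = "wss") {
  stopifnot(inherits(field, "wss_field"))
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lab_codes <- as.integer(field$labeling$labels)
  if (format == "csv") {
    n <- nrow(field$wall_points); nt <- length(field$times)
    df <- data.frame(
      point_id = rep(seq_len(n), nt),
      x = rep(field$wall_points[, 1], nt),
      y = rep(field$wall_points[, 2], nt),
      z = rep(field$wall_points[, 3], nt),
      area = rep(field$areas, nt),
      label = rep(as.character(field$labeling$labels), nt),
      t = rep(field$times, each = n),
      wx = as.vector(field$vectors[, 1, ]),
      wy = as.vector(field$vectors[, 2, ]),
      wz = as.vector(field$vectors[, 3, ]))
    path <- file.path(dir, paste0(prefix, "_series.csv"))
    write.csv(df, path, row.names = FALSE)
    return(invisible(path))
  }
  paths <- character(length(field$times))
  for (i in seq_along(field$times)) {
    paths[i] <- file.path(dir, sprintf("%s_%03d.vtp", prefix, i))
    write_vtp(NULL, paths[i], points = field$wall_points,
              point_data = list(WSS = field$vectors[, , i],
                                area = field$areas,
                                label = lab_codes),
              time_value = field$times[i])
  }
  invisible(paths)
}

#' Load an externally computed wall-shear time series
#'
#' Assembles a `wss_field` from per-timepoint VTP files (e.g. exported CFD
#' results) or from the long-format CSV written by [write_wss_series()].
#' VTP files are reordered by their embedded `TimeValue`; all files must
#' share point count and ordering and carry a `WSS` vector array.
#'
#' @param files character vector of `.vtp` paths (any order), or a single
#'   `.csv` path.
#' @param labeling optional `segment_labeling` overriding labels stored in
#'   the files (VTP files without a `label` array default to MPA).
#' @param period optional cycle length in s.
#' @return a [wss_field()].
#' @export
load_external_wss_series <- function(files, labeling = NULL, period = NULL) {
  if (length(files) == 1L && grepl("\\.csv$", files)) {
    df <- read.csv(files)
    need <- c("point_id", "t", "wx", "wy", "wz")
    if (!all(need %in% names(df)))
      stop("missing columns in WSS series CSV: ",
           paste(setdiff(need, names(df)), collapse = ", "))
    times <- sort(unique(df$t))
    df <- df[order(df$t, df$point_id), ]
    n <- length(unique(df$point_id))
    if (nrow(df) != n * length(times))
      stop("inconsistent point set across timepoints in ", files)
    first <- df[df$t == times[1L], ]
    vectors <- array(0, dim = c(n, 3L, length(times)))
    vectors[, 1, ] <- matrix(df$wx, n)
    vectors[, 2, ] <- matrix(df$wy, n)
    vectors[, 3, ] <- matrix(df$wz, n)
    lab <- if (!is.null(labeling)) labeling
      else segment_labeling(first$label, first$area)
    return(wss_field(cbind(first$x, first$y, first$z), first$area, times,
                     vectors, lab, period = period))
  }
  reads <- lapply(files, read_vtp)
  tv <- vapply(reads, `[[`, numeric(1), "time_value")
  if (anyNA(tv)) stop("missing TimeValue annotation in: ",
                      paste(files[is.na(tv)], collapse = ", "))
  ord <- order(tv)
  reads <- reads[ord]; tv <- tv[ord]; files <- files[ord]
  n <- nrow(reads[[1L]]$points)
  for (i in seq_along(reads)) {
    if (nrow(reads[[i]]$points) != n)
      stop(sprintf("point-count mismatch in %s (%d vs %d)",
                   files[i], nrow(reads[[i]]$points), n))
    if (is.null(reads[[i]]$point_data$WSS))
      stop("missing WSS array in ", files[i])
  }
  vectors <- array(0, dim = c(n, 3L, length(reads)))
  for (i in seq_along(reads)) vectors[, , i] <- reads[[i]]$point_data$WSS
  pd <- reads[[1L]]$point_data
  areas <- if (!is.null(pd$area)) pd$area else rep(1, n)
  lab <- if (!is.null(labeling)) labeling
    else if (!is.null(pd$label))
      segment_labeling(c("MPA", "LPA", "RPA", "extension")[pd$label], areas)
    else segment_labeling(rep("MPA", n), areas)
  wss_field(reads[[1L]]$points, areas, tv, vectors, lab, period = period)
}

#' Write a flow waveform as CSV
#'
#' Two columns, `time_s` and `flow_ml_s` (mL/s and cm^3/s are the same
#' unit).
#'
#' @param waveform a `flow_waveform`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_waveform_csv <- function(waveform, path) {
  stopifnot(inherits(waveform, "flow_waveform"))
  write.csv(data.frame(time_s = waveform$times, flow_ml_s = waveform$flows),
            path, row.names = FALSE)
  invisible(path)
}

#' Read a flow waveform from CSV
#'
#' @param path CSV with columns `time_s` and `flow_ml_s`.
#' @param heart_rate optional beats/min (inferred from sample spacing when
#'   omitted).
#' @return a `flow_waveform`.
#' @export
read_waveform_csv <- function(path, heart_rate = NULL) {
  df <- read.csv(path)
  if (!all(c("time_s", "flow_ml_s") %in% names(df)))
    stop("waveform CSV needs columns time_s, flow_ml_s")
  flow_waveform(df$time_s, df$flow_ml_s, heart_rate)
}

#' Write centerline coordinates as CSV
#' @param line a `centerline`.
#' @param path output CSV path (columns x, y, z).
#' @return `path`, invisibly.
#' @export
write_centerline_csv <- function(line, path) {
  stopifnot(inherits(line, "centerline"))
  df <- as.data.frame(line$points)
  names(df) <- c("x", "y", "z")
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a centerline from CSV (columns x, y, z)
#' @param path CSV path.
#' @return a `centerline`.
#' @export
read_centerline_csv <- function(path) centerline(read.csv(path))
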