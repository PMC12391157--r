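test_that("resampling yields uniform arclength steps and preserved endpoints", {
  line <- centerline(cbind(0, 0, seq(0, 5, by = 0.5)))
  rs <- resample_centerline(line, 0.1)
  expect_equal(nrow(rs$points), 51L)
  expect_equal(rs$points[1, ], line$points[1, ])
  expect_equal(rs$points[51, ], line$points[11, ])
  gaps <- diff(rs$arclength)
  expect_true(all(abs(gaps[-length(gaps)] - 0.1) < 1e-9))
  expect_lte(gaps[length(gaps)], 0.1 + 1e-9)

  # curved line: resampled length within one step of the original polyline
  th <- seq(0, pi, length.out = 300)
  arc <- centerline(cbind(2 * cos(th), 2 * sin(th), 0))
  rs2 <- resample_centerline(arc, 0.1)
  expect_lt(abs(total_length(rs2) - total_length(arc)), 0.1)
  expect_equal(rs2$points[1, ], arc$points[1, ])
  expect_equal(rs2$points[nrow(rs2$points), ], arc$points[300, ])
})

test_that("resampling with an over-long step degrades to endpoints with warning", {
  line <- centerline(cbind(0, 0, c(0, 1, 2)))
  expect_warning(rs <- resample_centerline(line, 10), "endpoints")
  expect_equal(nrow(rs$points), 2L)
})

test_that("curvature matches closed forms for circle, helix, straight line", {
  # circle of radius 2: kappa = 1/2 everywhere (input sampled densely
  # so linear-interpolation sag does not pollute the spline derivatives)
  th <- seq(0, pi, length.out = 2000)
  arc <- resample_centerline(
    centerline(cbind(2 * cos(th), 2 * sin(th), 0)), 0.1)
  cp <- curvature_profile(arc)
  expect_lt(abs(cp$mean_kappa - 0.5) / 0.5, 0.01)
  interior <- 11:(length(cp$kappa) - 10)   # spline end bias excluded
  expect_lt(max(abs(cp$kappa[interior] - 0.5)) / 0.5, 0.01)

  # helix x = cos t, y = sin t, z = t: kappa = r/(r^2 + c^2) = 1/2
  t <- seq(0, 4 * pi, length.out = 2000)
  hx <- resample_centerline(centerline(cbind(cos(t), sin(t), t)), 0.1)
  cph <- curvature_profile(hx)
  expect_lt(abs(cph$mean_kappa - 0.5) / 0.5, 0.01)

  # straight line: exactly zero (degenerate collinear case, not NaN)
  st <- resample_centerline(centerline(cbind(1, 2, seq(0, 5, by = 0.05))), 0.1)
  cps <- curvature_profile(st)
  expect_identical(max(cps$kappa), 0)
  expect_false(anyNA(cps$kappa))
})

test_that("curvature converges toward the closed form as the step shrinks", {
  th <- seq(0, pi, length.out = 3000)
  arc <- centerline(cbind(2 * cos(th), 2 * sin(th), 0))
  err <- vapply(c(0.2, 0.1, 0.05), function(h) {
    cp <- curvature_profile(resample_centerline(arc, h))
    abs(cp$mean_kappa - 0.5)
  }, numeric(1))
  expect_lt(err[2], 0.005)
  expect_lt(err[3], err[1])
})

test_that("tortuosity matches arc/chord closed forms and handles degeneracy", {
  # straight
  expect_equal(tortuosity(centerline(cbind(0, 0, 0:5)))$tortuosity, 0)
  # semicircle radius 2: pi/2 - 1
  th <- seq(0, pi, length.out = 2000)
  semi <- tortuosity(centerline(cbind(2 * cos(th), 2 * sin(th), 0)))
  expect_lt(abs(semi$tortuosity - (pi / 2 - 1)) / (pi / 2 - 1), 0.001)
  # quarter circle: (pi/4)/(sqrt(2)/2) - 1
  thq <- seq(0, pi / 2, length.out = 2000)
  quart <- tortuosity(centerline(cbind(cos(thq), sin(thq), 0)))
  expect_equal(quart$tortuosity, pi / (2 * sqrt(2)) - 1, tolerance = 1e-4)
  # closed loop rejected
  loop <- centerline(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 0, 0)))
  expect_error(tortuosity(loop), "coincide")
})

test_that("tortuosity is invariant under rigid motion and uniform scaling", {
  set.seed(11)
  th <- seq(0, 2, length.out = 200)
  pts <- cbind(2 * cos(th), 2 * sin(th), 0.3 * th)
  base <- tortuosity(centerline(pts))$tortuosity
  # random rotation (QR of a random matrix), translation, scale
  for (rep in 1:5) {
    q <- qr.Q(qr(matrix(rnorm(9), 3)))
    s <- runif(1, 0.2, 5)
    moved <- s * pts %*% q + matrix(rnorm(3), 200, 3, byrow = TRUE)
    expect_equal(tortuosity(centerline(moved))$tortuosity, base,
                 tolerance = 1e-9)
  }
})

test_that("branch splitting recovers construction labels and partitions area", {
  geo <- small_bifurcation()
  lab <- split_branches(geo$mesh, geo$centerlines)
  expect_setequal(as.character(unique(lab$labels)), c("MPA", "LPA", "RPA"))
  agree <- mean(as.character(lab$labels) ==
                  as.character(geo$labeling$labels))
  expect_gte(agree, 0.95)
  expect_equal(sum(lab$areas), sum(triangle_areas(geo$mesh)),
               tolerance = 1e-9)

  # full inlet-to-outlet paths sharing the trunk prefix also work
  full <- list(
    MPA = geo$centerlines$MPA,
    LPA = join_centerlines(geo$centerlines$MPA, geo$centerlines$LPA),
    RPA = join_centerlines(geo$centerlines$MPA, geo$centerlines$RPA))
  lab2 <- split_branches(geo$mesh, full)
  expect_gte(mean(as.character(lab2$labels) ==
                    as.character(geo$labeling$labels)), 0.95)
})

test_that("branch splitting is deterministic and invariant to point order", {
  geo <- small_bifurcation()
  lab1 <- split_branches(geo$mesh, geo$centerlines)
  lab2 <- split_branches(geo$mesh, geo$centerlines)
  expect_identical(lab1$labels, lab2$labels)
  set.seed(5)
  perm <- sample(nrow(geo$mesh$vertices))
  inv <- integer(length(perm)); inv[perm] <- seq_along(perm)
  mesh_p <- surface_mesh(geo$mesh$vertices[perm, ],
                         matrix(inv[geo$mesh$triangles], ncol = 3))
  lab3 <- split_branches(mesh_p, geo$centerlines)
  expect_identical(as.character(lab3$labels)[inv],
                   as.character(lab1$labels))
})

test_that("a single tube with only an MPA centerline is all MPA", {
  tg <- make_tube_geometry(tube_spec(function(t) cbind(0, 0, 5 * t), 1,
                                     12L, 10L))
  lab <- split_branches(tg$mesh, list(MPA = tg$centerline))
  expect_true(all(lab$labels == "MPA"))
})

test_that("flow extensions are five diameters long and round-trip cleanly", {
  for (r in c(1.0, 0.75)) {  # diameters 2.0 and 1.5 -> lengths 10 and 7.5
    tg <- make_tube_geometry(tube_spec(function(t) cbind(0, 0, 5 * t), r,
                                       12L, 12L))
    lab0 <- segment_labeling(rep("MPA", nrow(tg$mesh$vertices)),
                             vertex_areas(tg$mesh))
    ext <- add_flow_extensions(tg$mesh, lab0)
    expect_equal(ext$extensions$diameter, rep(2 * r, 2), tolerance = 1e-6)
    expect_equal(ext$extensions$length, rep(10 * r, 2), tolerance = 1e-6)
    trimmed <- trim_extensions(ext$mesh, ext$labeling)
    expect_equal(trimmed$mesh$vertices, tg$mesh$vertices)
  }
})

test_that("trimming removes extension values and preserves the rest", {
  lab <- segment_labeling(c("MPA", "LPA", "extension", "RPA", "extension"),
                          rep(1, 5))
  x <- c(1, 2, 3, 4, 5)
  expect_equal(trim_extensions(x, lab), c(1, 2, 4))
  # no extension points: identity
  lab2 <- segment_labeling(c("MPA", "LPA"), c(1, 1))
  expect_identical(trim_extensions(c(7, 8), lab2), c(7, 8))
  # everything trimmed: error
  lab3 <- segment_labeling(c("extension", "extension"), c(1, 1))
  expect_error(trim_extensions(c(1, 2), lab3), "empty analysis region")
})

test_that("whole-vessel area after trimming equals the sum of segment areas", {
  geo <- small_bifurcation()
  lab0 <- geo$labeling
  ext <- add_flow_extensions(
    make_tube_geometry(tube_spec(function(t) cbind(0, 0, 4 * t), 1,
                                 10L, 10L))$mesh)
  keep <- trim_extensions(ext$labeling$areas, ext$labeling)
  seg <- segment_summary(rep(1, sum(lab0$labels != "extension")), lab0)
  whole <- seg$area[seg$region == "whole"]
  expect_equal(whole, sum(seg$area[seg$region != "whole"]), tolerance = 1e-9)
})
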