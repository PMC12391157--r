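test_that("Poiseuille wall shear follows 4 mu Q / (pi R^3)", {
  expect_equal(poiseuille_wall_shear(78.54, 1), 4.00, tolerance = 1e-4)
  expect_equal(poiseuille_wall_shear(0, 1), 0)
  expect_equal(poiseuille_wall_shear(100, 2), poiseuille_wall_shear(100, 1) / 8)
  expect_equal(poiseuille_wall_shear(-50, 1), -poiseuille_wall_shear(50, 1))
  expect_error(poiseuille_wall_shear(10, 0), "positive")
})

test_that("Womersley number matches its definition", {
  expect_equal(womersley_number(1, 2 * pi * 75 / 60), 14.43, tolerance = 1e-3)
})

test_that("DC-only flow gives constant Poiseuille shear at all times", {
  n <- 32
  wf <- flow_waveform((0:(n - 1)) * 0.8 / n, rep(60, n), 75)
  ff <- fourier_decompose(wf, 10)
  tau <- womersley_wall_shear(ff, 1.1, times = (0:19) * 0.8 / 20)
  expect_equal(tau, rep(poiseuille_wall_shear(60, 1.1), 20), tolerance = 1e-12)
})

test_that("Womersley shear approaches the quasi-static limit as alpha -> 0", {
  period <- 6000                      # alpha_1 = 0.17 at R = 1 cm
  t <- seq(0, period, length.out = 61)[-61]
  wf <- flow_waveform(t, 50 + 20 * cos(2 * pi * t / period),
                      heart_rate = 60 / period)
  ff <- fourier_decompose(wf, 3)
  te <- seq(0, period, length.out = 9)[-9]
  tau <- womersley_wall_shear(ff, 1, times = te)
  quasi <- poiseuille_wall_shear(reconstruct_waveform(ff, te), 1)
  expect_lt(max(abs(tau - quasi) / abs(quasi)), 0.01)
})

test_that("cycle-mean Womersley shear equals Poiseuille of the mean flow", {
  wf <- make_flow_waveform(waveform_spec(forward_volume = 120,
                                         regurgitant_fraction = 0.4))
  ff <- fourier_decompose(wf, 10)
  for (R in c(0.6, 1.0, 1.4)) {
    tau <- womersley_wall_shear(ff, R, times = (0:19) * wf$period / 20)
    expect_equal(mean(tau), poiseuille_wall_shear(Re(ff$modes[1]), R),
                 tolerance = 1e-6)
  }
})

test_that("the high-alpha asymptotic branch stays finite and consistent", {
  fl <- fluid_properties()
  g <- pahemo:::womersley_gain(c(59, 61), c(1, 1), fl)
  # continuity across the series/asymptotic switch
  expect_lt(abs(Mod(g[2]) - Mod(g[1])) / Mod(g[1]), 0.1)
  g_big <- pahemo:::womersley_gain(c(150, 500, 2000), rep(1, 3), fl)
  expect_true(all(is.finite(Re(g_big)) & is.finite(Im(g_big))))
  # |gain| grows like mu * alpha / (pi R^3) in the inviscid-core limit
  expect_equal(Mod(g_big[3]) * pi / fl$viscosity, 2000, tolerance = 0.01 * 2000)
})

test_that("complex Bessel series matches known real-axis values", {
  # cross-check against base R besselJ on the real axis
  z <- c(0.5, 2, 7.3, 24)
  js <- pahemo:::besselj01_complex(complex(real = z))
  # series cancellation limits absolute accuracy to ~1e-9 near |z| = 24
  expect_equal(Re(js$J0), besselJ(z, 0), tolerance = 1e-6)
  expect_equal(Re(js$J1), besselJ(z, 1), tolerance = 1e-6)
  expect_lt(max(abs(Im(js$J0))), 1e-12)
})

test_that("synthesized fields: steady-mode constancy and branch symmetry", {
  geo <- small_bifurcation()
  n <- 32
  wf <- flow_waveform((0:(n - 1)) * 0.8 / n, rep(90, n), 75)
  ff <- fourier_decompose(wf, 10)
  fld <- synthesize_wss_field(geo$mesh, geo$centerlines, ff,
                              labeling = geo$labeling,
                              resistances = resistance_network(c(LPA = 2,
                                                                 RPA = 2)))
  spread <- apply(fld$vectors, 1, function(m) max(abs(m - m[, 1])))
  expect_lt(max(spread), 1e-9)

  # mirror-symmetric branches with equal resistance: identical WSS
  sym <- make_pa_bifurcation(default_pa_spec(
    lpa_radius = 0.85, rpa_radius = 0.85, lpa_arc_radius = 2.4,
    rpa_arc_radius = 2.4, lpa_sweep = 1.3, rpa_sweep = 1.3,
    axial_samples = 24L, circumferential_samples = 12L))
  wf2 <- make_flow_waveform(waveform_spec())
  ff2 <- fourier_decompose(wf2, 10)
  fld2 <- synthesize_wss_field(sym$mesh, sym$centerlines, ff2,
                               labeling = sym$labeling)
  mag <- sqrt(fld2$vectors[, 1, ]^2 + fld2$vectors[, 2, ]^2 +
                fld2$vectors[, 3, ]^2)
  l_idx <- sym$labeling$labels == "LPA"
  r_idx <- sym$labeling$labels == "RPA"
  expect_equal(mag[l_idx, ], mag[r_idx, ], tolerance = 1e-9)
})

test_that("smaller-radius branch carries higher wall shear at equal flow", {
  geo <- small_bifurcation()   # LPA radius < RPA radius, equal resistances
  st <- synthesize_steady_wss(geo$mesh, geo$centerlines, 115,
                              labeling = geo$labeling)
  s <- segment_summary(st$scalars, st$labeling)
  expect_gt(s$avg[s$region == "LPA"], s$avg[s$region == "RPA"])
})

test_that("segment-averaged WSS is stable under mesh refinement", {
  run_at <- function(ax, ci) {
    g <- make_pa_bifurcation(default_pa_spec(axial_samples = ax,
                                             circumferential_samples = ci))
    st <- synthesize_steady_wss(g$mesh, g$centerlines, 115,
                                labeling = g$labeling)
    segment_summary(st$scalars, st$labeling)$avg
  }
  coarse <- run_at(30L, 16L)
  fine <- run_at(45L, 24L)
  expect_lt(max(abs(coarse - fine) / coarse), 0.01)
})

test_that("external WSS series round-trips through VTP and CSV", {
  geo <- small_bifurcation()
  wf <- make_flow_waveform(waveform_spec())
  ff <- fourier_decompose(wf, 10)
  fld <- synthesize_wss_field(geo$mesh, geo$centerlines, ff,
                              labeling = geo$labeling)
  d <- withr::local_tempdir()
  paths <- write_wss_series(fld, d, format = "vtp")
  # shuffled file order: reordered by the embedded TimeValue
  back <- load_external_wss_series(rev(paths), period = fld$period)
  expect_equal(back$times, fld$times)
  expect_lt(max(abs(back$vectors - fld$vectors)), 1e-12)
  expect_equal(as.character(back$labeling$labels),
               as.character(fld$labeling$labels))
  csvp <- write_wss_series(fld, d, format = "csv")
  back2 <- load_external_wss_series(csvp, period = fld$period)
  expect_lt(max(abs(back2$vectors - fld$vectors)), 1e-12)
})

test_that("external series with inconsistent points or missing arrays error", {
  geo <- small_bifurcation()
  wf <- make_flow_waveform(waveform_spec())
  ff <- fourier_decompose(wf, 10)
  fld <- synthesize_wss_field(geo$mesh, geo$centerlines, ff,
                              labeling = geo$labeling)
  d <- withr::local_tempdir()
  paths <- write_wss_series(fld, d, format = "vtp")
  # corrupt one file: drop a point
  bad <- read_vtp(paths[3])
  write_vtp(NULL, paths[3], points = bad$points[-1, ],
            point_data = list(WSS = bad$point_data$WSS[-1, ]),
            time_value = bad$time_value)
  expect_error(load_external_wss_series(paths), "point-count mismatch.*_003")
  # single-timepoint series remains usable for steady metrics
  single <- load_external_wss_series(paths[1], labeling = fld$labeling)
  expect_equal(length(single$times), 1L)
  expect_equal(wss_at_timepoint(single, 1),
               sqrt(rowSums(fld$vectors[, , 1]^2)), tolerance = 1e-12)
})
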