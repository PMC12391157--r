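test_that("OSI extremes: unidirectional shear 0, fully reversing 0.5", {
  uni <- single_point_field(function(u) 10 + 5 * cos(2 * pi * u), 20L)
  expect_equal(osi_field(uni), 0)
  rev <- single_point_field(function(u) 5 * cos(2 * pi * u), 20L)
  expect_equal(osi_field(rev), 0.5, tolerance = 1e-9)
})

test_that("OSI nontrivial oracle: (1 + 2 cos) gives 0.152", {
  # closed form: mean |1 + 2 cos| over a cycle = 1/3 + 2 sqrt(3)/pi,
  # so OSI = (1 - 1/(1/3 + 2 sqrt(3)/pi))/2 = 0.15181
  fld <- single_point_field(function(u) 1 + 2 * cos(2 * pi * u), 2000L)
  expect_lt(abs(osi_field(fld) - 0.152), 0.001)
  expect_equal(osi_field(fld),
               0.5 * (1 - 1 / (1 / 3 + 2 * sqrt(3) / pi)),
               tolerance = 1e-5)
})

test_that("OSI is bounded, scale-invariant and zero only without reversal", {
  for (seed in 1:5) {
    fld <- random_field(seed = seed)
    osi <- osi_field(fld)
    expect_true(all(osi >= 0 & osi <= 0.5))
    # doubling magnitudes leaves OSI unchanged
    fld2 <- fld; fld2$vectors <- 2 * fld2$vectors
    expect_equal(osi_field(fld2), osi, tolerance = 1e-12)
  }
  # rotating direction without sign reversal keeps OSI below 0.5 but > 0
  n <- 36
  v <- array(0, dim = c(1, 3, n))
  th <- pi / 3 * sin(2 * pi * (0:(n - 1)) / n)
  v[1, 1, ] <- 8 * cos(th); v[1, 2, ] <- 8 * sin(th)
  fld3 <- wss_field(matrix(0, 1, 3), 1, (0:(n - 1)) / n, v,
                    segment_labeling("MPA", 1), period = 1)
  osi3 <- osi_field(fld3)
  expect_gt(osi3, 0)
  expect_lt(osi3, 0.5)
})

test_that("zero-shear points get OSI 0 with a warning", {
  fld <- single_point_field(function(u) rep(0, length(u)), 20L)
  expect_warning(osi <- osi_field(fld), "zero shear")
  expect_equal(osi, 0)
})

test_that("taWSS averages the magnitude and dominates the vector mean", {
  const <- single_point_field(function(u) rep(7.5, length(u)), 20L)
  expect_equal(tawss_field(const), 7.5)
  # A cos: mean magnitude 2A/pi
  fld <- single_point_field(function(u) 3 * cos(2 * pi * u), 4000L)
  expect_equal(tawss_field(fld), 2 * 3 / pi, tolerance = 1e-4)
  # triangle inequality against the mean vector, and linear scaling
  for (seed in 6:8) {
    rf <- random_field(seed = seed)
    ta <- tawss_field(rf)
    mv <- apply(rf$vectors, c(1, 2), mean)
    expect_true(all(ta >= sqrt(rowSums(mv^2)) - 1e-12))
    rf2 <- rf; rf2$vectors <- 2 * rf2$vectors
    expect_equal(tawss_field(rf2), 2 * ta, tolerance = 1e-12)
  }
})

test_that("timepoint slices select |WSS| at the requested output time", {
  rf <- random_field(seed = 12)
  s1 <- wss_at_timepoint(rf, 1)
  expect_equal(s1, sqrt(rowSums(rf$vectors[, , 1]^2)))
  expect_error(wss_at_timepoint(rf, 99), "out of range")
  # steady-only field: every slice equals the steady scalars
  const <- single_point_field(function(u) rep(4, length(u)), 20L)
  expect_equal(wss_at_timepoint(const, 1), wss_at_timepoint(const, 13))
})

test_that("systolic slice exceeds diastolic slice for a pulsatile case", {
  geo <- small_bifurcation()
  wf <- make_flow_waveform(waveform_spec())
  ff <- fourier_decompose(wf, 10)
  fld <- synthesize_wss_field(geo$mesh, geo$centerlines, ff,
                              labeling = geo$labeling)
  q20 <- approx(c(wf$times, wf$period), c(wf$flows, wf$flows[1]),
                xout = fld$times)$y
  sd <- find_systole_diastole(q20)
  sys <- segment_summary(wss_at_timepoint(fld, sd$systole_index),
                         fld$labeling)
  dia <- segment_summary(wss_at_timepoint(fld, sd$diastole_index),
                         fld$labeling)
  expect_true(all(sys$avg > dia$avg))
})

test_that("segment summaries: constants, weighted means, peak composition", {
  lab <- segment_labeling(c("MPA", "MPA", "LPA", "RPA", "RPA"),
                          c(2, 1, 3, 1, 1))
  s <- segment_summary(rep(4.2, 5), lab)
  expect_equal(s$avg, rep(4.2, 4))
  expect_equal(s$peak, rep(4.2, 4))
  x <- c(1, 2, 3, 4, 5)
  s2 <- segment_summary(x, lab)
  # whole-vessel avg is the area-weighted mean of segment avgs
  segs <- s2[s2$region != "whole", ]
  expect_equal(s2$avg[s2$region == "whole"],
               sum(segs$avg * segs$area) / sum(segs$area))
  expect_equal(s2$peak[s2$region == "whole"], max(segs$peak))
  expect_true(all(s2$peak >= s2$avg))
  # empty region omitted, not zero
  lab2 <- segment_labeling(c("MPA", "MPA"), c(1, 1))
  s3 <- segment_summary(c(1, 2), lab2)
  expect_false("LPA" %in% s3$region)
  # quantile peak is below the maximum
  s4 <- segment_summary(x, lab, peak_quantile = 0.75)
  expect_lt(s4$peak[s4$region == "whole"], max(x))
})

test_that("case summary: schema, steady-only path and symmetric branches", {
  geo <- small_bifurcation()
  wf <- make_flow_waveform(waveform_spec())
  ff <- fourier_decompose(wf, 10)
  st <- synthesize_steady_wss(geo$mesh, geo$centerlines, 100,
                              labeling = geo$labeling)
  pu <- synthesize_wss_field(geo$mesh, geo$centerlines, ff,
                             labeling = geo$labeling)
  full <- summarize_case(st, pu, wf)
  expect_setequal(full$region, c("whole", "MPA", "LPA", "RPA"))
  expect_true(all(c("wss_steady_avg", "wss_steady_peak", "tawss_avg",
                    "tawss_peak", "wss_systole_avg", "wss_systole_peak",
                    "wss_diastole_avg", "wss_diastole_peak", "osi_avg")
                  %in% names(full)))
  # steady-only: pulsatile columns absent, no error
  only <- summarize_case(st)
  expect_false("tawss_avg" %in% names(only))
  # symmetric branches agree to tight tolerance
  sym <- make_pa_bifurcation(default_pa_spec(
    lpa_radius = 0.85, rpa_radius = 0.85, lpa_arc_radius = 2.4,
    rpa_arc_radius = 2.4, lpa_sweep = 1.3, rpa_sweep = 1.3,
    axial_samples = 24L, circumferential_samples = 12L))
  sts <- synthesize_steady_wss(sym$mesh, sym$centerlines, 100,
                               labeling = sym$labeling)
  ss <- summarize_case(sts)
  expect_equal(ss$wss_steady_avg[ss$region == "LPA"],
               ss$wss_steady_avg[ss$region == "RPA"], tolerance = 1e-9)
})

test_that("narrowed left branch raises its steady WSS above the right", {
  narrowed <- make_pa_bifurcation(default_pa_spec(
    lpa_radius = 0.55, axial_samples = 24L, circumferential_samples = 12L))
  st <- synthesize_steady_wss(narrowed$mesh, narrowed$centerlines, 100,
                              labeling = narrowed$labeling)
  s <- summarize_case(st)
  expect_gt(s$wss_steady_avg[s$region == "LPA"],
            s$wss_steady_avg[s$region == "RPA"])
})

test_that("taWSS of a steady synthesized field equals the steady scalars", {
  geo <- small_bifurcation()
  n <- 32
  wf <- flow_waveform((0:(n - 1)) * 0.8 / n, rep(90, n), 75)
  ff <- fourier_decompose(wf, 10)
  fld <- synthesize_wss_field(geo$mesh, geo$centerlines, ff,
                              labeling = geo$labeling)
  st <- synthesize_steady_wss(geo$mesh, geo$centerlines, 90,
                              labeling = geo$labeling)
  expect_equal(tawss_field(fld), st$scalars, tolerance = 1e-9)
})
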