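test_that("adjusted linear fit recovers the generating coefficient", {
  sp <- cohort_spec(n_patients = 500,
                    linear_effects = c(wss_steady_avg_whole = -4.74),
                    noise_sd = 10, seed = 42)
  coh <- make_synthetic_cohort(sp)
  f <- fit_linear_outcome(coh$cohort, "rvedvi", "wss_steady_avg_whole")
  expect_lt(abs(f$effect_estimate - (-4.74)), 2 * f$se)
})

test_that("null predictors reject at about the nominal 5% rate", {
  set.seed(77)
  pvals <- vapply(1:200, function(i) {
    n <- 60
    d <- data.frame(rvedvi = rnorm(n, 145, 20), x = rnorm(n),
                    sex = rbinom(n, 1, 0.5), age_cmr1 = runif(n, 5, 20))
    d$age_cmr2 <- d$age_cmr1 + runif(n, 2, 5)
    fit_linear_outcome(d, "rvedvi", "x")$unadjusted_p
  }, numeric(1))
  rate <- mean(pvals < 0.05)
  expect_gt(rate, 0.005)
  expect_lt(rate, 0.12)
  # and the p-values look uniform overall
  expect_gt(suppressWarnings(ks.test(pvals, "punif")$p.value), 0.01)
})

test_that("collinear designs are rejected with the aliased term named", {
  set.seed(1)
  d <- data.frame(rvedvi = rnorm(30), x = rnorm(30),
                  sex = rbinom(30, 1, 0.5), age_cmr1 = runif(30, 5, 15))
  d$age_cmr2 <- d$age_cmr1 + runif(30, 2, 4)
  d$x2 <- d$x
  expect_error(
    fit_linear_outcome(d, "rvedvi", "x", covariates = c("x2", "sex")),
    "collinear|aliased")
  d$const <- 1
  expect_error(fit_linear_outcome(d, "rvedvi", "const"), "constant")
})

test_that("BH adjustment matches hand computation and a textbook oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.1, 0)), "0, 1")
  set.seed(8)
  for (k in 1:50) {
    p <- runif(sample(1:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_textbook(p), tolerance = 1e-12)
    # monotone in the order statistics
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
    expect_true(all(adj >= p - 1e-12))
  }
})

test_that("BH keeps the false discovery rate near nominal on all-null batches", {
  set.seed(19)
  any_disc <- vapply(1:200, function(i)
    any(bh_adjust(runif(8)) < 0.05), logical(1))
  expect_lte(mean(any_disc), 0.05 + 3 * sqrt(0.05 * 0.95 / 200))
})

test_that("Cox fit recovers a true log-hazard of 0.7 and the per-SD identity", {
  sp <- cohort_spec(n_patients = 500,
                    log_hazards = c(wss_steady_avg_whole = 0.7),
                    censoring_rate = 0.3, seed = 7)
  coh <- make_synthetic_cohort(sp)
  cx <- fit_cox(coh$survival, "wss_steady_avg_whole")
  expect_lt(abs(cx$log_hr - 0.7), 2 * cx$se)
  expect_true(cx$ci_low <= cx$hazard_ratio && cx$hazard_ratio <= cx$ci_high)
  expect_false(cx$separation)
  # normalization is a reparameterization: beta_norm = beta * SD(x)
  cxn <- fit_cox(coh$survival, "wss_steady_avg_whole", normalize = TRUE)
  expect_equal(cxn$log_hr,
               cx$log_hr * sd(coh$survival$wss_steady_avg_whole),
               tolerance = 1e-6)
  expect_error(fit_cox(transform(coh$survival, event = 0),
                       "wss_steady_avg_whole"), "no events")
})

test_that("perfectly separating predictors are flagged, not silently fitted", {
  d <- data.frame(time_days = c(10, 20, 30, 400, 500, 600),
                  event = c(1, 1, 1, 0, 0, 0),
                  x = c(10, 9, 8, 1, 2, 3),
                  age_cmr = c(10, 11, 12, 10, 11, 12),
                  sex = c(0, 1, 0, 1, 0, 1))
  cx <- suppressWarnings(fit_cox(d, "x"))
  expect_true(cx$separation)
})

test_that("median-time dichotomization follows the landmark rule", {
  rec <- data.frame(time_days = c(100, 200, 300), event = c(1, 1, 1))
  lab <- dichotomize_by_median_time(rec)
  expect_equal(as.integer(lab), c(1L, 1L, 0L))
  expect_equal(attr(lab, "median_time"), 200)
  # censored before the median are excluded; after it labeled 0
  rec2 <- data.frame(time_days = c(100, 300, 150, 500),
                     event = c(1, 1, 0, 0))
  lab2 <- dichotomize_by_median_time(rec2)
  expect_equal(as.integer(lab2), c(1L, 0L, NA_integer_, 0L))
  expect_error(dichotomize_by_median_time(
    data.frame(time_days = c(5, 6), event = c(0, 0))), "no events")
})

test_that("ROC cutoff equals the exhaustive brute-force criterion", {
  # perfectly separated scores reach sensitivity + specificity = 2
  perf <- roc_optimal_cutoff(c(1, 2, 3, 10, 11, 12),
                             c(0, 0, 0, 1, 1, 1))
  expect_equal(perf$criterion, 2)
  expect_gt(perf$cutoff, 3); expect_lt(perf$cutoff, 10)
  set.seed(123)
  for (k in 1:100) {
    n <- sample(10:60, 1)
    scores <- round(rnorm(n), sample(0:2, 1))
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    res <- roc_optimal_cutoff(scores, labels)
    expect_equal(res$criterion, roc_bruteforce(scores, labels),
                 tolerance = 1e-9)
  }
  expect_error(roc_optimal_cutoff(1:5, rep(1, 5)), "classes")
})

test_that("ROC cutoff agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(31)
  for (k in 1:10) {
    scores <- rnorm(80, mean = rep(c(0, 1), each = 40))
    labels <- rep(c(0, 1), each = 40)
    res <- roc_optimal_cutoff(scores, labels)
    r <- pROC::roc(labels, scores, quiet = TRUE, direction = "<")
    best <- pROC::coords(r, "best", best.method = "youden",
                         transpose = FALSE)
    expect_equal(res$criterion,
                 max(best$sensitivity + best$specificity), tolerance = 1e-9)
  }
})

test_that("Kaplan-Meier matches the hand product-limit example", {
  rec <- data.frame(time_days = c(1, 2, 3, 4, 5),
                    event = c(1, 0, 1, 0, 0))
  km <- km_curve(rec, rep("all", 5))
  s_at <- function(t) {
    d <- km[km$time <= t, ]
    if (nrow(d) == 0) 1 else d$survival[nrow(d)]
  }
  expect_equal(s_at(1), 0.8)
  expect_equal(s_at(3), 0.8 * (1 - 1 / 3), tolerance = 1e-12)
  # survival is non-increasing within a group and bounded
  expect_true(all(diff(km$survival) <= 1e-12))
  expect_true(all(km$survival >= 0 & km$survival <= 1))
  # no events: flat 1
  rec2 <- data.frame(time_days = c(3, 6, 9), event = c(0, 0, 0))
  km2 <- km_curve(rec2, rep("all", 3))
  expect_true(all(km2$survival == 1))
})
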