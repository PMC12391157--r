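# Shared fixture builders (constructed in code; no stored data).

# Single-wall-point shear field with magnitude magfun(u), u = t/T in [0,1),
# along a fixed unit direction.
single_point_field <- function(magfun, n = 20L, direction = c(1, 0, 0),
                               period = 1) {
  u <- (seq_len(n) - 1L) / n
  v <- array(0, dim = c(1L, 3L, n))
  for (k in 1:3) v[1L, k, ] <- magfun(u) * direction[k]
  wss_field(matrix(0, 1L, 3L), areas = 1, times = u * period, vectors = v,
            labeling = segment_labeling("MPA", 1), period = period)
}

# Random multi-point shear field (fixed-direction per point, random signed
# magnitude time series).
random_field <- function(npts = 25L, nt = 20L, seed = 1L) {
  set.seed(seed)
  dirs <- matrix(rnorm(npts * 3L), npts, 3L)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  v <- array(0, dim = c(npts, 3L, nt))
  for (i in seq_len(npts)) {
    mag <- rnorm(1, 10, 4) + rnorm(1, 0, 8) * cos(2 * pi * (0:(nt - 1)) / nt) +
      rnorm(1, 0, 4) * sin(4 * pi * (0:(nt - 1)) / nt)
    for (k in 1:3) v[i, k, ] <- mag * dirs[i, k]
  }
  wss_field(matrix(rnorm(npts * 3L), npts, 3L),
            areas = runif(npts, 0.5, 2), times = (0:(nt - 1)) / nt,
            vectors = v,
            labeling = segment_labeling(
              sample(c("MPA", "LPA", "RPA"), npts, replace = TRUE),
              runif(npts, 0.5, 2)),
            period = 1)
}

# Small default bifurcation (coarser mesh for speed), cached per session.
small_bifurcation <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- make_pa_bifurcation(default_pa_spec(axial_samples = 30L,
                                                    circumferential_samples = 16L))
    cache
  }
})

# Independent textbook BH step-up: min over j >= i of p_(j) m / j, capped.
bh_textbook <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- ps * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Brute-force ROC cutoff oracle: every observed score and midpoint, both
# directions, maximizing sensitivity + specificity.
roc_bruteforce <- function(scores, labels) {
  u <- sort(unique(scores))
  cand <- unique(c(u - 1e-9, u, (u[-length(u)] + u[-1]) / 2, u + 1e-9))
  best <- -Inf
  for (cut in cand) for (dir in c(">=", "<=")) {
    pred <- if (dir == ">=") scores >= cut else scores <= cut
    crit <- sum(pred & labels == 1) / sum(labels == 1) +
      sum(!pred & labels == 0) / sum(labels == 0)
    if (crit > best + 1e-12) best <- crit
  }
  best
}
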