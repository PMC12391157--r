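# Complex-argument Bessel functions J0 and J1 by power series, vectorized.
# Accurate (rel. error ~1e-14) for |z| up to ~60; the Womersley gain switches
# to an asymptotic ratio branch beyond that, so overflow never occurs.
besselj01_complex <- function(z) {
  z <- as.complex(z)
  q <- -(z * z) / 4          # series ratio base
  j0 <- term0 <- rep(1 + 0i, length(z))
  j1s <- term1 <- rep(1 + 0i, length(z))  # J1 = (z/2) * j1s
  for (k in 1:300) {
    term0 <- term0 * q / (k * k)
    term1 <- term1 * q / (k * (k + 1))
    j0 <- j0 + term0
    j1s <- j1s + term1
    if (max(abs(term0) / pmax(abs(j0), 1e-300)) < 1e-16 &&
        max(abs(term1) / pmax(abs(j1s), 1e-300)) < 1e-16) break
  }
  list(J0 = j0, J1 = (z / 2) * j1s)
}

# Complex wall-shear gain g(alpha) for a flow-forced oscillatory pipe mode:
# tau_k(t) = Re{ Q_k * g * exp(i k w t) } with Q_k the complex flow
# amplitude. Derivation: Womersley velocity profile
#   u = A [1 - J0(L r/R)/J0(L)],  L = i^(3/2) alpha,
# flow Q = A pi R^2 (1 - F),  F = 2 J1(L) / (L J0(L)),
# wall shear tau = -mu du/dr|_R = -mu A (L/R) J1(L)/J0(L), giving
#   g = -mu L (J1/J0) / (pi R^3 (1 - F)).
# alpha -> 0 recovers the Poiseuille gain 4 mu / (pi R^3).
womersley_gain <- function(alpha, radius, fluid) {
  mu <- fluid$viscosity
  radius <- rep_len(radius, length(alpha))
  g <- complex(real = 4 * mu / (pi * radius^3))
  ac <- which(alpha > 0)
  if (length(ac)) {
    a <- alpha[ac]
    lam <- a * exp(3i * pi / 4)     # i^(3/2) alpha
    ratio <- rep(0i, length(a))
    small <- abs(a) <= 60
    if (any(small)) {
      js <- besselj01_complex(lam[small])
      ratio[small] <- js$J1 / js$J0
    }
    if (any(!small)) {
      # Hankel asymptotics for Im(z) -> +Inf: J1/J0 -> i - 1/(2z)
      ratio[!small] <- 1i - 1 / (2 * lam[!small])
    }
    F10 <- 2 * ratio / lam
    g[ac] <- -mu * lam * ratio / (pi * radius[ac]^3 * (1 - F10))
  }
  g
}

#' Poiseuille wall shear stress
#'
#' Closed-form wall shear of fully-developed laminar pipe flow:
#' `WSS = 4 mu Q / (pi R^3)` (the wall value of `mu du/dy`); the sign follows
#' the sign of the flow.
#'
#' @param Q flow in cm^3/s (vectorized).
#' @param radius vessel radius in cm (> 0, vectorized).
#' @param fluid a [fluid_properties()].
#' @return wall shear stress in dynes/cm^2.
#' @examples
#' poiseuille_wall_shear(78.54, 1)  # ~ 4 dynes/cm^2
#' @export
poiseuille_wall_shear <- function(Q, radius, fluid = fluid_properties()) {
  if (any(radius <= 0)) stop("radius must be positive")
  4 * fluid$viscosity * Q / (pi * radius^3)
}

#' Womersley number
#'
#' `alpha = R sqrt(w rho / mu)`: the ratio of pulsatile inertia to viscous
#' effects in oscillatory pipe flow.
#'
#' @param radius cm.
#' @param omega angular frequency in rad/s.
#' @param fluid a [fluid_properties()].
#' @return dimensionless Womersley number.
#' @examples
#' womersley_number(1, 2 * pi * 75 / 60)  # ~ 14.4 at HR 75 and R = 1 cm
#' @export
womersley_number <- function(radius, omega, fluid = fluid_properties()) {
  radius * sqrt(omega * fluid$density / fluid$viscosity)
}

# Signed axial wall shear time series for one vessel radius (vector) over
# `times`; returns a length(radius) x length(times) matrix in dynes/cm^2.
# flow_scale multiplies all Fourier modes (branch flow fractions).
womersley_shear_matrix <- function(ff, radius, fluid, times, flow_scale = 1) {
  stopifnot(inherits(ff, "fourier_flow"))
  np <- length(radius); nt <- length(times)
  g0 <- 4 * fluid$viscosity / (pi * radius^3)
  tau <- matrix(Re(ff$modes[1L]) * flow_scale * g0, np, nt)
  nmode <- length(ff$modes)
  if (nmode > 1L) {
    for (k in seq_len(nmode - 1L)) {
      alpha <- womersley_number(radius, k * ff$omega, fluid)
      gk <- womersley_gain(alpha, radius, fluid)
      phase <- exp(1i * k * ff$omega * times)       # length nt
      amp <- ff$modes[k + 1L] * flow_scale * gk     # length np
      tau <- tau + 2 * Re(outer(amp, phase))
    }
  }
  tau
}

#' Womersley wall shear stress time series
#'
#' Analytic pulsatile wall shear for flow-forced oscillatory pipe flow: mode
#' 0 contributes the Poiseuille shear of the mean flow; each harmonic `k`
#' contributes the Womersley solution at Womersley number
#' `alpha_k = R sqrt(k w rho / mu)`. The result is the real superposition,
#' signed along the vessel axis.
#'
#' @param ff a `fourier_flow` (from [fourier_decompose()]).
#' @param radius vessel radius in cm.
#' @param fluid a [fluid_properties()].
#' @param times evaluation times in s.
#' @return signed wall shear (dynes/cm^2) at each time.
#' @export
womersley_wall_shear <- function(ff, radius, fluid = fluid_properties(),
                                 times) {
  if (length(radius) != 1L || radius <= 0) stop("radius must be a positive scalar")
  if (ff$omega <= 0) stop("fundamental frequency must be positive")
  drop(womersley_shear_matrix(ff, radius, fluid, times))
}

#' Synthesize a pulsatile wall-shear field over a labeled vessel wall
#'
#' Desk-scale analytic surrogate for a 3D pulsatile CFD solve: at every wall
#' point the local radius (distance to the nearest centerline point of its
#' branch) and the branch flow (inlet flow split by the outlet resistance
#' network) define a Womersley wall-shear time series directed along the
#' local centerline tangent. The periodic steady state is emitted directly
#' at `n_timepoints` evenly-spaced times across one cycle (default 20).
#'
#' @param mesh a `surface_mesh` of the vessel wall.
#' @param centerlines named list of `centerline`s (MPA required, LPA/RPA for
#'   branch flows).
#' @param ff a `fourier_flow` describing the inlet flow.
#' @param fluid a [fluid_properties()].
#' @param resistances a [resistance_network()] over the branch outlets
#'   (names must match branch centerlines), or NULL for a single tube.
#' @param labeling optional `segment_labeling`; computed via
#'   [split_branches()] when omitted.
#' @param n_timepoints output timepoints per cycle.
#' @return a [wss_field()].
#' @export
synthesize_wss_field <- function(mesh, centerlines, ff,
                                 fluid = fluid_properties(),
                                 resistances = NULL, labeling = NULL,
                                 n_timepoints = 20L) {
  stopifnot(inherits(mesh, "surface_mesh"), inherits(ff, "fourier_flow"))
  if (is.null(labeling)) labeling <- split_branches(mesh, centerlines)
  times <- (seq_len(n_timepoints) - 1L) * ff$period / n_timepoints
  np <- nrow(mesh$vertices)
  geom <- local_wall_geometry(mesh, centerlines, labeling)
  frac <- branch_flow_fractions(names(centerlines), resistances)
  vectors <- array(0, dim = c(np, 3L, n_timepoints))
  for (br in unique(as.character(geom$branch))) {
    idx <- which(geom$branch == br)
    tau <- womersley_shear_matrix(ff, geom$radius[idx], fluid, times,
                                  flow_scale = frac[[br]])
    for (tt in seq_len(n_timepoints)) {
      vectors[idx, , tt] <- tau[, tt] * geom$tangent[idx, , drop = FALSE]
    }
  }
  wss_field(mesh$vertices, labeling$areas, times, vectors, labeling,
            period = ff$period)
}

#' Synthesize a steady wall-shear field
#'
#' Poiseuille wall shear at every wall point from the steady inlet flow split
#' by the outlet resistances, with the local radius taken as the distance to
#' the nearest centerline point.
#'
#' @param mesh,centerlines,fluid,resistances,labeling as in
#'   [synthesize_wss_field()].
#' @param Q steady inlet flow in cm^3/s.
#' @return a [wss_steady_field()].
#' @export
synthesize_steady_wss <- function(mesh, centerlines, Q,
                                  fluid = fluid_properties(),
                                  resistances = NULL, labeling = NULL) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (is.null(labeling)) labeling <- split_branches(mesh, centerlines)
  geom <- local_wall_geometry(mesh, centerlines, labeling)
  frac <- branch_flow_fractions(names(centerlines), resistances)
  scalars <- numeric(nrow(mesh$vertices))
  for (br in unique(as.character(geom$branch))) {
    idx <- which(geom$branch == br)
    scalars[idx] <- abs(poiseuille_wall_shear(Q * frac[[br]],
                                              geom$radius[idx], fluid))
  }
  wss_steady_field(mesh$vertices, labeling$areas, scalars, labeling)
}

# Flow fraction reaching each branch: the MPA trunk carries the full inlet
# flow; LPA/RPA receive the resistance-network split (equal when NULL).
branch_flow_fractions <- function(branch_names, resistances) {
  frac <- list()
  outlets <- setdiff(branch_names, "MPA")
  if (length(outlets) == 0L) {
    frac[["MPA"]] <- 1
    return(frac)
  }
  if (is.null(resistances)) {
    f <- rep(1 / length(outlets), length(outlets))
    names(f) <- outlets
  } else {
    stopifnot(inherits(resistances, "resistance_network"))
    f <- resistances$fractions
    if (is.null(names(f))) names(f) <- outlets
    if (!all(outlets %in% names(f)))
      stop("resistance network names must match branch centerlines")
  }
  frac[["MPA"]] <- 1
  for (o in outlets) frac[[o]] <- unname(f[o])
  frac
}

# Per wall point: branch label, local radius (distance to nearest centerline
# point of its branch), and local centerline tangent. Wall points labeled
# "extension" fall back to the nearest centerline over all branches.
local_wall_geometry <- function(mesh, centerlines, labeling) {
  np <- nrow(mesh$vertices)
  branch <- as.character(labeling$labels)
  radius <- numeric(np)
  tangent <- matrix(0, np, 3L)
  near <- lapply(centerlines, function(cl)
    nearest_centerline_point(mesh$vertices, cl))
  ext <- branch == "extension"
  if (any(ext)) {
    warning("wall points labeled 'extension': using nearest-centerline fallback")
    d_all <- vapply(near, `[[`, numeric(np), "dist")
    branch[ext] <- names(centerlines)[max.col(-d_all, ties.method = "first")][ext]
  }
  for (br in unique(branch)) {
    if (is.null(near[[br]])) stop(sprintf("no centerline for branch %s", br))
    idx <- which(branch == br)
    nb <- near[[br]]
    radius[idx] <- nb$dist[idx]
    cp <- nb$polyline$points
    ncl <- nrow(cp)
    ci <- nb$index[idx]
    lo <- pmax(ci - 1L, 1L); hi <- pmin(ci + 1L, ncl)
    tg <- cp[hi, , drop = FALSE] - cp[lo, , drop = FALSE]
    tangent[idx, ] <- tg / sqrt(rowSums(tg^2))
  }
  if (any(radius <= 0)) {
    warning("wall point with undefined local radius: using branch median")
    for (br in unique(branch)) {
      idx <- which(branch == br)
      bad <- idx[radius[idx] <= 0]
      radius[bad] <- median(radius[idx[radius[idx] > 0]])
    }
  }
  list(branch = branch, radius = radius, tangent = tangent)
}
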