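## Self-adjoint k-space pseudospectral core (the scheme embedded in the
## differentiable twin operator), plus the shared sensor stencils and the
## public propagate() front end.
##
## Second-order-in-time scheme with the k-space correction: the spectral
## Laplacian multiplier -k^2 is replaced by -k^2 sinc^2(c_ref |k| dt / 2),
## which makes time stepping exact for a homogeneous medium at any stable
## dt.  Boundary absorption combines a damped-wave layer with a gentle
## multiplicative taper.  Every elementary operator (spectral Laplacian,
## diagonal damping/masks, linear sensor sampling) has a known transpose,
## so the exact adjoint of the propagate-and-record map -- needed for
## physics-informed training -- is a mechanical reverse sweep
## (propagateAdjointCore).  Production propagation with stronger boundary
## absorption lives in pml.R (split-field PML; not self-adjoint).

DEFAULT_CFL <- 0.3

## wavenumber magnitude-squared array for a grid (FFT ordering)
ksqArray <- function(grid) {
  shp <- grid@shape
  d <- length(shp)
  ks <- lapply(seq_len(d), function(a) {
    n <- shp[a]
    m <- c(seq(0L, floor((n - 1) / 2)), seq.int(-ceiling((n - 1) / 2), -1L))
    (2 * pi * m / (n * grid@spacing[a]))^2
  })
  arr <- array(0, dim = shp)
  for (a in seq_len(d)) arr <- arr + ks[[a]][slice.index(arr, a)]
  arr
}

## absorbing layer: damping rate field sigma(x) for the damped wave equation
## p_tt + 2 sigma p_t = c^2 Lap p, quadratic profile rising into the layer;
## sigma_max = alpha * c_max / dx (alpha in nepers per voxel crossing)
spongeSigma <- function(grid, layers, alpha, c_max) {
  shp <- grid@shape
  arr <- array(0, dim = shp)
  for (a in seq_along(shp)) {
    n <- shp[a]
    i <- seq_len(n)
    depth <- pmax(0, pmax(layers + 1 - i, i - (n - layers)))
    prof <- (depth / layers)^2
    arr <- pmax(arr, prof[slice.index(arr, a)])
  }
  alpha * c_max / min(grid@spacing) * arr
}

## complementary multiplicative taper in the same layer (quartic profile)
spongeMaskProfile <- function(grid, layers, sigma0) {
  shp <- grid@shape
  arr <- array(0, dim = shp)
  for (a in seq_along(shp)) {
    n <- shp[a]
    i <- seq_len(n)
    depth <- pmax(0, pmax(layers + 1 - i, i - (n - layers)))
    prof <- sigma0 * (depth / layers)^4
    arr <- arr + prof[slice.index(arr, a)]
  }
  exp(-arr)
}

## trilinear (bilinear in 2D) sampling stencil for sensor coordinates:
## linear indices (n_sens x 2^d) plus weights
sensorStencil <- function(grid, points) {
  d <- gridDim(grid)
  points <- matrix(points, ncol = d)
  n_sens <- nrow(points)
  shp <- grid@shape
  ci <- sapply(seq_len(d), function(a)
    (points[, a] - grid@origin[a]) / grid@spacing[a] + 1)
  ci <- matrix(ci, ncol = d)
  eps <- 1e-9
  for (a in seq_len(d)) {
    bad <- ci[, a] < 1 - eps | ci[, a] > shp[a] + eps
    if (any(bad))
      stop(sprintf("sensor point(s) outside the grid along axis %d", a))
  }
  i0 <- matrix(0L, n_sens, d); fr <- matrix(0, n_sens, d)
  for (a in seq_len(d)) {
    v <- pmin(pmax(ci[, a], 1), shp[a])
    base <- pmin(floor(v), max(1, shp[a] - 1))
    i0[, a] <- as.integer(base)
    fr[, a] <- v - base
  }
  strides <- cumprod(c(1, shp[-d]))
  corners <- as.matrix(expand.grid(rep(list(0:1), d)))
  idx <- matrix(0L, n_sens, nrow(corners))
  w <- matrix(0, n_sens, nrow(corners))
  for (j in seq_len(nrow(corners))) {
    off <- corners[j, ]
    lin <- rep(1, n_sens)
    wt <- rep(1, n_sens)
    for (a in seq_len(d)) {
      ia <- pmin(i0[, a] + off[a], shp[a])
      lin <- lin + (ia - 1L) * strides[a]
      wa <- if (off[a] == 0) 1 - fr[, a] else fr[, a]
      ## collapsed corner (single-voxel axis): weight folds to the base voxel
      wa[i0[, a] + off[a] > shp[a]] <- 0
      wt <- wt * wa
    }
    idx[, j] <- as.integer(lin)
    w[, j] <- wt
  }
  list(idx = idx, w = w, n = n_sens)
}

recordSensors <- function(p, stencil) {
  pm <- matrix(p[stencil$idx], nrow = stencil$n)
  rowSums(pm * stencil$w)
}

scatterSensors <- function(vals, stencil, npix) {
  out <- numeric(npix)
  contrib <- as.vector(stencil$w * vals)
  acc <- rowsum(contrib, group = as.vector(stencil$idx), reorder = TRUE)
  out[as.integer(rownames(acc))] <- acc[, 1]
  out
}

#' Maximum stable time step for a medium
#'
#' @param medium an [AcousticMedium].
#' @param cfl CFL number (default 0.3).
#' @return dt (s).
#' @export
maxStableDt <- function(medium, cfl = DEFAULT_CFL) {
  cfl * min(medium@grid@spacing) / max(medium@c)
}

## precompute everything the stepping loop needs
solverPlan <- function(medium, dt, sensor_points = NULL, sponge_layers = 12L,
                       sponge_alpha = 2, sponge_mask_sigma = 0.3,
                       use_attenuation = FALSE) {
  grid <- medium@grid
  hard_limit <- min(grid@spacing) / max(medium@c)
  if (dt > hard_limit + 1e-15)
    stop(sprintf(paste0("CFL condition violated: dt = %.4g s exceeds the ",
                        "maximum stable dt of %.4g s (recommended %.4g s at ",
                        "CFL %.2f)"),
                 dt, hard_limit, DEFAULT_CFL * hard_limit, DEFAULT_CFL))
  ksq <- ksqArray(grid)
  cref <- max(medium@c)
  arg <- cref * sqrt(ksq) * dt / 2
  sinc2 <- ifelse(arg == 0, 1, (sin(arg) / arg)^2)
  KS <- -ksq * sinc2
  if (use_attenuation && !is.null(medium@alpha_att)) {
    ## approximate homogeneous power-law attenuation applied in k-space:
    ## dB/(MHz^y cm) -> Np/m at f = c_ref |k| / (2 pi), one step of decay
    a_db <- mean(medium@alpha_att)
    f_mhz <- cref * sqrt(ksq) / (2 * pi) / 1e6
    alpha_np_m <- a_db * f_mhz^medium@att_power * 100 / 8.686
    att <- exp(-alpha_np_m * cref * dt)
  } else att <- NULL
  layers <- min(sponge_layers, floor((min(grid@shape) - 1) / 2))
  if (layers >= 1) {
    gam <- spongeSigma(grid, layers, sponge_alpha, cref) * dt
    mask <- spongeMaskProfile(grid, layers, sponge_mask_sigma)
  } else {
    gam <- array(0, dim = grid@shape)
    mask <- array(1, dim = grid@shape)
  }
  stencil <- if (is.null(sensor_points)) NULL
             else sensorStencil(grid, sensor_points)
  list(grid = grid, dt = dt, KS = KS, att = att,
       b = dt^2 * medium@c^2,
       d1 = 1 / (1 + gam), e = 1 - gam, mask = mask,
       stencil = stencil, npix = gridLength(grid))
}

applyLap <- function(p, plan) {
  P <- fft(array(p, dim = plan$grid@shape)) * plan$KS
  if (!is.null(plan$att)) P <- P * plan$att
  Re(fft(P, inverse = TRUE)) / plan$npix
}

## forward propagate-and-record: y[n] = C p(t_{n-1}); n_t samples from t = 0.
## Interior step is the exact (k-space corrected) three-term recurrence; in
## the absorbing layer it discretises p_tt + 2 sigma p_t = c^2 Lap p as
## cur' = d1 (2 cur + b Lap cur - e prev), d1 = 1/(1+sigma dt), e = 1-sigma dt.
propagateCore <- function(plan, p0, n_t) {
  C <- plan$stencil
  y <- matrix(0, C$n, n_t)
  prev <- as.vector(p0)
  y[, 1] <- recordSensors(prev, C)
  if (n_t == 1L) return(y)
  b <- as.vector(plan$b)
  cur <- prev + 0.5 * b * as.vector(applyLap(prev, plan))
  y[, 2] <- recordSensors(cur, C)
  if (n_t == 2L) return(y)
  d1 <- as.vector(plan$d1)
  e <- as.vector(plan$e)
  m <- as.vector(plan$mask)
  for (n in 3:n_t) {
    nxt <- m * (d1 * (2 * cur + b * as.vector(applyLap(cur, plan)) - e * prev))
    prev <- m * cur
    cur <- nxt
    y[, n] <- recordSensors(cur, C)
  }
  y
}

## exact adjoint of propagateCore: maps a sinogram-shaped adjoint input
## (n_sens x n_t) back to a volume-shaped gradient
propagateAdjointCore <- function(plan, ybar) {
  C <- plan$stencil
  n_t <- ncol(ybar)
  npix <- plan$npix
  b <- as.vector(plan$b)
  d1 <- as.vector(plan$d1)
  e <- as.vector(plan$e)
  lapT <- function(v) as.vector(applyLap(b * v, plan))  # (diag(b) L)^T = L diag(b)
  if (n_t == 1L) return(scatterSensors(ybar[, 1], C, npix))
  bp <- numeric(npix)
  bc <- scatterSensors(ybar[, n_t], C, npix)
  m <- as.vector(plan$mask)
  if (n_t > 2L) {
    for (n in (n_t - 2L):1L) {
      dbc <- d1 * (m * bc)
      bc_new <- m * bp + 2 * dbc + lapT(dbc)
      bp <- -e * dbc
      bc <- bc_new + scatterSensors(ybar[, n + 1L], C, npix)
    }
  }
  bp <- bp + scatterSensors(ybar[, 1], C, npix)
  bp + bc + 0.5 * lapT(bc)
}

## driven run: zero initial field, per-step additive (or Dirichlet) injection
## of signals at the stencil points; returns the final field
injectCore <- function(plan, signals, dirichlet = FALSE) {
  C <- plan$stencil
  n_t <- ncol(signals)
  npix <- plan$npix
  b <- as.vector(plan$b)
  d1 <- as.vector(plan$d1)
  e <- as.vector(plan$e)
  m <- as.vector(plan$mask)
  inject <- function(field, k) {
    if (dirichlet) {
      ## nearest-voxel Dirichlet enforcement
      j <- C$idx[cbind(seq_len(C$n), max.col(C$w, ties.method = "first"))]
      field[j] <- signals[, k]
      field
    } else field + b * scatterSensors(signals[, k], C, npix)
  }
  prev <- numeric(npix)
  cur <- inject(numeric(npix), 1L)
  if (n_t >= 2L) {
    for (n in 2:n_t) {
      nxt <- m * (d1 * (2 * cur + b * as.vector(applyLap(cur, plan)) - e * prev))
      prev <- m * cur
      cur <- inject(nxt, n)
    }
  }
  cur
}

#' Propagate an initial pressure field and record at sensor points
#'
#' Solves the lossless wave equation initial-value problem (initial pressure
#' `p0`, zero initial particle velocity -- the thermal-confinement source)
#' with the k-space pseudospectral scheme, and records the pressure time
#' series at each sensor point by multilinear interpolation.  A sponge
#' absorbing layer suppresses wrap-around reflections.
#'
#' @param p0 a [PressureVolume] (role `"p0"`).
#' @param medium an [AcousticMedium] on the same grid.
#' @param sensor_points n x d matrix of sensor coordinates (m).
#' @param duration recording duration (s).
#' @param dt time step (s); default `maxStableDt(medium)` (CFL 0.3).  A dt
#'   above the stability limit raises an error reporting the maximum stable dt.
#' @param pml_layers perfectly-matched-layer thickness in voxels (default 12).
#' @param pml_alpha PML peak absorption (nepers per voxel, default 2).
#' @param scheme `"pml"` (first-order pressure-velocity k-space scheme with a
#'   split-field PML; production path) or `"adjoint-core"` (the second-order
#'   self-adjoint scheme embedded in the differentiable forward operator).
#' @return list of [TimeSeries], one per sensor row.
#' @export
propagate <- function(p0, medium, sensor_points, duration, dt = NULL,
                      pml_layers = 12L, pml_alpha = 2,
                      scheme = c("pml", "adjoint-core")) {
  scheme <- match.arg(scheme)
  if (!sameGrid(p0@grid, medium@grid))
    stop("p0 and medium must share the same grid")
  if (is.null(dt)) dt <- maxStableDt(medium)
  n_t <- max(2L, as.integer(floor(duration / dt)) + 1L)
  if (scheme == "pml") {
    plan <- pmlPlan(medium, dt, sensor_points, pml_layers = pml_layers,
                    pml_alpha = pml_alpha)
    y <- pmlPropagateCore(plan, p0@values, n_t)
  } else {
    plan <- solverPlan(medium, dt, sensor_points,
                       sponge_layers = pml_layers)
    y <- propagateCore(plan, p0@values, n_t)
  }
  lapply(seq_len(nrow(y)), function(i) timeSeries(y[i, ], dt, 0))
}

#' Analytic detector signal of a uniform pressure sphere
#'
#' Closed-form solution of the spherical-mean forward model for a uniform
#' sphere of initial pressure in a homogeneous medium: the classical bipolar
#' N-wave, p(t) = p0_amp (r - c t) / (2 r) for |r - c t| <= a and zero
#' otherwise (r = detector distance, a = sphere radius).  Serves as the
#' independent oracle for the numerical solver.
#'
#' For any spherically symmetric initial pressure with radial profile f, the
#' exact exterior solution is p(r, t) = (r - c t) f(|r - c t|) / (2 r); the
#' hard sphere (`edge_width = 0`) recovers the N-wave above, and a sigmoid
#' edge profile f(rho) = p0_amp / (1 + exp((rho - a) / w)) gives the closed
#' form for a smooth-edged ball, the variant used when validating the
#' band-limited grid solver against a source the grid can represent.
#'
#' @param p0_amp sphere initial pressure (Pa).
#' @param radius sphere radius a (m).
#' @param detector_distance r, centre-to-detector distance (m); must exceed a.
#' @param c sound speed (m/s).
#' @param dt sampling interval (s).
#' @param duration signal duration (s); default 1.25 (r + a) / c.
#' @param edge_width sigmoid edge width w (m); 0 (default) = hard sphere.
#' @return a [TimeSeries] starting at t = 0.
#' @export
analyticSphereSignal <- function(p0_amp, radius, detector_distance, c, dt,
                                 duration = NULL, edge_width = 0) {
  if (detector_distance <= radius)
    stop("detector must lie outside the sphere")
  if (is.null(duration)) duration <- 1.25 * (detector_distance + radius) / c
  t <- seq(0, duration, by = dt)
  u <- detector_distance - c * t
  f <- if (edge_width > 0) p0_amp / (1 + exp((abs(u) - radius) / edge_width))
       else p0_amp * (abs(u) <= radius)
  timeSeries(u * f / (2 * detector_distance), dt, 0)
}

#' Rasterise a uniform sphere (or disc) of initial pressure
#'
#' With `edge_width = 0` each voxel receives the partial-volume fraction of
#' the hard sphere it covers (estimated by supersampling); with a positive
#' `edge_width` the sigmoid radial profile matching
#' [analyticSphereSignal()]'s smooth variant is evaluated at voxel centres.
#'
#' @param grid a [Grid].
#' @param center sphere centre (m), length = grid dimension.
#' @param radius sphere radius (m).
#' @param amplitude interior pressure (Pa).
#' @param supersample sub-samples per voxel edge for the hard sphere.
#' @param edge_width sigmoid edge width (m); 0 = hard sphere.
#' @return a [PressureVolume] with role `"p0"`.
#' @export
spherePressure <- function(grid, center, radius, amplitude = 1,
                           supersample = 4L, edge_width = 0) {
  d <- gridDim(grid)
  shp <- grid@shape
  ax_coords <- lapply(seq_len(d), function(a) gridCoords(grid, a) - center[a])
  if (edge_width > 0) {
    dist2 <- array(0, dim = shp)
    for (a in seq_len(d))
      dist2 <- dist2 + (ax_coords[[a]]^2)[slice.index(dist2, a)]
    vol <- amplitude / (1 + exp((sqrt(dist2) - radius) / edge_width))
    return(pressureVolume(vol, grid, role = "p0"))
  }
  off <- (seq_len(supersample) - 0.5) / supersample - 0.5
  vol <- array(0, dim = shp)
  subs <- as.matrix(expand.grid(rep(list(off), d)))
  for (s in seq_len(nrow(subs))) {
    dist2 <- array(0, dim = shp)
    for (a in seq_len(d)) {
      xa <- ax_coords[[a]] + subs[s, a] * grid@spacing[a]
      dist2 <- dist2 + (xa^2)[slice.index(dist2, a)]
    }
    vol <- vol + (dist2 <= radius^2)
  }
  pressureVolume(amplitude * vol / nrow(subs), grid, role = "p0")
}
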