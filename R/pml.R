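## First-order coupled pressure-velocity k-space scheme with a split-field
## perfectly matched layer (PML).  This is the production propagation path
## used by propagate() and time reversal: the PML absorbs outgoing waves with
## reflection far below any simple sponge, at the cost of not being
## self-adjoint -- the differentiable twin operator therefore uses the
## second-order scheme in solver.R instead.
##
## Scheme (per axis i, staggered grids, exponential PML integration):
##   du_i/dt = -(1/rho) d p / d x_i          - sigma_i u_i
##   dp_i/dt = -rho c^2 d u_i / d x_i        - sigma_i p_i ,   p = sum_i p_i
## Spatial derivatives are spectral with staggered half-voxel shifts and the
## k-space correction sinc(c_ref |k| dt / 2), which removes time-stepping
## dispersion for homogeneous media.

pmlProfile <- function(grid, axis, layers, alpha, c_max, stagger = 0) {
  n <- grid@shape[axis]
  i <- seq_len(n) + stagger
  depth <- pmax(0, pmax(layers + 1 - i, i - (n - layers)))
  (alpha * c_max / grid@spacing[axis]) * (depth / layers)^4
}

pmlPlan <- function(medium, dt, sensor_points = NULL, pml_layers = 12L,
                    pml_alpha = 2) {
  grid <- medium@grid
  d <- gridDim(grid)
  shp <- grid@shape
  hard_limit <- min(grid@spacing) / max(medium@c)
  if (dt > hard_limit + 1e-15)
    stop(sprintf(paste0("CFL condition violated: dt = %.4g s exceeds the ",
                        "maximum stable dt of %.4g s (recommended %.4g s at ",
                        "CFL %.2f)"),
                 dt, hard_limit, DEFAULT_CFL * hard_limit, DEFAULT_CFL))
  cref <- max(medium@c)
  ksq <- ksqArray(grid)
  arg <- cref * sqrt(ksq) * dt / 2
  kappa <- ifelse(arg == 0, 1, sin(arg) / arg)
  ## per-axis spectral derivative multipliers with +/- half-voxel shifts
  Dplus <- vector("list", d); Dminus <- vector("list", d)
  for (a in seq_len(d)) {
    n <- shp[a]
    m <- c(seq(0L, floor((n - 1) / 2)), seq.int(-ceiling((n - 1) / 2), -1L))
    k <- 2 * pi * m / (n * grid@spacing[a])
    if (n %% 2 == 0) k[n / 2 + 1] <- 0  # zero the Nyquist bin of odd operators
    kz <- k[slice.index(array(0, shp), a)]
    sh <- exp(1i * kz * grid@spacing[a] / 2)
    Dplus[[a]] <- 1i * kz * kappa * sh
    Dminus[[a]] <- 1i * kz * kappa / sh
  }
  layers <- min(pml_layers, floor((min(shp) - 1) / 2))
  decay_p <- vector("list", d); decay_u <- vector("list", d)
  for (a in seq_len(d)) {
    sp <- if (layers >= 1) pmlProfile(grid, a, layers, pml_alpha, cref)
          else rep(0, shp[a])
    su <- if (layers >= 1) pmlProfile(grid, a, layers, pml_alpha, cref, 0.5)
          else rep(0, shp[a])
    zz <- array(0, shp)
    decay_p[[a]] <- exp(-sp * dt / 2)[slice.index(zz, a)]
    decay_u[[a]] <- exp(-su * dt / 2)[slice.index(zz, a)]
  }
  stencil <- if (is.null(sensor_points)) NULL
             else sensorStencil(grid, sensor_points)
  list(grid = grid, d = d, dt = dt, shp = shp,
       Dplus = Dplus, Dminus = Dminus,
       decay_p = decay_p, decay_u = decay_u,
       rho = medium@rho, rc2 = medium@rho * medium@c^2,
       stencil = stencil, npix = gridLength(grid))
}

## advance (u, psplit) by one step; returns updated state
pmlStep <- function(state, plan, dt_u = plan$dt) {
  d <- plan$d
  p <- Reduce(`+`, state$psplit)
  P <- fft(p)
  for (a in seq_len(d)) {
    dpdx <- Re(fft(plan$Dplus[[a]] * P, inverse = TRUE)) / plan$npix
    state$u[[a]] <- plan$decay_u[[a]] *
      (plan$decay_u[[a]] * state$u[[a]] - dt_u / plan$rho * dpdx)
  }
  for (a in seq_len(d)) {
    dudx <- Re(fft(plan$Dminus[[a]] * fft(state$u[[a]]), inverse = TRUE)) /
      plan$npix
    state$psplit[[a]] <- plan$decay_p[[a]] *
      (plan$decay_p[[a]] * state$psplit[[a]] - plan$dt * plan$rc2 * dudx)
  }
  state
}

pmlInitState <- function(plan, p0 = NULL) {
  zero <- array(0, plan$shp)
  psplit <- lapply(seq_len(plan$d), function(a)
    if (is.null(p0)) zero else p0 / plan$d)
  u <- lapply(seq_len(plan$d), function(a) zero)
  list(u = u, psplit = psplit)
}

## forward run: record pressure at sensors for n_t samples (t = 0 first)
pmlPropagateCore <- function(plan, p0, n_t) {
  C <- plan$stencil
  y <- matrix(0, C$n, n_t)
  state <- pmlInitState(plan, array(p0, plan$shp))
  y[, 1] <- recordSensors(Reduce(`+`, state$psplit), C)
  if (n_t == 1L) return(y)
  ## first velocity update over dt/2 starts the staggered leapfrog from the
  ## zero-initial-velocity condition
  first <- TRUE
  for (n in 2:n_t) {
    state <- pmlStep(state, plan, dt_u = if (first) plan$dt / 2 else plan$dt)
    first <- FALSE
    y[, n] <- recordSensors(Reduce(`+`, state$psplit), C)
  }
  y
}

## driven run: zero initial field, additive (or Dirichlet) injection of
## per-sensor signals into the pressure field each step; returns final p
pmlInjectCore <- function(plan, signals, dirichlet = FALSE) {
  C <- plan$stencil
  n_t <- ncol(signals)
  state <- pmlInitState(plan)
  nearest <- C$idx[cbind(seq_len(C$n), max.col(C$w, ties.method = "first"))]
  inject <- function(state, k) {
    if (dirichlet) {
      val <- signals[, k] / plan$d
      for (a in seq_len(plan$d)) state$psplit[[a]][nearest] <- val
    } else {
      add <- array(scatterSensors(signals[, k], C, plan$npix) / plan$d,
                   plan$shp)
      for (a in seq_len(plan$d))
        state$psplit[[a]] <- state$psplit[[a]] + add
    }
    state
  }
  state <- inject(state, 1L)
  if (n_t >= 2L) {
    first <- TRUE
    for (n in 2:n_t) {
      state <- pmlStep(state, plan, dt_u = if (first) plan$dt / 2 else plan$dt)
      first <- FALSE
      state <- inject(state, n)
    }
  }
  Reduce(`+`, state$psplit)
}
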