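## Digital-twin detection chain: radiation-pulse convolution, finite-aperture
## sub-element summation, impulse-response convolution, and their composition
## into the unified forward operator F mapping initial pressure to the
## sinogram the instrument records.  All stages are linear, so F has an exact
## adjoint (adjointOperator) used for physics-informed training.

#' Construct a transducer array
#'
#' @param element_centers n x 3 matrix of element centre coordinates (m).
#' @param element_size aperture edge length(s) (m), scalar or length-2.
#' @param sub_pitch sub-element spacing (m); must divide the aperture evenly.
#' @param normal unit vector the array faces along.
#' @param layout integer length-2 rows x cols (defaults to n x 1).
#' @return a [TransducerArray].
#' @export
transducerArray <- function(element_centers, element_size = 3e-3,
                            sub_pitch = 1e-3, normal = c(1, 0, 0),
                            layout = NULL) {
  element_centers <- as.matrix(element_centers)
  if (ncol(element_centers) == 2L)
    element_centers <- cbind(element_centers, 0)
  if (is.null(layout)) layout <- c(nrow(element_centers), 1L)
  new("TransducerArray", element_centers = element_centers,
      element_size = rep_len(as.numeric(element_size), 2L),
      sub_pitch = as.numeric(sub_pitch), normal = as.numeric(normal),
      layout = as.integer(layout))
}

#' Planar matrix array
#'
#' Builds the standard planar matrix array: `nrows x ncols` square elements
#' at `pitch` spacing, centred on `center`, facing along `normal` (an
#' axis-aligned unit vector).  The experimental reference system is a 16 x 16
#' matrix (256 elements) of 3 mm elements subdivided into nine 1 x 1 mm
#' sub-elements.
#'
#' @param nrows,ncols element counts.
#' @param pitch element-centre spacing (m); default 3 mm (contiguous).
#' @param center array centre coordinate (m), length 3.
#' @param normal facing direction (axis-aligned).
#' @param element_size aperture edge (m); default = pitch.
#' @param sub_pitch sub-element spacing (m); default 1 mm.
#' @return a [TransducerArray].
#' @export
planarArray <- function(nrows = 16L, ncols = 16L, pitch = 3e-3,
                        center = c(0, 0, 0), normal = c(1, 0, 0),
                        element_size = pitch, sub_pitch = 1e-3) {
  ax <- which(abs(normal) > 1e-12)
  if (length(ax) != 1L) stop("normal must be axis-aligned")
  inplane <- setdiff(1:3, ax)
  r <- (seq_len(nrows) - (nrows + 1) / 2) * pitch
  c_ <- (seq_len(ncols) - (ncols + 1) / 2) * pitch
  gridrc <- expand.grid(r = r, c = c_)
  centers <- matrix(rep(center, each = nrow(gridrc)), ncol = 3)
  centers[, inplane[1]] <- centers[, inplane[1]] + gridrc$r
  centers[, inplane[2]] <- centers[, inplane[2]] + gridrc$c
  transducerArray(centers, element_size = element_size, sub_pitch = sub_pitch,
                  normal = normal, layout = c(nrows, ncols))
}

#' Number of array elements
#' @param array a [TransducerArray].
#' @export
nElements <- function(array) nrow(array@element_centers)

#' Sub-element displacement vectors of an array element
#'
#' Displacements from the element centre to each sub-element centre, lying in
#' the element plane.  A 3 x 3 mm element at 1 mm sub-pitch yields the nine
#' displacements \{-1, 0, +1\} mm squared; on a 2D grid the aperture has one
#' in-plane axis and the same element yields three sub-elements.
#'
#' @param array a [TransducerArray].
#' @param ndim spatial dimension of the simulation grid (2 or 3).
#' @return matrix (n_sub x ndim) of displacements (m).
#' @export
subElementOffsets <- function(array, ndim = 3L) {
  ax <- which(abs(array@normal[seq_len(ndim)]) > 1e-12)
  if (length(ax) != 1L) stop("array normal must be axis-aligned")
  inplane <- setdiff(seq_len(ndim), ax)
  offs <- lapply(seq_along(inplane), function(j) {
    n_sub <- as.integer(round(array@element_size[j] / array@sub_pitch))
    (seq_len(n_sub) - (n_sub + 1) / 2) * array@sub_pitch
  })
  g <- as.matrix(expand.grid(offs))
  out <- matrix(0, nrow(g), ndim)
  for (j in seq_along(inplane)) out[, inplane[j]] <- g[, j]
  out
}

## sub-element sensor points for all elements: (n_elem * n_sub) x ndim,
## plus the element index of each row
arraySensorPoints <- function(array, ndim) {
  offs <- subElementOffsets(array, ndim)
  centers <- array@element_centers[, seq_len(ndim), drop = FALSE]
  n_e <- nrow(centers); n_s <- nrow(offs)
  pts <- matrix(0, n_e * n_s, ndim)
  group <- integer(n_e * n_s)
  for (e in seq_len(n_e)) {
    rows <- (e - 1L) * n_s + seq_len(n_s)
    pts[rows, ] <- sweep(offs, 2, centers[e, ], `+`)
    group[rows] <- e
  }
  list(points = pts, group = group, n_sub = n_s)
}

setMethod("show", "TransducerArray", function(object) {
  cat(sprintf(paste0("TransducerArray: %d x %d elements (%g x %g mm aperture,",
                     " %g mm sub-pitch)\n"),
              object@layout[1], object@layout[2],
              object@element_size[1] * 1e3, object@element_size[2] * 1e3,
              object@sub_pitch * 1e3))
})

#' Construct a transducer impulse response
#'
#' The damped-sinusoid kind models the element as a damped harmonic
#' oscillator, IR(t) = exp(-pi f0 t / q) sin(2 pi f0 t), sampled until the
#' envelope has decayed to 0.1% and energy-normalised (sum of squares = 1),
#' so filtering preserves overall signal scale.
#'
#' @param kind `"delta"`, `"damped-sinusoid"` or `"samples"`.
#' @param f0 centre frequency (Hz).
#' @param q quality factor.
#' @param dt sampling interval (s).
#' @param samples user-supplied samples for kind `"samples"`.
#' @return an [ImpulseResponse].
#' @export
impulseResponse <- function(kind = c("damped-sinusoid", "delta", "samples"),
                            f0 = 1e6, q = 2, dt = 1e-7, samples = NULL) {
  kind <- match.arg(kind)
  if (kind == "delta")
    return(new("ImpulseResponse", kind = kind, f0 = NA_real_, q = NA_real_,
               dt = dt, samples = 1))
  if (kind == "samples") {
    if (is.null(samples) || sum(samples^2) == 0)
      stop("impulse response must not be identically zero")
    s <- samples / sqrt(sum(samples^2))
    return(new("ImpulseResponse", kind = kind, f0 = NA_real_, q = NA_real_,
               dt = dt, samples = s))
  }
  t_end <- q * log(1e3) / (pi * f0)
  t <- seq(0, t_end, by = dt)
  s <- exp(-pi * f0 * t / q) * sin(2 * pi * f0 * t)
  if (sum(s^2) == 0) stop("impulse response must not be identically zero")
  s <- s / sqrt(sum(s^2))
  new("ImpulseResponse", kind = kind, f0 = f0, q = q, dt = dt, samples = s)
}

## convolution kernels on the signal time base ------------------------------

convFull <- function(x, y) {
  if (length(x) == 1L) return(x * y)
  if (length(y) == 1L) return(y * x)
  stats::convolve(x, rev(y), type = "open")
}

## resample a kernel defined at dt_from onto dt_to by linear interpolation
resampleKernel <- function(s, dt_from, dt_to) {
  if (abs(dt_from - dt_to) < 1e-15 * dt_to) return(s)
  t_old <- (seq_along(s) - 1) * dt_from
  t_new <- seq(0, max(t_old), by = dt_to)
  stats::approx(t_old, s, xout = t_new, rule = 2)$y
}

pulseKernel <- function(pulse, dt) {
  if (pulse@kind == "delta") return(1)
  s <- resampleKernel(pulse@samples, pulse@dt, dt)
  s / (sum(s) * dt) * dt  # renormalise to unit area, then discretise
}

irKernel <- function(ir, dt) {
  if (ir@kind == "delta") return(1)
  s <- resampleKernel(ir@samples, ir@dt, dt)
  s / sqrt(sum(s^2))
}

## causal linear convolution truncated to the input length
convTrunc <- function(s, kern) {
  n <- length(s)
  convFull(s, kern)[seq_len(n)]
}

## exact adjoint of convTrunc
convTruncAdjoint <- function(zbar, kern) {
  n <- length(zbar)
  k <- length(kern)
  if (k == 1L) return(kern * zbar)
  convFull(zbar, rev(kern))[k:(k + n - 1L)]
}

#' Convolve a recorded signal with the radiation pulse profile
#'
#' Models the finite duration of the radiation pulse: the instantaneous
#' (delta-excitation) detector signal is convolved with the pulse temporal
#' profile.  A unit-area pulse preserves the signal integral; the delta pulse
#' is the identity.
#'
#' @param signal a [TimeSeries].
#' @param pulse a [PulseProfile] (resampled onto the signal dt if needed).
#' @return a [TimeSeries] on the same time base.
#' @export
applyPulse <- function(signal, pulse) {
  if (length(pulse@samples) == 0) stop("empty pulse")
  kern <- pulseKernel(pulse, signal@dt)
  timeSeries(convTrunc(signal@samples, kern), signal@dt, signal@t0)
}

#' Sum sub-element signals into one element signal
#'
#' Finite-aperture detection: the element output is the (weighted) sum of
#' the field sampled at its sub-element centres.
#'
#' @param sub_signals list of [TimeSeries] sharing dt, t0 and length.
#' @param weights optional weights (default all 1).
#' @return a [TimeSeries].
#' @export
finiteElementSignal <- function(sub_signals, weights = NULL) {
  if (length(sub_signals) == 0) stop("no sub-element signals")
  dts <- vapply(sub_signals, function(s) s@dt, numeric(1))
  t0s <- vapply(sub_signals, function(s) s@t0, numeric(1))
  ns <- vapply(sub_signals, function(s) length(s@samples), integer(1))
  if (max(dts) - min(dts) > 1e-15 * max(dts) || max(t0s) - min(t0s) > 1e-15 ||
      length(unique(ns)) != 1L)
    stop("sub-element signals must share dt, t0 and length")
  if (is.null(weights)) weights <- rep(1, length(sub_signals))
  acc <- numeric(ns[1])
  for (i in seq_along(sub_signals))
    acc <- acc + weights[i] * sub_signals[[i]]@samples
  timeSeries(acc, dts[1], t0s[1])
}

#' Filter a signal with the transducer impulse response
#'
#' @param signal a [TimeSeries].
#' @param ir an [ImpulseResponse] (resampled onto the signal dt if needed).
#' @return a [TimeSeries].
#' @export
applyImpulseResponse <- function(signal, ir) {
  kern <- irKernel(ir, signal@dt)
  timeSeries(convTrunc(signal@samples, kern), signal@dt, signal@t0)
}

#' Bundle a digital-twin configuration
#'
#' @param pulse a [PulseProfile].
#' @param array a [TransducerArray].
#' @param ir an [ImpulseResponse].
#' @param medium an [AcousticMedium].
#' @param duration recording duration (s).
#' @param dt recording/solver time step (s); default `maxStableDt(medium)`.
#' @return a [TwinConfig].
#' @export
twinConfig <- function(pulse, array, ir, medium, duration, dt = NULL) {
  if (is.null(dt)) dt <- maxStableDt(medium)
  new("TwinConfig", pulse = pulse, array = array, ir = ir, medium = medium,
      duration = duration, dt = dt)
}

setMethod("show", "TwinConfig", function(object) {
  cat(sprintf(paste0("TwinConfig: %d-element array, %s pulse, %s IR, ",
                     "%.1f us window at dt %.3g us\n"),
              nElements(object@array), object@pulse@kind, object@ir@kind,
              object@duration * 1e6, object@dt * 1e6))
})

## internal: plan + kernel cache for repeated applications of F / F^T
twinPlan <- function(twin) {
  grid <- twin@medium@grid
  d <- gridDim(grid)
  sp <- arraySensorPoints(twin@array, d)
  plan <- solverPlan(twin@medium, twin@dt, sp$points)
  n_t <- max(2L, as.integer(floor(twin@duration / twin@dt)) + 1L)
  kern <- convFull(pulseKernel(twin@pulse, twin@dt), irKernel(twin@ir, twin@dt))
  list(plan = plan, group = sp$group, n_sub = sp$n_sub, n_t = n_t,
       n_elem = nElements(twin@array), kern = kern, dt = twin@dt)
}

## F as a matrix-free linear map on plain arrays (used in training loops)
twinForwardRaw <- function(p0_values, tp) {
  y <- propagateCore(tp$plan, p0_values, tp$n_t)
  elem <- rowsum(y, tp$group, reorder = TRUE)
  for (i in seq_len(nrow(elem))) elem[i, ] <- convTrunc(elem[i, ], tp$kern)
  elem
}

## exact adjoint of twinForwardRaw
twinAdjointRaw <- function(sino_bar, tp) {
  elem <- sino_bar
  for (i in seq_len(nrow(elem))) elem[i, ] <- convTruncAdjoint(elem[i, ], tp$kern)
  subbar <- elem[tp$group, , drop = FALSE]
  propagateAdjointCore(tp$plan, subbar)
}

#' Unified digital-twin forward operator F
#'
#' Composes acoustic propagation to every sub-element sensor point,
#' radiation-pulse convolution, finite-element summation over sub-elements
#' and impulse-response filtering into the single linear operator
#' F mapping an initial pressure volume to the recorded sinogram
#' (one channel per array element).
#'
#' @param p0 a [PressureVolume] on the twin's medium grid.
#' @param twin a [TwinConfig].
#' @return a [Sinogram] (units flag `"relative"`: detected units).
#' @export
forwardOperator <- function(p0, twin) {
  if (!sameGrid(p0@grid, twin@medium@grid))
    stop("p0 must live on the twin's medium grid")
  tp <- twinPlan(twin)
  data <- twinForwardRaw(p0@values, tp)
  sinogram(data, dt = tp$dt, t0 = 0, channel_map = seq_len(tp$n_elem),
           units_flag = "relative")
}

#' Adjoint of the digital-twin forward operator
#'
#' Applies the exact adjoint F^T of [forwardOperator()] to a sinogram:
#' impulse-response and pulse correlation, distribution over sub-elements,
#' and the adjoint of the propagate-and-record map.  This is the gradient
#' back-path of the sinogram-domain physics loss.
#'
#' @param s a [Sinogram] with the twin's geometry.
#' @param twin a [TwinConfig].
#' @return a [PressureVolume] (role `"p_rec"`; an adjoint image, not a
#'   physical pressure).
#' @export
adjointOperator <- function(s, twin) {
  tp <- twinPlan(twin)
  if (nrow(s@data) != tp$n_elem)
    stop("sinogram channel count does not match the twin array")
  vol <- twinAdjointRaw(s@data, tp)
  pressureVolume(array(vol, dim = twin@medium@grid@shape),
                 twin@medium@grid, role = "p_rec")
}
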