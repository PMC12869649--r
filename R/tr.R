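## Time-reversal reconstruction: the recorded sinogram is reversed in time
## and re-emitted from the detector locations through the medium; waves
## refocus at their sources and the field at the final reversed-time step is
## the reconstruction.

#' Time-reversal configuration
#'
#' @param medium an [AcousticMedium] (the prior acoustic knowledge used
#'   during back-propagation).
#' @param array the [TransducerArray] that recorded the sinogram.
#' @param grid reconstruction [Grid]; default the medium grid.
#' @param injection_mode `"additive-source"` (default) or `"dirichlet"`.
#' @return a [TRConfig].
#' @export
trConfig <- function(medium, array, grid = NULL,
                     injection_mode = "additive-source") {
  if (is.null(grid)) grid <- medium@grid
  new("TRConfig", medium = medium, array = array, grid = grid,
      injection_mode = injection_mode)
}

#' Reverse a sinogram in time
#'
#' Flips the time axis of every channel (reversed sample k = original sample
#' N - 1 - k, zero-based); dt and the channel map are preserved and t0 is
#' kept at the window start so the reversed recording occupies the same
#' window.  Applying the operation twice returns the original sinogram.
#'
#' @param s a [Sinogram].
#' @return a [Sinogram].
#' @export
reverseSinogram <- function(s) {
  sinogram(s@data[, rev(seq_len(ncol(s@data))), drop = FALSE], dt = s@dt,
           t0 = s@t0, channel_map = s@channel_map, units_flag = s@units_flag)
}

#' Time-reversal reconstruction of initial pressure
#'
#' Back-propagates the time-reversed sinogram from the array's sub-element
#' locations through the medium with the k-space PML solver (each element's
#' signal is re-emitted from its sub-element points), and returns the field
#' at the final reversed-time step.  With a limited-view (planar) array the
#' reconstruction localises sources but distorts morphology and amplitude
#' and may contain negative values; no positivity clamp is applied, so the
#' enhancement network sees realistic artifacts.
#'
#' @param s a [Sinogram]; channel count must match the array.
#' @param cfg a [TRConfig].
#' @return a [PressureVolume] with role `"p_rec"` (relative units).
#' @export
trReconstruct <- function(s, cfg) {
  d <- gridDim(cfg@grid)
  sp <- arraySensorPoints(cfg@array, d)
  if (nrow(s@data) != nElements(cfg@array))
    stop(sprintf("sinogram has %d channels but the array has %d elements",
                 nrow(s@data), nElements(cfg@array)))
  if (all(s@data == 0))
    return(pressureVolume(array(0, cfg@grid@shape), cfg@grid, role = "p_rec"))
  plan <- pmlPlan(cfg@medium, s@dt, sp$points)
  rev_data <- s@data[, rev(seq_len(ncol(s@data))), drop = FALSE]
  ## each sub-element re-emits its element's signal (aperture split evenly)
  signals <- rev_data[sp$group, , drop = FALSE] / sp$n_sub
  vol <- pmlInjectCore(plan, signals,
                       dirichlet = cfg@injection_mode == "dirichlet")
  pressureVolume(array(vol, cfg@grid@shape), cfg@grid, role = "p_rec")
}
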