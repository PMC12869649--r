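## Single-point pressure-to-dose calibration: reconstructed pressure is on a
## relative (detected) scale, so a single reference location with known
## delivered dose anchors the conversion K = D_c / p_c.

#' Compute a calibration factor
#'
#' @param d_c delivered dose at the calibration point (cGy), e.g. from
#'   machine log files (the tank protocol delivers 1.72 cGy per pulse at the
#'   Bragg peak; the torso protocol 1.88 cGy).
#' @param p_c reconstructed pressure at the same location (relative units);
#'   must be positive.
#' @param location grid coordinate (voxel index) of the calibration point.
#' @return a [CalibrationFactor] with k = d_c / p_c.
#' @export
calibrationFactor <- function(d_c, p_c, location = NA_real_) {
  if (!is.finite(p_c) || p_c <= 0)
    stop("calibration point has no signal (p_c must be > 0)")
  if (d_c < 0) stop("reference dose must be >= 0")
  new("CalibrationFactor", k = d_c / p_c, reference_dose = d_c,
      reference_pressure = p_c, reference_location = as.numeric(location))
}

setMethod("show", "CalibrationFactor", function(object) {
  cat(sprintf("CalibrationFactor: k = %.4g cGy/unit (D_c = %.4g cGy, p_c = %.4g)\n",
              object@k, object@reference_dose, object@reference_pressure))
})

#' Read the calibration pressure from a prediction
#'
#' Returns p_c at an explicit voxel location or at the argmax voxel
#' (`"auto-peak"`, the Bragg-peak convention), optionally averaged over the
#' surrounding 3^d neighbourhood.
#'
#' @param p_pred a [PressureVolume].
#' @param location integer voxel index vector, or `"auto-peak"`.
#' @param neighborhood if TRUE, mean over the 3^d voxel neighbourhood.
#' @return list with `p_c` and `location`.
#' @export
calibrationPressure <- function(p_pred, location = "auto-peak",
                                neighborhood = FALSE) {
  v <- p_pred@values
  dims <- dim(v)
  if (identical(location, "auto-peak")) {
    location <- arrayInd(which.max(v), dims)[1, ]
  }
  location <- as.integer(location)
  if (neighborhood) {
    ix <- lapply(seq_along(dims), function(a)
      max(1L, location[a] - 1L):min(dims[a], location[a] + 1L))
    p_c <- mean(do.call(`[`, c(list(v), ix)))
  } else {
    p_c <- v[matrix(location, 1)]
  }
  list(p_c = p_c, location = location)
}

#' Apply a calibration factor to a predicted pressure volume
#'
#' Scales the (relative) pressure voxelwise by k, yielding absolute dose in
#' cGy; at the calibration voxel the output equals D_c exactly.
#'
#' @param p_pred a [PressureVolume].
#' @param k a [CalibrationFactor].
#' @return a [DoseVolume] in cGy (negative reconstruction values are clamped
#'   to zero, as dose is non-negative by definition).
#' @export
applyCalibration <- function(p_pred, k) {
  vals <- pmax(k@k * p_pred@values, 0)
  doseVolume(vals, p_pred@grid,
             meta = list(units = "cGy", calibration_k = k@k,
                         reference_dose_cGy = k@reference_dose))
}
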