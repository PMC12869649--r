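#' Construct an acoustic medium
#'
#' Scalar inputs are broadcast over the grid.
#'
#' @param grid a [Grid].
#' @param c sound speed (m/s), scalar or array.
#' @param rho density (kg/m^3), scalar or array.
#' @param grueneisen Grueneisen parameter, scalar or array.
#' @param eta_th heat-conversion fraction in (0, 1].
#' @param alpha_att optional attenuation coefficient (dB/(MHz^y cm)).
#' @param att_power attenuation power-law exponent y.
#' @return an [AcousticMedium].
#' @export
acousticMedium <- function(grid, c = 1500, rho = 1000, grueneisen = 0.11,
                           eta_th = 1, alpha_att = NULL, att_power = 1.1) {
  bc <- function(x) {
    if (length(x) == 1L) array(x, dim = grid@shape)
    else asShapedArray(x, grid@shape)
  }
  new("AcousticMedium", grid = grid, c = bc(c), rho = bc(rho),
      grueneisen = bc(grueneisen), eta_th = eta_th,
      alpha_att = if (is.null(alpha_att)) NULL else bc(alpha_att),
      att_power = att_power)
}

#' Homogeneous water medium
#'
#' Water at room temperature: c = 1500 m/s, rho = 1000 kg/m^3,
#' Grueneisen parameter 0.11, all absorbed dose converted to heat.
#'
#' @param grid a [Grid].
#' @export
waterMedium <- function(grid) acousticMedium(grid)

setMethod("show", "AcousticMedium", function(object) {
  cat(sprintf(paste0("AcousticMedium: %s voxels, c in [%.0f, %.0f] m/s, ",
                     "rho in [%.0f, %.0f] kg/m^3, eta_th %.2f\n"),
              paste(object@grid@shape, collapse = " x "),
              min(object@c), max(object@c), min(object@rho), max(object@rho),
              object@eta_th))
})

#' Convert absorbed dose to initial acoustic pressure
#'
#' Applies the Grueneisen relation p0 = Gamma * eta_th * D * rho voxelwise:
#' dose (Gy = J/kg) times density gives the absorbed energy density (J/m^3 =
#' Pa), scaled by the heat fraction and the Grueneisen parameter.
#'
#' @param dose a [DoseVolume].
#' @param medium an [AcousticMedium] on the same grid.
#' @return a [PressureVolume] with role `"p0"` (Pa).
#' @examples
#' g <- regularGrid(c(8, 8), 1e-3)
#' d <- doseVolume(array(0.0172, c(8, 8)), g)
#' max(volumeValues(doseToPressure(d, waterMedium(g))))  # 1.892 Pa
#' @export
doseToPressure <- function(dose, medium) {
  if (!sameGrid(dose@grid, medium@grid))
    stop("dose and medium must share the same grid")
  p0 <- medium@grueneisen * medium@eta_th * dose@values * medium@rho
  pressureVolume(p0, dose@grid, role = "p0")
}
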