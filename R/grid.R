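#' Construct a regular grid
#'
#' @param shape integer vector of voxel counts per axis (length 1-3).
#' @param spacing voxel edge length(s) in metres; recycled to the number of axes.
#' @param origin physical coordinate of the first voxel centre (m); default 0.
#' @return a [Grid].
#' @examples
#' g <- regularGrid(c(64, 64), spacing = 1e-3)
#' gridCoords(g, 1)[1:3]
#' @export
regularGrid <- function(shape, spacing, origin = NULL) {
  shape <- as.integer(shape)
  d <- length(shape)
  spacing <- rep_len(as.numeric(spacing), d)
  if (is.null(origin)) origin <- rep(0, d)
  origin <- rep_len(as.numeric(origin), d)
  new("Grid", shape = shape, spacing = spacing, origin = origin)
}

#' Number of spatial axes of a grid
#' @param grid a [Grid].
#' @export
gridDim <- function(grid) length(grid@shape)

#' Voxel counts of a grid
#' @param grid a [Grid].
#' @export
gridShape <- function(grid) grid@shape

#' Voxel spacings of a grid (m)
#' @param grid a [Grid].
#' @export
gridSpacing <- function(grid) grid@spacing

#' Voxel-centre coordinates along one axis (m)
#' @param grid a [Grid].
#' @param axis axis index.
#' @export
gridCoords <- function(grid, axis) {
  grid@origin[axis] + (seq_len(grid@shape[axis]) - 1L) * grid@spacing[axis]
}

#' Total number of voxels
#' @param grid a [Grid].
#' @export
gridLength <- function(grid) prod(grid@shape)

setMethod("show", "Grid", function(object) {
  cat(sprintf("Grid: %s voxels, spacing %s mm, origin %s mm\n",
              paste(object@shape, collapse = " x "),
              paste(signif(object@spacing * 1e3, 4), collapse = " x "),
              paste(signif(object@origin * 1e3, 4), collapse = ", ")))
})

## shared small helpers ------------------------------------------------------

sameGrid <- function(a, b) {
  identical(a@shape, b@shape) &&
    isTRUE(all.equal(a@spacing, b@spacing, tolerance = 1e-12)) &&
    isTRUE(all.equal(a@origin, b@origin, tolerance = 1e-12))
}

asShapedArray <- function(x, shape) {
  array(as.numeric(x), dim = as.integer(shape))
}

#' Construct a dose volume
#' @param values numeric array of dose values (Gy).
#' @param grid a [Grid] matching `dim(values)`.
#' @param meta optional beam descriptor list.
#' @export
doseVolume <- function(values, grid, meta = list()) {
  new("DoseVolume", grid = grid, values = asShapedArray(values, grid@shape),
      meta = meta)
}

#' Construct a pressure volume
#' @param values numeric array of pressure values.
#' @param grid a [Grid] matching `dim(values)`.
#' @param role `"p0"`, `"p_rec"` or `"p_pred"`.
#' @export
pressureVolume <- function(values, grid, role = "p0") {
  new("PressureVolume", grid = grid,
      values = asShapedArray(values, grid@shape), role = role)
}

#' Extract the value array of a volume
#' @param x a [DoseVolume] or [PressureVolume].
#' @export
volumeValues <- function(x) x@values

#' Extract the grid of a volume
#' @param x a [DoseVolume] or [PressureVolume].
#' @export
volumeGrid <- function(x) x@grid

#' Role of a pressure volume
#' @param x a [PressureVolume].
#' @export
pressureRole <- function(x) x@role

setMethod("show", "DoseVolume", function(object) {
  cat(sprintf("DoseVolume: %s voxels, max %.4g Gy",
              paste(object@grid@shape, collapse = " x "), max(object@values)))
  if (!is.null(object@meta$modality))
    cat(sprintf(" [%s]", object@meta$modality))
  cat("\n")
})

setMethod("show", "PressureVolume", function(object) {
  cat(sprintf("PressureVolume (role %s): %s voxels, range [%.4g, %.4g]\n",
              object@role, paste(object@grid@shape, collapse = " x "),
              min(object@values), max(object@values)))
})

#' Construct a time series
#' @param samples numeric pressure samples.
#' @param dt sampling interval (s).
#' @param t0 time of the first sample (s).
#' @export
timeSeries <- function(samples, dt, t0 = 0) {
  new("TimeSeries", samples = as.numeric(samples), dt = as.numeric(dt),
      t0 = as.numeric(t0))
}

#' Time axis of a time series
#' @param ts a [TimeSeries].
#' @export
timeAxis <- function(ts) ts@t0 + (seq_along(ts@samples) - 1L) * ts@dt

setMethod("show", "TimeSeries", function(object) {
  cat(sprintf("TimeSeries: %d samples, dt %.3g us, t0 %.3g us\n",
              length(object@samples), object@dt * 1e6, object@t0 * 1e6))
})

#' Construct a sinogram
#' @param data channels x samples matrix.
#' @param dt sampling interval (s).
#' @param t0 start time (s).
#' @param channel_map channel -> element mapping; default identity.
#' @param units_flag `"absolute"` or `"relative"`.
#' @export
sinogram <- function(data, dt, t0 = 0, channel_map = seq_len(nrow(data)),
                     units_flag = "absolute") {
  new("Sinogram", data = data, dt = as.numeric(dt), t0 = as.numeric(t0),
      channel_map = as.integer(channel_map), units_flag = units_flag)
}

#' Sinogram data matrix
#' @param s a [Sinogram].
#' @export
sinogramData <- function(s) s@data

#' Number of sinogram channels
#' @param s a [Sinogram].
#' @export
nChannels <- function(s) nrow(s@data)

setMethod("show", "Sinogram", function(object) {
  cat(sprintf("Sinogram: %d channels x %d samples, dt %.3g us (%s units)\n",
              nrow(object@data), ncol(object@data), object@dt * 1e6,
              object@units_flag))
})
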