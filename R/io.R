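## Container I/O.  Gridded data (volumes, sinograms, media) are stored in a
## structured serialized archive: a named list of datasets plus an `attrs`
## list (spacing, origin, units, role, ...), validated on read so a missing
## attribute fails with its name.  Catalogs and reports are CSV; configs are
## YAML.

writeContainer <- function(datasets, attrs, path) {
  for (nm in names(datasets))
    if (any(!is.finite(datasets[[nm]])))
      stop(sprintf("refusing to write non-finite values in dataset '%s'", nm))
  obj <- list(datasets = datasets, attrs = attrs,
              format = "radiacoustics-container", version = 1L)
  saveRDS(obj, path)
  invisible(path)
}

readContainer <- function(path, required_attrs = character()) {
  obj <- readRDS(path)
  if (!identical(obj$format, "radiacoustics-container"))
    stop("not a radiacoustics container: ", path)
  for (a in required_attrs)
    if (is.null(obj$attrs[[a]]))
      stop(sprintf("container is missing required attribute '%s'", a))
  obj
}

#' Write a volume to a container file
#'
#' Stores the value array as dataset `dose` or `pressure` (by class) with
#' grid attributes `spacing`, `origin`, `units` and role/beam metadata.
#' Round trips are bitwise lossless; volumes containing non-finite values
#' are refused.
#'
#' @param vol a [DoseVolume] or [PressureVolume].
#' @param path output file path.
#' @export
writeVolume <- function(vol, path) {
  if (is(vol, "DoseVolume")) {
    writeContainer(list(dose = vol@values),
                   list(spacing = vol@grid@spacing, origin = vol@grid@origin,
                        units = "Gy", meta = vol@meta), path)
  } else if (is(vol, "PressureVolume")) {
    writeContainer(list(pressure = vol@values),
                   list(spacing = vol@grid@spacing, origin = vol@grid@origin,
                        units = "Pa", role = vol@role), path)
  } else stop("vol must be a DoseVolume or PressureVolume")
}

#' Read a volume from a container file
#'
#' @param path container file written by [writeVolume()].
#' @return the stored [DoseVolume] or [PressureVolume].
#' @export
readVolume <- function(path) {
  obj <- readContainer(path, c("spacing", "origin", "units"))
  grid <- regularGrid(dim(obj$datasets[[1]]), obj$attrs$spacing,
                      obj$attrs$origin)
  if (!is.null(obj$datasets$dose))
    doseVolume(obj$datasets$dose, grid, meta = obj$attrs$meta)
  else if (!is.null(obj$datasets$pressure))
    pressureVolume(obj$datasets$pressure, grid, role = obj$attrs$role)
  else stop("container holds neither a 'dose' nor a 'pressure' dataset")
}

#' Write / read a sinogram container
#'
#' Dataset `data` (channels x samples) with attributes `dt`, `t0`,
#' `units_flag` and the channel map.
#'
#' @param s a [Sinogram].
#' @param path file path.
#' @export
writeSinogram <- function(s, path) {
  writeContainer(list(data = s@data),
                 list(dt = s@dt, t0 = s@t0, units_flag = s@units_flag,
                      channel_map = s@channel_map), path)
}

#' @rdname writeSinogram
#' @export
readSinogram <- function(path) {
  obj <- readContainer(path, c("dt", "t0", "units_flag"))
  sinogram(obj$datasets$data, dt = obj$attrs$dt, t0 = obj$attrs$t0,
           channel_map = obj$attrs$channel_map,
           units_flag = obj$attrs$units_flag)
}

#' Write / read a medium container
#'
#' Datasets `c`, `rho`, `grueneisen` with grid attributes.
#'
#' @param medium an [AcousticMedium].
#' @param path file path.
#' @export
writeMedium <- function(medium, path) {
  writeContainer(list(c = medium@c, rho = medium@rho,
                      grueneisen = medium@grueneisen),
                 list(spacing = medium@grid@spacing,
                      origin = medium@grid@origin,
                      eta_th = medium@eta_th), path)
}

#' @rdname writeMedium
#' @export
readMedium <- function(path) {
  obj <- readContainer(path, c("spacing", "origin", "eta_th"))
  grid <- regularGrid(dim(obj$datasets$c), obj$attrs$spacing,
                      obj$attrs$origin)
  acousticMedium(grid, c = obj$datasets$c, rho = obj$datasets$rho,
                 grueneisen = obj$datasets$grueneisen,
                 eta_th = obj$attrs$eta_th)
}

#' Write / read a dataset catalog as a CSV manifest
#'
#' Columns: id, modality, energy_MeV, shift_x_mm, shift_y_mm, excluded,
#' split.
#'
#' @param catalog a [DatasetCatalog].
#' @param path CSV path.
#' @export
writeCatalog <- function(catalog, path) {
  utils::write.csv(catalog@entries, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCatalog
#' @export
readCatalog <- function(path) {
  e <- utils::read.csv(path, stringsAsFactors = FALSE)
  e$split[is.na(e$split)] <- ""
  counts <- list(total = nrow(e), excluded = sum(e$excluded),
                 usable = sum(!e$excluded),
                 train = sum(e$split == "train"), val = sum(e$split == "val"),
                 test = sum(e$split == "test"))
  new("DatasetCatalog", entries = e, counts = counts, seed = NA_integer_)
}
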