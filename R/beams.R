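## Synthetic beam models: proton pencil beams with an analytic Bragg curve,
## collimated FLASH-electron fields, radiation pulse profiles and the
## water-tank experiment catalog.

#' Proton pencil-beam specification
#'
#' @param energy beam kinetic energy (MeV).
#' @param entry entry point (m); length must match the grid dimension when used.
#' @param direction axis-aligned unit vector (beam axis); default +x.
#' @param sigma_lateral lateral Gaussian width (m); default 4 mm.
#' @param range_alpha,range_p range-energy power-law coefficients, R[cm] =
#'   alpha * E[MeV]^p; water defaults alpha = 0.0022, p = 1.77.
#' @param fluence_scale peak (Bragg) dose in Gy; default 1.
#' @param distal_sigma distal falloff width (m); default 3 mm.
#' @return a [ProtonBeamSpec].
#' @export
protonBeamSpec <- function(energy, entry = c(0, 0, 0),
                           direction = c(1, 0, 0), sigma_lateral = 4e-3,
                           range_alpha = 0.0022, range_p = 1.77,
                           fluence_scale = 1, distal_sigma = 3e-3) {
  new("ProtonBeamSpec", energy = energy, entry = as.numeric(entry),
      direction = as.numeric(direction), sigma_lateral = sigma_lateral,
      range_alpha = range_alpha, range_p = range_p,
      fluence_scale = fluence_scale, distal_sigma = distal_sigma)
}

#' Proton range from the range-energy power law
#'
#' R = alpha * E^p, returned in metres (alpha parameterised in cm, E in MeV).
#' @param spec a [ProtonBeamSpec].
#' @export
protonRange <- function(spec) {
  spec@range_alpha * spec@energy^spec@range_p * 1e-2
}

## Analytic depth-dose: entrance plateau that fades out just before the peak
## (so the curve's argmax stays on the power-law range) plus an asymmetric
## Gaussian Bragg peak with a slow proximal rise and a sharp distal falloff.
braggDepthDose <- function(z, R, distal_sigma, plateau = 0.25) {
  prox_sigma <- pmax(0.07 * R, 2e-3)
  peak <- ifelse(z <= R,
                 exp(-(z - R)^2 / (2 * prox_sigma^2)),
                 exp(-(z - R)^2 / (2 * distal_sigma^2)))
  ## plateau rises gently with depth and is switched off 2 distal sigmas
  ## before the peak so it cannot displace the argmax
  plat <- plateau * (1 + 0.5 * z / R) / (1 + exp((z - (R - 2 * distal_sigma)) /
                                                 (distal_sigma / 2)))
  d <- peak + plat
  d[z < 0] <- 0
  d
}

beamAxisIndex <- function(direction) which(abs(direction) > 1e-12)

#' Generate a proton pencil-beam dose volume
#'
#' Builds a separable dose field: an analytic depth-dose curve with a
#' pronounced Bragg peak at depth R = alpha E^p along the beam axis, times a
#' lateral Gaussian of width `sigma_lateral`.  The volume is normalised so the
#' maximum voxel equals `fluence_scale` (Gy per pulse).
#'
#' @param spec a [ProtonBeamSpec].
#' @param grid a [Grid]; must extend past the Bragg peak along the beam axis.
#' @return a [DoseVolume].
#' @examples
#' g <- regularGrid(c(64, 48), spacing = 1e-3)
#' d <- protonPencilBeam(protonBeamSpec(55, entry = c(0, 0.024)), g)
#' max(volumeValues(d))
#' @export
protonPencilBeam <- function(spec, grid) {
  d <- gridDim(grid)
  entry <- rep_len(spec@entry, d)
  dir <- rep_len(spec@direction, d)
  if (abs(sqrt(sum(dir^2)) - 1) > 1e-9)
    stop("beam direction must be a unit vector")
  ax <- beamAxisIndex(dir)
  R <- protonRange(spec)
  zc <- (gridCoords(grid, ax) - entry[ax]) * sign(dir[ax])
  if (R > max(zc))
    stop(sprintf(paste0("Bragg peak at %.1f mm lies outside the grid; the ",
                        "grid must extend to at least %.1f mm along axis %d"),
                 R * 1e3, R * 1e3, ax))
  depth <- braggDepthDose(zc, R, spec@distal_sigma)
  lat <- lapply(setdiff(seq_len(d), ax), function(a) {
    exp(-(gridCoords(grid, a) - entry[a])^2 / (2 * spec@sigma_lateral^2))
  })
  vol <- separableField(grid, ax, depth, lat)
  m <- max(vol)
  if (m > 0 && spec@fluence_scale > 0) vol <- vol * (spec@fluence_scale / m)
  else vol <- vol * 0
  doseVolume(vol, grid,
             meta = list(modality = "proton", energy_MeV = spec@energy,
                         entry = entry, direction = dir,
                         range_m = R))
}

## outer product of a depth profile (on axis ax) with lateral profiles
separableField <- function(grid, ax, depth, lateral) {
  d <- gridDim(grid)
  profs <- vector("list", d)
  profs[[ax]] <- depth
  j <- 1L
  for (a in setdiff(seq_len(d), ax)) { profs[[a]] <- lateral[[j]]; j <- j + 1L }
  out <- profs[[1]]
  if (d >= 2) out <- outer(out, profs[[2]])
  if (d >= 3) out <- outer(out, profs[[3]])
  array(out, dim = grid@shape)
}

#' FLASH-electron field specification
#'
#' @param field_size collimator aperture (m), scalar or length-2.
#' @param r50 depth of 50% dose (m).
#' @param surface_dose_fraction entrance dose relative to max; default 0.85.
#' @param dose_per_pulse Gy per pulse; default 1 (the FLASH protocol delivers
#'   1 Gy in 1 us per pulse).
#' @param pulse_duration s; default 1e-6.
#' @param entry entry point (m).
#' @param direction axis-aligned unit vector.
#' @param penumbra_sigma lateral penumbra width (m); default 2 mm.
#' @return an [ElectronBeamSpec].
#' @export
electronBeamSpec <- function(field_size, r50, surface_dose_fraction = 0.85,
                             dose_per_pulse = 1, pulse_duration = 1e-6,
                             entry = c(0, 0, 0), direction = c(1, 0, 0),
                             penumbra_sigma = 2e-3) {
  if (any(!is.finite(field_size)) || any(field_size <= 0))
    stop("field_size must be > 0")
  new("ElectronBeamSpec", field_size = rep_len(as.numeric(field_size), 2L),
      r50 = r50, surface_dose_fraction = surface_dose_fraction,
      dose_per_pulse = dose_per_pulse, pulse_duration = pulse_duration,
      entry = as.numeric(entry), direction = as.numeric(direction),
      penumbra_sigma = penumbra_sigma)
}

electronDepthDose <- function(z, r50, sdf) {
  zmax <- 0.6 * r50
  w <- 0.05 * r50
  build <- pmin(1, sdf + (1 - sdf) * (z / zmax))
  fall <- 1 / (1 + exp((z - r50) / w))
  d <- build * fall
  d[z < 0] <- 0
  d
}

## top-hat with Gaussian penumbra, normalised to 1 on the central axis
penumbraProfile <- function(x, half_width, sigma) {
  p <- pnorm((x + half_width) / sigma) - pnorm((x - half_width) / sigma)
  p / (pnorm(half_width / sigma) - pnorm(-half_width / sigma))
}

#' Generate a collimated FLASH-electron dose volume
#'
#' Dose is a lateral top-hat of the collimator size with Gaussian-penumbra
#' edges, times an electron depth-dose curve (build-up to a maximum, then a
#' sigmoid falloff passing through 50% at `r50`).  Maximum voxel dose equals
#' `dose_per_pulse`.
#'
#' @param spec an [ElectronBeamSpec].
#' @param grid a [Grid]; must extend past `r50` along the beam axis.
#' @return a [DoseVolume].
#' @export
electronFlashBeam <- function(spec, grid) {
  d <- gridDim(grid)
  entry <- rep_len(spec@entry, d)
  dir <- rep_len(spec@direction, d)
  ax <- beamAxisIndex(dir)
  zc <- (gridCoords(grid, ax) - entry[ax]) * sign(dir[ax])
  if (spec@r50 > max(zc))
    stop(sprintf("r50 at %.1f mm is deeper than the grid extent along axis %d",
                 spec@r50 * 1e3, ax))
  depth <- electronDepthDose(zc, spec@r50, spec@surface_dose_fraction)
  lataxes <- setdiff(seq_len(d), ax)
  lat <- lapply(seq_along(lataxes), function(j) {
    a <- lataxes[j]
    penumbraProfile(gridCoords(grid, a) - entry[a],
                    spec@field_size[j] / 2, spec@penumbra_sigma)
  })
  vol <- separableField(grid, ax, depth, lat)
  vol <- vol * (spec@dose_per_pulse / max(vol))
  doseVolume(vol, grid,
             meta = list(modality = "electron", r50_m = spec@r50,
                         dose_per_pulse_Gy = spec@dose_per_pulse,
                         pulse_duration_s = spec@pulse_duration,
                         entry = entry, direction = dir))
}

#' Instantaneous dose rate of a pulsed delivery
#'
#' @param dose_per_pulse dose delivered in one pulse (Gy).
#' @param pulse_duration pulse duration (s).
#' @return dose rate in Gy/s; e.g. 1 Gy in 1 us gives 1e6 Gy/s.
#' @export
instantaneousDoseRate <- function(dose_per_pulse, pulse_duration) {
  if (!is.finite(pulse_duration) || pulse_duration <= 0)
    stop("pulse_duration must be > 0")
  dose_per_pulse / pulse_duration
}

#' Imaging frame rate under N-pulse averaging
#'
#' @param pulse_rate_hz beam pulse repetition rate (Hz).
#' @param n_average number of pulses averaged per frame.
#' @return frames per second; e.g. a 750 Hz beam with 10-signal averaging
#'   images at 75 frames per second.
#' @export
imagingFrameRate <- function(pulse_rate_hz, n_average) {
  if (n_average < 1) stop("n_average must be >= 1")
  pulse_rate_hz / n_average
}

#' Build a radiation pulse temporal profile
#'
#' Non-delta kinds are normalised to unit area (sum x dt = 1) so convolving a
#' signal with the pulse preserves its integral; the delta kind is a single
#' unit sample (identity under convolution).
#'
#' @param kind `"delta"`, `"box"`, `"gaussian"` or `"double-gaussian"`.
#' @param duration pulse duration (s): box width, or 6 sigma for the
#'   Gaussian kinds (the double-Gaussian places two lobes within it).
#' @param dt sampling interval (s).
#' @return a [PulseProfile].
#' @export
makePulse <- function(kind = c("delta", "box", "gaussian", "double-gaussian"),
                      duration = 0, dt = 1e-7) {
  kind <- match.arg(kind)
  if (dt <= 0) stop("dt must be > 0")
  if (duration < 0) stop("duration must be >= 0")
  if (kind == "delta")
    return(new("PulseProfile", samples = 1, dt = dt, kind = kind))
  n <- max(1L, as.integer(round(duration / dt)))
  t <- (seq_len(n) - 0.5) * dt
  s <- switch(kind,
    box = rep(1, n),
    gaussian = {
      sig <- duration / 6
      exp(-(t - duration / 2)^2 / (2 * sig^2))
    },
    "double-gaussian" = {
      sig <- duration / 12
      exp(-(t - duration / 3)^2 / (2 * sig^2)) +
        0.6 * exp(-(t - 2 * duration / 3)^2 / (2 * sig^2))
    })
  s <- s / (sum(s) * dt)
  new("PulseProfile", samples = s, dt = dt, kind = kind)
}

#' Water-tank experiment catalog
#'
#' Enumerates the full factorial of proton beam energies x transducer
#' positions that defines the tank protocol (with `n_positions = 5`:
#' centre plus 1 cm shifts left/right/up/down), marks a seeded random subset
#' as excluded (emulating recordings dropped for interference) and assigns
#' train/validation/test split tags to the remainder.  The reference protocol
#' (7 energies x 5 positions, 2 excluded, 20/5/8 split) yields 35 total and
#' 33 usable sinograms.
#'
#' @param n_energies number of beam energies.
#' @param n_positions number of array positions (5 = centre + 4 shifts).
#' @param n_excluded number of entries to exclude.
#' @param split integer length-3 (train, val, test) sizes.
#' @param seed integer seed; the catalog is reproducible from it.
#' @param energies optional explicit energies (MeV); default evenly spaced
#'   50-74 MeV (desk-scale tank).
#' @param shift_mm off-centre shift magnitude in mm (default 10).
#' @return a [DatasetCatalog].
#' @export
watertankCatalog <- function(n_energies = 7, n_positions = 5, n_excluded = 2,
                             split = c(20, 5, 8), seed = 1L,
                             energies = NULL, shift_mm = 10) {
  total <- n_energies * n_positions
  if (total < n_excluded + sum(split))
    stop("split sizes plus exclusions exceed the number of catalog entries")
  if (is.null(energies))
    energies <- if (n_energies == 1) 62 else seq(50, 74, length.out = n_energies)
  shifts <- positionShifts(n_positions, shift_mm)
  e <- expand.grid(pos = seq_len(n_positions), energy = energies)
  entries <- data.frame(
    id = sprintf("wt-%03d", seq_len(total)),
    modality = "proton",
    energy_MeV = e$energy,
    shift_x_mm = shifts$x[e$pos],
    shift_y_mm = shifts$y[e$pos],
    excluded = FALSE,
    split = "",
    stringsAsFactors = FALSE)
  set.seed(seed)
  if (n_excluded > 0)
    entries$excluded[sample.int(total, n_excluded)] <- TRUE
  usable <- which(!entries$excluded)
  if (sum(split) > length(usable))
    stop("split sizes exceed usable entries")
  tags <- rep(c("train", "val", "test"), times = split)
  pick <- sample(usable, sum(split))
  entries$split[pick] <- tags
  counts <- list(total = total, excluded = sum(entries$excluded),
                 usable = sum(!entries$excluded),
                 train = split[1], val = split[2], test = split[3])
  new("DatasetCatalog", entries = entries, counts = counts,
      seed = as.integer(seed))
}

## centre + shifts of +-shift_mm on the two lateral axes; additional
## positions (beyond 5) repeat the four directions at growing multiples
positionShifts <- function(n_positions, shift_mm) {
  k <- seq_len(max(0L, n_positions - 1L))
  ring <- 1L + (k - 1L) %/% 4L
  dir <- (k - 1L) %% 4L
  x <- c(0, ring * shift_mm * c(-1, 1, 0, 0)[dir + 1L])
  y <- c(0, ring * shift_mm * c(0, 0, 1, -1)[dir + 1L])
  list(x = x[seq_len(n_positions)], y = y[seq_len(n_positions)])
}

#' Catalog entries
#' @param catalog a [DatasetCatalog].
#' @export
catalogEntries <- function(catalog) catalog@entries

#' Catalog counts
#' @param catalog a [DatasetCatalog].
#' @export
catalogCounts <- function(catalog) catalog@counts

setMethod("show", "DatasetCatalog", function(object) {
  cnt <- object@counts
  cat(sprintf(paste0("DatasetCatalog: %d entries (%d usable, %d excluded); ",
                     "split %d/%d/%d train/val/test\n"),
              cnt$total, cnt$usable, cnt$excluded, cnt$train, cnt$val,
              cnt$test))
})
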