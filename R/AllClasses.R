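#' @import methods
#' @importFrom stats fft rnorm runif pnorm sd cor
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))
setClassUnion("arrayOrNULL", c("array", "NULL"))

#' Regular voxel grid
#'
#' Describes a regular Cartesian grid: voxel counts per axis, voxel edge
#' lengths (metres) and the physical coordinate of the centre of voxel
#' (1,1,...) (voxel-centre convention).  Grids may be 1-, 2- or 3-dimensional;
#' the 2D mode is used throughout the fast test paths, 3D is the product path.
#'
#' @slot shape integer vector of voxel counts per axis.
#' @slot spacing numeric vector of voxel edge lengths per axis (m).
#' @slot origin numeric vector, physical coordinate of the first voxel centre (m).
#' @export
setClass("Grid", representation(shape = "integer", spacing = "numeric",
                                origin = "numeric"))

setValidity("Grid", function(object) {
  d <- length(object@shape)
  if (d < 1L || d > 3L) return("grid must have 1 to 3 axes")
  if (length(object@spacing) != d || length(object@origin) != d)
    return("shape, spacing and origin must have the same length")
  if (any(object@shape < 1L)) return("all voxel counts must be >= 1")
  if (any(!is.finite(object@spacing)) || any(object@spacing <= 0))
    return("all spacings must be finite and > 0")
  if (any(!is.finite(object@origin))) return("origin must be finite")
  TRUE
})

#' Absorbed-dose volume
#'
#' A scalar field of absorbed dose (Gy) on a [Grid], with a free-form beam
#' descriptor (`meta`): modality, energy, entry point, direction.
#' Dose is non-negative and finite everywhere.
#'
#' @slot grid a [Grid].
#' @slot values array of dose values (Gy), dim equal to `shape(grid)`.
#' @slot meta list describing the beam that produced the dose.
#' @export
setClass("DoseVolume", representation(grid = "Grid", values = "array",
                                      meta = "list"))

setValidity("DoseVolume", function(object) {
  if (!identical(dim(object@values), as.integer(object@grid@shape)))
    return("values dim does not match grid shape")
  if (any(!is.finite(object@values))) return("dose values must be finite")
  if (any(object@values < 0)) return("dose values must be >= 0")
  TRUE
})

#' Acoustic-pressure volume
#'
#' A scalar pressure field (Pa, or relative units downstream of detection) on
#' a [Grid].  The `role` records where the field sits in the pipeline:
#' `"p0"` (initial pressure; must be non-negative), `"p_rec"` (time-reversal
#' reconstruction; may contain negative limited-view artifacts) or `"p_pred"`
#' (network prediction).
#'
#' @slot grid a [Grid].
#' @slot values pressure array, dim equal to `shape(grid)`.
#' @slot role character, one of `"p0"`, `"p_rec"`, `"p_pred"`.
#' @export
setClass("PressureVolume", representation(grid = "Grid", values = "array",
                                          role = "character"))

setValidity("PressureVolume", function(object) {
  if (!identical(dim(object@values), as.integer(object@grid@shape)))
    return("values dim does not match grid shape")
  if (any(!is.finite(object@values))) return("pressure values must be finite")
  if (!object@role %in% c("p0", "p_rec", "p_pred"))
    return("role must be one of p0, p_rec, p_pred")
  if (object@role == "p0" && any(object@values < 0))
    return("initial pressure (role p0) must be >= 0")
  TRUE
})

#' Uniformly sampled pressure time series
#'
#' @slot samples numeric vector of pressure samples (Pa).
#' @slot dt sampling interval (s).
#' @slot t0 time of the first sample (s).
#' @export
setClass("TimeSeries", representation(samples = "numeric", dt = "numeric",
                                      t0 = "numeric"))

setValidity("TimeSeries", function(object) {
  if (length(object@dt) != 1L || !is.finite(object@dt) || object@dt <= 0)
    return("dt must be a single finite value > 0")
  if (length(object@t0) != 1L || !is.finite(object@t0))
    return("t0 must be a single finite value")
  if (any(!is.finite(object@samples))) return("samples must be finite")
  TRUE
})

#' Radiation pulse temporal profile
#'
#' Normalised temporal profile of the radiation pulse, used to modulate the
#' instantaneous acoustic source.  Non-delta profiles integrate (sum x dt) to
#' one; the delta kind is a single unit sample.
#'
#' @slot samples normalised amplitude samples (1/s for non-delta kinds).
#' @slot dt sampling interval (s).
#' @slot kind one of `"delta"`, `"box"`, `"gaussian"`, `"double-gaussian"`.
#' @export
setClass("PulseProfile", representation(samples = "numeric", dt = "numeric",
                                        kind = "character"))

setValidity("PulseProfile", function(object) {
  if (!object@kind %in% c("delta", "box", "gaussian", "double-gaussian"))
    return("unknown pulse kind")
  if (!is.finite(object@dt) || object@dt <= 0) return("dt must be > 0")
  if (object@kind == "delta") {
    if (!identical(object@samples, 1)) return("delta pulse must be a single unit sample")
  } else {
    if (abs(sum(object@samples) * object@dt - 1) > 1e-8)
      return("pulse must have unit area (sum x dt = 1)")
  }
  TRUE
})

#' Transducer impulse response
#'
#' Temporal response of a transducer element to an ideal pressure impulse.
#' The parametric kind models the element as a damped harmonic oscillator,
#' IR(t) = exp(-pi f0 t / q) sin(2 pi f0 t), energy-normalised; `"delta"` is
#' the identity response and `"samples"` takes user-supplied samples.
#'
#' @slot kind one of `"delta"`, `"damped-sinusoid"`, `"samples"`.
#' @slot f0 centre frequency (Hz; damped-sinusoid kind).
#' @slot q quality factor (damped-sinusoid kind).
#' @slot dt sampling interval (s).
#' @slot samples energy-normalised samples (non-delta kinds).
#' @export
setClass("ImpulseResponse", representation(kind = "character", f0 = "numeric",
                                           q = "numeric", dt = "numeric",
                                           samples = "numeric"))

setValidity("ImpulseResponse", function(object) {
  if (!object@kind %in% c("delta", "damped-sinusoid", "samples"))
    return("unknown impulse-response kind")
  if (object@kind == "damped-sinusoid") {
    if (!is.finite(object@f0) || object@f0 <= 0) return("f0 must be > 0")
    if (!is.finite(object@q) || object@q <= 0) return("q must be > 0")
  }
  if (object@kind != "delta") {
    if (!is.finite(object@dt) || object@dt <= 0) return("dt must be > 0")
    nrg <- sum(object@samples^2)
    if (nrg == 0) return("impulse response must not be identically zero")
    if (abs(nrg - 1) > 1e-6) return("impulse-response samples must be energy-normalised")
  }
  TRUE
})

#' Matrix transducer array
#'
#' Planar array of square detection elements.  Each element of aperture
#' `element_size` is subdivided into sub-elements on a `sub_pitch` grid;
#' detection integrates (sums) the field over the sub-element centres,
#' modelling the finite aperture.
#'
#' @slot element_centers n x 3 matrix of element centre coordinates (m).
#' @slot element_size numeric length-2, aperture edge lengths (m).
#' @slot sub_pitch sub-element spacing (m); must divide the aperture evenly.
#' @slot normal unit vector the array faces along.
#' @slot layout integer length-2, rows x cols of the matrix array.
#' @export
setClass("TransducerArray", representation(element_centers = "matrix",
                                           element_size = "numeric",
                                           sub_pitch = "numeric",
                                           normal = "numeric",
                                           layout = "integer"))

setValidity("TransducerArray", function(object) {
  if (ncol(object@element_centers) != 3L)
    return("element_centers must be an n x 3 matrix")
  if (any(object@element_size <= 0)) return("element_size must be > 0")
  if (object@sub_pitch <= 0) return("sub_pitch must be > 0")
  nsub <- object@element_size / object@sub_pitch
  if (any(abs(nsub - round(nsub)) > 1e-9))
    return("sub_pitch must divide element_size evenly")
  if (abs(sqrt(sum(object@normal^2)) - 1) > 1e-9)
    return("normal must be a unit vector")
  if (prod(object@layout) != nrow(object@element_centers))
    return("layout inconsistent with number of element centers")
  TRUE
})

#' Channels x time sinogram
#'
#' Pressure recordings from every array element: a channels x time-samples
#' matrix with its sampling interval, start time and the channel-to-element
#' mapping.  `units_flag` records whether values are on an absolute pascal
#' scale or a relative (detected) scale.
#'
#' @slot data channels x samples matrix.
#' @slot dt sampling interval (s).
#' @slot t0 time of the first sample (s).
#' @slot channel_map integer vector mapping channel -> element index.
#' @slot units_flag `"absolute"` or `"relative"`.
#' @export
setClass("Sinogram", representation(data = "matrix", dt = "numeric",
                                    t0 = "numeric", channel_map = "integer",
                                    units_flag = "character"))

setValidity("Sinogram", function(object) {
  if (any(!is.finite(object@data))) return("sinogram data must be finite")
  if (!is.finite(object@dt) || object@dt <= 0) return("dt must be > 0")
  if (length(object@channel_map) != nrow(object@data))
    return("channel_map length must equal channel count")
  if (!object@units_flag %in% c("absolute", "relative"))
    return("units_flag must be 'absolute' or 'relative'")
  TRUE
})

#' Acoustic medium maps
#'
#' Heterogeneous acoustic properties on a [Grid]: speed of sound `c` (m/s),
#' density `rho` (kg/m^3), Grueneisen parameter `grueneisen` (dimensionless)
#' and heat-conversion fraction `eta_th`.  An optional power-law attenuation
#' map is carried but attenuation is off by default (the generation model
#' assumes it negligible).
#'
#' @slot grid a [Grid].
#' @slot c sound-speed array (m/s).
#' @slot rho density array (kg/m^3).
#' @slot grueneisen Grueneisen parameter array.
#' @slot eta_th scalar heat-conversion fraction in (0, 1].
#' @slot alpha_att optional attenuation coefficient array (dB/(MHz^y cm)).
#' @slot att_power attenuation power-law exponent y.
#' @export
setClass("AcousticMedium", representation(grid = "Grid", c = "array",
                                          rho = "array", grueneisen = "array",
                                          eta_th = "numeric",
                                          alpha_att = "arrayOrNULL",
                                          att_power = "numeric"))

setValidity("AcousticMedium", function(object) {
  shp <- as.integer(object@grid@shape)
  for (nm in c("c", "rho", "grueneisen")) {
    v <- slot(object, nm)
    if (!identical(dim(v), shp)) return(sprintf("'%s' dim does not match grid", nm))
    if (any(!is.finite(v))) return(sprintf("'%s' must be finite", nm))
  }
  if (any(object@c <= 0)) return("sound speed must be > 0 everywhere")
  if (any(object@rho <= 0)) return("density must be > 0 everywhere")
  if (any(object@grueneisen <= 0)) return("Grueneisen parameter must be > 0")
  if (!is.finite(object@eta_th) || object@eta_th <= 0 || object@eta_th > 1)
    return("eta_th must be in (0, 1]")
  TRUE
})

#' Digital-twin configuration
#'
#' Bundles the radiation pulse profile, transducer array, impulse response,
#' acoustic medium and recording window that together define the unified
#' linear forward operator F mapping an initial pressure volume to the
#' sinogram the instrument would record.
#'
#' @slot pulse a [PulseProfile].
#' @slot array a [TransducerArray].
#' @slot ir an [ImpulseResponse].
#' @slot medium an [AcousticMedium].
#' @slot duration recording duration (s).
#' @slot dt recording/solver time step (s).
#' @export
setClass("TwinConfig", representation(pulse = "PulseProfile",
                                      array = "TransducerArray",
                                      ir = "ImpulseResponse",
                                      medium = "AcousticMedium",
                                      duration = "numeric", dt = "numeric"))

setValidity("TwinConfig", function(object) {
  if (!is.finite(object@duration) || object@duration <= 0)
    return("duration must be > 0")
  if (!is.finite(object@dt) || object@dt <= 0) return("dt must be > 0")
  TRUE
})

#' Time-reversal configuration
#'
#' @slot medium an [AcousticMedium] (prior acoustic knowledge used in TR).
#' @slot array the [TransducerArray] the sinogram was recorded with.
#' @slot grid reconstruction [Grid].
#' @slot injection_mode `"additive-source"` (default) or `"dirichlet"`.
#' @export
setClass("TRConfig", representation(medium = "AcousticMedium",
                                    array = "TransducerArray", grid = "Grid",
                                    injection_mode = "character"))

setValidity("TRConfig", function(object) {
  if (!object@injection_mode %in% c("additive-source", "dirichlet"))
    return("injection_mode must be 'additive-source' or 'dirichlet'")
  if (!identical(object@grid@shape, object@medium@grid@shape))
    return("reconstruction grid and medium grid must agree")
  TRUE
})

#' Proton pencil-beam description
#'
#' Parametric surrogate for a treatment-planning pencil beam: an analytic
#' depth-dose curve with a pronounced Bragg peak at range R = alpha E^p
#' (range-energy power law in water, R in cm, E in MeV) times a lateral
#' Gaussian.
#'
#' @slot energy beam kinetic energy (MeV).
#' @slot entry entry point (m).
#' @slot direction axis-aligned unit vector, beam direction.
#' @slot sigma_lateral lateral Gaussian width (m).
#' @slot range_alpha,range_p range-energy power-law coefficients (cm, MeV).
#' @slot fluence_scale peak (Bragg) dose (Gy).
#' @slot distal_sigma distal falloff width (m).
#' @export
setClass("ProtonBeamSpec", representation(energy = "numeric", entry = "numeric",
                                          direction = "numeric",
                                          sigma_lateral = "numeric",
                                          range_alpha = "numeric",
                                          range_p = "numeric",
                                          fluence_scale = "numeric",
                                          distal_sigma = "numeric"))

setValidity("ProtonBeamSpec", function(object) {
  if (!is.finite(object@energy) || object@energy <= 0) return("energy must be > 0")
  if (abs(sqrt(sum(object@direction^2)) - 1) > 1e-9)
    return("direction must have unit norm")
  if (sum(abs(object@direction) > 1e-12) != 1L)
    return("only axis-aligned beam directions are supported")
  if (object@sigma_lateral <= 0) return("sigma_lateral must be > 0")
  if (object@range_alpha <= 0 || object@range_p <= 0)
    return("range-energy coefficients must be > 0")
  if (object@fluence_scale < 0) return("fluence_scale must be >= 0")
  if (object@distal_sigma <= 0) return("distal_sigma must be > 0")
  TRUE
})

#' Collimated FLASH-electron field description
#'
#' @slot field_size collimator aperture (m x m).
#' @slot r50 depth of 50% dose (m).
#' @slot surface_dose_fraction entrance dose relative to max, in (0, 1].
#' @slot dose_per_pulse dose per pulse (Gy).
#' @slot pulse_duration pulse duration (s).
#' @slot entry entry point (m).
#' @slot direction axis-aligned unit vector.
#' @slot penumbra_sigma lateral penumbra width (m).
#' @export
setClass("ElectronBeamSpec", representation(field_size = "numeric",
                                            r50 = "numeric",
                                            surface_dose_fraction = "numeric",
                                            dose_per_pulse = "numeric",
                                            pulse_duration = "numeric",
                                            entry = "numeric",
                                            direction = "numeric",
                                            penumbra_sigma = "numeric"))

setValidity("ElectronBeamSpec", function(object) {
  if (any(!is.finite(object@field_size)) || any(object@field_size <= 0))
    return("field_size must be > 0")
  if (!is.finite(object@r50) || object@r50 <= 0) return("r50 must be > 0")
  f <- object@surface_dose_fraction
  if (!is.finite(f) || f <= 0 || f > 1)
    return("surface_dose_fraction must be in (0, 1]")
  if (object@dose_per_pulse <= 0) return("dose_per_pulse must be > 0")
  if (object@pulse_duration <= 0) return("pulse_duration must be > 0")
  if (abs(sqrt(sum(object@direction^2)) - 1) > 1e-9)
    return("direction must have unit norm")
  if (sum(abs(object@direction) > 1e-12) != 1L)
    return("only axis-aligned beam directions are supported")
  if (object@penumbra_sigma <= 0) return("penumbra_sigma must be > 0")
  TRUE
})

#' Experiment dataset catalog
#'
#' Enumerates a factorial beam-energies x array-positions protocol with
#' seeded exclusions and train/validation/test split tags.
#'
#' @slot entries data.frame with columns id, modality, energy_MeV, shift_x_mm,
#'   shift_y_mm, excluded, split.
#' @slot counts named list of totals per category.
#' @slot seed integer seed the catalog was drawn with.
#' @export
setClass("DatasetCatalog", representation(entries = "data.frame",
                                          counts = "list", seed = "integer"))

setValidity("DatasetCatalog", function(object) {
  e <- object@entries
  need <- c("id", "modality", "energy_MeV", "shift_x_mm", "shift_y_mm",
            "excluded", "split")
  if (!all(need %in% names(e))) return("catalog entries missing required columns")
  cnt <- object@counts
  if (cnt$total != nrow(e)) return("counts$total inconsistent with entries")
  if (cnt$excluded != sum(e$excluded)) return("counts$excluded inconsistent")
  if (cnt$usable != sum(!e$excluded)) return("counts$usable inconsistent")
  tags <- e$split[!e$excluded]
  if (any(e$split[e$excluded] != "")) return("excluded entries must carry no split tag")
  for (s in c("train", "val", "test"))
    if (cnt[[s]] != sum(tags == s)) return(sprintf("counts$%s inconsistent", s))
  TRUE
})

#' Single-point pressure-to-dose calibration factor
#'
#' K = D_c / p_c: dose per unit reconstructed pressure, anchored at a
#' reference location (the Bragg peak in the tank protocol) whose delivered
#' dose D_c is known from machine logs and whose reconstructed pressure p_c
#' is read from the prediction.
#'
#' @slot k calibration factor (cGy per relative pressure unit).
#' @slot reference_dose D_c (cGy).
#' @slot reference_pressure p_c (relative units).
#' @slot reference_location grid coordinate (voxel index) of the anchor.
#' @export
setClass("CalibrationFactor", representation(k = "numeric",
                                             reference_dose = "numeric",
                                             reference_pressure = "numeric",
                                             reference_location = "numeric"))

setValidity("CalibrationFactor", function(object) {
  if (!is.finite(object@reference_pressure) || object@reference_pressure <= 0)
    return("reference pressure p_c must be > 0")
  if (object@reference_dose < 0) return("reference dose must be >= 0")
  if (abs(object@k - object@reference_dose / object@reference_pressure) > 1e-12 *
      max(1, abs(object@k)))
    return("k must equal reference_dose / reference_pressure")
  TRUE
})

#' Gamma-index acceptance criteria
#'
#' @slot delta_d distance-to-agreement criterion (mm).
#' @slot delta_dose dose-difference criterion as a fraction of the
#'   normalisation (global max reference) dose.
#' @slot low_dose_threshold fraction of max reference dose below which
#'   reference voxels are excluded from scoring.
#' @export
setClass("GammaCriteria", representation(delta_d = "numeric",
                                         delta_dose = "numeric",
                                         low_dose_threshold = "numeric"))

setValidity("GammaCriteria", function(object) {
  if (object@delta_d <= 0) return("delta_d must be > 0")
  if (object@delta_dose <= 0 || object@delta_dose >= 1)
    return("delta_dose must be in (0, 1)")
  t <- object@low_dose_threshold
  if (t < 0 || t >= 1) return("low_dose_threshold must be in [0, 1)")
  TRUE
})

#' Enhancement-network architecture configuration
#'
#' A compact additive-skip convolutional encoder-decoder (U-Net family):
#' `depth` resolution levels, `base_channels` features at the first level
#' (doubling per level), and a final activation that is either softplus
#' (`"nonneg"`, guaranteeing non-negative output) or identity (`"linear"`).
#'
#' @slot depth number of resolution levels (>= 1).
#' @slot base_channels feature maps at the first level.
#' @slot shape spatial input/output shape (must be divisible by 2^(depth-1)).
#' @slot final_activation `"nonneg"` or `"linear"`.
#' @export
setClass("NetworkConfig", representation(depth = "integer",
                                         base_channels = "integer",
                                         shape = "integer",
                                         final_activation = "character"))

setValidity("NetworkConfig", function(object) {
  if (object@depth < 1L) return("depth must be >= 1")
  if (object@base_channels < 1L) return("base_channels must be >= 1")
  if (!object@final_activation %in% c("nonneg", "linear"))
    return("final_activation must be 'nonneg' or 'linear'")
  f <- 2L^(object@depth - 1L)
  if (any(object@shape %% f != 0L))
    return("input shape must be divisible by 2^(depth-1)")
  TRUE
})

#' Training configuration for the enhancement network
#'
#' `lambda1` weights the image-domain (pressure) loss, `lambda2` the
#' sinogram-domain physics loss; `lambda2 = NA` requests the automatic
#' balancing that scales the physics term so both terms start within a
#' factor of two at epoch 0.
#'
#' @slot lambda1,lambda2 loss weights (>= 0, not both 0; lambda2 may be NA for auto).
#' @slot lr learning-rate of the adaptive first-order optimiser.
#' @slot epochs number of epochs (>= 1).
#' @slot batch_size minibatch size.
#' @slot seed integer seed for init and batching.
#' @slot normalization per-sample scale policy (`"max"`).
#' @export
setClass("TrainConfig", representation(lambda1 = "numeric", lambda2 = "numeric",
                                       lr = "numeric", epochs = "integer",
                                       batch_size = "integer", seed = "integer",
                                       normalization = "character"))

setValidity("TrainConfig", function(object) {
  if (object@lambda1 < 0) return("lambda1 must be >= 0")
  if (!is.na(object@lambda2) && object@lambda2 < 0) return("lambda2 must be >= 0")
  if (!is.na(object@lambda2) && object@lambda1 == 0 && object@lambda2 == 0)
    return("lambda1 and lambda2 must not both be 0")
  if (object@epochs < 1L) return("epochs must be >= 1")
  if (object@batch_size < 1L) return("batch_size must be >= 1")
  if (object@lr <= 0) return("lr must be > 0")
  if (!object@normalization %in% c("max", "none"))
    return("normalization must be 'max' or 'none'")
  TRUE
})

#' One training sample for the enhancement network
#'
#' @slot p_rec time-reversal reconstruction (network input).
#' @slot p0 ground-truth initial pressure, or NULL for self-supervised samples.
#' @slot s_m measured sinogram the physics loss compares against.
#' @slot scale stored per-sample normalisation factor.
#' @export
setClass("TrainingSample", representation(p_rec = "PressureVolume",
                                          p0 = "ANY", s_m = "Sinogram",
                                          scale = "numeric"))

setValidity("TrainingSample", function(object) {
  if (!is.null(object@p0)) {
    if (!is(object@p0, "PressureVolume")) return("p0 must be a PressureVolume or NULL")
    if (!identical(object@p0@grid@shape, object@p_rec@grid@shape))
      return("p_rec and p0 must share a grid")
  }
  if (!is.finite(object@scale) || object@scale <= 0) return("scale must be > 0")
  TRUE
})
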