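## S4 classes for the SFDI processing chain.

#' Optical description of a semi-infinite homogeneous turbid medium
#'
#' @slot mu_a absorption coefficient (mm^-1)
#' @slot mu_s_prime reduced scattering coefficient (mm^-1)
#' @slot g scattering anisotropy of the Henyey-Greenstein phase function
#' @slot n_medium refractive index inside the medium
#' @slot n_ambient refractive index of the ambient (detection) side
#' @exportClass MediumSpec
setClass("MediumSpec",
  representation(mu_a = "numeric", mu_s_prime = "numeric", g = "numeric",
                 n_medium = "numeric", n_ambient = "numeric"),
  prototype(g = 0.9, n_medium = 1.0, n_ambient = 1.0))

setValidity("MediumSpec", function(object) {
  msgs <- character()
  if (length(object@mu_a) != 1 || !is.finite(object@mu_a) || object@mu_a < 0)
    msgs <- c(msgs, "mu_a must be a single finite value >= 0")
  if (length(object@mu_s_prime) != 1 || !is.finite(object@mu_s_prime) || object@mu_s_prime <= 0)
    msgs <- c(msgs, "mu_s_prime must be a single finite value > 0")
  if (length(object@g) != 1 || !is.finite(object@g) || object@g <= -1 || object@g >= 1)
    msgs <- c(msgs, "g must lie strictly inside (-1, 1)")
  if (length(object@n_medium) != 1 || !is.finite(object@n_medium) || object@n_medium < 1)
    msgs <- c(msgs, "n_medium must be >= 1")
  if (length(object@n_ambient) != 1 || !is.finite(object@n_ambient) || object@n_ambient < 1)
    msgs <- c(msgs, "n_ambient must be >= 1")
  if (length(msgs) == 0 && !is.finite(object@mu_s_prime / (1 - object@g)))
    msgs <- c(msgs, "derived mu_s = mu_s_prime/(1-g) is not finite")
  if (length(msgs)) msgs else TRUE
})

#' Construct a MediumSpec
#'
#' @param mu_a absorption coefficient (mm^-1)
#' @param mu_s_prime reduced scattering coefficient (mm^-1)
#' @param g anisotropy (default 0.9, soft-tissue convention)
#' @param n_medium,n_ambient refractive indices (default matched, 1.0)
#' @return a validated \linkS4class{MediumSpec}
#' @export
mediumSpec <- function(mu_a, mu_s_prime, g = 0.9, n_medium = 1.0, n_ambient = 1.0) {
  new("MediumSpec", mu_a = as.numeric(mu_a), mu_s_prime = as.numeric(mu_s_prime),
      g = as.numeric(g), n_medium = as.numeric(n_medium), n_ambient = as.numeric(n_ambient))
}

#' Radially binned diffuse reflectance from a pencil-beam Monte Carlo run
#'
#' Radial point-response of a semi-infinite medium: escaping photon weight per
#' unit area in uniform annuli around the entry point, plus total diffuse
#' reflectance and the full energy ledger of the simulation.
#'
#' @slot bin_edges annulus edges (mm), uniform, half-open [r_i, r_{i+1})
#' @slot R_per_area diffuse reflectance per unit area in each annulus (mm^-2)
#' @slot total_diffuse scalar total diffuse reflectance (per unit incident power)
#' @slot n_photons photon count launched
#' @slot seed RNG seed used
#' @slot escaped_specular_excluded always TRUE: specular entry loss is removed
#'   before launch (cross-polarized detection geometry)
#' @slot meta energy ledger and run metadata (absorbed, capped weight, ...)
#' @exportClass RadialReflectance
setClass("RadialReflectance",
  representation(bin_edges = "numeric", R_per_area = "numeric",
                 total_diffuse = "numeric", n_photons = "numeric",
                 seed = "numeric", escaped_specular_excluded = "logical",
                 meta = "list"))

setValidity("RadialReflectance", function(object) {
  msgs <- character()
  if (length(object@bin_edges) != length(object@R_per_area) + 1)
    msgs <- c(msgs, "bin_edges must have one more element than R_per_area")
  if (any(object@R_per_area < 0)) msgs <- c(msgs, "R_per_area must be >= 0")
  if (object@total_diffuse < 0 || object@total_diffuse > 1 + 1e-12)
    msgs <- c(msgs, "total_diffuse must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' Bidirectional lookup table of spatial-frequency-domain diffuse reflectance
#'
#' Grid of diffuse reflectance over (mu_a, mu_s') at each spatial frequency,
#' built by White Monte Carlo.  Forward use: interpolate reflectance at given
#' optical properties.  Inverse use: recover (mu_a, mu_s') from a (DC, AC)
#' reflectance pair (\code{\link{invertPixel}}).
#'
#' @slot mu_a_grid ascending absorption grid (mm^-1)
#' @slot mu_s_prime_grid ascending reduced scattering grid (mm^-1)
#' @slot fx_list spatial frequencies (mm^-1); always contains 0
#' @slot R array [i_mu_a, i_mu_s_prime, i_fx] of diffuse reflectance
#' @slot meta g, n_medium, n_ambient, n_photons, seed, build timestamp, warnings
#' @exportClass ReflectanceLUT
setClass("ReflectanceLUT",
  representation(mu_a_grid = "numeric", mu_s_prime_grid = "numeric",
                 fx_list = "numeric", R = "array", meta = "list"))

setValidity("ReflectanceLUT", function(object) {
  msgs <- character()
  d <- dim(object@R)
  if (length(d) != 3) msgs <- c(msgs, "R must be a 3-d array")
  else {
    if (d[1] != length(object@mu_a_grid) || d[2] != length(object@mu_s_prime_grid) ||
        d[3] != length(object@fx_list))
      msgs <- c(msgs, "dim(R) must match the grid lengths")
  }
  if (is.unsorted(object@mu_a_grid, strictly = TRUE)) msgs <- c(msgs, "mu_a_grid must be strictly ascending")
  if (is.unsorted(object@mu_s_prime_grid, strictly = TRUE)) msgs <- c(msgs, "mu_s_prime_grid must be strictly ascending")
  if (!any(object@fx_list == 0)) msgs <- c(msgs, "fx_list must contain 0")
  if (any(object@R < 0 | object@R > 1)) msgs <- c(msgs, "R must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' Raw frames for one {wavelength, spatial frequency} acquisition condition
#'
#' DC mode holds the light-on and light-off planar-illumination frames
#' (I_ON, I_OFF); AC mode holds four phase-shifted frames at projected phases
#' 0, 90, 180 and 270 degrees (I_phi1..I_phi4).
#'
#' @slot wavelength nm
#' @slot fx spatial frequency (mm^-1); 0 iff mode is "DC"
#' @slot pixel_pitch mm per pixel
#' @slot mode "DC" or "AC"
#' @slot frames named list of equal-shape nonnegative matrices
#'   (DC: on, off; AC: phi1..phi4)
#' @exportClass PhaseImageSet
setClass("PhaseImageSet",
  representation(wavelength = "numeric", fx = "numeric", pixel_pitch = "numeric",
                 mode = "character", frames = "list"))

setValidity("PhaseImageSet", function(object) {
  msgs <- character()
  need <- if (identical(object@mode, "DC")) c("on", "off")
          else if (identical(object@mode, "AC")) paste0("phi", 1:4)
          else return("mode must be 'DC' or 'AC'")
  if (!setequal(names(object@frames), need))
    msgs <- c(msgs, paste0("frames must be exactly {", paste(need, collapse = ", "), "}"))
  else {
    dims <- lapply(object@frames, dim)
    if (length(unique(dims)) != 1) msgs <- c(msgs, "all frames must share one shape")
    if (any(vapply(object@frames, function(f) any(f < 0), logical(1))))
      msgs <- c(msgs, "frame intensities must be >= 0")
  }
  if (identical(object@mode, "DC") && object@fx != 0)
    msgs <- c(msgs, "DC mode requires fx = 0")
  if (identical(object@mode, "AC") && object@fx <= 0)
    msgs <- c(msgs, "AC mode requires fx > 0")
  if (object@pixel_pitch <= 0) msgs <- c(msgs, "pixel_pitch must be > 0")
  if (length(msgs)) msgs else TRUE
})

#' Demodulated image at one {wavelength, spatial frequency}
#'
#' @slot wavelength nm
#' @slot fx mm^-1
#' @slot M nonnegative demodulated pixel values (arbitrary intensity units)
#' @slot n_clamped count of pixels clamped to zero (DC mode sensor noise)
#' @exportClass DemodulatedImage
setClass("DemodulatedImage",
  representation(wavelength = "numeric", fx = "numeric", M = "matrix",
                 n_clamped = "numeric"),
  prototype(n_clamped = 0))

setValidity("DemodulatedImage", function(object) {
  if (any(object@M < 0)) "M must be >= 0 elementwise" else TRUE
})

#' Calibrated diffuse reflectance image
#'
#' @slot wavelength nm
#' @slot fx mm^-1
#' @slot R diffuse reflectance per pixel (dimensionless)
#' @slot valid_mask per-pixel validity; invalid pixels are flagged, never clipped
#' @exportClass ReflectanceImage
setClass("ReflectanceImage",
  representation(wavelength = "numeric", fx = "numeric", R = "matrix",
                 valid_mask = "matrix"))

setValidity("ReflectanceImage", function(object) {
  msgs <- character()
  if (!identical(dim(object@R), dim(object@valid_mask)))
    msgs <- c(msgs, "R and valid_mask must share one shape")
  if (!is.logical(object@valid_mask)) msgs <- c(msgs, "valid_mask must be logical")
  v <- object@R[object@valid_mask]
  if (length(v) && any(v < 0 | v > 1.2))
    msgs <- c(msgs, "valid reflectance must lie in [0, 1.2]")
  if (length(msgs)) msgs else TRUE
})

#' Known optical properties of the calibration phantom
#'
#' @slot properties data.frame with columns wavelength, mu_a, mu_s_prime
#' @slot label identity/lot label
#' @exportClass CalibrationPhantomSpec
setClass("CalibrationPhantomSpec",
  representation(properties = "data.frame", label = "character"))

setValidity("CalibrationPhantomSpec", function(object) {
  p <- object@properties
  msgs <- character()
  if (!all(c("wavelength", "mu_a", "mu_s_prime") %in% names(p)))
    msgs <- c(msgs, "properties needs columns wavelength, mu_a, mu_s_prime")
  else {
    if (anyDuplicated(p$wavelength)) msgs <- c(msgs, "duplicate wavelength rows")
    if (any(p$mu_a < 0) || any(p$mu_s_prime <= 0)) msgs <- c(msgs, "non-physical phantom properties")
  }
  if (length(msgs)) msgs else TRUE
})

#' @param properties data.frame(wavelength, mu_a, mu_s_prime)
#' @param label free-text phantom identity
#' @rdname CalibrationPhantomSpec-class
#' @export
calibrationPhantomSpec <- function(properties, label = "phantom") {
  new("CalibrationPhantomSpec", properties = as.data.frame(properties), label = label)
}

#' Per-pixel optical property map at one wavelength
#'
#' @slot wavelength nm
#' @slot mu_a absorption map (mm^-1)
#' @slot mu_s_prime reduced scattering map (mm^-1)
#' @slot valid_mask per-pixel validity
#' @slot reason integer reason codes: 0 ok, 1 masked input, 2 out-of-gamut
#' @exportClass OpticalPropertyMap
setClass("OpticalPropertyMap",
  representation(wavelength = "numeric", mu_a = "matrix", mu_s_prime = "matrix",
                 valid_mask = "matrix", reason = "matrix"))

setValidity("OpticalPropertyMap", function(object) {
  dims <- list(dim(object@mu_a), dim(object@mu_s_prime), dim(object@valid_mask), dim(object@reason))
  if (length(unique(dims)) != 1) return("all maps must share one shape")
  TRUE
})

#' Extinction coefficient table for water and lipid
#'
#' Pure-substance absorption per unit volume fraction (mm^-1 at 100 percent),
#' so that unmixed concentrations are volume fractions.  Values shipped with
#' the package are approximate digitizations of the standard literature series
#' (see \code{provenance}); they are replaceable data, not ground truth.
#'
#' @slot wavelengths nm
#' @slot eps_water pure-water absorption (mm^-1)
#' @slot eps_lipid pure-lipid absorption (mm^-1)
#' @slot provenance citation string per series
#' @exportClass ExtinctionTable
setClass("ExtinctionTable",
  representation(wavelengths = "numeric", eps_water = "numeric",
                 eps_lipid = "numeric", provenance = "character"))

setValidity("ExtinctionTable", function(object) {
  msgs <- character()
  n <- length(object@wavelengths)
  if (length(object@eps_water) != n || length(object@eps_lipid) != n)
    msgs <- c(msgs, "series lengths must match wavelengths")
  if (anyDuplicated(object@wavelengths)) msgs <- c(msgs, "wavelengths must be unique")
  if (any(object@eps_water <= 0) || any(object@eps_lipid <= 0))
    msgs <- c(msgs, "extinction entries must be strictly positive")
  if (length(msgs)) msgs else TRUE
})

#' Per-pixel water/lipid volume fraction map
#'
#' @slot C_water water volume fraction per pixel
#' @slot C_lipid lipid volume fraction per pixel
#' @slot residual per-pixel least-squares residual norm (mm^-1)
#' @slot valid_mask pixels with all input absorption maps valid
#' @slot negativity_mask pixels where a fitted concentration is negative
#'   (retained, flagged, never clipped)
#' @exportClass ChromophoreMap
setClass("ChromophoreMap",
  representation(C_water = "matrix", C_lipid = "matrix", residual = "matrix",
                 valid_mask = "matrix", negativity_mask = "matrix"))

setValidity("ChromophoreMap", function(object) {
  msgs <- character()
  if (any(object@residual < 0, na.rm = TRUE)) msgs <- c(msgs, "residual must be >= 0")
  dims <- list(dim(object@C_water), dim(object@C_lipid), dim(object@residual), dim(object@valid_mask))
  if (length(unique(dims)) != 1) msgs <- c(msgs, "all maps must share one shape")
  if (length(msgs)) msgs else TRUE
})

#' Synthetic scene: spatial maps of composition and scattering
#'
#' A scene holds per-pixel water and lipid volume fractions plus a power-law
#' scattering model mu_s'(lambda) = amplitude * (lambda/lambda0)^(-b), from
#' which wavelength-resolved optical property maps follow.
#'
#' @slot pixel_pitch mm per pixel
#' @slot C_water,C_lipid volume fraction maps
#' @slot scatter_amplitude mu_s' at the reference wavelength (mm^-1)
#' @slot scatter_power scattering power b
#' @slot lambda0 reference wavelength (nm)
#' @slot regions named list of half-open 0-based ROI rectangles
#'   c(row0, row1, col0, col1); may include an in-frame "phantom" patch
#' @exportClass Scene
setClass("Scene",
  representation(pixel_pitch = "numeric", C_water = "matrix", C_lipid = "matrix",
                 scatter_amplitude = "matrix", scatter_power = "numeric",
                 lambda0 = "numeric", regions = "list"),
  prototype(scatter_power = 1.6, lambda0 = 970, regions = list()))

setValidity("Scene", function(object) {
  msgs <- character()
  dims <- list(dim(object@C_water), dim(object@C_lipid), dim(object@scatter_amplitude))
  if (length(unique(dims)) != 1) msgs <- c(msgs, "maps must share one shape")
  if (any(object@C_water < 0 | object@C_water > 1.05) ||
      any(object@C_lipid < 0 | object@C_lipid > 1.05))
    msgs <- c(msgs, "volume fractions must lie in [0, 1.05]")
  if (any(object@scatter_amplitude <= 0)) msgs <- c(msgs, "scatter_amplitude must be > 0")
  if (length(msgs)) msgs else TRUE
})

#' Camera/illumination model for the synthetic forward renderer
#'
#' @slot gain counts per unit diffuse reflectance
#' @slot illumination multiplicative illumination field (matrix, or 0x0 for flat)
#' @slot ambient_offset counts added to every frame
#' @slot read_noise_sd Gaussian read noise (counts)
#' @slot shot_scale shot-noise scale: sd = shot_scale * sqrt(counts)
#' @slot bit_depth output bit depth for quantization; NA renders continuous
#'   (no rounding), used for exactness checks
#' @exportClass AcquisitionModel
setClass("AcquisitionModel",
  representation(gain = "numeric", illumination = "matrix", ambient_offset = "numeric",
                 read_noise_sd = "numeric", shot_scale = "numeric", bit_depth = "numeric"),
  prototype(gain = 30000, illumination = matrix(numeric(0), 0, 0), ambient_offset = 1000,
            read_noise_sd = 30, shot_scale = 1, bit_depth = 16))

setValidity("AcquisitionModel", function(object) {
  msgs <- character()
  if (object@gain <= 0) msgs <- c(msgs, "gain must be > 0")
  if (object@read_noise_sd < 0 || object@shot_scale < 0)
    msgs <- c(msgs, "noise parameters must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Schedule for synthetic time-series experiments
#'
#' @slot n_timepoints number of imaging timepoints (>= 2)
#' @slot water_loss total fractional water loss over the series (desiccation) or
#'   step drop at the exercise boundary
#' @slot convention "relative" (fraction of current water) or "absolute"
#'   (percentage points of volume fraction)
#' @slot k scattering-hydration coupling: relative mu_s' change = k * relative
#'   water change (mechanistic stand-in, default 2)
#' @slot n_pre pre-event timepoints (exercise series)
#' @slot recovery_tau exponential recovery time constant in timepoints (exercise)
#' @exportClass TimeSeriesSpec
setClass("TimeSeriesSpec",
  representation(n_timepoints = "numeric", water_loss = "numeric",
                 convention = "character", k = "numeric",
                 n_pre = "numeric", recovery_tau = "numeric"),
  prototype(convention = "relative", k = 2, n_pre = 5, recovery_tau = 8))

setValidity("TimeSeriesSpec", function(object) {
  msgs <- character()
  if (object@n_timepoints < 2) msgs <- c(msgs, "n_timepoints must be >= 2")
  if (!is.finite(object@k)) msgs <- c(msgs, "coupling k must be finite")
  if (!object@convention %in% c("relative", "absolute"))
    msgs <- c(msgs, "convention must be 'relative' or 'absolute'")
  if (length(msgs)) msgs else TRUE
})

#' @param n_timepoints,water_loss,convention,k,n_pre,recovery_tau see slots
#' @rdname TimeSeriesSpec-class
#' @export
timeSeriesSpec <- function(n_timepoints, water_loss = 0.02, convention = "relative",
                           k = 2, n_pre = 5, recovery_tau = 8) {
  new("TimeSeriesSpec", n_timepoints = n_timepoints, water_loss = water_loss,
      convention = convention, k = k, n_pre = n_pre, recovery_tau = recovery_tau)
}
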