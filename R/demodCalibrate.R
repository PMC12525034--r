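## Demodulation of raw phase-shifted stacks and calibration against a
## reference phantom of known optical properties.

#' Construct a PhaseImageSet
#'
#' @param wavelength nm
#' @param fx spatial frequency (mm^-1); 0 for DC
#' @param frames named list of matrices: \code{on}/\code{off} for DC,
#'   \code{phi1}..\code{phi4} (projected phases 0/90/180/270 deg) for AC
#' @param pixel_pitch mm per pixel
#' @return a validated \linkS4class{PhaseImageSet}
#' @export
phaseImageSet <- function(wavelength, fx, frames, pixel_pitch = 0.5) {
  mode <- if (fx == 0) "DC" else "AC"
  new("PhaseImageSet", wavelength = as.numeric(wavelength), fx = as.numeric(fx),
      pixel_pitch = as.numeric(pixel_pitch), mode = mode, frames = frames)
}

#' DC demodulation: light-on minus light-off
#'
#' M = I_ON - I_OFF elementwise.  Negative results (sensor noise) are clamped
#' to zero and the number of clamped pixels recorded.
#'
#' @param images a DC-mode \linkS4class{PhaseImageSet}
#' @return a \linkS4class{DemodulatedImage}
#' @export
demodulateDC <- function(images) {
  stopifnot(is(images, "PhaseImageSet"))
  validObject(images)
  if (images@mode != "DC") stop("demodulateDC requires a DC-mode PhaseImageSet")
  M <- images@frames$on - images@frames$off
  n_neg <- sum(M < 0)
  if (n_neg > 0) M[M < 0] <- 0
  new("DemodulatedImage", wavelength = images@wavelength, fx = images@fx,
      M = M, n_clamped = n_neg)
}

#' AC demodulation of four phase-shifted frames
#'
#' M = 1/2 sqrt((I_phi2 - I_phi4)^2 + (I_phi1 - I_phi3)^2): the quadrature
#' pair (phi2 - phi4, phi1 - phi3) recovers the envelope amplitude of the
#' projected sinusoid independently of the local spatial phase.
#'
#' @param images an AC-mode \linkS4class{PhaseImageSet}
#' @return a \linkS4class{DemodulatedImage}
#' @export
demodulateAC <- function(images) {
  stopifnot(is(images, "PhaseImageSet"))
  validObject(images)
  if (images@mode != "AC") stop("demodulateAC requires an AC-mode PhaseImageSet")
  f <- images@frames
  M <- 0.5 * sqrt((f$phi2 - f$phi4)^2 + (f$phi1 - f$phi3)^2)
  new("DemodulatedImage", wavelength = images@wavelength, fx = images@fx, M = M)
}

#' @describeIn PhaseImageSet-class demodulate according to mode (DC or AC)
#' @param x a PhaseImageSet
#' @param ... unused
#' @export
setMethod("demodulate", "PhaseImageSet", function(x, ...) {
  if (x@mode == "DC") demodulateDC(x) else demodulateAC(x)
})

#' Calibrate demodulated sample values to diffuse reflectance
#'
#' Per-pixel ratio calibration against the reference phantom:
#' R_sample = R_phantom_predicted * M_sample / M_phantom.  Performing the
#' division pixelwise flat-fields the illumination profile out of the result.
#' Pixels where the phantom signal falls below the noise floor, or where the
#' calibrated reflectance exceeds 1.2, are masked invalid (never clipped).
#'
#' @param M_sample,M_phantom \linkS4class{DemodulatedImage}s at the same
#'   wavelength and spatial frequency
#' @param R_phantom_predicted scalar diffuse reflectance of the phantom, in
#'   (0, 1), from \code{\link{predictPhantomReflectance}}
#' @param noise_floor_frac phantom pixels below this fraction of the phantom
#'   median are masked (default 0.01)
#' @return a \linkS4class{ReflectanceImage}
#' @export
calibrateReflectance <- function(M_sample, M_phantom, R_phantom_predicted,
                                 noise_floor_frac = 0.01) {
  stopifnot(is(M_sample, "DemodulatedImage"), is(M_phantom, "DemodulatedImage"))
  if (M_sample@wavelength != M_phantom@wavelength || M_sample@fx != M_phantom@fx)
    stop("sample and phantom demodulated images must share wavelength and fx ",
         "(cross-condition calibration is not allowed)")
  if (!identical(dim(M_sample@M), dim(M_phantom@M)))
    stop("sample and phantom shapes differ")
  if (R_phantom_predicted <= 0 || R_phantom_predicted >= 1)
    stop("R_phantom_predicted must lie in (0, 1)")
  floor_val <- noise_floor_frac * median(M_phantom@M)
  denom_ok <- M_phantom@M > floor_val
  R <- matrix(NA_real_, nrow(M_sample@M), ncol(M_sample@M))
  R[denom_ok] <- R_phantom_predicted * M_sample@M[denom_ok] / M_phantom@M[denom_ok]
  valid <- denom_ok & !is.na(R) & R <= 1.2 & R >= 0
  R[!denom_ok] <- NA_real_
  new("ReflectanceImage", wavelength = M_sample@wavelength, fx = M_sample@fx,
      R = R, valid_mask = valid)
}

#' Predict the calibration phantom's diffuse reflectance from the LUT
#'
#' Bilinear interpolation of the lookup table at the phantom's known
#' (mu_a, mu_s') for the requested wavelength and spatial frequency.
#'
#' @param phantom a \linkS4class{CalibrationPhantomSpec}
#' @param lut a \linkS4class{ReflectanceLUT}
#' @param wavelength nm, must be present in the phantom spec
#' @param fx one of the LUT spatial frequencies
#' @return scalar dimensionless reflectance
#' @export
predictPhantomReflectance <- function(phantom, lut, wavelength, fx) {
  stopifnot(is(phantom, "CalibrationPhantomSpec"), is(lut, "ReflectanceLUT"))
  p <- phantom@properties
  row <- p[p$wavelength == wavelength, ]
  if (nrow(row) != 1)
    stop("phantom properties not specified at ", wavelength, " nm")
  if (row$mu_a < min(lut@mu_a_grid) || row$mu_a > max(lut@mu_a_grid))
    stop("phantom mu_a = ", row$mu_a, " mm^-1 outside the LUT mu_a grid")
  if (row$mu_s_prime < min(lut@mu_s_prime_grid) || row$mu_s_prime > max(lut@mu_s_prime_grid))
    stop("phantom mu_s' = ", row$mu_s_prime, " mm^-1 outside the LUT mu_s' grid")
  lutReflectance(lut, row$mu_a, row$mu_s_prime, fx)
}
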