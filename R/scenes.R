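## Synthetic forward renderer and scenario generators: homogeneous Intralipid
## dilutions, desiccation time series and pre/post-exercise series with an
## in-frame reference phantom, rendered down to raw phase-shifted frames.

#' Construct a Scene
#'
#' Scalars are expanded to homogeneous maps of the given shape.
#'
#' @param C_water,C_lipid volume fractions (scalar or matrix)
#' @param mu_s_prime reduced scattering at the reference wavelength
#'   (scalar or matrix, mm^-1)
#' @param shape c(rows, cols), used when maps are scalar
#' @param pixel_pitch mm per pixel
#' @param scatter_power scattering power b in mu_s'(lambda) = a (lambda/lambda0)^-b
#' @param lambda0 reference wavelength (nm)
#' @param regions named list of half-open 0-based ROI rectangles c(row0, row1, col0, col1)
#' @return a validated \linkS4class{Scene}
#' @export
scene <- function(C_water, C_lipid, mu_s_prime, shape = c(24, 24),
                  pixel_pitch = 0.5, scatter_power = 1.6, lambda0 = 970,
                  regions = list()) {
  expand <- function(x) if (is.matrix(x)) x else matrix(x, shape[1], shape[2])
  new("Scene", pixel_pitch = pixel_pitch, C_water = expand(C_water),
      C_lipid = expand(C_lipid), scatter_amplitude = expand(mu_s_prime),
      scatter_power = scatter_power, lambda0 = lambda0, regions = regions)
}

#' Construct an AcquisitionModel
#'
#' @param gain counts per unit reflectance
#' @param illumination multiplicative field matrix, or NULL for flat
#' @param ambient_offset counts
#' @param read_noise_sd Gaussian read noise (counts)
#' @param shot_scale shot-noise scale (sd = shot_scale * sqrt(counts))
#' @param bit_depth quantization depth; NA disables quantization
#' @return an \linkS4class{AcquisitionModel}
#' @export
acquisitionModel <- function(gain = 30000, illumination = NULL, ambient_offset = 1000,
                             read_noise_sd = 30, shot_scale = 1, bit_depth = 16) {
  if (is.null(illumination)) illumination <- matrix(numeric(0), 0, 0)
  new("AcquisitionModel", gain = gain, illumination = illumination,
      ambient_offset = ambient_offset, read_noise_sd = read_noise_sd,
      shot_scale = shot_scale, bit_depth = as.numeric(bit_depth))
}

#' Wavelength-resolved optical properties of a scene
#'
#' Forward composition model: mu_a = C_water eps_water(lambda) +
#' C_lipid eps_lipid(lambda) per pixel, and power-law scattering
#' mu_s'(lambda) = amplitude (lambda/lambda0)^(-b).
#'
#' @param scn a \linkS4class{Scene}
#' @param table an \linkS4class{ExtinctionTable}
#' @param wavelength nm, must be present in the table
#' @return an \linkS4class{OpticalPropertyMap} (all pixels valid)
#' @export
sceneOpticalProperties <- function(scn, table, wavelength) {
  stopifnot(is(scn, "Scene"), is(table, "ExtinctionTable"))
  i <- match(wavelength, table@wavelengths)
  if (is.na(i)) stop("wavelength ", wavelength, " nm absent from the extinction table")
  mu_a <- scn@C_water * table@eps_water[i] + scn@C_lipid * table@eps_lipid[i]
  mu_s <- scn@scatter_amplitude * (wavelength / scn@lambda0)^(-scn@scatter_power)
  d <- dim(mu_a)
  new("OpticalPropertyMap", wavelength = as.numeric(wavelength), mu_a = mu_a,
      mu_s_prime = mu_s, valid_mask = matrix(TRUE, d[1], d[2]),
      reason = matrix(0L, d[1], d[2]))
}

# add noise and quantize one frame of clean counts (uses the ambient R RNG
# stream; callers seed via withSeed)
.acquireFrame <- function(clean, model) {
  I <- clean
  if (model@read_noise_sd > 0 || model@shot_scale > 0) {
    d <- dim(I)
    I <- I + rnorm(length(I), sd = model@read_noise_sd) +
      rnorm(length(I)) * model@shot_scale * sqrt(pmax(I, 0))
    dim(I) <- d
  }
  if (is.finite(model@bit_depth)) {
    I <- pmin(pmax(round(I), 0), 2^model@bit_depth - 1)
  } else {
    I <- pmax(I, 0)
  }
  I
}

# render one {wavelength, fx} condition from per-pixel (R_dc, R_ac)
.renderCondition <- function(R_dc, R_ac, fx, model, pixel_pitch, wavelength) {
  d <- dim(R_dc)
  illum <- if (length(model@illumination)) model@illumination else matrix(1, d[1], d[2])
  if (!identical(dim(illum), d)) stop("illumination profile shape mismatch")
  sig <- illum * model@gain
  if (fx == 0) {
    frames <- list(on = .acquireFrame(sig * R_dc + model@ambient_offset, model),
                   off = .acquireFrame(matrix(model@ambient_offset, d[1], d[2]), model))
  } else {
    x <- matrix(rep((seq_len(d[2]) - 1) * pixel_pitch, each = d[1]), d[1], d[2])
    frames <- lapply(0:3, function(k) {
      pattern <- R_dc + R_ac * sin(2 * pi * fx * x + k * pi / 2)
      .acquireFrame(sig * pattern + model@ambient_offset, model)
    })
    names(frames) <- paste0("phi", 1:4)
  }
  phaseImageSet(wavelength, fx, frames, pixel_pitch)
}

#' Render raw phase-shifted frames for a scene and its calibration phantom
#'
#' Per pixel, (R_DC, R_AC) are looked up by forward interpolation of the LUT
#' at the scene's wavelength-resolved optical properties; AC frames are
#' I_k = illum * gain * (R_DC + R_AC sin(2 pi fx x + phi_k)) + ambient + noise
#' with phi_k in {0, 90, 180, 270} degrees, DC frames are the light-on /
#' light-off pair.  A matching homogeneous phantom stack is rendered under the
#' identical acquisition model.  Fully seeded and reproducible.
#'
#' @param scn a \linkS4class{Scene}
#' @param model an \linkS4class{AcquisitionModel}
#' @param lut a \linkS4class{ReflectanceLUT}
#' @param table an \linkS4class{ExtinctionTable}
#' @param phantom a \linkS4class{CalibrationPhantomSpec}
#' @param wavelengths nm (default 970, 1050, 1200)
#' @param fx_list spatial frequencies; must match the LUT (default c(0, 0.1))
#' @param seed mandatory seed for the noise draws
#' @return list with elements \code{sample} and \code{phantom}, each a list of
#'   \linkS4class{PhaseImageSet}s keyed "w{wavelength}_fx{fx}"
#' @export
renderRaw <- function(scn, model, lut, table, phantom,
                      wavelengths = c(970, 1050, 1200), fx_list = c(0, 0.1), seed) {
  stopifnot(is(scn, "Scene"), is(model, "AcquisitionModel"),
            is(lut, "ReflectanceLUT"), is(phantom, "CalibrationPhantomSpec"))
  if (missing(seed)) stop("seed is mandatory")
  if (!all(fx_list %in% lut@fx_list)) stop("fx_list must be a subset of the LUT frequencies")
  d <- dim(scn@C_water)
  out <- list(sample = list(), phantom = list())
  withSeed(subSeed(seed, 11), {
    for (wl in wavelengths) {
      props <- sceneOpticalProperties(scn, table, wl)
      bad <- which(props@mu_a < min(lut@mu_a_grid) | props@mu_a > max(lut@mu_a_grid) |
                   props@mu_s_prime < min(lut@mu_s_prime_grid) |
                   props@mu_s_prime > max(lut@mu_s_prime_grid))
      if (length(bad))
        stop("scene properties outside the LUT gamut at ", wl, " nm; pixels: ",
             paste(utils::head(bad, 10), collapse = ", "),
             if (length(bad) > 10) " ..." else "")
      prow <- phantom@properties[phantom@properties$wavelength == wl, ]
      if (nrow(prow) != 1) stop("phantom properties missing at ", wl, " nm")
      for (fx in fx_list) {
        R_dc <- matrix(lutReflectance(lut, props@mu_a, props@mu_s_prime, 0), d[1], d[2])
        R_fx <- if (fx == 0) R_dc
                else matrix(lutReflectance(lut, props@mu_a, props@mu_s_prime, fx), d[1], d[2])
        key <- sprintf("w%g_fx%g", wl, fx)
        out$sample[[key]] <- .renderCondition(R_dc, R_fx, fx, model, scn@pixel_pitch, wl)
        p_dc <- matrix(lutReflectance(lut, prow$mu_a, prow$mu_s_prime, 0), d[1], d[2])
        p_fx <- if (fx == 0) p_dc
                else matrix(lutReflectance(lut, prow$mu_a, prow$mu_s_prime, fx), d[1], d[2])
        out$phantom[[key]] <- .renderCondition(p_dc, p_fx, fx, model, scn@pixel_pitch, wl)
      }
    }
  })
  out
}

#' Homogeneous Intralipid dilution scenes
#'
#' One homogeneous scene per lipid fraction, with water = 1 - lipid and
#' reduced scattering scaled proportionally to the lipid fraction from the
#' 10 percent-Intralipid reference value.
#'
#' @param lipid_fractions lipid volume fractions in (0, 1)
#'   (the dilution study uses 0.05, 0.10, 0.15, 0.20)
#' @param musp_ref mu_s' of the 10 percent reference at \code{lambda0} (mm^-1)
#' @param lipid_ref lipid fraction of the reference (default 0.10)
#' @param shape,pixel_pitch,scatter_power,lambda0 scene geometry and
#'   scattering model, see \code{\link{scene}}
#' @return list of \linkS4class{Scene}s
#' @export
makeDilutionSeries <- function(lipid_fractions, musp_ref = 1.2, lipid_ref = 0.10,
                               shape = c(24, 24), pixel_pitch = 0.5,
                               scatter_power = 1.6, lambda0 = 970) {
  stopifnot(all(lipid_fractions > 0 & lipid_fractions < 1))
  lapply(lipid_fractions, function(cl)
    scene(C_water = 1 - cl, C_lipid = cl,
          mu_s_prime = musp_ref * cl / lipid_ref, shape = shape,
          pixel_pitch = pixel_pitch, scatter_power = scatter_power,
          lambda0 = lambda0))
}

#' Desiccation time series of scenes
#'
#' Water content decreases per the schedule; reduced scattering follows
#' multiplicatively through the hydration-scattering coupling k (relative
#' mu_s' change = k * relative water change), giving a monotone series.
#'
#' @param spc a \linkS4class{TimeSeriesSpec}; \code{water_loss} is the total
#'   loss over the series, interpreted per \code{convention}
#' @param base starting \linkS4class{Scene}
#' @return list of \linkS4class{Scene}s, length \code{n_timepoints}
#' @export
makeDesiccationSeries <- function(spc, base) {
  stopifnot(is(spc, "TimeSeriesSpec"), is(base, "Scene"))
  validObject(spc)
  n <- spc@n_timepoints
  out <- vector("list", n)
  out[[1]] <- base
  cur <- base
  for (t in 2:n) {
    if (spc@convention == "relative") {
      f <- (1 - spc@water_loss)^(1 / (n - 1))
      delta_rel <- f - 1
      Cw <- cur@C_water * f
    } else {
      step <- spc@water_loss / (n - 1)
      delta_rel <- -step / mean(cur@C_water)
      Cw <- cur@C_water - step
    }
    if (any(Cw < 0)) stop("schedule drives C_water below zero at timepoint ", t)
    nxt <- cur
    nxt@C_water <- Cw
    nxt@scatter_amplitude <- cur@scatter_amplitude * (1 + spc@k * delta_rel)
    out[[t]] <- nxt
    cur <- nxt
  }
  out
}

#' Pre/post-exercise time series with a static in-frame phantom
#'
#' Baseline timepoints are identical; at the exercise boundary dermal water
#' steps down by \code{water_loss} (relative), with coupled mu_s', and then
#' recovers exponentially toward baseline with time constant
#' \code{recovery_tau} (in timepoints).  Pixels inside the scene's
#' \code{phantom} region never change.
#'
#' @param spc a \linkS4class{TimeSeriesSpec} (n_pre baseline timepoints out of
#'   n_timepoints total)
#' @param base starting \linkS4class{Scene}; must carry a region named
#'   \code{phantom}
#' @return list of \linkS4class{Scene}s
#' @export
makeExerciseSeries <- function(spc, base) {
  stopifnot(is(spc, "TimeSeriesSpec"), is(base, "Scene"))
  validObject(spc)
  if (!"phantom" %in% names(base@regions))
    stop("base scene must carry a region named 'phantom' (in-frame reference)")
  n <- spc@n_timepoints
  n_pre <- spc@n_pre
  if (n_pre >= n) stop("n_pre must be smaller than n_timepoints")
  pm <- roiMask(dim(base@C_water), base@regions$phantom)
  out <- vector("list", n)
  for (t in seq_len(n)) {
    if (t <= n_pre) { out[[t]] <- base; next }
    drop_t <- spc@water_loss * exp(-((t - n_pre) - 1) / spc@recovery_tau)
    scn <- base
    scn@C_water[!pm] <- base@C_water[!pm] * (1 - drop_t)
    scn@scatter_amplitude[!pm] <- base@scatter_amplitude[!pm] * (1 - spc@k * drop_t)
    out[[t]] <- scn
  }
  out
}

# logical mask for a half-open 0-based ROI rectangle c(row0, row1, col0, col1)
roiMask <- function(d, roi) {
  if (roi[1] < 0 || roi[3] < 0 || roi[2] > d[1] || roi[4] > d[2] ||
      roi[1] >= roi[2] || roi[3] >= roi[4])
    stop("ROI out of bounds or empty: [", paste(roi, collapse = ", "), ")")
  m <- matrix(FALSE, d[1], d[2])
  m[(roi[1] + 1):roi[2], (roi[3] + 1):roi[4]] <- TRUE
  m
}
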