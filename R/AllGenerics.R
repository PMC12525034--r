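## Generics, accessors and show methods.

#' @export
setGeneric("muA", function(x) standardGeneric("muA"))
#' @export
setGeneric("muSPrime", function(x) standardGeneric("muSPrime"))
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))
#' @export
setGeneric("reflectance", function(x) standardGeneric("reflectance"))
#' @export
setGeneric("demodulate", function(x, ...) standardGeneric("demodulate"))

#' @describeIn MediumSpec-class absorption coefficient (mm^-1)
#' @param x object
#' @export
setMethod("muA", "MediumSpec", function(x) x@mu_a)
#' @describeIn MediumSpec-class reduced scattering coefficient (mm^-1)
#' @export
setMethod("muSPrime", "MediumSpec", function(x) x@mu_s_prime)

#' @describeIn OpticalPropertyMap-class absorption map
#' @param x object
#' @export
setMethod("muA", "OpticalPropertyMap", function(x) x@mu_a)
#' @describeIn OpticalPropertyMap-class reduced scattering map
#' @export
setMethod("muSPrime", "OpticalPropertyMap", function(x) x@mu_s_prime)
#' @describeIn OpticalPropertyMap-class validity mask
#' @export
setMethod("validMask", "OpticalPropertyMap", function(x) x@valid_mask)

#' @describeIn ReflectanceImage-class reflectance matrix
#' @param x object
#' @export
setMethod("reflectance", "ReflectanceImage", function(x) x@R)
#' @describeIn ReflectanceImage-class validity mask
#' @export
setMethod("validMask", "ReflectanceImage", function(x) x@valid_mask)
#' @describeIn ChromophoreMap-class validity mask
#' @export
setMethod("validMask", "ChromophoreMap", function(x) x@valid_mask)

setMethod("show", "MediumSpec", function(object) {
  cat(sprintf("MediumSpec: mu_a=%.4g mm^-1, mu_s'=%.4g mm^-1, g=%.2f, n=%.2f/%.2f\n",
              object@mu_a, object@mu_s_prime, object@g, object@n_medium, object@n_ambient))
})

setMethod("show", "RadialReflectance", function(object) {
  cat(sprintf("RadialReflectance: %d bins to %.1f mm, %g photons, total diffuse %.5f\n",
              length(object@R_per_area), max(object@bin_edges),
              object@n_photons, object@total_diffuse))
})

setMethod("show", "ReflectanceLUT", function(object) {
  cat(sprintf("ReflectanceLUT: %d x %d grid, fx = {%s} mm^-1\n",
              length(object@mu_a_grid), length(object@mu_s_prime_grid),
              paste(object@fx_list, collapse = ", ")))
  cat(sprintf("  mu_a [%.4g, %.4g], mu_s' [%.4g, %.4g] mm^-1; g=%.2f, n=%.2f, %g photons/node\n",
              min(object@mu_a_grid), max(object@mu_a_grid),
              min(object@mu_s_prime_grid), max(object@mu_s_prime_grid),
              object@meta$g, object@meta$n_medium, object@meta$n_photons))
})

setMethod("show", "PhaseImageSet", function(object) {
  d <- dim(object@frames[[1]])
  cat(sprintf("PhaseImageSet [%s]: %d nm, fx=%.3g mm^-1, %d x %d px (%s)\n",
              object@mode, object@wavelength, object@fx, d[1], d[2],
              paste(names(object@frames), collapse = ", ")))
})

setMethod("show", "OpticalPropertyMap", function(object) {
  ok <- object@valid_mask
  cat(sprintf("OpticalPropertyMap @ %d nm: %d x %d px, %.1f%% valid\n",
              object@wavelength, nrow(object@mu_a), ncol(object@mu_a),
              100 * mean(ok)))
  if (any(ok))
    cat(sprintf("  mu_a median %.4g, mu_s' median %.4g mm^-1 (valid pixels)\n",
                median(object@mu_a[ok]), median(object@mu_s_prime[ok])))
})

setMethod("show", "ChromophoreMap", function(object) {
  ok <- object@valid_mask
  cat(sprintf("ChromophoreMap: %d x %d px, %.1f%% valid, %.1f%% negative-flagged\n",
              nrow(object@C_water), ncol(object@C_water), 100 * mean(ok),
              100 * mean(object@negativity_mask)))
  if (any(ok))
    cat(sprintf("  median water %.1f%%, lipid %.1f%% of pure substance\n",
                100 * median(object@C_water[ok]), 100 * median(object@C_lipid[ok])))
})

setMethod("show", "ExtinctionTable", function(object) {
  cat("ExtinctionTable (pure-substance absorption, mm^-1):\n")
  print(data.frame(wavelength_nm = object@wavelengths,
                   eps_water = object@eps_water, eps_lipid = object@eps_lipid))
  cat(sprintf("  design-matrix condition number: %.3g\n", conditionNumber(object)))
})

setMethod("show", "Scene", function(object) {
  d <- dim(object@C_water)
  cat(sprintf("Scene: %d x %d px @ %.3g mm/px, water %.2f-%.2f, lipid %.2f-%.2f\n",
              d[1], d[2], object@pixel_pitch, min(object@C_water), max(object@C_water),
              min(object@C_lipid), max(object@C_lipid)))
  if (length(object@regions))
    cat("  regions:", paste(names(object@regions), collapse = ", "), "\n")
})
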