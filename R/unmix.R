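## Water/lipid chromophore unmixing from multi-wavelength absorption maps.

#' Load an extinction coefficient table
#'
#' Reads a versioned CSV with columns wavelength_nm, eps_water_mm1,
#' eps_lipid_mm1, source.  The default is the table shipped with the package:
#' approximate digitizations of the standard pure-water and pure-lipid
#' absorption series at 970, 1050 and 1200 nm, expressed as absorption per
#' unit volume fraction (mm^-1 at 100 percent) so that fitted concentrations
#' come out as volume fractions.  When working from molar spectra, the
#' conventional equivalences are 55.6 M for 100 percent water and 0.9 g/mL
#' for 100 percent lipid.
#'
#' @param path CSV path; default is the packaged table
#' @return an \linkS4class{ExtinctionTable}
#' @export
loadExtinctionTable <- function(path = system.file("extdata", "swir_extinction.csv",
                                                   package = "swirsfdi")) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  tab <- new("ExtinctionTable", wavelengths = d$wavelength_nm,
             eps_water = d$eps_water_mm1, eps_lipid = d$eps_lipid_mm1,
             provenance = d$source)
  kappa <- conditionNumber(tab)
  if (!is.finite(kappa)) stop("extinction design matrix is singular")
  tab
}

#' Condition number of the extinction design matrix
#'
#' @param table an \linkS4class{ExtinctionTable}
#' @return 2-norm condition number of the (n_wavelength x 2) design matrix
#' @export
conditionNumber <- function(table) {
  E <- cbind(table@eps_water, table@eps_lipid)
  s <- svd(E)$d
  s[1] / s[length(s)]
}

# design matrix restricted to a wavelength subset, in the given order
designMatrix <- function(table, wavelengths) {
  idx <- match(wavelengths, table@wavelengths)
  if (anyNA(idx))
    stop("extinction table lacks wavelength(s): ",
         paste(wavelengths[is.na(idx)], collapse = ", "))
  cbind(water = table@eps_water[idx], lipid = table@eps_lipid[idx])
}

#' Unmix water and lipid volume fractions from absorption maps
#'
#' Per-pixel ordinary least squares of
#' mu_a(lambda) = eps_water(lambda) C_water + eps_lipid(lambda) C_lipid
#' over the available wavelengths (with three wavelengths and two chromophores
#' the system is overdetermined by one equation).  The solution is
#' unconstrained: negative concentrations are retained and flagged in the
#' negativity mask rather than clipped, preserving diagnosability.
#'
#' @param mu_a_maps list of \linkS4class{OpticalPropertyMap}s, one per
#'   wavelength, co-registered to the same shape
#' @param table an \linkS4class{ExtinctionTable} covering those wavelengths
#' @return a \linkS4class{ChromophoreMap}
#' @export
unmixChromophores <- function(mu_a_maps, table) {
  stopifnot(is(table, "ExtinctionTable"), length(mu_a_maps) >= 2)
  lapply(mu_a_maps, function(m) stopifnot(is(m, "OpticalPropertyMap")))
  wl <- vapply(mu_a_maps, function(m) m@wavelength, numeric(1))
  if (anyDuplicated(wl)) stop("duplicated wavelength rows make the design singular")
  dims <- lapply(mu_a_maps, function(m) dim(m@mu_a))
  if (length(unique(dims)) != 1) stop("absorption maps are not co-registered (shapes differ)")
  d <- dims[[1]]

  E <- designMatrix(table, wl)
  # rhs: n_lambda x n_pixel matrix of absorption values
  A <- vapply(mu_a_maps, function(m) as.vector(m@mu_a), numeric(prod(d)))
  A <- t(matrix(A, nrow = prod(d)))
  valid <- Reduce(`&`, lapply(mu_a_maps, function(m) m@valid_mask))
  A[is.na(A)] <- 0  # masked pixels are excluded via valid; keep algebra finite

  C <- solve(crossprod(E), crossprod(E, A))          # 2 x n_pixel
  res <- sqrt(colSums((E %*% C - A)^2))

  Cw <- matrix(C[1, ], d[1], d[2]); Cl <- matrix(C[2, ], d[1], d[2])
  Cw[!valid] <- NA_real_; Cl[!valid] <- NA_real_
  resm <- matrix(res, d[1], d[2]); resm[!valid] <- NA_real_
  neg <- valid & (Cw < 0 | Cl < 0)
  new("ChromophoreMap", C_water = Cw, C_lipid = Cl, residual = resm,
      valid_mask = valid, negativity_mask = neg)
}

#' Express chromophore volume fractions as percent of pure substance
#'
#' percent = 100 * volume fraction.  The convention follows the standard
#' normalization of 55.6 M as 100 percent water and 0.9 g/mL as 100 percent
#' lipid, which is what makes volume fractions and "percent of pure
#' substance" interchangeable when the extinction inputs are per-unit-volume.
#'
#' @param map a \linkS4class{ChromophoreMap}
#' @return list with matrices \code{water} and \code{lipid} in percent
#' @export
toPercent <- function(map) {
  stopifnot(is(map, "ChromophoreMap"))
  list(water = 100 * map@C_water, lipid = 100 * map@C_lipid)
}
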