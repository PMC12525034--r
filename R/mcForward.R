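## Monte Carlo forward model: radial point response, Hankel transform to the
## spatial frequency domain, diffusion-approximation oracle, and the White-MC
## lookup table builder.

# shared defaults for the transport geometry
.MC_R_MAX <- 100      # mm; escaping photons beyond this feed total_diffuse only
.MC_N_BINS <- 2000
.MC_TAU_MAX <- 1e5    # optical pathlength cap (mean free paths), see vignette
.MC_W_THRESHOLD <- 1e-4
.MC_ROULETTE_M <- 10

#' Simulate the radial diffuse-reflectance point response
#'
#' Variance-reduced photon transport in a semi-infinite homogeneous medium:
#' pencil beam normally incident at the origin, specular entry reflection
#' removed before launch, absorbed weight deposited by albedo weighting,
#' Henyey-Greenstein deflection sampling, angle-resolved unpolarized Fresnel
#' reflection/escape at the boundary, and Russian roulette below the weight
#' threshold.  Escaping weight is accumulated into the annulus containing its
#' exit radius; weight escaping beyond \code{r_max} counts toward
#' \code{total_diffuse} but not the radial bins.
#'
#' @param medium a \linkS4class{MediumSpec}
#' @param n_photons photon count (>= 1e4 for any statistical claim)
#' @param r_max maximum binned exit radius (mm)
#' @param n_bins number of uniform radial bins
#' @param seed mandatory RNG seed (integer)
#' @return a \linkS4class{RadialReflectance}
#' @examples
#' rr <- simulateRadialReflectance(mediumSpec(0.01, 1), n_photons = 1e4, seed = 7)
#' rr@total_diffuse
#' @export
simulateRadialReflectance <- function(medium, n_photons, r_max = .MC_R_MAX,
                                      n_bins = .MC_N_BINS, seed) {
  stopifnot(is(medium, "MediumSpec"))
  validObject(medium)
  if (missing(seed)) stop("seed is mandatory")
  if (n_bins <= 0 || r_max <= 0) stop("n_bins and r_max must be positive")
  if (n_photons <= 0) stop("n_photons must be positive")
  mu_s <- medium@mu_s_prime / (1 - medium@g)
  k <- .mc_transport(medium@mu_a, mu_s, medium@g,
                     medium@n_medium / medium@n_ambient,
                     as.integer(n_photons), FALSE,
                     as.numeric(seed), 0, .MC_TAU_MAX, .MC_W_THRESHOLD, .MC_ROULETTE_M)
  edges <- seq(0, r_max, length.out = n_bins + 1)
  dr <- r_max / n_bins
  inside <- k$exit_r < r_max
  ib <- pmin(floor(k$exit_r[inside] / dr), n_bins - 1) + 1
  wsum <- numeric(n_bins)
  if (length(ib)) {
    agg <- rowsum(k$exit_w[inside], ib)
    wsum[as.integer(rownames(agg))] <- agg[, 1]
  }
  area <- pi * (edges[-1]^2 - edges[-(n_bins + 1)]^2)
  total <- (k$escaped + k$capped_weight) / n_photons
  conservation <- (k$escaped + k$absorbed + k$roulette_net + k$capped_weight) /
    n_photons - k$launch_weight
  new("RadialReflectance",
      bin_edges = edges, R_per_area = wsum / (n_photons * area),
      total_diffuse = total, n_photons = as.numeric(n_photons),
      seed = as.numeric(seed), escaped_specular_excluded = TRUE,
      meta = list(absorbed = k$absorbed / n_photons,
                  specular = k$specular,
                  launch_weight = k$launch_weight,
                  beyond_rmax = sum(k$exit_w[!inside]) / n_photons,
                  capped_weight = k$capped_weight / n_photons,
                  capped_n = k$capped_n,
                  roulette_net = k$roulette_net / n_photons,
                  conservation_error = conservation,
                  sum_w = k$sum_w, sum_w2 = k$sum_w2,
                  g = medium@g, n_medium = medium@n_medium,
                  n_ambient = medium@n_ambient, mu_a = medium@mu_a,
                  mu_s_prime = medium@mu_s_prime))
}

#' Zero-order Hankel transform of a radial point response
#'
#' Projects the radial diffuse reflectance onto a spatial frequency:
#' \code{2 pi sum_i R(r_i) J0(2 pi fx r_i) r_i dr} over the bin midpoints.
#' At fx = 0 this is the plain area integral of the binned response.
#'
#' @param radial a \linkS4class{RadialReflectance}
#' @param fx spatial frequency (mm^-1), >= 0
#' @return dimensionless spatial-frequency-domain reflectance
#' @export
hankelReflectance <- function(radial, fx) {
  stopifnot(is(radial, "RadialReflectance"))
  if (fx < 0) stop("fx must be >= 0")
  edges <- radial@bin_edges
  mid <- (edges[-1] + edges[-length(edges)]) / 2
  dr <- diff(edges)
  2 * pi * sum(radial@R_per_area * besselJ(2 * pi * fx * mid, 0) * mid * dr)
}

#' Diffusion-approximation spatial-frequency-domain reflectance
#'
#' Closed-form semi-infinite diffusion reflectance with the scalar attenuation
#' mu_eff' = sqrt(3 mu_a mu_tr + (2 pi fx)^2) and an extrapolated-boundary
#' condition parameterized through the internal-reflection parameter A derived
#' from the refractive index ratio.  Used as a deterministic oracle for the
#' Monte Carlo model in the diffusive regime (mu_s'/mu_a >> 1, low fx).
#'
#' @param medium a \linkS4class{MediumSpec}
#' @param fx spatial frequency (mm^-1), vectorized
#' @return dimensionless reflectance
#' @export
diffusionRd <- function(medium, fx) {
  stopifnot(is(medium, "MediumSpec"))
  validObject(medium)
  if (medium@mu_a > 0 && medium@mu_s_prime / medium@mu_a < 10)
    warning("mu_s'/mu_a < 10: diffusion approximation is unreliable here")
  n <- medium@n_medium / medium@n_ambient
  r_eff <- if (abs(n - 1) < 1e-12) 0 else 0.0636 * n + 0.668 + 0.710 / n - 1.440 / n^2
  A <- (1 - r_eff) / (2 * (1 + r_eff))
  mu_tr <- medium@mu_a + medium@mu_s_prime
  a_prime <- medium@mu_s_prime / mu_tr
  mu_eff <- sqrt(3 * medium@mu_a * mu_tr + (2 * pi * fx)^2)
  x <- mu_eff / mu_tr
  3 * A * a_prime / ((x + 1) * (x + 3 * A))
}

#' Build a White-Monte-Carlo reflectance lookup table
#'
#' One zero-absorption transport run is performed per mu_s' grid value, with
#' per-photon exit radius and total pathlength records; the mu_a axis is then
#' filled by pathlength rescaling (each escaping photon's weight multiplied by
#' exp(-mu_a * L)), and each (mu_a, mu_s') ensemble is projected onto the
#' requested spatial frequencies with the per-photon Hankel estimator
#' \code{mean(w J0(2 pi fx r))}.  All nodes share one RNG substream (common
#' random numbers), which makes the table's monotonicity in both axes
#' structural rather than statistical; the invariants are asserted after the
#' build.
#'
#' @param mu_a_grid,mu_s_prime_grid strictly ascending grids (mm^-1), >= 2 points
#' @param fx_list spatial frequencies (mm^-1); must contain 0
#' @param g anisotropy (default 0.9)
#' @param n_medium,n_ambient refractive indices; a LUT is only valid for
#'   samples with matching indices (recorded in meta)
#' @param n_photons photons per mu_s' node
#' @param seed mandatory RNG seed
#' @param r_max maximum exit radius entering the transform (mm)
#' @return a \linkS4class{ReflectanceLUT}
#' @export
buildLUT <- function(mu_a_grid = defaultMuAGrid(), mu_s_prime_grid = defaultMuSPrimeGrid(),
                     fx_list = c(0, 0.1), g = 0.9, n_medium = 1.33, n_ambient = 1.0,
                     n_photons = 1e5, seed, r_max = .MC_R_MAX) {
  if (missing(seed)) stop("seed is mandatory")
  if (length(mu_a_grid) < 2 || length(mu_s_prime_grid) < 2)
    stop("grids need at least 2 points")
  if (is.unsorted(mu_a_grid, strictly = TRUE) || is.unsorted(mu_s_prime_grid, strictly = TRUE))
    stop("grids must be strictly ascending")
  if (!any(fx_list == 0)) stop("fx_list must contain 0")
  warn <- character()
  if (min(mu_s_prime_grid) < 10 * max(mu_a_grid))
    warn <- c(warn, sprintf(
      "grid corner (mu_a=%.3g, mu_s'=%.3g) is outside the validated regime mu_s' >= 10 mu_a",
      max(mu_a_grid), min(mu_s_prime_grid)))

  na <- length(mu_a_grid); ns <- length(mu_s_prime_grid); nf <- length(fx_list)
  R <- array(NA_real_, dim = c(na, ns, nf))
  capped <- numeric(ns)
  for (j in seq_len(ns)) {
    mu_s <- mu_s_prime_grid[j] / (1 - g)
    k <- .mc_transport(0, mu_s, g, n_medium / n_ambient,
                       as.integer(n_photons), TRUE,
                       as.numeric(seed), 0, .MC_TAU_MAX, .MC_W_THRESHOLD, .MC_ROULETTE_M)
    capped[j] <- k$capped_weight / n_photons
    inside <- k$exit_r < r_max
    r <- k$exit_r[inside]; l <- k$exit_l[inside]; w <- k$exit_w[inside]
    j0 <- vapply(fx_list, function(fx) besselJ(2 * pi * fx * r, 0),
                 numeric(length(r)))
    if (is.null(dim(j0))) j0 <- matrix(j0, nrow = length(r))
    for (i in seq_len(na)) {
      wa <- w * exp(-mu_a_grid[i] * l)
      R[i, j, ] <- colSums(wa * j0) / n_photons
    }
  }
  R[R < 0] <- 0
  # The physical surface is monotone (decreasing in mu_a, increasing in mu_s');
  # the White-MC estimator makes the DC entries structurally so, but AC entries
  # can carry sub-noise wiggles where the true slope vanishes (oscillating-J0
  # far field near the gamut edge).  Project each frequency slab onto the
  # doubly-monotone cone by alternating pool-adjacent-violators passes; the
  # adjustment magnitude (recorded in meta) is at the Monte Carlo noise level.
  iso_adjust <- 0
  for (kf in seq_len(nf)) {
    slab <- R[, , kf]
    orig <- slab
    for (pass in 1:10) {
      before <- slab
      for (j in seq_len(ns)) slab[, j] <- -stats::isoreg(-slab[, j])$yf
      for (i in seq_len(na)) slab[i, ] <- stats::isoreg(slab[i, ])$yf
      if (identical(slab, before)) break
    }
    # snap away last-ulp pooling residue: exact non-increase in mu_a, then
    # exact non-decrease in mu_s' (running max preserves the mu_a property)
    for (j in seq_len(ns)) slab[, j] <- cummin(slab[, j])
    for (i in seq_len(na)) slab[i, ] <- cummax(slab[i, ])
    iso_adjust <- max(iso_adjust, max(abs(slab - orig)))
    R[, , kf] <- slab
  }
  i0 <- which(fx_list == 0)
  for (kf in seq_len(nf)) if (kf != i0) R[, , kf] <- pmin(R[, , kf], R[, , i0])

  lut <- new("ReflectanceLUT", mu_a_grid = as.numeric(mu_a_grid),
             mu_s_prime_grid = as.numeric(mu_s_prime_grid),
             fx_list = as.numeric(fx_list), R = R,
             meta = list(g = g, n_medium = n_medium, n_ambient = n_ambient,
                         n_photons = n_photons, seed = as.numeric(seed),
                         r_max = r_max, tau_max = .MC_TAU_MAX,
                         capped_fraction = capped, warnings = warn,
                         isotonic_max_adjust = iso_adjust,
                         built = format(Sys.time(), tz = "UTC"),
                         version = as.character(utils::packageVersion("swirsfdi"))))
  for (w in warn) warning(w)
  assertLUTInvariants(lut)
  lut
}

#' Assert the structural invariants of a reflectance LUT
#'
#' Errors unless R is monotone decreasing in mu_a (strictly so at fx = 0,
#' where White-MC rescaling makes the decrease exact; AC entries may tie
#' where the true slope vanishes at the gamut edge), monotone increasing in
#' mu_s' (strictly at fx = 0), and R(fx > 0) <= R(fx = 0) elementwise.
#'
#' @param lut a \linkS4class{ReflectanceLUT}
#' @return invisibly TRUE
#' @export
assertLUTInvariants <- function(lut) {
  R <- lut@R
  i0 <- which(lut@fx_list == 0)
  for (kf in seq_along(lut@fx_list)) {
    strict <- kf == i0
    da <- apply(R[, , kf, drop = FALSE], c(2, 3), diff)
    ds <- apply(R[, , kf, drop = FALSE], c(1, 3), diff)
    if (any(if (strict) da >= 0 else da > 0))
      stop("LUT invariant violated: R not ",
           if (strict) "strictly " else "", "decreasing in mu_a at fx = ",
           lut@fx_list[kf])
    if (any(if (strict) ds <= 0 else ds < 0))
      stop("LUT invariant violated: R not increasing in mu_s' at fx = ",
           lut@fx_list[kf])
    if (any(R[, , kf] > R[, , i0] + 1e-12))
      stop("LUT invariant violated: R(fx=", lut@fx_list[kf], ") > R(fx=0)")
  }
  invisible(TRUE)
}

#' Default LUT grids
#'
#' Log-spaced grids covering the optical properties of SWIR tissue and
#' Intralipid phantoms with margin: mu_a 0.001-0.5 mm^-1, mu_s' 0.25-5 mm^-1.
#' The mu_s' lower bound stays in the regime where the AC (fx = 0.1 mm^-1)
#' response is a monotone function of the optical properties; below roughly
#' 0.1 mm^-1 the transport mean free path exceeds the projected period and the
#' AC reflectance is genuinely non-monotone in mu_a, which would break the
#' table's invertibility (see the methods vignette).
#'
#' @param n number of grid points
#' @return numeric grid
#' @export
defaultMuAGrid <- function(n = 48) exp(seq(log(0.001), log(0.5), length.out = n))

#' @rdname defaultMuAGrid
#' @export
defaultMuSPrimeGrid <- function(n = 48) exp(seq(log(0.25), log(5), length.out = n))

#' White-MC rescaled total diffuse reflectance at arbitrary absorption
#'
#' Convenience estimator used for consistency checks: reweights a
#' zero-absorption run's per-photon records by exp(-mu_a * L).
#'
#' @param medium a \linkS4class{MediumSpec}; its mu_a is ignored (the run is at 0)
#' @param mu_a absorption values to rescale to (mm^-1), vectorized
#' @param n_photons photon count
#' @param seed RNG seed
#' @return data.frame with mu_a, Rd and the Monte Carlo standard error of Rd
#' @export
whiteMCReflectance <- function(medium, mu_a, n_photons, seed) {
  stopifnot(is(medium, "MediumSpec"))
  mu_s <- medium@mu_s_prime / (1 - medium@g)
  k <- .mc_transport(0, mu_s, medium@g, medium@n_medium / medium@n_ambient,
                     as.integer(n_photons), TRUE,
                     as.numeric(seed), 0, .MC_TAU_MAX, .MC_W_THRESHOLD, .MC_ROULETTE_M)
  out <- lapply(mu_a, function(a) {
    wa <- k$exit_w * exp(-a * k$exit_l)
    m <- sum(wa) / n_photons
    v <- sum(wa^2) / n_photons - m^2
    c(Rd = m, se = sqrt(v / n_photons))
  })
  data.frame(mu_a = mu_a, do.call(rbind, out))
}
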