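## Internal helpers: seeding and log-log bilinear interpolation on LUT grids.

# Derive a bounded positive sub-seed from a user seed and a purpose offset.
# Kept below 2^31 so it is always a valid R integer.
subSeed <- function(seed, offset) {
  ((as.numeric(seed) %% 65521) * 32749 + offset) %% 2147483629 + 1
}

# Evaluate expr with R's RNG temporarily seeded; restore the caller's stream.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Bilinear interpolation of lut@R[, , i_fx] at (mu_a, mu_s_prime), carried out
# in log(mu_a) x log(mu_s') coordinates where the surface is most linear.
# Vectorized over pixels; out-of-grid points return NA.
lutInterp <- function(lut, mu_a, mu_s_prime, i_fx) {
  la <- log(mu_a); ls <- log(mu_s_prime)
  ga <- log(lut@mu_a_grid); gs <- log(lut@mu_s_prime_grid)
  na <- length(ga); ns <- length(gs)
  out <- rep(NA_real_, length(la))
  ok <- is.finite(la) & is.finite(ls) &
    la >= ga[1] & la <= ga[na] & ls >= gs[1] & ls <= gs[ns]
  if (!any(ok)) return(out)
  la <- la[ok]; ls <- ls[ok]
  ia <- pmin(pmax(findInterval(la, ga), 1L), na - 1L)
  is_ <- pmin(pmax(findInterval(ls, gs), 1L), ns - 1L)
  ta <- (la - ga[ia]) / (ga[ia + 1L] - ga[ia])
  ts <- (ls - gs[is_]) / (gs[is_ + 1L] - gs[is_])
  Rf <- lut@R[, , i_fx]
  v00 <- Rf[cbind(ia, is_)]
  v10 <- Rf[cbind(ia + 1L, is_)]
  v01 <- Rf[cbind(ia, is_ + 1L)]
  v11 <- Rf[cbind(ia + 1L, is_ + 1L)]
  out[ok] <- (1 - ta) * (1 - ts) * v00 + ta * (1 - ts) * v10 +
    (1 - ta) * ts * v01 + ta * ts * v11
  out
}

# index of an fx value in a LUT, with tolerance
fxIndex <- function(lut, fx) {
  i <- which(abs(lut@fx_list - fx) < 1e-9)
  if (length(i) != 1)
    stop("fx = ", fx, " mm^-1 is not in the LUT (fx_list = ",
         paste(lut@fx_list, collapse = ", "), ")")
  i
}

#' Forward-interpolate LUT reflectance at given optical properties
#'
#' Bilinear interpolation of the table in log(mu_a) x log(mu_s') coordinates.
#'
#' @param lut a \linkS4class{ReflectanceLUT}
#' @param mu_a,mu_s_prime optical properties (mm^-1), vectorized
#' @param fx one of the table's spatial frequencies (mm^-1)
#' @return reflectance vector; NA where properties fall outside the grid
#' @export
lutReflectance <- function(lut, mu_a, mu_s_prime, fx) {
  stopifnot(is(lut, "ReflectanceLUT"))
  lutInterp(lut, mu_a, mu_s_prime, fxIndex(lut, fx))
}
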