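## Bidirectional use of the lookup table: recover (mu_a, mu_s') from a
## calibrated (DC, AC) reflectance pair by interpolated-forward-model least
## squares with coarse grid seeding and a shrinking pattern search in
## log-property coordinates.

# Vectorized core: invert many (R_dc, R_ac) pairs against a two-frequency LUT.
# Returns a data.frame with mu_a, mu_s_prime, residual and an ok flag.
# Tie-breaking prefers smaller mu_a: candidate moves are ordered so the first
# minimum found by which.min is the one with the smallest mu_a step.
invertReflectanceCore <- function(lut, R_dc, R_ac,
                                  residual_tol = 1e-3, step_tol = 1e-6) {
  i_dc <- fxIndex(lut, 0)
  fx_ac <- setdiff(lut@fx_list, 0)
  if (length(fx_ac) != 1)
    stop("inversion requires a LUT with exactly two spatial frequencies [0, f_ac]")
  i_ac <- fxIndex(lut, fx_ac)

  n <- length(R_dc)
  ga <- log(lut@mu_a_grid); gs <- log(lut@mu_s_prime_grid)
  finite <- is.finite(R_dc) & is.finite(R_ac)
  if (!all(finite)) stop("non-finite reflectance input to inversion")

  obj_at <- function(u, v) {
    rd <- lutInterp(lut, exp(u), exp(v), i_dc)
    ra <- lutInterp(lut, exp(u), exp(v), i_ac)
    (rd - R_dc)^2 + (ra - R_ac)^2
  }

  # coarse seeding on the full node grid
  Rdc_n <- lut@R[, , i_dc]; Rac_n <- lut@R[, , i_ac]
  best <- rep(Inf, n); bu <- numeric(n); bv <- numeric(n)
  for (j in seq_along(gs)) {
    for (i in seq_along(ga)) {
      o <- (Rdc_n[i, j] - R_dc)^2 + (Rac_n[i, j] - R_ac)^2
      upd <- o < best
      if (any(upd)) { best[upd] <- o[upd]; bu[upd] <- ga[i]; bv[upd] <- gs[j] }
    }
  }

  # shrinking 3x3 pattern search; bilinear surface, deterministic
  h <- max(diff(ga), diff(gs))
  span <- max(ga[length(ga)] - ga[1], gs[length(gs)] - gs[1])
  offs <- expand.grid(du = c(-1, 0, 1), dv = c(-1, 0, 1))
  offs <- offs[order(offs$du, offs$dv), ]  # smaller mu_a candidates first
  u <- bu; v <- bv; fcur <- obj_at(u, v)
  while (h > step_tol * span) {
    for (pass in 1:8) {            # exploit the current scale before shrinking
      moved <- FALSE
      for (r in seq_len(nrow(offs))) {
        if (offs$du[r] == 0 && offs$dv[r] == 0) next
        uu <- pmin(pmax(u + offs$du[r] * h, ga[1]), ga[length(ga)])
        vv <- pmin(pmax(v + offs$dv[r] * h, gs[1]), gs[length(gs)])
        o <- obj_at(uu, vv)
        upd <- o < fcur
        if (any(upd)) {
          u[upd] <- uu[upd]; v[upd] <- vv[upd]; fcur[upd] <- o[upd]
          moved <- TRUE
        }
      }
      if (!moved) break
    }
    h <- h * 0.5
  }
  residual <- sqrt(fcur)
  ok <- residual <= residual_tol
  data.frame(mu_a = exp(u), mu_s_prime = exp(v), residual = residual, ok = ok)
}

#' Invert one calibrated reflectance pair to optical properties
#'
#' Finds the (mu_a, mu_s') whose bilinear-interpolated (DC, AC) reflectance
#' best matches the input in the least-squares sense.  Pairs whose residual
#' exceeds \code{residual_tol} (in reflectance units) are flagged out-of-gamut
#' and carry NA properties.
#'
#' @param R_dc,R_ac dimensionless reflectance at fx = 0 and at the LUT's AC
#'   frequency
#' @param lut a two-frequency \linkS4class{ReflectanceLUT}
#' @param residual_tol gamut tolerance on the residual (default 1e-3)
#' @return list with mu_a, mu_s_prime, residual, ok
#' @examples
#' \dontrun{
#' invertPixel(0.55, 0.40, lut)
#' }
#' @export
invertPixel <- function(R_dc, R_ac, lut, residual_tol = 1e-3) {
  stopifnot(is(lut, "ReflectanceLUT"), length(R_dc) == 1, length(R_ac) == 1)
  res <- invertReflectanceCore(lut, R_dc, R_ac, residual_tol = residual_tol)
  if (!res$ok[1])
    return(list(mu_a = NA_real_, mu_s_prime = NA_real_,
                residual = res$residual[1], ok = FALSE))
  list(mu_a = res$mu_a[1], mu_s_prime = res$mu_s_prime[1],
       residual = res$residual[1], ok = TRUE)
}

#' Invert calibrated DC/AC reflectance images to an optical property map
#'
#' Per-pixel inversion on the intersection of the input validity masks.
#' Masked-out pixels carry reason code 1 (masked input); pixels whose residual
#' exceeds the gamut tolerance carry reason code 2 (out-of-gamut).
#'
#' @param R_dc_img,R_ac_img \linkS4class{ReflectanceImage}s at the same
#'   wavelength and shape (fx = 0 and the LUT AC frequency)
#' @param lut a two-frequency \linkS4class{ReflectanceLUT}
#' @param residual_tol gamut tolerance (default 1e-3)
#' @param verbose print a one-line summary of the invalid fraction
#' @return an \linkS4class{OpticalPropertyMap}
#' @export
invertMap <- function(R_dc_img, R_ac_img, lut, residual_tol = 1e-3,
                      verbose = FALSE) {
  stopifnot(is(R_dc_img, "ReflectanceImage"), is(R_ac_img, "ReflectanceImage"))
  if (R_dc_img@wavelength != R_ac_img@wavelength)
    stop("DC and AC reflectance images are at different wavelengths")
  if (!identical(dim(R_dc_img@R), dim(R_ac_img@R)))
    stop("DC and AC image shapes differ")
  d <- dim(R_dc_img@R)
  input_ok <- R_dc_img@valid_mask & R_ac_img@valid_mask
  mu_a <- matrix(NA_real_, d[1], d[2])
  mu_s <- matrix(NA_real_, d[1], d[2])
  reason <- matrix(1L, d[1], d[2])      # 1 = masked input
  if (any(input_ok)) {
    res <- invertReflectanceCore(lut, R_dc_img@R[input_ok], R_ac_img@R[input_ok],
                                 residual_tol = residual_tol)
    mu_a[input_ok] <- ifelse(res$ok, res$mu_a, NA_real_)
    mu_s[input_ok] <- ifelse(res$ok, res$mu_s_prime, NA_real_)
    reason[input_ok] <- ifelse(res$ok, 0L, 2L)  # 2 = out-of-gamut
  }
  valid <- reason == 0L
  if (verbose)
    message(sprintf("invertMap @ %g nm: %.1f%% invalid (%.1f%% masked input, %.1f%% out-of-gamut)",
                    R_dc_img@wavelength, 100 * mean(!valid),
                    100 * mean(reason == 1L), 100 * mean(reason == 2L)))
  new("OpticalPropertyMap", wavelength = R_dc_img@wavelength,
      mu_a = mu_a, mu_s_prime = mu_s, valid_mask = valid, reason = reason)
}
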