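# Shared fixtures, built once per test run and cached.
#
# The small LUT (12 x 12 nodes, 1e4 photons/node) is deliberately coarse: the
# round-trip and pipeline tests exercise consistency between the forward
# renderer and the inverter on the SAME table, so table noise cancels.  The
# acceptance tests build their own denser table.

.fixtures <- new.env(parent = emptyenv())

testLUT <- function() {
  if (is.null(.fixtures$lut)) {
    .fixtures$lut <- suppressWarnings(buildLUT(
      mu_a_grid = defaultMuAGrid(12), mu_s_prime_grid = defaultMuSPrimeGrid(12),
      n_photons = 1e4, seed = 20260920))
  }
  .fixtures$lut
}

testExtinction <- function() {
  if (is.null(.fixtures$ext)) .fixtures$ext <- loadExtinctionTable()
  .fixtures$ext
}

# 10% Intralipid calibration phantom: mu_a from pure-component mixing,
# mu_s' from the packaged reference with power-law wavelength scaling
testPhantom <- function(table = testExtinction()) {
  wl <- table@wavelengths
  calibrationPhantomSpec(data.frame(
    wavelength = wl,
    mu_a = 0.9 * table@eps_water + 0.1 * table@eps_lipid,
    mu_s_prime = 1.2 * (wl / 970)^(-1.6)),
    label = "IL10-test")
}

noiselessModel <- function(illumination = NULL)
  acquisitionModel(illumination = illumination, read_noise_sd = 0,
                   shot_scale = 0, bit_depth = NA)

defaultSkinScene <- function(shape = c(16, 16), regions = list())
  scene(C_water = 0.65, C_lipid = 0.15, mu_s_prime = 1.8, shape = shape,
        pixel_pitch = 0.5, scatter_power = 1.2, regions = regions)

# Independent brute-force oracle for the 2-chromophore least-squares fit:
# exhaustive scan of the objective, coarse pass over a wide box then a
# 1e-4-step refinement around the coarse optimum.
oracleUnmix <- function(E, mu, center, half = 0.5, step = 1e-4) {
  scan <- function(cw, cl) {
    obj <- outer(cw, cl, function(a, b)
      (E[1, 1] * a + E[1, 2] * b - mu[1])^2 +
      (E[2, 1] * a + E[2, 2] * b - mu[2])^2 +
      (E[3, 1] * a + E[3, 2] * b - mu[3])^2)
    best <- which(obj == min(obj), arr.ind = TRUE)[1, ]
    c(cw[best[1]], cl[best[2]])
  }
  coarse <- scan(seq(center[1] - half, center[1] + half, by = 0.01),
                 seq(center[2] - half, center[2] + half, by = 0.01))
  scan(seq(coarse[1] - 0.015, coarse[1] + 0.015, by = step),
       seq(coarse[2] - 0.015, coarse[2] + 0.015, by = step))
}
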