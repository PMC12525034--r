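# Monte Carlo transport: energy bookkeeping, determinism, the Hankel
# projection, and agreement with the diffusion-approximation oracle.

test_that("zero absorption with a matched boundary conserves all launched weight", {
  rr <- simulateRadialReflectance(mediumSpec(0, 1, g = 0.9), n_photons = 2e4, seed = 101)
  expect_equal(rr@total_diffuse, 1.0, tolerance = 1e-9)
  expect_lt(abs(rr@meta$conservation_error), 1e-6)
})

test_that("the energy ledger balances for absorbing, index-mismatched media", {
  rr <- simulateRadialReflectance(mediumSpec(0.05, 1, n_medium = 1.4),
                                  n_photons = 2e4, seed = 102)
  expect_lt(abs(rr@meta$conservation_error), 1e-6)
  expect_gt(rr@meta$absorbed, 0)
  expect_true(rr@escaped_specular_excluded)
  expect_equal(rr@meta$specular, ((1.4 - 1) / (1.4 + 1))^2)
  expect_true(rr@total_diffuse > 0 && rr@total_diffuse < 1)
})

test_that("identical seed and inputs give bitwise-identical results", {
  a <- simulateRadialReflectance(mediumSpec(0.01, 1), n_photons = 5e3, seed = 7)
  b <- simulateRadialReflectance(mediumSpec(0.01, 1), n_photons = 5e3, seed = 7)
  expect_identical(a@R_per_area, b@R_per_area)
  expect_identical(a@total_diffuse, b@total_diffuse)
  c <- simulateRadialReflectance(mediumSpec(0.01, 1), n_photons = 5e3, seed = 8)
  expect_false(identical(a@total_diffuse, c@total_diffuse))
})

test_that("non-physical media and degenerate geometry are rejected", {
  expect_error(mediumSpec(-0.1, 1), "mu_a")
  expect_error(mediumSpec(0.1, -1), "mu_s_prime")
  expect_error(mediumSpec(0.1, 1, g = 1), "g must")
  expect_error(simulateRadialReflectance(mediumSpec(0.01, 1), 1e3, r_max = -5, seed = 1),
               "positive")
  expect_error(simulateRadialReflectance(mediumSpec(0.01, 1), 1e3, n_bins = 0, seed = 1),
               "positive")
  expect_error(simulateRadialReflectance(mediumSpec(0.01, 1), 1e3), "seed")
})

test_that("the Hankel transform at fx = 0 recovers the binned total", {
  rr <- simulateRadialReflectance(mediumSpec(0.01, 1), n_photons = 2e4, seed = 103)
  binned_total <- rr@total_diffuse - rr@meta$beyond_rmax - rr@meta$capped_weight
  expect_equal(hankelReflectance(rr, 0), binned_total, tolerance = 0.005)
})

test_that("a single thin annulus transforms to total * J0(2 pi fx r0)", {
  edges <- seq(0, 10, length.out = 201)
  rpa <- numeric(200)
  i0 <- 60  # mass concentrated in one bin
  mid <- (edges[i0] + edges[i0 + 1]) / 2
  area <- pi * (edges[i0 + 1]^2 - edges[i0]^2)
  rpa[i0] <- 0.5 / area
  rr <- new("RadialReflectance", bin_edges = edges, R_per_area = rpa,
            total_diffuse = 0.5, n_photons = 1, seed = 0,
            escaped_specular_excluded = TRUE, meta = list())
  for (fx in c(0.05, 0.1, 0.2))
    expect_equal(hankelReflectance(rr, fx), 0.5 * besselJ(2 * pi * fx * mid, 0),
                 tolerance = 1e-10)
  expect_error(hankelReflectance(rr, -0.1), "fx")
})

test_that("diffusion oracle has the right limits and monotonicity", {
  m <- mediumSpec(1e-9, 1)
  expect_equal(diffusionRd(m, 0), 1.0, tolerance = 1e-3)
  m2 <- mediumSpec(0.01, 1)
  rd <- diffusionRd(m2, c(0, 0.05, 0.1, 0.2, 0.5))
  expect_true(all(diff(rd) < 0))
  expect_warning(diffusionRd(mediumSpec(0.5, 1), 0), "diffusion approximation")
})

test_that("MC agrees with the diffusion oracle in the diffusive regime", {
  m <- mediumSpec(0.01, 1, g = 0.9)
  rr <- simulateRadialReflectance(m, n_photons = 1e5, seed = 104)
  for (fx in c(0, 0.1)) {
    mc <- if (fx == 0) rr@total_diffuse else hankelReflectance(rr, fx)
    expect_equal(mc, diffusionRd(m, fx), tolerance = 0.10)
  }
})

test_that("media differing only in anisotropy agree through mu_s' (similarity)", {
  r9 <- simulateRadialReflectance(mediumSpec(0.01, 1, g = 0.9), n_photons = 1e5, seed = 105)
  r0 <- simulateRadialReflectance(mediumSpec(0.01, 1, g = 0.0), n_photons = 1e5, seed = 106)
  expect_equal(r9@total_diffuse, r0@total_diffuse, tolerance = 0.03)
})

test_that("White-MC rescaling matches direct simulation within 3x combined SE", {
  m <- mediumSpec(0, 1, g = 0.9, n_medium = 1.33)
  white <- whiteMCReflectance(m, mu_a = c(0.01, 0.05, 0.1), n_photons = 5e4, seed = 107)
  for (i in seq_len(nrow(white))) {
    dm <- mediumSpec(white$mu_a[i], 1, g = 0.9, n_medium = 1.33)
    rr <- simulateRadialReflectance(dm, n_photons = 5e4, seed = 200 + i)
    v <- rr@meta$sum_w2 / rr@n_photons - (rr@meta$sum_w / rr@n_photons)^2
    se_direct <- sqrt(v / rr@n_photons)
    combined <- sqrt(se_direct^2 + white$se[i]^2)
    expect_lt(abs(white$Rd[i] - rr@meta$sum_w / rr@n_photons), 3 * combined)
  }
})
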