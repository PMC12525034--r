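# Synthetic scenes and the forward renderer: composition model, determinism,
# illumination flat-fielding, and the scenario generators.

test_that("scene optical properties follow the linear composition model", {
  tab <- testExtinction()
  s_pure <- scene(C_water = 1, C_lipid = 0, mu_s_prime = 1, shape = c(4, 4))
  p <- sceneOpticalProperties(s_pure, tab, 970)
  expect_equal(p@mu_a[1, 1], tab@eps_water[1], tolerance = 1e-12)
  s_mix <- scene(C_water = 0.9, C_lipid = 0.1, mu_s_prime = 1, shape = c(4, 4))
  p2 <- sceneOpticalProperties(s_mix, tab, 1200)
  expect_equal(p2@mu_a[1, 1], 0.9 * tab@eps_water[3] + 0.1 * tab@eps_lipid[3],
               tolerance = 1e-12)
  # b = 0 -> flat scattering across wavelengths
  s_flat <- scene(0.9, 0.1, 1.5, shape = c(4, 4), scatter_power = 0)
  for (wl in tab@wavelengths)
    expect_equal(sceneOpticalProperties(s_flat, tab, wl)@mu_s_prime[1, 1], 1.5)
  expect_error(sceneOpticalProperties(s_mix, tab, 800), "absent")
})

test_that("rendering is deterministic per seed, down to TIFF bytes", {
  scn <- defaultSkinScene(shape = c(8, 8))
  model <- acquisitionModel()  # default noise on
  r1 <- renderRaw(scn, model, testLUT(), testExtinction(), testPhantom(), seed = 9)
  r2 <- renderRaw(scn, model, testLUT(), testExtinction(), testPhantom(), seed = 9)
  expect_identical(r1, r2)
  r3 <- renderRaw(scn, model, testLUT(), testExtinction(), testPhantom(), seed = 10)
  expect_false(identical(r1$sample$w970_fx0@frames$on, r3$sample$w970_fx0@frames$on))
  d1 <- tempfile(); d2 <- tempfile()
  writeRawDir(r1, d1); writeRawDir(r2, d2)
  f <- "sample_970nm_fx0.1_phi1.tif"
  expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                   readBin(file.path(d2, f), "raw", 1e6))
})

test_that("raw TIFF stacks round-trip through the manifest", {
  scn <- defaultSkinScene(shape = c(6, 6))
  raw <- renderRaw(scn, acquisitionModel(), testLUT(), testExtinction(),
                   testPhantom(), seed = 12)
  dir <- tempfile()
  mpath <- writeRawDir(raw, dir)
  back <- readRawDir(mpath)
  expect_setequal(names(back$sample), names(raw$sample))
  expect_equal(back$sample$w970_fx0@frames$on, raw$sample$w970_fx0@frames$on)
  expect_equal(back$phantom$`w1200_fx0.1`@frames$phi3,
               raw$phantom$`w1200_fx0.1`@frames$phi3)
})

test_that("per-pixel calibration cancels a +/-30% illumination profile", {
  d <- c(12, 12)
  illum <- matrix(seq(0.7, 1.3, length.out = prod(d)), d[1], d[2])
  scn <- defaultSkinScene(shape = d)
  res <- runSynthetic(scn, noiselessModel(illumination = illum), seed = 3)
  R <- res$reflectance[["970"]]$dc@R
  expect_lt(diff(range(R)) / mean(R), 1e-6)
})

test_that("noiseless homogeneous scenes recover water content within 0.5%", {
  scn <- defaultSkinScene(shape = c(10, 10))
  res <- runSynthetic(scn, seed = 21)
  expect_true(all(res$chromo@valid_mask))
  expect_lt(max(abs(res$chromo@C_water - 0.65)), 0.005)
  expect_lt(max(abs(res$chromo@C_lipid - 0.15)), 0.005)
})

test_that("dilution series scenes encode the declared water/lipid fractions", {
  scenes <- makeDilutionSeries(c(0.05, 0.10, 0.15, 0.20), shape = c(4, 4))
  expect_length(scenes, 4)
  water <- vapply(scenes, function(s) s@C_water[1, 1], numeric(1))
  expect_equal(water, c(0.95, 0.90, 0.85, 0.80))
  musp <- vapply(scenes, function(s) s@scatter_amplitude[1, 1], numeric(1))
  expect_equal(musp[4] / musp[2], 2)   # 20% scene scatters twice the 10% scene
  expect_error(makeDilutionSeries(c(0, 0.5)), "lipid_fractions")
})

test_that("desiccation series couple scattering to water loss via k", {
  base <- defaultSkinScene(shape = c(4, 4))
  sp0 <- timeSeriesSpec(4, water_loss = 0.02, k = 0)
  s0 <- makeDesiccationSeries(sp0, base)
  musp0 <- vapply(s0, function(s) s@scatter_amplitude[1, 1], numeric(1))
  expect_equal(diff(range(musp0)), 0)          # decoupled limit
  water <- vapply(s0, function(s) s@C_water[1, 1], numeric(1))
  expect_true(all(diff(water) < 0))
  expect_equal(water[4] / water[1], 0.98, tolerance = 1e-10)
  # one 2% relative step with k = 2 -> 4% relative mu_s' decrease
  sp2 <- timeSeriesSpec(2, water_loss = 0.02, k = 2)
  s2 <- makeDesiccationSeries(sp2, base)
  expect_equal(s2[[2]]@scatter_amplitude[1, 1] / s2[[1]]@scatter_amplitude[1, 1],
               0.96, tolerance = 1e-10)
  # impossible schedules rejected
  expect_error(makeDesiccationSeries(timeSeriesSpec(3, water_loss = 0.9,
                                                    convention = "absolute"),
                                     defaultSkinScene(shape = c(2, 2))),
               "below zero")
})

test_that("recovered desiccation mu_s' decreases monotonically (noiseless)", {
  base <- defaultSkinScene(shape = c(6, 6))
  series <- makeDesiccationSeries(timeSeriesSpec(4, water_loss = 0.02, k = 2), base)
  musp <- vapply(series, function(s) {
    res <- runSynthetic(s, seed = 31)
    mean(res$props[["1050"]]@mu_s_prime)
  }, numeric(1))
  expect_true(all(diff(musp) < 0))
})

test_that("exercise series keep the in-frame phantom static and step the skin", {
  base <- defaultSkinScene(shape = c(10, 10),
                           regions = list(phantom = c(0, 4, 0, 4)))
  sp <- timeSeriesSpec(8, water_loss = 0.03, k = 2, n_pre = 3, recovery_tau = 4)
  series <- makeExerciseSeries(sp, base)
  expect_length(series, 8)
  pm <- swirsfdi:::roiMask(c(10, 10), c(0, 4, 0, 4))
  for (s in series) {
    expect_equal(s@C_water[pm], base@C_water[pm])
    expect_equal(s@scatter_amplitude[pm], base@scatter_amplitude[pm])
  }
  # skin drops at the boundary then recovers toward baseline
  skin_musp <- vapply(series, function(s) s@scatter_amplitude[8, 8], numeric(1))
  expect_equal(skin_musp[1], skin_musp[3])
  expect_lt(skin_musp[4], skin_musp[1])
  expect_true(all(diff(skin_musp[4:8]) > 0))
  expect_lt(skin_musp[8], skin_musp[1] + 1e-12)
  # null scenario: zero-magnitude step leaves everything at baseline
  s_null <- makeExerciseSeries(timeSeriesSpec(5, water_loss = 0, n_pre = 2), base)
  for (s in s_null) expect_equal(s@C_water, base@C_water)
  expect_error(makeExerciseSeries(sp, defaultSkinScene(shape = c(10, 10))),
               "phantom")
})

test_that("scenes outside the LUT gamut are rejected with pixel locations", {
  hot <- scene(C_water = 1, C_lipid = 0, mu_s_prime = 20, shape = c(3, 3))
  expect_error(renderRaw(hot, noiselessModel(), testLUT(), testExtinction(),
                         testPhantom(), seed = 1),
               "outside the LUT gamut")
})
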