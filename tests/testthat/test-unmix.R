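# Water/lipid unmixing: exact algebraic recovery, the grid-search oracle for
# noisy fits, linearity, and percent conversion.

mkPropMap <- function(mu_a, wavelength, valid = NULL) {
  d <- dim(mu_a)
  if (is.null(valid)) valid <- matrix(TRUE, d[1], d[2])
  new("OpticalPropertyMap", wavelength = wavelength, mu_a = mu_a,
      mu_s_prime = matrix(1, d[1], d[2]), valid_mask = valid,
      reason = matrix(ifelse(valid, 0L, 1L), d[1], d[2]))
}

mapsFrom <- function(Cw, Cl, table, d = c(5, 5)) {
  lapply(seq_along(table@wavelengths), function(i)
    mkPropMap(matrix(Cw * table@eps_water[i] + Cl * table@eps_lipid[i], d[1], d[2]),
              table@wavelengths[i]))
}

test_that("in-span absorption vectors are recovered to machine precision", {
  tab <- testExtinction()
  cm <- unmixChromophores(mapsFrom(0.70, 0.10, tab), tab)
  expect_equal(max(abs(cm@C_water - 0.70)), 0, tolerance = 1e-12)
  expect_equal(max(abs(cm@C_lipid - 0.10)), 0, tolerance = 1e-12)
  expect_equal(max(cm@residual), 0, tolerance = 1e-12)
  expect_false(any(cm@negativity_mask))
  # pure water column
  cw <- unmixChromophores(mapsFrom(1, 0, tab), tab)
  expect_equal(cw@C_water[1, 1], 1, tolerance = 1e-12)
  expect_equal(cw@C_lipid[1, 1], 0, tolerance = 1e-12)
})

test_that("noisy fits match an exhaustive grid-search oracle within one step", {
  tab <- testExtinction()
  E <- cbind(tab@eps_water, tab@eps_lipid)
  set.seed(5)
  for (case in 1:5) {
    truth <- c(runif(1, 0.5, 0.9), runif(1, 0.05, 0.3))
    mu <- as.vector(E %*% truth) * (1 + rnorm(3, sd = 0.03))
    maps <- lapply(1:3, function(i) mkPropMap(matrix(mu[i], 1, 1), tab@wavelengths[i]))
    fit <- unmixChromophores(maps, tab)
    best <- oracleUnmix(E, mu, truth)   # exhaustive 1e-4-step scan
    expect_lt(abs(fit@C_water[1, 1] - best[1]), 1.5e-4)
    expect_lt(abs(fit@C_lipid[1, 1] - best[2]), 1.5e-4)
  }
})

test_that("unmixing is linear and flags (but keeps) negative solutions", {
  tab <- testExtinction()
  m1 <- mapsFrom(0.6, 0.2, tab)
  a <- 2.5
  m2 <- lapply(m1, function(m) mkPropMap(a * m@mu_a, m@wavelength))
  c1 <- unmixChromophores(m1, tab); c2 <- unmixChromophores(m2, tab)
  expect_equal(c2@C_water, a * c1@C_water, tolerance = 1e-10)
  expect_equal(c2@C_lipid, a * c1@C_lipid, tolerance = 1e-10)
  # breaking the span downward at one wavelength forces a negative lipid weight
  mu_neg <- mapsFrom(0.9, 0, tab)
  mu_neg[[3]]@mu_a <- mu_neg[[3]]@mu_a * 0.5   # break the span downward at 1200 nm
  fit <- unmixChromophores(mu_neg, tab)
  expect_true(all(fit@negativity_mask))
  expect_true(all(fit@C_lipid < 0))
  expect_true(all(fit@residual >= 0))
})

test_that("water + lipid fractions sum to ~1 for water/lipid-only scenes", {
  tab <- testExtinction()
  for (cl in c(0.05, 0.10, 0.15, 0.20)) {
    cm <- unmixChromophores(mapsFrom(1 - cl, cl, tab, d = c(2, 2)), tab)
    s <- cm@C_water[1, 1] + cm@C_lipid[1, 1]
    expect_gte(s, 0.98); expect_lte(s, 1.02)
  }
})

test_that("degenerate designs and mismatched inputs are rejected", {
  tab <- testExtinction()
  maps <- mapsFrom(0.7, 0.1, tab)
  expect_error(unmixChromophores(list(maps[[1]], maps[[1]]), tab), "duplicated wavelength")
  bad <- maps; bad[[2]] <- mkPropMap(matrix(0.1, 3, 3), 1050)
  expect_error(unmixChromophores(bad, tab), "co-registered")
  expect_error(unmixChromophores(maps[1], tab), "length")
  # invalid input pixels are excluded from the output mask
  v <- matrix(TRUE, 5, 5); v[1, ] <- FALSE
  maps[[1]]@valid_mask <- v
  cm <- unmixChromophores(maps, tab)
  expect_false(any(cm@valid_mask[1, ]))
  expect_true(all(is.na(cm@C_water[1, ])))
})

test_that("percent conversion scales volume fractions by 100", {
  tab <- testExtinction()
  for (cw in c(0.95, 0.90, 0.85, 0.80)) {
    cm <- unmixChromophores(mapsFrom(cw, 1 - cw, tab, d = c(2, 2)), tab)
    pct <- toPercent(cm)
    expect_equal(pct$water[1, 1], 100 * cw, tolerance = 1e-9)
    expect_equal(pct$lipid[1, 1], 100 * (1 - cw), tolerance = 1e-9)
  }
  zero <- unmixChromophores(mapsFrom(0 + 1e-15, 1e-15, tab, d = c(2, 2)), tab)
  expect_equal(toPercent(zero)$water[1, 1], 0, tolerance = 1e-9)
})

test_that("the shipped extinction table is well-conditioned and documented", {
  tab <- testExtinction()
  expect_setequal(tab@wavelengths, c(970, 1050, 1200))
  expect_true(all(tab@eps_water > 0) && all(tab@eps_lipid > 0))
  expect_true(is.finite(conditionNumber(tab)))
  expect_true(all(nzchar(tab@provenance)))
})
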