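# LUT inversion: node identities, forward-inverse round trips, noise
# response, gamut flagging and mask propagation.

test_that("a node's reflectance pair inverts to that node exactly", {
  lut <- testLUT()
  i0 <- which(lut@fx_list == 0)
  for (idx in list(c(3, 4), c(7, 9), c(10, 2))) {
    res <- invertPixel(lut@R[idx[1], idx[2], i0], lut@R[idx[1], idx[2], 2], lut)
    expect_true(res$ok)
    expect_equal(res$mu_a, lut@mu_a_grid[idx[1]], tolerance = 1e-4)
    expect_equal(res$mu_s_prime, lut@mu_s_prime_grid[idx[2]], tolerance = 1e-4)
  }
})

test_that("noiseless forward-inverse round trip is exact to 0.5% per axis", {
  lut <- testLUT()
  set.seed(42)
  n <- 200
  # central 80% of the gamut in axis (log) coordinates
  ua <- range(log(lut@mu_a_grid)); us <- range(log(lut@mu_s_prime_grid))
  mu_a <- exp(runif(n, ua[1] + 0.1 * diff(ua), ua[2] - 0.1 * diff(ua)))
  mu_s <- exp(runif(n, us[1] + 0.1 * diff(us), us[2] - 0.1 * diff(us)))
  rdc <- lutReflectance(lut, mu_a, mu_s, 0)
  rac <- lutReflectance(lut, mu_a, mu_s, 0.1)
  inv <- swirsfdi:::invertReflectanceCore(lut, rdc, rac)
  expect_true(all(inv$ok))
  expect_lt(max(abs(inv$mu_a / mu_a - 1)), 0.005)
  expect_lt(max(abs(inv$mu_s_prime / mu_s - 1)), 0.005)
})

test_that("1% reflectance noise keeps median recovery errors small", {
  lut <- testLUT()
  set.seed(43)
  n <- 200
  ua <- range(log(lut@mu_a_grid)); us <- range(log(lut@mu_s_prime_grid))
  mu_a <- exp(runif(n, ua[1] + 0.1 * diff(ua), ua[2] - 0.1 * diff(ua)))
  mu_s <- exp(runif(n, us[1] + 0.1 * diff(us), us[2] - 0.1 * diff(us)))
  rdc <- lutReflectance(lut, mu_a, mu_s, 0) * (1 + rnorm(n, sd = 0.01))
  rac <- lutReflectance(lut, mu_a, mu_s, 0.1) * (1 + rnorm(n, sd = 0.01))
  inv <- swirsfdi:::invertReflectanceCore(lut, rdc, rac, residual_tol = Inf)
  expect_lt(median(abs(inv$mu_a / mu_a - 1)), 0.05)
  expect_lt(median(abs(inv$mu_s_prime / mu_s - 1)), 0.03)
})

test_that("reflectance pairs outside the gamut are flagged, not fitted", {
  lut <- testLUT()
  res <- invertPixel(0.9, 0.89, lut)
  expect_false(res$ok)
  expect_true(is.na(res$mu_a) && is.na(res$mu_s_prime))
  expect_gt(res$residual, 1e-3)
  expect_error(invertPixel(NaN, 0.5, lut), "non-finite")
})

test_that("the inversion objective has no competing minima away from the solution", {
  # An exhaustive fine-grid scan of the objective.  The piecewise-bilinear
  # surface produces faceting artifacts (several discrete "minima" strung
  # along the narrow solution valley), so uniqueness is asserted as: every
  # local minimum lies either in the global minimum's neighborhood or at an
  # objective two orders of magnitude worse — no separated competitive basin.
  lut <- testLUT()
  set.seed(44)
  ga <- log(lut@mu_a_grid); gs <- log(lut@mu_s_prime_grid)
  uf <- seq(ga[1], ga[length(ga)], length.out = 70)
  vf <- seq(gs[1], gs[length(gs)], length.out = 70)
  for (case in 1:20) {
    mu_a <- exp(runif(1, ga[2], ga[length(ga) - 1]))
    mu_s <- exp(runif(1, gs[2], gs[length(gs) - 1]))
    rdc <- lutReflectance(lut, mu_a, mu_s, 0)
    rac <- lutReflectance(lut, mu_a, mu_s, 0.1)
    obj <- outer(uf, vf, function(u, v)
      (lutReflectance(lut, exp(u), exp(v), 0) - rdc)^2 +
      (lutReflectance(lut, exp(u), exp(v), 0.1) - rac)^2)
    gcell <- which(obj == min(obj), arr.ind = TRUE)[1, ]
    for (i in 2:(length(uf) - 1)) for (j in 2:(length(vf) - 1)) {
      nb <- obj[(i - 1):(i + 1), (j - 1):(j + 1)]
      if (obj[i, j] < min(nb[-5]) && max(abs(c(i, j) - gcell)) > 5)
        expect_gte(obj[i, j], 100 * (min(obj) + 1e-8))
    }
  }
})

test_that("invertMap propagates masks with reason codes and vectorizes", {
  lut <- testLUT()
  i0 <- which(lut@fx_list == 0)
  node <- c(6, 7)
  d <- c(10, 10)
  mk <- function(val, mask) new("ReflectanceImage", wavelength = 970, fx = 0,
                                R = matrix(val, d[1], d[2]), valid_mask = mask)
  mask <- matrix(TRUE, d[1], d[2]); mask[1:5, ] <- FALSE   # 50% masked
  rdc <- mk(lut@R[node[1], node[2], i0], mask)
  rac <- new("ReflectanceImage", wavelength = 970, fx = 0.1,
             R = matrix(lut@R[node[1], node[2], 2], d[1], d[2]),
             valid_mask = matrix(TRUE, d[1], d[2]))
  pm <- invertMap(rdc, rac, lut)
  expect_lte(mean(pm@valid_mask), 0.5)
  expect_true(all(pm@reason[1:5, ] == 1L))
  expect_true(all(pm@reason[6:10, ] == 0L))
  expect_equal(pm@mu_a[6, 1], lut@mu_a_grid[node[1]], tolerance = 1e-4)
  expect_true(all(is.na(pm@mu_a[1:5, ])))
  # wavelength mismatch rejected
  rac2 <- rac; rac2@wavelength <- 1050
  expect_error(invertMap(rdc, rac2, lut), "wavelength")
})

test_that("a two-phase checkerboard scene inverts to the checkerboard", {
  lut <- testLUT()
  d <- c(8, 8)
  chk <- outer(1:d[1], 1:d[2], function(i, j) (i + j) %% 2 == 0)
  mu_a <- ifelse(chk, 0.02, 0.08)
  mu_s <- ifelse(chk, 0.8, 2.0)
  rdc <- matrix(lutReflectance(lut, mu_a, mu_s, 0), d[1], d[2])
  rac <- matrix(lutReflectance(lut, mu_a, mu_s, 0.1), d[1], d[2])
  all_ok <- matrix(TRUE, d[1], d[2])
  pm <- invertMap(new("ReflectanceImage", wavelength = 970, fx = 0, R = rdc, valid_mask = all_ok),
                  new("ReflectanceImage", wavelength = 970, fx = 0.1, R = rac, valid_mask = all_ok),
                  lut)
  expect_true(all(pm@valid_mask))
  expect_lt(max(abs(pm@mu_a / mu_a - 1)), 0.005)
  expect_lt(max(abs(pm@mu_s_prime / mu_s - 1)), 0.005)
})
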