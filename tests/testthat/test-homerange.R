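test_that("the Gaussian reference bandwidth scales as n_eff^(-1/3)", {
  S <- matrix(c(2, 0.5, 0.5, 1), 2)
  expect_equal(reference_bandwidth(S, 1), S)
  expect_equal(reference_bandwidth(diag(2), 1000), 0.1 * diag(2))
  expect_equal(reference_bandwidth(S, 8), 0.5 * S)
  expect_error(reference_bandwidth(S, 0), "positive")
  expect_error(reference_bandwidth(matrix(c(1, 2, 2, 1), 2), 10),
               "positive definite")
})

test_that("density grids normalize, peak at the data, and vanish far away", {
  # single repeated location: maximum at that location
  xy <- matrix(rep(c(300, -200), each = 5), 5, 2)
  est <- estimate_density(xy, diag(2) * 100)
  peak <- which(est$density == max(est$density), arr.ind = TRUE)[1, ]
  expect_lt(abs(est$x[peak[1]] - 300), est$cell[1])
  expect_lt(abs(est$y[peak[2]] + 200), est$cell[2])

  # normalization contract on an IID Gaussian sample
  set.seed(51)
  z <- matrix(rnorm(2000), 1000, 2)
  est2 <- kde(z)
  expect_gte(est2$mass, 0.99)
  expect_lte(est2$mass, 1.0 + 1e-6)

  # far points carry essentially no density
  far <- hrbias:::density_at(est2, matrix(c(50, 50), 1, 2))
  expect_lt(far, max(est2$density) * 1e-10)

  # a too-coarse grid is flagged, not silently accepted
  est3 <- estimate_density(z, diag(2) * 0.01, grid = list(cells = 16))
  expect_true(any(grepl("coarser", est3$diagnostics)))
})

test_that("contour areas reproduce the chi-square closed form", {
  hr <- gaussian_homerange(sd = 1)
  expect_equal(area_at_quantile(hr, 0.95) * 1e6, chi2_95_area,
               tolerance = 0.02)
  expect_equal(area_at_quantile(hr, 0.5) * 1e6, pi * qchisq(0.5, 2),
               tolerance = 0.02)
  # area tends to 0 with q, and is monotone in q
  expect_lt(area_at_quantile(hr, 1e-4), area_at_quantile(hr, 0.05))
  qs <- c(0.1, 0.3, 0.5, 0.7, 0.9, 0.99)
  expect_true(all(diff(area_at_quantile(hr, qs)) >= 0))
  expect_error(area_at_quantile(hr, 1.2), "quantile")
})

test_that("inclusion fractions are self-consistent with the contours", {
  hr <- gaussian_homerange(sd = 1)
  set.seed(52)
  pts <- matrix(rnorm(4000), 2000, 2)
  expect_equal(inclusion_fraction(hr, 0.95, pts), 0.95, tolerance = 0.02)
  expect_equal(inclusion_fraction(hr, 0.5, pts), 0.5, tolerance = 0.05)
  # all points at the peak are inside any contour
  expect_equal(inclusion_fraction(hr, 0.99, matrix(0, 5, 2)), 1)
  # points far outside support are in none
  expect_equal(inclusion_fraction(hr, 0.5, matrix(100, 5, 2)), 0)
})

test_that("AKDE widens the bandwidth by the effective-sample-size rule", {
  # an IID-selected model makes AKDE identical to conventional KDE
  iid <- movement_model("IID", sigma = 1e4)
  tr <- simulate_track(iid, reg_times(400, 3600), seed = 53)
  f <- fit_movement(tr, "IID")
  expect_equal(akde(tr, f)$bandwidth, kde(tr)$bandwidth, tolerance = 1e-12)

  # bandwidth ratio (n / N_area)^{1/3} for the same reference covariance
  S <- matrix(c(3, 1, 1, 2), 2)
  expect_equal(reference_bandwidth(S, 8),
               reference_bandwidth(S, 1000) * (1000 / 8)^(1 / 3),
               tolerance = 1e-12)

  # autocorrelated track: AKDE n_eff ~ T/tau_p and the 95% area grows
  tau <- 86400
  tr2 <- ou_track(n = 1000, dt = 8 * tau / 999, tau_p_days = 1, seed = 54)
  f2 <- fit_movement(tr2, "OU")
  a_kde <- kde(tr2); a_akde <- akde(tr2, f2)
  expect_equal(a_akde$effective_n, effective_sample_size(f2, tr2$schedule))
  expect_lt(a_akde$effective_n, 20)
  expect_gt(area_at_quantile(a_akde, 0.95), area_at_quantile(a_kde, 0.95))
  expect_error(akde(tr2, movement_model("OU", sigma = 1, tau_p = 1)),
               "fitted")
})

test_that("the small-sample area correction obeys its contract", {
  set.seed(55)
  z <- matrix(rnorm(400), 200, 2)
  est <- kde(z)
  corrected <- apply_area_correction(est)
  f <- corrected$correction
  expect_gt(f, 1)
  # decreasing in n_eff, asymptotically 1
  est5 <- est; est5$effective_n <- 5
  est50 <- est; est50$effective_n <- 50
  expect_gt(apply_area_correction(est5)$correction,
            apply_area_correction(est50)$correction)
  estInf <- est; estInf$effective_n <- 1e9
  expect_equal(apply_area_correction(estInf)$correction, 1,
               tolerance = 1e-8)
  # bookkeeping identity: corrected area / raw area = recorded factor
  expect_equal(area_at_quantile(corrected, 0.95) /
               area_at_quantile(est, 0.95), f, tolerance = 1e-12)
  # unestimable below N = 2
  est2 <- est; est2$effective_n <- 2
  flagged <- apply_area_correction(est2)
  expect_true(is.na(flagged$correction))
  expect_true(any(grepl("not estimable", flagged$diagnostics)))
})

test_that("areas converge under grid refinement and rasters round-trip", {
  set.seed(56)
  z <- matrix(rnorm(1200), 600, 2)
  a128 <- area_at_quantile(kde(z, grid = list(cells = 128)), 0.95)
  a256 <- area_at_quantile(kde(z, grid = list(cells = 256)), 0.95)
  expect_lt(abs(a256 - a128) / a256, 0.02)

  est <- kde(z, grid = list(cells = 64))
  f <- tempfile(fileext = ".txt")
  write_density(est, f)
  lines <- readLines(f)
  expect_match(lines[1], "^origin ")
  expect_match(lines[3], "^ncols 64$")
  raster <- utils::read.table(f, skip = 5)
  expect_equal(dim(raster), c(64, 64))
  expect_equal(sum(raster) * prod(est$cell), est$mass, tolerance = 1e-8)
})
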