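test_that("tracks split at the temporal midpoint", {
  tr <- ou_track(n = 100, dt = 3600, seed = 61)
  h <- split_half(tr)
  expect_equal(n_locations(h$training), 50)
  expect_equal(n_locations(h$heldout), 50)
  expect_lt(max(h$training$schedule$times), min(h$heldout$schedule$times))

  # irregular: 70% of fixes in the first half of the span -> 70/30 split
  tms <- c(seq(0, 49, length.out = 70), seq(51, 100, length.out = 30))
  tri <- track("i", tms, rnorm(100), rnorm(100))
  hi <- split_half(tri)
  expect_equal(n_locations(hi$training), 70)
  expect_equal(n_locations(hi$heldout), 30)

  # partition identity: concatenating halves reproduces the track
  expect_equal(c(h$training$schedule$times, h$heldout$schedule$times),
               tr$schedule$times)
  expect_equal(rbind(h$training$xy, h$heldout$xy), tr$xy)
  expect_error(split_half(track("s", 1:3, 1:3, 1:3)), "at least 4")
})

test_that("Bhattacharyya distance matches its closed forms", {
  expect_equal(bhattacharyya_gaussian(c(1, 2), diag(2), c(1, 2), diag(2)), 0)
  # mean shift with identity covariances: |d|^2 / 8
  expect_equal(bhattacharyya_gaussian(c(2, 2), diag(2), c(0, 0), diag(2)),
               8 / 8)
  # equal means, I vs 4I: 0.5 * log(det(2.5 I) / sqrt(det I * det 4I))
  expect_equal(bhattacharyya_gaussian(c(0, 0), diag(2), c(0, 0),
                                      4 * diag(2)),
               0.5 * log(6.25 / 4), tolerance = 1e-12)
  expect_error(bhattacharyya_gaussian(c(0, 0), diag(0, 2), c(0, 0),
                                      diag(0, 2)), "singular")
})

test_that("the comparability gate passes nulls and rejects shifted halves", {
  tau <- 86400
  # identical halves (copied data): D_B = 0, pass
  half <- ou_track(n = 100, dt = 3600, seed = 62)
  g0 <- comparability_gate(half, half, family = "OU", seed = 1)
  expect_equal(g0$D_B, 0)
  expect_true(g0$pass)
  expect_equal(g0$ci[1], 0)

  # null case: both halves of one long OU realization
  null_pass <- vapply(1:10, function(i) {
    tr <- ou_track(n = 400, dt = 40 * tau / 399, seed = 620 + i)
    h <- split_half(tr)
    comparability_gate(h$training, h$heldout, family = "OU",
                       seed = i)$pass
  }, TRUE)
  expect_gte(mean(null_pass), 0.8)

  # alternative: halves whose means differ by 5 sigma
  alt_excl <- vapply(1:10, function(i) {
    m1 <- movement_model("OU", mu = c(0, 0), sigma = 1e6, tau_p = tau)
    m2 <- movement_model("OU", mu = c(5e3, 0), sigma = 1e6, tau_p = tau)
    a <- simulate_track(m1, reg_times(200, 20 * tau / 199), seed = 700 + i)
    b <- simulate_track(m2, reg_times(200, 20 * tau / 199) + 20 * tau,
                        seed = 800 + i)
    !comparability_gate(a, b, family = "OU", seed = i)$pass
  }, TRUE)
  expect_gte(mean(alt_excl), 0.9)

  # fit failure is an exclusion with a reason, not an error
  bad <- track("b", 1:4, rep(1, 4), rep(1, 4))
  gb <- comparability_gate(bad, half, family = "OU")
  expect_false(gb$pass)
  expect_true(nzchar(gb$reason))
})

test_that("held-out inclusion and the contour ratio score coverage", {
  hr <- gaussian_homerange(sd = 1)
  set.seed(63)
  held <- matrix(rnorm(4000), 2000, 2)
  expect_equal(crossval_inclusion(hr, held, 0.95), 95, tolerance = 2)
  expect_equal(crossval_inclusion(hr, matrix(0, 10, 2), 0.5), 100)
  expect_equal(crossval_inclusion(hr, matrix(100, 10, 2), 0.95), 0)

  # self-consistent held-out set: ratio about 1
  br <- bias_ratio(hr, held, 0.95)
  expect_equal(br$ratio, 1, tolerance = 0.15)
  expect_false(br$unattainable)

  # held-out from a Gaussian with double the variance: ratio about 2
  held2 <- matrix(rnorm(4000, sd = sqrt(2)), 2000, 2)
  br2 <- bias_ratio(hr, held2, 0.95)
  expect_equal(br2$ratio, 2, tolerance = 0.3)

  # held-out points beyond the grid support are flagged
  br3 <- bias_ratio(hr, rbind(held[1:50, ], matrix(50, 50, 2)), 0.95)
  expect_true(br3$unattainable)
})

test_that("the contour ratio exceeds 1 exactly when inclusion falls short", {
  hr <- gaussian_homerange(sd = 1)
  set.seed(64)
  for (sd in c(0.6, 0.8, 1, 1.3, 1.7)) {
    held <- matrix(rnorm(1000, sd = sd), 500, 2)
    inc <- crossval_inclusion(hr, held, 0.95)
    br <- bias_ratio(hr, held, 0.95)$ratio
    if (inc < 95) expect_gte(br, 1 - 1e-9)
    if (inc > 95) expect_lte(br, 1 + 1e-9)
  }
})

test_that("median bootstrap intervals behave", {
  expect_equal(unname(median_ci(rep(5, 20), seed = 1)), c(5, 5, 5))
  x <- rnorm(50)
  ci <- median_ci(x, seed = 2)
  expect_lte(ci["lower"], ci["median"])
  expect_gte(ci["upper"], ci["median"])
})
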