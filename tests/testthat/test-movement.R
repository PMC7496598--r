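test_that("positional ACF matches the process laws and their limits", {
  ou <- movement_model("OU", sigma = 1e6, tau_p = 100)
  expect_equal(positional_acf(ou, 0), 1)
  expect_equal(positional_acf(ou, 100), exp(-1))
  iid <- movement_model("IID", sigma = 1e6)
  expect_equal(positional_acf(iid, 0), 1)
  expect_equal(positional_acf(iid, 1e-9), 0)
  expect_error(positional_acf(ou, -1), "non-negative")

  # OU correlation is monotone non-increasing and in [0, 1]
  lags <- seq(0, 1000, by = 10)
  r <- positional_acf(ou, lags)
  expect_true(all(diff(r) <= 0) && all(r >= 0 & r <= 1))

  # OUF -> OU as tau_v -> 0 (sup-norm on a lag grid)
  ouf_small <- movement_model("OUF", sigma = 1e6, tau_p = 100, tau_v = 1e-4)
  expect_lt(max(abs(positional_acf(ouf_small, lags) -
                    positional_acf(ou, lags))), 1e-5)

  # tau_v = tau_p uses the analytic confluent limit, continuously
  ouf_eq <- movement_model("OUF", sigma = 1e6, tau_p = 100, tau_v = 100)
  ouf_near <- movement_model("OUF", sigma = 1e6, tau_p = 100,
                             tau_v = 100 * (1 - 1e-6))
  expect_equal(positional_acf(ouf_eq, 50), (1 + 0.5) * exp(-0.5))
  expect_lt(max(abs(positional_acf(ouf_eq, lags) -
                    positional_acf(ouf_near, lags))), 1e-4)
  expect_error(movement_model("OUF", sigma = 1, tau_p = 10, tau_v = 20),
               "tau_v <= tau_p")
})

test_that("exact simulation reproduces process moments and seeds", {
  # IID: sample mean within Monte-Carlo error of mu
  iid <- movement_model("IID", mu = c(100, -50), sigma = 1e4)
  tr <- simulate_track(iid, reg_times(1e4, 60), seed = 11)
  se <- sqrt(1e4 / 1e4)  # sd/sqrt(n) = 100/100
  expect_lt(abs(mean(tr$xy[, 1]) - 100), 4 * se)
  expect_lt(abs(mean(tr$xy[, 2]) + 50), 4 * se)

  # OU at dt = tau_p/10: lag-tau_p autocorrelation about exp(-1)
  tau <- 3600 * 24
  ou <- movement_model("OU", sigma = 1e6, tau_p = tau)
  tr <- simulate_track(ou, reg_times(1e4, tau / 10), seed = 12)
  k <- 10  # lag tau_p in steps
  x <- tr$xy[, 1] - mean(tr$xy[, 1])
  r <- sum(x[-(1:k)] * x[seq_len(length(x) - k)]) / sum(x^2)
  expect_lt(abs(r - exp(-1)), 0.08)

  # empirical variance near diag(sigma) (within 3 MC SEs of the
  # autocorrelation-adjusted sampling error)
  v <- apply(tr$xy, 2, var)
  n_eff <- tr$schedule$duration / tau
  expect_lt(max(abs(v - 1e6) / 1e6), 3 * sqrt(2 / n_eff))

  # seed determinism, caller RNG untouched
  t1 <- simulate_track(ou, reg_times(50, 600), seed = 99)
  t2 <- simulate_track(ou, reg_times(50, 600), seed = 99)
  expect_identical(t1$xy, t2$xy)
  set.seed(1); a <- runif(1)
  set.seed(1); invisible(simulate_track(ou, reg_times(5, 60), seed = 3))
  expect_identical(runif(1), a)
})

test_that("sequential and dense likelihood evaluations agree", {
  # brute-force Kronecker oracle on a tiny OU track
  m <- movement_model("OU", mu = c(5, -3),
                      sigma = matrix(c(4, 1, 1, 2), 2), tau_p = 50)
  tr <- track("t", c(0, 30, 100), x = c(4, 6, 5), y = c(-2, -4, -3))
  expect_equal(log_likelihood(tr, m), dense_oracle_loglik(tr, m),
               tolerance = 1e-12)
  expect_equal(log_likelihood(tr, m, method = "dense"),
               dense_oracle_loglik(tr, m), tolerance = 1e-12)

  # IID reduces to independent bivariate-normal log densities
  iid <- movement_model("IID", mu = c(0, 0), sigma = diag(c(4, 9)))
  tr2 <- track("t", c(0, 10, 20), x = c(1, -2, 0.5), y = c(3, 0, -1))
  manual <- sum(dnorm(tr2$xy[, 1], 0, 2, log = TRUE)) +
            sum(dnorm(tr2$xy[, 2], 0, 3, log = TRUE))
  expect_equal(log_likelihood(tr2, iid), manual, tolerance = 1e-12)

  # 10-significant-digit agreement on irregular 200-point tracks
  for (fam in c("OU", "OUF")) {
    mod <- movement_model(fam, mu = c(10, 20),
                          sigma = matrix(c(3e6, 5e5, 5e5, 2e6), 2),
                          tau_p = 86400,
                          tau_v = if (fam == "OUF") 8640)
    set.seed(7)
    tms <- sort(sample(seq(0, 40 * 86400, by = 600), 200))
    trk <- simulate_track(mod, tms, seed = 8)
    ls <- log_likelihood(trk, mod, method = "sequential")
    ld <- log_likelihood(trk, mod, method = "dense")
    expect_lt(abs(ls - ld) / abs(ld), 1e-10)
  }
})

test_that("maximum likelihood fits recover generating parameters", {
  # IID has closed-form ML: sample mean and ML covariance
  iid <- movement_model("IID", mu = c(7, -7), sigma = diag(c(100, 400)))
  tr <- simulate_track(iid, reg_times(200, 60), seed = 21)
  f <- fit_movement(tr, "IID")
  expect_equal(f$mu, unname(colMeans(tr$xy)), tolerance = 1e-10)
  ctr <- sweep(tr$xy, 2, colMeans(tr$xy))
  expect_equal(f$sigma, crossprod(ctr) / 200, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_true(is.finite(f$aicc))

  # OU recovery: T = 50 tau_p, n = 1000
  tau <- 86400
  tr <- ou_track(n = 1000, dt = 50 * tau / 999, tau_p_days = 1, seed = 22)
  f <- fit_movement(tr, "OU")
  expect_lt(abs(f$tau_p - tau) / tau, 0.25)
  expect_gte(f$loglik,
             log_likelihood(tr, movement_model("OU", mu = c(0, 0),
                                               sigma = 1e6, tau_p = tau)))
  expect_true(all(is.finite(f$ci)))

  # OUF data: fitted OUF beats OU by AICc in most replicates
  ouf <- movement_model("OUF", sigma = 1e6, tau_p = 10 * 3600,
                        tau_v = 3600)
  wins <- 0
  for (i in 1:20) {
    trk <- simulate_track(ouf, reg_times(300, 1200), seed = 300 + i)
    fo <- fit_movement(trk, "OU"); fu <- fit_movement(trk, "OUF")
    wins <- wins + (fu$aicc < fo$aicc)
  }
  expect_gte(wins, 11)
})

test_that("AICc model selection identifies the generating family", {
  # white noise -> IID in most replicates
  iid <- movement_model("IID", sigma = 1e4)
  picks <- vapply(1:20, function(i) {
    trk <- simulate_track(iid, reg_times(200, 3600), seed = 400 + i)
    select_movement(trk)$family
  }, "")
  expect_gte(mean(picks == "IID"), 0.8)

  # strongly autocorrelated OUF (dt much shorter than tau_v) -> OUF
  ouf <- movement_model("OUF", sigma = 1e6, tau_p = 86400, tau_v = 86400 / 5)
  trk <- simulate_track(ouf, reg_times(800, 86400 / 50), seed = 77)
  sel <- select_movement(trk)
  expect_equal(sel$family, "OUF")
  expect_equal(nrow(sel$selection), 3)

  # minimal n = 5 returns some family without error
  tiny <- simulate_track(iid, reg_times(5, 3600), seed = 5)
  expect_true(select_movement(tiny)$family %in% c("IID", "OU", "OUF"))
  expect_error(select_movement(simulate_track(iid, reg_times(4, 3600),
                                              seed = 5)), "at least 5")
})

test_that("effective sample size follows T over tau_p, clamped to n", {
  sch <- sampling_schedule(reg_times(500, 100 * 86400 / 499))
  ou <- movement_model("OU", sigma = 1, tau_p = 10 * 86400)
  ou$loglik <- -1  # mark as fitted
  expect_equal(effective_sample_size(ou, sch), 10)

  iid <- movement_model("IID", sigma = 1)
  expect_equal(effective_sample_size(iid, sch), 500)

  # T = tau_p / 2 gives 0.5 even with 1000 fixes
  sch2 <- sampling_schedule(reg_times(1000, 86400 / 999))
  ou2 <- movement_model("OU", sigma = 1, tau_p = 2 * 86400)
  expect_equal(effective_sample_size(ou2, sch2), 0.5)

  # strictly decreasing in tau_p at fixed T
  taus <- c(1, 2, 5, 10, 50) * 86400
  ns <- vapply(taus, function(tp)
    effective_sample_size(movement_model("OU", sigma = 1, tau_p = tp),
                          sch), 0)
  expect_true(all(diff(ns) < 0))
})

test_that("fitted models serialize to JSON and back", {
  tr <- ou_track(n = 200, dt = 7200, seed = 31)
  f <- fit_movement(tr, "OU")
  js <- model_to_json(f)
  back <- model_from_json(js)
  expect_equal(back$family, "OU")
  expect_equal(back$tau_p, f$tau_p, tolerance = 1e-12)
  expect_equal(back$sigma, f$sigma, tolerance = 1e-12)
  expect_equal(back$aicc, f$aicc, tolerance = 1e-12)
  expect_equal(back$ci["tau_p", ], f$ci["tau_p", ], tolerance = 1e-12,
               ignore_attr = TRUE)
})
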