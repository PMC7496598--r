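# shared fixtures: all synthetic, generated in code

# regular schedule of n fixes at interval dt (seconds)
reg_times <- function(n, dt) seq(0, by = dt, length.out = n)

# quick OU track in convenient units (tau_p in days, sigma in m^2/dim)
ou_track <- function(n = 500, dt = 3600, tau_p_days = 1, sigma = 1e6,
                     mu = c(0, 0), seed = 1, id = "ou") {
  m <- movement_model("OU", mu = mu, sigma = sigma,
                      tau_p = tau_p_days * 86400)
  simulate_track(m, reg_times(n, dt), seed = seed, id = id)
}

# dense-oracle log-likelihood: literal 2n-dimensional Gaussian built from
# the Kronecker covariance sigma (x) R -- independent of the package's
# factorized evaluation
dense_oracle_loglik <- function(tr, model) {
  n <- nrow(tr$xy)
  R <- positional_acf(model, abs(outer(tr$schedule$times,
                                       tr$schedule$times, "-")))
  K <- kronecker(model$sigma, R)
  v <- c(tr$xy[, 1] - model$mu[1], tr$xy[, 2] - model$mu[2])
  ch <- chol(K)
  w <- backsolve(ch, v, transpose = TRUE)
  as.numeric(-0.5 * (2 * n * log(2 * pi) + 2 * sum(log(diag(ch))) +
                     sum(w^2)))
}

# an exact (grid-evaluated) standard bivariate Gaussian "homerange" object,
# for testing the contour/area machinery in isolation
gaussian_homerange <- function(sd = 1, cells = 400, half_width = 6) {
  cx <- seq(-half_width * sd, half_width * sd, length.out = cells)
  cell <- diff(cx[1:2])
  dens <- outer(stats::dnorm(cx, sd = sd), stats::dnorm(cx, sd = sd))
  structure(list(method = "KDE", bandwidth = diag(2) * 0, rot = diag(2),
                 origin = rep(cx[1] - cell / 2, 2), cell = rep(cell, 2),
                 cells = cells, density = dens, x = cx, y = cx,
                 source_n = NA, effective_n = Inf, mass = sum(dens) * cell^2,
                 correction = 1, diagnostics = character(),
                 area_unit = "km2"),
            class = "homerange")
}

chi2_95_area <- pi * stats::qchisq(0.95, 2)  # 95% area of unit Gaussian
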