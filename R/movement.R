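#' Continuous-time movement models
#'
#' Specifies one of the three range-resident stationary Gaussian movement
#' processes used throughout the package:
#' \describe{
#'   \item{IID}{independent positions, no autocorrelation;}
#'   \item{OU}{Ornstein-Uhlenbeck: correlated positions, uncorrelated
#'     velocities; positional correlation decays as \eqn{e^{-t/\tau_p}};}
#'   \item{OUF}{OU-foraging: correlated positions and velocities; positional
#'     correlation \eqn{(\tau_p e^{-t/\tau_p} - \tau_v e^{-t/\tau_v}) /
#'     (\tau_p - \tau_v)}.}
#' }
#' \code{tau_p} is the range-crossing (positional autocorrelation) timescale;
#' \code{tau_v} the velocity autocorrelation timescale (OUF only, with
#' \code{0 < tau_v <= tau_p}). \code{sigma} is the 2x2 spatial covariance of
#' the stationary range distribution, in square meters.
#'
#' @param family one of \code{"IID"}, \code{"OU"}, \code{"OUF"}.
#' @param mu length-2 mean location (meters).
#' @param sigma 2x2 symmetric positive-definite spatial covariance (m^2), or
#'   a single number for an isotropic range.
#' @param tau_p positional autocorrelation timescale in seconds (OU, OUF).
#' @param tau_v velocity autocorrelation timescale in seconds (OUF).
#' @return An object of class \code{"movement_model"}. Models returned by
#'   [fit_movement()] additionally carry \code{loglik}, \code{aicc},
#'   \code{ci}, and fit diagnostics.
#' @seealso [fit_movement()], [simulate_track()], [positional_acf()]
#' @examples
#' m <- movement_model("OU", mu = c(0, 0), sigma = 1e6, tau_p = 86400)
#' positional_acf(m, 86400)   # exp(-1)
#' @export
movement_model <- function(family = c("IID", "OU", "OUF"), mu = c(0, 0),
                           sigma = diag(2), tau_p = NULL, tau_v = NULL) {
  family <- match.arg(family)
  if (length(sigma) == 1) sigma <- diag(rep(as.numeric(sigma), 2))
  sigma <- (sigma + t(sigma)) / 2
  if (!all(dim(sigma) == c(2, 2)) || any(!is.finite(sigma)))
    stop("sigma must be a finite 2x2 matrix")
  if (det(sigma) <= 0 || sigma[1, 1] <= 0)
    stop("sigma must be positive definite")
  if (family != "IID") {
    if (is.null(tau_p) || tau_p <= 0) stop(family, " requires tau_p > 0")
  } else tau_p <- NULL
  if (family == "OUF") {
    if (is.null(tau_v) || tau_v <= 0) stop("OUF requires tau_v > 0")
    if (tau_v > tau_p) stop("OUF requires tau_v <= tau_p")
  } else tau_v <- NULL
  structure(list(family = family, mu = as.numeric(mu), sigma = sigma,
                 tau_p = tau_p, tau_v = tau_v,
                 loglik = NULL, aicc = NULL, ci = NULL, n = NULL),
            class = "movement_model")
}

n_params <- function(family)
  switch(family, IID = 5, OU = 6, OUF = 7)  # 2 mean + 3 covariance + timescales

#' Positional autocorrelation function
#'
#' The correlation between positions separated by a time lag, under the
#' model's process law. All families have correlation 1 at lag zero; the IID
#' correlation drops to 0 at any positive lag; OU decays as
#' \eqn{e^{-t/\tau_p}}; OUF decays as
#' \eqn{(\tau_p e^{-t/\tau_p} - \tau_v e^{-t/\tau_v})/(\tau_p - \tau_v)},
#' with the analytic limit \eqn{(1 + t/\tau_p) e^{-t/\tau_p}} when
#' \eqn{\tau_v = \tau_p}.
#'
#' @param model a \code{\link{movement_model}}.
#' @param lag non-negative time lag(s) in seconds.
#' @return Correlation value(s) in \[0, 1\].
#' @export
positional_acf <- function(model, lag) {
  stopifnot(inherits(model, "movement_model"))
  if (any(lag < 0)) stop("lag must be non-negative")
  switch(model$family,
    IID = as.numeric(lag == 0),
    OU  = exp(-lag / model$tau_p),
    OUF = {
      tp <- model$tau_p; tv <- model$tau_v
      if (abs(tp - tv) <= 1e-8 * tp)
        (1 + lag / tp) * exp(-lag / tp)
      else
        (tp * exp(-lag / tp) - tv * exp(-lag / tv)) / (tp - tv)
    })
}

# Evaluate and restore the RNG around seeded draws so no hidden global
# state leaks between calls.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

# Unit-variance sample path of the temporal process at the given instants.
unit_path <- function(family, times, tau_p, tau_v) {
  n <- length(times)
  switch(family,
    IID = stats::rnorm(n),
    OU  = ou_sim_cpp(times, tau_p, stats::rnorm(n)),
    OUF = ouf_sim_cpp(times, tau_p, tau_v,
                      matrix(stats::rnorm(2 * n), n, 2)))
}

#' Simulate a track from a movement model
#'
#' Draws positions at the scheduled instants from the process's exact
#' finite-dimensional Gaussian distribution (exact conditional transitions,
#' never Euler steps). The x and y components are independent standard paths
#' sharing the temporal correlation structure, mixed through the Cholesky
#' factor of \code{sigma}.
#'
#' @param model a \code{\link{movement_model}}.
#' @param schedule a \code{\link{sampling_schedule}} or numeric times
#'   (seconds).
#' @param seed integer seed; the draw is deterministic given the seed and the
#'   caller's RNG state is left untouched.
#' @param id individual identifier for the returned track.
#' @return A \code{\link{track}}.
#' @export
simulate_track <- function(model, schedule, seed = NULL, id = "sim") {
  stopifnot(inherits(model, "movement_model"))
  sch <- if (inherits(schedule, "sampling_schedule")) schedule
         else sampling_schedule(schedule)
  with_seed(seed, {
    u <- cbind(unit_path(model$family, sch$times, model$tau_p, model$tau_v),
               unit_path(model$family, sch$times, model$tau_p, model$tau_v))
    A <- t(chol(model$sigma))
    xy <- u %*% t(A)
    track(id, sch, model$mu[1] + xy[, 1], model$mu[2] + xy[, 2])
  })
}

#' @rdname simulate_track
#' @param object a fitted or specified \code{\link{movement_model}}.
#' @param nsim number of tracks to draw.
#' @param ... unused.
#' @return \code{simulate.movement_model}: a list of \code{nsim} tracks (a
#'   single track if \code{nsim = 1}).
#' @export
simulate.movement_model <- function(object, nsim = 1, seed = NULL,
                                    schedule, ...) {
  out <- with_seed(seed, lapply(seq_len(nsim), function(i)
    simulate_track(object, schedule, seed = NULL,
                   id = paste0("sim", i))))
  if (nsim == 1) out[[1]] else out
}

# --- likelihood ------------------------------------------------------------

# log det R and M = V' R^{-1} V for the unit-variance temporal correlation
# matrix R implied by (family, tau_p, tau_v) at the given instants.
# method "sequential" uses the O(n) Markov/Kalman recursions; "dense" builds
# R explicitly (the brute-force oracle for small n).
corr_quadforms <- function(family, times, tau_p, tau_v, V,
                           method = c("sequential", "dense")) {
  method <- match.arg(method)
  if (family == "IID")
    return(list(logdet = 0, M = crossprod(V)))
  if (method == "sequential") {
    qf <- if (family == "OU") ou_quadforms_cpp(times, tau_p, V)
          else ouf_quadforms_cpp(times, tau_p, tau_v, V)
    return(qf)
  }
  m <- movement_model(family, sigma = diag(2), tau_p = tau_p, tau_v = tau_v)
  R <- positional_acf(m, abs(outer(times, times, "-")))
  ch <- tryCatch(chol(R), error = function(e)
    stop("correlation matrix numerically non-positive-definite"))
  W <- backsolve(ch, V, transpose = TRUE)
  list(logdet = 2 * sum(log(diag(ch))), M = crossprod(W))
}

#' Log-likelihood of a track under a movement model
#'
#' The log of the 2n-dimensional Gaussian density implied by the process: x
#' and y contribute through a shared temporal correlation matrix R and the
#' spatial covariance \code{sigma}, \deqn{\log L = -\tfrac12 (2n \log 2\pi +
#' n \log\det\Sigma + 2 \log\det R + \mathrm{tr}(\Sigma^{-1} D' R^{-1} D)),}
#' with D the mean-centered coordinate matrix. The default evaluation is the
#' O(n) Markov/state-space recursion; \code{method = "dense"} evaluates the
#' full multivariate normal directly and serves as the small-n oracle.
#'
#' @param tr a \code{\link{track}}.
#' @param model a fully specified \code{\link{movement_model}}.
#' @param method \code{"sequential"} (default) or \code{"dense"}.
#' @return Log-density in nats.
#' @export
log_likelihood <- function(tr, model, method = c("sequential", "dense")) {
  stopifnot(inherits(tr, "track"), inherits(model, "movement_model"))
  method <- match.arg(method)
  n <- n_locations(tr)
  if (n < 1 || (model$family != "IID" && n < 2))
    stop("track too short for this family")
  D <- sweep(tr$xy, 2, model$mu)
  qf <- corr_quadforms(model$family, tr$schedule$times, model$tau_p,
                       model$tau_v, D, method)
  si <- solve(model$sigma)
  quad <- sum(si * qf$M)  # tr(Sigma^-1 M), both symmetric
  ld_sigma <- determinant(model$sigma, logarithm = TRUE)$modulus
  as.numeric(-0.5 * (2 * n * log(2 * pi) + n * ld_sigma + 2 * qf$logdet + quad))
}

# Profile log-likelihood: for fixed timescales the mean is the GLS estimate
# and sigma the ML spatial covariance, both available in closed form from
# M = [1 X]' R^{-1} [1 X].
profile_fit <- function(family, times, xy, tau_p = NULL, tau_v = NULL) {
  n <- nrow(xy)
  V <- cbind(1, xy)
  qf <- corr_quadforms(family, times, tau_p, tau_v, V)
  M <- qf$M
  if (M[1, 1] <= 0) return(NULL)
  mu <- M[1, 2:3] / M[1, 1]
  Q <- M[2:3, 2:3] - tcrossprod(M[1, 2:3]) / M[1, 1]
  sigma <- (Q + t(Q)) / (2 * n)
  ds <- det(sigma)
  if (!is.finite(ds) || ds <= 0 || sigma[1, 1] <= 0) return(NULL)
  ll <- -0.5 * (2 * n * log(2 * pi) + n * log(ds) + 2 * qf$logdet + 2 * n)
  list(mu = mu, sigma = sigma, loglik = as.numeric(ll), gls_weight = M[1, 1])
}

# Initial tau_p guess from the empirical variogram: the lag at which the
# semivariance first reaches (1 - 1/e) of its plateau.
guess_tau_p <- function(tr) {
  vg <- try(variogram(tr), silent = TRUE)
  T <- tr$schedule$duration
  if (inherits(vg, "try-error") || length(vg$lag) < 3) return(T / 5)
  plateau <- mean(utils::tail(vg$semivariance, max(2, length(vg$lag) %/% 3)))
  if (!is.finite(plateau) || plateau <= 0) return(T / 5)
  i <- which(vg$semivariance >= (1 - exp(-1)) * plateau)[1]
  if (is.na(i)) return(T)
  max(vg$lag[i], tr$schedule$dt / 2)
}

aicc_value <- function(loglik, k, n) {
  if (n <= k + 1) return(Inf)
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit a movement model to a track by maximum likelihood
#'
#' Fits one of the IID / OU / OUF processes, or (default) fits all three and
#' selects the AICc-best family. The mean and spatial covariance are profiled
#' analytically; the timescales are optimized numerically on the log scale
#' with multiple starts seeded by a variogram-derived guess of \code{tau_p}.
#' AICc uses k = 5 (IID), 6 (OU), 7 (OUF) parameters (2 mean + 3 covariance
#' + timescales) and n = number of locations, so comparisons are internally
#' consistent. Confidence intervals for the timescales come from the inverse
#' observed information of the profile likelihood on the log scale.
#'
#' @param tr a \code{\link{track}}.
#' @param family \code{"auto"} (AICc selection, ties broken toward fewer
#'   parameters) or one of \code{"IID"}, \code{"OU"}, \code{"OUF"}.
#' @param level confidence level for parameter intervals.
#' @return A fitted \code{\link{movement_model}} with \code{loglik},
#'   \code{aicc}, \code{n}, \code{ci} (rows \code{tau_p}, \code{tau_v} where
#'   present), and for \code{family = "auto"} the per-family AICc table in
#'   \code{$selection}.
#' @examples
#' m <- movement_model("OU", sigma = 1e6, tau_p = 3600 * 24)
#' tr <- simulate_track(m, seq(0, 40 * 86400, by = 3 * 3600), seed = 1)
#' fit <- fit_movement(tr, "OU")
#' summary(fit)
#' @export
fit_movement <- function(tr, family = c("auto", "IID", "OU", "OUF"),
                         level = 0.95) {
  stopifnot(inherits(tr, "track"))
  family <- match.arg(family)
  if (family == "auto") return(select_movement(tr, level = level))
  n <- n_locations(tr)
  times <- tr$schedule$times
  T <- tr$schedule$duration
  z <- stats::qnorm(1 - (1 - level) / 2)

  finish <- function(pf, tau_p = NULL, tau_v = NULL, ci = NULL, diag = list()) {
    m <- movement_model(family, mu = pf$mu, sigma = pf$sigma,
                        tau_p = tau_p, tau_v = tau_v)
    m$loglik <- pf$loglik
    m$n <- n
    m$aicc <- aicc_value(pf$loglik, n_params(family), n)
    mu_se <- sqrt(pmax(diag(pf$sigma), 0) / pf$gls_weight)
    ci_mu <- rbind(mu_x = pf$mu[1] + c(-1, 1) * z * mu_se[1],
                   mu_y = pf$mu[2] + c(-1, 1) * z * mu_se[2])
    # log-scale interval for the spatial variances using the effective
    # degrees of freedom (autocorrelation-adjusted)
    n_eff <- if (family == "IID") n else max(min(T / tau_p, n), 2)
    lse <- sqrt(2 / n_eff)
    ci_sig <- rbind(
      sigma_xx = pf$sigma[1, 1] * exp(c(-1, 1) * z * lse),
      sigma_yy = pf$sigma[2, 2] * exp(c(-1, 1) * z * lse))
    ci_all <- rbind(ci_mu, ci_sig, ci)
    colnames(ci_all) <- c("lower", "upper")
    m$ci <- ci_all
    m$diagnostics <- diag
    m
  }

  if (family == "IID") {
    if (n < 3) stop("IID fit needs at least 3 locations")
    pf <- profile_fit("IID", times, tr$xy)
    if (is.null(pf)) stop("degenerate track: sample covariance not PD")
    return(finish(pf))
  }
  if (n < 5) stop(family, " fit needs at least 5 locations")

  tp0 <- guess_tau_p(tr)
  dt <- min(diff(times))
  lo <- log(dt / 20); hi <- log(50 * T)

  if (family == "OU") {
    obj <- function(lt) {
      pf <- profile_fit("OU", times, tr$xy, tau_p = exp(lt))
      if (is.null(pf)) return(1e12)
      -pf$loglik
    }
    grid <- unique(pmin(pmax(log(c(tp0 / 8, tp0 / 2, tp0, 4 * tp0, T / 2)),
                             lo), hi))
    vals <- vapply(grid, obj, 0)
    lt0 <- grid[which.min(vals)]
    op <- stats::optim(lt0, obj, method = "Brent",
                       lower = lo, upper = hi)
    tau_p <- exp(op$par)
    pf <- profile_fit("OU", times, tr$xy, tau_p = tau_p)
    if (is.null(pf)) stop("OU fit failed: degenerate profile likelihood")
    h <- num_hessian(function(p) obj(p), op$par)
    se <- if (is.finite(h) && h > 0) sqrt(1 / h) else Inf
    ci <- rbind(tau_p = tau_p * exp(c(-1, 1) * z * se))
    return(finish(pf, tau_p = tau_p, ci = ci,
                  diag = list(convergence = op$convergence,
                              log_se = se)))
  }

  # OUF: optimize (log tau_p, logit of tau_v/tau_p)
  obj2 <- function(p) {
    tp <- exp(p[1]); tv <- tp * stats::plogis(p[2])
    pf <- profile_fit("OUF", times, tr$xy, tau_p = tp, tau_v = tv)
    if (is.null(pf)) return(1e12)
    -pf$loglik
  }
  starts <- list(c(log(tp0), stats::qlogis(0.1)),
                 c(log(tp0), stats::qlogis(0.5)),
                 c(log(max(tp0 / 4, dt)), stats::qlogis(0.2)),
                 c(log(min(4 * tp0, T)), stats::qlogis(0.05)))
  best <- NULL
  for (s in starts) {
    s[1] <- min(max(s[1], lo), hi)
    op <- stats::optim(s, obj2, method = "Nelder-Mead",
                       control = list(maxit = 500, reltol = 1e-10))
    if (is.null(best) || op$value < best$value) best <- op
  }
  tau_p <- exp(best$par[1])
  tau_v <- tau_p * stats::plogis(best$par[2])
  pf <- profile_fit("OUF", times, tr$xy, tau_p = tau_p, tau_v = tau_v)
  if (is.null(pf)) stop("OUF fit failed: degenerate profile likelihood")
  H <- num_hessian2(obj2, best$par)
  ci <- tryCatch({
    Vc <- solve(H)
    se <- sqrt(pmax(diag(Vc), 0))
    # delta method on log tau_v = log tau_p + log plogis(u)
    dv <- c(1, stats::plogis(-best$par[2]))  # d log tau_v / d(p1, p2)
    se_tv <- sqrt(max(t(dv) %*% Vc %*% dv, 0))
    rbind(tau_p = tau_p * exp(c(-1, 1) * z * se[1]),
          tau_v = tau_v * exp(c(-1, 1) * z * se_tv))
  }, error = function(e)
    rbind(tau_p = c(0, Inf), tau_v = c(0, Inf)))
  finish(pf, tau_p = tau_p, tau_v = tau_v, ci = ci,
         diag = list(convergence = best$convergence))
}

# central-difference second derivative (scalar)
num_hessian <- function(f, x, h = 1e-3) {
  (f(x + h) - 2 * f(x) + f(x - h)) / h^2
}

# central-difference Hessian (2-parameter)
num_hessian2 <- function(f, x, h = 1e-3) {
  H <- matrix(0, 2, 2)
  for (i in 1:2) {
    ei <- c(0, 0); ei[i] <- h
    H[i, i] <- (f(x + ei) - 2 * f(x) + f(x - ei)) / h^2
    for (j in seq_len(i - 1)) {
      ej <- c(0, 0); ej[j] <- h
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h^2)
    }
  }
  H
}

#' Select among IID, OU and OUF by AICc
#'
#' Fits every family the track can support and returns the AICc-minimizing
#' fit; ties are broken toward fewer parameters.
#'
#' @inheritParams fit_movement
#' @return The selected fitted \code{\link{movement_model}}; the per-family
#'   AICc table is attached as \code{$selection}.
#' @export
select_movement <- function(tr, level = 0.95) {
  stopifnot(inherits(tr, "track"))
  if (n_locations(tr) < 5) stop("model selection needs at least 5 locations")
  fams <- c("IID", "OU", "OUF")
  fits <- lapply(fams, function(f)
    tryCatch(fit_movement(tr, f, level = level), error = function(e) NULL))
  ok <- !vapply(fits, is.null, TRUE)
  if (!any(ok)) stop("no movement model could be fitted")
  aiccs <- vapply(fits[ok], function(m) m$aicc, 0)
  # families are ordered by parameter count, so which.min's first-match
  # tie-break favors the simpler model
  best <- fits[ok][[which.min(aiccs)]]
  best$selection <- data.frame(family = fams[ok], aicc = aiccs,
                               delta = aiccs - min(aiccs))
  best
}

#' Effective sample size for home-range area estimation
#'
#' The equivalent number of statistically independent locations,
#' \eqn{N_{area} \approx T / \tau_p} for autocorrelated (OU/OUF) processes,
#' clamped to at most the number of observations; for IID data every
#' location is independent and \eqn{N_{area} = n}.
#'
#' @param model a fitted \code{\link{movement_model}}.
#' @param schedule the track's \code{\link{sampling_schedule}} (or numeric
#'   times).
#' @return \code{N_area}, a positive dimensionless number.
#' @export
effective_sample_size <- function(model, schedule) {
  stopifnot(inherits(model, "movement_model"))
  sch <- if (inherits(schedule, "sampling_schedule")) schedule
         else sampling_schedule(schedule)
  n <- length(sch$times)
  if (model$family == "IID") return(n)
  if (is.null(model$tau_p)) stop("model has no tau_p")
  if (sch$duration <= 0) stop("schedule duration must be positive")
  min(sch$duration / model$tau_p, n)
}

# --- methods ---------------------------------------------------------------

#' @export
print.movement_model <- function(x, ...) {
  cat(sprintf("%s movement model%s\n", x$family,
              if (is.null(x$loglik)) " (specified)" else " (fitted)"))
  cat(sprintf("  mean: (%.1f, %.1f) m\n", x$mu[1], x$mu[2]))
  cat(sprintf("  sigma: [%.4g, %.4g; %.4g] m^2\n",
              x$sigma[1, 1], x$sigma[1, 2], x$sigma[2, 2]))
  if (!is.null(x$tau_p))
    cat(sprintf("  tau_p: %.4g days\n", x$tau_p / 86400))
  if (!is.null(x$tau_v))
    cat(sprintf("  tau_v: %.4g days\n", x$tau_v / 86400))
  if (!is.null(x$loglik))
    cat(sprintf("  logLik %.2f, AICc %.2f (n = %d)\n",
                x$loglik, x$aicc, x$n))
  invisible(x)
}

#' @export
coef.movement_model <- function(object, ...) {
  out <- c(mu_x = object$mu[1], mu_y = object$mu[2],
           sigma_xx = object$sigma[1, 1], sigma_xy = object$sigma[1, 2],
           sigma_yy = object$sigma[2, 2])
  if (!is.null(object$tau_p)) out <- c(out, tau_p = object$tau_p)
  if (!is.null(object$tau_v)) out <- c(out, tau_v = object$tau_v)
  out
}

#' @export
logLik.movement_model <- function(object, ...) {
  if (is.null(object$loglik)) stop("model has not been fitted")
  structure(object$loglik, df = n_params(object$family),
            nobs = object$n, class = "logLik")
}

#' Small-sample corrected Akaike information criterion
#'
#' @param object a fitted object carrying \code{aicc} (e.g. a
#'   \code{\link{movement_model}}).
#' @return The AICc value.
#' @export
AICc <- function(object) UseMethod("AICc")

#' @export
AICc.movement_model <- function(object) {
  if (is.null(object$aicc)) stop("model has not been fitted")
  object$aicc
}

#' @export
summary.movement_model <- function(object, ...) {
  structure(list(model = object), class = "summary.movement_model")
}

#' @export
print.summary.movement_model <- function(x, ...) {
  m <- x$model
  print(m)
  if (!is.null(m$ci)) {
    cat("  95% confidence intervals:\n")
    ci <- m$ci
    for (i in seq_len(nrow(ci)))
      cat(sprintf("    %-9s [%.4g, %.4g]\n", rownames(ci)[i],
                  ci[i, 1], ci[i, 2]))
  }
  if (!is.null(m$selection)) {
    cat("  model selection (AICc):\n")
    s <- m$selection
    for (i in seq_len(nrow(s)))
      cat(sprintf("    %-4s %10.2f (delta %.2f)\n", s$family[i], s$aicc[i],
                  s$delta[i]))
  }
  invisible(x)
}

#' Serialize a fitted movement model to JSON
#'
#' @param model a \code{\link{movement_model}}.
#' @param file optional path; if omitted the JSON string is returned.
#' @return JSON string (invisibly, if written to file).
#' @export
model_to_json <- function(model, file = NULL) {
  stopifnot(inherits(model, "movement_model"))
  obj <- list(family = model$family, mu = model$mu,
              sigma = as.vector(model$sigma),
              tau_p = model$tau_p, tau_v = model$tau_v,
              loglik = model$loglik, aicc = model$aicc, n = model$n,
              ci = if (!is.null(model$ci))
                list(parameter = rownames(model$ci),
                     lower = model$ci[, 1], upper = model$ci[, 2]))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(file)) return(js)
  writeLines(js, file)
  invisible(js)
}

#' @rdname model_to_json
#' @param json a JSON string or file path produced by [model_to_json()].
#' @export
model_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  m <- movement_model(obj$family, mu = obj$mu,
                      sigma = matrix(obj$sigma, 2, 2),
                      tau_p = obj$tau_p, tau_v = obj$tau_v)
  m$loglik <- obj$loglik; m$aicc <- obj$aicc; m$n <- obj$n
  if (!is.null(obj$ci)) {
    ci <- cbind(lower = obj$ci$lower, upper = obj$ci$upper)
    rownames(ci) <- obj$ci$parameter
    m$ci <- ci
  }
  m
}
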