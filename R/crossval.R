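#' Split a track at its temporal midpoint
#'
#' Half-sample block cross-validation splits each track into two contiguous
#' blocks at the midpoint of the sampling span (time-based, not
#' count-based, so irregular schedules split by time). The training block
#' strictly precedes the held-out block and every fix lands in exactly one
#' half.
#'
#' @param tr a \code{\link{track}} with at least 4 locations.
#' @return A list with \code{training} and \code{heldout} tracks.
#' @export
split_half <- function(tr) {
  stopifnot(inherits(tr, "track"))
  n <- n_locations(tr)
  if (n < 4) stop("split_half needs at least 4 locations")
  tms <- tr$schedule$times
  mid <- tms[1] + tr$schedule$duration / 2
  first <- tms < mid
  if (!any(first) || all(first)) stop("degenerate split: empty half")
  list(training = track_subset(tr, which(first)),
       heldout = track_subset(tr, which(!first)))
}

#' Bhattacharyya distance between two bivariate Gaussians
#'
#' \deqn{D_B = \tfrac18 \Delta\mu' S^{-1} \Delta\mu + \tfrac12 \ln
#' \frac{\det S}{\sqrt{\det \Sigma_1 \det \Sigma_2}}, \quad
#' S = (\Sigma_1 + \Sigma_2)/2.} Zero iff the Gaussians are identical;
#' used as the similarity measure between the Gaussian range distributions
#' (mean and covariance) of the two data halves.
#'
#' @param mean1,mean2 length-2 mean vectors.
#' @param cov1,cov2 2x2 positive-definite covariance matrices.
#' @return Non-negative distance (dimensionless).
#' @export
bhattacharyya_gaussian <- function(mean1, cov1, mean2, cov2) {
  S <- (cov1 + cov2) / 2
  dS <- det(S)
  if (dS <= 0) stop("singular pooled covariance")
  dmu <- as.numeric(mean1 - mean2)
  as.numeric(sum(dmu * solve(S, dmu)) / 8 +
             0.5 * log(dS / sqrt(det(cov1) * det(cov2))))
}

# draw a plausible (mu, sigma) from the sampling distribution of a Gaussian
# range fit with effective sample size n_eff, centred at (mu0, sigma0)
draw_range_params <- function(mu0, sigma0, n_eff) {
  df <- max(round(n_eff), 3)
  mu <- as.numeric(mu0 + t(chol(sigma0 / n_eff)) %*% stats::rnorm(2))
  # Wishart draw via Bartlett decomposition
  L <- t(chol(sigma0 / df))
  A <- matrix(0, 2, 2)
  A[1, 1] <- sqrt(stats::rchisq(1, df))
  A[2, 2] <- sqrt(stats::rchisq(1, df - 1))
  A[2, 1] <- stats::rnorm(1)
  W <- L %*% A %*% t(A) %*% t(L)
  list(mu = mu, sigma = (W + t(W)) / 2)
}

#' Comparability gate for block cross-validation
#'
#' Block cross-validation assumes both halves of the data arise from the
#' same process. The gate fits the selected movement-model family to each
#' half, computes the Bhattacharyya distance between the implied Gaussian
#' range distributions, and compares it with a parametric-bootstrap null:
#' parameter draws for both halves centred at the pooled fit, with
#' uncertainty scaled by each half's effective sample size. The individual
#' is excluded when the observed distance exceeds the null 95th percentile
#' (equivalently, when the debiased confidence interval on \eqn{D_B}
#' excludes zero).
#'
#' @param training,heldout the two half-tracks from [split_half()].
#' @param family model family to fit to each half (\code{"auto"} selects by
#'   AICc on the training half and reuses that family).
#' @param n_boot bootstrap size (default 200).
#' @param seed RNG seed for the bootstrap draws.
#' @param level gate confidence level.
#' @return A list with \code{pass} (logical), \code{D_B}, \code{ci}
#'   (debiased interval, clamped at 0), \code{p_value}, and the two
#'   half-fits. Fit failure in either half returns \code{pass = FALSE} with
#'   a reason.
#' @export
comparability_gate <- function(training, heldout, family = "auto",
                               n_boot = 200, seed = NULL, level = 0.95) {
  fit_half <- function(tr, fam)
    tryCatch(fit_movement(tr, fam), error = function(e) e)
  f1 <- fit_half(training, family)
  if (inherits(f1, "error"))
    return(list(pass = FALSE, D_B = NA_real_, ci = c(NA, NA),
                p_value = NA_real_, reason = conditionMessage(f1)))
  fam <- if (family == "auto") f1$family else family
  f2 <- fit_half(heldout, fam)
  if (inherits(f2, "error"))
    return(list(pass = FALSE, D_B = NA_real_, ci = c(NA, NA),
                p_value = NA_real_, reason = conditionMessage(f2)))
  db <- bhattacharyya_gaussian(f1$mu, f1$sigma, f2$mu, f2$sigma)
  n1 <- effective_sample_size(f1, training$schedule)
  n2 <- effective_sample_size(f2, heldout$schedule)
  # pooled range distribution (precision-weighted mean, averaged covariance)
  w <- n1 / (n1 + n2)
  mu_p <- w * f1$mu + (1 - w) * f2$mu
  sig_p <- w * f1$sigma + (1 - w) * f2$sigma
  null_db <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    a <- draw_range_params(mu_p, sig_p, n1)
    b2 <- draw_range_params(mu_p, sig_p, n2)
    bhattacharyya_gaussian(a$mu, a$sigma, b2$mu, b2$sigma)
  }, 0))
  q_null <- stats::quantile(null_db, level, names = FALSE)
  ci <- c(max(0, db - q_null), db + q_null)
  p <- mean(null_db >= db)
  list(pass = db <= q_null, D_B = db, ci = ci, p_value = p,
       fit_training = f1, fit_heldout = f2)
}

#' Held-out inclusion percentage
#'
#' The percentage of held-out locations that fall within the q-contour of
#' the home range estimated from the training half. Values consistently
#' below 100q indicate the estimator underestimates the range.
#'
#' @param est the training-half \code{"homerange"} estimate.
#' @param heldout the held-out \code{\link{track}}.
#' @param q coverage quantile in (0, 1).
#' @return Percentage in \[0, 100\].
#' @export
crossval_inclusion <- function(est, heldout, q) {
  xy <- if (inherits(heldout, "track")) heldout$xy else as.matrix(heldout)
  if (nrow(xy) < 1) stop("empty held-out set")
  100 * inclusion_fraction(est, q, xy)
}

#' Contour-ratio bias statistic
#'
#' Finds the smallest contour of the training-half estimate that captures a
#' fraction \code{q_target} of the held-out locations and returns the ratio
#' of its area to the nominal \code{q_target}-contour area. For example, if
#' the 95\% area holds only 90\% of the held-out points while the 97\%
#' contour holds 95\%, the statistic is area(97\%) / area(95\%). Ratios
#' above 1 mean the nominal area underestimates actual coverage needs. When
#' some held-out points lie beyond the grid support the target coverage is
#' unattainable; the ratio is then computed against the full-support area
#' and flagged.
#'
#' @param est the training-half \code{"homerange"} estimate.
#' @param heldout the held-out \code{\link{track}}.
#' @param q_target target coverage in (0, 1).
#' @return A list with \code{ratio}, the matched quantile's density
#'   threshold coverage \code{achieved}, and \code{unattainable} flag.
#' @export
bias_ratio <- function(est, heldout, q_target) {
  xy <- if (inherits(heldout, "track")) heldout$xy else as.matrix(heldout)
  m <- nrow(xy)
  if (m < 1) stop("empty held-out set")
  dens <- density_at(est, xy)
  cellarea <- prod(est$cell)
  nominal <- sum(est$density >= contour_threshold(est, q_target)) * cellarea
  # smallest threshold region covering >= q_target of held-out points:
  # take the q_target-th largest point density as the threshold
  k <- ceiling(q_target * m)
  thr <- sort(dens, decreasing = TRUE)[k]
  unattainable <- thr <= 0
  area_star <- if (unattainable) est$cells^2 * cellarea
               else sum(est$density >= thr) * cellarea
  list(ratio = area_star / nominal,
       achieved = mean(dens >= thr),
       unattainable = unattainable)
}

#' Cross-validate one individual's home-range estimates
#'
#' One-stop half-sample block cross-validation: splits the track, runs the
#' comparability gate, estimates KDE and/or AKDE home ranges on the
#' training half, and scores held-out inclusion and the contour-ratio bias
#' statistic at each quantile. Excluded individuals carry the gate outcome
#' and no coverage statistics.
#'
#' @param tr a \code{\link{track}}.
#' @param methods subset of \code{c("KDE", "AKDE")}.
#' @param quantiles coverage quantiles.
#' @param family movement-model family for the gate and AKDE
#'   (\code{"auto"} = AICc selection).
#' @param grid grid specification for the density estimates.
#' @param correction score the small-sample-corrected estimates (default
#'   TRUE, matching the estimation workflow).
#' @param gate run the comparability gate (default TRUE).
#' @param n_boot,seed bootstrap controls for the gate.
#' @return A data.frame with one row per method x quantile: columns
#'   \code{individual_id, method, q, inclusion_pct, bias_ratio, N_area,
#'   gate, D_B}.
#' @export
crossval_track <- function(tr, methods = c("KDE", "AKDE"),
                           quantiles = c(0.5, 0.95), family = "auto",
                           grid = list(), correction = TRUE, gate = TRUE,
                           n_boot = 200, seed = NULL) {
  halves <- split_half(tr)
  g <- if (gate)
    comparability_gate(halves$training, halves$heldout, family = family,
                       n_boot = n_boot, seed = seed)
  else list(pass = TRUE, D_B = NA_real_,
            fit_training = fit_movement(halves$training, family))
  gate_status <- if (isTRUE(g$pass)) "pass" else "excluded"
  grid_df <- expand.grid(method = methods, q = quantiles,
                         stringsAsFactors = FALSE)
  if (!isTRUE(g$pass))
    return(data.frame(individual_id = tr$id, grid_df,
                      inclusion_pct = NA_real_, bias_ratio = NA_real_,
                      N_area = NA_real_, gate = gate_status, D_B = g$D_B))
  fit_tr <- g$fit_training
  n_area <- effective_sample_size(fit_tr, halves$training$schedule)
  ests <- list()
  if ("KDE" %in% methods)
    ests$KDE <- kde(halves$training, grid = grid, correction = correction)
  if ("AKDE" %in% methods)
    ests$AKDE <- akde(halves$training, fit_tr, grid = grid,
                      correction = correction)
  rows <- lapply(seq_len(nrow(grid_df)), function(i) {
    est <- ests[[grid_df$method[i]]]
    br <- bias_ratio(est, halves$heldout, grid_df$q[i])
    data.frame(individual_id = tr$id, method = grid_df$method[i],
               q = grid_df$q[i],
               inclusion_pct = round(
                 crossval_inclusion(est, halves$heldout, grid_df$q[i]), 1),
               bias_ratio = br$ratio, N_area = n_area,
               gate = gate_status, D_B = g$D_B)
  })
  do.call(rbind, rows)
}

#' Median with a bootstrap confidence interval
#'
#' @param x numeric values (NAs dropped).
#' @param n_boot bootstrap resamples (default 1000).
#' @param level confidence level.
#' @param seed RNG seed.
#' @return Named vector \code{median, lower, upper}.
#' @export
median_ci <- function(x, n_boot = 1000, level = 0.95, seed = NULL) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(c(median = NA, lower = NA, upper = NA))
  meds <- with_seed(seed, vapply(seq_len(n_boot), function(b)
    stats::median(sample(x, replace = TRUE)), 0))
  a <- (1 - level) / 2
  c(median = stats::median(x),
    lower = stats::quantile(meds, a, names = FALSE),
    upper = stats::quantile(meds, 1 - a, names = FALSE))
}
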