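#' Autocorrelation decay lag
#'
#' Positional autocorrelation decays exponentially at rate \eqn{1/\tau_p},
#' so the time for all but a fraction \code{alpha} of the original
#' autocorrelation to decay is \deqn{\tau_\alpha = \tau_p \ln(1/\alpha).}
#' With the conventional 95\% confidence level (\code{alpha = 0.05}) this is
#' \eqn{\approx 3 \tau_p}, the thinning interval used to bring tracking data
#' to approximate statistical independence.
#'
#' @param tau_p positional autocorrelation timescale (seconds), > 0.
#' @param alpha residual correlation level in (0, 1\].
#' @return \code{tau_alpha} in seconds.
#' @examples
#' decay_lag(1, 0.05)   # ~ 3
#' @export
decay_lag <- function(tau_p, alpha = 0.05) {
  if (any(tau_p <= 0)) stop("tau_p must be positive")
  if (any(alpha <= 0 | alpha > 1)) stop("alpha must lie in (0, 1]")
  tau_p * log(1 / alpha)
}

#' Thin a track to a minimum sampling gap
#'
#' Greedy left-to-right retention: the first fix is kept, then every next
#' fix whose gap from the last kept fix is at least \code{min_gap}. On a
#' regular schedule this retains about \code{1 + floor(T / min_gap)} fixes.
#' Model-informed thinning to independence uses
#' \code{min_gap = decay_lag(tau_p, 0.05)} (about \code{3 * tau_p}).
#'
#' @param tr a \code{\link{track}}.
#' @param min_gap minimum retained gap in seconds, > 0.
#' @return The thinned \code{\link{track}} (possibly a single fix).
#' @export
thin_track <- function(tr, min_gap) {
  stopifnot(inherits(tr, "track"))
  if (min_gap <= 0) stop("min_gap must be positive")
  tms <- tr$schedule$times
  keep <- integer(length(tms))
  keep[1] <- 1L
  k <- 1L
  last <- tms[1]
  for (i in seq_along(tms)[-1]) {
    if (tms[i] - last >= min_gap) {
      k <- k + 1L
      keep[k] <- i
      last <- tms[i]
    }
  }
  track_subset(tr, keep[seq_len(k)])
}

#' Lag-1 autocorrelation of positions
#'
#' Sample lag-1 autocorrelation of the mean-centered coordinates, averaged
#' over the x and y dimensions — the residual-autocorrelation diagnostic
#' for thinned data.
#'
#' @param tr a \code{\link{track}} with at least 3 locations.
#' @return Correlation in \[-1, 1\]; 0 (with a \code{"zero_variance"}
#'   attribute) for a degenerate constant track.
#' @export
lag1_acf <- function(tr) {
  stopifnot(inherits(tr, "track"))
  n <- n_locations(tr)
  if (n < 3) stop("lag-1 ACF needs at least 3 locations")
  acf1 <- function(z) {
    z <- z - mean(z)
    s <- sum(z^2)
    if (s == 0) return(NA_real_)
    sum(z[-1] * z[-length(z)]) / s
  }
  r <- c(acf1(tr$xy[, 1]), acf1(tr$xy[, 2]))
  if (all(is.na(r))) return(structure(0, zero_variance = TRUE))
  mean(r, na.rm = TRUE)
}

#' Thinning report for one track
#'
#' Thins a track to the model-informed independence gap
#' \eqn{\tau_\alpha = \tau_p \ln(1/\alpha)} and accounts for the cost:
#' retained sample size, percentage of data lost, and residual lag-1
#' autocorrelation before and after. Tracks with two or fewer retained
#' fixes are flagged unestimable (no home-range estimate is possible on
#' them) but still reported.
#'
#' @param tr a \code{\link{track}}.
#' @param tau_p positional autocorrelation timescale (seconds), typically
#'   from a fitted movement model.
#' @param alpha residual correlation level (default 0.05, i.e. a gap of
#'   about \code{3 * tau_p}).
#' @return A list of class \code{"thinning_report"}: \code{alpha},
#'   \code{tau_alpha}, \code{n_before}, \code{n_after},
#'   \code{data_loss_pct}, \code{lag1_acf_before}, \code{lag1_acf_after},
#'   \code{estimable}, and the thinned \code{track}.
#' @export
thin_report <- function(tr, tau_p, alpha = 0.05) {
  stopifnot(inherits(tr, "track"))
  tau_alpha <- decay_lag(tau_p, alpha)
  thin <- thin_track(tr, tau_alpha)
  n0 <- n_locations(tr); n1 <- n_locations(thin)
  structure(list(
    alpha = alpha, tau_alpha = tau_alpha,
    n_before = n0, n_after = n1,
    data_loss_pct = 100 * (1 - n1 / n0),
    lag1_acf_before = if (n0 >= 3) as.numeric(lag1_acf(tr)) else NA_real_,
    lag1_acf_after = if (n1 >= 3) as.numeric(lag1_acf(thin)) else NA_real_,
    estimable = n1 > 2,
    track = thin), class = "thinning_report")
}

#' @export
print.thinning_report <- function(x, ...) {
  cat(sprintf("Thinning to tau_alpha = %.3g days (alpha = %.3g):\n",
              x$tau_alpha / 86400, x$alpha))
  cat(sprintf("  %d -> %d fixes (%.1f%% data loss)%s\n", x$n_before,
              x$n_after, x$data_loss_pct,
              if (!x$estimable) " [unestimable]" else ""))
  cat(sprintf("  lag-1 ACF %.3f -> %.3f\n",
              x$lag1_acf_before, x$lag1_acf_after))
  invisible(x)
}
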