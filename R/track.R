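#' Sampling schedules
#'
#' A sampling schedule is the ordered set of instants (seconds) at which an
#' animal was relocated. The duration \code{T} is the span from first to last
#' fix; the nominal interval \code{dt} is the median gap, which need not be
#' constant.
#'
#' @param times numeric vector of sampling instants in seconds, strictly
#'   increasing.
#' @return An object of class \code{"sampling_schedule"} with elements
#'   \code{times}, \code{duration} and \code{dt}.
#' @examples
#' sch <- sampling_schedule(seq(0, 3600 * 24, by = 3600))
#' sch$duration / 3600
#' @export
sampling_schedule <- function(times) {
  times <- as.numeric(times)
  if (length(times) == 0) stop("a schedule needs at least one instant")
  if (anyNA(times) || any(!is.finite(times))) stop("non-finite sampling times")
  if (is.unsorted(times, strictly = TRUE))
    stop("sampling times must be strictly increasing")
  n <- length(times)
  structure(list(
    times = times,
    duration = if (n >= 2) times[n] - times[1] else 0,
    dt = if (n >= 2) stats::median(diff(times)) else NA_real_
  ), class = "sampling_schedule")
}

#' @export
print.sampling_schedule <- function(x, ...) {
  cat(sprintf("Sampling schedule: %d fixes over %.3g days (median dt %.3g h)\n",
              length(x$times), x$duration / 86400, x$dt / 3600))
  invisible(x)
}

#' Animal tracks
#'
#' A track is one individual's timestamped planar relocations: a sampling
#' schedule plus (x, y) coordinates in meters. Coordinates are planar
#' (projected) meters; geodetic data must be projected before use.
#'
#' @param id individual identifier (coerced to character).
#' @param times sampling instants (seconds) or a
#'   \code{\link{sampling_schedule}}.
#' @param x,y numeric coordinate vectors in meters, one value per instant.
#' @return An object of class \code{"track"}: a list with \code{id},
#'   \code{schedule}, and an n-by-2 coordinate matrix \code{xy}.
#' @seealso [read_tracks()], [fit_movement()], [variogram()]
#' @examples
#' tr <- track("ind1", c(0, 60, 120), x = c(0, 5, 3), y = c(0, -2, 1))
#' tr
#' @export
track <- function(id, times, x, y) {
  sch <- if (inherits(times, "sampling_schedule")) times
         else sampling_schedule(times)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(sch$times) || length(y) != length(sch$times))
    stop("need exactly one position per sampling instant")
  if (anyNA(x) || anyNA(y) || any(!is.finite(c(x, y))))
    stop("all coordinates must be finite")
  structure(list(id = as.character(id)[1], schedule = sch,
                 xy = cbind(x = x, y = y)),
            class = "track")
}

n_locations <- function(tr) nrow(tr$xy)

#' @export
print.track <- function(x, ...) {
  cat(sprintf("Track '%s': %d locations over %.3g days\n", x$id,
              n_locations(x), x$schedule$duration / 86400))
  invisible(x)
}

#' @export
summary.track <- function(object, ...) {
  xy <- object$xy
  out <- list(id = object$id, n = nrow(xy),
              duration_days = object$schedule$duration / 86400,
              dt_hours = object$schedule$dt / 3600,
              center = colMeans(xy), sd = apply(xy, 2, stats::sd))
  class(out) <- "summary.track"
  out
}

#' @export
print.summary.track <- function(x, ...) {
  cat(sprintf("Track '%s': n = %d, T = %.3g days, dt = %.3g h\n",
              x$id, x$n, x$duration_days, x$dt_hours))
  cat(sprintf("  center (%.1f, %.1f) m; SD (%.1f, %.1f) m\n",
              x$center[1], x$center[2], x$sd[1], x$sd[2]))
  invisible(x)
}

#' Subset a track by index
#'
#' @param tr a \code{\link{track}}.
#' @param i integer or logical index into the locations (kept in time order).
#' @return A \code{\link{track}} with the selected locations.
#' @export
track_subset <- function(tr, i) {
  idx <- seq_len(n_locations(tr))[i]
  if (length(idx) == 0) stop("empty subset")
  track(tr$id, tr$schedule$times[idx], tr$xy[idx, 1], tr$xy[idx, 2])
}

#' Read and write tracking data as CSV
#'
#' The native dialect has columns \code{individual_id, timestamp, x, y} with
#' timestamps either numeric seconds or ISO-8601 strings, and coordinates in
#' planar meters. A Movebank-flavored reader maps
#' \code{individual-local-identifier, timestamp, utm-easting, utm-northing}
#' onto the same fields.
#'
#' @param file path to a CSV file.
#' @param dialect \code{"native"} or \code{"movebank"}.
#' @return \code{read_tracks}: a named list of \code{\link{track}} objects.
#' @export
read_tracks <- function(file, dialect = c("native", "movebank")) {
  dialect <- match.arg(dialect)
  df <- utils::read.csv(file, check.names = FALSE, stringsAsFactors = FALSE)
  cols <- switch(dialect,
    native   = c(id = "individual_id", t = "timestamp", x = "x", y = "y"),
    movebank = c(id = "individual-local-identifier", t = "timestamp",
                 x = "utm-easting", y = "utm-northing"))
  missing_cols <- setdiff(unname(cols), names(df))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  ts <- df[[cols["t"]]]
  secs <- if (is.numeric(ts)) as.numeric(ts) else
    as.numeric(as.POSIXct(ts, tz = "UTC"))
  if (anyNA(secs)) stop("unparseable timestamps")
  ids <- as.character(df[[cols["id"]]])
  out <- lapply(split(seq_along(ids), ids), function(i) {
    o <- i[order(secs[i])]
    track(ids[o[1]], secs[o], df[[cols["x"]]][o], df[[cols["y"]]][o])
  })
  out[order(names(out))]
}

#' @rdname read_tracks
#' @param tracks a \code{\link{track}} or list of tracks.
#' @return \code{write_tracks}: the file path, invisibly.
#' @export
write_tracks <- function(tracks, file) {
  if (inherits(tracks, "track")) tracks <- list(tracks)
  df <- do.call(rbind, lapply(tracks, function(tr)
    data.frame(individual_id = tr$id, timestamp = tr$schedule$times,
               x = tr$xy[, 1], y = tr$xy[, 2])))
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}
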