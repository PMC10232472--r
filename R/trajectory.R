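# Trajectory data model and track-table I/O.
#
# A trajectory is one uniformly sampled 2D track; an ensemble is a set of
# trajectories sharing the sampling interval. Durations are random in typical
# tracking experiments (particles enter and leave the focal volume), so the
# ensemble carries survival counts N(t) = #{i : T_i >= t} which drive all
# censoring-aware averages downstream.

#' Construct a single 2D trajectory
#'
#' @param x,y numeric coordinate vectors in micrometres, one entry per frame.
#' @param dt sampling interval in seconds.
#' @param id trajectory label.
#' @param t0 absolute start time in seconds (default 0).
#' @return an object of class \code{"trajectory"} with fields \code{id},
#'   \code{dt}, \code{x}, \code{y}, \code{t0}. The duration is
#'   \code{(length(x) - 1) * dt}.
#' @examples
#' tr <- trajectory(x = c(0, 1, 2), y = c(0, 0, 0), dt = 0.05)
#' duration(tr)
#' @export
trajectory <- function(x, y, dt, id = "track", t0 = 0) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have the same length")
  if (length(x) < 2L) stop("a trajectory needs at least 2 points")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("trajectory '", id, "' has non-finite coordinates")
  stopifnot_scalar(dt, "dt")
  if (dt <= 0) stop("dt must be positive")
  structure(list(id = as.character(id), dt = dt, x = x, y = y, t0 = t0),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory '%s': %d points, dt = %g s, T = %g s>\n",
              x$id, length(x$x), x$dt, duration(x)))
  invisible(x)
}

#' Trajectory duration(s) in seconds
#'
#' @param x a \code{trajectory} or \code{track_ensemble}.
#' @return numeric duration(s) \code{T = (n - 1) * dt}.
#' @export
duration <- function(x) UseMethod("duration")

#' @export
duration.trajectory <- function(x) (length(x$x) - 1L) * x$dt

#' @export
duration.track_ensemble <- function(x)
  vapply(x$trajectories, duration.trajectory, numeric(1))

#' Construct a trajectory ensemble
#'
#' @param trajectories list of \code{trajectory} objects sharing \code{dt}.
#' @param label free-text tag (cell line, simulation tag, ...).
#' @return an object of class \code{"track_ensemble"} with fields
#'   \code{trajectories}, \code{dt}, \code{label}.
#' @export
track_ensemble <- function(trajectories, label = "") {
  if (!length(trajectories)) stop("ensemble must contain at least one trajectory")
  ok <- vapply(trajectories, inherits, logical(1), what = "trajectory")
  if (!all(ok)) stop("all elements must be trajectory objects")
  dts <- vapply(trajectories, `[[`, numeric(1), "dt")
  dt <- stats::median(dts)
  if (any(abs(dts - dt) > 1e-6 * dt))
    stop("trajectories do not share a common sampling interval")
  structure(list(trajectories = trajectories, dt = dt, label = label),
            class = "track_ensemble")
}

#' @export
print.track_ensemble <- function(x, ...) {
  Ts <- duration(x)
  cat(sprintf("<track_ensemble%s: %d trajectories, dt = %g s, T in [%g, %g] s>\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              length(x$trajectories), x$dt, min(Ts), max(Ts)))
  invisible(x)
}

#' @export
length.track_ensemble <- function(x) length(x$trajectories)

#' @export
as.data.frame.track_ensemble <- function(x, ...) {
  do.call(rbind, lapply(x$trajectories, function(tr) {
    n <- length(tr$x)
    data.frame(track_id = tr$id, frame = 0:(n - 1L),
               t_s = tr$t0 + (0:(n - 1L)) * tr$dt,
               x_um = tr$x, y_um = tr$y,
               stringsAsFactors = FALSE)
  }))
}

#' Read a track table
#'
#' Reads the canonical comma-separated track table with header
#' \code{track_id,frame,t_s,x_um,y_um} (one row per localization). The
#' sampling interval is inferred as the median inter-frame time and timestamp
#' uniformity is validated per track (relative tolerance 1e-6). Tracks with
#' fewer than 2 points are dropped with a warning.
#'
#' @param path path to a CSV file.
#' @param format input format; only \code{"csv"} is supported.
#' @return a \code{\link{track_ensemble}}.
#' @seealso \code{\link{write_tracks}}
#' @export
read_tracks <- function(path, format = "csv") {
  format <- match.arg(format, "csv")
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("track_id", "frame", "t_s", "x_um", "y_um")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("track table is missing required column(s): ",
         paste(miss, collapse = ", "))
  df <- df[order(df$track_id, df$frame), , drop = FALSE]

  # infer dt from the pooled inter-frame times
  dts <- unlist(lapply(split(df$t_s, df$track_id), function(t)
    if (length(t) > 1L) diff(t) else numeric(0)), use.names = FALSE)
  if (!length(dts)) stop("no track has 2 or more points")
  dt <- stats::median(dts)
  if (dt <= 0) stop("inferred sampling interval is not positive")

  trs <- list(); dropped <- 0L
  for (id in unique(df$track_id)) {
    g <- df[df$track_id == id, , drop = FALSE]
    if (nrow(g) < 2L) { dropped <- dropped + 1L; next }
    k <- seq_len(nrow(g)) - 1L
    expect <- g$t_s[1L] + k * dt
    if (any(abs(g$t_s - expect) > 1e-6 * max(dt, abs(expect))))
      stop("track '", id, "' has non-uniform timestamps (tolerance 1e-6)")
    trs[[length(trs) + 1L]] <-
      trajectory(g$x_um, g$y_um, dt = dt, id = id, t0 = g$t_s[1L])
  }
  if (dropped > 0L)
    warning(dropped, " track(s) with fewer than 2 points dropped")
  if (!length(trs)) stop("no usable tracks in ", path)
  track_ensemble(trs, label = basename(path))
}

#' Write a track table
#'
#' Writes the canonical column order \code{track_id,frame,t_s,x_um,y_um},
#' rows grouped by track with frames ascending.
#'
#' @param ensemble a non-empty \code{\link{track_ensemble}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_tracks <- function(ensemble, path) {
  if (!inherits(ensemble, "track_ensemble")) stop("not a track_ensemble")
  if (!length(ensemble$trajectories)) stop("ensemble is empty")
  df <- as.data.frame(ensemble)
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write track table to ", path)
  invisible(path)
}

#' Keep trajectories at least \code{T_min} seconds long
#'
#' Returns the sub-ensemble \code{\{i : T_i >= T_min\}}; the input is left
#' untouched. An empty result is allowed (with a message) so that callers can
#' scan thresholds.
#'
#' @param ensemble a \code{\link{track_ensemble}}.
#' @param T_min minimum duration in seconds.
#' @return a \code{track_ensemble} (possibly with zero trajectories).
#' @export
filter_min_duration <- function(ensemble, T_min) {
  stopifnot_scalar(T_min, "T_min")
  if (T_min < 0) stop("T_min must be >= 0")
  if (T_min == 0) return(ensemble)
  keep <- duration(ensemble) >= T_min - 1e-9
  if (!any(keep)) {
    message("filter_min_duration: no trajectory of duration >= ", T_min, " s")
    out <- ensemble
    out$trajectories <- list()
    if (!is.null(out$weights)) out$weights <- numeric(0)
    return(out)
  }
  out <- ensemble
  out$trajectories <- ensemble$trajectories[keep]
  if (!is.null(out$weights)) out$weights <- out$weights[keep]
  out
}

#' Survival counts N(t)
#'
#' Number of trajectories still present at each requested lag,
#' \code{N(t) = #\{i : T_i >= t\}}. This is the per-lag denominator of the
#' censoring-aware ensemble MSD.
#'
#' @param ensemble a \code{\link{track_ensemble}}.
#' @param lags non-negative multiples of \code{dt}, in seconds.
#' @return integer vector of counts, non-increasing in \code{lags}.
#' @export
survival_counts <- function(ensemble, lags) {
  m <- steps_of(lags, ensemble$dt)
  Ts <- duration(ensemble)
  vapply(m, function(mm) sum(Ts >= mm * ensemble$dt - 1e-9), integer(1))
}
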