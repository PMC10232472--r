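# Mean squared displacement estimators.
#
# Three estimators are distinguished throughout:
#   eMSD   - ensemble average of squared displacements from the (possibly
#            aged) origin, averaging at lag t over exactly the trajectories
#            still alive at t_a + t. This censoring-aware denominator N(t)
#            is what couples random durations to the apparent MSD exponent.
#   tMSD   - time average along one trajectory over all overlapping start
#            frames (the standard sliding-window estimator).
#   e-tMSD - unweighted ensemble mean of per-trajectory tMSDs.
# Ageing variants discard t_a seconds from the start of every trajectory,
# so the usable duration becomes T' = T - t_a.

new_msd_curve <- function(lag, value, count, kind, t_a = 0, T_min = 0,
                          source_label = "", min_count = 10L) {
  df <- data.frame(lag_s = lag, msd_um2 = value, count = as.integer(count),
                   low_count = as.integer(count) < min_count)
  structure(df, class = c("msd_curve", "data.frame"),
            kind = kind, t_a = t_a, T_min = T_min, source_label = source_label)
}

#' @export
print.msd_curve <- function(x, ...) {
  cat(sprintf("<%s curve: %d lags up to %g s, t_a = %g s, T_min = %g s>\n",
              attr(x, "kind"), nrow(x) - 1L, max(x$lag_s),
              attr(x, "t_a"), attr(x, "T_min")))
  print.data.frame(utils::head(as.data.frame(x), 8L), row.names = FALSE)
  if (nrow(x) > 8L) cat("  ...\n")
  invisible(x)
}

#' Export an MSD curve as a tidy table
#'
#' @param curve an \code{msd_curve} (or a list of them).
#' @return a data.frame with columns
#'   \code{kind,t_a_s,T_min_s,lag_s,msd_um2,count}.
#' @export
msd_table <- function(curve) {
  if (inherits(curve, "msd_curve")) curve <- list(curve)
  do.call(rbind, lapply(curve, function(cv)
    data.frame(kind = attr(cv, "kind"), t_a_s = attr(cv, "t_a"),
               T_min_s = attr(cv, "T_min"), lag_s = cv$lag_s,
               msd_um2 = cv$msd_um2, count = cv$count,
               stringsAsFactors = FALSE)))
}

# Per-trajectory time-averaged MSD over start frames a..(n-1-m); returns
# values and start-frame counts for lags 1..m_max (in frames).
.tmsd_vec <- function(x, y, a, m_max) {
  n <- length(x)
  L <- n - a
  m_max <- min(m_max, L - 1L)
  xs <- x[(a + 1L):n]; ys <- y[(a + 1L):n]
  vals <- numeric(m_max); cnt <- integer(m_max)
  for (m in seq_len(m_max)) {
    dx <- xs[(1L + m):L] - xs[1:(L - m)]
    dy <- ys[(1L + m):L] - ys[1:(L - m)]
    vals[m] <- sum(dx * dx + dy * dy) / (L - m)
    cnt[m] <- L - m
  }
  list(values = vals, counts = cnt)
}

#' Time-averaged MSD of a single trajectory
#'
#' Sliding-window time average of squared 2D displacements. With an ageing
#' time \code{t_a > 0} the first \code{t_a} seconds are discarded and the
#' average runs over start frames in \code{[t_a, t_a + T' - t]} with
#' \code{T' = T - t_a}.
#'
#' @param traj a \code{\link{trajectory}}.
#' @param t_a ageing time in seconds (multiple of \code{dt}).
#' @param max_lag largest lag to evaluate, in seconds (default: all lags).
#' @return an \code{msd_curve} of kind \code{"tMSD"}; counts are the number
#'   of start frames per lag.
#' @export
tmsd <- function(traj, t_a = 0, max_lag = NULL) {
  if (!inherits(traj, "trajectory")) stop("not a trajectory")
  dt <- traj$dt
  a <- steps_of(t_a, dt, "t_a")
  n <- length(traj$x)
  if (n - 1L - a < 2L)
    stop("trajectory '", traj$id, "' fully aged away (T - t_a < 2*dt)")
  m_max <- n - 1L - a
  if (!is.null(max_lag)) m_max <- min(m_max, steps_of(max_lag, dt, "max_lag"))
  tv <- .tmsd_vec(traj$x, traj$y, a, m_max)
  new_msd_curve(lag = c(0, seq_len(m_max) * dt),
                value = c(0, tv$values),
                count = c(n - a, tv$counts),
                kind = "tMSD", t_a = t_a, source_label = traj$id)
}

#' Ensemble-averaged MSD
#'
#' Averages squared displacements from the (aged) origin over exactly the
#' trajectories alive at each lag: at lag \code{t} only trajectories with
#' \code{T_i >= t_a + t} contribute, and the per-lag count equals the
#' survival count \code{N(t_a + t)}. No imputation is performed; this
#' censoring is the mechanism by which duration-dependent diffusivities bend
#' the pooled MSD downwards at long lags.
#'
#' @param ensemble a \code{\link{track_ensemble}}.
#' @param t_a ageing time in seconds (multiple of \code{dt}).
#' @param T_min duration condition: only trajectories with \code{T >= T_min}
#'   enter (the conditional eMSD of duration-resolved analyses).
#' @param max_lag largest lag in seconds (default: longest available).
#' @return an \code{msd_curve} of kind \code{"eMSD"}.
#' @export
emsd <- function(ensemble, t_a = 0, T_min = 0, max_lag = NULL) {
  if (!inherits(ensemble, "track_ensemble")) stop("not a track_ensemble")
  dt <- ensemble$dt
  a <- steps_of(t_a, dt, "t_a")
  ens <- filter_min_duration(ensemble, T_min)
  ns <- vapply(ens$trajectories, function(tr) length(tr$x), integer(1))
  alive <- ns - 1L >= a + 1L
  if (!any(alive))
    stop("no trajectory survives the ageing time t_a = ", t_a, " s")
  M <- max(ns[alive]) - 1L - a
  if (!is.null(max_lag)) M <- min(M, steps_of(max_lag, dt, "max_lag"))
  sums <- numeric(M); cnts <- integer(M)
  for (tr in ens$trajectories[alive]) {
    m <- min(length(tr$x) - 1L - a, M)
    if (m < 1L) next
    i0 <- a + 1L
    dx <- tr$x[(i0 + 1L):(i0 + m)] - tr$x[i0]
    dy <- tr$y[(i0 + 1L):(i0 + m)] - tr$y[i0]
    sums[1:m] <- sums[1:m] + dx * dx + dy * dy
    cnts[1:m] <- cnts[1:m] + 1L
  }
  keep <- cnts > 0L
  new_msd_curve(lag = c(0, (seq_len(M) * dt)[keep]),
                value = c(0, (sums[keep] / cnts[keep])),
                count = c(sum(alive), cnts[keep]),
                kind = "eMSD", t_a = t_a, T_min = T_min,
                source_label = ens$label)
}

#' Ensemble-time-averaged MSD
#'
#' Unweighted mean over trajectories of the per-trajectory time-averaged MSD;
#' at each lag only trajectories whose tMSD is defined there contribute.
#' Equal per-trajectory weights (rather than weighting by the number of
#' increments) keep this the plain ensemble mean of tMSDs.
#'
#' @inheritParams emsd
#' @return an \code{msd_curve} of kind \code{"e-tMSD"}; counts are the number
#'   of trajectories contributing per lag.
#' @export
etmsd <- function(ensemble, t_a = 0, T_min = 0, max_lag = NULL) {
  if (!inherits(ensemble, "track_ensemble")) stop("not a track_ensemble")
  dt <- ensemble$dt
  a <- steps_of(t_a, dt, "t_a")
  ens <- filter_min_duration(ensemble, T_min)
  ns <- vapply(ens$trajectories, function(tr) length(tr$x), integer(1))
  usable <- ns - 1L - a >= 2L
  if (!any(usable))
    stop("no trajectory survives the ageing time t_a = ", t_a, " s")
  M <- max(ns[usable]) - 1L - a
  if (!is.null(max_lag)) M <- min(M, steps_of(max_lag, dt, "max_lag"))
  sums <- numeric(M); cnts <- integer(M)
  for (tr in ens$trajectories[usable]) {
    m <- min(length(tr$x) - 1L - a, M)
    if (m < 1L) next
    tv <- .tmsd_vec(tr$x, tr$y, a, m)
    sums[1:m] <- sums[1:m] + tv$values
    cnts[1:m] <- cnts[1:m] + 1L
  }
  keep <- cnts > 0L
  new_msd_curve(lag = c(0, (seq_len(M) * dt)[keep]),
                value = c(0, (sums[keep] / cnts[keep])),
                count = c(sum(usable), cnts[keep]),
                kind = "e-tMSD", t_a = t_a, T_min = T_min,
                source_label = ens$label)
}
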