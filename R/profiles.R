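# Duration-resolved summaries: conditional diffusion coefficients D_alpha(t|T)
# across minimum-duration thresholds, the decay of the time-averaged MSD with
# trajectory duration, and the ageing sweep over delayed-start times.

new_duration_profile <- function(table, fit, kind) {
  structure(list(table = table, fit = fit, kind = kind),
            class = "duration_profile")
}

#' @export
print.duration_profile <- function(x, ...) {
  cat(sprintf("<duration_profile (%s): %d entries>\n", x$kind, nrow(x$table)))
  print.data.frame(x$table, row.names = FALSE, digits = 4)
  if (!is.null(x$fit$gamma))
    cat(sprintf("  power-law profile: D ~ T^-gamma, gamma = %.3f\n",
                x$fit$gamma))
  if (!is.null(x$fit$b))
    cat(sprintf("  exponential profile: a*exp(-b*T), a = %.4g, b = %.4g /s\n",
                x$fit$a, x$fit$b))
  invisible(x)
}

#' Conditional diffusion coefficients across duration thresholds
#'
#' For each threshold \code{T} the conditional ensemble MSD (over trajectories
#' with duration at least \code{T}) is fitted by a power law on \code{window},
#' giving the conditional generalized diffusion coefficient
#' \code{D_alpha(t|T)}; the profile of \code{D_alpha} against \code{T} is then
#' itself fitted by a power law \code{D ~ T^-gamma} in log-log coordinates.
#'
#' @param ensemble a \code{\link{track_ensemble}}.
#' @param thresholds ascending minimum durations in seconds.
#' @param window power-law fit window \code{c(t_lo, t_hi)} in seconds.
#' @param min_traj minimum number of trajectories for a threshold to be kept
#'   (dropped entries produce a warning).
#' @param with_offset passed to \code{\link{fit_power_law}}.
#' @return a \code{duration_profile}; \code{$table} has one row per kept
#'   threshold (T, alpha, D_alpha, n), \code{$fit} holds \code{gamma} and the
#'   prefactor of the profile power law.
#' @export
conditional_diffusion_profile <- function(ensemble, thresholds, window,
                                          min_traj = 50L, with_offset = FALSE) {
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be strictly ascending")
  rows <- list()
  for (tau in thresholds) {
    sub <- filter_min_duration(ensemble, tau)
    n <- length(sub$trajectories)
    if (n < min_traj) {
      warning(sprintf(
        "threshold T >= %g s dropped: %d trajectories < min_traj = %d",
        tau, n, min_traj))
      next
    }
    cur <- emsd(sub, t_a = 0, T_min = 0, max_lag = window[2])
    fit <- fit_power_law(cur, window, with_offset = with_offset)
    rows[[length(rows) + 1L]] <-
      data.frame(T_s = tau, alpha = fit$alpha, D_alpha = fit$D_alpha, n = n)
  }
  if (!length(rows)) stop("no threshold retained enough trajectories")
  tab <- do.call(rbind, rows)
  fit <- list(gamma = NA_real_, prefactor = NA_real_)
  pos <- tab$T_s > 0
  if (sum(pos) >= 3L) {
    lf <- stats::lm(log10(D_alpha) ~ log10(T_s), data = tab[pos, ])
    fit$gamma <- -unname(stats::coef(lf)[2L])
    fit$prefactor <- 10^unname(stats::coef(lf)[1L])
    fit$rmse_log <- sqrt(mean(stats::resid(lf)^2))
  }
  new_duration_profile(tab, fit, "conditional_emsd")
}

# Log-spaced duration bin edges covering [lo, hi].
.log_bins <- function(lo, hi, n_bins) exp(seq(log(lo), log(hi),
                                              length.out = n_bins + 1L))

#' Time-averaged MSD at a fixed lag as a function of trajectory duration
#'
#' Groups trajectories into duration bins (logarithmic by default, as the
#' heavy-tailed duration distribution makes linear bins sparse), averages the
#' per-trajectory tMSD at the requested lag within each bin, and fits the
#' exponential decay \code{a * exp(-b * T)} over bin centres by nonlinear
#' least squares. With \code{mode = "min_duration"} the grouping is cumulative
#' (all trajectories with \code{T >=} threshold) instead of binned.
#'
#' @param ensemble a \code{\link{track_ensemble}}.
#' @param lag evaluation lag in seconds (multiple of \code{dt}).
#' @param n_bins number of logarithmic duration bins.
#' @param range duration range \code{c(lo, hi)} to bin (default: observed).
#' @param thresholds thresholds for \code{mode = "min_duration"} (defaults to
#'   the bin edges).
#' @param mode \code{"binned"} (default) or \code{"min_duration"}.
#' @param min_traj minimum trajectories per kept bin.
#' @param n_boot bootstrap resamples for the (a, b) confidence intervals.
#' @param seed bootstrap seed.
#' @return a \code{duration_profile}; \code{$table} has per-bin mean tMSD,
#'   \code{$fit} holds \code{a} (um^2), \code{b} (1/s) and their 95\% CIs.
#' @export
etmsd_vs_duration <- function(ensemble, lag, n_bins = 12L, range = NULL,
                              thresholds = NULL,
                              mode = c("binned", "min_duration"),
                              min_traj = 50L, n_boot = 200L, seed = NULL) {
  mode <- match.arg(mode)
  dt <- ensemble$dt
  m <- steps_of(lag, dt, "lag")
  if (m < 1L) stop("lag must be at least dt")
  Ts <- duration(ensemble)
  usable <- Ts >= (m + 1L) * dt - 1e-9  # tMSD needs one start frame at lag
  if (!any(usable)) stop("no trajectory long enough for lag = ", lag, " s")
  trs <- ensemble$trajectories[usable]
  Tu <- Ts[usable]
  tm <- vapply(trs, function(tr) .tmsd_vec(tr$x, tr$y, 0L, m)$values[m],
               numeric(1))

  if (mode == "binned") {
    if (is.null(range)) range <- c(min(Tu), max(Tu) + 1e-9)
    edges <- .log_bins(range[1], range[2], n_bins)
    grp <- findInterval(Tu, edges, rightmost.closed = TRUE)
    ok_grp <- grp >= 1L & grp <= n_bins
    rows <- lapply(seq_len(n_bins), function(g) {
      in_g <- ok_grp & grp == g
      if (sum(in_g) < min_traj) return(NULL)
      data.frame(T_s = mean(Tu[in_g]), etmsd_um2 = mean(tm[in_g]),
                 n = sum(in_g))
    })
    grp_id <- grp
  } else {
    if (is.null(thresholds))
      thresholds <- .log_bins(min(Tu), max(Tu), n_bins)[seq_len(n_bins)]
    rows <- lapply(thresholds, function(tau) {
      in_g <- Tu >= tau - 1e-9
      if (sum(in_g) < min_traj) return(NULL)
      data.frame(T_s = tau, etmsd_um2 = mean(tm[in_g]), n = sum(in_g))
    })
    grp_id <- NULL
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) < 3L)
    stop("fewer than 3 duration bins with at least ", min_traj,
         " trajectories")
  tab <- do.call(rbind, rows)

  exp_fit <- function(Tc, v) {
    b0 <- if (v[1] > v[length(v)] && v[length(v)] > 0)
      log(v[1] / v[length(v)]) / (Tc[length(Tc)] - Tc[1]) else 0.01
    fit <- minpack.lm::nlsLM(v ~ a * exp(-b * Tc),
                             start = list(a = max(v), b = max(b0, 1e-4)),
                             control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- stats::coef(fit)
    list(a = cf[["a"]], b = cf[["b"]],
         rss = sum(stats::resid(fit)^2))
  }
  fit <- exp_fit(tab$T_s, tab$etmsd_um2)

  a_ci <- b_ci <- c(NA_real_, NA_real_)
  if (n_boot > 0L && mode == "binned") {
    ab <- with_seed(seed, {
      out <- matrix(NA_real_, n_boot, 2L)
      for (bb in seq_len(n_boot)) {
        idx <- sample.int(length(tm), replace = TRUE)
        mt <- tapply(tm[idx], grp_id[idx], mean)
        ct <- tapply(Tu[idx], grp_id[idx], mean)
        nn <- tapply(idx, grp_id[idx], length)
        keep <- nn >= min_traj
        if (sum(keep) < 3L) next
        fb <- tryCatch(exp_fit(as.numeric(ct[keep]), as.numeric(mt[keep])),
                       error = function(e) NULL)
        if (!is.null(fb)) out[bb, ] <- c(fb$a, fb$b)
      }
      out
    })
    a_ci <- unname(stats::quantile(ab[, 1], c(0.025, 0.975), na.rm = TRUE))
    b_ci <- unname(stats::quantile(ab[, 2], c(0.025, 0.975), na.rm = TRUE))
  }

  new_duration_profile(
    tab,
    list(a = fit$a, b = fit$b, a_ci = a_ci, b_ci = b_ci, rss = fit$rss,
         lag = lag, n_boot = n_boot, seed = seed),
    paste0("etmsd_vs_duration_", mode))
}

#' Ageing sweep of ensemble MSDs
#'
#' Recomputes the ensemble and ensemble-time-averaged MSDs for each ageing
#' time (discarding \code{t_a} seconds from every trajectory, so usable
#' durations shrink to \code{T' = T - t_a}), fits the eMSD power law on
#' \code{window}, and flags statistical ageing when the fitted amplitude at
#' the window mid-point decreases monotonically in \code{t_a} with the first
#' and last bootstrap intervals disjoint.
#'
#' @param ensemble a \code{\link{track_ensemble}}.
#' @param t_a_list ageing times in seconds (multiples of \code{dt}).
#' @param window eMSD power-law fit window \code{c(t_lo, t_hi)} in seconds.
#' @param n_boot bootstrap resamples per ageing time.
#' @param seed bootstrap seed.
#' @param with_offset passed to \code{\link{fit_power_law}}.
#' @return a list of class \code{"ageing_sweep"}: \code{$entries} (one element
#'   per ageing time with the two curves and the fit), \code{$amplitudes},
#'   \code{$ages} (logical).
#' @export
ageing_sweep <- function(ensemble, t_a_list, window, n_boot = 100L,
                         seed = NULL, with_offset = FALSE) {
  Ts <- duration(ensemble)
  if (max(Ts) <= max(t_a_list))
    stop("all trajectories are shorter than the largest ageing time")
  entries <- list()
  for (k in seq_along(t_a_list)) {
    ta <- t_a_list[k]
    ec <- emsd(ensemble, t_a = ta, max_lag = window[2])
    tc <- etmsd(ensemble, t_a = ta, max_lag = window[2])
    fit <- fit_power_law(ec, window, with_offset = with_offset,
                         ensemble = ensemble, n_boot = n_boot,
                         seed = if (is.null(seed)) NULL else seed + k)
    entries[[k]] <- list(t_a = ta, emsd = ec, etmsd = tc, fit = fit)
  }
  amps <- vapply(entries, function(e) e$fit$amp_mid, numeric(1))
  lo <- vapply(entries, function(e) e$fit$amp_ci[1], numeric(1))
  hi <- vapply(entries, function(e) e$fit$amp_ci[2], numeric(1))
  monotone <- all(diff(amps) < 0)
  separated <- is.finite(hi[length(hi)]) && is.finite(lo[1]) &&
    hi[length(hi)] < lo[1]
  structure(list(entries = entries,
                 amplitudes = data.frame(t_a_s = t_a_list, amp_um2 = amps,
                                         amp_lo = lo, amp_hi = hi),
                 ages = monotone && separated, window = window),
            class = "ageing_sweep")
}

#' @export
print.ageing_sweep <- function(x, ...) {
  cat(sprintf("<ageing_sweep over t_a = {%s} s, window %g-%g s: ages = %s>\n",
              paste(x$amplitudes$t_a_s, collapse = ", "),
              x$window[1], x$window[2], x$ages))
  print.data.frame(x$amplitudes, row.names = FALSE, digits = 4)
  invisible(x)
}
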