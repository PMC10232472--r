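# Power-law fitting of MSD curves, MSD(t) = 4 * D_alpha * t^alpha, optionally
# with an additive offset c >= 0 that absorbs static localization error and
# other quasi-constant short-time contributions. Confidence intervals come
# from a seeded bootstrap over trajectories (resample, recompute the curve,
# refit), which respects the strong between-trajectory correlation of MSD
# points that a per-lag bootstrap would ignore.

# Per-trajectory contribution matrix at the given lag steps: squared
# displacement from the aged origin (eMSD) or per-trajectory tMSD value
# (e-tMSD); NA where the trajectory does not reach the lag. Column means
# (na.rm) reproduce the corresponding curve exactly, so bootstrap resampling
# reduces to row resampling.
per_traj_msd_matrix <- function(ensemble, kind, t_a, T_min, lag_steps) {
  dt <- ensemble$dt
  a <- steps_of(t_a, dt, "t_a")
  ens <- filter_min_duration(ensemble, T_min)
  trs <- ens$trajectories
  M <- matrix(NA_real_, length(trs), length(lag_steps))
  for (i in seq_along(trs)) {
    tr <- trs[[i]]
    n <- length(tr$x)
    avail <- n - 1L - a
    if (kind == "eMSD") {
      ok <- lag_steps <= avail
      if (any(ok)) {
        i0 <- a + 1L
        dx <- tr$x[i0 + lag_steps[ok]] - tr$x[i0]
        dy <- tr$y[i0 + lag_steps[ok]] - tr$y[i0]
        M[i, ok] <- dx * dx + dy * dy
      }
    } else {
      if (avail >= 2L) {
        mm <- min(max(lag_steps), avail)
        tv <- .tmsd_vec(tr$x, tr$y, a, mm)
        ok <- lag_steps <= mm
        M[i, ok] <- tv$values[lag_steps[ok]]
      }
    }
  }
  M
}

.loglog_fit <- function(lag, value) {
  fit <- stats::lm(log10(value) ~ log10(lag))
  cf <- stats::coef(fit)
  list(alpha = unname(cf[2L]), D_alpha = 10^unname(cf[1L]) / 4,
       rmse_log = sqrt(mean(stats::resid(fit)^2)))
}

.offset_fit <- function(lag, value) {
  st <- .loglog_fit(lag, value)
  fit <- minpack.lm::nlsLM(
    value ~ 4 * D * lag^alpha + c0,
    start = list(D = max(st$D_alpha, 1e-8), alpha = st$alpha,
                 c0 = max(min(value) / 2, 1e-9)),
    lower = c(D = 1e-12, alpha = -2, c0 = 0),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  pred <- 4 * cf[["D"]] * lag^cf[["alpha"]] + cf[["c0"]]
  list(alpha = cf[["alpha"]], D_alpha = cf[["D"]], offset = cf[["c0"]],
       rmse_log = sqrt(mean((log10(pmax(pred, 1e-300)) - log10(value))^2)))
}

#' Fit a power law to an MSD curve
#'
#' Without an offset the fit is a least-squares line in log-log coordinates;
#' with \code{with_offset = TRUE} it is a nonlinear least-squares fit of
#' \code{4 * D * t^alpha + c} with \code{c >= 0}. If the generating ensemble
#' is supplied, 95\% confidence intervals for \code{alpha}, \code{D_alpha}
#' and the fitted amplitude at the window mid-point are obtained by a seeded
#' bootstrap over trajectories.
#'
#' @param curve an \code{msd_curve} from \code{\link{emsd}},
#'   \code{\link{etmsd}} or \code{\link{tmsd}}.
#' @param window fit window \code{c(t_lo, t_hi)} in seconds; at least 4 lag
#'   points with sufficient counts must fall inside.
#' @param with_offset fit an additive non-negative offset (default FALSE).
#' @param ensemble optional \code{\link{track_ensemble}} the curve was
#'   computed from, enabling bootstrap confidence intervals.
#' @param n_boot number of bootstrap resamples (default 200).
#' @param seed seed for the bootstrap.
#' @param min_count minimum per-lag count for a point to enter the fit.
#' @return an object of class \code{"power_law_fit"} with elements
#'   \code{alpha}, \code{D_alpha}, \code{offset} (NA unless fitted),
#'   \code{window}, \code{alpha_ci}, \code{D_ci}, \code{amp_mid},
#'   \code{amp_ci}, \code{rmse_log}, \code{n_points}.
#' @export
fit_power_law <- function(curve, window, with_offset = FALSE, ensemble = NULL,
                          n_boot = 200L, seed = NULL, min_count = 10L) {
  if (!inherits(curve, "msd_curve")) stop("not an msd_curve")
  if (length(window) != 2L || window[1] >= window[2])
    stop("window must be c(t_lo, t_hi) with t_lo < t_hi")
  sel <- curve$lag_s >= window[1] - 1e-9 & curve$lag_s <= window[2] + 1e-9 &
    curve$lag_s > 0 & curve$count >= min_count & is.finite(curve$msd_um2)
  if (sum(sel) < 4L)
    stop("fewer than 4 usable lag points in the fit window [",
         window[1], ", ", window[2], "] s")
  lag <- curve$lag_s[sel]; val <- curve$msd_um2[sel]
  if (!with_offset && any(val <= 0))
    stop("non-positive MSD values in window; log-log fit undefined")

  base <- if (with_offset) .offset_fit(lag, val) else .loglog_fit(lag, val)

  alpha_ci <- D_ci <- amp_ci <- c(NA_real_, NA_real_)
  t_mid <- window_mid(window)
  amp_mid <- 4 * base$D_alpha * t_mid^base$alpha + (base$offset %||% 0)
  boot <- NULL
  if (!is.null(ensemble) && n_boot > 0L &&
      attr(curve, "kind") %in% c("eMSD", "e-tMSD")) {
    dt <- ensemble$dt
    steps <- steps_of(lag, dt)
    M <- per_traj_msd_matrix(ensemble, attr(curve, "kind"),
                             attr(curve, "t_a"), attr(curve, "T_min"), steps)
    boot <- with_seed(seed, {
      out <- matrix(NA_real_, n_boot, 3L,
                    dimnames = list(NULL, c("alpha", "D_alpha", "amp_mid")))
      for (b in seq_len(n_boot)) {
        idx <- sample.int(nrow(M), replace = TRUE)
        v <- colMeans(M[idx, , drop = FALSE], na.rm = TRUE)
        cnt <- colSums(!is.na(M[idx, , drop = FALSE]))
        ok <- cnt >= min_count & is.finite(v) & (with_offset | v > 0)
        if (sum(ok) < 4L) next
        fb <- tryCatch(
          if (with_offset) .offset_fit(lag[ok], v[ok])
          else .loglog_fit(lag[ok], v[ok]),
          error = function(e) NULL)
        if (is.null(fb)) next
        out[b, ] <- c(fb$alpha, fb$D_alpha,
                      4 * fb$D_alpha * t_mid^fb$alpha + (fb$offset %||% 0))
      }
      out
    })
    q <- function(j) unname(stats::quantile(boot[, j], c(0.025, 0.975),
                                            na.rm = TRUE))
    alpha_ci <- q("alpha"); D_ci <- q("D_alpha"); amp_ci <- q("amp_mid")
  }

  structure(list(alpha = base$alpha, D_alpha = base$D_alpha,
                 offset = base$offset %||% NA_real_, window = window,
                 alpha_ci = alpha_ci, D_ci = D_ci,
                 amp_mid = amp_mid, amp_ci = amp_ci,
                 rmse_log = base$rmse_log, n_points = length(lag),
                 n_boot = if (is.null(boot)) 0L else n_boot, seed = seed,
                 kind = attr(curve, "kind"), t_a = attr(curve, "t_a"),
                 T_min = attr(curve, "T_min")),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit (%s, window %g-%g s): alpha = %.3f", x$kind,
              x$window[1], x$window[2], x$alpha))
  if (is.finite(x$alpha_ci[1]))
    cat(sprintf(" [%.3f, %.3f]", x$alpha_ci[1], x$alpha_ci[2]))
  cat(sprintf(", D_alpha = %.4g um^2/s^alpha", x$D_alpha))
  if (is.finite(x$offset)) cat(sprintf(", offset = %.4g um^2", x$offset))
  cat(">\n")
  invisible(x)
}
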