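# Ergodicity diagnostics: tMSD amplitude scatter and the ergodicity-breaking
# parameter EB(t,T) = <zeta^2> - 1 with zeta_i = tMSD_i(t) / e-tMSD(t);
# maximum-likelihood fitting of the generalized-Gamma scatter distribution
# PDF(zeta) ~ zeta^(nu-1) * exp(-a/zeta - zeta/b); and the single-trajectory
# dynamical-functional estimators E (ergodicity) and F (mixing).

#' Amplitude scatter of time-averaged MSDs
#'
#' Computes \code{zeta_i = tMSD_i(lag) / mean_j tMSD_j(lag)} over the
#' trajectories with duration at least \code{max(T_min, lag + dt)}, and the
#' ergodicity-breaking parameter \code{EB = <zeta^2> - 1}. The normalizer is
#' the mean of exactly the tMSD set being scattered, which makes
#' \code{mean(zeta) == 1} and \code{EB == var(zeta)} exact identities.
#'
#' @param ensemble a \code{\link{track_ensemble}}.
#' @param lag evaluation lag in seconds (multiple of \code{dt}).
#' @param T_min duration condition in seconds.
#' @return an object of class \code{"amplitude_scatter"}: \code{lag},
#'   \code{zeta} (per-trajectory values), \code{eb}, \code{n}.
#' @export
amplitude_scatter <- function(ensemble, lag, T_min = 0) {
  dt <- ensemble$dt
  m <- steps_of(lag, dt, "lag")
  if (m < 1L) stop("lag must be at least dt")
  Ts <- duration(ensemble)
  keep <- Ts >= max(T_min, (m + 1L) * dt) - 1e-9
  if (sum(keep) < 2L)
    stop("need at least 2 trajectories of duration >= ",
         max(T_min, (m + 1L) * dt), " s")
  tm <- vapply(ensemble$trajectories[keep],
               function(tr) .tmsd_vec(tr$x, tr$y, 0L, m)$values[m], numeric(1))
  norm <- mean(tm)
  if (norm <= 0) stop("all tracks immobile at lag ", lag, " s: zero normalizer")
  zeta <- tm / norm
  structure(list(lag = lag, zeta = zeta, eb = mean(zeta^2) - 1,
                 n = length(zeta)),
            class = "amplitude_scatter")
}

#' @export
print.amplitude_scatter <- function(x, ...) {
  cat(sprintf("<amplitude_scatter at lag %g s: n = %d, EB = %.4g>\n",
              x$lag, x$n, x$eb))
  invisible(x)
}

#' Ergodicity-breaking parameter against trajectory duration
#'
#' Two protocols: \code{mode = "binned"} groups trajectories into logarithmic
#' duration bins and computes EB within each bin; \code{mode = "min_duration"}
#' recomputes EB over the cumulative subsets \code{\{T_i >= T\}} (discarding
#' shorter trajectories). Both candidate decay forms are fitted and reported
#' with residuals: the plateau form \code{c0 + c1/T} and the exponential
#' \code{A * exp(-k * T)}.
#'
#' @inheritParams etmsd_vs_duration
#' @param mode \code{"binned"} or \code{"min_duration"}.
#' @return a list of class \code{"eb_profile"}: \code{$table} with columns
#'   \code{T_s, eb, n}, and \code{$fits} with both fitted forms and their
#'   residual sums of squares.
#' @export
eb_vs_duration <- function(ensemble, lag, mode = c("binned", "min_duration"),
                           n_bins = 8L, range = NULL, thresholds = NULL,
                           min_traj = 50L) {
  mode <- match.arg(mode)
  dt <- ensemble$dt
  m <- steps_of(lag, dt, "lag")
  Ts <- duration(ensemble)
  usable <- Ts >= (m + 1L) * dt - 1e-9
  trs <- ensemble$trajectories[usable]
  Tu <- Ts[usable]
  tm <- vapply(trs, function(tr) .tmsd_vec(tr$x, tr$y, 0L, m)$values[m],
               numeric(1))
  eb_of <- function(v) {
    z <- v / mean(v)
    mean(z^2) - 1
  }
  if (mode == "binned") {
    if (is.null(range)) range <- c(min(Tu), max(Tu) + 1e-9)
    edges <- .log_bins(range[1], range[2], n_bins)
    grp <- findInterval(Tu, edges, rightmost.closed = TRUE)
    rows <- lapply(seq_len(n_bins), function(g) {
      in_g <- grp == g
      if (sum(in_g) < min_traj) return(NULL)
      data.frame(T_s = mean(Tu[in_g]), eb = eb_of(tm[in_g]), n = sum(in_g))
    })
  } else {
    if (is.null(thresholds))
      thresholds <- .log_bins(min(Tu), max(Tu), n_bins)[seq_len(n_bins)]
    rows <- lapply(thresholds, function(tau) {
      in_g <- Tu >= tau - 1e-9
      if (sum(in_g) < min_traj) return(NULL)
      data.frame(T_s = tau, eb = eb_of(tm[in_g]), n = sum(in_g))
    })
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) < 3L) stop("fewer than 3 usable duration groups")
  tab <- do.call(rbind, rows)

  plateau <- stats::lm(eb ~ I(1 / T_s), data = tab)
  cfp <- stats::coef(plateau)
  fits <- list(plateau = list(c0 = unname(cfp[1]), c1 = unname(cfp[2]),
                              rss = sum(stats::resid(plateau)^2)),
               exponential = tryCatch({
                 f <- minpack.lm::nlsLM(
                   eb ~ A * exp(-k * T_s), data = tab,
                   start = list(A = max(tab$eb), k = 0.1),
                   control = minpack.lm::nls.lm.control(maxiter = 200))
                 cf <- stats::coef(f)
                 list(A = cf[["A"]], k = cf[["k"]],
                      rss = sum(stats::resid(f)^2))
               }, error = function(e) list(A = NA, k = NA, rss = NA)))
  structure(list(table = tab, fits = fits, lag = lag, mode = mode),
            class = "eb_profile")
}

#' @export
print.eb_profile <- function(x, ...) {
  cat(sprintf("<eb_profile (%s) at lag %g s>\n", x$mode, x$lag))
  print.data.frame(x$table, row.names = FALSE, digits = 4)
  cat(sprintf("  plateau c0 + c1/T: c0 = %.4g, c1 = %.4g (rss %.3g)\n",
              x$fits$plateau$c0, x$fits$plateau$c1, x$fits$plateau$rss))
  cat(sprintf("  exponential A*exp(-kT): A = %.4g, k = %.4g (rss %.3g)\n",
              x$fits$exponential$A, x$fits$exponential$k,
              x$fits$exponential$rss))
  invisible(x)
}

## ---- generalized-Gamma scatter distribution -------------------------------

# log normalization constant of zeta^(nu-1) exp(-a/zeta - zeta/b) on (0, Inf),
# by numerical integration on the log scale (u = log zeta), centred and
# scaled at the integrand mode for stability at extreme parameters.
.gg_logZ <- function(a, b, nu) {
  zstar <- (nu + sqrt(nu^2 + 4 * a / b)) * b / 2
  ustar <- log(zstar)
  e0 <- nu * ustar - a / zstar - zstar / b
  sd <- 1 / sqrt(a / zstar + zstar / b)
  w <- max(40 * sd, 8)
  f <- function(u) exp(nu * u - a * exp(-u) - exp(u) / b - e0)
  I <- stats::integrate(f, ustar - w, ustar, rel.tol = 1e-10,
                        subdivisions = 400L)$value +
    stats::integrate(f, ustar, ustar + w, rel.tol = 1e-10,
                     subdivisions = 400L)$value
  e0 + log(I)
}

#' Generalized-Gamma scatter density
#'
#' Density \code{f(x) = x^(nu-1) * exp(-a/x - x/b) / Z(a, b, nu)} on
#' \code{(0, Inf)}, the three-parameter form used for the distribution of the
#' tMSD amplitude scatter zeta; \code{Z} is obtained by numerical
#' integration.
#'
#' @param x quantiles (positive).
#' @param a lower-tail parameter (> 0).
#' @param b upper-tail scale (> 0).
#' @param nu shape.
#' @param log return log density.
#' @return density values.
#' @export
dgengamma_scatter <- function(x, a, b, nu, log = FALSE) {
  lz <- .gg_logZ(a, b, nu)
  ld <- ifelse(x > 0, (nu - 1) * base::log(x) - a / x - x / b - lz, -Inf)
  if (log) ld else exp(ld)
}

#' Sample from the generalized-Gamma scatter distribution
#'
#' Inverse-CDF sampling on a numerically integrated CDF (dense grid on the
#' log scale, trapezoidal accumulation, monotone interpolation).
#'
#' @param n number of draws.
#' @inheritParams dgengamma_scatter
#' @param seed RNG seed.
#' @return numeric vector of positive draws.
#' @export
rgengamma_scatter <- function(n, a, b, nu, seed = NULL) {
  zstar <- (nu + sqrt(nu^2 + 4 * a / b)) * b / 2
  ustar <- log(zstar)
  sd <- 1 / sqrt(a / zstar + zstar / b)
  w <- max(40 * sd, 8)
  u <- seq(ustar - w, ustar + w, length.out = 16384L)
  e0 <- nu * ustar - a / zstar - zstar / b
  g <- exp(nu * u - a * exp(-u) - exp(u) / b - e0)
  cdf <- c(0, cumsum((g[-1] + g[-length(g)]) / 2 * diff(u)))
  cdf <- cdf / cdf[length(cdf)]
  keep <- c(TRUE, diff(cdf) > 0)
  with_seed(seed, {
    p <- stats::runif(n)
    exp(stats::approx(cdf[keep], u[keep], xout = p, rule = 2)$y)
  })
}

#' Maximum-likelihood generalized-Gamma fit of the amplitude scatter
#'
#' Fits \code{(a, b, nu)} of the generalized-Gamma scatter density by
#' maximum likelihood, with the normalization constant computed by numerical
#' integration and a seeded multi-start Nelder-Mead search in log-parameter
#' space. Non-positive scatter values are excluded and counted.
#'
#' @param zeta numeric vector of scatter values, or an
#'   \code{\link{amplitude_scatter}} object.
#' @param n_starts number of optimizer starts.
#' @param seed seed controlling the start perturbations.
#' @return an object of class \code{"gengamma_fit"}: \code{a}, \code{b},
#'   \code{nu}, \code{loglik}, \code{n_used}, \code{n_excluded},
#'   \code{converged}.
#' @export
fit_generalized_gamma <- function(zeta, n_starts = 8L, seed = NULL) {
  if (inherits(zeta, "amplitude_scatter")) zeta <- zeta$zeta
  pos <- zeta[is.finite(zeta) & zeta > 0]
  n_exc <- length(zeta) - length(pos)
  if (length(pos) < 100L)
    stop("need at least 100 strictly positive scatter values")
  mz <- mean(pos); vz <- stats::var(pos)
  if (sqrt(vz) / mz < 1e-10) stop("degenerate sample: all values equal")
  S1 <- sum(base::log(pos)); S2 <- sum(1 / pos); S3 <- sum(pos)
  n <- length(pos)

  nll <- function(th) {
    a <- exp(th[1]); b <- exp(th[2]); nu <- exp(th[3])
    lz <- tryCatch(.gg_logZ(a, b, nu), error = function(e) NA_real_)
    if (!is.finite(lz)) return(1e10)
    val <- -((nu - 1) * S1 - a * S2 - S3 / b - n * lz)
    if (!is.finite(val)) 1e10 else val
  }

  # moment-flavoured centre (gamma-like scale/shape, small lower-tail a),
  # perturbed log-normally for the multi-start
  centre <- base::log(c(a = mz / 10, b = max(vz / mz, 1e-8),
                        nu = max(mz^2 / vz, 0.2)))
  best <- NULL
  with_seed(seed, {
    for (s in seq_len(n_starts)) {
      th0 <- centre + if (s == 1L) 0 else stats::rnorm(3L, sd = 1)
      opt <- tryCatch(
        stats::optim(th0, nll, method = "Nelder-Mead",
                     control = list(maxit = 2000L, reltol = 1e-10)),
        error = function(e) NULL)
      if (!is.null(opt) && (is.null(best) || opt$value < best$value))
        best <- opt
    }
  })
  if (is.null(best) || best$value >= 1e10)
    stop("generalized-Gamma fit did not converge (all starts failed)")
  par <- exp(best$par)
  structure(list(a = unname(par[1]), b = unname(par[2]), nu = unname(par[3]),
                 loglik = -best$value, n_used = n, n_excluded = n_exc,
                 converged = best$convergence == 0L),
            class = "gengamma_fit")
}

#' @export
print.gengamma_fit <- function(x, ...) {
  cat(sprintf(paste0("<gengamma_fit: a = %.4g, b = %.4g, nu = %.3f ",
                     "(loglik %.1f, n = %d, excluded %d)>\n"),
              x$a, x$b, x$nu, x$loglik, x$n_used, x$n_excluded))
  invisible(x)
}

## ---- single-trajectory ergodicity / mixing functionals --------------------

# The "ensemble counterpart" subtracted by the mixing statistic: the squared
# modulus of the time-averaged phase. Isolated here so the normalization can
# be changed in one place without touching callers.
.dynamical_baseline <- function(phase) Mod(mean(phase))^2

#' Single-trajectory ergodicity and mixing estimators
#'
#' Dynamical-functional test on one trajectory. For each coordinate the
#' time-averaged dynamical functional at lag \code{n dt} is the time average
#' over start frames of \code{exp(i * (X(s + n dt) - X(s)))}; the mixing
#' estimator \code{F(n)} is its real part minus the squared modulus of the
#' time-averaged phase, and the ergodicity estimator \code{E(n)} is the
#' Cesaro (running) average of \code{F} over lags \code{1..n}. Both converge
#' to zero at large lag for ergodic, mixing Gaussian processes; a
#' non-mixing deterministic oscillation keeps \code{F} oscillating. The two
#' coordinates are averaged.
#'
#' @param traj a \code{\link{trajectory}} with at least 50 points.
#' @param lags lags in seconds at which to report (multiples of \code{dt},
#'   all below the trajectory duration); default: every lag up to half the
#'   duration.
#' @return an object of class \code{"ergodicity_functional"}: \code{lags},
#'   \code{E}, \code{F}.
#' @export
ergodicity_mixing_functionals <- function(traj, lags = NULL) {
  if (!inherits(traj, "trajectory")) stop("not a trajectory")
  n <- length(traj$x)
  if (n < 50L) stop("trajectory must have at least 50 points")
  dt <- traj$dt
  if (is.null(lags)) lags <- seq_len((n - 1L) %/% 2L) * dt
  m <- steps_of(lags, dt, "lags")
  if (any(m < 1L) || any(m >= n))
    stop("lags must lie strictly between 0 and the trajectory duration")
  m_max <- max(m)

  per_coord <- function(X) {
    ph <- exp(1i * X)
    base <- .dynamical_baseline(ph)
    Fm <- vapply(seq_len(m_max), function(mm)
      Re(mean(ph[(1L + mm):n] * Conj(ph[1:(n - mm)]))) - base, numeric(1))
    Em <- cumsum(Fm) / seq_len(m_max)
    list(E = Em, F = Fm)
  }
  cx <- per_coord(traj$x)
  cy <- per_coord(traj$y)
  structure(list(lags = m * dt,
                 E = (cx$E[m] + cy$E[m]) / 2,
                 F = (cx$F[m] + cy$F[m]) / 2),
            class = "ergodicity_functional")
}

#' @export
print.ergodicity_functional <- function(x, ...) {
  k <- length(x$lags)
  cat(sprintf(
    "<ergodicity_functional: %d lags; at %g s E = %.4f, F = %.4f>\n",
    k, x$lags[k], x$E[k], x$F[k]))
  invisible(x)
}
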