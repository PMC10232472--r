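# Ensemble-heterogeneous FBM simulator.
#
# Each trajectory is the coordinate-wise sum of two independent 2D FBM
# components: a motor-driven persistent component (H1, diffusivity D1 set
# once per trajectory from its duration) and a short-time antipersistent
# component (H2, constant D2). Durations are drawn from a truncated Pareto
# law PDF(T) ~ T^-mu. The coupling D1(T) -- fast particles leave the focal
# volume sooner, so long trajectories are slow -- is the ensemble
# heterogeneity that makes pooled, censoring-aware MSDs look subdiffusive
# and aged even though every single trajectory is an ergodic FBM.

#' Parameters of the heterogeneous FBM simulator
#'
#' @param H1 Hurst exponent of the persistent component (per-coordinate MSD
#'   ~ t^(2*H1)); default 0.75 so the component MSD grows as t^1.5.
#' @param H2 Hurst exponent of the short-time component; default 0.1.
#' @param D2 diffusivity of the short-time component (um^2/s^(2*H2)).
#' @param d1_c_low,d1_g_low,d1_c_high,d1_g_high,T_c piecewise rule for the
#'   duration-dependent diffusivity of component 1:
#'   \code{D1 = d1_c_low * T^-d1_g_low} for \code{T < T_c} and
#'   \code{D1 = d1_c_high * T^-d1_g_high} for \code{T >= T_c} (the boundary
#'   itself is assigned to the high-duration branch).
#' @param mu duration power-law exponent, PDF(T) ~ T^-mu.
#' @param T_min,T_max duration truncation in seconds. The default window
#'   [2, 200] s keeps the intermediate lag decade 0.2-2 s free of survival
#'   censoring, which is required for the simulated ensemble to retain the
#'   superdiffusive exponent 2*H1 there (see the package vignette).
#' @param dt sampling interval (s).
#' @param n_traj default number of trajectories.
#' @param noise_sigma static localization error, per-coordinate standard
#'   deviation in um (0 = off).
#' @param noise_convention \code{"all_points"} or \code{"origin_clean"}
#'   (first point of each track left noise-free).
#' @param seed default RNG seed.
#' @return a validated list of class \code{"hfbm_params"}.
#' @export
hfbm_params <- function(H1 = 0.75, H2 = 0.1, D2 = 0.009,
                        d1_c_low = 0.25, d1_g_low = 0.1,
                        d1_c_high = 0.5, d1_g_high = 1.15, T_c = 2,
                        mu = 2, T_min = 2, T_max = 200, dt = 0.05,
                        n_traj = 10000L, noise_sigma = 0,
                        noise_convention = c("all_points", "origin_clean"),
                        seed = NULL) {
  noise_convention <- match.arg(noise_convention)
  p <- list(H1 = H1, H2 = H2, D2 = D2,
            d1_c_low = d1_c_low, d1_g_low = d1_g_low,
            d1_c_high = d1_c_high, d1_g_high = d1_g_high, T_c = T_c,
            mu = mu, T_min = T_min, T_max = T_max, dt = dt,
            n_traj = as.integer(n_traj), noise_sigma = noise_sigma,
            noise_convention = noise_convention, seed = seed)
  if (p$H1 <= 0 || p$H1 >= 1 || p$H2 <= 0 || p$H2 >= 1)
    stop("Hurst exponents must be in (0, 1)")
  if (p$D2 < 0) stop("D2 must be >= 0")
  if (p$d1_c_low <= 0 || p$d1_c_high <= 0)
    stop("D1 coefficients must be > 0")
  if (p$mu <= 1) stop("mu must be > 1")
  if (p$T_min < 2 * p$dt) stop("T_min must be at least 2*dt")
  if (p$T_max <= p$T_min) stop("T_max must exceed T_min")
  if (p$noise_sigma < 0) stop("noise_sigma must be >= 0")
  structure(p, class = "hfbm_params")
}

#' @export
print.hfbm_params <- function(x, ...) {
  cat(sprintf(
    paste0("<hfbm_params: H1 = %g, H2 = %g, D2 = %g, D1 = %g*T^-%g (T<%g)",
           " / %g*T^-%g, T ~ T^-%g on [%g, %g] s, dt = %g s>\n"),
    x$H1, x$H2, x$D2, x$d1_c_low, x$d1_g_low, x$T_c,
    x$d1_c_high, x$d1_g_high, x$mu, x$T_min, x$T_max, x$dt))
  invisible(x)
}

#' Quantile function of the truncated Pareto duration law
#'
#' Inverse CDF of the density proportional to \code{T^-mu} on
#' \code{[T_min, T_max]}; \code{T_max = Inf} is allowed for \code{mu > 1}.
#'
#' @param p probabilities in [0, 1].
#' @param mu power-law exponent (> 1).
#' @param T_min,T_max truncation bounds in seconds.
#' @return durations in seconds; \code{p = 0} maps to \code{T_min}.
#' @export
qduration <- function(p, mu = 2, T_min = 2, T_max = 200) {
  if (mu <= 1) stop("mu must be > 1")
  if (T_max <= T_min) stop("T_max must exceed T_min")
  e <- 1 - mu
  hi <- if (is.finite(T_max)) T_max^e else 0
  (T_min^e - p * (T_min^e - hi))^(1 / e)
}

#' Sample power-law-distributed trajectory durations
#'
#' I.i.d. inverse-CDF draws from the truncated Pareto density
#' \code{~ T^-mu} on \code{[T_min, T_max]}; if \code{dt} is given, each
#' duration is snapped down to a multiple of \code{dt} (at least
#' \code{2*dt}) so it sits on the frame grid.
#'
#' @param n number of draws.
#' @inheritParams qduration
#' @param dt optional sampling interval for grid snapping (s).
#' @param seed RNG seed.
#' @return numeric vector of durations (s).
#' @export
sample_durations <- function(n, mu = 2, T_min = 2, T_max = 200, dt = NULL,
                             seed = NULL) {
  Tval <- with_seed(seed, qduration(stats::runif(n), mu, T_min, T_max))
  if (!is.null(dt)) Tval <- pmax(floor(Tval / dt + 1e-9) * dt, 2 * dt)
  Tval
}

# Stratified variant: equal draw counts in log-spaced duration bins over
# strat_range, each drawn from the Pareto law conditioned on its bin;
# per-trajectory weights (true bin probability / assigned fraction) are
# returned so pooled averages can be reweighted.
sample_durations_stratified <- function(n, mu, T_min, T_max, dt,
                                        strat_range = c(T_min, T_max),
                                        strat_bins = 20L) {
  edges <- .log_bins(max(strat_range[1], T_min), min(strat_range[2], T_max),
                     strat_bins)
  e <- 1 - mu
  cdf <- function(x) (T_min^e - x^e) / (T_min^e - T_max^e)
  per <- rep(n %/% strat_bins, strat_bins)
  per[seq_len(n %% strat_bins)] <- per[seq_len(n %% strat_bins)] + 1L
  Tval <- numeric(0); wt <- numeric(0)
  for (b in seq_len(strat_bins)) {
    plo <- cdf(edges[b]); phi <- cdf(edges[b + 1L])
    u <- stats::runif(per[b], plo, phi)
    Tb <- qduration(u, mu, T_min, T_max)
    Tval <- c(Tval, Tb)
    wt <- c(wt, rep((phi - plo) / (per[b] / n), per[b]))
  }
  Tval <- pmax(floor(Tval / dt + 1e-9) * dt, 2 * dt)
  list(durations = Tval, weights = wt)
}

#' Duration-dependent diffusivity of the persistent component
#'
#' Piecewise power law \code{D1(T)}: \code{d1_c_low * T^-d1_g_low} below
#' \code{T_c} and \code{d1_c_high * T^-d1_g_high} from \code{T_c} on. With
#' the default constants the two branches do not meet at \code{T_c}: the
#' small jump (0.2333 vs 0.2253 at 2 s) is intentional and documented.
#'
#' @param T durations in seconds (> 0).
#' @param params an \code{\link{hfbm_params}} object.
#' @return diffusivities in um^2/s^(2*H1).
#' @export
d1_of_duration <- function(T, params = hfbm_params()) {
  if (any(T <= 0)) stop("T must be positive")
  ifelse(T < params$T_c,
         params$d1_c_low * T^(-params$d1_g_low),
         params$d1_c_high * T^(-params$d1_g_high))
}

# Build trajectories from a vector of step counts by batched fGn synthesis,
# grouped by length so circulant eigenvalues and FFTs are shared.
.build_fbm_tracks <- function(nsteps, dt, H1, D1, H2 = NULL, D2 = 0,
                              id_prefix = "sim") {
  trs <- vector("list", length(nsteps))
  for (n in sort(unique(nsteps))) {
    idx <- which(nsteps == n)
    cnt <- length(idx)
    inc <- .fgn_draw(H1, D1[idx[1]], n, dt, 2L * cnt)
    if (!is.null(H2) && D2 > 0)
      inc <- inc + .fgn_draw(H2, D2, n, dt, 2L * cnt)
    pos <- apply(inc, 2L, cumsum)
    if (n == 1L) pos <- matrix(pos, nrow = 1L)
    for (j in seq_len(cnt)) {
      trs[[idx[j]]] <- trajectory(
        x = c(0, pos[, 2L * j - 1L]), y = c(0, pos[, 2L * j]),
        dt = dt, id = sprintf("%s%06d", id_prefix, idx[j]))
    }
  }
  trs
}

#' Simulate an ensemble-heterogeneous FBM ensemble
#'
#' Per trajectory: draw a duration from the truncated Pareto law, set the
#' persistent-component diffusivity \code{D1 = d1_of_duration(T)}, generate
#' two independent 2D FBM components of that duration (H1 with D1; H2 with
#' D2) and sum them coordinate-wise; optionally add Gaussian localization
#' noise. Deterministic under a fixed seed.
#'
#' @param n_traj number of trajectories (default from \code{params}).
#' @param params an \code{\link{hfbm_params}} object.
#' @param seed RNG seed (default from \code{params}).
#' @param stratified use stratified duration sampling (equal counts per
#'   logarithmic duration bin) for duration-resolved analyses that need
#'   long-duration statistics; sampling weights are stored in
#'   \code{$weights}.
#' @param strat_range,strat_bins stratification window and bin count.
#' @return a \code{\link{track_ensemble}}; with \code{stratified = TRUE} it
#'   carries a \code{weights} field aligned with the trajectories.
#' @export
simulate_hfbm_ensemble <- function(n_traj = NULL, params = hfbm_params(),
                                   seed = NULL, stratified = FALSE,
                                   strat_range = NULL, strat_bins = 20L) {
  n_traj <- as.integer(n_traj %||% params$n_traj)
  seed <- seed %||% params$seed
  with_seed(seed, {
    if (stratified) {
      sd_ <- sample_durations_stratified(
        n_traj, params$mu, params$T_min, params$T_max, params$dt,
        strat_range = strat_range %||% c(params$T_min, params$T_max),
        strat_bins = strat_bins)
      dur <- sd_$durations; wts <- sd_$weights
    } else {
      dur <- sample_durations(n_traj, params$mu, params$T_min, params$T_max,
                              dt = params$dt)
      wts <- NULL
    }
    nsteps <- as.integer(round(dur / params$dt))
    D1 <- d1_of_duration(nsteps * params$dt, params)
    trs <- .build_fbm_tracks(nsteps, params$dt, params$H1, D1,
                             params$H2, params$D2, id_prefix = "hfbm")
    ens <- track_ensemble(trs, label = "hFBM simulation")
    if (!is.null(wts)) ens$weights <- wts
    if (params$noise_sigma > 0)
      ens <- add_localization_noise(ens, params$noise_sigma,
                                    params$noise_convention)
    ens
  })
}

#' Simulate a homogeneous FBM control ensemble
#'
#' One-component FBM with a common Hurst exponent and diffusivity for every
#' trajectory, at caller-supplied durations. This is the no-ageing,
#' fully ergodic control: any ageing or EB structure seen here is a finite-
#' sample artefact, so it calibrates what the heterogeneous ensemble adds.
#'
#' @param durations trajectory durations in seconds (snapped down to the
#'   frame grid, minimum \code{2*dt}).
#' @param H Hurst exponent.
#' @param D diffusivity (um^2/s^(2H)).
#' @param dt sampling interval (s).
#' @param seed RNG seed.
#' @return a \code{\link{track_ensemble}}.
#' @export
simulate_homogeneous_fbm <- function(durations, H, D, dt = 0.05,
                                     seed = NULL) {
  if (!length(durations)) stop("durations must be non-empty")
  nsteps <- pmax(as.integer(floor(durations / dt + 1e-9)), 2L)
  with_seed(seed, {
    trs <- .build_fbm_tracks(nsteps, dt, H, rep(D, length(nsteps)),
                             id_prefix = "fbm")
    track_ensemble(trs, label = sprintf("homogeneous FBM H=%g", H))
  })
}

#' Add static localization noise to an ensemble
#'
#' Adds i.i.d. zero-mean Gaussian offsets (standard deviation \code{sigma}
#' per coordinate) to every localization. Under \code{"all_points"} both
#' endpoints of any displacement are noisy, offsetting 2D MSD curves by
#' \code{4 sigma^2}; \code{"origin_clean"} leaves each track's first point
#' noise-free, so displacement-from-origin statistics (eMSD) carry only the
#' single-endpoint offset \code{2 sigma^2} while time-averaged MSDs keep
#' (almost) the full \code{4 sigma^2} -- the asymmetric reading of additive
#' noise that splits eMSD from e-tMSD at short lags.
#'
#' @param ensemble a \code{\link{track_ensemble}}.
#' @param sigma per-coordinate noise standard deviation (um).
#' @param convention \code{"all_points"} or \code{"origin_clean"}.
#' @param seed RNG seed.
#' @return a new \code{track_ensemble} with perturbed coordinates.
#' @export
add_localization_noise <- function(ensemble, sigma,
                                   convention = c("all_points",
                                                  "origin_clean"),
                                   seed = NULL) {
  convention <- match.arg(convention)
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(ensemble)
  with_seed(seed, {
    out <- ensemble
    out$trajectories <- lapply(ensemble$trajectories, function(tr) {
      n <- length(tr$x)
      ex <- stats::rnorm(n, 0, sigma)
      ey <- stats::rnorm(n, 0, sigma)
      if (convention == "origin_clean") { ex[1L] <- 0; ey[1L] <- 0 }
      tr$x <- tr$x + ex
      tr$y <- tr$y + ey
      tr
    })
    out
  })
}
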