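# Fixture builders shared across test files. Larger simulated ensembles are
# memoised so several files can reuse one realization.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# deterministic ballistic track: x = v * t, y = 0
ballistic_track <- function(v = 1, n = 3, dt = 1, id = "ball") {
  k <- 0:(n - 1)
  trajectory(x = v * k * dt, y = rep(0, n), dt = dt, id = id)
}

# tiny ensemble with prescribed durations (straight-line tracks)
duration_ensemble <- function(durations_s, dt = 1) {
  trs <- lapply(seq_along(durations_s), function(i) {
    n <- round(durations_s[i] / dt) + 1
    ballistic_track(v = 1, n = n, dt = dt, id = paste0("d", i))
  })
  track_ensemble(trs)
}

random_ensemble <- function(n_traj = 12, seed = 99, dt = 0.5) {
  set.seed(seed)
  trs <- lapply(seq_len(n_traj), function(i) {
    n <- sample(2:30, 1)
    trajectory(cumsum(rnorm(n)), cumsum(rnorm(n)), dt = dt,
               id = paste0("r", i))
  })
  track_ensemble(trs)
}

# Brownian ensemble whose per-track diffusivity is exactly T^-0.65: ground
# truth for the conditional-diffusion exponent gamma
het_brownian_ensemble <- function(n_traj = 4000, gamma = 0.65, seed = 31) {
  memo(sprintf("hetbm_%d_%g_%d", n_traj, gamma, seed), {
    set.seed(seed)
    Ts <- sample_durations(n_traj, mu = 2, T_min = 1, T_max = 1000, dt = 0.05)
    ns <- as.integer(round(Ts / 0.05))
    trs <- lapply(seq_len(n_traj), function(i) {
      inc <- generate_fgn(0.5, Ts[i]^(-gamma), ns[i], 0.05, n_series = 2)
      trajectory(c(0, cumsum(inc[, 1])), c(0, cumsum(inc[, 2])), dt = 0.05,
                 id = paste0("b", i))
    })
    track_ensemble(trs, "heterogeneous Brownian")
  })
}

# the default heterogeneous FBM ensemble used by several analyses
hfbm_fixture <- function() memo("hfbm20k",
                                simulate_hfbm_ensemble(20000, seed = 101))

# homogeneous FBM control with the same duration law
homogeneous_fixture <- function(H = 0.375, D = 0.1) {
  memo(sprintf("hom_%g_%g", H, D), {
    Ts <- sample_durations(5000, mu = 2, T_min = 2, T_max = 200, dt = 0.05,
                           seed = 42)
    simulate_homogeneous_fbm(Ts, H = H, D = D, dt = 0.05, seed = 43)
  })
}
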