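test_that("conditional diffusion profile recovers a known duration coupling", {
  # per-track D set to T^-0.65 exactly: the profile exponent must come back
  ens <- het_brownian_ensemble(gamma = 0.65)
  # fit window capped at the smallest threshold so no survival censoring
  # perturbs the conditional amplitudes inside the window
  prof <- conditional_diffusion_profile(ens, thresholds = c(1, 2, 4, 8, 16),
                                        window = c(0.2, 1))
  expect_lt(abs(prof$fit$gamma - 0.65), 0.05)
  expect_true(all(diff(prof$table$D_alpha) < 0))
})

test_that("conditional diffusion profile is flat for a homogeneous ensemble", {
  ens <- homogeneous_fixture()
  prof <- conditional_diffusion_profile(ens, thresholds = c(2, 4, 8, 16),
                                        window = c(0.2, 2))
  expect_equal(prof$fit$gamma, 0, tolerance = 0.05)
})

test_that("under-populated thresholds are dropped with a warning", {
  ens <- duration_ensemble(c(2, 3, 10, 12), dt = 1)
  expect_warning(
    expect_error(conditional_diffusion_profile(ens, 5, c(1, 4),
                                               min_traj = 50),
                 "no threshold"),
    "min_traj")
})

test_that("exponential duration decay is recovered exactly from exact bins", {
  # ballistic speeds arranged so tMSD(lag | T) = a * exp(-b T) exactly
  a <- 4; b <- 0.1; lag <- 1
  Ts <- c(4, 8, 16, 32)
  trs <- list()
  for (i in seq_along(Ts)) {
    v <- sqrt(a * exp(-b * Ts[i])) / lag
    for (j in 1:2)
      trs[[length(trs) + 1L]] <-
        ballistic_track(v = v, n = Ts[i] + 1, dt = 1,
                        id = paste0("t", i, "_", j))
  }
  ens <- track_ensemble(trs)
  prof <- etmsd_vs_duration(ens, lag = 1, n_bins = 4, range = c(3.9, 32.1),
                            min_traj = 2, n_boot = 0)
  expect_equal(prof$fit$b, b, tolerance = 1e-6)
  expect_equal(prof$fit$a, a, tolerance = 1e-5)

  # duration-independent amplitudes give b ~ 0
  flat <- track_ensemble(lapply(seq_along(Ts), function(i)
    ballistic_track(v = 0.3, n = Ts[i] + 1, dt = 1, id = paste0("f", i))))
  pf <- etmsd_vs_duration(flat, lag = 1, n_bins = 4, range = c(3.9, 32.1),
                          min_traj = 1, n_boot = 0)
  expect_lt(abs(pf$fit$b), 1e-3)

  expect_error(etmsd_vs_duration(ens, lag = 1, n_bins = 2,
                                 range = c(3.9, 32.1), min_traj = 2),
               "fewer than 3")
})

test_that("ageing sweep flags the heterogeneous ensemble but not controls", {
  # ballistic: eMSD(t, t_a) = v^2 t^2 for every t_a -> no ageing
  ball <- track_ensemble(lapply(1:30, function(i)
    ballistic_track(v = 0.5, n = 81, dt = 0.25, id = paste0("b", i))))
  sw <- ageing_sweep(ball, t_a_list = c(0, 1, 2), window = c(0.5, 4),
                     n_boot = 20, seed = 1)
  expect_false(sw$ages)
  a0 <- sw$entries[[1]]$emsd
  a2 <- sw$entries[[3]]$emsd
  common <- intersect(a0$lag_s, a2$lag_s)
  expect_equal(a0$msd_um2[match(common, a0$lag_s)],
               a2$msd_um2[match(common, a2$lag_s)], tolerance = 1e-12)

  # homogeneous FBM with the experiment-like duration law: no ageing
  hom <- homogeneous_fixture()
  swh <- ageing_sweep(hom, t_a_list = c(0, 1, 2), window = c(0.2, 1),
                      n_boot = 40, seed = 2)
  expect_false(swh$ages)
  amps <- swh$amplitudes
  for (k in 2:nrow(amps))   # curves coincide within bootstrap error
    expect_true(amps$amp_um2[k] <= amps$amp_hi[1] + 1e-12 &&
                  amps$amp_um2[k] >= amps$amp_lo[1] - 1e-12)

  # heterogeneous FBM: amplitude strictly decreasing beyond CIs
  het <- hfbm_fixture()
  swx <- ageing_sweep(het, t_a_list = c(0, 2, 5), window = c(0.2, 1),
                      n_boot = 40, seed = 3)
  expect_true(swx$ages)
  expect_true(all(diff(swx$amplitudes$amp_um2) < 0))
  expect_error(ageing_sweep(hom, c(0, 1000), c(0.2, 1)), "shorter")
})
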