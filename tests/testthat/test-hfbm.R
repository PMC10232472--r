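test_that("duration-dependent diffusivity follows the piecewise rule", {
  p <- hfbm_params()
  expect_identical(d1_of_duration(1, p), 0.25)
  expect_equal(d1_of_duration(4, p), 0.5 * 4^-1.15, tolerance = 1e-12)
  # documented discontinuity at the branch point: 2 s uses the long branch
  expect_equal(d1_of_duration(2 - 1e-9, p), 0.25 * 2^-0.1, tolerance = 1e-6)
  expect_equal(d1_of_duration(2, p), 0.5 * 2^-1.15, tolerance = 1e-12)
  expect_error(d1_of_duration(-1, p), "positive")
})

test_that("duration sampling inverts the truncated Pareto law", {
  expect_equal(qduration(0, mu = 2, T_min = 0.25, T_max = 200), 0.25)
  expect_equal(qduration(0.5, mu = 2, T_min = 0.25, T_max = Inf), 0.5)
  expect_equal(qduration(1, mu = 2, T_min = 2, T_max = 200), 200)

  # Kolmogorov-Smirnov distance against the closed-form CDF
  Tv <- sample_durations(1e5, mu = 2, T_min = 0.25, T_max = 200, seed = 14)
  e <- -1
  cdf <- function(x) (0.25^e - x^e) / (0.25^e - 200^e)
  ks <- suppressWarnings(ks.test(Tv, cdf))
  expect_lt(unname(ks$statistic), 0.01)

  # grid snapping: multiples of dt, at least 2 dt
  Ts <- sample_durations(1000, mu = 2, T_min = 0.25, T_max = 10, dt = 0.05,
                         seed = 15)
  expect_true(all(abs(Ts / 0.05 - round(Ts / 0.05)) < 1e-9))
  expect_true(all(Ts >= 0.1 - 1e-12))
})

test_that("ensembles are bit-identical under a fixed seed", {
  e1 <- simulate_hfbm_ensemble(200, seed = 16)
  e2 <- simulate_hfbm_ensemble(200, seed = 16)
  expect_identical(e1, e2)
  e3 <- simulate_hfbm_ensemble(200, seed = 17)
  expect_false(identical(e1, e3))
})

test_that("a single-component setup reduces to plain FBM", {
  p <- hfbm_params(D2 = 0, T_min = 1, T_max = 1 + 1e-9)
  ens <- simulate_hfbm_ensemble(3000, p, seed = 18)
  expect_true(all(abs(duration(ens) - 1) < 1e-9))
  cur <- emsd(ens)
  fit <- fit_power_law(cur, c(0.1, 0.9))
  expect_equal(fit$alpha, 1.5, tolerance = 0.05)
  expect_equal(fit$D_alpha, 0.25, tolerance = 0.05)  # d1 at T = 1 s
})

test_that("homogeneous FBM control is ergodic with the right exponent", {
  ens <- homogeneous_fixture()                       # H = 0.375, 5000 tracks
  ec <- emsd(ens, max_lag = 2)
  tc <- etmsd(ens, max_lag = 2)
  sel <- ec$lag_s >= 0.1 - 1e-9 & ec$lag_s <= 2 + 1e-9
  rel <- abs(tc$msd_um2[sel] - ec$msd_um2[sel]) / ec$msd_um2[sel]
  expect_lt(max(rel), 0.05)
  fit <- fit_power_law(ec, c(0.2, 2))
  expect_equal(fit$alpha, 2 * 0.375, tolerance = 0.05)

  bro <- simulate_homogeneous_fbm(rep(5, 5000), H = 0.5, D = 0.05,
                                  dt = 0.05, seed = 44)
  expect_equal(fit_power_law(emsd(bro, max_lag = 2), c(0.2, 2))$alpha, 1,
               tolerance = 0.05)
})

test_that("heterogeneous ensemble shows spurious long-time subdiffusion", {
  het <- hfbm_fixture()
  pooled <- fit_power_law(emsd(het, max_lag = 20), c(3, 20))
  expect_lt(pooled$alpha, 1)
  subcur <- emsd(het, T_min = 8, max_lag = 20)
  sub <- fit_power_law(subcur, c(3, 20))
  # conditioning on long durations removes most of the apparent subdiffusion
  expect_gt(sub$alpha - pooled$alpha, 0.3)
  # and within the censoring-free part of the window (t < T threshold) the
  # superdiffusive exponent 2*H1 is fully conserved
  expect_equal(fit_power_law(subcur, c(3, 8), with_offset = TRUE)$alpha, 1.5,
               tolerance = 0.15)
  subint <- fit_power_law(emsd(het, T_min = 8, max_lag = 2), c(0.2, 2),
                          with_offset = TRUE)
  expect_equal(subint$alpha, 1.5, tolerance = 0.15)
})

test_that("aged eMSD is non-increasing in ageing time for the hFBM model", {
  het <- hfbm_fixture()
  curves <- lapply(c(0, 2, 5), function(ta)
    emsd(het, t_a = ta, max_lag = 1))
  rows <- 5:21   # lag grid row m+1 holds lag m*dt; rows for 0.2-1 s
  for (k in 2:3) {
    v_prev <- curves[[k - 1]]$msd_um2[rows]
    v_cur <- curves[[k]]$msd_um2[rows]
    # non-increasing at every lag up to Monte-Carlo slack
    expect_true(all(v_cur <= v_prev * 1.05))
    expect_lt(mean(v_cur / v_prev), 1)
  }
})

test_that("stratified sampling records weights and fills long-duration bins", {
  ens <- simulate_hfbm_ensemble(2400, seed = 19, stratified = TRUE,
                                strat_range = c(2, 40), strat_bins = 12)
  expect_length(ens$weights, 2400)
  expect_true(all(ens$weights > 0))
  # equal bin occupancy by construction
  Ts <- duration(ens)
  expect_gt(sum(Ts >= 20), 200)  # far above the ~2% a plain Pareto gives
  # mean weight equals the Pareto mass of the stratified window
  mass <- (1 / 2 - 1 / 40) / (1 / 2 - 1 / 200)
  expect_equal(mean(ens$weights), mass, tolerance = 1e-9)
})

test_that("localization noise offsets MSDs by the closed-form constants", {
  D <- 0.05; sig <- 0.1; dt <- 0.05
  base <- simulate_homogeneous_fbm(rep(2, 4000), H = 0.5, D = D, dt = dt,
                                   seed = 20)
  expect_identical(add_localization_noise(base, 0), base)

  noisy <- add_localization_noise(base, sig, "all_points", seed = 21)
  clean0 <- add_localization_noise(base, sig, "origin_clean", seed = 22)
  lag <- 0.5
  e_all <- emsd(noisy, max_lag = 1)
  t_all <- etmsd(noisy, max_lag = 1)
  i <- round(lag / dt) + 1L  # row for lag on the frame grid
  # both curves offset by 4 sigma^2 (two noisy 2D endpoints); bounds are
  # a few Monte-Carlo standard errors at 4000 tracks
  expect_lt(abs(e_all$msd_um2[i] - (4 * D * lag + 4 * sig^2)), 0.008)
  expect_lt(abs(t_all$msd_um2[i] - (4 * D * lag + 4 * sig^2)), 0.008)

  # origin-clean: eMSD keeps only the single-endpoint 2 sigma^2 offset,
  # tMSD (almost all start frames noisy) keeps ~ 4 sigma^2
  e_cl <- emsd(clean0, max_lag = 1)
  t_cl <- etmsd(clean0, max_lag = 1)
  expect_lt(abs(e_cl$msd_um2[i] - (4 * D * lag + 2 * sig^2)), 0.008)
  expect_lt(abs(t_cl$msd_um2[i] - (4 * D * lag + 4 * sig^2)), 0.008)
})
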