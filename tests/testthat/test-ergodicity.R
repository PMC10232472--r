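test_that("amplitude scatter identities hold exactly", {
  tr <- trajectory(cumsum(rnorm(30)), cumsum(rnorm(30)), dt = 1)
  same <- track_ensemble(list(tr, tr, tr, tr))
  sc <- amplitude_scatter(same, lag = 3)
  expect_equal(sc$zeta, rep(1, 4))
  expect_equal(sc$eb, 0, tolerance = 1e-12)

  b1 <- ballistic_track(v = 1, n = 6, dt = 1)        # tMSD(1) = 1
  b2 <- ballistic_track(v = sqrt(3), n = 6, dt = 1)  # tMSD(1) = 3
  sc2 <- amplitude_scatter(track_ensemble(list(b1, b2)), lag = 1)
  expect_equal(sort(sc2$zeta), c(0.5, 1.5))
  expect_equal(sc2$eb, 0.25, tolerance = 1e-12)

  rnd <- random_ensemble(n_traj = 20, seed = 10)
  sc3 <- amplitude_scatter(rnd, lag = rnd$dt)
  expect_equal(mean(sc3$zeta), 1, tolerance = 1e-12)
  expect_equal(sc3$eb, mean((sc3$zeta - 1)^2), tolerance = 1e-12)
  expect_gte(sc3$eb, 0)

  still <- track_ensemble(list(trajectory(rep(0, 5), rep(0, 5), dt = 1),
                               trajectory(rep(1, 5), rep(1, 5), dt = 1)))
  expect_error(amplitude_scatter(still, lag = 1), "immobile")
})

test_that("Brownian EB scales as lag over duration", {
  Ts <- sample_durations(5000, mu = 2, T_min = 0.4, T_max = 50, dt = 0.05,
                         seed = 61)
  ens <- simulate_homogeneous_fbm(Ts, H = 0.5, D = 0.05, dt = 0.05,
                                  seed = 62)
  eb <- eb_vs_duration(ens, lag = 0.2, mode = "binned", n_bins = 8,
                       min_traj = 60)
  expect_gte(nrow(eb$table), 4)
  sl <- coef(lm(log(eb) ~ log(T_s), data = eb$table))[2]
  expect_equal(unname(sl), -1, tolerance = 0.15)
  expect_true(all(diff(eb$table$eb) < 0))
})

test_that("EB-vs-duration reports both decay forms and handles hFBM subsets", {
  het <- hfbm_fixture()
  eb <- eb_vs_duration(het, lag = 0.2, mode = "min_duration",
                       thresholds = c(2, 4, 8, 16, 32), min_traj = 50)
  expect_equal(nrow(eb$table), 5)
  # amplitude scatter narrows as slow long-duration tracks dominate
  expect_lt(eb$table$eb[5], eb$table$eb[1])
  expect_true(is.finite(eb$fits$plateau$rss))
  expect_true(is.finite(eb$fits$exponential$rss))
  expect_gt(eb$fits$exponential$k, 0)

  idsame <- track_ensemble(rep(list(
    trajectory(cumsum(rnorm(40)), cumsum(rnorm(40)), dt = 1)), 60))
  ebs <- eb_vs_duration(idsame, lag = 1, mode = "min_duration",
                        thresholds = c(1, 2, 3), min_traj = 10)
  expect_true(all(abs(ebs$table$eb) < 1e-12))
})

test_that("single-trajectory E and F behave per the dynamical-functional test", {
  const <- trajectory(rep(2, 100), rep(-1, 100), dt = 1)
  ef0 <- ergodicity_mixing_functionals(const, lags = c(1, 5, 20))
  expect_equal(ef0$F, rep(0, 3), tolerance = 1e-12)
  expect_equal(ef0$E, rep(0, 3), tolerance = 1e-12)

  # long FBM track: both estimators vanish at large lag
  x <- c(0, cumsum(generate_fgn(0.375, 1, 10000, 0.05, seed = 71)[, 1]))
  y <- c(0, cumsum(generate_fgn(0.375, 1, 10000, 0.05, seed = 72)[, 1]))
  tr <- trajectory(x, y, dt = 0.05, id = "fbm")
  ef <- ergodicity_mixing_functionals(tr, lags = seq(5, 100, by = 5))
  k <- length(ef$lags)
  expect_lt(abs(ef$E[k]), 0.1)
  expect_lt(abs(ef$F[k]), 0.1)

  # deterministic oscillation: F keeps oscillating (non-mixing)
  set.seed(73)
  k0 <- 0:5000
  osc <- trajectory(cos(0.05 * k0) + rnorm(5001, 0, 0.01),
                    cos(0.05 * k0 + 1) + rnorm(5001, 0, 0.01), dt = 1)
  efo <- ergodicity_mixing_functionals(osc, lags = 1:300)
  expect_gt(max(efo$F) - min(efo$F), 0.2)

  expect_error(ergodicity_mixing_functionals(const, lags = 200), "duration")
  expect_error(
    ergodicity_mixing_functionals(trajectory(1:10, 1:10, dt = 1)),
    "at least 50")
})
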