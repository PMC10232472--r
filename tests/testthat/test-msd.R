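test_that("tMSD matches trivial closed forms", {
  const <- trajectory(rep(1, 10), rep(-2, 10), dt = 0.5, id = "still")
  expect_true(all(tmsd(const)$msd_um2 == 0))

  ball <- ballistic_track(v = 1, n = 3, dt = 1)
  tv <- tmsd(ball)
  expect_equal(tv$msd_um2, c(0, 1, 4))
  expect_equal(tv$count, c(3, 2, 1))
})

test_that("tMSD equals the brute-force double loop, aged and unaged", {
  set.seed(12)
  tr <- trajectory(cumsum(rnorm(50)), cumsum(rnorm(50)), dt = 0.2)
  brute <- function(a, m) {
    n <- length(tr$x)
    starts <- (a + 1):(n - m)
    mean((tr$x[starts + m] - tr$x[starts])^2 +
           (tr$y[starts + m] - tr$y[starts])^2)
  }
  for (t_a in c(0, 0.4)) {
    a <- round(t_a / 0.2)
    tv <- tmsd(tr, t_a = t_a)
    for (m in seq_len(49 - a))
      expect_equal(tv$msd_um2[m + 1], brute(a, m), tolerance = 1e-12)
  }
  expect_error(tmsd(trajectory(1:3, 1:3, dt = 1), t_a = 2), "aged away")
})

test_that("eMSD averages over survivors only and matches brute force", {
  one <- track_ensemble(list(trajectory(c(0, 3), c(0, 4), dt = 1)))
  expect_equal(emsd(one)$msd_um2, c(0, 25))

  two <- track_ensemble(list(trajectory(c(0, 1), c(0, 0), dt = 1),
                             trajectory(c(0, 3), c(0, 0), dt = 1)))
  expect_equal(emsd(two)$msd_um2[2], 5)

  rnd <- random_ensemble(n_traj = 14, seed = 8)
  cur <- emsd(rnd)
  Ts <- vapply(rnd$trajectories, duration, numeric(1))
  for (j in seq(2, nrow(cur), by = 3)) {
    m <- round(cur$lag_s[j] / rnd$dt)
    vals <- vapply(rnd$trajectories[Ts >= m * rnd$dt - 1e-9], function(tr)
      (tr$x[1 + m] - tr$x[1])^2 + (tr$y[1 + m] - tr$y[1])^2, numeric(1))
    expect_equal(cur$msd_um2[j], mean(vals), tolerance = 1e-12)
    expect_equal(cur$count[j], length(vals))
  }
  # counts are the survival counts
  expect_identical(cur$count, survival_counts(rnd, cur$lag_s))
  expect_equal(cur$msd_um2[1], 0)
  expect_error(emsd(rnd, t_a = 1000 * rnd$dt), "survives")
})

test_that("e-tMSD is the unweighted mean of per-trajectory tMSDs", {
  tr <- trajectory(cumsum(rnorm(20)), cumsum(rnorm(20)), dt = 1)
  same <- track_ensemble(list(tr, tr, tr))
  expect_equal(etmsd(same)$msd_um2, tmsd(tr)$msd_um2, tolerance = 1e-12)

  b1 <- ballistic_track(v = 1, n = 5, dt = 1, id = "s")   # tMSD(1) = 1
  b2 <- ballistic_track(v = sqrt(3), n = 5, dt = 1, id = "f") # tMSD(1) = 3
  expect_equal(etmsd(track_ensemble(list(b1, b2)))$msd_um2[2], 2)

  rnd <- random_ensemble(n_traj = 10, seed = 3)
  cur <- etmsd(rnd)
  m <- 4
  per <- vapply(rnd$trajectories[vapply(rnd$trajectories, function(tr)
    length(tr$x), integer(1)) - 1 >= m + 1],
    function(tr) tmsd(tr)$msd_um2[m + 1], numeric(1))
  expect_equal(cur$msd_um2[m + 1], mean(per), tolerance = 1e-12)
  expect_equal(cur$msd_um2[1], 0)
})

test_that("msd_table exports the tidy contract columns", {
  rnd <- random_ensemble(n_traj = 5, seed = 4)
  tab <- msd_table(list(emsd(rnd), etmsd(rnd)))
  expect_identical(names(tab),
                   c("kind", "t_a_s", "T_min_s", "lag_s", "msd_um2", "count"))
  expect_setequal(unique(tab$kind), c("eMSD", "e-tMSD"))
})
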