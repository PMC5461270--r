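synthetic_traj <- function(t, z_r, z_l = rep(-0.001, length(t))) {
  tibble::tibble(t = t, x_trunk = 0.5 * t, z_trunk = 0.92,
                 z_rfoot = z_r, z_lfoot = z_l,
                 grounded_r = z_r <= 0, grounded_l = z_l <= 0)
}

test_that("event detection recovers crossings and honours the debounce", {
  t <- seq(0, 10, by = 0.01)
  z <- -0.05 * sin(2 * pi * t)       # grounded on [0, .5], airborne on (.5, 1)
  ev <- detect_events(synthetic_traj(t, z))
  r <- ev[ev$foot == "right", ]
  lo <- r$t[r$event == "liftoff"]
  td <- r$t[r$event == "touchdown"]
  expect_equal(lo, seq(0.51, 9.51, by = 1), tolerance = 0.011)
  expect_equal(td, seq(1.01, 9.01, by = 1), tolerance = 0.011)

  # constant contact: no events
  ev0 <- detect_events(synthetic_traj(t, rep(-0.01, length(t))))
  expect_equal(nrow(ev0[ev0$foot == "right", ]), 0)

  # chatter faster than the debounce collapses into the surrounding episode
  zc <- rep(-0.01, length(t))
  zc[t > 2 & t < 2.5] <- 0.05
  zc[t > 2.2 & t < 2.21] <- -0.01    # 10 ms blip inside a flight episode
  evc <- detect_events(synthetic_traj(t, zc), debounce = 0.02)
  rc <- evc[evc$foot == "right", ]
  expect_equal(nrow(rc), 2)          # one liftoff, one touchdown only
})

test_that("step intervals, ranges, and shortfall reporting", {
  ev <- tibble::tibble(foot = "right", event = "touchdown",
                       t = seq(0, 49.5, by = 0.5))
  si <- step_intervals(ev, steps = c(11, 100))
  expect_equal(si$summary$n, 90)
  expect_equal(si$summary$mean, 0.5)
  expect_equal(si$summary$sd, 0)
  expect_equal(si$summary$shortfall, 0L)

  # alternating intervals
  tt <- cumsum(rep(c(0.2, 0.4), 10))
  si2 <- step_intervals(tibble::tibble(foot = "left", event = "touchdown",
                                       t = c(0, tt)), steps = NULL)
  expect_equal(si2$summary$mean, 0.3)

  short <- step_intervals(ev[1:20, ], steps = c(11, 100))
  expect_equal(short$summary$shortfall, 80L)
})

test_that("count_steps uses a half-open window", {
  ev <- tibble::tibble(foot = c("left", "left", "left", "right"),
                       event = "touchdown", t = c(1, 2, 3, 2.5))
  expect_equal(count_steps(ev, c(1, 3)), c(right = 1, left = 2))
  expect_equal(count_steps(ev, c(3, 4)), c(right = 0, left = 1))
  expect_equal(count_steps(ev, c(5, 6)), c(right = 0, left = 0))
})

test_that("peak heights recover flight apexes and normalize by trunk height", {
  t <- seq(0, 2, by = 0.001)
  z <- ifelse(t > 0.5 & t < 1.5, 0.092 * sin(pi * (t - 0.5)), -0.001)
  traj <- synthetic_traj(t, z)
  pk <- peak_heights(traj, detect_events(traj), trunk_height = 0.92)
  pr <- pk[pk$foot == "right", ]
  expect_equal(nrow(pr), 1)
  expect_equal(pr$height, 0.092, tolerance = 1e-3)
  expect_equal(pr$height_norm, 0.1, tolerance = 1e-3)
  expect_equal(pr$t_peak, 1, tolerance = 0.01)

  grounded_only <- synthetic_traj(t, rep(-0.01, length(t)))
  pk0 <- peak_heights(grounded_only, detect_events(grounded_only), 0.92)
  expect_equal(nrow(pk0[pk0$foot == "right", ]), 0)
})

test_that("mean velocity is displacement over duration", {
  traj <- tibble::tibble(t = seq(0, 10, 0.1), x_trunk = 2 * seq(0, 10, 0.1))
  expect_equal(mean_velocity(traj, c(0, 10)), 2)
  back <- tibble::tibble(t = 0:10, x_trunk = c(0:5, 4:0))
  expect_equal(mean_velocity(back, c(0, 10)), 0)
  expect_equal(mean_velocity(back, c(0, 5)), 1)
})

test_that("pearson correlation matches the textbook formula and cor.test", {
  x <- c(1, 2, 4, 7, 11)
  y <- c(0.8, 2.4, 3.7, 8.1, 10.2)
  got <- pearson_test(x, y)
  r_manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t_manual <- r_manual * sqrt((length(x) - 2) / (1 - r_manual^2))
  p_manual <- 2 * stats::pt(-abs(t_manual), length(x) - 2)
  expect_equal(got$r, r_manual, tolerance = 1e-12)
  expect_equal(got$df, length(x) - 2)
  expect_equal(got$p, p_manual, tolerance = 1e-12)

  expect_equal(pearson_test(1:10, 2 * (1:10) + 1)$r, 1)
  expect_equal(pearson_test(1:10, -(1:10))$r, -1)
  expect_error(pearson_test(rep(1, 5), 1:5), "variance")

  set.seed(9)
  for (i in 1:20) {
    x <- stats::rnorm(8); y <- stats::rnorm(8)
    rm <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(pearson_test(x, y)$r, rm, tolerance = 1e-10)
  }
})

test_that("unpaired t-test is the pooled-variance Student form", {
  x <- c(1.1, 2.3, 3.2)
  y <- c(2.0, 3.1, 4.4)
  got <- unpaired_t_test(x, y)
  sp2 <- ((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
    (length(x) + length(y) - 2)
  t_manual <- (mean(x) - mean(y)) /
    sqrt(sp2 * (1 / length(x) + 1 / length(y)))
  expect_equal(got$t, t_manual, tolerance = 1e-12)
  expect_equal(got$df, length(x) + length(y) - 2)
  expect_equal(got$p, 2 * stats::pt(-abs(t_manual), got$df), tolerance = 1e-12)

  same <- unpaired_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(unpaired_t_test(y, x)$t, -got$t)

  set.seed(10)
  for (i in 1:20) {
    x <- stats::rnorm(6); y <- stats::rnorm(7, 0.5)
    sp2 <- ((5) * stats::var(x) + (6) * stats::var(y)) / 11
    tm <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 6 + 1 / 7))
    expect_equal(unpaired_t_test(x, y)$t, tm, tolerance = 1e-10)
  }
})

test_that("event detection is invariant to mild decimation", {
  sim <- default_short_run()
  tr <- sim$trajectory
  ev1 <- detect_events(tr)
  ev2 <- detect_events(tr[seq(1, nrow(tr), by = 5), ])  # 5 ms sampling
  td1 <- ev1$t[ev1$event == "touchdown" & ev1$foot == "right"]
  td2 <- ev2$t[ev2$event == "touchdown" & ev2$foot == "right"]
  expect_equal(length(td1), length(td2))
  expect_equal(td1, td2, tolerance = 0.006)
})
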