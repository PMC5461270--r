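test_that("axis vectors follow the role and geometry conventions", {
  p <- sidestep_params()
  st <- sidestep_state(trunk = c(0, 0.92), rfoot = c(0.5, 0),
                       lfoot = c(-0.5, 0))
  ax <- axis_vectors(st, 1)
  expect_equal(unname(ax["interleg", ]), c(1, 0))        # trailing -> leading
  expect_equal(unname(ax["rleg", ]),
               c(-0.5, 0.92) / sqrt(0.5^2 + 0.92^2))     # foot -> trunk
  expect_equal(rowSums(ax^2), c(interleg = 1, rleg = 1, lleg = 1))

  # flipping the desired direction flips the inter-leg axis
  expect_equal(unname(axis_vectors(st, -1)["interleg", ]), c(-1, 0))

  bad <- sidestep_state(trunk = c(0.5, 0), rfoot = c(0.5, 0),
                        lfoot = c(-0.5, 0))
  expect_error(axis_vectors(bad, 1), "coincident")
})

test_that("leg switching coefficients implement the phase and override rules", {
  p <- sidestep_params()
  L0 <- p$L0_leg
  # grounded, no overrides: propulsion
  expect_equal(switching_coefficient_leg(TRUE, "posterior", 0.6, L0, p), 1)
  # flight halves the magnitude
  expect_equal(switching_coefficient_leg(FALSE, "posterior", 0.6, 0.9 * L0, p),
               0.5)
  # balance: anterior leg within 0.2 m, any phase
  expect_equal(switching_coefficient_leg(TRUE, "anterior", 0.15, L0, p), -1)
  expect_equal(switching_coefficient_leg(FALSE, "anterior", 0.15, L0, p), -0.5)
  # swing: over-extended posterior leg in flight, halved by the flight factor
  expect_equal(switching_coefficient_leg(FALSE, "posterior", 0.6, 1.05 * L0, p),
               -0.5)
  # same extension while grounded: no swing override
  expect_equal(switching_coefficient_leg(TRUE, "posterior", 0.6, 1.05 * L0, p),
               1)
})

test_that("inter-leg switching coefficient covers all phases", {
  p <- sidestep_params()
  L0 <- p$L0_leg
  expect_equal(
    switching_coefficient_interleg("double_support", TRUE, TRUE, L0, p), 0)
  expect_equal(
    switching_coefficient_interleg("double_flight", FALSE, FALSE, 0.5 * L0, p),
    0.5)
  expect_equal(
    switching_coefficient_interleg("double_flight", FALSE, FALSE, 0.7 * L0, p),
    -0.5)
  expect_equal(
    switching_coefficient_interleg("single_support", TRUE, FALSE, 0.7 * L0, p),
    -1)
  expect_equal(
    switching_coefficient_interleg("single_support", FALSE, TRUE, L0, p), 0)
})

test_that("local/residual split is exact and follows the projection", {
  lr <- local_residual(c(2, 0), c(1, 0), 1)
  expect_equal(lr$local, c(2, 0))
  expect_equal(lr$residual, c(0, 0))

  lr2 <- local_residual(c(2, 0), c(0, 1), 1)
  expect_equal(lr2$local, c(0, 0))
  expect_equal(lr2$residual, c(2, 0))

  lr3 <- local_residual(c(2, 0), c(1, 0), 0)
  expect_equal(lr3$local, c(0, 0))
  expect_equal(lr3$residual, c(2, 0))

  set.seed(4)
  for (i in 1:20) {
    vd <- stats::rnorm(2)
    ang <- stats::runif(1, 0, 2 * pi)
    sp <- local_residual(vd, c(cos(ang), sin(ang)),
                         sample(c(-1, -0.5, 0, 0.5, 1), 1))
    expect_equal(sp$local + sp$residual, vd, tolerance = 1e-14)
  }
})

test_that("mobility index matches its closed forms and stays in (0,1)", {
  p <- sidestep_params()
  expect_equal(mobility(c(1, 0), c(1, 0), p),
               exp(-4 * log(2) * 1e-10 / (1 + 1e-4)))
  expect_equal(mobility(c(1, 0), c(0, 0), p),
               exp(-4 * log(2) * (1 + 1e-10) / (1 + 1e-4)))
  expect_equal(mobility(c(1, 0), c(0, 0), p), 2^-4, tolerance = 1e-3)
  expect_equal(mobility(c(0, 0), c(0, 0), p),
               exp(-4 * log(2) * 1e-10 / 1e-4))
  set.seed(5)
  for (i in 1:50) {
    k <- mobility(stats::rnorm(2, 0, 3), stats::rnorm(2, 0, 3), p)
    expect_gt(k, 0)
    expect_lt(k, 1)
  }
})

test_that("cross requests and command mixing follow the projection algebra", {
  axes <- rbind(c(1, 0), c(0, 1), c(sqrt(0.5), sqrt(0.5)))
  residuals <- rbind(c(0, 1), c(1, 0), c(1, 1))
  req <- cross_requests(residuals, axes)
  expect_equal(req[1, 2, ], c(1, 0))         # parallel residual passes through
  expect_equal(req[2, 1, ], c(0, 1))
  expect_equal(req[1, 1, ], c(0, 0))         # no self-request

  # limits of the mixing rule
  locals <- rbind(c(1, 0), c(0, 1), c(0.5, 0.5))
  low <- combine_commands(locals, req, c(1e-12, 1e-12, 1e-12))
  expect_equal(low, locals, tolerance = 1e-9)
  high <- combine_commands(locals, req, c(1, 1, 1) - 1e-12)
  expect_equal(high[1, ], req[1, 2, ] + req[1, 3, ], tolerance = 1e-9)

  # random instance against direct evaluation
  set.seed(6)
  k <- stats::runif(3, 0.05, 0.95)
  mixed <- combine_commands(locals, req, k)
  for (i in 1:3) {
    js <- setdiff(1:3, i)
    expect_equal(mixed[i, ], prod(1 - k[js]) * locals[i, ] +
                   k[js[1]] * req[i, js[1], ] + k[js[2]] * req[i, js[2], ])
  }
})

test_that("actuator force is linear in the velocity error along the axis", {
  p <- sidestep_params()
  e <- c(1, 0)
  expect_equal(actuator_force(c(0.3, 0), c(0.3, 0), e, p), c(0, 0))
  f <- actuator_force(c(0.1, 0), c(0, 0), e, p)
  expect_equal(f, c(300, 0))  # gain 3000 kg/s times 0.1 m/s
  expect_equal(actuator_force(c(-0.1, 0), c(0, 0), e, p), -f)
})

test_that("control_step equals the straight-line oracle on random states", {
  p <- sidestep_params()
  set.seed(7)
  for (i in 1:200) {
    st <- random_state()
    vd <- sample(c(-2, 2), 1)
    got <- control_step(st, vd, p)
    want <- oracle_control(st, vd, p)
    expect_equal(unname(got$forces), unname(want$forces), tolerance = 1e-12)
    expect_equal(unlist(got$diagnostics[, c("a_1", "a_2", "a_3")],
                        use.names = FALSE), want$a)
    expect_equal(unlist(got$diagnostics[, c("k_1", "k_2", "k_3")],
                        use.names = FALSE), want$k, tolerance = 1e-12)
  }
})

test_that("control_step is mirror-equivariant to floating-point identity", {
  p <- sidestep_params()
  set.seed(8)
  for (i in 1:25) {
    st <- random_state()
    a <- control_step(st, 2, p)
    b <- control_step(mirror_state(st), -2, p)
    expect_identical(unname(a$forces), unname(mirror_forces(b$forces)))
    # the mirror map swaps the two legs, so k_2 and k_3 exchange
    expect_identical(unname(unlist(a$diagnostics[, c("k_1", "k_2", "k_3")])),
                     unname(unlist(b$diagnostics[, c("k_1", "k_3", "k_2")])))
  }
})

test_that("symmetric rest with zero command yields no net trunk push", {
  p <- sidestep_params()
  st <- make_initial_state(p)
  ctl <- control_step(st, 0, p)
  expect_equal(ctl$forces["trunk", "fx"], 0)
  expect_equal(sum(ctl$forces[, "fx"]), 0)   # internal: action-reaction
  expect_equal(sum(ctl$forces[, "fz"]), 0)
})

test_that("per-step invariants hold along a live run", {
  sim <- default_short_run()
  tr <- sim$trajectory
  expect_true(all(tr$a_1 %in% c(-1, -0.5, 0, 0.5, 1)))
  expect_true(all(tr$a_2 %in% c(-1, -0.5, 0, 0.5, 1)))
  expect_true(all(tr$a_3 %in% c(-1, -0.5, 0, 0.5, 1)))
  expect_true(all(tr$k_1 > 0 & tr$k_1 < 1))
  expect_true(all(tr$k_2 > 0 & tr$k_2 < 1))
  expect_true(all(tr$k_3 > 0 & tr$k_3 < 1))

  # Eq. 3 identity v_local + v_residual = v_d at machine precision on
  # states reconstructed from the log
  p <- sim$params
  rows <- tr[unique(round(seq(1, nrow(tr), length.out = 100))), ]
  for (j in seq_len(nrow(rows))) {
    r <- rows[j, ]
    st <- sidestep_state(t = r$t, trunk = c(r$x_trunk, r$z_trunk),
                         rfoot = c(r$x_rfoot, r$z_rfoot),
                         lfoot = c(r$x_lfoot, r$z_lfoot),
                         v_trunk = c(r$vx_trunk, r$vz_trunk),
                         v_rfoot = c(r$vx_rfoot, r$vz_rfoot),
                         v_lfoot = c(r$vx_lfoot, r$vz_lfoot))
    d <- control_step(st, r$vd_x, p)$diagnostics
    vsum <- d$v_local[[1]] + d$v_residual[[1]]
    expect_lt(max(abs(vsum - cbind(rep(r$vd_x, 3), 0))), 1e-12)
  }
})
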