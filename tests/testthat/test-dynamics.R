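test_that("contact classification reflects foot height and desired direction", {
  p <- sidestep_params()
  st <- make_initial_state(p)
  ct <- classify_contact(st, 1)
  expect_true(ct$grounded_r && ct$grounded_l)
  expect_equal(ct$phase, "double_support")
  expect_equal(ct$anterior, "right")

  air <- sidestep_state(trunk = c(0, 0.92), rfoot = c(0.5, 0.05),
                        lfoot = c(-0.5, 0.05))
  expect_equal(classify_contact(air, 1)$phase, "double_flight")

  # anterior assignment flips with the sign of the desired velocity
  expect_equal(classify_contact(st, -1)$anterior, "left")

  one <- sidestep_state(trunk = c(0, 0.9), rfoot = c(0.5, 0.02),
                        lfoot = c(-0.5, 0))
  expect_equal(classify_contact(one, 1)$phase, "single_support")
})

test_that("passive leg force: rest, contact stiffening, extension limit", {
  p <- sidestep_params()
  L0 <- p$L0_leg
  expect_equal(passive_leg_force(L0, 0, TRUE, p), 0)
  expect_equal(passive_leg_force(L0, 0, FALSE, p), 0)

  # same elongation: contact-phase force at least as large as flight-phase
  dL <- 0.05
  expect_gte(abs(passive_leg_force(L0 + dL, 0, TRUE, p)),
             abs(passive_leg_force(L0 + dL, 0, FALSE, p)))

  # stiffened branch exceeds the linear extrapolation of the base branch
  f_ext <- passive_leg_force(1.2 * L0, 0, FALSE, p)
  f_lin <- -p$k_leg_flight * 0.2 * L0
  expect_lt(f_ext, f_lin)  # both negative (restoring), stiffened is larger

  # continuity at the 1.1 L0 breakpoint
  eps <- 1e-9
  expect_equal(passive_leg_force(1.1 * L0 - eps, 0, TRUE, p),
               passive_leg_force(1.1 * L0 + eps, 0, TRUE, p),
               tolerance = 1e-6)

  expect_error(passive_leg_force(-0.1, 0, TRUE, p), "positive")
})

test_that("ground reaction is unilateral and clamped", {
  p <- sidestep_params()
  expect_equal(unname(ground_reaction(c(0, 0.01), c(0, 0), p)), c(0, 0))
  d <- 0.01
  f <- ground_reaction(c(0, -d), c(0, 0), p)
  expect_equal(unname(f), c(0, p$k_ground * d))
  # strong upward velocity: spring + damper would be negative, clamped to 0
  f2 <- ground_reaction(c(0, -0.001), c(0, 10), p)
  expect_equal(f2[["fz"]], 0)
  # horizontal viscous resistance while penetrating
  f3 <- ground_reaction(c(0, -0.001), c(2, 0), p)
  expect_equal(f3[["fx"]], -p$b_friction * 2)
})

test_that("auxiliary trunk force engages strictly inside the gap and is a pair", {
  p <- sidestep_params()
  far <- sidestep_state(trunk = c(0, 0.9), rfoot = c(0.3, 0), lfoot = c(-0.4, 0))
  expect_true(all(auxiliary_trunk_force(far, p) == 0))

  near <- sidestep_state(trunk = c(0, 0.9), rfoot = c(0.10, 0),
                         lfoot = c(-0.5, 0), v_trunk = c(0.5, 0))
  f <- auxiliary_trunk_force(near, p)
  expect_lt(f["trunk", "fx"], 0)             # repelled away from the near foot
  expect_equal(sum(f[, "fx"]), 0)            # action-reaction
  expect_equal(sum(abs(f[, "fz"])), 0)       # horizontal only

  boundary <- sidestep_state(trunk = c(0, 0.9), rfoot = c(0.15, 0),
                             lfoot = c(-0.5, 0))
  expect_true(all(auxiliary_trunk_force(boundary, p) == 0))
})

test_that("assembled passive forces match a term-by-term oracle", {
  p <- sidestep_params()
  st <- make_initial_state(p)
  f0 <- assemble_passive_forces(st, 1, p)
  expect_equal(f0["trunk", "fx"], 0)   # symmetric rest: no lateral trunk force

  set.seed(11)
  for (i in 1:25) {
    st <- random_state()
    expect_equal(assemble_passive_forces(st, 1, p), oracle_passive(st, 1, p),
                 tolerance = 1e-12)
  }
})

test_that("passive forces are mirror-equivariant to the bit", {
  p <- sidestep_params()
  set.seed(12)
  for (i in 1:10) {
    st <- random_state()
    f <- assemble_passive_forces(st, 1, p)
    fm <- assemble_passive_forces(mirror_state(st), -1, p)
    expect_identical(unname(f), unname(mirror_forces(fm)))
  }
})

test_that("forward Euler step follows the stated update", {
  p <- sidestep_params()
  st <- make_initial_state(p)

  # actuator forces exactly canceling gravity (passive forces vanish at the
  # rest posture): velocities unchanged, positions advance by v dt
  grav <- matrix(c(0, 0, 0, p$m_trunk * p$g, p$m_foot * p$g, p$m_foot * p$g),
                 3, 2)
  st1 <- step_dynamics(st, grav, p)
  expect_equal(unname(st1[-1]), unname(st[-1]))
  expect_equal(st1[["t"]], p$dt)

  # zero actuator force from a lifted symmetric posture: gravity only
  lift <- sidestep_state(trunk = c(0, 1.2), rfoot = c(0.5, 0.3),
                         lfoot = c(-0.5, 0.3))
  st2 <- step_dynamics(lift, matrix(0, 3, 2), p)
  dvz <- c(st2[["vz_trunk"]], st2[["vz_rfoot"]], st2[["vz_lfoot"]])
  # leg springs at that posture are nonzero, so isolate gravity by removing
  # the passive contribution analytically via the oracle
  fp <- oracle_passive(lift, 1, p)
  expected <- p$dt * (fp[, "fz"] / c(p$m_trunk, p$m_foot, p$m_foot) - p$g)
  expect_equal(unname(dvz), unname(expected), tolerance = 1e-12)

  expect_error(step_dynamics(st, matrix(Inf, 3, 2), p), "non-finite")
})

test_that("momentum change equals the accumulated external impulse", {
  p <- sidestep_params()
  warm <- run_sidestep(p, v_d = 2, duration = 0.5, log_diag = FALSE)
  st <- warm$final_state
  m <- c(p$m_trunk, p$m_foot, p$m_foot)

  momentum <- function(s) {
    c(sum(m * s[c("vx_trunk", "vx_rfoot", "vx_lfoot")]),
      sum(m * s[c("vz_trunk", "vz_rfoot", "vz_lfoot")]))
  }
  impulse <- c(0, 0)
  p0 <- momentum(st)
  n_steps <- 10000
  for (i in seq_len(n_steps)) {
    g_r <- ground_reaction(st[c("x_rfoot", "z_rfoot")],
                           st[c("vx_rfoot", "vz_rfoot")], p)
    g_l <- ground_reaction(st[c("x_lfoot", "z_lfoot")],
                           st[c("vx_lfoot", "vz_lfoot")], p)
    ext <- c(g_r[["fx"]] + g_l[["fx"]],
             g_r[["fz"]] + g_l[["fz"]] - sum(m) * p$g)
    impulse <- impulse + p$dt * ext
    fa <- sidestepr:::cpp_control_step(as.numeric(st), 2, p)$force_mass
    st <- step_dynamics(st, fa, p, 1)
  }
  dp <- momentum(st) - p0
  expect_equal(dp, impulse, tolerance = 1e-7)
})
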