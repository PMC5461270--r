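#' Actuator axis unit vectors
#'
#' The inter-leg axis points from the trailing (posterior) foot to the leading
#' (anterior) foot; each leg axis points from its foot to the trunk, so
#' positive actuator action drives the trunk along the axis.
#'
#' @param state state vector.
#' @param desired_dir sign of the desired lateral velocity.
#' @return A 3 x 2 matrix of unit vectors, rows `interleg`, `rleg`, `lleg`.
#' @examples
#' axis_vectors(make_initial_state(sidestep_params()), +1)
#' @export
axis_vectors <- function(state, desired_dir = 1) {
  s <- as.numeric(state)
  trunk <- s[2:3]; rfoot <- s[4:5]; lfoot <- s[6:7]
  ct <- classify_contact(state, desired_dir)
  ant <- if (ct$anterior == "right") rfoot else lfoot
  post <- if (ct$anterior == "right") lfoot else rfoot
  unit <- function(v) {
    n <- sqrt(sum(v^2))
    if (n == 0) stop("coincident actuator endpoints", call. = FALSE)
    v / n
  }
  out <- rbind(interleg = unit(ant - post),
               rleg = unit(trunk - rfoot),
               lleg = unit(trunk - lfoot))
  colnames(out) <- c("x", "z")
  out
}

#' Switching coefficient of a leg actuator
#'
#' The per-leg discrete role selector. Base value +1 (propulsion); the flight
#' phase halves the magnitude (the airborne leg cannot push the ground);
#' the balance rule (anterior leg with horizontal trunk-foot distance below
#' `d_balance`, in any phase) forces the sign negative; the swing rule
#' (posterior leg in flight, extended over its natural length) also forces
#' the sign negative. Balance takes precedence over swing; the two rules
#' target different legs so they never conflict in practice.
#'
#' @param grounded is the foot grounded?
#' @param role `"anterior"` or `"posterior"` relative to the desired direction.
#' @param trunk_foot_dx horizontal trunk-to-foot distance (m, nonnegative).
#' @param leg_length current leg length (m).
#' @param params a [sidestep_params()] object.
#' @return One of -1, -1/2, 1/2, 1.
#' @examples
#' p <- sidestep_params()
#' switching_coefficient_leg(TRUE, "posterior", 0.5, p$L0_leg, p)   # 1
#' switching_coefficient_leg(FALSE, "posterior", 0.5, 1.05 * p$L0_leg, p)
#' @export
switching_coefficient_leg <- function(grounded, role, trunk_foot_dx,
                                      leg_length, params) {
  stopifnot(role %in% c("anterior", "posterior"))
  sign <- 1
  if (role == "anterior" && trunk_foot_dx < params$d_balance) {
    sign <- -1
  } else if (role == "posterior" && !grounded && leg_length > params$L0_leg) {
    sign <- -1
  }
  sign * (if (grounded) 1 else 0.5)
}

#' Switching coefficient of the inter-leg actuator
#'
#' Zero in double support and in single support (no contribution to trunk
#' velocity while either leg is planted), +1/2 in double flight; retraction
#' override when the posterior leg is longer than `swing_ratio * L0`: -1
#' during anterior-leg support, -1/2 during double flight (the flight-phase
#' halving composes with the negative sign).
#'
#' @param phase `"double_support"`, `"single_support"`, or `"double_flight"`.
#' @param anterior_grounded,posterior_grounded grounded flags by role.
#' @param posterior_length posterior leg length (m).
#' @param params a [sidestep_params()] object.
#' @return One of -1, -1/2, 0, 1/2.
#' @examples
#' p <- sidestep_params()
#' switching_coefficient_interleg("double_support", TRUE, TRUE, p$L0_leg, p)
#' @export
switching_coefficient_interleg <- function(phase, anterior_grounded,
                                           posterior_grounded,
                                           posterior_length, params) {
  long_post <- posterior_length > params$swing_ratio * params$L0_leg
  if (phase == "double_support") {
    0
  } else if (phase == "double_flight") {
    if (long_post) -0.5 else 0.5
  } else {
    if (anterior_grounded && !posterior_grounded && long_post) -1 else 0
  }
}

#' Local / residual decomposition of the global command
#'
#' Splits the global desired velocity into the component actuator `i` can
#' generate along its own axis, scaled by the switching coefficient, and the
#' residual it must request from the other actuators:
#' `v_local = a * (e . v_d) e`, `v_residual = v_d - v_local`. The two parts
#' sum to the command exactly.
#'
#' @param v_d desired velocity 2-vector (m/s).
#' @param e_xi axis unit 2-vector.
#' @param a_i switching coefficient.
#' @return List with `local` and `residual` 2-vectors.
#' @examples
#' local_residual(c(2, 0), c(1, 0), 1)
#' @export
local_residual <- function(v_d, e_xi, a_i) {
  local <- a_i * sum(e_xi * v_d) * e_xi
  list(local = local, residual = v_d - local)
}

#' Velocity produced by an actuator at the trunk
#'
#' The velocity each actuator realizes at the trunk, projected onto its axis
#' and expressed as a 2-vector along that axis. For the legs this is the
#' trunk's velocity (the trunk is the leg's moving endpoint); the inter-leg
#' actuator spans the two feet and produces no trunk velocity directly, so
#' its produced velocity is identically zero.
#'
#' @param state state vector.
#' @param actuator `"interleg"`, `"rleg"`, or `"lleg"`.
#' @param desired_dir sign of the desired velocity (fixes leading/trailing).
#' @return Velocity 2-vector (m/s).
#' @examples
#' produced_velocity(make_initial_state(sidestep_params()), "rleg")
#' @export
produced_velocity <- function(state, actuator = c("interleg", "rleg", "lleg"),
                              desired_dir = 1) {
  actuator <- match.arg(actuator)
  if (actuator == "interleg") return(c(0, 0))
  s <- as.numeric(state)
  e <- axis_vectors(state, desired_dir)[actuator, ]
  v_trunk <- s[8:9]
  sum(v_trunk * e) * e
}

#' Mobility index
#'
#' `k = exp(-4 ln2 (||v_local - v_produced||^2 + eps1) /
#' (||v_local||^2 + eps2))`: the regularized ratio of dynamic to kinematic
#' mobility mapped through a half-decay exponential. Values near 1 mark a
#' mobile actuator (it achieves its local command), values near 0 an
#' immobile one. Strictly inside (0, 1) for finite inputs.
#'
#' @param v_local local desired velocity 2-vector.
#' @param v_produced produced velocity 2-vector.
#' @param params a [sidestep_params()] object (for `eps1`, `eps2`).
#' @return Scalar in (0, 1).
#' @examples
#' mobility(c(1, 0), c(0, 0), sidestep_params())  # ~ 2^-4
#' @export
mobility <- function(v_local, v_produced, params) {
  num <- sum((v_local - v_produced)^2) + params$eps1
  den <- sum(v_local^2) + params$eps2
  exp(-4 * log(2) * num / den)
}

#' Cross-actuator velocity requests
#'
#' The request from actuator `j` to actuator `i` is the projection of `j`'s
#' residual onto `i`'s axis: `v_ij = (e_i . r_j) e_i`.
#'
#' @param residuals 3 x 2 matrix of residual vectors (rows = actuators).
#' @param axes 3 x 2 matrix of axis unit vectors.
#' @return A 3 x 3 x 2 array; `[i, j, ]` is the request from `j` to `i`
#'   (diagonal zero).
#' @examples
#' ax <- rbind(c(1, 0), c(0, 1), c(1, 0))
#' cross_requests(matrix(1, 3, 2), ax)
#' @export
cross_requests <- function(residuals, axes) {
  out <- array(0, dim = c(3, 3, 2))
  for (i in 1:3) {
    for (j in 1:3) {
      if (i == j) next
      out[i, j, ] <- sum(axes[i, ] * residuals[j, ]) * axes[i, ]
    }
  }
  out
}

#' Mixed velocity command
#'
#' `v_cmd_i = prod_{j != i} (1 - k_j) v_local_i + sum_{j != i} k_j v_ij`:
#' mobile neighbours inhibit an actuator's own local command (first term) and
#' recruit it to serve their residuals (second term).
#'
#' @param locals 3 x 2 matrix of local desired velocities.
#' @param requests 3 x 3 x 2 request array from [cross_requests()].
#' @param mobilities length-3 vector of mobility indices.
#' @return 3 x 2 matrix of velocity commands.
#' @examples
#' req <- array(0, c(3, 3, 2))
#' combine_commands(matrix(1, 3, 2), req, c(0.5, 0.5, 0.5))
#' @export
combine_commands <- function(locals, requests, mobilities) {
  out <- matrix(0, 3, 2)
  for (i in 1:3) {
    js <- setdiff(1:3, i)
    inhib <- prod(1 - mobilities[js])
    excit <- mobilities[js[1]] * requests[i, js[1], ] +
      mobilities[js[2]] * requests[i, js[2], ]
    out[i, ] <- inhib * locals[i, ] + excit
  }
  out
}

#' Proportional actuator force
#'
#' `F = G (v_cmd - v_produced)`, applied along the actuator axis as an equal
#' and opposite pair on the actuator's two endpoint masses (net system force
#' zero).
#'
#' @param v_command mixed velocity command 2-vector.
#' @param v_produced produced velocity 2-vector.
#' @param e_xi axis unit vector.
#' @param params a [sidestep_params()] object (for `gain`).
#' @return Force 2-vector (N) along the axis, as applied to the axis-positive
#'   endpoint (trunk for the legs, leading foot for the inter-leg).
#' @examples
#' actuator_force(c(0.1, 0), c(0, 0), c(1, 0), sidestep_params())  # 300 N
#' @export
actuator_force <- function(v_command, v_produced, e_xi, params) {
  params$gain * sum((v_command - v_produced) * e_xi) * e_xi
}

#' One full control step
#'
#' Executes the switching-mobility pipeline in order — axes, switching
#' coefficients, local/residual split, produced velocities, mobility indices,
#' cross requests, command mixing, proportional forces — for the lateral
#' command `v_d = (v_d_x, 0)`, and returns the per-mass actuator forces with
#' full diagnostics.
#'
#' @param state state vector.
#' @param v_d_x desired lateral trunk velocity (m/s), signed.
#' @param params a [sidestep_params()] object.
#' @return A list: `forces` (3 x 2 per-mass matrix, N) and `diagnostics`, a
#'   one-row tibble with the axis vectors, `a_1..a_3`, `k_1..k_3`, local,
#'   residual, produced, and command velocities, axial force scalars, and the
#'   contact classification. Actuator order: inter-leg, right leg, left leg.
#' @examples
#' st <- make_initial_state(sidestep_params())
#' ctl <- control_step(st, 2, sidestep_params())
#' colSums(ctl$forces)   # internal forces: zero net system force
#' @export
control_step <- function(state, v_d_x, params) {
  raw <- cpp_control_step(as.numeric(state), v_d_x, params)
  forces <- raw$force_mass
  colnames(forces) <- c("fx", "fz")
  diag <- tibble::tibble(
    a_1 = raw$a[1], a_2 = raw$a[2], a_3 = raw$a[3],
    k_1 = raw$k[1], k_2 = raw$k[2], k_3 = raw$k[3],
    f_1 = raw$force_axial[1], f_2 = raw$force_axial[2],
    f_3 = raw$force_axial[3],
    phase = c("double_support", "single_support", "double_flight")[raw$phase + 1],
    anterior = c("right", "left")[raw$anterior],
    axes = list(raw$axes), v_local = list(raw$v_local),
    v_residual = list(raw$v_residual), v_produced = list(raw$v_produced),
    v_command = list(raw$v_command)
  )
  list(forces = forces, diagnostics = diag)
}
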