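#' System state of the three-mass model
#'
#' A state is a named numeric vector of length 13: time `t` followed by the
#' frontal-plane positions (`x_*`, `z_*`) and velocities (`vx_*`, `vz_*`) of
#' the trunk, right foot, and left foot.
#'
#' @param t time (s).
#' @param trunk,rfoot,lfoot position 2-vectors `c(x, z)` (m).
#' @param v_trunk,v_rfoot,v_lfoot velocity 2-vectors `c(vx, vz)` (m/s).
#' @return Named numeric state vector.
#' @examples
#' sidestep_state(trunk = c(0, 0.92), rfoot = c(0.53, 0), lfoot = c(-0.53, 0))
#' @export
sidestep_state <- function(t = 0, trunk, rfoot, lfoot,
                           v_trunk = c(0, 0), v_rfoot = c(0, 0),
                           v_lfoot = c(0, 0)) {
  s <- c(t, trunk, rfoot, lfoot, v_trunk, v_rfoot, v_lfoot)
  if (length(s) != 13 || !all(is.finite(s))) {
    stop("state requires finite 2-vectors for all positions and velocities",
         call. = FALSE)
  }
  names(s) <- c("t", "x_trunk", "z_trunk", "x_rfoot", "z_rfoot",
                "x_lfoot", "z_lfoot", "vx_trunk", "vz_trunk",
                "vx_rfoot", "vz_rfoot", "vx_lfoot", "vz_lfoot")
  s
}

#' Initial standing state
#'
#' The reference initial condition: all masses motionless, trunk at
#' `(0, trunk_height)`, feet on the ground symmetric about zero so the three
#' masses form an equilateral triangle (double-support stance, every actuator
#' at its natural length, hence zero initial spring force).
#'
#' @param params a [sidestep_params()] object.
#' @return Named numeric state vector.
#' @examples
#' make_initial_state(sidestep_params())
#' @export
make_initial_state <- function(params) {
  half <- params$trunk_height / sqrt(3)
  sidestep_state(
    t = 0,
    trunk = c(0, params$trunk_height),
    rfoot = c(half, 0),
    lfoot = c(-half, 0)
  )
}

#' Contact and role classification
#'
#' A foot is grounded iff its height is at or below ground level (z = 0). The
#' phase is double support, single support, or double flight accordingly. The
#' anterior (leading) foot is the one farther along the desired direction;
#' the assignment flips when the sign of the desired velocity flips.
#'
#' @param state state vector (see [sidestep_state()]).
#' @param desired_dir sign of the desired lateral velocity (+1 or -1).
#' @return A one-row tibble with `grounded_r`, `grounded_l`, `phase`
#'   (`"double_support"`, `"single_support"`, `"double_flight"`), and
#'   `anterior` (`"right"` or `"left"`).
#' @examples
#' st <- make_initial_state(sidestep_params())
#' classify_contact(st, +1)
#' @export
classify_contact <- function(state, desired_dir = 1) {
  dir <- if (desired_dir < 0) -1L else 1L
  raw <- cpp_classify_contact(as.numeric(state), dir)
  tibble::tibble(
    grounded_r = raw[["grounded_r"]] > 0,
    grounded_l = raw[["grounded_l"]] > 0,
    phase = c("double_support", "single_support", "double_flight")[raw[["phase"]] + 1],
    anterior = c("right", "left")[raw[["anterior"]]]
  )
}

#' Passive axial leg force
#'
#' Spring-damper force of one leg about its natural length `L0`. The elastic
#' coefficient takes the contact-phase value while the foot is grounded and
#' the flight value otherwise; elongation beyond `ext_ratio * L0` engages the
#' stiffened extension-limit branch, piecewise-linear and continuous at the
#' breakpoint. Positive values push the endpoints apart.
#'
#' @param length current leg length (m), positive.
#' @param lengthening_rate d(length)/dt (m/s).
#' @param grounded is the foot in ground contact?
#' @param params a [sidestep_params()] object.
#' @return Axial force (N), scalar.
#' @examples
#' p <- sidestep_params()
#' passive_leg_force(p$L0_leg, 0, grounded = TRUE, p)   # zero at rest
#' @export
passive_leg_force <- function(length, lengthening_rate, grounded, params) {
  vapply(seq_along(length), function(i) {
    cpp_leg_force(length[i], lengthening_rate[i], isTRUE(grounded), params)
  }, numeric(1))
}

#' Ground reaction force on one foot
#'
#' Unilateral viscoelastic ground: zero above ground level; while penetrating,
#' the vertical component is `max(0, -k_ground * z - b_ground * vz)` and the
#' horizontal component is viscous resistance `-b_friction * vx`.
#'
#' @param pos foot position `c(x, z)` (m).
#' @param vel foot velocity `c(vx, vz)` (m/s).
#' @param params a [sidestep_params()] object.
#' @return Named numeric force 2-vector `c(fx, fz)` (N).
#' @examples
#' ground_reaction(c(0, -0.01), c(0, 0), sidestep_params())
#' @export
ground_reaction <- function(pos, vel, params) {
  cpp_ground_reaction(as.numeric(pos), as.numeric(vel), params)
}

#' Auxiliary trunk viscoelasticity
#'
#' Fall-prevention force pair engaged when the horizontal distance between
#' the trunk and a foot is strictly below `d_aux` (0.15 m by default): a
#' spring on the gap deficit plus damping on the closing rate, applied
#' horizontally, equal and opposite on trunk and foot.
#'
#' @param state state vector.
#' @param params a [sidestep_params()] object.
#' @return A 3 x 2 matrix of per-mass horizontal/vertical forces (N), rows
#'   `trunk`, `rfoot`, `lfoot`.
#' @examples
#' st <- make_initial_state(sidestep_params())
#' auxiliary_trunk_force(st, sidestep_params())  # zero at the wide stance
#' @export
auxiliary_trunk_force <- function(state, params) {
  s <- as.numeric(state)
  f_r <- cpp_aux_gap_force(s[2] - s[4], s[8] - s[10], params)
  f_l <- cpp_aux_gap_force(s[2] - s[6], s[8] - s[12], params)
  out <- matrix(0, 3, 2, dimnames = list(c("trunk", "rfoot", "lfoot"),
                                         c("fx", "fz")))
  out["trunk", "fx"] <- f_r + f_l
  out["rfoot", "fx"] <- -f_r
  out["lfoot", "fx"] <- -f_l
  out
}

#' Assembled passive forces
#'
#' Sum of leg viscoelasticity (with the extension limit), inter-leg
#' spring-damper, ground reaction, and auxiliary trunk components per mass.
#' Gravity is excluded. All internal (actuator-axis and auxiliary) components
#' obey action-reaction, so they sum to zero over the system.
#'
#' @param state state vector.
#' @param desired_dir sign of the desired lateral velocity (used only for the
#'   contact classification carried along with the forces).
#' @param params a [sidestep_params()] object.
#' @return A 3 x 2 matrix of per-mass forces (N), rows `trunk`, `rfoot`,
#'   `lfoot`, columns `fx`, `fz`.
#' @examples
#' st <- make_initial_state(sidestep_params())
#' assemble_passive_forces(st, 1, sidestep_params())
#' @export
assemble_passive_forces <- function(state, desired_dir = 1, params) {
  dir <- if (desired_dir < 0) -1L else 1L
  cpp_passive_forces(as.numeric(state), dir, params)
}

#' One forward-Euler integration step
#'
#' Advances the state by `params$dt` under the equation of motion
#' `m x'' = F_actuator + m g + F_passive`, with passive forces assembled
#' internally and the actuator forces supplied by the caller. Forward Euler:
#' positions advance with the current velocities, velocities with the current
#' accelerations.
#'
#' @param state state vector.
#' @param actuator_forces 3 x 2 matrix of per-mass actuator forces (N), rows
#'   trunk / right foot / left foot.
#' @param params a [sidestep_params()] object.
#' @param desired_dir sign of the desired velocity (for the contact-dependent
#'   leg stiffness).
#' @return The updated state vector, `t` advanced by `dt`.
#' @examples
#' st <- make_initial_state(sidestep_params())
#' step_dynamics(st, matrix(0, 3, 2), sidestep_params())
#' @export
step_dynamics <- function(state, actuator_forces, params, desired_dir = 1) {
  stopifnot(is.matrix(actuator_forces), all(dim(actuator_forces) == c(3, 2)))
  if (!all(is.finite(actuator_forces))) {
    stop("non-finite actuator forces; state: ",
         paste(signif(as.numeric(state), 6), collapse = " "), call. = FALSE)
  }
  dir <- if (desired_dir < 0) -1L else 1L
  cpp_step_dynamics(as.numeric(state), actuator_forces, dir, params)
}
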