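#' Model parameters for the three-mass sidestep model
#'
#' Builds the validated parameter set used by every simulation function. The
#' defaults define the package's reference configuration: a trunk-dominant
#' human-like mass split, leg and ground viscoelasticity tuned so that the
#' default model locomotes laterally and changes direction at every tested
#' timing, and the controller constants (proportional gain 3000 kg/s,
#' regularizers 1e-10 / 1e-4, time step 1e-5 s) of the switching mobility
#' scheme. Thresholds use strict inequalities everywhere.
#'
#' Geometry: the three masses rest in an equilateral triangle with the trunk
#' apex at `trunk_height`, so the natural length of each leg actuator and of
#' the inter-leg actuator is `2 * trunk_height / sqrt(3)`.
#'
#' @param trunk_height initial vertical trunk position (m); also sets the
#'   natural actuator lengths via the equilateral-triangle rest posture.
#' @param m_trunk,m_foot trunk and per-foot point masses (kg).
#' @param g gravitational acceleration (m/s^2).
#' @param k_leg_flight,k_leg_contact leg elastic coefficient in the flight and
#'   ground-contact phases (N/m); contact must be at least the flight value.
#' @param b_leg leg damping coefficient (N s/m).
#' @param ext_mult multiplier applied to the leg elastic coefficient for
#'   elongation beyond `ext_ratio * L0` (extension limit, continuous at the
#'   breakpoint).
#' @param ext_ratio elongation ratio triggering the stiffened branch.
#' @param k_inter,b_inter inter-leg (hip ab/adductor) elasticity and damping.
#' @param k_ground,b_ground vertical ground stiffness and damping (unilateral
#'   Kelvin-Voigt, clamped at zero).
#' @param b_friction horizontal viscous ground resistance while grounded.
#' @param k_aux,b_aux auxiliary trunk viscoelasticity engaged when the
#'   horizontal trunk-foot distance falls below `d_aux`.
#' @param d_aux engagement distance of the auxiliary trunk force (m).
#' @param d_balance horizontal trunk-to-anterior-foot distance below which the
#'   anterior leg switches to balancing (m).
#' @param swing_ratio posterior-leg length ratio (of `L0`) above which the
#'   inter-leg actuator switches to swing retraction.
#' @param gain proportional gain G of every actuator (kg/s).
#' @param eps1,eps2 regularizers in the mobility index.
#' @param dt integrator time step (s), forward Euler.
#' @param fall_z trunk height below which a run counts as a fall (m).
#'
#' @return A named list of class `"sidestep_params"` including the derived
#'   natural lengths `L0_leg` and `L0_inter`.
#' @examples
#' p <- sidestep_params()
#' p$L0_leg
#' @export
sidestep_params <- function(trunk_height = 0.92,
                            m_trunk = 48,
                            m_foot = 12,
                            g = 9.8,
                            k_leg_flight = 6000,
                            k_leg_contact = 16000,
                            b_leg = 350,
                            ext_mult = 10,
                            ext_ratio = 1.1,
                            k_inter = 10000,
                            b_inter = 2000,
                            k_ground = 30000,
                            b_ground = 2500,
                            b_friction = 20000,
                            k_aux = 6000,
                            b_aux = 300,
                            d_aux = 0.15,
                            d_balance = 0.2,
                            swing_ratio = 0.6,
                            gain = 3000,
                            eps1 = 1e-10,
                            eps2 = 1e-4,
                            dt = 1e-5,
                            fall_z = 0.4) {
  p <- list(
    trunk_height = trunk_height, m_trunk = m_trunk, m_foot = m_foot, g = g,
    L0_leg = 2 * trunk_height / sqrt(3), L0_inter = 2 * trunk_height / sqrt(3),
    k_leg_flight = k_leg_flight, k_leg_contact = k_leg_contact, b_leg = b_leg,
    ext_mult = ext_mult, ext_ratio = ext_ratio,
    k_inter = k_inter, b_inter = b_inter,
    k_ground = k_ground, b_ground = b_ground, b_friction = b_friction,
    k_aux = k_aux, b_aux = b_aux, d_aux = d_aux,
    d_balance = d_balance, swing_ratio = swing_ratio,
    gain = gain, eps1 = eps1, eps2 = eps2, dt = dt, fall_z = fall_z
  )
  validate_params(p)
  structure(p, class = "sidestep_params")
}

validate_params <- function(p) {
  positive <- c(
    "trunk_height", "m_trunk", "m_foot", "g", "L0_leg", "L0_inter",
    "k_leg_flight", "k_leg_contact", "b_leg", "ext_mult", "ext_ratio",
    "k_inter", "b_inter", "k_ground", "b_ground", "b_friction",
    "k_aux", "b_aux", "d_aux", "d_balance", "swing_ratio", "gain",
    "eps1", "eps2", "dt", "fall_z"
  )
  bad <- positive[!vapply(p[positive], function(v) {
    is.numeric(v) && length(v) == 1 && is.finite(v) && v > 0
  }, logical(1))]
  if (length(bad) > 0) {
    stop("parameters must be positive finite scalars: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (p$k_leg_contact < p$k_leg_flight) {
    stop("contact-phase leg elasticity must be >= flight-phase elasticity",
         call. = FALSE)
  }
  invisible(p)
}

#' @export
print.sidestep_params <- function(x, ...) {
  cat("<sidestep_params>\n")
  cat(sprintf("  masses: trunk %.3g kg, feet %.3g kg each; g = %.3g m/s^2\n",
              x$m_trunk, x$m_foot, x$g))
  cat(sprintf("  rest posture: trunk at %.3g m, natural length %.4g m\n",
              x$trunk_height, x$L0_leg))
  cat(sprintf("  leg: k = %.4g (flight) / %.4g (contact) N/m, b = %.4g N s/m\n",
              x$k_leg_flight, x$k_leg_contact, x$b_leg))
  cat(sprintf("  extension limit: x%.3g beyond %.3g L0\n",
              x$ext_mult, x$ext_ratio))
  cat(sprintf("  inter-leg: k = %.4g N/m, b = %.4g N s/m\n",
              x$k_inter, x$b_inter))
  cat(sprintf("  ground: k = %.4g, b = %.4g (vertical), b = %.4g (horizontal)\n",
              x$k_ground, x$b_ground, x$b_friction))
  cat(sprintf("  auxiliary trunk: k = %.4g, b = %.4g inside %.3g m\n",
              x$k_aux, x$b_aux, x$d_aux))
  cat(sprintf("  controller: gain %.4g kg/s, balance %.3g m, swing %.3g L0\n",
              x$gain, x$d_balance, x$swing_ratio))
  cat(sprintf("  integration: forward Euler, dt = %.3g s; fall below %.3g m\n",
              x$dt, x$fall_z))
  invisible(x)
}

#' Modify a parameter set
#'
#' Returns a copy of `params` with the named values replaced and the result
#' re-validated. Used by the sensitivity sweep to scale single parameters.
#'
#' @param params a `sidestep_params` object.
#' @param ... named replacement values.
#' @return A validated `sidestep_params` object.
#' @examples
#' p <- update_params(sidestep_params(), gain = 6000)
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "sidestep_params"))
  repl <- list(...)
  unknown <- setdiff(names(repl), names(params))
  if (length(unknown) > 0) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  params[names(repl)] <- repl
  validate_params(params)
  structure(params, class = "sidestep_params")
}
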