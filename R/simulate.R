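traj_tibble <- function(mat, log_diag) {
  base <- c("t", "x_trunk", "z_trunk", "x_rfoot", "z_rfoot", "x_lfoot",
            "z_lfoot", "vx_trunk", "vz_trunk", "vx_rfoot", "vz_rfoot",
            "vx_lfoot", "vz_lfoot", "grounded_r", "grounded_l")
  diagc <- c("phase", "anterior", "a_1", "a_2", "a_3", "k_1", "k_2", "k_3",
             "vd_x")
  colnames(mat) <- if (log_diag) c(base, diagc) else base
  out <- tibble::as_tibble(mat)
  out$grounded_r <- out$grounded_r > 0
  out$grounded_l <- out$grounded_l > 0
  if (log_diag) {
    out$phase <- c("double_support", "single_support",
                   "double_flight")[out$phase + 1]
    out$anterior <- c("right", "left")[out$anterior]
  }
  out
}

status_label <- function(code) {
  c("completed", "reached", "fell", "diverged")[code + 1]
}

#' Run a sidestep simulation
#'
#' Fixed-step simulation of the three-mass model under a constant lateral
#' velocity command (optionally switching sign once at `t_switch`),
#' interleaving one control step and one forward-Euler dynamics step at every
#' `dt`. The run terminates at `duration`, at a fall (trunk below the fall
#' threshold), or at numerical divergence; the trajectory is logged at a
#' configurable decimation.
#'
#' @param params a [sidestep_params()] object.
#' @param v_d desired lateral trunk velocity (m/s), signed; held constant
#'   unless `t_switch` is given.
#' @param duration simulated time horizon (s).
#' @param t_switch optional time at which the command switches to
#'   `v_d_post` (s); `NULL` for a constant command.
#' @param v_d_post post-switch command (m/s), default `-v_d`.
#' @param state0 initial state; defaults to [make_initial_state()].
#' @param log_dt trajectory logging interval (s); must be a multiple of
#'   `params$dt`. Default 1e-3 s.
#' @param log_diag also log controller diagnostics (phase, roles, switching
#'   coefficients, mobility indices, active command)? Default `TRUE`.
#' @return An object of class `"sidestep_sim"`: a list with `trajectory`
#'   (tibble, one row per logged sample), `status` (`"completed"`, `"fell"`,
#'   or `"diverged"`), `fall_time`, `final_state`, and `params`.
#' @examples
#' sim <- run_sidestep(sidestep_params(), v_d = 2, duration = 0.05)
#' sim$trajectory
#' @export
run_sidestep <- function(params, v_d = 2, duration = 5, t_switch = NULL,
                         v_d_post = -v_d, state0 = make_initial_state(params),
                         log_dt = 1e-3, log_diag = TRUE) {
  stopifnot(inherits(params, "sidestep_params"), duration > 0)
  log_every <- as.integer(round(log_dt / params$dt))
  if (log_every < 1 || abs(log_every * params$dt - log_dt) > 1e-12) {
    stop("log_dt must be a positive multiple of params$dt", call. = FALSE)
  }
  raw <- cpp_simulate(as.numeric(state0), params, v_d,
                      if (is.null(t_switch)) NA_real_ else t_switch,
                      v_d_post, duration, NA_real_, log_every, log_diag)
  structure(list(
    trajectory = traj_tibble(raw$trajectory, log_diag),
    status = status_label(raw$status),
    fall_time = raw$fall_time,
    final_state = raw$final_state,
    t_switch = raw$t_switch,
    params = params
  ), class = "sidestep_sim")
}

#' @export
print.sidestep_sim <- function(x, ...) {
  tr <- x$trajectory
  cat(sprintf("<sidestep_sim> %s, %.3f s simulated, %d logged samples\n",
              x$status, max(tr$t) - min(tr$t), nrow(tr)))
  cat(sprintf("  trunk lateral displacement: %+.3f m\n",
              tr$x_trunk[nrow(tr)] - tr$x_trunk[1]))
  invisible(x)
}

#' One direction-change trial
#'
#' Runs the model at `v_d = +target_speed` until `t_switch`, then switches
#' the command to `-target_speed` and continues until the trunk has moved
#' `reach_dist` (2 m) in the new direction relative to its lateral position
#' at the switch instant. The reaching time is that interval, resolved at the
#' integrator step. A trial fails on a fall or when the cap
#' (`t_switch + timeout`) passes without reaching.
#'
#' @param params a [sidestep_params()] object.
#' @param t_switch command switch time (s), positive.
#' @param target_speed magnitude of the desired lateral velocity (m/s).
#' @param reach_dist displacement defining task completion (m).
#' @param timeout post-switch time cap (s).
#' @param log_dt,log_diag trajectory logging controls, as in
#'   [run_sidestep()].
#' @return An object of class `"sidestep_trial"`: a list with the one-row
#'   summary tibble `result` (`t_switch`, `reach_time`, `success`, `fall`,
#'   `timeout`, `trailing_stance` — was the pre-switch trailing foot grounded
#'   at the switch instant — plus per-foot post-switch step counts and peak
#'   foot heights), the full `trajectory`, and `params`.
#' @examples
#' \donttest{
#' tr <- direction_change_trial(sidestep_params(), t_switch = 1.5)
#' tr$result
#' }
#' @export
direction_change_trial <- function(params, t_switch, target_speed = 2,
                                   reach_dist = 2, timeout = 15,
                                   log_dt = 1e-3, log_diag = FALSE) {
  stopifnot(inherits(params, "sidestep_params"), t_switch > 0)
  log_every <- as.integer(round(log_dt / params$dt))
  raw <- cpp_simulate(as.numeric(make_initial_state(params)), params,
                      target_speed, t_switch, -target_speed,
                      t_switch + timeout, reach_dist, log_every, log_diag)
  trajectory <- traj_tibble(raw$trajectory, log_diag)
  success <- raw$status == 1
  fall <- raw$status %in% c(2, 3)
  # pre-switch trailing foot: the posterior foot w.r.t. the initial command
  trailing_grounded <- if (target_speed >= 0) raw$grounded_l_at_switch
                       else raw$grounded_r_at_switch

  reach_time <- if (success) raw$reach_time else NA_real_
  counts <- c(right = NA_real_, left = NA_real_)
  peaks <- c(right = NA_real_, left = NA_real_)
  if (success) {
    events <- detect_events(trajectory)
    window <- c(t_switch, t_switch + reach_time)
    counts <- count_steps(events, window)
    pk <- peak_heights(trajectory, events, trunk_height = params$trunk_height)
    for (ft in c("right", "left")) {
      sel <- pk$foot == ft & pk$t_peak >= window[1] & pk$t_peak < window[2]
      peaks[ft] <- if (any(sel)) max(pk$height[sel]) else 0
    }
  }
  result <- tibble::tibble(
    t_switch = t_switch,
    reach_time = reach_time,
    success = success,
    fall = fall,
    timeout = raw$status == 0,
    trailing_stance = trailing_grounded > 0,
    steps_rfoot = counts[["right"]],
    steps_lfoot = counts[["left"]],
    peak_rfoot = peaks[["right"]],
    peak_lfoot = peaks[["left"]]
  )
  structure(list(result = result, trajectory = trajectory, params = params),
            class = "sidestep_trial")
}

#' @export
print.sidestep_trial <- function(x, ...) {
  r <- x$result
  cat(sprintf("<sidestep_trial> switch at %.3f s: %s\n", r$t_switch,
              if (r$success) sprintf("reached in %.3f s", r$reach_time)
              else if (r$fall) "fell" else "timed out"))
  invisible(x)
}
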