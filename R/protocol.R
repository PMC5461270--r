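#' Direction-change timing sweep
#'
#' Runs [direction_change_trial()] at `n` switch times `t_start + (j-1) *
#' spacing`, labels each trial by the contact phase at the switch instant
#' (trailing-foot-grounded vs other), and aggregates the reaching-time
#' statistics. Trial failures (falls, timeouts) are recorded in the result
#' table, not raised.
#'
#' @param params a [sidestep_params()] object.
#' @param t_start first switch time (s).
#' @param spacing grid spacing (s), default 0.03.
#' @param n number of trials, default 101.
#' @param target_speed,reach_dist,timeout forwarded to
#'   [direction_change_trial()].
#' @param keep_trajectories keep each trial's trajectory in the result
#'   (memory-heavy)? Default `FALSE`.
#' @param progress print one line per trial? Default `FALSE`.
#' @return An object of class `"sidestep_sweep"`: list with `trials` (tibble,
#'   one row per trial), `params`, and the sweep settings.
#' @examples
#' \donttest{
#' sw <- sweep_timings(sidestep_params(), n = 3)
#' sw$trials
#' }
#' @export
sweep_timings <- function(params, t_start = 1.5, spacing = 0.03, n = 101,
                          target_speed = 2, reach_dist = 2, timeout = 15,
                          keep_trajectories = FALSE, progress = FALSE) {
  stopifnot(n >= 2, spacing > 0, t_start > 0)
  switch_times <- t_start + (seq_len(n) - 1) * spacing
  trials <- purrr::map(switch_times, function(ts) {
    tr <- direction_change_trial(params, ts, target_speed = target_speed,
                                 reach_dist = reach_dist, timeout = timeout)
    if (progress) {
      message(sprintf("t_switch = %.3f s: %s", ts,
                      if (tr$result$success)
                        sprintf("reached in %.3f s", tr$result$reach_time)
                      else "failed"))
    }
    if (keep_trajectories) tr else tr["result"]
  })
  result <- purrr::list_rbind(purrr::map(trials, "result"))
  structure(list(
    trials = result,
    trajectories = if (keep_trajectories) purrr::map(trials, "trajectory"),
    params = params,
    t_start = t_start, spacing = spacing, n = n,
    target_speed = target_speed, reach_dist = reach_dist, timeout = timeout
  ), class = "sidestep_sweep")
}

#' @export
print.sidestep_sweep <- function(x, ...) {
  tr <- x$trials
  cat(sprintf("<sidestep_sweep> %d trials, switch %.3f..%.3f s (step %.3f s)\n",
              nrow(tr), min(tr$t_switch), max(tr$t_switch), x$spacing))
  cat(sprintf("  success %d/%d; reaching time %.3f +/- %.3f s\n",
              sum(tr$success), nrow(tr), mean(tr$reach_time, na.rm = TRUE),
              stats::sd(tr$reach_time, na.rm = TRUE)))
  invisible(x)
}

#' Parameter-sensitivity sweep
#'
#' Scales one parameter group — leg elasticity (flight and contact together),
#' ground elasticity, or the actuator gain — by each factor in `factors`
#' (default the half-decade grid 10^-1, 10^-1/2, 1, 10^1/2, 10) and reruns a
#' reduced direction-change timing sweep per condition, reporting whether the
#' direction change succeeded at every tested timing.
#'
#' @param params a [sidestep_params()] object.
#' @param which `"leg_elasticity"`, `"ground_elasticity"`, or `"gain"`; any
#'   subset, default all three.
#' @param factors positive multipliers, default `10^seq(-1, 1, by = 0.5)`.
#' @param n_timings trials per condition (default 10, spanning the same grid
#'   span as the full sweep with coarser spacing).
#' @param t_start,spacing timing grid controls; `spacing` here is the reduced
#'   grid spacing, default chosen so `n_timings` trials span the full sweep.
#' @param ... forwarded to [sweep_timings()].
#' @return A tibble with one row per (parameter, factor): success counts and
#'   an `all_success` flag.
#' @examples
#' \donttest{
#' sensitivity_sweep(sidestep_params(), which = "gain", factors = 1,
#'                   n_timings = 2)
#' }
#' @export
sensitivity_sweep <- function(params,
                              which = c("leg_elasticity", "ground_elasticity",
                                        "gain"),
                              factors = 10^seq(-1, 1, by = 0.5),
                              n_timings = 10, t_start = 1.5,
                              spacing = 0.33, ...) {
  which <- match.arg(which, several.ok = TRUE)
  stopifnot(all(factors > 0))
  grid <- tidyr::expand_grid(parameter = which, factor = factors)
  rows <- purrr::pmap(grid, function(parameter, factor) {
    p <- switch(parameter,
      leg_elasticity = update_params(params,
        k_leg_flight = params$k_leg_flight * factor,
        k_leg_contact = params$k_leg_contact * factor),
      ground_elasticity = update_params(params,
        k_ground = params$k_ground * factor),
      gain = update_params(params, gain = params$gain * factor)
    )
    sw <- sweep_timings(p, t_start = t_start, spacing = spacing,
                        n = n_timings, ...)
    tibble::tibble(
      parameter = parameter, factor = factor,
      n_trials = nrow(sw$trials),
      n_success = sum(sw$trials$success),
      all_success = all(sw$trials$success),
      mean_reach_time = mean(sw$trials$reach_time, na.rm = TRUE)
    )
  })
  purrr::list_rbind(rows)
}
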