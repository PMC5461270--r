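#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a simulation, trial, or sweep
#'
#' `tidy()` returns the per-sample, per-trial, or per-event observations of a
#' result object as a tibble; `glance()` returns a one-row summary.
#'
#' @param x a `sidestep_sim`, `sidestep_trial`, or `sidestep_sweep` object.
#' @param ... unused.
#' @return A tibble.
#' @name sidestep-tidiers
NULL

#' @rdname sidestep-tidiers
#' @export
tidy.sidestep_sim <- function(x, ...) x$trajectory

#' @rdname sidestep-tidiers
#' @export
glance.sidestep_sim <- function(x, ...) {
  tr <- x$trajectory
  tibble::tibble(
    status = x$status,
    duration = max(tr$t) - min(tr$t),
    displacement = tr$x_trunk[nrow(tr)] - tr$x_trunk[1],
    mean_speed = abs(tr$x_trunk[nrow(tr)] - tr$x_trunk[1]) /
      (max(tr$t) - min(tr$t)),
    n_samples = nrow(tr)
  )
}

#' @rdname sidestep-tidiers
#' @export
tidy.sidestep_trial <- function(x, ...) x$result

#' @rdname sidestep-tidiers
#' @export
glance.sidestep_trial <- function(x, ...) x$result

#' @rdname sidestep-tidiers
#' @export
tidy.sidestep_sweep <- function(x, ...) x$trials

#' @rdname sidestep-tidiers
#' @export
glance.sidestep_sweep <- function(x, ...) {
  tr <- x$trials
  grp <- function(sel) tr$reach_time[sel & tr$success]
  tibble::tibble(
    n = nrow(tr),
    n_success = sum(tr$success),
    n_fall = sum(tr$fall),
    n_timeout = sum(tr$timeout),
    mean_reach_time = mean(tr$reach_time, na.rm = TRUE),
    sd_reach_time = stats::sd(tr$reach_time, na.rm = TRUE),
    mean_reach_trailing = mean(grp(tr$trailing_stance)),
    mean_reach_other = mean(grp(!tr$trailing_stance))
  )
}
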