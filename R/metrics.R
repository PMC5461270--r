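#' Gait event detection
#'
#' Extracts touchdown (airborne-to-grounded) and liftoff
#' (grounded-to-airborne) times per foot from a uniformly sampled trajectory,
#' using the logged contact flags (foot height at or below ground level).
#' Contact or flight episodes shorter than the debounce window are treated as
#' chatter and merged into the surrounding episode, so touchdowns and
#' liftoffs strictly alternate.
#'
#' @param trajectory trajectory tibble from [run_sidestep()] or
#'   [direction_change_trial()] (columns `t`, `grounded_r`, `grounded_l`).
#' @param debounce minimum episode duration (s), default 0.02.
#' @return A tibble with columns `foot` (`"right"`/`"left"`), `event`
#'   (`"touchdown"`/`"liftoff"`), and `t`, ordered by foot then time.
#' @examples
#' traj <- tibble::tibble(t = seq(0, 1, 0.01),
#'                        grounded_r = rep(c(TRUE, FALSE), each = 50)[1:101],
#'                        grounded_l = TRUE)
#' detect_events(traj)
#' @export
detect_events <- function(trajectory, debounce = 0.02) {
  stopifnot(all(c("t", "grounded_r", "grounded_l") %in% names(trajectory)))
  one_foot <- function(t, grounded) {
    g <- as.logical(grounded)
    dt_samp <- stats::median(diff(t))
    # iteratively absorb the shortest interior episode below the debounce
    # window into its surroundings until none remain
    repeat {
      r <- rle(g)
      if (length(r$lengths) <= 2) break
      interior <- 2:(length(r$lengths) - 1)
      short <- interior[r$lengths[interior] * dt_samp < debounce]
      if (length(short) == 0) break
      i <- short[which.min(r$lengths[short])]
      ends <- cumsum(r$lengths)
      starts <- c(1, utils::head(ends, -1) + 1)
      g[starts[i]:ends[i]] <- !r$values[i]
    }
    r <- rle(g)
    if (length(r$lengths) < 2) {
      return(tibble::tibble(event = character(0), t = numeric(0)))
    }
    ends <- cumsum(r$lengths)
    starts <- c(1, utils::head(ends, -1) + 1)
    tibble::tibble(event = ifelse(r$values[-1], "touchdown", "liftoff"),
                   t = t[starts[-1]])
  }
  out <- dplyr::bind_rows(
    dplyr::mutate(one_foot(trajectory$t, trajectory$grounded_r),
                  foot = "right"),
    dplyr::mutate(one_foot(trajectory$t, trajectory$grounded_l),
                  foot = "left")
  )
  dplyr::arrange(dplyr::select(out, foot, event, t), foot, t)
}

#' Step intervals and their statistics
#'
#' A step interval is the time between successive touchdowns of the same
#' foot. `steps` selects a 1-based range of steps per foot — e.g. the default
#' `c(11, 100)` keeps the 90 intervals that end with touchdowns 11 through
#' 100, skipping the transient at simulation start.
#'
#' @param events event tibble from [detect_events()].
#' @param steps integer range `c(first, last)` of touchdown indices whose
#'   closing intervals to keep; `NULL` keeps all.
#' @return A list with `intervals` (tibble: `foot`, `step`, `interval`) and
#'   `summary` (tibble: per-foot `n`, `mean`, `sd`, `cv`). If a foot has
#'   fewer touchdowns than `steps[2]`, its `shortfall` column reports how
#'   many are missing.
#' @examples
#' ev <- tibble::tibble(foot = "right", event = "touchdown",
#'                      t = seq(0, 5, 0.5))
#' step_intervals(ev, steps = c(2, 11))$summary
#' @export
step_intervals <- function(events, steps = c(11, 100)) {
  td <- dplyr::filter(events, event == "touchdown")
  per_foot <- function(d) {
    tt <- sort(d$t)
    n_td <- length(tt)
    iv <- tibble::tibble(step = seq_len(max(n_td - 1, 0)) + 1,
                         interval = diff(tt))
    shortfall <- 0L
    if (!is.null(steps)) {
      if (n_td < steps[2]) shortfall <- as.integer(steps[2] - n_td)
      iv <- dplyr::filter(iv, step >= steps[1], step <= steps[2])
    }
    list(iv = iv, shortfall = shortfall)
  }
  res <- lapply(split(td, td$foot), per_foot)
  intervals <- purrr::list_rbind(
    purrr::imap(res, function(r, ft) dplyr::mutate(r$iv, foot = ft,
                                                   .before = 1)))
  summary <- purrr::list_rbind(purrr::imap(res, function(r, ft) {
    tibble::tibble(
      foot = ft, n = nrow(r$iv),
      mean = mean(r$iv$interval), sd = stats::sd(r$iv$interval),
      cv = stats::sd(r$iv$interval) / mean(r$iv$interval),
      shortfall = r$shortfall
    )
  }))
  list(intervals = intervals, summary = summary)
}

#' Count steps in a time window
#'
#' Number of touchdowns per foot inside the half-open window
#' `[window[1], window[2])`; an event exactly at the window start counts, one
#' at the end does not.
#'
#' @param events event tibble from [detect_events()].
#' @param window numeric `c(start, end)` (s).
#' @return Named numeric vector `c(right = ..., left = ...)`.
#' @examples
#' ev <- tibble::tibble(foot = "left", event = "touchdown", t = c(1, 2, 3))
#' count_steps(ev, c(1, 3))
#' @export
count_steps <- function(events, window) {
  td <- dplyr::filter(events, event == "touchdown",
                      t >= window[1], t < window[2])
  c(right = sum(td$foot == "right"), left = sum(td$foot == "left"))
}

#' Peak foot heights per flight phase
#'
#' For each airborne episode of each foot (liftoff to the next touchdown),
#' the maximum vertical foot position, optionally normalized by the trunk
#' height for histogram use.
#'
#' @param trajectory trajectory tibble (columns `t`, `z_rfoot`, `z_lfoot`).
#' @param events event tibble from [detect_events()].
#' @param trunk_height normalization constant (m); peaks are reported both
#'   raw and normalized.
#' @return A tibble: `foot`, `t_liftoff`, `t_touchdown`, `t_peak`, `height`
#'   (m), `height_norm`.
#' @examples
#' p <- sidestep_params()
#' \donttest{
#' sim <- run_sidestep(p, v_d = 2, duration = 2)
#' peak_heights(sim$trajectory, detect_events(sim$trajectory),
#'              trunk_height = p$trunk_height)
#' }
#' @export
peak_heights <- function(trajectory, events, trunk_height = 0.92) {
  per_foot <- function(ft) {
    zcol <- if (ft == "right") trajectory$z_rfoot else trajectory$z_lfoot
    ev <- dplyr::arrange(dplyr::filter(events, foot == ft), t)
    lo <- ev$t[ev$event == "liftoff"]
    rows <- purrr::map(lo, function(t0) {
      tds <- ev$t[ev$event == "touchdown" & ev$t > t0]
      t1 <- if (length(tds) > 0) min(tds) else max(trajectory$t)
      sel <- trajectory$t >= t0 & trajectory$t <= t1
      if (!any(sel)) return(NULL)
      i <- which(sel)[which.max(zcol[sel])]
      tibble::tibble(foot = ft, t_liftoff = t0,
                     t_touchdown = if (length(tds) > 0) t1 else NA_real_,
                     t_peak = trajectory$t[i], height = zcol[i],
                     height_norm = zcol[i] / trunk_height)
    })
    purrr::list_rbind(purrr::compact(rows))
  }
  out <- dplyr::bind_rows(per_foot("right"), per_foot("left"))
  if (nrow(out) == 0) {
    out <- tibble::tibble(foot = character(0), t_liftoff = numeric(0),
                          t_touchdown = numeric(0), t_peak = numeric(0),
                          height = numeric(0), height_norm = numeric(0))
  }
  out
}

#' Mean lateral trunk speed over a window
#'
#' Magnitude of the net lateral trunk displacement across the window divided
#' by the window duration.
#'
#' @param trajectory trajectory tibble (columns `t`, `x_trunk`).
#' @param window numeric `c(start, end)` (s) inside the trajectory span.
#' @return Scalar speed (m/s).
#' @examples
#' traj <- tibble::tibble(t = 0:10, x_trunk = 2 * (0:10))
#' mean_velocity(traj, c(0, 10))
#' @export
mean_velocity <- function(trajectory, window) {
  stopifnot(window[2] > window[1],
            window[1] >= min(trajectory$t) - 1e-9,
            window[2] <= max(trajectory$t) + 1e-9)
  x_at <- function(tt) {
    stats::approx(trajectory$t, trajectory$x_trunk, xout = tt)$y
  }
  abs(x_at(window[2]) - x_at(window[1])) / (window[2] - window[1])
}

#' Pearson correlation with degrees of freedom
#'
#' Sample Pearson correlation between two equal-length vectors with
#' `df = n - 2` and the two-sided p-value.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return A one-row tibble: `r`, `df`, `p`, `n`.
#' @examples
#' pearson_test(1:10, (1:10)^2)
#' @export
pearson_test <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in at least one input", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), df = unname(ct$parameter),
                 p = ct$p.value, n = length(x))
}

#' Unpaired Student t-test
#'
#' Two-sample pooled-variance (Student, not Welch) t-test with
#' `df = n1 + n2 - 2` and the two-sided p-value.
#'
#' @param x,y numeric samples, each of length >= 2.
#' @return A one-row tibble: `t`, `df`, `p`, `mean_x`, `mean_y`.
#' @examples
#' unpaired_t_test(c(1, 2, 3), c(2, 3, 4))
#' @export
unpaired_t_test <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  tt <- stats::t.test(x, y, var.equal = TRUE)
  tibble::tibble(t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, mean_x = mean(x), mean_y = mean(y))
}
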