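protocol_defaults <- function() {
  # n_trials rather than a bare `n`: YAML 1.1 readers parse the key `n` as a
  # boolean, which would silently mangle round-trips
  list(target_speed = 2, t_start = 1.5, spacing = 0.03, n_trials = 101,
       reach_dist = 2, timeout = 15)
}

output_defaults <- function() {
  list(out_dir = ".", log_dt = 1e-3, format = "csv")
}

#' Load a run configuration
#'
#' Reads a YAML configuration with up to three blocks — `params` (model
#' parameters, see [sidestep_params()]), `protocol` (target speed, timing
#' grid, reaching distance, timeout), and `output` (directory, logging
#' interval, format) — validates it, and fills unset keys with the package
#' defaults. Unknown keys anywhere are rejected with an itemized error.
#'
#' @param path path to a YAML file.
#' @return A list of class `"sidestep_config"` with elements `params`
#'   (a `sidestep_params` object), `protocol`, `output`, and `hash` (a
#'   digest of the canonicalized content, stable under key reordering).
#' @examples
#' cfg_file <- tempfile(fileext = ".yaml")
#' writeLines("protocol:\n  n_trials: 5", cfg_file)
#' load_config(cfg_file)$protocol$n_trials
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  bad <- setdiff(names(raw), c("params", "protocol", "output"))
  if (length(bad) > 0) {
    stop("unknown config block(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  check_block <- function(block, defaults, label) {
    unknown <- setdiff(names(block), names(defaults))
    if (length(unknown) > 0) {
      stop(sprintf("unknown key(s) in '%s': %s", label,
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
    utils::modifyList(defaults, block %||% list())
  }
  par_defaults <- formals(sidestep_params)
  par_defaults <- lapply(par_defaults, eval)
  par_block <- raw$params %||% list()
  unknown <- setdiff(names(par_block), names(par_defaults))
  if (length(unknown) > 0) {
    stop("unknown key(s) in 'params': ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  params <- do.call(sidestep_params, utils::modifyList(par_defaults, par_block))
  cfg <- list(
    params = params,
    protocol = check_block(raw$protocol, protocol_defaults(), "protocol"),
    output = check_block(raw$output, output_defaults(), "output")
  )
  cfg$hash <- config_hash(cfg)
  structure(cfg, class = "sidestep_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# order-independent content digest: serialize the canonicalized (sorted-key)
# structure and fold the bytes with a polynomial rolling hash (exact in
# doubles, modulus < 2^31)
config_hash <- function(cfg) {
  canon <- function(x) {
    if (is.list(x)) {
      x <- lapply(x, canon)
      x[order(names(x))]
    } else {
      x
    }
  }
  payload <- c(canon(unclass(cfg$params)),
               canon(cfg$protocol), canon(cfg$output))
  bytes <- as.numeric(serialize(payload, NULL, ascii = TRUE))
  mod <- 2147483647
  h <- 0
  for (b in bytes) h <- (h * 257 + b) %% mod
  sprintf("%08x", h)
}

#' Write a configuration to YAML
#'
#' Serializes a config (or a bare parameter set) so that [load_config()]
#' round-trips it losslessly.
#'
#' @param config a `sidestep_config` from [load_config()], or a
#'   `sidestep_params` object (wrapped with default protocol/output blocks).
#' @param path output path.
#' @return `path`, invisibly.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' write_config(sidestep_params(), f)
#' @export
write_config <- function(config, path) {
  if (inherits(config, "sidestep_params")) {
    config <- list(params = config, protocol = protocol_defaults(),
                   output = output_defaults())
  }
  p <- unclass(config$params)
  p$L0_leg <- NULL
  p$L0_inter <- NULL  # derived from trunk_height on load
  yaml::write_yaml(list(params = p, protocol = config$protocol,
                        output = config$output), path)
  invisible(path)
}

format_num <- function(x) {
  ifelse(is.na(x), "NA", trimws(formatC(x, digits = 12, format = "g")))
}

#' Write result tables deterministically
#'
#' Writes a tibble (e.g. `sweep$trials`, a sensitivity table, or a
#' trajectory) as CSV with fixed 12-significant-digit float formatting, or as
#' JSON with sorted keys, so identical results produce identical bytes.
#'
#' @param results a data frame.
#' @param path output path; the extension (`.csv` or `.json`) selects the
#'   format.
#' @return `path`, invisibly.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_results(tibble::tibble(a = 1, b = 2), f)
#' readLines(f)
#' @export
write_results <- function(results, path) {
  stopifnot(is.data.frame(results))
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    ordered <- results[, sort(names(results)), drop = FALSE]
    jsonlite::write_json(ordered, path, digits = NA, auto_unbox = FALSE,
                         na = "null", pretty = TRUE)
  } else {
    out <- results
    num <- vapply(out, is.numeric, logical(1))
    out[num] <- lapply(out[num], format_num)
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param path CSV or Parquet trajectory file.
#' @return A trajectory tibble.
#' @export
read_trajectory <- function(path) {
  ext <- tolower(tools::file_ext(path))
  out <- if (ext == "parquet") {
    tibble::as_tibble(arrow::read_parquet(path))
  } else {
    tibble::as_tibble(utils::read.csv(path))
  }
  out$grounded_r <- as.logical(out$grounded_r)
  out$grounded_l <- as.logical(out$grounded_l)
  out
}

#' Write a trajectory
#'
#' CSV (text, deterministic formatting) for ordinary runs, or compact
#' columnar Parquet for long runs.
#'
#' @param trajectory trajectory tibble.
#' @param path output path; `.parquet` selects the binary columnar format,
#'   anything else CSV.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "parquet") {
    arrow::write_parquet(trajectory, path)
  } else {
    write_results(trajectory, path)
  }
  invisible(path)
}

#' Deterministic short regression fixtures
#'
#' Short reference runs on the default parameter set for regression testing:
#' `"standing"` (0.5 s, zero command, the symmetric stance holds station) and
#' `"sidestep"` (2 s at +2 m/s, net positive displacement). Regeneration is
#' bit-identical across runs because the simulator has no stochastic
#' component.
#'
#' @param name fixture name, `"standing"` or `"sidestep"`.
#' @return A `sidestep_sim` object.
#' @examples
#' \donttest{
#' fx <- make_fixture("standing")
#' max(abs(fx$trajectory$x_trunk))
#' }
#' @export
make_fixture <- function(name = c("standing", "sidestep")) {
  name <- match.arg(name)
  p <- sidestep_params()
  switch(name,
    standing = run_sidestep(p, v_d = 0, duration = 0.5),
    sidestep = run_sidestep(p, v_d = 2, duration = 2)
  )
}
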