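#' Build a stimulus protocol by name
#'
#' Thin dispatcher used by config files and the command line: `"block"`
#' forwards to [stim_block()], `"pulse_train"` to [stim_pulse_train()].
#'
#' @param kind `"block"` or `"pulse_train"`.
#' @param ... Passed to the underlying constructor.
#' @return A [stimulus_protocol()].
#' @examples
#' make_stimulus("block", duration_ms = 300)
#' make_stimulus("pulse_train", freq_hz = 50, n_pulses = 10)
#' @export
make_stimulus <- function(kind = c("block", "pulse_train"), ...) {
  kind <- match.arg(kind)
  switch(kind,
         block = stim_block(...),
         pulse_train = stim_pulse_train(...))
}

config_field_names <- function() {
  list(
    model = names(formals(model_params)),
    scenario = names(formals(scenario_context)),
    task = setdiff(names(formals(task_config)),
                   c("alpha", "ldopa", "seed", "dt")),
    top = c("dt", "seed", "out_dir", "log_level")
  )
}

#' Load a run configuration from a YAML or JSON file
#'
#' Accepts either flat key-value files whose keys mirror the
#' [model_params()] and [scenario_context()] field names exactly, or
#' files with `model:`, `scenario:` and `task:` blocks plus top-level
#' `dt`, `seed`, `out_dir`, `log_level`. Absent keys take the published
#' defaults; unknown keys are rejected with a message naming the
#' offending key; an empty file yields the full default configuration.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @param quiet Suppress the echo of the resolved configuration.
#' @return An object of class `tan_config`: a list with `params`
#'   (a `tan_params`), `context` (a `tan_context`), `task` (a
#'   `tan_task_config`), `dt`, `seed`, `out_dir`, `log_level`.
#' @export
load_config <- function(path, quiet = FALSE) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) {
    stop("config file must contain a key-value mapping: ", path,
         call. = FALSE)
  }
  fields <- config_field_names()

  model_kv <- as.list(raw[["model"]] %||% list())
  scen_kv <- as.list(raw[["scenario"]] %||% list())
  task_kv <- as.list(raw[["task"]] %||% list())
  flat <- raw[setdiff(names(raw), c("model", "scenario", "task"))]
  for (nm in names(flat)) {
    if (nm %in% fields$model) {
      model_kv[[nm]] <- flat[[nm]]
    } else if (nm %in% fields$scenario) {
      scen_kv[[nm]] <- flat[[nm]]
    } else if (nm %in% fields$top) {
      # handled below
    } else {
      stop("unknown config key '", nm, "' in ", path, call. = FALSE)
    }
  }
  for (nm in names(model_kv)) {
    if (!nm %in% fields$model) {
      stop("unknown model parameter '", nm, "' in ", path, call. = FALSE)
    }
  }
  for (nm in names(scen_kv)) {
    if (!nm %in% fields$scenario) {
      stop("unknown scenario key '", nm, "' in ", path, call. = FALSE)
    }
  }
  for (nm in names(task_kv)) {
    if (!nm %in% fields$task) {
      stop("unknown task key '", nm, "' in ", path, call. = FALSE)
    }
  }
  numeric_like <- c(fields$model, fields$scenario)
  for (nm in intersect(names(c(model_kv, scen_kv)), numeric_like)) {
    v <- c(model_kv, scen_kv)[[nm]]
    if (!is.numeric(v)) {
      stop("config key '", nm, "' must be numeric, got '",
           paste(v, collapse = ", "), "'", call. = FALSE)
    }
  }
  dt <- flat[["dt"]] %||% 1
  seed <- flat[["seed"]] %||% 1
  task_kv$seed <- seed
  task_kv$dt <- dt
  task_kv$alpha <- scen_kv$alpha %||% 1
  task_kv$ldopa <- scen_kv$ldopa %||% 0
  if (!is.null(task_kv$trials_per_phase)) {
    task_kv$trials_per_phase <- unlist(task_kv$trials_per_phase)
  }
  if (!is.null(task_kv$action_span)) {
    task_kv$action_span <- unlist(task_kv$action_span)
  }
  cfg <- list(
    params = do.call(model_params, model_kv),
    context = do.call(scenario_context, scen_kv),
    task = do.call(task_config, task_kv),
    dt = dt, seed = seed,
    out_dir = flat[["out_dir"]] %||% ".",
    log_level = flat[["log_level"]] %||% "info"
  )
  class(cfg) <- "tan_config"
  if (!quiet && !identical(cfg$log_level, "quiet")) {
    message("resolved config: dt = ", cfg$dt, " ms, seed = ", cfg$seed,
            ", rpe = ", cfg$context$rpe, ", alpha = ", cfg$context$alpha,
            ", ldopa = ", cfg$context$ldopa)
  }
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# format doubles at full precision so CSV round trips are exact
fmt_full <- function(df) {
  df[] <- lapply(df, function(col) {
    if (is.double(col)) sprintf("%.17g", col) else col
  })
  df
}

#' Write and read simulation traces, sweep tables and experiments
#'
#' Plain-text serialization: traces and sweep tables as CSV with a
#' mandatory header, `.` decimal separator and round-trip-exact
#' numeric formatting; pause metrics and experiment summaries as JSON.
#'
#' @param trace,sweep,experiment,pause,weights Objects produced by
#'   [simulate_tan()], the `sweep_*()` functions, [run_experiment()],
#'   [detect_pause()] and [weight_state()].
#' @param path Output file path (for `write_experiment`, the CSV path;
#'   the JSON summary is written alongside with suffix
#'   `_summary.json`).
#' @return The input, invisibly (writers); a tibble or object of the
#'   corresponding class (readers).
#' @name tan-io
NULL

#' @rdname tan-io
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "tan_trace"))
  readr::write_csv(
    fmt_full(tibble::as_tibble(trace)[
      c("t_ms", "v_tan", "i_sahp", "i_h", "da")]),
    path)
  invisible(trace)
}

#' @rdname tan-io
#' @export
read_trace <- function(path) {
  read_csv_exact(path)
}

# read a CSV whose numeric columns must reproduce the written doubles
# exactly: parse as text, convert with strtod (correctly rounded)
read_csv_exact <- function(path, keep_character = character(0)) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"))
  for (nm in setdiff(names(df), keep_character)) {
    df[[nm]] <- as.numeric(df[[nm]])
  }
  df
}

#' @rdname tan-io
#' @export
write_pause_metrics <- function(pause, path) {
  stopifnot(inherits(pause, "tan_pause"))
  jsonlite::write_json(unclass(pause), path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(pause)
}

#' @rdname tan-io
#' @export
write_sweep <- function(sweep, path) {
  stopifnot(inherits(sweep, "tan_sweep"))
  readr::write_csv(fmt_full(tibble::as_tibble(sweep)), path)
  invisible(sweep)
}

#' @rdname tan-io
#' @export
read_sweep <- function(path) {
  out <- read_csv_exact(path, keep_character = "axis_name")
  attr(out, "axis_name") <- out$axis_name[1]
  class(out) <- c("tan_sweep", class(out))
  out
}

#' @rdname tan-io
#' @export
write_experiment <- function(experiment, path) {
  stopifnot(inherits(experiment, "tan_experiment"))
  df <- tibble::as_tibble(experiment) |>
    dplyr::rename(error = "actual_error")
  readr::write_csv(
    fmt_full(df[c("session", "phase", "trial", "endpoint", "error",
                  "perceived_error", "reward", "rpe", "tp_ms",
                  "da_integral")]),
    path)
  summ <- attr(experiment, "summary")
  jsonlite::write_json(summ, sub("\\.csv$", "_summary.json", path),
                       digits = NA, dataframe = "columns")
  invisible(experiment)
}

#' @rdname tan-io
#' @export
read_experiment <- function(path) {
  read_csv_exact(path, keep_character = "phase")
}

#' @rdname tan-io
#' @export
write_weights <- function(weights, path) {
  stopifnot(inherits(weights, "tan_weights"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      list(w1 = weights$w1, w2 = weights$w2,
           lambda1 = weights$lambda1, lambda2 = weights$lambda2,
           dw = weights$dw),
      path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  } else {
    readr::write_csv(fmt_full(tidy(weights)), path)
  }
  invisible(weights)
}

#' @rdname tan-io
#' @param lambda1,lambda2,dw Rates to attach when reading the CSV long
#'   format (which stores the matrices only).
#' @export
read_weights <- function(path, lambda1 = 1, lambda2 = 1, dw = 0.01) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    return(weight_state(x$w1, x$w2, x$lambda1, x$lambda2, x$dw))
  }
  df <- read_csv_exact(path, keep_character = "pathway")
  mk <- function(p) {
    sub <- df[df$pathway == p, ]
    m <- matrix(0, max(sub$j), max(sub$i))
    m[cbind(sub$j, sub$i)] <- sub$value
    m
  }
  weight_state(mk("direct"), mk("indirect"), lambda1, lambda2, dw)
}
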