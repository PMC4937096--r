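# configuration loading and result serialization. Configs are JSON (or
# YAML when the yaml package is available), with sections env, strategy_a,
# strategy_b, experiment, output; unknown keys are rejected and all
# defaults are materialized so the echoed sidecar fully describes a run.

experiment_keys <- c("name", "n", "base_seed", "axis", "grid", "levels",
                     "census", "series", "include_none", "n_boot")
experiment_names <- c("run-pair", "correlations", "sweep-volatility",
                      "sweep-generosity", "payoff", "inequality")

check_keys <- function(given, allowed, section) {
  bad <- setdiff(names(given), allowed)
  if (length(bad))
    stop("config: unknown key", if (length(bad) > 1) "s", " in '", section,
         "': ", paste(bad, collapse = ", "), call. = FALSE)
}

build_section <- function(given, constructor, section) {
  check_keys(given, names(formals(constructor)), section)
  tryCatch(do.call(constructor, given),
           error = function(e) stop("config: invalid '", section, "': ",
                                    conditionMessage(e), call. = FALSE))
}

#' Load and validate a run configuration
#'
#' Reads a JSON (or YAML, if the `yaml` package is installed) configuration
#' with sections `env`, `strategy_a`, `strategy_b`, `experiment`, and
#' `output`. All defaults are materialized — an empty file yields the
#' all-defaults baseline configuration — and unknown or invalid keys raise
#' a named configuration error. Entries in `overrides` (e.g. from
#' command-line flags) beat file values.
#'
#' @param path Path to a `.json`/`.yaml`/`.yml` file, or `NULL` for
#'   defaults only.
#' @param overrides Named list overriding individual keys: `seed`, `n`,
#'   `outdir`, `trajectories`, and any `experiment` key.
#' @return A list of class `herdpool_config` with fully materialized
#'   `env` ([env_params()]), `strategy_a`/`strategy_b`
#'   ([strategy_params()]), `experiment`, and `output` sections.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  raw <- list()
  if (!is.null(path)) {
    if (!file.exists(path))
      stop("config: file not found: ", path, call. = FALSE)
    raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("config: YAML configs need the 'yaml' package; use JSON",
             call. = FALSE)
      yaml::read_yaml(path)
    } else {
      jsonlite::read_json(path, simplifyVector = TRUE)
    }
    if (is.null(raw)) raw <- list()
  }
  check_keys(raw, c("env", "strategy_a", "strategy_b", "experiment",
                    "output"), "top level")

  exp_raw <- if (is.null(raw$experiment)) list() else raw$experiment
  check_keys(exp_raw, experiment_keys, "experiment")
  out_raw <- if (is.null(raw$output)) list() else raw$output
  check_keys(out_raw, c("dir", "trajectories"), "output")

  # flag-style overrides beat file values
  check_keys(overrides, c("seed", "n", "outdir", "trajectories",
                          experiment_keys), "overrides")
  if (!is.null(overrides$seed)) exp_raw$base_seed <- overrides$seed
  if (!is.null(overrides$outdir)) out_raw$dir <- overrides$outdir
  if (!is.null(overrides$trajectories))
    out_raw$trajectories <- overrides$trajectories
  for (key in intersect(names(overrides), experiment_keys))
    exp_raw[[key]] <- overrides[[key]]

  experiment <- utils::modifyList(
    list(name = "correlations", n = NULL, base_seed = 1L, axis = "size",
         grid = NULL, levels = seq(0, 1, by = 0.1), census = "living_final",
         series = FALSE, include_none = FALSE, n_boot = 1000L),
    exp_raw)
  if (!experiment$name %in% experiment_names)
    stop("config: unknown experiment name '", experiment$name,
         "'; expected one of ", paste(experiment_names, collapse = ", "),
         call. = FALSE)
  experiment$base_seed <- as.integer(experiment$base_seed)

  cfg <- list(
    env = build_section(as.list(raw$env), env_params, "env"),
    strategy_a = build_section(as.list(raw$strategy_a), strategy_params,
                               "strategy_a"),
    strategy_b = build_section(as.list(raw$strategy_b), strategy_params,
                               "strategy_b"),
    experiment = experiment,
    output = utils::modifyList(list(dir = ".", trajectories = FALSE),
                               out_raw))
  class(cfg) <- "herdpool_config"
  cfg
}

# plain-list view of a config for the JSON sidecar (Inf is not valid JSON)
config_as_list <- function(cfg) {
  strip <- function(x) {
    x <- unclass(x)
    if (!is.null(x$credit_size) && is.infinite(x$credit_size))
      x$credit_size <- "inf"
    x
  }
  list(env = strip(cfg$env),
       strategy_a = strip(cfg$strategy_a),
       strategy_b = strip(cfg$strategy_b),
       experiment = cfg$experiment[!vapply(cfg$experiment, is.null,
                                           logical(1))],
       output = cfg$output)
}

#' @export
print.herdpool_config <- function(x, ...) {
  cat("herdpool run configuration — experiment:", x$experiment$name,
      "(base seed", paste0(x$experiment$base_seed, ")"), "\n")
  print(x$env)
  cat("strategy_a: "); print(x$strategy_a)
  cat("strategy_b: "); print(x$strategy_b)
  invisible(x)
}

write_csv_stable <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

write_sidecar <- function(outdir, config, extra = list()) {
  if (is.null(config)) return(invisible(NULL))
  body <- c(config_as_list(config), extra)
  jsonlite::write_json(body, file.path(outdir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Write experiment results to an output directory
#'
#' Serializes any herdpool result object as tidy CSV files with a stable
#' column order (plus a `config.json` sidecar when `config` is given), so
#' re-running the same configuration and seed yields byte-identical files.
#'
#' @param x A result object (`herdpool_replicates`,
#'   `herdpool_correlations`, `herdpool_sweep`, `herdpool_generosity`,
#'   `herdpool_payoff`, or `herdpool_inequality`).
#' @param outdir Output directory (created if missing).
#' @param config Optional [load_config()] object echoed to `config.json`.
#' @param ... Unused.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(x, outdir, config = NULL, ...) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir))
    stop("write_results: cannot create output directory: ", outdir,
         call. = FALSE)
  UseMethod("write_results")
}

#' @export
write_results.herdpool_replicates <- function(x, outdir, config = NULL, ...) {
  st <- attr(x, "strategies")
  df <- data.frame(replicate = x$replicate, seed = x$seed,
                   strategy_a = st$a$kind, strategy_b = st$b$kind,
                   survival_a = x$survival_a, survival_b = x$survival_b,
                   censored_a = x$censored_a, censored_b = x$censored_b,
                   herd_a = x$herd_a, herd_b = x$herd_b)
  paths <- write_csv_stable(df, file.path(outdir, "replicates.csv"))
  traj <- attr(x, "trajectories")
  if (!is.null(traj)) {
    long <- do.call(rbind, lapply(seq_len(dim(traj)[3]), function(i) {
      data.frame(replicate = i,
                 year = rep(as.integer(rownames(traj)), 2L),
                 agent = rep(c("a", "b"), each = nrow(traj)),
                 herd = c(traj[, 1, i], traj[, 2, i]))
    }))
    paths <- c(paths,
               write_csv_stable(long, file.path(outdir, "trajectories.csv")))
  }
  write_sidecar(outdir, config)
  invisible(paths)
}

#' @export
write_results.herdpool_correlations <- function(x, outdir, config = NULL, ...) {
  paths <- write_csv_stable(as.data.frame(x),
                            file.path(outdir, "summary.csv"))
  write_sidecar(outdir, config)
  invisible(paths)
}

#' @export
write_results.herdpool_sweep <- function(x, outdir, config = NULL, ...) {
  df <- as.data.frame(x)
  names(df)[names(df) == "value"] <- attr(x, "axis")
  paths <- write_csv_stable(df, file.path(outdir, "summary.csv"))
  write_sidecar(outdir, config, extra = list(axis = attr(x, "axis")))
  invisible(paths)
}

#' @export
write_results.herdpool_generosity <- function(x, outdir, config = NULL, ...) {
  df <- rbind(x$table, x$baseline)
  names(df)[names(df) == "value"] <- "generosity"
  paths <- write_csv_stable(df, file.path(outdir, "summary.csv"))
  write_sidecar(outdir, config, extra = list(thresholds = x$thresholds))
  invisible(paths)
}

#' @export
write_results.herdpool_payoff <- function(x, outdir, config = NULL, ...) {
  strategies <- rownames(x$payoff)
  df <- expand.grid(focal = strategies, partner = strategies,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$pct_survive <- mapply(function(f, p) x$payoff[f, p],
                           df$focal, df$partner)
  df$ci_lo <- mapply(function(f, p) x$ci_lo[f, p], df$focal, df$partner)
  df$ci_hi <- mapply(function(f, p) x$ci_hi[f, p], df$focal, df$partner)
  paths <- write_csv_stable(df, file.path(outdir, "summary.csv"))
  write_sidecar(outdir, config, extra = list(dominant = x$dominant))
  invisible(paths)
}

#' @export
write_results.herdpool_inequality <- function(x, outdir, config = NULL, ...) {
  paths <- write_csv_stable(x$table, file.path(outdir, "summary.csv"))
  for (cname in names(x$lorenz))
    paths <- c(paths, write_csv_stable(
      as.data.frame(x$lorenz[[cname]]),
      file.path(outdir, paste0("lorenz_", cname, ".csv"))))
  if (!is.null(x$series))
    paths <- c(paths,
               write_csv_stable(x$series, file.path(outdir, "gini_series.csv")))
  write_sidecar(outdir, config, extra = list(census = attr(x, "census")))
  invisible(paths)
}
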