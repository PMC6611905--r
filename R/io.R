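# Output writers and run configuration. All artifacts are plain CSV/JSON;
# every one embeds the resolved parameter set (and seed, where stochastic)
# as a '# params:' JSON comment line, so results diff cleanly and are
# reproducible from the file alone.

params_json <- function(params, extra = NULL) {
  jsonlite::toJSON(c(unclass(params), extra), auto_unbox = TRUE, digits = NA)
}

write_csv_artifact <- function(df, path, params, extra = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# params: ", params_json(params, extra)), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Write a flow field to CSV
#'
#' @param ff A data frame from [flow_field()].
#' @param path Output CSV path.
#' @param params The generating [model_params()] (echoed in a header
#'   comment).
#' @return The path, invisibly.
#' @export
write_flow_field <- function(ff, path, params) {
  cols <- c("z_H", "z_C", "z_W", "x_H", "x_C", "x_W",
            "omega_H", "omega_C", "omega_W", "omega_bar",
            "xdot_H", "xdot_C", "xdot_W")
  write_csv_artifact(ff[, cols], path, params)
}

#' Write a stationary distribution to CSV (and its regime summary to JSON)
#'
#' @param dist A `crime_stationary` object.
#' @param path Output CSV path (`z_H, z_C, z_W, pi`).
#' @param summary_path Optional JSON path for the
#'   [summarize_distribution()] regime summary.
#' @return The CSV path, invisibly.
#' @export
write_stationary <- function(dist, path, summary_path = NULL) {
  df <- data.frame(dist$space$states, pi = dist$pi)
  write_csv_artifact(df, path, dist$params)
  if (!is.null(summary_path)) {
    sm <- summarize_distribution(dist)
    jsonlite::write_json(
      list(expected_x = as.list(sm$expected_x), label = sm$label,
           top_states = sm$top_states, params = unclass(dist$params)),
      summary_path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  invisible(path)
}

#' Write a phase diagram to CSV
#'
#' @param phase A data frame from [sweep_phase_diagram()].
#' @param path Output CSV path.
#' @param params The base parameter vector of the sweep.
#' @return The path, invisibly.
#' @export
write_phase_diagram <- function(phase, path, params) {
  write_csv_artifact(as.data.frame(phase), path, params)
}

#' Write a Monte Carlo trajectory to CSV (and its manifest to JSON)
#'
#' @param traj A `crime_trajectory` from [run_simulation()].
#' @param path Output CSV path (`iteration, replicate, x_H, x_C, x_W`;
#'   the across-replicate average uses `replicate = "mean"`).
#' @param manifest_path Optional JSON path for the run manifest (params,
#'   seed, iterations, replicates, initial state).
#' @return The CSV path, invisibly.
#' @export
write_trajectory <- function(traj, path, manifest_path = NULL) {
  write_csv_artifact(as.data.frame(traj), path, traj$params,
                     extra = list(seed = traj$seed))
  if (!is.null(manifest_path))
    jsonlite::write_json(
      list(params = unclass(traj$params), seed = traj$seed,
           iterations = traj$iterations, replicates = traj$replicates,
           init = as.list(stats::setNames(traj$init,
                                          c("z_H", "z_C", "z_W")))),
      manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load and resolve a run configuration
#'
#' Reads an optional YAML or JSON configuration file and merges it with
#' explicit overrides (overrides win). The `preset` entry selects a
#' [scenario_preset()]; entries under `params` override individual model
#' parameters; remaining entries are command options (`axis1`, `axis2`,
#' `init`, `iterations`, `replicates`, `seed`, `out`, `composition`,
#' `quiet`, `mu_mode`). The resolved configuration is fully explicit:
#' every model parameter has a value, validation errors name the
#' offending field, and unknown fields are rejected.
#'
#' @param path Optional path to a `.yaml`/`.yml`/`.json` config file.
#' @param overrides Named list merged over the file contents (e.g. from
#'   command-line flags).
#' @return A list of class `run_config` with `params` (a `crime_params`)
#'   and `options`.
#' @examples
#' cfg <- load_run_config(overrides = list(preset = "CO",
#'                                         params = list(beta_S = 100)))
#' cfg$params$beta_S
#' @export
load_run_config <- function(path = NULL, overrides = list()) {
  raw <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
      jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
    if (is.null(raw)) raw <- list()
  }
  for (nm in names(overrides)) {
    if (nm == "params" && !is.null(raw$params))
      raw$params[names(overrides$params)] <- overrides$params
    else raw[[nm]] <- overrides[[nm]]
  }
  known <- c("preset", "params", "axis1", "axis2", "init", "iterations",
             "replicates", "seed", "out", "composition", "quiet", "mu_mode")
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown config field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  pover <- as.list(raw$params)
  badp <- setdiff(names(pover), names(formals(model_params)))
  if (length(badp))
    stop("unknown model parameter(s): ", paste(badp, collapse = ", "),
         call. = FALSE)
  params <- if (!is.null(raw$preset)) do.call(scenario_preset,
                                              c(list(raw$preset), pover))
            else do.call(model_params, pover)
  opts <- raw[setdiff(names(raw), c("preset", "params"))]
  if (is.null(opts$seed)) opts$seed <- 1L
  if (is.null(opts$quiet)) opts$quiet <- FALSE
  if (is.null(opts$mu_mode)) opts$mu_mode <- "all"
  structure(list(params = params, options = opts), class = "run_config")
}

#' Execute a named command and write its artifacts
#'
#' Dispatch point shared by the command-line script and interactive use.
#' Commands: `"flowfield"` (replicator flow table), `"stationary"`
#' (stationary distribution CSV + regime summary JSON), `"sweep"`
#' (phase-diagram CSV over `axis1`/`axis2`), `"simulate"` (Monte Carlo
#' trajectory CSV + manifest JSON), `"thresholds"` (analytic two-type
#' threshold report JSON). Output paths derive from the `out` option
#' (default: the command name in the working directory). Partial outputs
#' are removed on failure; progress is logged to standard error unless
#' `quiet`.
#'
#' @param name Command name.
#' @param config A `run_config` from [load_run_config()].
#' @return Invisibly, the character vector of files written.
#' @export
run_command <- function(name, config) {
  if (!inherits(config, "run_config"))
    stop("config must come from load_run_config()", call. = FALSE)
  cmds <- c("flowfield", "stationary", "sweep", "simulate", "thresholds")
  if (!is.character(name) || length(name) != 1L || !name %in% cmds)
    stop("unknown command; usage: one of ", paste(cmds, collapse = ", "),
         call. = FALSE)
  p <- config$params
  o <- config$options
  out <- if (is.null(o$out)) name else o$out
  log <- function(...) if (!isTRUE(o$quiet)) message(sprintf(...))
  written <- character(0)
  ok <- FALSE
  on.exit(if (!ok) unlink(written))
  t0 <- proc.time()[["elapsed"]]
  log("command '%s': Z = %d, N = %d, %d population states, seed = %s",
      name, p$Z, p$N, (p$Z + 1) * (p$Z + 2) / 2, format(o$seed))
  switch(name,
    flowfield = {
      f <- paste0(out, ".csv")
      write_flow_field(flow_field(p), f, p)
      written <- f
    },
    stationary = {
      dist <- stationary_distribution(build_transition_matrix(p, o$mu_mode))
      f <- paste0(out, ".csv"); j <- paste0(out, "_summary.json")
      written <- c(f, j)
      write_stationary(dist, f, summary_path = j)
      log("regime: %s", summarize_distribution(dist)$label)
    },
    sweep = {
      if (is.null(o$axis1)) stop("sweep requires an 'axis1' option",
                                 call. = FALSE)
      ph <- sweep_phase_diagram(p, o$axis1, o$axis2, mu_mode = o$mu_mode)
      f <- paste0(out, ".csv")
      write_phase_diagram(ph, f, p)
      written <- f
    },
    simulate = {
      if (is.null(o$init)) stop("simulate requires an 'init' option",
                                call. = FALSE)
      iters <- if (is.null(o$iterations)) 1000L else o$iterations
      reps <- if (is.null(o$replicates)) 1L else o$replicates
      tr <- run_simulation(p, unlist(o$init), iters, reps, seed = o$seed)
      f <- paste0(out, ".csv"); j <- paste0(out, "_manifest.json")
      written <- c(f, j)
      write_trajectory(tr, f, manifest_path = j)
    },
    thresholds = {
      comp <- if (!is.null(o$composition)) unlist(o$composition)
              else c(p$N / 2, 0, p$N - p$N / 2)
      p2 <- p; p2$Z <- p$N
      p2 <- validate_params(unclass(p2))
      rep_ <- analytic_thresholds(p2, group_composition(comp[1], comp[2],
                                                        comp[3]))
      f <- paste0(out, ".json")
      jsonlite::write_json(c(unclass(rep_), list(params = unclass(p2))),
                           f, auto_unbox = TRUE, digits = NA)
      written <- f
    })
  ok <- TRUE
  log("command '%s' finished in %.1f s; wrote: %s", name,
      proc.time()[["elapsed"]] - t0, paste(written, collapse = ", "))
  invisible(written)
}
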