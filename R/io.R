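# Configuration, dispatch, serialization. Dimensional units (pA, nS, ms,
# mV) at the user boundary; every stochastic step carries an explicit seed
# recorded in the manifest.

parse_het_block <- function(block) {
  specs <- lapply(block, function(b) {
    if (!is.null(b$kind) && b$kind == "mixture")
      dist_mixture(b$mean1, b$sd1, b$mean2, b$sd2, b$weight,
                   truncate_at_zero = isTRUE(b$truncate_at_zero))
    else
      dist_normal(b$mean, b$sd, truncate_at_zero = isTRUE(b$truncate_at_zero))
  })
  do.call(het_spec, specs)
}

#' Read a run configuration from YAML or JSON
#'
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @return The configuration list, validated by [validate_run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
  validate_run_config(cfg)
}

#' Validate a run configuration
#'
#' Checks the command name, the parameter block, and that every stochastic
#' command carries a seed; unknown parameter names are reported.
#'
#' @param cfg configuration list.
#' @return The validated configuration (invisibly unchanged).
#' @export
validate_run_config <- function(cfg) {
  commands <- c("nondim", "simulate-network", "simulate-mf", "predict-rates",
                "invert-rates", "pburst-sweep", "hopf-scan")
  problems <- character(0)
  if (is.null(cfg$command)) problems <- c(problems, "missing key: command")
  else if (!cfg$command %in% commands)
    problems <- c(problems, paste0("unknown command: ", cfg$command))
  if (!is.null(cfg$params)) {
    known <- names(formals(izh_params))
    bad <- setdiff(names(cfg$params), known)
    if (length(bad))
      problems <- c(problems, paste0("unknown parameter key(s): ",
                                     paste(bad, collapse = ", ")))
  }
  stochastic <- c("simulate-network", "predict-rates", "invert-rates")
  if (!is.null(cfg$command) && cfg$command %in% stochastic &&
      is.null(cfg$seed))
    problems <- c(problems, paste0("missing key: seed (required for ",
                                   cfg$command, ")"))
  if (length(problems))
    stop("invalid run config:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  invisible(cfg)
}

config_params <- function(cfg) {
  if (is.null(cfg$params)) izh_params()
  else do.call(izh_params, cfg$params)
}

config_het <- function(cfg) {
  if (is.null(cfg$heterogeneity)) NULL else parse_het_block(cfg$heterogeneity)
}

#' Execute a run configuration
#'
#' Dispatches to the subcommand named in the configuration, writes the
#' result tables as CSV (fixed column orders, a units comment line first)
#' plus a JSON manifest recording the inputs, seeds and package version.
#'
#' @param cfg a configuration list or a path to a YAML/JSON file.
#' @param out_dir output directory (created if missing).
#' @return Invisibly, a list with the computed result and the manifest.
#' @export
run_config <- function(cfg, out_dir = ".") {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  validate_run_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- config_params(cfg)
  het <- config_het(cfg)
  seed <- if (is.null(cfg$seed)) NA_integer_ else as.integer(cfg$seed)

  result <- switch(
    cfg$command,
    "nondim" = {
      q <- nondimensionalize(params)
      data.frame(name = c("alpha", "v_peak", "v_reset", "w_jump", "a", "b",
                          "I", "g", "tau_s", "s_jump", "e_r"),
                 value = c(q$alpha, q$v_peak, q$v_reset, q$w_jump, q$a, q$b,
                           q$I, q$g, q$tau_s, q$s_jump, q$e_r))
    },
    "simulate-network" = {
      ncfg <- network_config(N = cfg$N %||% 1000, params = params,
                             het = het, T_sim = cfg$T_sim %||% 2000,
                             dt = cfg$dt %||% 0.025, seed = seed)
      sim <- simulate_network(ncfg)
      list(spikes = sim$spikes, trace = sim$trace)
    },
    "simulate-mf" = {
      p <- nondimensionalize(params)
      system <- cfg$system %||% "mfi"
      grid <- if (system != "mfi")
        beta_grid(het, params, M = cfg$M %||% 1000,
                  mode = cfg$grid_mode %||% "montecarlo", seed = seed)
      else NULL
      sol <- integrate_mf(system, p, grid, t_end = cfg$t_end %||% 2000)
      as.data.frame(sol)
    },
    "predict-rates" = {
      p <- nondimensionalize(params)
      grid <- beta_grid(het, params, M = cfg$M %||% 1000,
                        mode = cfg$grid_mode %||% "montecarlo", seed = seed)
      map <- steady_rate_map(grid, p, mode = "dynamics")
      est <- predict_rate_density(map, het[[attr(map, "param")]])
      as.data.frame(est)
    },
    "invert-rates" = {
      rates <- utils::read.csv(cfg$rates_csv, comment.char = "#")[[1]]
      est <- invert_rate_density(rates, params, param = cfg$param %||% "I_app",
                                 beta_range = unlist(cfg$beta_range))
      as.data.frame(est)
    },
    "pburst-sweep" = {
      sweep_pburst(unlist(cfg$I_values), unlist(cfg$g_values), params,
                   sigma_I = cfg$sigma_I %||% 500, M = cfg$M %||% 41)
    },
    "hopf-scan" = {
      fac <- mf_factory(params, scan = cfg$scan %||% "g_syn", het = het,
                        M = cfg$M %||% 20)
      bp <- hopf_bisect(fac, unlist(cfg$interval))
      data.frame(kind = bp$kind,
                 value = if (bp$kind == "hopf") bp$value else NA_real_)
    })

  files <- write_results(result, out_dir, prefix = cfg$command)
  manifest <- list(command = cfg$command, config = cfg,
                   seed = seed, files = files,
                   package = "hetmf",
                   version = as.character(utils::packageVersion("hetmf")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  manifest_path <- file.path(out_dir, paste0(cfg$command, "_manifest.json"))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, force = TRUE)
  invisible(list(result = result, manifest = manifest,
                 manifest_path = manifest_path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

units_header <- function(df) {
  units <- c(time_ms = "ms", time = "dimensionless time", V_mean = "mV",
             W_mean = "pA", g_mean = "nS", s = "dimensionless",
             neuron_id = "index", I_app = "pA", g_syn = "nS",
             value = "native units", density = "1/native units",
             rate = "1/dimensionless time", beta_hat = "native units")
  got <- units[names(df)]
  got[is.na(got)] <- "dimensionless"
  paste0("# units: ", paste(names(df), got, sep = " = ", collapse = ", "))
}

#' Write result tables as CSV with a units header line
#'
#' Data frames are written as `<prefix>.csv`; named lists of data frames as
#' `<prefix>_<name>.csv`. The first line is a `#` comment mapping columns
#' to units; read back with `read.csv(..., comment.char = "#")`.
#'
#' @param result data frame or named list of data frames.
#' @param out_dir output directory.
#' @param prefix file-name prefix.
#' @return Character vector of the files written.
#' @export
write_results <- function(result, out_dir, prefix = "result") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_one <- function(df, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(units_header(df), con)
    utils::write.csv(df, con, row.names = FALSE)
    path
  }
  if (is.data.frame(result)) {
    write_one(result, file.path(out_dir, paste0(prefix, ".csv")))
  } else {
    vapply(names(result), function(nm)
      write_one(result[[nm]],
                file.path(out_dir, paste0(prefix, "_", nm, ".csv"))),
      character(1))
  }
}
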