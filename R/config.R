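# Config files and full-precision CSV I/O shared by the library and the
# command-line front end.

#' Write a data frame as CSV at full double precision
#'
#' Numeric columns are formatted with 17 significant digits so that
#' reading the file back with [utils::read.csv()] reproduces the doubles
#' exactly (round-trip identity).
#'
#' @param df data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_csv_full <- function(df, path) {
  out <- df
  text_cols <- integer(0)
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      out[[j]] <- ifelse(is.na(out[[j]]), NA, sprintf("%.17g", out[[j]]))
    } else if (is.character(out[[j]]) || is.factor(out[[j]])) {
      text_cols <- c(text_cols, j)
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = text_cols,
                   na = "NA")
  invisible(path)
}

#' Read a simulation scenario configuration file
#'
#' YAML file with any subset of the [scenario_config()] parameters
#' (`dose_scenario`, `spike`, `p_zero`, `alpha_X`, `beta_X`, `gamma_X`,
#' `beta1`, `intercept`, `slope`, `quad`, `sigma_Y`, `N`, `M`) plus
#' optional run settings: `name`, `seed`, `models` (vector of strategy
#' ids 1-9), `grid` (explicit dose vector), `hc_type`, `knot_scale`.
#' Unknown fields and invalid values raise an error naming the field.
#' Note that YAML treats a bare `N` as a boolean, so the sample-size key
#' must be written quoted (`"N": 1000`).
#'
#' @param path path to the YAML file.
#' @return A list with elements `config` (a `"dr_scenario"`), `name`,
#'   `seed`, `models`, `grid`, `hc_type`, `knot_scale`.
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path))
    stop("config error: file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  scen_fields <- c("dose_scenario", "spike", "p_zero", "alpha_X", "beta_X",
                   "gamma_X", "beta1", "intercept", "slope", "quad",
                   "sigma_Y", "N", "M")
  run_fields <- c("name", "seed", "models", "grid", "hc_type", "knot_scale")
  if ("FALSE" %in% names(raw))
    stop("config error: found a key that YAML parsed as a boolean; ",
         "write the sample-size field as \"N\" (quoted)", call. = FALSE)
  unknown <- setdiff(names(raw), c(scen_fields, run_fields))
  if (length(unknown))
    stop("config error: unknown field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- tryCatch(do.call(scenario_config, raw[intersect(names(raw),
                                                         scen_fields)]),
                  error = function(e)
                    stop("config error: ", conditionMessage(e),
                         call. = FALSE))
  models <- raw$models %||% 1:9
  if (!all(models %in% 1:9))
    stop("config error: models must be strategy ids between 1 and 9",
         call. = FALSE)
  list(config = cfg,
       name = raw$name %||% tools::file_path_sans_ext(basename(path)),
       seed = raw$seed, models = as.integer(models), grid = raw$grid,
       hc_type = raw$hc_type %||% "HC1",
       knot_scale = raw$knot_scale %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a configured scenario and write its metrics CSV
#'
#' Loads the configuration with [read_scenario_config()], runs
#' [run_scenario()] with the configured strategy subset, grid, replicate
#' count and seed, and writes one metrics CSV (one row per strategy x
#' grid dose) plus a JSON run manifest next to it.
#'
#' @param path config file path.
#' @param out_dir output directory (created if needed).
#' @param seed override the config's seed.
#' @param M override the config's replicate count.
#' @param verbose passed to [run_scenario()].
#' @return Path of the metrics CSV, invisibly; the metrics object in the
#'   `"metrics"` attribute.
#' @export
run_scenario_config <- function(path, out_dir = ".", seed = NULL, M = NULL,
                                verbose = FALSE) {
  rc <- read_scenario_config(path)
  cfg <- rc$config
  specs <- catalog_models(rc$knot_scale)[rc$models]
  grid <- if (is.null(rc$grid)) default_grid(cfg) else
    check_doses(as.numeric(rc$grid), "grid dose")
  seed <- seed %||% rc$seed
  M <- M %||% cfg$M
  metrics <- run_scenario(cfg, specs, grid, M = M, seed = seed,
                          hc_type = rc$hc_type, verbose = verbose)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  csv_path <- file.path(out_dir, paste0(rc$name, "_metrics.csv"))
  write_csv_full(as.data.frame(metrics), csv_path)
  write_manifest(file.path(out_dir, paste0(rc$name, "_manifest.json")),
                 command = "simulate", config = path, seed = seed,
                 outputs = csv_path,
                 extra = list(M = M, models = rc$models,
                              failures = unname(attr(metrics, "n_failures"))))
  invisible(structure(csv_path, metrics = metrics))
}

# Sidecar manifest recording how an output was produced. JSON via
# jsonlite when available, otherwise a minimal key: value text file.
write_manifest <- function(path, command, config = NULL, seed = NULL,
                           outputs = character(0), extra = list()) {
  info <- c(list(command = command,
                 package_version = as.character(utils::packageVersion("slabspline")),
                 timestamp = format(Sys.time(), tz = "UTC"),
                 config = config, seed = seed, outputs = outputs), extra)
  info <- info[!vapply(info, is.null, logical(1))]
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(info, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    writeLines(paste0(names(info), ": ",
                      vapply(info, function(v) paste(format(v), collapse = " "),
                             character(1))), path)
  }
  invisible(path)
}
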