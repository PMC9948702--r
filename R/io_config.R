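# Configuration parsing/validation, growth-table I/O, result serialization
# and run manifests.

CONFIG_KEYS <- c("K", "n_wells", "inoculum_slots", "inoculum_slot_density",
                 "t_wells", "t_pool", "n_cycles", "pool_init_total",
                 "extinction_eps", "dt", "nonviable_mode", "inoculum_mode",
                 "init_proportions", "seed", "d",
                 "growth_model", "ecology_distribution", "intervention")
GROWTH_KEYS <- c("base_rates", "crossfeed_factor", "death_rate", "pool_rates",
                 "overrides_file")
DIST_KEYS <- c("kind", "mu", "feedback_scaling", "ban_metabolite",
               "feedback_start")
INTERVENTION_KEYS <- c("feedback_start_cycle", "tpool_scale",
                       "equalization_alpha")

#' Load a run configuration file
#'
#' Reads a YAML configuration and returns a fully validated [scenario()].
#' Omitted keys take the standard defaults (`K = 10`, `d = -2`,
#' `t_wells = 20`, 96 wells, uniform ecologies, ...); unknown keys are
#' rejected with an error naming the key. An empty file yields the default
#' scenario.
#'
#' Recognized top-level keys are the [cycle_config()] arguments plus `d`
#' (alias for `growth_model.death_rate`) and three sections:
#' `growth_model` (`base_rates`, `crossfeed_factor`, `death_rate`,
#' `pool_rates`, `overrides_file`), `ecology_distribution` (`kind`, `mu`,
#' `feedback_scaling`, `ban_metabolite`, `feedback_start`) and
#' `intervention` (`feedback_start_cycle`, `tpool_scale`,
#' `equalization_alpha`).
#'
#' @param path Path to a YAML file.
#' @param name Scenario name (default: the file name).
#' @return A `pw_scenario`.
#' @export
load_config <- function(path, name = NULL) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config file must contain a YAML mapping",
                          call. = FALSE)
  unknown <- setdiff(names(raw), CONFIG_KEYS)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  gm <- raw[["growth_model"]]
  if (!is.null(gm)) {
    bad <- setdiff(names(gm), GROWTH_KEYS)
    if (length(bad)) {
      stop("unknown growth_model key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  } else {
    gm <- list()
  }
  if (!is.null(raw[["d"]])) {
    if (!is.null(gm$death_rate) && gm$death_rate != raw[["d"]]) {
      stop("`d` and `growth_model.death_rate` disagree", call. = FALSE)
    }
    gm$death_rate <- raw[["d"]]
  }
  ds <- raw[["ecology_distribution"]]
  if (!is.null(ds)) {
    bad <- setdiff(names(ds), DIST_KEYS)
    if (length(bad)) {
      stop("unknown ecology_distribution key(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  } else {
    ds <- list()
  }
  iv <- raw[["intervention"]]
  if (!is.null(iv)) {
    bad <- setdiff(names(iv), INTERVENTION_KEYS)
    if (length(bad)) {
      stop("unknown intervention key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  } else {
    iv <- list()
  }

  cfg_args <- raw[intersect(names(raw), setdiff(CONFIG_KEYS,
    c("d", "growth_model", "ecology_distribution", "intervention")))]
  if (!is.null(cfg_args$init_proportions)) {
    cfg_args$init_proportions <- as.numeric(cfg_args$init_proportions)
  }
  config <- do.call(cycle_config, cfg_args)

  overrides <- if (!is.null(gm$overrides_file)) {
    read_growth_table(gm$overrides_file)
  } else {
    default_overrides()
  }
  params <- growth_params(
    base_rates = if (!is.null(gm$base_rates)) as.numeric(gm$base_rates),
    crossfeed_factor = gm$crossfeed_factor %||% 0.95,
    death_rate = gm$death_rate %||% -2,
    pool_rates = if (!is.null(gm$pool_rates)) as.numeric(gm$pool_rates),
    overrides = overrides
  )

  kind <- ds$kind %||% "uniform"
  if (identical(kind, "feedback")) {
    # feedback from the first cycle, on a uniform base
    kind <- "uniform"
    ds$feedback_start <- ds$feedback_start %||% 1L
  }
  feedback_start <- iv$feedback_start_cycle %||% ds$feedback_start
  if (!is.null(iv$tpool_scale)) {
    stopifnot(iv$tpool_scale > 0)
    config$t_pool <- config$t_pool * iv$tpool_scale
  }
  if (!is.null(iv$equalization_alpha)) {
    params <- equalize_params(params, iv$equalization_alpha)
  }

  scenario(name %||% tools::file_path_sans_ext(basename(path)),
           config = config, params = params,
           dist_kind = kind, mu = ds$mu,
           ban_metabolite = ds$ban_metabolite,
           feedback_start = feedback_start,
           feedback_scaling = ds$feedback_scaling %||% "identity")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a scenario back to a YAML configuration file
#'
#' `load_config(dump_config(scn, path))` reproduces the scenario (overrides
#' are written alongside as `<path>_overrides.csv` when they differ from the
#' defaults).
#'
#' @param scn A [scenario()] object.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
dump_config <- function(scn, path) {
  stopifnot(inherits(scn, "pw_scenario"))
  cfg <- scn$config
  out <- list(
    K = cfg$K, n_wells = cfg$n_wells, inoculum_slots = cfg$inoculum_slots,
    inoculum_slot_density = cfg$inoculum_slot_density,
    t_wells = cfg$t_wells, t_pool = cfg$t_pool, n_cycles = cfg$n_cycles,
    pool_init_total = cfg$pool_init_total,
    extinction_eps = cfg$extinction_eps, dt = cfg$dt,
    nonviable_mode = cfg$nonviable_mode, inoculum_mode = cfg$inoculum_mode,
    init_proportions = unname(cfg$init_proportions),
    growth_model = list(
      base_rates = unname(scn$params$base_rates),
      crossfeed_factor = scn$params$crossfeed_factor,
      death_rate = scn$params$death_rate,
      pool_rates = unname(scn$params$pool_rates)
    ),
    ecology_distribution = Filter(Negate(is.null), list(
      kind = scn$dist_kind, mu = scn$mu,
      feedback_scaling = scn$feedback_scaling,
      ban_metabolite = scn$ban_metabolite,
      feedback_start = scn$feedback_start
    ))
  )
  if (!is.null(cfg$seed)) out$seed <- cfg$seed
  if (!isTRUE(all.equal(scn$params$overrides, default_overrides()))) {
    ov_path <- paste0(path, "_overrides.csv")
    write.csv(scn$params$overrides, ov_path, row.names = FALSE)
    out$growth_model$overrides_file <- ov_path
  }
  yaml::write_yaml(out, path, precision = 15L)
  invisible(path)
}

#' Read a growth-rate override table
#'
#' CSV with required header `ecology_index, membership_mask, strain, rate`;
#' `membership_mask` is a 4-character 0/1 string in canonical strain order
#' (ADE, TRP, HIS, LYS). Duplicate (ecology, mask, strain) keys, bad masks,
#' unknown strains and non-numeric rates are rejected with row-numbered
#' errors. An empty table (header only) is valid: the parametric rate rule
#' is then used everywhere.
#'
#' @param path CSV path.
#' @return A validated override `data.frame`.
#' @export
read_growth_table <- function(path) {
  if (!file.exists(path)) {
    stop("growth table not found: ", path, call. = FALSE)
  }
  tab <- read.csv(path, colClasses = "character", strip.white = TRUE)
  need <- c("ecology_index", "membership_mask", "strain", "rate")
  if (!all(need %in% names(tab))) {
    stop("growth table must have header columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (nrow(tab) == 0L) return(validate_overrides(NULL))
  idx <- suppressWarnings(as.integer(tab$ecology_index))
  bad <- which(is.na(idx) | idx < 1L | idx > 16L)
  if (length(bad)) {
    stop("growth table: invalid ecology_index at row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  bad <- which(nchar(tab$membership_mask) != 4L |
                 grepl("[^01]", tab$membership_mask))
  if (length(bad)) {
    stop("growth table: membership_mask must be a 4-character 0/1 string ",
         "at row(s) ", paste(bad, collapse = ", "), call. = FALSE)
  }
  bad <- which(!tab$strain %in% STRAINS)
  if (length(bad)) {
    stop("growth table: unknown strain at row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  rate <- suppressWarnings(as.numeric(tab$rate))
  bad <- which(is.na(rate))
  if (length(bad)) {
    stop("growth table: non-numeric rate at row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  validate_overrides(data.frame(ecology_index = idx,
                                membership_mask = tab$membership_mask,
                                strain = tab$strain, rate = rate,
                                stringsAsFactors = FALSE))
}

#' Serialize replicate results
#'
#' Writes `summary.csv` (per-cycle means), `runs.csv` (one row per run and
#' cycle) and `config.json` (full configuration, seeds and package version)
#' into a directory. The manifest plus the package reproduce `runs.csv`
#' byte-identically.
#'
#' @param summ A [run_replicates()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(summ, dir) {
  stopifnot(inherits(summ, "pw_summary"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- nrow(summ$mean_proportions) - 1L
  summary_df <- data.frame(
    cycle = 0:n,
    summ$mean_proportions,
    mean_death_rate = c(NA_real_, summ$mean_death_rate),
    row.names = NULL
  )
  write.csv(summary_df, file.path(dir, "summary.csv"), row.names = FALSE)
  write.csv(summ$runs, file.path(dir, "runs.csv"), row.names = FALSE)
  manifest <- run_manifest(summ)
  jsonlite::write_json(manifest, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Run manifest
#'
#' Everything needed to reproduce a [run_replicates()] result: the scenario
#' configuration, growth model, distribution settings, master and derived seeds,
#' and the package version.
#'
#' @param summ A `pw_summary`.
#' @return A list suitable for JSON serialization.
#' @export
run_manifest <- function(summ) {
  stopifnot(inherits(summ, "pw_summary"))
  scn <- summ$scenario
  list(
    scenario = scn$name,
    n_runs = summ$n_runs,
    master_seed = summ$seed,
    derived_seeds = vapply(seq_len(summ$n_runs),
                           function(r) derive_seed(summ$seed, r), integer(1)),
    config = unclass(scn$config),
    growth_model = list(
      base_rates = as.list(scn$params$base_rates),
      crossfeed_factor = scn$params$crossfeed_factor,
      death_rate = scn$params$death_rate,
      pool_rates = as.list(scn$params$pool_rates),
      overrides = scn$params$overrides
    ),
    ecology_distribution = Filter(Negate(is.null), list(
      kind = scn$dist_kind, mu = scn$mu,
      ban_metabolite = scn$ban_metabolite,
      feedback_start = scn$feedback_start,
      feedback_scaling = scn$feedback_scaling
    )),
    package_version = as.character(packageVersion("poolwell")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
}

#' Read serialized results back
#'
#' Parses the `runs.csv`/`summary.csv` written by [write_results()] into the
#' corresponding data frames.
#'
#' @param dir Directory written by [write_results()].
#' @return A list with `summary` and `runs` data frames and the parsed
#'   `manifest`.
#' @export
read_results <- function(dir) {
  runs <- read.csv(file.path(dir, "runs.csv"))
  runs$extinct <- as.logical(runs$extinct)
  runs$extinction_cycle <- as.integer(runs$extinction_cycle)
  list(
    summary = read.csv(file.path(dir, "summary.csv")),
    runs = runs,
    manifest = jsonlite::read_json(file.path(dir, "config.json"))
  )
}
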