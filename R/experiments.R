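# Scenario presets, replicate orchestration and rescue interventions.

#' Equalize growth rates toward their mean
#'
#' Moves every rate a fraction `alpha` of the way to the vector mean:
#' `r'_i = r_i + alpha * (mean(r) - r_i)`. The mean is preserved exactly;
#' `alpha = 0` is the identity and `alpha = 1` collapses all rates onto the
#' mean. Growth-rate equalization (e.g. via temperature, pH or genetic
#' modification) is one of the two rescue interventions.
#'
#' @param rates Numeric rate vector.
#' @param alpha Equalization fraction in \[0, 1\].
#' @return Rate vector of the same length and names.
#' @export
apply_equalization <- function(rates, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha < 0 || alpha > 1) {
    stop("`alpha` must be a single number in [0, 1]", call. = FALSE)
  }
  rates + alpha * (mean(rates) - rates)
}

#' Equalize a full growth-parameter set
#'
#' Applies [apply_equalization()] uniformly to the base rates, the pool
#' rates, and each override group (rates sharing an ecology index and
#' membership mask). The death rate is untouched.
#'
#' @param params A [growth_params()] object.
#' @inheritParams apply_equalization
#' @return A new `pw_growth_params` object.
#' @export
equalize_params <- function(params, alpha) {
  stopifnot(inherits(params, "pw_growth_params"))
  ov <- params$overrides
  if (nrow(ov)) {
    key <- paste(ov$ecology_index, ov$membership_mask)
    for (k in unique(key)) {
      i <- key == k
      ov$rate[i] <- apply_equalization(ov$rate[i], alpha)
    }
  }
  growth_params(
    base_rates = apply_equalization(params$base_rates, alpha),
    crossfeed_factor = params$crossfeed_factor,
    death_rate = params$death_rate,
    pool_rates = apply_equalization(params$pool_rates, alpha),
    overrides = ov
  )
}

#' Simulation scenario
#'
#' Bundles a [cycle_config()], [growth_params()], a base ecology
#' distribution specification and an optional metabolic-feedback start cycle
#' into a named, runnable scenario.
#'
#' @param name Scenario label.
#' @param config A [cycle_config()].
#' @param params A [growth_params()].
#' @param dist_kind `"uniform"` or `"poisson"` base ecology distribution.
#' @param mu Poisson mean (required when `dist_kind = "poisson"`).
#' @param ban_metabolite Optional metabolite whose ecologies are removed from
#'   the base distribution (keystone restriction), or `NULL`.
#' @param feedback_start First cycle with metabolic feedback, or `NULL`.
#' @param feedback_scaling Passed to [feedback_distribution()].
#' @return An object of class `pw_scenario`.
#' @export
scenario <- function(name, config = cycle_config(),
                     params = growth_params(),
                     dist_kind = c("uniform", "poisson"), mu = NULL,
                     ban_metabolite = NULL, feedback_start = NULL,
                     feedback_scaling = c("identity", "4x")) {
  dist_kind <- match.arg(dist_kind)
  feedback_scaling <- match.arg(feedback_scaling)
  stopifnot(inherits(config, "pw_config"), inherits(params, "pw_growth_params"))
  if (dist_kind == "poisson" && is.null(mu)) {
    stop("`mu` is required for a poisson ecology distribution", call. = FALSE)
  }
  if (!is.null(ban_metabolite)) {
    ban_metabolite <- match.arg(ban_metabolite, METABOLITES)
  }
  structure(
    list(name = name, config = config, params = params,
         dist_kind = dist_kind, mu = mu, ban_metabolite = ban_metabolite,
         feedback_start = feedback_start,
         feedback_scaling = feedback_scaling),
    class = "pw_scenario"
  )
}

#' Base ecology distribution of a scenario
#'
#' @param scn A [scenario()] object.
#' @return Length-16 probability vector.
#' @export
base_distribution <- function(scn) {
  stopifnot(inherits(scn, "pw_scenario"))
  dist <- switch(scn$dist_kind,
                 uniform = uniform_distribution(),
                 poisson = poisson_distribution(scn$mu))
  if (!is.null(scn$ban_metabolite)) {
    dist <- restrict_distribution(dist, scn$ban_metabolite)
  }
  dist
}

#' @export
print.pw_scenario <- function(x, ...) {
  cat("Scenario:", x$name, "\n")
  cat(sprintf("  ecology distribution: %s%s%s\n", x$dist_kind,
              if (!is.null(x$mu)) sprintf(" (mu = %g)", x$mu) else "",
              if (!is.null(x$ban_metabolite))
                sprintf(", %s ecologies banned", x$ban_metabolite) else ""))
  if (!is.null(x$feedback_start)) {
    cat("  metabolic feedback from cycle", x$feedback_start, "\n")
  }
  print(x$config)
  invisible(x)
}

# deterministic per-run seed derivation from a master seed (kept < 2^31)
derive_seed <- function(seed, run) {
  as.integer((as.numeric(seed) %% 2147483647 + 104729 * run) %% 2147483647)
}

#' Run replicate lineages of a scenario
#'
#' Runs `n_runs` independent lineages with deterministically derived per-run
#' seeds and aggregates per-cycle means and extinction statistics. Extinct
#' runs contribute zero proportions (and death rate 1) to the means from
#' their extinction cycle onward, matching how mean trajectories decay to
#' zero on collapse.
#'
#' @param scn A [scenario()] object.
#' @param n_runs Number of replicate runs (default 100).
#' @param seed Master integer seed; run `r` uses a seed derived from it, so
#'   adding replicates never perturbs earlier runs.
#' @return An object of class `pw_summary`: list with `mean_proportions`
#'   ((n_cycles + 1) x 4 matrix, cycle 0 row first), `mean_death_rate`
#'   (length n_cycles), `extinction_fraction`, `extinction_cycles`,
#'   `extinction_time_histogram` (counts per cycle), `runs` (long
#'   data.frame of every run's records) and the scenario.
#' @export
run_replicates <- function(scn, n_runs = 100L, seed = 1L) {
  stopifnot(inherits(scn, "pw_scenario"), n_runs >= 1)
  dist <- base_distribution(scn)
  n <- scn$config$n_cycles

  prop_sum <- matrix(0, n + 1L, 4L, dimnames = list(NULL, STRAINS))
  death_sum <- numeric(n)
  ext_cycles <- integer(0)
  runs <- vector("list", n_runs)

  for (r in seq_len(n_runs)) {
    res <- run_lineage(scn$config, scn$params, distribution = dist,
                       feedback_start = scn$feedback_start,
                       feedback_scaling = scn$feedback_scaling,
                       seed = derive_seed(seed, r))
    prop_sum <- prop_sum + as.matrix(res$records[, STRAINS])
    if (n > 0) death_sum <- death_sum + res$records$death_rate[-1L]
    if (res$extinct) ext_cycles <- c(ext_cycles, res$extinction_cycle)
    runs[[r]] <- cbind(run = r, res$records,
                       extinct = res$extinct,
                       extinction_cycle = if (res$extinct)
                         res$extinction_cycle else NA_integer_)
  }

  hist <- if (n > 0) {
    tabulate(ext_cycles, nbins = n)
  } else {
    integer(0)
  }
  structure(
    list(name = scn$name, n_runs = as.integer(n_runs), seed = as.integer(seed),
         mean_proportions = prop_sum / n_runs,
         mean_death_rate = if (n > 0) death_sum / n_runs else numeric(0),
         extinction_fraction = length(ext_cycles) / n_runs,
         extinction_cycles = ext_cycles,
         extinction_time_histogram = setNames(hist, seq_len(n)),
         runs = do.call(rbind, runs),
         scenario = scn),
    class = "pw_summary"
  )
}

#' @export
print.pw_summary <- function(x, ...) {
  n <- nrow(x$mean_proportions) - 1L
  cat(sprintf("Scenario '%s': %d runs x %d cycles\n", x$name, x$n_runs, n))
  last <- x$mean_proportions[n + 1L, ]
  cat("  mean final proportions:",
      paste(sprintf("%s=%.3f", STRAINS, last), collapse = "  "), "\n")
  if (n > 0) {
    cat(sprintf("  mean final death rate : %.3f\n", x$mean_death_rate[n]))
  }
  cat(sprintf("  extinction fraction   : %.2f\n", x$extinction_fraction))
  invisible(x)
}

#' @export
plot.pw_summary <- function(x, ...) {
  n <- nrow(x$mean_proportions) - 1L
  cols <- c(ADE = "#1f3b8f", TRP = "#c23b22", HIS = "#6db3e8", LYS = "#e6b800")
  graphics::matplot(0:n, x$mean_proportions, type = "b", pch = 19, lty = 1,
                    col = cols, ylim = c(0, 1), xlab = "cycle",
                    ylab = "mean pool proportion", main = x$name, ...)
  if (n > 0) {
    graphics::lines(seq_len(n), x$mean_death_rate, lty = 2, col = "grey40")
  }
  graphics::legend("topleft", bty = "n",
                   legend = c(paste0(STRAINS, "-up"), "mean death rate"),
                   col = c(cols, "grey40"), lty = c(1, 1, 1, 1, 2),
                   pch = c(rep(19, 4), NA))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Presets: the study's experiments, pinned to the printed parameters
# (K = 10, d = -2, t_wells = 20, 96 wells, 10 cycles, equal initial
# proportions). Scan presets return a named list of scenarios.

#' Scenario presets
#'
#' Ready-made scenarios for the package's experiments:
#' \describe{
#'   \item{`preset_baseline()`}{uniform ecologies, `t_pool = 2`.}
#'   \item{`preset_timescale_scan()`}{pool-phase durations on a doubling
#'     grid; longer pool phases hand control to the pool fitnesses and the
#'     HIS overproducer takes over.}
#'   \item{`preset_capacity_contrast()`}{carrying capacities compared at a
#'     fixed inoculum density (slot density pinned to the `K = 10` value,
#'     1.25), so larger wells grow exponentially for longer.}
#'   \item{`preset_poisson_scan()`}{Poisson-weighted ecologies with means
#'     1, 3.5 and 9 (niche availability).}
#'   \item{`preset_feedback_interventions()`}{metabolic feedback starting
#'     early (cycle 1), intermediate (cycle 5) or late (cycle 9), with
#'     `t_pool = 1.28`.}
#'   \item{`preset_rescue_tpool()`}{the intermediate/late feedback scenarios
#'     with the pool phase halved (`t_pool` scaled by 0.5).}
#'   \item{`preset_rescue_equalization()`}{the intermediate/late feedback
#'     scenarios with all growth rates pulled 50% toward their mean.}
#'   \item{`preset_null_single_well()`}{single-well null model
#'     (`n_wells = 1`); almost every lineage collapses.}
#'   \item{`preset_keystone_trp()`}{uniform ecologies with all
#'     TRP-containing ecologies removed, making the TRP overproducer a
#'     keystone member.}
#' }
#'
#' @param t_pool Pool-phase duration.
#' @param tpool_values,K_values,mu_values,start_cycles Scan grids.
#' @param scale Pool-duration rescue factor (default 0.5).
#' @param alpha Equalization rescue fraction (default 0.5).
#' @return A `pw_scenario`, or a named list of them for scan presets.
#' @name presets
NULL

#' @rdname presets
#' @export
preset_baseline <- function(t_pool = 2) {
  scenario("baseline", cycle_config(t_pool = t_pool))
}

#' @rdname presets
#' @export
preset_timescale_scan <- function(tpool_values = c(0.32, 1.28, 5.12)) {
  out <- lapply(tpool_values, function(tp) {
    scenario(sprintf("timescale_tpool_%g", tp), cycle_config(t_pool = tp))
  })
  setNames(out, sprintf("tpool_%g", tpool_values))
}

#' @rdname presets
#' @export
preset_capacity_contrast <- function(K_values = c(10, 100), t_pool = 2) {
  out <- lapply(K_values, function(K) {
    scenario(sprintf("capacity_K_%g", K),
             cycle_config(K = K, t_pool = t_pool,
                          inoculum_slot_density = 10 / 8))
  })
  setNames(out, sprintf("K_%g", K_values))
}

#' @rdname presets
#' @export
preset_poisson_scan <- function(mu_values = c(1, 3.5, 9), t_pool = 2) {
  out <- lapply(mu_values, function(mu) {
    scenario(sprintf("poisson_mu_%g", mu), cycle_config(t_pool = t_pool),
             dist_kind = "poisson", mu = mu)
  })
  setNames(out, sprintf("mu_%g", mu_values))
}

#' @rdname presets
#' @export
preset_feedback_interventions <- function(start_cycles = c(1, 5, 9),
                                          t_pool = 1.28) {
  out <- lapply(start_cycles, function(s) {
    scenario(sprintf("feedback_start_%d", s), cycle_config(t_pool = t_pool),
             feedback_start = s)
  })
  setNames(out, sprintf("start_%d", start_cycles))
}

#' @rdname presets
#' @export
preset_rescue_tpool <- function(start_cycles = c(5, 9), scale = 0.5,
                                t_pool = 1.28) {
  stopifnot(is.numeric(scale), length(scale) == 1L, scale > 0)
  out <- lapply(start_cycles, function(s) {
    scenario(sprintf("rescue_tpool_start_%d", s),
             cycle_config(t_pool = t_pool * scale), feedback_start = s)
  })
  setNames(out, sprintf("start_%d", start_cycles))
}

#' @rdname presets
#' @export
preset_rescue_equalization <- function(start_cycles = c(5, 9), alpha = 0.5,
                                       t_pool = 1.28) {
  out <- lapply(start_cycles, function(s) {
    scenario(sprintf("rescue_equalization_start_%d", s),
             cycle_config(t_pool = t_pool),
             params = equalize_params(growth_params(), alpha),
             feedback_start = s)
  })
  setNames(out, sprintf("start_%d", start_cycles))
}

#' @rdname presets
#' @export
preset_null_single_well <- function(t_pool = 1.28) {
  scenario("null_single_well", cycle_config(n_wells = 1L, t_pool = t_pool))
}

#' @rdname presets
#' @export
preset_keystone_trp <- function(t_pool = 2) {
  scenario("keystone_trp", cycle_config(t_pool = t_pool),
           ban_metabolite = "TRP")
}

#' List / fetch presets by name
#'
#' @return `list_presets()`: character vector of preset names;
#'   `get_preset(name, ...)`: the corresponding scenario or scenario list.
#' @param name A preset name from `list_presets()`.
#' @param ... Passed to the preset function.
#' @export
list_presets <- function() {
  c("baseline", "timescale_scan", "capacity_contrast", "poisson_scan",
    "feedback_interventions", "rescue_tpool", "rescue_equalization",
    "null_single_well", "keystone_trp")
}

#' @rdname list_presets
#' @export
get_preset <- function(name, ...) {
  fns <- list(
    baseline = preset_baseline,
    timescale_scan = preset_timescale_scan,
    capacity_contrast = preset_capacity_contrast,
    poisson_scan = preset_poisson_scan,
    feedback_interventions = preset_feedback_interventions,
    rescue_tpool = preset_rescue_tpool,
    rescue_equalization = preset_rescue_equalization,
    null_single_well = preset_null_single_well,
    keystone_trp = preset_keystone_trp
  )
  if (!name %in% names(fns)) {
    stop("unknown preset '", name, "'; see list_presets()", call. = FALSE)
  }
  fns[[name]](...)
}
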