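# The pool -> wells -> pool cycle: ecology sampling, community inoculation,
# well-phase integration, death-rate bookkeeping, normalization, pool growth
# and extinction detection.

#' Run configuration for the pool-well cycle
#'
#' Defaults pin the headline setup: carrying capacity `K = 10`, 96 wells,
#' a 4-slot inoculum of total density `K/2` (each slot `K/8`), `t_wells = 20`,
#' `t_pool = 2`, 10 cycles, equal initial proportions (0.25 each) and the
#' pool renormalized to total density 1 after every well phase.
#'
#' @param K Carrying capacity of each well (> 0).
#' @param n_wells Number of wells per well phase (>= 1).
#' @param inoculum_slots Number of independent slot draws per inoculum
#'   (default 4).
#' @param inoculum_slot_density Density contributed by each slot; default
#'   `K/8`, so the default total inoculum is `K/2`. Set explicitly to hold
#'   inoculum densities fixed while varying `K` (carrying-capacity contrast).
#' @param t_wells Duration of the structured well phase.
#' @param t_pool Duration of the unstructured pool phase.
#' @param n_cycles Number of pool-well cycles (>= 0).
#' @param pool_init_total Total pool density after renormalization
#'   (default 1).
#' @param extinction_eps Frequency below which a strain is treated as extinct
#'   (default 1e-6).
#' @param dt RK4 step size for the well phase (default 0.01).
#' @param nonviable_mode `"logistic"` (non-viable wells decay under the same
#'   logistic equation with rate `d`) or `"exponential"` (pure exponential
#'   decay).
#' @param inoculum_mode `"slots"` (4 ordered slot draws of density `K/8`,
#'   4^4 = 256 ordered outcomes) or `"multinomial"` (`K/2` unit-density
#'   individual draws).
#' @param init_proportions Initial pool proportions (4 non-negative values
#'   summing to 1).
#' @param seed Optional integer seed stored with the config and used by
#'   [run_lineage()] when no explicit seed is given.
#' @return An object of class `pw_config`.
#' @export
cycle_config <- function(K = 10, n_wells = 96L, inoculum_slots = 4L,
                         inoculum_slot_density = NULL,
                         t_wells = 20, t_pool = 2, n_cycles = 10L,
                         pool_init_total = 1, extinction_eps = 1e-6,
                         dt = 0.01,
                         nonviable_mode = c("logistic", "exponential"),
                         inoculum_mode = c("slots", "multinomial"),
                         init_proportions = rep(0.25, 4),
                         seed = NULL) {
  nonviable_mode <- match.arg(nonviable_mode)
  inoculum_mode <- match.arg(inoculum_mode)
  chk <- function(ok, key, constraint) {
    if (!ok) stop(sprintf("`%s` must be %s", key, constraint), call. = FALSE)
  }
  num1 <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)
  chk(num1(K) && K > 0, "K", "> 0")
  chk(num1(n_wells) && n_wells >= 1 && n_wells == as.integer(n_wells),
      "n_wells", "an integer >= 1")
  chk(num1(inoculum_slots) && inoculum_slots >= 1 &&
        inoculum_slots == as.integer(inoculum_slots),
      "inoculum_slots", "an integer >= 1")
  if (is.null(inoculum_slot_density)) inoculum_slot_density <- K / 8
  chk(num1(inoculum_slot_density) && inoculum_slot_density > 0,
      "inoculum_slot_density", "> 0")
  chk(num1(t_wells) && t_wells >= 0, "t_wells", ">= 0")
  chk(num1(t_pool) && t_pool >= 0, "t_pool", ">= 0")
  chk(num1(n_cycles) && n_cycles >= 0 && n_cycles == as.integer(n_cycles),
      "n_cycles", "an integer >= 0")
  chk(num1(pool_init_total) && pool_init_total > 0, "pool_init_total", "> 0")
  chk(num1(extinction_eps) && extinction_eps > 0 && extinction_eps < 1,
      "extinction_eps", "in (0, 1)")
  chk(num1(dt) && dt > 0, "dt", "> 0")
  chk(is.numeric(init_proportions) && length(init_proportions) == 4L &&
        !anyNA(init_proportions) && all(init_proportions >= 0) &&
        abs(sum(init_proportions) - 1) < 1e-9,
      "init_proportions", "4 non-negative values summing to 1")
  if (!is.null(seed)) {
    chk(num1(seed) && seed == as.integer(seed), "seed", "an integer")
    seed <- as.integer(seed)
  }
  structure(
    list(K = K, n_wells = as.integer(n_wells),
         inoculum_slots = as.integer(inoculum_slots),
         inoculum_slot_density = inoculum_slot_density,
         t_wells = t_wells, t_pool = t_pool, n_cycles = as.integer(n_cycles),
         pool_init_total = pool_init_total, extinction_eps = extinction_eps,
         dt = dt, nonviable_mode = nonviable_mode,
         inoculum_mode = inoculum_mode,
         init_proportions = setNames(as.numeric(init_proportions), STRAINS),
         seed = seed),
    class = "pw_config"
  )
}

#' @export
print.pw_config <- function(x, ...) {
  cat("Pool-well cycle configuration\n")
  cat(sprintf("  K = %g, %d wells, %d cycles, t_pool = %g, t_wells = %g\n",
              x$K, x$n_wells, x$n_cycles, x$t_pool, x$t_wells))
  cat(sprintf("  inoculum: %d slots x density %g (%s mode), pool total %g\n",
              x$inoculum_slots, x$inoculum_slot_density, x$inoculum_mode,
              x$pool_init_total))
  cat(sprintf("  dt = %g, non-viable wells: %s, extinction eps = %g\n",
              x$dt, x$nonviable_mode, x$extinction_eps))
  invisible(x)
}

#' Sample well ecologies
#'
#' Draws `n_wells` independent ecology indices from an ecology distribution.
#'
#' @param dist Length-16 probability vector (see
#'   [as_ecology_distribution()]).
#' @param n_wells Number of draws.
#' @return Integer vector of canonical ecology indices.
#' @export
sample_ecologies <- function(dist, n_wells) {
  dist <- as_ecology_distribution(dist)
  sample.int(16L, size = n_wells, replace = TRUE, prob = dist)
}

#' Sample a well inoculum from the pool
#'
#' Draws `slots` independent strain identities weighted by the current pool
#' frequencies; each slot contributes density `slot_density` (default `K/8`)
#' to its strain, for a total inoculum of `slots * slot_density` (= `K/2` at
#' the defaults). The ordered slot assignment has `4^slots` = 256 distinct
#' outcomes at the default 4 slots.
#'
#' @param pool_freqs Pool frequency 4-vector (sums to 1).
#' @param K Carrying capacity (used for the default slot density `K/8`).
#' @param slots Number of slot draws.
#' @param slot_density Density per slot (default `K/8`).
#' @return A list with `densities` (named 4-vector) and `members` (character
#'   vector of strains with positive density).
#' @export
sample_community <- function(pool_freqs, K, slots = 4L, slot_density = K / 8) {
  if (!is.numeric(pool_freqs) || length(pool_freqs) != 4L ||
      anyNA(pool_freqs) || any(pool_freqs < 0)) {
    stop("`pool_freqs` must be 4 non-negative frequencies", call. = FALSE)
  }
  if (sum(pool_freqs) <= 0) {
    stop("pool is extinct: no strains to sample", call. = FALSE)
  }
  draws <- sample.int(4L, size = slots, replace = TRUE, prob = pool_freqs)
  counts <- tabulate(draws, nbins = 4L)
  dens <- setNames(counts * slot_density, STRAINS)
  list(densities = dens, members = STRAINS[counts > 0L])
}

#' Enumerate ordered inoculum outcomes
#'
#' All distinct ordered assignments of strains to inoculum slots
#' (`4^slots` rows; 256 at the default 4 slots), with the resulting
#' membership mask of each.
#'
#' @param slots Number of inoculum slots.
#' @return A `data.frame` with one column per slot plus `membership_mask`.
#' @export
inoculum_outcomes <- function(slots = 4L) {
  g <- do.call(expand.grid, c(rep(list(STRAINS), slots),
                              list(KEEP.OUT.ATTRS = FALSE,
                                   stringsAsFactors = FALSE)))
  names(g) <- paste0("slot", seq_len(slots))
  g$membership_mask <- apply(g, 1L, function(r) membership_mask(unique(r)))
  g
}

#' Run one structured well phase
#'
#' Samples an ecology and an inoculum for each well, classifies viability,
#' integrates the logistic dynamics for `t_wells`, and aggregates.
#'
#' @param pool_freqs Current pool frequency 4-vector.
#' @param dist Ecology distribution for this phase.
#' @param config A [cycle_config()] object.
#' @param params A [growth_params()] object.
#' @param tables Optional precomputed [rate tables][growth_rates] (internal
#'   speed-up; computed on the fly when `NULL`).
#' @return A list with `densities` (per-strain totals over wells),
#'   `death_rate` (fraction of non-viable wells), `ecology_histogram`
#'   (counts over the 16 indices).
#' @export
run_well_phase <- function(pool_freqs, dist, config, params = growth_params(),
                           tables = NULL) {
  stopifnot(inherits(config, "pw_config"), inherits(params, "pw_growth_params"))
  dist <- as_ecology_distribution(dist)
  if (is.null(tables)) tables <- rate_tables(params)
  nw <- config$n_wells

  eco <- sample_ecologies(dist, nw)

  # inoculate: counts[w, s] slot draws of strain s in well w
  if (config$inoculum_mode == "slots") {
    draws <- matrix(
      sample.int(4L, size = nw * config$inoculum_slots, replace = TRUE,
                 prob = pool_freqs),
      nrow = nw
    )
    counts <- vapply(1:4, function(s) rowSums(draws == s), numeric(nw))
    counts <- matrix(counts, nrow = nw) # guard nw == 1
    unit <- config$inoculum_slot_density
  } else {
    n_units <- max(1L, as.integer(round(config$K / 2)))
    counts <- t(stats::rmultinom(nw, size = n_units, prob = pool_freqs))
    unit <- (config$K / 2) / n_units
  }
  dens0 <- counts * unit

  mask <- as.integer(counts[, 1] > 0) * 8L + as.integer(counts[, 2] > 0) * 4L +
    as.integer(counts[, 3] > 0) * 2L + as.integer(counts[, 4] > 0) * 1L
  viab <- tables$viable[cbind(eco, mask)]

  # per-well rate rows; non-members have NA in the table but zero density,
  # so their rate can be anything finite -- use 0
  rates <- matrix(0, nrow = nw, ncol = 4L)
  for (s in 1:4) {
    r <- tables$rates[cbind(eco, mask, s)]
    r[is.na(r)] <- 0
    rates[, s] <- r
  }

  bracket <- if (config$nonviable_mode == "logistic") rep(TRUE, nw) else viab
  final <- if (config$t_wells > 0) {
    wells_rk4(dens0, rates, config$K, config$t_wells, config$dt, bracket)
  } else {
    dens0
  }
  final <- clamp_densities(final)

  list(
    densities = setNames(colSums(final), STRAINS),
    death_rate = mean(!viab),
    ecology_histogram = tabulate(eco, nbins = 16L)
  )
}

#' Normalize aggregated well output into the next pool
#'
#' @param densities Per-strain aggregated densities from the well phase.
#' @param pool_init_total Total density of the renormalized pool (default 1).
#' @return A list with `freqs`, `densities` (freqs scaled to
#'   `pool_init_total`) and `extinct` (`TRUE` when the total is zero).
#' @export
normalize_to_pool <- function(densities, pool_init_total = 1) {
  tot <- sum(densities)
  if (tot <= 0) {
    zero <- setNames(numeric(length(densities)), names(densities))
    return(list(freqs = zero, densities = zero, extinct = TRUE))
  }
  freqs <- densities / tot
  list(freqs = freqs, densities = freqs * pool_init_total, extinct = FALSE)
}

#' Run one pool-well lineage
#'
#' Alternates the structured well phase and the unstructured pool phase for
#' `n_cycles` cycles. Each cycle: (1) choose the ecology distribution (the
#' base distribution, or the metabolic-feedback distribution derived from the
#' current pool frequencies once `feedback_start` is reached); (2) run the
#' well phase; (3) renormalize the aggregated output into the pool; (4) grow
#' the pool exponentially for `t_pool` and record the proportions. A lineage
#' is extinct when the aggregated well output is zero or every strain
#' frequency falls below `extinction_eps`; afterwards proportions are
#' identically zero and the recorded death rate is 1.
#'
#' @param config A [cycle_config()] object.
#' @param params A [growth_params()] object.
#' @param distribution Base ecology distribution: a length-16 probability
#'   vector, or a function `(cycle, pool_freqs) -> probability vector` for
#'   custom schedules.
#' @param feedback_start First cycle (1-based) at which the metabolic
#'   feedback distribution replaces the base distribution, or `NULL` for
#'   never.
#' @param feedback_scaling Passed to [feedback_distribution()].
#' @param seed Optional integer seed (defaults to `config$seed`).
#' @return An object of class `pw_run`: list with `records` (data.frame of
#'   cycle 0..n proportions and per-phase death rates), `ecology_histogram`
#'   (cycles x 16 counts), `extinct`, `extinction_cycle`, `config`.
#' @export
run_lineage <- function(config, params = growth_params(),
                        distribution = uniform_distribution(),
                        feedback_start = NULL,
                        feedback_scaling = c("identity", "4x"),
                        seed = config$seed) {
  stopifnot(inherits(config, "pw_config"), inherits(params, "pw_growth_params"))
  feedback_scaling <- match.arg(feedback_scaling)
  if (!is.null(feedback_start)) {
    stopifnot(length(feedback_start) == 1L, feedback_start >= 1)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  tables <- rate_tables(params)

  base_dist <- if (is.function(distribution)) NULL
               else as_ecology_distribution(distribution)
  pick_dist <- function(cycle, freqs) {
    if (!is.null(feedback_start) && cycle >= feedback_start) {
      return(feedback_distribution(freqs, scaling = feedback_scaling))
    }
    if (is.function(distribution)) {
      return(as_ecology_distribution(distribution(cycle, freqs)))
    }
    base_dist
  }

  n <- config$n_cycles
  props <- matrix(0, nrow = n + 1L, ncol = 4L,
                  dimnames = list(NULL, STRAINS))
  props[1L, ] <- config$init_proportions
  death <- rep(NA_real_, n)
  hist <- matrix(0L, nrow = n, ncol = 16L)
  extinct <- FALSE
  extinction_cycle <- NA_integer_

  freqs <- config$init_proportions
  for (cyc in seq_len(n)) {
    if (extinct) {
      death[cyc] <- 1
      next
    }
    dist <- pick_dist(cyc, freqs)
    wp <- run_well_phase(freqs, dist, config, params, tables = tables)
    death[cyc] <- wp$death_rate
    hist[cyc, ] <- wp$ecology_histogram

    pool <- normalize_to_pool(wp$densities, config$pool_init_total)
    if (pool$extinct) {
      extinct <- TRUE
      extinction_cycle <- cyc
      next
    }
    y <- integrate_pool(pool$densities, params$pool_rates, config$t_pool)
    freqs <- pool_frequencies(y)
    freqs[freqs < config$extinction_eps] <- 0
    if (sum(freqs) <= 0) {
      extinct <- TRUE
      extinction_cycle <- cyc
      next
    }
    freqs <- freqs / sum(freqs)
    props[cyc + 1L, ] <- freqs
  }

  records <- data.frame(cycle = 0:n, props,
                        death_rate = c(NA_real_, death), row.names = NULL)
  structure(
    list(records = records, ecology_histogram = hist, extinct = extinct,
         extinction_cycle = extinction_cycle, config = config),
    class = "pw_run"
  )
}

#' @export
print.pw_run <- function(x, ...) {
  n <- x$config$n_cycles
  cat(sprintf("Pool-well lineage: %d cycle%s, %d wells\n",
              n, if (n == 1) "" else "s", x$config$n_wells))
  if (x$extinct) {
    cat("  extinct at cycle", x$extinction_cycle, "\n")
  } else {
    last <- x$records[nrow(x$records), STRAINS]
    cat("  final proportions:",
        paste(sprintf("%s=%.3f", STRAINS, unlist(last)), collapse = "  "), "\n")
  }
  invisible(x)
}

#' @export
plot.pw_run <- function(x, ...) {
  rec <- x$records
  cols <- c(ADE = "#1f3b8f", TRP = "#c23b22", HIS = "#6db3e8", LYS = "#e6b800")
  graphics::matplot(rec$cycle, as.matrix(rec[, STRAINS]), type = "b",
                    pch = 19, lty = 1, col = cols, ylim = c(0, 1),
                    xlab = "cycle", ylab = "pool proportion", ...)
  ok <- !is.na(rec$death_rate)
  graphics::lines(rec$cycle[ok], rec$death_rate[ok], lty = 2, col = "grey40")
  graphics::legend("topleft", bty = "n",
                   legend = c(paste0(STRAINS, "-up"), "well death rate"),
                   col = c(cols, "grey40"), lty = c(1, 1, 1, 1, 2),
                   pch = c(rep(19, 4), NA))
  invisible(x)
}
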