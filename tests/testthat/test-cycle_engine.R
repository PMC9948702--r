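test_that("configuration validation names the offending key and constraint", {
  expect_error(cycle_config(K = -1), "`K` must be > 0")
  expect_error(cycle_config(n_wells = 0), "n_wells")
  expect_error(cycle_config(t_pool = -1), "t_pool")
  expect_error(cycle_config(init_proportions = c(1, 1, 1, 1)),
               "init_proportions")
  expect_error(cycle_config(extinction_eps = 2), "extinction_eps")
  cfg <- cycle_config()
  # default inoculum: 4 slots x K/8 = K/2
  expect_equal(cfg$inoculum_slots * cfg$inoculum_slot_density, cfg$K / 2)
})

test_that("ecology sampling follows the given distribution", {
  set.seed(3)
  idx <- sample_ecologies(point_mass_dist(16), 96)
  expect_length(idx, 96L)
  expect_true(all(idx == 16L))
  freq <- tabulate(sample_ecologies(uniform_distribution(), 1e5), 16) / 1e5
  expect_true(all(abs(freq - 0.0625) < 0.01))
})

test_that("inocula are 4 slots of K/8 totalling K/2", {
  set.seed(4)
  # monoculture pool: the whole K/2 goes to one strain
  com <- sample_community(c(1, 0, 0, 0), K = 10)
  expect_equal(unname(com$densities), c(5, 0, 0, 0))
  expect_equal(com$members, "ADE")
  # any draw totals exactly K/2; expectation is K/8 per strain
  tot <- replicate(200, sum(sample_community(rep(0.25, 4), K = 10)$densities))
  expect_true(all(tot == 5))
  m <- rowMeans(replicate(2000, sample_community(rep(0.25, 4),
                                                 K = 10)$densities))
  expect_true(all(abs(m - 10 / 8) < 0.1))
  expect_error(sample_community(c(0, 0, 0, 0), K = 10), "extinct")
})

test_that("the ordered slot assignment has exactly 256 outcomes", {
  out <- inoculum_outcomes()
  expect_equal(nrow(out), 256L)
  key <- apply(out[, 1:4], 1, paste, collapse = "")
  expect_equal(anyDuplicated(key), 0L)
  expect_equal(length(unique(out$membership_mask)), 15L)
})

test_that("well-phase death rate reflects viability under the ecology draw", {
  cfg <- cycle_config()
  # rich point-mass ecology: nothing dies
  set.seed(5)
  wp <- run_well_phase(rep(0.25, 4), point_mass_dist(16), cfg)
  expect_equal(wp$death_rate, 0)
  expect_equal(sum(wp$ecology_histogram), cfg$n_wells)
  expect_equal(wp$ecology_histogram[16], cfg$n_wells)
  # pure HIS-up pool, uniform ecologies: death expectation 14/16
  set.seed(6)
  rates <- replicate(300, run_well_phase(c(0, 0, 1, 0),
                                         uniform_distribution(),
                                         cfg)$death_rate)
  expect_lt(abs(mean(rates) - 14 / 16), 0.02)
  # analytic expectation from exhaustive viability enumeration, per strain
  for (s in seq_along(strains())) {
    viable_n <- sum(vapply(1:16, function(i) viable(i, strains()[s]),
                           logical(1)))
    expect_equal(1 - viable_n / 16, 14 / 16)
  }
})

test_that("normalization rescales to the pool inoculum or flags extinction", {
  out <- normalize_to_pool(c(2, 2, 4, 2))
  expect_equal(unname(out$freqs), c(0.2, 0.2, 0.4, 0.2))
  expect_equal(sum(out$densities), 1)
  expect_false(out$extinct)
  out <- normalize_to_pool(c(0, 0, 0, 0))
  expect_true(out$extinct)
  expect_equal(unname(out$freqs), rep(0, 4))
})

test_that("a zero-cycle run records only the initial proportions", {
  res <- run_lineage(cycle_config(n_cycles = 0), seed = 1)
  expect_equal(nrow(res$records), 1L)
  expect_equal(unname(unlist(res$records[1, strains()])), rep(0.25, 4))
  expect_false(res$extinct)
})

test_that("proportions stay on the simplex until extinction, then zero", {
  # late metabolic feedback collapses the lineage
  res <- run_lineage(quick_config(t_pool = 1.28, n_cycles = 8),
                     feedback_start = 5, seed = 123)
  props <- as.matrix(res$records[, strains()])
  for (i in seq_len(nrow(props))) {
    cyc <- res$records$cycle[i]
    if (!res$extinct || cyc < res$extinction_cycle) {
      expect_equal(sum(props[i, ]), 1)
      expect_true(all(props[i, ] >= 0))
    } else {
      expect_equal(unname(props[i, ]), rep(0, 4))
      expect_equal(res$records$death_rate[res$records$cycle >
                                            res$extinction_cycle],
                   rep(1, sum(res$records$cycle > res$extinction_cycle)))
    }
  }
})

test_that("exchangeable strains stay near equal proportions in a rich ecology", {
  prm <- symmetric_params()
  final <- sapply(1:30, function(r) {
    res <- run_lineage(quick_config(n_cycles = 3), params = prm,
                       distribution = point_mass_dist(16), seed = 1000 + r)
    unlist(res$records[nrow(res$records), strains()])
  })
  expect_equal(unname(rowMeans(final)), rep(0.25, 4), tolerance = 0.05)
  # every run stays on the simplex with no deaths
  res <- run_lineage(quick_config(n_cycles = 3), params = prm,
                     distribution = point_mass_dist(16), seed = 9)
  expect_equal(res$records$death_rate[-1], rep(0, 3))
})

test_that("a fixed seed reproduces a run bit-identically", {
  cfg <- quick_config(t_pool = 1.28)
  a <- run_lineage(cfg, feedback_start = 3, seed = 77)
  b <- run_lineage(cfg, feedback_start = 3, seed = 77)
  expect_identical(a$records, b$records)
  expect_identical(a$ecology_histogram, b$ecology_histogram)
})

test_that("alternative inoculum and non-viable modes run coherently", {
  # multinomial individuals: K/2 unit draws, total still K/2
  cfg <- quick_config(inoculum_mode = "multinomial", n_cycles = 2)
  set.seed(8)
  wp <- run_well_phase(rep(0.25, 4), point_mass_dist(16), cfg)
  expect_equal(wp$death_rate, 0)
  res <- run_lineage(cfg, distribution = uniform_distribution(), seed = 21)
  expect_false(anyNA(res$records$death_rate[-1]))
  # exponential non-viable decay empties dead wells just as completely
  cfg2 <- quick_config(nonviable_mode = "exponential", t_pool = 1.28)
  res2 <- run_lineage(cfg2, seed = 22)
  props <- as.matrix(res2$records[, strains()])
  expect_true(all(abs(rowSums(props)[!res2$extinct |
    res2$records$cycle < res2$extinction_cycle] - 1) < 1e-9))
})

test_that("custom distribution schedules are honoured", {
  # function schedule: rich ecology on odd cycles, barren on even ones
  sched <- function(cycle, freqs) {
    if (cycle %% 2 == 1) point_mass_dist(16) else point_mass_dist(1)
  }
  res <- run_lineage(quick_config(n_cycles = 2), distribution = sched,
                     seed = 42)
  expect_equal(res$records$death_rate[2], 0)  # rich: all viable
  # barren: only wells containing all four strains survive
  expect_gte(res$records$death_rate[3], 0)
  expect_equal(sum(res$ecology_histogram[1, ]), 24)
})
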