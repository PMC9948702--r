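test_that("uniform distribution is exactly 1/16 everywhere", {
  d <- uniform_distribution()
  expect_equal(d, rep(0.0625, 16))
  expect_equal(sum(d), 1)
  expect_equal(d[14] + d[16], 0.125)
})

test_that("poisson weighting shifts mass toward rich ecologies as mu grows", {
  # mu = 1: indices 1 and 2 tie for the mode (PMF equal at k = 0 and 1)
  d1 <- poisson_distribution(1)
  expect_equal(d1[2], max(d1))
  expect_equal(d1[1], d1[2])
  expect_equal(sum(d1), 1)
  # direct PMF oracle
  expect_equal(d1, dpois(0:15, 1) / sum(dpois(0:15, 1)))
  # the two HIS-permissive ecologies (14, 16) gain mass monotonically in mu
  grid <- c(0.5, 1, 2, 3.5, 5, 9, 12)
  mass14_16 <- vapply(grid, function(mu) {
    d <- poisson_distribution(mu)
    d[14] + d[16]
  }, numeric(1))
  expect_true(all(diff(mass14_16) > 0))
  d9 <- poisson_distribution(9)
  expect_gt((d9[14] + d9[16]) / (d1[14] + d1[16]), 1e6)
  # expected ecology index is non-decreasing in mu
  mean_idx <- vapply(grid, function(mu) {
    sum(poisson_distribution(mu) * 1:16)
  }, numeric(1))
  expect_true(all(diff(mean_idx) >= 0))
  expect_error(poisson_distribution(0), "positive")
  expect_error(poisson_distribution(-2), "positive")
})

test_that("metabolic feedback is the product-Bernoulli of producer frequencies", {
  # a pool fixed for HIS-up only ever generates the HIS-only ecology,
  # where the HIS-up monoculture itself starves
  d <- feedback_distribution(c(0, 0, 1, 0))
  his_only <- ecology_index(c(0, 0, 1, 0))
  expect_equal(d[his_only], 1)
  expect_equal(sum(d), 1)
  expect_false(viable(his_only, "HIS"))

  d <- feedback_distribution(rep(0.25, 4))
  expect_equal(d[1], 0.75^4) # barren ecology: all four absent
  expect_equal(d[1], 0.31640625)
  expect_equal(sum(d), 1)

  # marginals equal the producer frequencies, equivariantly under permutation
  marginal <- function(d) {
    pres <- as.matrix(enumerate_ecologies()[, metabolites()])
    drop(d %*% pres)
  }
  f <- c(0.1, 0.2, 0.3, 0.4)
  expect_equal(unname(marginal(feedback_distribution(f))), f)
  perm <- c(3, 1, 4, 2)
  expect_equal(unname(marginal(feedback_distribution(f[perm]))), f[perm])

  # 4x scaling saturates at 1
  d4 <- feedback_distribution(c(0.5, 0.5, 0, 0), scaling = "4x")
  expect_equal(sum(d4[enumerate_ecologies()$ADE == 1 &
                        enumerate_ecologies()$TRP == 1]), 1)

  expect_error(feedback_distribution(c(0.5, 0.5, 0.5, 0.5)), "sum to 1")
  expect_error(feedback_distribution(c(-0.5, 0.5, 0.5, 0.5)), "non-negative")
})

test_that("keystone restriction removes banned ecologies and renormalizes", {
  d <- restrict_distribution(uniform_distribution(), "TRP")
  eco <- enumerate_ecologies()
  expect_equal(sum(d > 0), 8L)
  expect_equal(d[eco$TRP == 0], rep(0.125, 8))
  expect_equal(d[eco$TRP == 1], rep(0, 8))
  expect_equal(sum(d), 1)
  # banning everything that carries mass is an error
  trp_only <- point_mass_dist(ecology_index(c(0, 1, 0, 0)))
  expect_error(restrict_distribution(trp_only, "TRP"), "mass")
})

test_that("sampling frequencies match each distribution (chi-square GOF)", {
  set.seed(202)
  n <- 1e5
  for (d in list(uniform_distribution(),
                 feedback_distribution(c(0.1, 0.2, 0.3, 0.4)))) {
    counts <- tabulate(sample_ecologies(d, n), nbins = 16)
    p <- suppressWarnings(chisq.test(counts[d > 0], p = d[d > 0]))$p.value
    expect_gt(p, 0.001)
  }
  # poisson tails have tiny expected counts: use a simulated null
  d <- poisson_distribution(3.5)
  counts <- tabulate(sample_ecologies(d, n), nbins = 16)
  p <- chisq.test(counts, p = d, simulate.p.value = TRUE, B = 2000)$p.value
  expect_gt(p, 0.001)
})

test_that("distribution validation catches malformed vectors", {
  expect_error(as_ecology_distribution(rep(0.1, 10)), "16")
  expect_error(as_ecology_distribution(c(rep(0.07, 15), -0.05)),
               "non-negative")
  expect_error(as_ecology_distribution(rep(0.07, 16)), "sum to 1")
})
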