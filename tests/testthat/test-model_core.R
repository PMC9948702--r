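test_that("ecology enumeration is a canonical bijection over the 16 states", {
  eco <- enumerate_ecologies()
  expect_equal(nrow(eco), 16L)
  pres <- as.matrix(eco[, metabolites()])
  expect_equal(anyDuplicated(apply(pres, 1, paste, collapse = "")), 0L)
  # richness-ascending ordering with the stated extremes
  expect_equal(unname(pres[1, ]), c(0L, 0L, 0L, 0L))
  expect_equal(unname(pres[16, ]), c(1L, 1L, 1L, 1L))
  expect_true(all(diff(eco$richness) >= 0))
  # index 14 is (1,1,0,1): ADE, TRP, LYS present, HIS absent
  expect_equal(unname(ecology_presence(14)), c(1L, 1L, 0L, 1L))
  # index -> presence -> index is the identity
  for (i in 1:16) expect_identical(ecology_index(ecology_presence(i)), i)
})

test_that("strain identities cover the four metabolites", {
  expect_setequal(vapply(strains(), strain_produces, character(1)),
                  metabolites())
  for (s in strains()) {
    req <- strain_requires(s)
    expect_length(req, 3L)
    expect_false(strain_produces(s) %in% req)
  }
})

test_that("metabolite_source distinguishes ecology, cross-feeding and absence", {
  all4 <- strains()
  expect_equal(metabolite_source(c(1, 1, 1, 1), all4, "HIS"), "ECOLOGY")
  expect_equal(metabolite_source(c(0, 0, 0, 0), all4, "HIS"), "CROSSFED")
  expect_equal(metabolite_source(c(0, 0, 0, 0), c("ADE", "TRP"), "HIS"),
               "ABSENT")
  # ecology supply shadows cross-feeding when both are present
  expect_equal(metabolite_source(c(0, 0, 1, 0), c("HIS", "ADE"), "HIS"),
               "ECOLOGY")
})

test_that("viability requires every member's three foreign metabolites", {
  expect_false(viable(c(1, 1, 0, 0), c("ADE", "TRP")))
  expect_true(viable(c(0, 0, 0, 0), strains()))
  expect_true(viable(c(1, 1, 1, 1), "HIS"))
  expect_false(viable(c(0, 0, 0, 0), "HIS"))
  expect_false(viable(16, character(0))) # empty community is non-viable
})

all_memberships <- function() {
  out <- list()
  for (m in 1:15) out[[m]] <- strains()[bitwAnd(m, c(8L, 4L, 2L, 1L)) > 0L]
  out
}

test_that("viability is monotone in the ecology and total at the rich one", {
  eco <- enumerate_ecologies()
  for (S in all_memberships()) {
    expect_true(viable(16, S)) # rich ecology supports every community
    for (i in 1:16) {
      if (!viable(i, S)) next
      pres <- ecology_presence(i)
      for (m in which(pres == 0L)) {
        richer <- pres
        richer[m] <- 1L
        expect_true(viable(richer, S))
      }
    }
  }
})

test_that("exactly two ecologies support each monoculture", {
  for (s in strains()) {
    ok <- which(vapply(1:16, function(i) viable(i, s), logical(1)))
    expect_length(ok, 2L)
    expect_equal(ok[2], 16L)
  }
  # the HIS-up monoculture survives precisely in ecologies 14 and 16
  expect_equal(which(vapply(1:16, function(i) viable(i, "HIS"), logical(1))),
               c(14L, 16L))
})

test_that("growth rates follow the override and parametric rules", {
  params <- growth_params()
  # shipped override: barren ecology, all four strains
  expect_equal(unname(growth_rates(1, strains(), params)),
               unname(printed_rates))
  # non-viable pairing: every member at the death rate
  expect_equal(unname(growth_rates(ecology_index(c(1, 1, 0, 0)),
                                   c("ADE", "TRP"), params)),
               c(-2, -2))
  # fully supplemented monoculture: exactly the base rate (factor^0 = 1)
  expect_equal(growth_rates(16, "HIS", params)[["HIS"]],
               params$base_rates[["HIS"]])
  # one cross-fed requirement: one factor
  # ecology (1,1,0,1) + {HIS, LYS}: HIS gets ADE,TRP,LYS from ecology;
  # LYS gets ADE,TRP from ecology and HIS cross-fed
  r <- growth_rates(14, c("HIS", "LYS"), params)
  expect_equal(r[["HIS"]], params$base_rates[["HIS"]])
  expect_equal(r[["LYS"]],
               params$base_rates[["LYS"]] * params$crossfeed_factor)
})

test_that("rates are the death rate iff non-viable, over all pairings", {
  params <- growth_params()
  for (i in 1:16) {
    for (S in all_memberships()) {
      r <- growth_rates(i, S, params)
      expect_length(r, length(S))
      if (viable(i, S)) {
        expect_true(all(r > 0))
      } else {
        expect_true(all(r == params$death_rate))
      }
    }
  }
})

test_that("the parametric rule and shipped override agree at the calibration point", {
  params <- growth_params(overrides = NULL)
  expect_equal(unname(growth_rates(1, strains(), params)),
               unname(printed_rates), tolerance = 1e-12)
})

test_that("override validation rejects malformed tables", {
  bad_mask <- data.frame(ecology_index = 1, membership_mask = "111",
                         strain = "ADE", rate = 1)
  expect_error(growth_params(overrides = bad_mask), "mask")
  not_member <- data.frame(ecology_index = 1, membership_mask = "0111",
                           strain = "ADE", rate = 1)
  expect_error(growth_params(overrides = not_member), "absent")
  dup <- default_overrides()[c(1, 1), ]
  expect_error(growth_params(overrides = dup), "duplicate")
  bad_idx <- data.frame(ecology_index = 17, membership_mask = "1111",
                        strain = "ADE", rate = 1)
  expect_error(growth_params(overrides = bad_idx), "ecology_index")
})

test_that("membership masks round-trip", {
  expect_equal(membership_mask(c("ADE", "HIS")), "1010")
  expect_equal(membership_mask(strains()), "1111")
  for (S in all_memberships()) {
    expect_setequal(poolwell:::mask_to_members(membership_mask(S)), S)
  }
})
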