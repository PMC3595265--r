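quiet_params <- function(...) sim_params(crossover_rate = 0,
                                         conversion_rate = 0, ...)

test_that("with all rates zero every life-cycle operation preserves the array", {
  cell <- cell_state(rep(c("Z", "Y"), c(60, 65)))
  kids <- mitotic_division(cell, quiet_params())
  expect_length(kids, 2)
  for (k in kids) expect_identical(as.character(k$array),
                                   as.character(cell$array))
  spores <- meiotic_ascospores(cell, quiet_params())
  expect_length(spores, 8)
  for (s in spores) expect_identical(as.character(s$array),
                                     as.character(cell$array))
  tip <- hyphal_tip_transfer(cell, quiet_params(), divisions = 7)
  expect_identical(as.character(tip$array), as.character(cell$array))
  expect_equal(tip$generation, 7)
  same <- hyphal_tip_transfer(cell, quiet_params(), divisions = 0)
  expect_identical(as.character(same$array), as.character(cell$array))
})

test_that("fully reciprocal divisions conserve the summed daughter length", {
  set.seed(3)
  pars <- sim_params(crossover_rate = 2, reciprocal_fraction = 1,
                     n_min = 1, n_max = 10000)
  cell <- cell_state(rep(c("Z", "Y"), c(60, 60)))
  for (rep in 1:20) {
    kids <- mitotic_division(cell, pars)
    expect_equal(sum(lengths(lapply(kids, `[[`, "array"))),
                 2 * length(cell$array))
  }
  spores <- meiotic_ascospores(cell, pars)
  expect_length(spores, 8)
  expect_equal(sum(lengths(lapply(spores, `[[`, "array"))),
               8 * length(cell$array))
})

test_that("every daughter returned by a division respects the viability bounds", {
  set.seed(8)
  pars <- sim_params(crossover_rate = 3, reciprocal_fraction = 0.3,
                     conversion_rate = 1, n_min = 40, n_max = 200)
  cell <- cell_state(rep(c("Z", "Y"), c(60, 60)))
  for (rep in 1:50) {
    kids <- mitotic_division(cell, pars)
    for (k in kids) {
      expect_gte(length(k$array), 40)
      expect_lte(length(k$array), 200)
    }
  }
  set.seed(8)
  pars_death <- sim_params(crossover_rate = 3, reciprocal_fraction = 0.3,
                           n_min = 40, n_max = 200,
                           boundary_policy = "death")
  for (rep in 1:50) {
    kids <- mitotic_division(cell, pars_death)
    expect_gte(length(kids), 1)
    for (k in kids) {
      expect_gte(length(k$array), 40)
      expect_lte(length(k$array), 200)
    }
  }
})

test_that("a non-viable parameterization is reported, not looped forever", {
  pars <- sim_params(crossover_rate = 30, reciprocal_fraction = 0.5,
                     n_min = 10, n_max = 10, retry_cap = 5)
  cell <- cell_state(rep(c("Z", "Y"), c(5, 5)))
  expect_error(mitotic_division(cell, pars), "retry|non-viable")
})

test_that("seeded hyphal-tip transfers are reproducible", {
  pars <- sim_params(crossover_rate = 0.5)
  cell <- cell_state(rep(c("Z", "Y"), c(60, 65)))
  set.seed(123)
  a <- hyphal_tip_transfer(cell, pars)
  set.seed(123)
  b <- hyphal_tip_transfer(cell, pars)
  expect_identical(as.character(a$array), as.character(b$array))
})

test_that("neutral divisions leave the mean variant frequency unchanged", {
  set.seed(21)
  pars <- sim_params(crossover_rate = 0.5, n_min = 12, n_max = 600)
  # independent lineages: fresh arrangement per replicate (a single fixed
  # arrangement has a small deterministic arrangement bias)
  freqs <- replicate(4000, {
    cell <- cell_state(sample(rep(c("Z", "Y"), c(60, 60))))
    kids <- mitotic_division(cell, pars)
    k <- kids[[sample.int(length(kids), 1)]]
    type_frequency(composition(k$array, c("Z", "Y")), "Z")
  })
  se <- stats::sd(freqs) / sqrt(length(freqs))
  expect_lt(abs(mean(freqs) - 0.5), 2 * se + 1e-12)
})

test_that("a lineage with no exchange mechanism never homogenizes", {
  cell <- cell_state(rep(c("Z", "Y"), c(10, 10)))
  r <- fixation_run(cell, quiet_params(), max_divisions = 30)
  expect_true(r$censored)
  expect_identical(r$fixed_type, NA_character_)
  # already-monotypic lineage fixes instantly
  r0 <- fixation_run(cell_state(rep("Z", 10)), quiet_params())
  expect_equal(r0$divisions, 0)
  expect_identical(r0$fixed_type, "Z")
})

test_that("homogenization proceeds: monotypic lineages accumulate over time", {
  set.seed(31)
  pars <- sim_params(crossover_rate = 1, n_min = 2, n_max = 100)
  horizon <- c(10, 40, 160)
  frac_fixed <- vapply(horizon, function(h) {
    mean(replicate(60, {
      r <- fixation_run(cell_state(sample(rep(c("Z", "Y"), c(10, 10)))),
                        pars, max_divisions = h)
      !r$censored
    }))
  }, numeric(1))
  # non-decreasing within sampling error (one-sided 2 SE slack)
  slack <- 2 * sqrt(0.25 / 60)
  expect_true(all(diff(frac_fixed) > -slack))
  expect_gt(frac_fixed[length(frac_fixed)], frac_fixed[1] - slack)
})
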