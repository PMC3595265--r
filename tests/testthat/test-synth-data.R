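test_that("clone sampling respects the composition and the sample size", {
  expect_equal(sample_clones(c(Z = 40, Y = 0), 60),
               c(Z = 60L, Y = 0L))
  expect_equal(sample_clones(c(Z = 0, Y = 40), 10, "hypergeometric"),
               c(Z = 0L, Y = 10L))
  expect_error(sample_clones(c(Z = 5, Y = 5), 20, "hypergeometric"),
               "without replacement")
  set.seed(1)
  a <- sample_clones(c(Z = 60, Y = 60), 60)
  set.seed(1)
  b <- sample_clones(c(Z = 60, Y = 60), 60)
  expect_identical(a, b)
  expect_equal(sum(a), 60)
})

test_that("binomial clone sampling is unbiased for the composition frequency", {
  set.seed(33)
  draws <- replicate(10000, sample_clones(c(Z = 60, Y = 60), 60)[["Z"]])
  se <- sqrt(60 * 0.5 * 0.5 / 10000)
  expect_lt(abs(mean(draws) - 30), 2 * se)
})

test_that("null datasets have the designed shape and exact row sums", {
  des <- study_design(seed = 10)
  tab <- generate_null_dataset(des)
  expect_equal(nrow(tab), 4 + 4 * 2 * 5)
  expect_true(all(tab$total == 60))
  expect_true(all(tab$count_Z + tab$count_Y == 60))
  expect_equal(sum(tab$stage == "baseline"), 4)
  empty <- generate_null_dataset(study_design(n_transfers = 0, seed = 1))
  expect_true(all(empty$stage == "baseline"))
})

test_that("generation is bit-reproducible from design and seed", {
  des <- study_design(seed = 77)
  expect_identical(generate_null_dataset(des), generate_null_dataset(des))
  prs <- sim_params(crossover_rate = 0.2)
  d1 <- generate_drift_dataset(des, prs)
  d2 <- generate_drift_dataset(des, prs)
  expect_identical(d1$counts, d2$counts)
  expect_identical(d1$trajectories, d2$trajectories)
})

test_that("drift datasets with zero rates keep the true composition fixed", {
  des <- study_design(isolates = c("A", "B"), seed = 4)
  d <- generate_drift_dataset(des, sim_params(crossover_rate = 0,
                                              conversion_rate = 0))
  expect_true(all(d$trajectories$true_Z == round(0.5 * 125)))
  expect_true(all(d$trajectories$array_length == 125))
  expect_true(all(d$counts$count_Z + d$counts$count_Y == 60))
})

test_that("drift datasets track the simulator and log true trajectories", {
  des <- study_design(isolates = "A", seed = 19)
  d <- generate_drift_dataset(des, sim_params(crossover_rate = 0.5,
                                              reciprocal_fraction = 0.3))
  tr <- d$trajectories
  expect_equal(nrow(tr), 2 * 5)
  expect_true(all(tr$true_Z + tr$true_Y == tr$array_length))
  expect_true(all(tr$array_length >= 12 & tr$array_length <= 600))
  # mitotic lineage drifts: not every observation equals the baseline
  expect_gt(stats::sd(tr$true_Z / tr$array_length), 0)
})

test_that("fixture generation honours arbitrary compatible cut maps", {
  fx <- make_amplicon_fixtures(seed = 5, amplicon_length = 500,
                               cuts = list(Z = 250L, Y = c(100L, 400L)))
  site <- recognition_site()
  expect_equal(find_sites(fx[["type_Z"]], site), 250L)
  expect_equal(find_sites(fx[["type_Y"]], site), c(100L, 400L))
  expect_error(
    make_amplicon_fixtures(seed = 5, cuts = list(Z = 460L, Y = c(525L, 526L))),
    "overlap")
})
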