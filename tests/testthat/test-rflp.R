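test_that("recognition sites validate their pattern and cut offset", {
  s <- recognition_site("ACGT", 1)
  expect_equal(s$pattern, "ACGT")
  expect_error(recognition_site("ACXT"), "IUPAC")
  expect_error(recognition_site("ACGT", 5), "cut_offset")
  expect_error(recognition_site(""), "non-empty")
})

test_that("site search returns shifted, sorted, deduplicated cut positions", {
  site <- recognition_site("ACGT", 1)
  expect_equal(find_sites("ACGTACGT", site), c(1L, 5L))
  expect_equal(find_sites("GGGGGGGG", site), integer(0))
  expect_error(find_sites("AC!T", site))
  # IUPAC ambiguity in the pattern: AY matches AC and AT
  expect_equal(find_sites("ACGAT", recognition_site("AY", 0)), c(0L, 3L))
})

test_that("an engineered single-site amplicon cuts where it was placed", {
  site <- recognition_site()
  fx <- make_amplicon_fixtures(site, seed = 404)
  s <- as.character(fx[["type_Z"]])
  expect_equal(find_sites(s, site), 460L)
  # independent oracle: plain string search for the literal pattern
  hits <- gregexpr(site$pattern, s, fixed = TRUE)[[1]]
  expect_equal(as.integer(hits) - 1L + site$cut_offset, 460L)
})

test_that("digest fragments tile the linear amplicon", {
  expect_equal(digest(920, 460)$fragments, c(460L, 460L))
  expect_equal(digest(920)$fragments, 920L)
  expect_equal(digest(920, c(525, 860))$fragments, c(525L, 335L, 60L))
  expect_error(digest(920, c(0, 500)), "inside")
  expect_error(digest(920, 920), "inside")
  expect_error(digest(920, c(500, 400)), "increasing")
  set.seed(12)
  for (rep in 1:25) {
    len <- sample(100:2000, 1)
    cuts <- sort(sample(seq_len(len - 1), sample(0:6, 1)))
    d <- digest(len, cuts)
    expect_equal(sum(d$fragments), len)
    expect_length(d$fragments, length(cuts) + 1)
  }
})

test_that("the detectability filter drops only sub-threshold fragments", {
  expect_equal(detectable(c(525, 335, 60), 100), c(525, 335))
  expect_equal(detectable(numeric(0), 100), numeric(0))
  expect_equal(detectable(100, 100), 100)  # boundary kept by >= rule
  expect_equal(detectable(digest(920, c(525, 860))), c(525L, 335L))
})

test_that("clones are scored by tolerant multiset matching", {
  expect_equal(score_clone(c(460, 460)), "Z")
  expect_equal(score_clone(c(525, 335)), "Y")
  expect_equal(score_clone(920), "unknown")          # undigested
  expect_equal(score_clone(c(335, 525)), "Y")        # permutation-invariant
  expect_equal(score_clone(c(450, 470)), "Z")        # within 20 bp sizing
  expect_equal(score_clone(c(430, 460)), "unknown")  # 30 bp off
  # ambiguity scores unknown rather than guessing
  expect_equal(score_clone(c(460, 460),
                           patterns = list(A = c(460, 460),
                                           B = c(455, 465))),
               "unknown")
})

test_that("fixture amplicons round-trip through the full typing chain", {
  site <- recognition_site()
  fx <- make_amplicon_fixtures(site, seed = 2718)
  expected_cuts <- list(type_Z = 460L, type_Y = c(525L, 860L))
  expected_type <- c(type_Z = "Z", type_Y = "Y")
  for (nm in names(fx)) {
    cuts <- find_sites(fx[[nm]], site)
    expect_identical(cuts, expected_cuts[[nm]])
    d <- digest(Biostrings::nchar(fx[[nm]]), cuts)
    expect_equal(sum(d$fragments), 920)
    expect_equal(score_clone(detectable(d)), expected_type[[nm]])
  }
})

test_that("fixtures also work with an ambiguous, offset-cutting pattern", {
  site <- recognition_site("RCGY", 2)
  fx <- make_amplicon_fixtures(site, seed = 99)
  expect_identical(find_sites(fx[["type_Y"]], site), c(525L, 860L))
  expect_equal(score_clone(detectable(digest(920, c(525L, 860L)))), "Y")
})
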