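test_that("percentage normalization matches hand-computed profiles", {
  uni <- normalize_fractions(rep(3.5, 14))
  expect_equal(uni$percentages, rep(100 / 14, 14))
  expect_equal(sum(uni$percentages), 100)

  last <- normalize_fractions(c(rep(0, 13), 7))
  expect_equal(last$percentages, c(rep(0, 13), 100))

  tri <- normalize_fractions(1:14)
  expect_equal(tri$percentages, 100 * (1:14) / 105)

  expect_error(normalize_fractions(rep(1, 13)), "expected 14")
  expect_error(normalize_fractions(rep(0, 14)), "total abundance")
  expect_error(normalize_fractions(c(rep(1, 13), -1)), "non-negative")
  # configurable fraction count re-parameterizes the invariant
  expect_equal(sum(normalize_fractions(1:10, n_fractions = 10)$percentages),
               100)
})

test_that("normalization is idempotent and scale-invariant", {
  set.seed(31)
  for (k in 1:20) {
    raw <- runif(14, 0, 10)
    p1 <- normalize_fractions(raw)
    p2 <- normalize_fractions(p1$percentages)
    expect_equal(p2$percentages, p1$percentages)
    s <- runif(1, 0.01, 100)
    p3 <- normalize_fractions(s * raw)
    expect_equal(p3$percentages, p1$percentages)
    expect_equal(shift_summary(p3)$heavy_share, shift_summary(p1)$heavy_share)
    expect_equal(shift_summary(p3)$mean_fraction_index,
                 shift_summary(p1)$mean_fraction_index)
  }
})

test_that("shift summaries match hand-computed values", {
  uni <- normalize_fractions(rep(1, 14))
  s <- shift_summary(uni, heavy_start = 8)
  expect_equal(s$heavy_share, 700 / 14)
  expect_equal(s$mean_fraction_index, 7.5)

  light <- normalize_fractions(c(5, rep(0, 13)))
  s2 <- shift_summary(light)
  expect_equal(s2$heavy_share, 0)
  expect_equal(s2$mean_fraction_index, 1.0)

  expect_error(shift_summary(uni, heavy_start = 0), "heavy_start")
  expect_error(shift_summary(uni, heavy_start = 15), "heavy_start")
})

test_that("heavy_share is monotone non-increasing in heavy_start", {
  set.seed(44)
  for (k in 1:10) {
    p <- normalize_fractions(runif(14))
    shares <- vapply(1:14, function(h) shift_summary(p, h)$heavy_share, 0)
    expect_true(all(diff(shares) <= 1e-12))
  }
})

test_that("condition comparison is antisymmetric and guards mRNA identity", {
  a <- gen_polysome(rep(1 / 14, 14), shift = 0.15, mrna = "m", condition = "t",
                    seed = 1)
  b <- gen_polysome(rep(1 / 14, 14), shift = 0, mrna = "m", condition = "c",
                    seed = 2)
  ab <- compare_conditions(a, b)
  ba <- compare_conditions(b, a)
  expect_equal(ab$delta_heavy_share, -ba$delta_heavy_share)
  expect_equal(ab$delta_mean_index, -ba$delta_mean_index)
  expect_gt(ab$delta_heavy_share, 0)  # positive = first profile heavier

  same <- compare_conditions(a, a)
  expect_equal(same$delta_heavy_share, 0)
  expect_equal(same$delta_mean_index, 0)

  other <- gen_polysome(rep(1 / 14, 14), mrna = "other", seed = 3)
  expect_error(compare_conditions(a, other), "different mRNAs")
})

test_that("shifted-pair deltas match the closed-form expectation at depth", {
  mean_profile <- (14:1) / sum(14:1)  # light-biased baseline
  shift <- 0.2
  a <- gen_polysome(mean_profile, shift = shift, depth = 1e5, mrna = "m",
                    seed = 11)
  b <- gen_polysome(mean_profile, shift = 0, depth = 1e5, mrna = "m",
                    seed = 12)
  exp_a <- polysome_expected_percent(mean_profile, shift)
  exp_b <- polysome_expected_percent(mean_profile, 0)
  truth <- sum(exp_a[8:14]) - sum(exp_b[8:14])
  d <- compare_conditions(a, b)
  # multinomial SE of a percentage at depth 1e5 is ~0.16 points; allow 4 SE
  expect_lt(abs(d$delta_heavy_share - truth), 0.65)
})

test_that("long-format fraction tables round-trip through normalization", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "frac.tsv")
  tab <- expand.grid(fraction_index = 1:14,
                     mrna = c("CXCL8", "ACTB"),
                     condition = "mac", stringsAsFactors = FALSE)
  set.seed(9)
  tab$abundance <- runif(nrow(tab), 0.1, 5)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  profs <- read_fraction_table(path)
  expect_length(profs, 2L)
  raw <- tab$abundance[tab$mrna == "CXCL8"]
  expect_equal(profs[["CXCL8:mac"]]$percentages, 100 * raw / sum(raw))

  bad <- tab[-1, ]
  utils::write.table(bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_fraction_table(path), "exactly once")
})
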