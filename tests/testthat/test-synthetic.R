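test_that("generators are pure functions of parameters and seed", {
  expect_identical(gen_transcript(seed = 42)$seq, gen_transcript(seed = 42)$seq)
  expect_false(identical(gen_transcript(seed = 42)$seq,
                         gen_transcript(seed = 43)$seq))
  ref <- gen_transcript(seed = 1)
  expect_identical(gen_homolog_set(ref, seed = 9)[[1]]$seq,
                   gen_homolog_set(ref, seed = 9)[[1]]$seq)
  expect_identical(gen_ct_table(c(a = 2), seed = 4),
                   gen_ct_table(c(a = 2), seed = 4))
  expect_identical(gen_polysome(rep(1 / 14, 14), seed = 4)$fractions,
                   gen_polysome(rep(1 / 14, 14), seed = 4)$fractions)

  # generators draw from named substreams: the global RNG is untouched
  set.seed(1234); before <- .Random.seed
  invisible(gen_transcript(seed = 5))
  expect_identical(.Random.seed, before)
})

test_that("gen_transcript hits its compositional targets", {
  pure <- gen_transcript(utr3_len = 400, au_utr3 = 1.0, seed = 2)
  utr3 <- extract_utrs(pure)$utr3
  expect_equal(au_fraction(utr3), 1.0)
  expect_equal(au_profile(utr3)$first100_au, 1.0)

  # CDS structure: starts ATG, ends with a stop, frame intact
  tx <- gen_transcript(cds_len = 99, seed = 3)
  cds <- substr(tx$seq, tx$cds_start, tx$cds_end)
  expect_equal(substr(cds, 1, 3), "ATG")
  expect_true(substr(cds, 97, 99) %in% c("TAA", "TAG", "TGA"))

  # binomial concentration of the realized proximal AU around its target
  target <- 0.6
  band <- 3 * sqrt(target * (1 - target) / 100)
  hits <- 0L
  for (s in 1:200) {
    tx <- gen_transcript(utr3_len = 400, au_utr3 = target, seed = s)
    f <- au_profile(extract_utrs(tx)$utr3)$first100_au
    if (abs(f - target) <= band) hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.99)
})

test_that("proximal AU override shapes only the 3'-UTR head", {
  tx <- gen_transcript(utr3_len = 400, au_utr3 = 0.2,
                       proximal_au = list(len = 100, au = 0.9), seed = 6)
  utr3 <- extract_utrs(tx)$utr3
  expect_gt(au_profile(utr3)$first100_au, 0.5)
  expect_lt(au_fraction(subregion(utr3, 101, 400)), 0.5)
  expect_true(classify_aps(utr3)$is_aps_positive)
})

test_that("homologs are exact copies at rate 0 and diverge at rate 0.5", {
  ref <- gen_transcript(utr3_len = 200, seed = 8)
  utr3 <- extract_utrs(ref)$utr3
  same <- gen_homolog_set(utr3, n_species = 3, substitution_rate = 0,
                          seed = 2)
  for (h in same) expect_identical(h$seq, utr3$seq)

  # the conserved block is never substituted
  hom <- gen_homolog_set(utr3, n_species = 5, substitution_rate = 0.5,
                         conserved_block = c(50, 37), seed = 3)
  for (h in hom)
    expect_identical(substr(h$seq, 50, 86), substr(utr3$seq, 50, 86))
  expect_error(gen_homolog_set(utr3, conserved_block = c(190, 37)),
               "outside")

  # null: at rate 0.5 with no block, no long perfect column run
  long_runs <- 0L
  for (s in 1:40) {
    h <- gen_homolog_set(utr3, n_species = 4, substitution_rate = 0.5,
                         seed = s)
    b <- find_conserved_blocks(utr3, h, min_len = 15)
    if (nrow(b) > 0L) long_runs <- long_runs + 1L
  }
  expect_lte(long_runs / 40, 0.05)
})

test_that("noiseless quantification inputs round-trip exactly", {
  ct <- gen_ct_table(c(s = 4), ct_sigma = 0, n_replicates = 3, seed = 1)
  expect_equal(ddct_table(ct, "target", "ref", "control")$fold_change[1], 4.0)

  lum <- gen_luminescence(true_ratio = 8, cv = 0, n = 4, seed = 1)
  expect_equal(reporter_fold_change(lum$utr, lum$control)$summary, 3.0)

  b <- gen_bands(c(control = 1.0, inhibitor = 0.125), band_cv = 0, seed = 1)
  ph <- b[b$protein == "phospho", ]; tot <- b[b$protein == "total", ]
  wr <- western_ratio(ph$raw, tot$raw, background = ph$background,
                      lanes = ph$lane)
  expect_equal(phospho_fold_change(wr$ratio[1], wr$ratio[2]), 8.0)
})

test_that("unshifted polysome sampling converges to its mean profile", {
  mean_profile <- (1:14) / sum(1:14)
  prof <- gen_polysome(mean_profile, shift = 0, depth = 1e6, seed = 10)
  expect_lt(max(abs(prof$percentages - 100 * mean_profile)), 0.2)
  expect_error(gen_polysome(c(0.5, 0.6)), "sum to 1")
})

test_that("estimator bias stays within Monte-Carlo error across seeds", {
  # ddct fold under Ct noise
  folds <- vapply(1:100, function(s) {
    ct <- gen_ct_table(c(s = 4), ct_sigma = 0.2, n_replicates = 3, seed = s)
    ddct_table(ct, "target", "ref", "control")$fold_change[1]
  }, 0)
  se <- stats::sd(folds) / sqrt(length(folds))
  expect_lt(abs(mean(folds) - 4), max(3 * se, 0.15))

  # reporter log2 fold under 10% CV
  l2 <- vapply(1:100, function(s) {
    lum <- gen_luminescence(true_ratio = 4, cv = 0.1, n = 6, seed = s)
    reporter_fold_change(lum$utr, lum$control)$summary
  }, 0)
  se2 <- stats::sd(l2) / sqrt(length(l2))
  expect_lt(abs(mean(l2) - 2), max(3 * se2, 0.05))

  # heavy-share delta under multinomial sampling
  mean_profile <- rep(1 / 14, 14)
  truth <- sum(polysome_expected_percent(mean_profile, 0.1)[8:14]) - 50
  deltas <- vapply(1:100, function(s) {
    a <- gen_polysome(mean_profile, shift = 0.1, mrna = "m", seed = s)
    b <- gen_polysome(mean_profile, shift = 0, mrna = "m", seed = s + 5000)
    compare_conditions(a, b)$delta_heavy_share
  }, 0)
  se3 <- stats::sd(deltas) / sqrt(length(deltas))
  expect_lt(abs(mean(deltas) - truth), 3 * se3)
})
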