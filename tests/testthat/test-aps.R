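test_that("au_fraction counts A/T with N in the denominator only", {
  expect_equal(au_fraction("ATATAT"), 1.0)
  expect_equal(au_fraction("GCGCGC"), 0.0)
  expect_equal(au_fraction("ATGC"), 0.5)
  expect_equal(au_fraction("ATNNG"), 0.4)
  expect_error(au_fraction(""), "empty")
})

test_that("au_profile windows match brute-force recounts", {
  # constant-composition windows
  block <- paste0(strrep("AT", 30), strrep("GC", 20))  # 60% AU per 100 nt
  s <- strrep(block, 3)
  prof <- au_profile(region("c", "custom", 1, nchar(s), s),
                     window = 100, step = 100)
  expect_equal(prof$points$au_fraction, rep(0.6, 3))

  two <- paste0(strrep("AT", 50), strrep("GC", 50))
  prof2 <- au_profile(two, window = 100, step = 100)
  expect_equal(prof2$points$au_fraction, c(1.0, 0.0))

  # oracle recount of every window on a random region
  set.seed(33)
  s <- random_seq(500)
  prof3 <- au_profile(s, window = 100, step = 10)
  expect_equal(prof3$points$window_start, seq(1, 401, by = 10))
  for (i in seq_len(nrow(prof3$points))) {
    w0 <- prof3$points$window_start[i]
    expect_equal(prof3$points$au_fraction[i],
                 oracle_au_fraction(substr(s, w0, w0 + 99)))
  }
  expect_false(prof3$short_region_flag)
  expect_equal(prof3$first100_au, oracle_au_fraction(substr(s, 1, 100)))

  # short regions: no full window, flagged proximal statistic
  short <- au_profile(random_seq(60), window = 100, step = 10)
  expect_equal(nrow(short$points), 0L)
  expect_true(short$short_region_flag)
  expect_error(au_profile(s, window = 0), "positive")
})

test_that("classify_aps applies strict AU threshold and inclusive length", {
  head60 <- paste0(strrep("AT", 30), strrep("GC", 20))  # 60 AU / 100
  pos <- paste0(head60, random_seq_gc(300))
  call <- classify_aps(pos)
  expect_true(call$is_aps_positive)
  expect_equal(call$first100_au_percent, 60)

  # 299 nt with 90% AU head: length rule is inclusive at 300, so 299 fails
  head90 <- paste0(strrep("AT", 45), strrep("GC", 5))
  short <- paste0(head90, random_seq_gc(199))
  call2 <- classify_aps(short)
  expect_false(call2$length_ok)
  expect_true(call2$au_ok)
  expect_false(call2$is_aps_positive)
  call2b <- classify_aps(paste0(head90, random_seq_gc(200)))
  expect_true(call2b$is_aps_positive)

  # exactly 50% AU head: strict exceed, negative
  head50 <- paste0(strrep("AT", 25), strrep("GC", 25))
  call3 <- classify_aps(paste0(head50, random_seq_gc(300)))
  expect_true(call3$length_ok)
  expect_false(call3$au_ok)
  expect_false(call3$is_aps_positive)
})

test_that("classify_aps matches the brute-force oracle on random UTRs", {
  set.seed(77)
  for (k in 1:300) {
    n <- sample(50:2000, 1)
    s <- random_seq(n)
    call <- classify_aps(s)
    expect_identical(call$is_aps_positive, oracle_aps_positive(s))
    expect_equal(call$first100_au_percent,
                 100 * oracle_au_fraction(substr(s, 1, min(100, n))))
  }
})

test_that("classify_aps is invariant under U/T representation", {
  set.seed(13)
  for (k in 1:20) {
    s <- random_seq(400)
    rna <- chartr("T", "U", s)
    expect_identical(classify_aps(s)$is_aps_positive,
                     classify_aps(rna)$is_aps_positive)
    expect_equal(classify_aps(s)$first100_au_percent,
                 classify_aps(rna)$first100_au_percent)
  }
})

test_that("raising threshold or min_len never turns a negative call positive", {
  set.seed(41)
  for (k in 1:10) {
    s <- random_seq(sample(100:600, 1))
    grid <- expand.grid(threshold = c(30, 40, 50, 60, 70),
                        min_len = c(100, 200, 300, 400))
    calls <- mapply(function(th, ml)
      classify_aps(s, threshold = th, min_len = ml)$is_aps_positive,
      grid$threshold, grid$min_len)
    for (i in seq_len(nrow(grid))) for (j in seq_len(nrow(grid))) {
      if (grid$threshold[j] >= grid$threshold[i] &&
          grid$min_len[j] >= grid$min_len[i] && calls[j])
        expect_true(calls[i])
    }
  }
})

test_that("scan_are finds overlapping pentamers and clusters nearby hits", {
  one <- scan_are("ATTTA")
  expect_equal(one$start, 1L)
  expect_equal(one$end, 5L)

  tandem <- scan_are("ATTTATTTA")
  expect_equal(tandem$start, c(1L, 5L))
  expect_equal(unique(tandem$cluster_id), 1L)

  expect_equal(nrow(scan_are("GGGGGGG")), 0L)

  # hits separated by more than the cluster gap get distinct clusters
  spread <- scan_are(paste0("ATTTA", strrep("G", 6), "ATTTA"))
  expect_equal(spread$cluster_id, c(1L, 2L))
  near <- scan_are(paste0("ATTTA", strrep("G", 5), "ATTTA"))
  expect_equal(near$cluster_id, c(1L, 1L))
})
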