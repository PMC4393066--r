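test_that("jsd_divergence matches the entropy decomposition", {
  # identical halves
  expect_equal(jsd_divergence(10, 4, 10, 4), 0)
  # maximal contrast: all-GC vs all-AT, equal sizes
  expect_equal(jsd_divergence(4, 4, 4, 0), 1)
  # frozen value computed from the three entropy terms by hand:
  # left 8 bp / 6 GC, right 8 bp / 2 GC; pooled p = 0.5 so H2(p) = 1,
  # H2(0.75) = H2(0.25) = 0.8112781244591328 -> D = 0.1887218755408672
  expect_equal(jsd_divergence(8, 6, 8, 2), 0.1887218755408672,
               tolerance = 1e-15)
  expect_error(jsd_divergence(0, 0, 4, 2), "non-empty")
  expect_true(all(jsd_divergence(c(5, 9), c(1, 8), c(7, 3), c(6, 1)) >= 0))
})

test_that("best_split finds the forced split and honours min_len", {
  bs <- best_split(gcd_sequence("x", "GGGGAAAA"), min_len = 1)
  expect_equal(bs$position, 4)
  expect_equal(bs$djs, 1)
  expect_null(best_split(gcd_sequence("x", "GGGGAAAA"), min_len = 5))
  # ties break toward the leftmost position
  bs2 <- best_split(gcd_sequence("x", "GAGAGAGA"), min_len = 2)
  d <- vapply(2:6, function(k)
    jsd_divergence(k, sum(strsplit("GAGAGAGA", "")[[1]][1:k] == "G"),
                   8 - k, 4 - sum(strsplit("GAGAGAGA", "")[[1]][1:k] == "G")),
    numeric(1))
  expect_equal(bs2$position, (2:6)[which.max(d)])
})

test_that("best_split agrees with an exhaustive brute-force scan", {
  set.seed(37)
  for (i in 1:60) {
    n <- sample(40:400, 1)
    res <- random_residues(n, runif(1, 0.2, 0.8))
    ml <- sample(c(2, 5, 11), 1)
    got <- best_split(gcd_sequence("x", res), min_len = ml)
    want <- brute_force_split(res, ml)
    expect_equal(got$position, want$position)
    expect_equal(got$djs, want$djs, tolerance = 1e-12)
  }
})

test_that("GC counts are additive across any split", {
  set.seed(41)
  s <- gcd_sequence("x", random_residues(500, 0.45))
  ind <- as.integer(strsplit(seq_residues(s), "")[[1]] %in% c("G", "C"))
  total <- sum(ind)
  for (k in c(1, 100, 250, 499)) {
    expect_equal(sum(ind[1:k]) + sum(ind[(k + 1):500]), total)
  }
})

test_that("segmentation tiles its region and is deterministic", {
  m <- test_model()
  set.seed(43)
  sp <- synthetic_genome_spec(
    tibble::tibble(length = c(12000, 9000, 15000), gc = c(0.3, 0.6, 0.4)),
    seed = 77)
  g <- generate_genome(sp)
  d1 <- segment_sequence(g$sequence, m)
  d2 <- segment_sequence(g$sequence, m)
  expect_identical(d1, d2)
  expect_equal(d1$start[1], 0)
  expect_equal(d1$end[nrow(d1)], seq_length(g$sequence))
  expect_true(all(d1$start[-1] == d1$end[-nrow(d1)]))
  expect_true(all(d1$length >= 3000))
})

test_that("a region below 2*min_len is a single forced domain", {
  m <- test_model()
  s <- gcd_sequence("x", random_residues(5000, 0.5))
  d <- segment_sequence(s, m, min_len = 3000)
  expect_equal(nrow(d), 1L)
  expect_warning(segment_sequence(s, m, min_len = 6000), "single domain")
})

test_that("a strong two-block mosaic is recovered with an accurate boundary", {
  m <- test_model()
  sp <- synthetic_genome_spec(
    tibble::tibble(length = c(50000, 50000), gc = c(0.30, 0.60)), seed = 5)
  g <- generate_genome(sp)
  d <- segment_sequence(g$sequence, m)
  expect_gte(nrow(d), 2L)
  expect_true(any(abs(d$end - 50000) <= 2000 & d$end < 1e5))
  sc <- score_boundaries(g$truth,
                         tibble::tibble(start = d$start + 1, end = d$end),
                         tolerance = 2000)
  expect_equal(sc$recall, 1)
})

test_that("calibrated thresholds decrease with length and are reproducible", {
  m <- calibrate_halting(c(6000, 20000, 60000), c(0.4), replicates = 120,
                         quantile = 0.95, min_len = 3000, seed = 9)
  m2 <- calibrate_halting(c(6000, 20000, 60000), c(0.4), replicates = 120,
                          quantile = 0.95, min_len = 3000, seed = 9)
  expect_identical(m$table, m2$table)
  thr <- m$table$threshold
  expect_true(all(diff(thr) <= 0))
  expect_true(all(thr > 0))
  # interpolated lookups respect monotonicity too
  look <- halting_threshold(m, c(6000, 10000, 20000, 40000, 60000, 2e5), 0.4)
  expect_true(all(diff(look) <= 1e-12))
})

test_that("the stored quantile controls the fresh exceedance rate", {
  m <- calibrate_halting(c(10000, 20000), c(0.4), replicates = 400,
                         quantile = 0.9, min_len = 3000, seed = 12)
  set.seed(13)
  n_new <- 300
  exceed <- mean(vapply(seq_len(n_new), function(i) {
    cs <- c(0, cumsum(runif(10000) < 0.4))
    d <- gcdomains:::best_split_cum(cs, 0L, 10000L, 3000L)$djs
    d > halting_threshold(m, 10000, 0.4)
  }, logical(1)))
  se <- sqrt(0.1 * 0.9 / n_new)
  expect_lt(abs(exceed - 0.1), 4 * se + 0.02)
})

test_that("halting model serialization round-trips exactly", {
  m <- test_model()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_halting_model(m, f)
  m2 <- read_halting_model(f)
  expect_equal(m2$table$threshold, m$table$threshold, tolerance = 0)
  expect_equal(m2$quantile, m$quantile)
  expect_equal(m2$min_len, m$min_len)
  expect_equal(halting_threshold(m2, 17000, 0.42),
               halting_threshold(m, 17000, 0.42))
})

test_that("calibration rejects invalid settings", {
  expect_error(calibrate_halting(6000, 0.4, replicates = 100), "sparse")
  expect_error(calibrate_halting(c(6e3, 1e4), 0.4, replicates = 10),
               "replicates")
  expect_error(calibrate_halting(c(6e3, 1e4), 0.4, replicates = 100,
                                 quantile = 0.4), "quantile")
})

test_that("tidy, glance and autoplot work on a halting model", {
  m <- test_model()
  td <- tidy(m)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("length", "gc", "threshold"))
  gl <- glance(m)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$quantile, 0.95)
  expect_s3_class(autoplot(m), "ggplot")
})
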