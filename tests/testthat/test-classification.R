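base_records <- function() {
  tibble::tibble(
    source_id = "s",
    start = c(1, 300002, 600003),
    end = c(300001, 600002, 900003),
    length = c(300001, 300001, 300001),
    gc = c(0.35, 0.61, 0.45),
    gc_std = 0.01,
    homogeneity = c(1, 1, 0),
    is_n_segment = FALSE
  )
}

test_that("classification applies the printed thresholds literally", {
  r <- classify_domains(base_records())
  # >300 kb AND homogeneous -> isochoric; 300,001 bp qualifies
  expect_equal(r$size_class, c("isochoric", "isochoric", "short"))
  expect_equal(r$gc_band, c("low", "other", "high"))
  expect_equal(r$rich_class, c("GC-poor", "GC-rich", "GC-rich"))

  # exactly 300,000 bp stays short (strict >)
  r2 <- classify_domains(dplyr::mutate(base_records(), length = 300000))
  expect_true(all(r2$size_class == "short"))

  # the 40% edge belongs to the high band (half-open bands)
  r3 <- classify_domains(dplyr::mutate(base_records(), gc = c(0.399999,
                                                              0.40, 0.20)))
  expect_equal(r3$gc_band, c("low", "high", "low"))

  # rich cut is strict: exactly 0.3762 is GC-poor
  r4 <- classify_domains(dplyr::mutate(base_records(),
                                       gc = c(0.3762, 0.37621, 0.1)))
  expect_equal(r4$rich_class, c("GC-poor", "GC-rich", "GC-poor"))
})

test_that("N segments carry NA class labels", {
  r <- classify_domains(dplyr::mutate(base_records(),
                                      is_n_segment = c(FALSE, TRUE, FALSE),
                                      gc = c(0.35, 0, 0.45)))
  expect_true(is.na(r$size_class[2]))
  expect_true(is.na(r$gc_band[2]))
  expect_true(is.na(r$rich_class[2]))
})

test_that("raising the isochoric cutoff never increases isochoric coverage", {
  r <- base_records()
  cov_for <- function(min_bp) {
    cl <- classify_domains(r, isochoric_min = min_bp)
    sum(cl$length[cl$size_class == "isochoric"])
  }
  covs <- vapply(c(1e5, 2e5, 3e5, 3.5e5, 1e6), cov_for, numeric(1))
  expect_true(all(diff(covs) <= 0))
})

test_that("coverage_summary partitions each source to fractions summing to 1", {
  r <- classify_domains(base_records())
  cov <- coverage_summary(r)
  per <- cov[cov$source_id == "s", ]
  expect_equal(sum(per$fraction), 1)
  expect_equal(sum(per$bp), sum(r$length))
  all_row <- cov[cov$source_id == "all", ]
  expect_equal(sum(all_row$fraction), 1)

  # single domain covering a source
  one <- classify_domains(tibble::tibble(
    source_id = "t", start = 1, end = 1000, length = 1000, gc = 0.5,
    gc_std = 0, homogeneity = 1, is_n_segment = FALSE))
  cov1 <- coverage_summary(one)
  expect_equal(cov1$fraction[cov1$source_id == "t"], 1)

  # two equal halves of different classes
  two <- classify_domains(tibble::tibble(
    source_id = "u", start = c(1, 501), end = c(500, 1000),
    length = 500, gc = 0.5, gc_std = 0, homogeneity = c(1, 0),
    is_n_segment = FALSE), isochoric_min = 100)
  cov2 <- coverage_summary(two)
  expect_equal(sort(cov2$fraction[cov2$source_id == "u"]), c(0.5, 0.5))

  # homogeneity stratification also partitions (N its own stratum)
  withN <- classify_domains(tibble::tibble(
    source_id = "v", start = c(1, 501, 601), end = c(500, 600, 1000),
    length = c(500, 100, 400), gc = c(0.5, 0, 0.3), gc_std = 0,
    homogeneity = c(1, NA, 0), is_n_segment = c(FALSE, TRUE, FALSE)))
  covh <- coverage_summary(dplyr::mutate(withN,
                                         homogeneity = as.character(
                                           withN$homogeneity)),
                           by = "homogeneity")
  expect_equal(sum(covh$fraction[covh$source_id == "v"]), 1)
  expect_true("n_island" %in% covh$class)

  expect_error(coverage_summary(dplyr::mutate(r, end = end - 1)),
               "do not tile")
})

test_that("coverage_summary recovers the generator's truth on a mosaic", {
  set.seed(61)
  lens <- c(4000, 6000, 10000)
  gcs <- c(0.30, 0.55, 0.30)
  ends <- cumsum(lens)
  rec <- classify_domains(tibble::tibble(
    source_id = "m", start = c(1, ends[-3] + 1), end = ends,
    length = lens, gc = gcs, gc_std = 0.01,
    homogeneity = 1, is_n_segment = FALSE), isochoric_min = 5000)
  cov <- coverage_summary(rec)
  iso <- cov[cov$source_id == "m" & cov$class == "isochoric", ]
  expect_equal(iso$bp, 16000)   # blocks 2 and 3 exceed 5 kb
  expect_equal(iso$fraction, 16000 / 20000)
})

test_that("coverage_matrix fractions sum to 1 per source over non-N records", {
  r <- classify_domains(base_records())
  cm <- coverage_matrix(r)
  expect_equal(sum(cm$fraction), 1)
  expect_true(all(cm$bp >= 0))
})
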