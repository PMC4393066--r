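test_that("map_n_islands finds maximal runs", {
  expect_equal(nrow(map_n_islands(gcd_sequence("x", "ACGT"))), 0L)
  m <- map_n_islands(gcd_sequence("x", "ANNGT"))
  expect_equal(m$start, 1)
  expect_equal(m$end, 3)
  m2 <- map_n_islands(gcd_sequence("x", "NNACGNN"))
  expect_equal(m2$start, c(0, 5))
  expect_equal(m2$end, c(2, 7))
  expect_equal(attr(m2, "source_length"), 7)
})

test_that("strip_ns removes N and its map inverts the removal", {
  st <- strip_ns(gcd_sequence("x", "ANNGT"))
  expect_equal(seq_residues(st$sequence), "AGT")
  expect_equal(st$map$stripped_start, c(0, 1))
  expect_equal(st$map$orig_start, c(0, 3))
  expect_equal(st$map$orig_end, c(1, 5))

  st2 <- strip_ns(gcd_sequence("x", "NA"))
  expect_equal(seq_residues(st2$sequence), "A")
  expect_equal(st2$map$orig_start, 1)

  s <- gcd_sequence("x", "ACGTACGT")
  st3 <- strip_ns(s)
  expect_equal(seq_residues(st3$sequence), seq_residues(s))
  expect_equal(nrow(st3$map), 1L)

  expect_error(strip_ns(gcd_sequence("x", "NNN")), "entirely N")
})

test_that("round-trip: stripping then restoring one domain recovers all non-N positions", {
  set.seed(21)
  for (i in 1:15) {
    chars <- sample(c("A", "C", "G", "T", "N"), 400, replace = TRUE,
                    prob = c(0.2, 0.2, 0.2, 0.2, 0.2))
    if (all(chars == "N")) chars[1] <- "A"
    s <- gcd_sequence("x", paste(chars, collapse = ""))
    isl <- map_n_islands(s)
    st <- strip_ns(s)
    doms <- tibble::tibble(start = 0, end = seq_length(st$sequence))
    r <- restore_domains(doms, st$map, isl, max_mask = 1e9)
    expect_equal(sum(r$orig_end - r$orig_start), 400)
    covered <- unlist(Map(function(a, b) seq(a, b - 1),
                          r$orig_start[!r$is_n_segment],
                          r$orig_end[!r$is_n_segment]))
    inside_kept <- unlist(Map(function(a, b) seq(a, b - 1),
                              st$map$orig_start, st$map$orig_end))
    expect_true(all(inside_kept %in% covered))
  }
})

test_that("the mask-or-split rule follows the 50 kb default exactly", {
  # 200-unit sequence with a 50-unit island dead center, one stripped domain
  s <- gcd_sequence("w", paste0(strrep("G", 75), strrep("N", 50),
                                strrep("A", 75)))
  isl <- map_n_islands(s)
  st <- strip_ns(s)
  doms <- tibble::tibble(start = 0, end = 150)
  split3 <- restore_domains(doms, st$map, isl, max_mask = 50)
  expect_equal(nrow(split3), 3L)
  expect_equal(split3$orig_start, c(0, 75, 125))
  expect_equal(split3$orig_end, c(75, 125, 200))
  expect_equal(split3$is_n_segment, c(FALSE, TRUE, FALSE))

  masked <- restore_domains(doms, st$map, isl, max_mask = 51)
  expect_equal(nrow(masked), 1L)
  expect_false(masked$is_n_segment)
  expect_equal(masked$orig_end, 200)
})

test_that("junction and edge islands follow the tie rules", {
  # island exactly between two domains
  s <- gcd_sequence("j", paste0(strrep("G", 30), strrep("N", 10),
                                strrep("A", 30)))
  isl <- map_n_islands(s)
  st <- strip_ns(s)
  doms <- tibble::tibble(start = c(0, 30), end = c(30, 60))
  small <- restore_domains(doms, st$map, isl, max_mask = 11)
  expect_equal(nrow(small), 2L)
  expect_equal(small$orig_end, c(40, 70))     # masked: upstream domain grows
  big <- restore_domains(doms, st$map, isl, max_mask = 10)
  expect_equal(nrow(big), 3L)
  expect_true(big$is_n_segment[2])
  expect_equal(big$orig_start, c(0, 30, 40))

  # leading island: no upstream domain exists, so masked size joins the first
  s2 <- gcd_sequence("l", paste0(strrep("N", 5), strrep("G", 20)))
  r2 <- restore_domains(tibble::tibble(start = 0, end = 20),
                        strip_ns(s2)$map, map_n_islands(s2), max_mask = 6)
  expect_equal(nrow(r2), 1L)
  expect_equal(r2$orig_start, 0)
  # trailing island joins the last domain
  s3 <- gcd_sequence("t", paste0(strrep("G", 20), strrep("N", 5)))
  r3 <- restore_domains(tibble::tibble(start = 0, end = 20),
                        strip_ns(s3)$map, map_n_islands(s3), max_mask = 6)
  expect_equal(nrow(r3), 1L)
  expect_equal(r3$orig_end, 25)
})

test_that("raising max_mask never increases the number of segments", {
  set.seed(31)
  for (i in 1:10) {
    chars <- sample(c("G", "A", "N"), 500, replace = TRUE,
                    prob = c(0.35, 0.35, 0.3))
    chars[1] <- "A"
    s <- gcd_sequence("x", paste(chars, collapse = ""))
    isl <- map_n_islands(s)
    st <- strip_ns(s)
    sl <- seq_length(st$sequence)
    cut <- sort(sample(1:(sl - 1), 2))
    doms <- tibble::tibble(start = c(0, cut), end = c(cut, sl))
    counts <- vapply(c(0, 2, 5, 10, 50, 1000), function(mm)
      nrow(restore_domains(doms, st$map, isl, max_mask = mm)), numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("restore_domains rejects a non-tiling segmentation", {
  s <- gcd_sequence("x", "ACGTNNACGT")
  st <- strip_ns(s)
  isl <- map_n_islands(s)
  expect_error(restore_domains(tibble::tibble(start = 0, end = 7),
                               st$map, isl), "does not tile")
  expect_error(restore_domains(tibble::tibble(start = c(0, 5), end = c(4, 8)),
                               st$map, isl), "does not tile")
})
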