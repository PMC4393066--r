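# Shared fixtures: a fast low-replicate halting model for unit tests and a
# brute-force split oracle kept independent of the package's scan.

# Small model over short lengths; calibrated once per test run.
test_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- calibrate_halting(c(6e3, 12.5e3, 25e3, 5e4, 1e5),
                                  c(0.2, 0.35, 0.5, 0.65),
                                  replicates = 150, quantile = 0.95,
                                  min_len = 3000, seed = 104729)
    cache
  }
})

shipped_model <- function() default_halting_model()

# Exhaustive O(L^2) maximal-divergence scan, written from the entropy
# definition (independent of best_split's cumulative-count path).
brute_force_split <- function(residues, min_len) {
  v <- as.integer(strsplit(residues, "")[[1]] %in% c("G", "C"))
  L <- length(v)
  if (L < 2 * min_len) return(NULL)
  ent <- function(p) {
    if (p <= 0 || p >= 1) return(0)
    -p * log2(p) - (1 - p) * log2(1 - p)
  }
  best_pos <- NA_integer_
  best_d <- -Inf
  for (k in min_len:(L - min_len)) {
    gl <- sum(v[1:k])
    gr <- sum(v) - gl
    d <- ent(sum(v) / L) - (k / L) * ent(gl / k) -
      ((L - k) / L) * ent(gr / (L - k))
    if (d > best_d + 1e-15) {
      best_d <- d
      best_pos <- k
    }
  }
  list(position = best_pos, djs = best_d)
}

random_residues <- function(n, gc = 0.5) {
  paste(sample(c("G", "C", "A", "T"), n, replace = TRUE,
               prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2)),
        collapse = "")
}

# The canonical desk-scale input: 200 kb at exact GC 35% with a 50 kb N run
# spliced in at its center.
gap_example_spec <- function(scale = 1) {
  synthetic_genome_spec(
    blocks = tibble::tibble(length = 150000 * scale, gc = 0.35),
    n_islands = tibble::tibble(at = 75000 * scale, length = 50000 * scale),
    seed = 20130418 %% 1000, id = "example")
}
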