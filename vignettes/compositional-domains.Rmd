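---
title: "Segmenting genomes into compositional domains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting genomes into compositional domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcdomains)
library(tibble)
```

## The model

Animal genomes are mosaics of *compositional domains*: contiguous regions
whose GC content differs significantly from that of their upstream and
downstream neighbours. Domain sizes span roughly 3 kb to beyond 10 Mb, and
long (&gt;300 kb) compositionally homogeneous domains are the classical
*isochores*. `gcdomains` infers this mosaic from sequence alone, with no
user-tuned segmentation parameter.

The core is recursive binary segmentation on the Jensen–Shannon divergence.
For a candidate split of a segment of $n$ bases into a left part
($n_l$ bases, GC fraction $p_l$) and a right part ($n_r$, $p_r$), with
pooled GC fraction $p$:

$$
D_{JS} = H_2(p) \;-\; \frac{n_l}{n} H_2(p_l) \;-\; \frac{n_r}{n} H_2(p_r),
\qquad
H_2(q) = -q\log_2 q - (1-q)\log_2(1-q).
$$

`best_split()` scans every admissible split point (both parts at least
`min_len` bp) in a single pass over cumulative GC counts and takes the
maximum, ties broken toward the leftmost position. `segment_sequence()`
accepts the split when its divergence exceeds a *dynamic halting
threshold* and recurses into both parts; otherwise the segment is emitted
as a domain. The entropy base (bits) does not affect the argmax; it is
fixed so thresholds and statistics are reportable.

## The dynamic halting criterion

A fixed divergence cutoff biases the domain-size spectrum, because the
maximal divergence of even a perfectly homogeneous segment depends on the
segment's length and composition. The halting rule used here is therefore
defined operationally as a null quantile: for a segment of length $L$ and
pooled GC $p$, the threshold $t(L, p)$ is the empirical 0.95 quantile of
the maximal admissible $D_{JS}$ over i.i.d. homogeneous sequences with the
same $L$ and $p$. A split must beat what chance alone would produce in a
homogeneous segment of identical geometry.

`calibrate_halting()` estimates $t$ by Monte Carlo on a
(length × GC) grid and interpolates the *log* threshold bilinearly on
(log length, GC) — null thresholds decay roughly as a power of length, so
this scale interpolates well and stays positive; thresholds are made
non-increasing in length at each GC by isotonic regression, since longer
homogeneous segments have smaller expected maximal divergence. The
shipped model (`default_halting_model()`) was calibrated once with 1000
replicates per grid point over lengths 6 kb–800 kb and GC 0.20–0.70 at
`min_len = 3000`, seed 42; lengths beyond the grid are extrapolated as a
power law on the last log-log slope, GC outside the grid is clamped. The model is a plain-text table
(`write_halting_model()` / `read_halting_model()`), so the choice is
inspectable and regenerable (`gcdomains calibrate`). The exact threshold
constants of earlier implementations are not recoverable from published
material, so this calibration procedure *is* the contract here: it
reproduces the stated behaviour — dynamic, length-dependent,
parameter-free for the user — with the quantile (0.95) as the only fixed
choice, directly interpretable as a ~5% false-split rate on homogeneous
sequence.

```{r thresholds, fig.width = 6, fig.height = 3.5, eval = FALSE}
autoplot(default_halting_model())
```

Key tunables and their defaults:

| parameter | default | unit | meaning |
|---|---|---|---|
| `min_len` | 3000 | bp | smallest domain; observed domains start near 3 kb |
| `max_mask` | 50000 | bp | N islands shorter than this are masked, others split |
| `window` | 1024 | bp | windowed-GC series for GC spread and homogeneity |
| `alpha` | 0.05 | — | one-sided level of the homogeneity F test |
| `isochoric_min` | 300000 | bp | strict lower bound for "isochoric" domains |
| `low_band`, `high_band` | [0.20, 0.40), [0.40, 0.60) | GC | half-open GC bands |
| `rich_cut` | 0.3762 | GC | GC-rich/GC-poor split (insect-genome mean GC) |

## N islands

Assembly gaps and ambiguous stretches appear as runs of `N`.
`map_n_islands()` records every maximal run; `strip_ns()` removes them and
keeps an exact coordinate map; segmentation runs on the N-free sequence;
`restore_domains()` maps domains back and applies the mask-or-split rule:
islands shorter than `max_mask` (default 50 kb) are absorbed into the
domain they interrupt, leaving it contiguous, while islands at least that
long split the domain into a left part, a flagged N segment (GC reported
as 0, homogeneity not applicable), and a right part. The boundary
semantics follow the rule's two clauses consistently: "&lt; 50 kb" masks,
and a 50 kb island splits. A canonical example: a 200 kb sequence of
uniform 35% GC with a 50 kb N run at its center yields three segments —
1–75 kb at GC 35%, 75–125 kb flagged with GC 0, and 125–200 kb at GC 35%.

Two decisions the rule leaves open are fixed deterministically: a
masked-size island sitting exactly on a junction between two domains is
appended to the upstream (left) domain (downstream at the sequence start,
where no upstream domain exists), and two distinct domains are never
merged across an island. A domain that absorbed masked Ns keeps genomic
coordinates and length, but its GC statistics are computed over its non-N
residues only, so gaps do not dilute composition.

## The homogeneity test

After segmentation, each domain is labelled homogeneous or nonhomogeneous
*relative to the chromosome or region it resides on*: the variance of the
domain's windowed GC series is compared to the variance of the host's
series with a one-sided F test (`test_homogeneity()`). Only excess
variance disqualifies — a domain quieter than its chromosome is
homogeneous by any reading. The host series includes the domain's own
windows; with hosts much longer than domains the overlap is negligible
and the type-I error tracks `alpha` (checked by simulation in the test
suite). The 1024 bp default window gives at least two windows for the
smallest (3 kb) domains while damping binomial noise; domains with fewer
than two windows are untestable and default to nonhomogeneous, with a
`testable` flag on the verdict. No multiple-testing correction is applied
across domains; verdicts are raw per-domain calls.

## Classification and output

`classify_domains()` labels each record: `size_class` is `"isochoric"`
only when the domain exceeds 300 kb *and* is homogeneous, since the
isochore concept denotes long homogeneous domains; `gc_band` uses
half-open bands [20%, 40%) and [40%, 60%) so the shared 40% edge is
unambiguous, with `"other"` for domains outside both (e.g. a 61% GC
domain); `rich_class` splits at 37.62% GC. All cuts are configurable.

The pipeline (`run_pipeline()`, or `gcdomains run` on the command line)
writes one TSV per run (`seg_no_ns.txt`) with columns `source_id`,
`start`, `end`, `length`, `gc`, `gc_std`, `homogeneity`, `is_n_segment`,
`size_class`, `gc_band`, `rich_class`. Coordinates are 1-based inclusive
in output; internally everything is 0-based half-open. The first four
statistics columns keep the legacy order (coordinates, GC, GC standard
deviation, homogeneity indicator); classification columns are appended.
Every tunable is echoed as a `#`-prefixed header so a table documents the
run that produced it. Multi-record FASTA files are processed
record-by-record (scaffold mode); records shorter than ten times
`min_len` trigger a logged warning because short-domain calls on small
scaffolds are unreliable.

## The synthetic-genome generator

`generate_genome()` builds mosaic test genomes from a block specification:
each block has a length and a GC fraction, bases drawn i.i.d. with
P(G or C) = gc, and N islands spliced at stated positions. *Exact mode*
instead places exactly `round(gc * length)` G/C bases at evenly spaced
positions, making block GC bit-exact — that is what lets the 200 kb gap
example above be checked deterministically rather than in expectation.

What the generator emulates is precisely the model's own assumption:
piecewise-constant GC with independent bases. Real genomes violate this
in ways the simulations do not probe — autocorrelated composition,
repeats, CpG islands, soft-masked regions, gradual (non-step) GC
gradients — so passing benchmarks demonstrates correctness of the
algorithmics and calibration, not that any particular biological genome
is segmented "truly". Benchmarks score inferred against true boundaries
with `score_boundaries()` (greedy nearest matching within a tolerance,
each boundary used once; the reported offset is the mean absolute
distance of matched pairs).

## Numerical choices and degenerate inputs

* `0·log 0 = 0` in all entropy terms; divergences are clamped at ≥ 0 by
  construction.
* Oracle agreement between the one-pass scan and an exhaustive
  recomputation is exact to 1e-12.
* Ties in the split scan go to the leftmost position; recursion uses an
  explicit stack processed left to right, so results and logs are
  deterministic.
* Regions shorter than `2·min_len` cannot split; shorter than `min_len`
  they are emitted as a single domain with a warning.
* An all-N record becomes a single flagged N segment; an all-N *region*
  passed to `strip_ns()` is an error.
* A host with constant windowed GC (zero variance) accepts any
  equal-variance domain and rejects any more-variable one.
* Simulation sizes in the test-suite and in `scripts/acceptance.R` are
  desk-scale by design: 50–200 kb sequences, hundreds of replicates —
  large enough for the binomial tolerances quoted with each check, small
  enough to run anywhere.

## Known limitations

* The halting calibration is the package's own operational definition;
  other implementations of the same idea used unpublished constants, so
  absolute domain counts on real genomes need not match older published
  tallies (which also depend on genome build).
* Segmentation is binary on GC only; 4-symbol or dinucleotide alphabets,
  HMM and Bayesian change-point alternatives are out of scope.
* The homogeneity host variance includes the tested domain's windows;
  excluding them would be a one-line variant but changes verdicts only
  for domains comparable in size to their host.
* Fractions of a domain's GC at third codon positions, gene content, and
  any downstream comparative analyses are outside this package.
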