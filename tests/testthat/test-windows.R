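test_that("window means are the arithmetic means of member sites", {
  rec <- compute_snp_index(mk_sites(
    pos = c(1e6, 1.5e6, 2e6),
    fr_r = c(6L, 8L, 12L), fr_o = c(14L, 12L, 8L),
    sm_r = c(2L, 0L, 0L), sm_o = c(18L, 20L, 20L)))
  # deltas: 0.3-0.1, 0.4-0, 0.6-0 = 0.2, 0.4, 0.6
  w <- sliding_windows(rec, window = 5e6, step = 1e4)
  w0 <- w[w$start == 0, ]
  expect_identical(w0$n_snps, 3L)
  expect_equal(w0$mean_delta, 0.4)
  # singleton window: mean equals the site's own delta
  wlast <- w[w$start == 1.99e6, ]
  expect_identical(wlast$n_snps, 1L)
  expect_equal(wlast$mean_delta, 0.6)
})

test_that("a site belongs to exactly the windows its half-open span dictates", {
  # brute-force enumeration oracle for a site at 5,000,001
  p <- 5000001
  starts <- seq(0, 10e6, by = 1e4)
  member <- starts <= (p - 1) & (p - 1) < starts + 5e6
  expect_identical(sum(member), 500L)

  rec <- compute_snp_index(mk_sites(pos = p, fr_r = 10L, fr_o = 10L,
                                    sm_r = 10L, sm_o = 10L))
  w <- sliding_windows(rec, window = 5e6, step = 1e4)
  expect_identical(nrow(w), 500L)
  expect_identical(min(w$start), 1e4)
  expect_identical(max(w$start), 5e6)
})

test_that("window means are invariant to input record order", {
  set.seed(5)
  n <- 400
  rec <- compute_snp_index(mk_sites(
    pos = seq_len(n) * 1e4,
    fr_r = rpois(n, 15) + 1L, fr_o = rpois(n, 15) + 1L,
    sm_r = rpois(n, 15) + 1L, sm_o = rpois(n, 15) + 1L))
  shuffled <- rec[sample.int(n), ]
  expect_error(sliding_windows(shuffled), "not sorted")
  resorted <- shuffled[order(shuffled$chrom, shuffled$pos), ]
  expect_equal(sliding_windows(resorted), sliding_windows(rec),
               ignore_attr = TRUE)
})

test_that("null bands are centred, symmetric, and narrow with depth", {
  ci <- null_ci(n_bulk = 30, depths = c(10, 30, 100), reps = 20000, seed = 8)
  # symmetry about zero within Monte-Carlo tolerance
  expect_lt(max(abs(ci$ci95_lo + ci$ci95_hi)), 0.05)
  expect_lt(max(abs(ci$ci99_lo + ci$ci99_hi)), 0.08)
  # bands widen monotonically as depth decreases
  expect_true(all(diff(ci$ci95_hi) < 0))
  expect_true(all(diff(ci$ci99_hi) < 0))
  # 99% band encloses the 95% band
  expect_true(all(ci$ci99_hi > ci$ci95_hi))
  # determinism
  ci2 <- null_ci(n_bulk = 30, depths = c(10, 30, 100), reps = 20000, seed = 8)
  expect_identical(as.data.frame(ci), as.data.frame(ci2))
  expect_error(null_ci(reps = 500), "reps")
})

test_that("the BC1 null design centres the single-bulk index at 1/4", {
  x <- null_index_draws(30, 50, 50000, population = "BC1", seed = 3)
  expect_lt(abs(mean(x) - 0.25), 0.005)
  f2 <- null_index_draws(30, 50, 50000, population = "F2", seed = 3)
  expect_lt(abs(mean(f2) - 0.5), 0.005)
})

test_that("window bands are means of member-site bands, interpolated in depth", {
  ci <- null_ci(n_bulk = 30, depths = c(10, 20, 100), reps = 20000, seed = 14)
  # all sites at one tabulated depth: window band equals that row
  rec <- compute_snp_index(mk_sites(pos = c(1e4, 2e4, 3e4),
                                    fr_r = 5L, fr_o = 5L, sm_r = 5L, sm_o = 5L))
  w <- attach_ci(sliding_windows(rec), rec, ci)
  expect_true(all(abs(w$ci95_hi - ci$ci95_hi[ci$depth == 10]) < 1e-12))
  # mixed depths 10 and 100 in equal numbers: midpoint of the two bands
  rec2 <- compute_snp_index(mk_sites(pos = c(1e4, 2e4),
                                     fr_r = c(5L, 50L), fr_o = c(5L, 50L),
                                     sm_r = c(5L, 50L), sm_o = c(5L, 50L)))
  w2 <- attach_ci(sliding_windows(rec2), rec2, ci)
  mid <- mean(ci$ci95_hi[ci$depth %in% c(10, 100)])
  expect_equal(w2$ci95_hi[w2$n_snps == 2], rep(mid, sum(w2$n_snps == 2)))
  # interpolated bounds at depth 15 agree with an explicitly simulated row
  # (tolerance covers both Monte-Carlo noise and the 1/depth lattice)
  ci15 <- null_ci(n_bulk = 30, depths = 15, reps = 20000, seed = 15)
  interp <- approx(c(10, 20), ci$ci95_hi[ci$depth %in% c(10, 20)], xout = 15)$y
  expect_lt(abs(interp - ci15$ci95_hi), 0.05)
  expect_error(attach_ci(w, rec, ci[0, ]), "empty")
})

test_that("effective depth uses the shallower bulk by default", {
  ci <- null_ci(n_bulk = 30, depths = c(10, 100), reps = 20000, seed = 9)
  rec <- compute_snp_index(mk_sites(pos = 1e4, fr_r = 5L, fr_o = 5L,
                                    sm_r = 50L, sm_o = 50L))
  w_min <- attach_ci(sliding_windows(rec), rec, ci, depth_rule = "min")
  w_mean <- attach_ci(sliding_windows(rec), rec, ci, depth_rule = "mean")
  expect_equal(w_min$ci95_hi, ci$ci95_hi[ci$depth == 10])
  expect_lt(w_mean$ci95_hi, w_min$ci95_hi) # deeper effective depth, narrower
})

test_that("region calling merges across small gaps and respects the tail", {
  mkw <- function(start, delta, hi = 0.3) {
    w <- data.frame(chrom = "chr1", start = start, end = start + 5e6,
                    n_snps = 10L, mean_fr = 0.5, mean_sm = 0.5,
                    mean_delta = delta,
                    ci95_lo = -hi, ci95_hi = hi,
                    ci99_lo = -hi - 0.1, ci99_hi = hi + 0.1)
    attr(w, "window") <- 5e6; attr(w, "step") <- 1e4
    w
  }
  # nothing exceeds the band
  expect_identical(nrow(call_regions(mkw(c(0, 1e4), c(0.1, 0.2)))), 0L)
  # two significant windows separated by one below threshold merge
  w <- mkw(c(0, 1e4, 2e4), c(0.5, 0.1, 0.5))
  r <- call_regions(w, max_gap = 1e4)
  expect_identical(nrow(r), 1L)
  expect_identical(r$n_windows, 2L)
  expect_identical(r$start, 0)
  expect_identical(r$end, 2e4 + 5e6)
  expect_equal(r$peak_delta, 0.5)
  # far-apart windows stay separate regions
  w2 <- mkw(c(0, 20e6), c(0.5, 0.6))
  expect_identical(nrow(call_regions(w2, max_gap = 1e4)), 2L)
  # lower tail calls maintainer-parent regions
  w3 <- mkw(c(0, 1e4), c(-0.5, -0.5))
  expect_identical(nrow(call_regions(w3)), 0L)
  expect_identical(nrow(call_regions(w3, tail = "lower")), 1L)
  # min_span filters short regions
  w4 <- mkw(0, 0.5)
  expect_identical(nrow(call_regions(w4, min_span = 6e6)), 0L)
})

test_that("strict band exceedance is conservative and mid-P is near nominal", {
  ci <- null_ci(n_bulk = 30, depths = 20:40, reps = 20000, seed = 30)
  set.seed(31)
  d <- pmin(pmax(rpois(40000, 30), 20), 40)
  delta <- numeric(length(d))
  for (dep in unique(d)) {
    sel <- d == dep
    delta[sel] <- null_index_draws(30, dep, sum(sel)) -
      null_index_draws(30, dep, sum(sel))
  }
  strict <- ci_exceedance(delta, d, ci, ties = "strict")
  half <- ci_exceedance(delta, d, ci, ties = "half")
  incl <- ci_exceedance(delta, d, ci, ties = "inclusive")
  expect_lt(strict, 0.05)
  expect_gt(incl, strict)
  expect_lt(abs(half - 0.05), 0.015)
})
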