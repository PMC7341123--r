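# window membership: a site at 1-based position p belongs to the window
# with 0-based start s (span [s, s+W)) iff s <= p-1 < s+W. Window starts
# are anchored at multiples of `step` from each chromosome start.

.lv_col <- function(level, side) sprintf("ci%g_%s", level * 100, side)

#' Sliding-window means of SNP-index and delta(SNP-index)
#'
#' Tiles each chromosome with windows of `window` bp advanced by `step` bp
#' and reports the unweighted arithmetic mean of `fr_index`, `sm_index` and
#' `delta` over member sites. Windows containing no sites are omitted (no
#' statistic is invented for them).
#'
#' @param records filtered output of [compute_snp_index()], sorted by
#'   (chrom, pos).
#' @param window window span in bp (default 5 Mb).
#' @param step window increment in bp (default 10 kb).
#' @param chrom_lengths optional named vector of chromosome lengths; when
#'   given, window starts run to the last multiple of `step` below each
#'   length, otherwise to the last site.
#' @return data.frame with `chrom`, `start` (0-based), `end`
#'   (`start + window`), `n_snps`, `mean_fr`, `mean_sm`, `mean_delta`;
#'   window and step sizes kept as attributes.
#' @export
sliding_windows <- function(records, window = 5e6, step = 1e4,
                            chrom_lengths = NULL) {
  if (window <= 0) stop("window must be > 0")
  if (step <= 0) stop("step must be > 0")
  .check_sorted(records$chrom, records$pos)
  out <- lapply(unique(records$chrom), function(ch) {
    r <- records[records$chrom == ch, , drop = FALSE]
    if (nrow(r) == 0L) return(NULL)
    smax <- max(r$pos) - 1
    if (!is.null(chrom_lengths) && ch %in% names(chrom_lengths))
      smax <- min(smax, chrom_lengths[[ch]] - 1)
    starts <- seq(0, floor(smax / step) * step, by = step)
    idx <- function(x) findInterval(x, r$pos)
    lo <- idx(starts); hi <- idx(starts + window)
    n <- hi - lo
    keep <- n > 0L
    csum <- function(v) {
      cs <- c(0, cumsum(v))
      cs[hi + 1L] - cs[lo + 1L]
    }
    data.frame(chrom = ch, start = starts[keep], end = starts[keep] + window,
               n_snps = n[keep],
               mean_fr = csum(r$fr_index)[keep] / n[keep],
               mean_sm = csum(r$sm_index)[keep] / n[keep],
               mean_delta = csum(r$delta)[keep] / n[keep],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "window") <- window
  attr(res, "step") <- step
  res
}

#' Single-bulk null SNP-index draws
#'
#' Simulates the observed SNP-index of one bulk at one read depth under the
#' no-QTL null: the bulk restorer-allele frequency is `p = B/(2n)` with
#' `B ~ Binomial(2n, 1/2)` (F2 design; `Binomial(n, 1/2)` for BC1), and the
#' index is `Binomial(depth, p)/depth`. By the law of total variance its
#' variance is `(1/4 - 1/(8n))/depth + 1/(8n)` for F2. These draws are the
#' building block of [null_ci()].
#'
#' @param n_bulk individuals in the bulk.
#' @param depth read depth.
#' @param reps number of draws.
#' @param population `"F2"` or `"BC1"`.
#' @param seed optional seed.
#' @return numeric vector of `reps` simulated indices.
#' @export
#' @examples
#' v <- var(null_index_draws(30, 10, 5e4, seed = 1))
#' all.equal(v, (0.25 - 1/240)/10 + 1/240, tolerance = 0.05)
null_index_draws <- function(n_bulk, depth, reps,
                             population = c("F2", "BC1"), seed = NULL) {
  population <- match.arg(population)
  .maybe_seed(seed)
  b <- if (population == "F2") rbinom(reps, 2L * n_bulk, 0.5)
       else rbinom(reps, n_bulk, 0.5)
  rbinom(reps, depth, b / (2 * n_bulk)) / depth
}

#' Monte-Carlo confidence bands for delta(SNP-index) under no QTL
#'
#' Simulates the null distribution of delta(SNP-index) at each read depth:
#' for each bulk independently, the bulk restorer-allele frequency is
#' `p = B/(2n)` with `B ~ Binomial(2n, 1/2)` for an F2 design (each of the
#' `2n` bulk chromosomes is restorer-type with probability 1/2;
#' `B ~ Binomial(n, 1/2)` for BC1), the observed index is
#' `Binomial(depth, p)/depth`, and delta is the FR minus the SM index.
#' Empirical quantiles at `(1 - level)/2` and `1 - (1 - level)/2` give the
#' band. Bands are symmetric about 0 and widen as depth decreases (up to
#' Monte-Carlo noise).
#'
#' @param n_bulk individuals per bulk (default 30).
#' @param depths integer vector of read depths to tabulate. The default grid
#'   is dense up to 100x and sparse above (bands change slowly at high
#'   depth); depths beyond the grid are clamped when the table is used.
#' @param levels confidence levels.
#' @param reps Monte-Carlo replicates per depth (>= 1000).
#' @param population `"F2"` or `"BC1"`.
#' @param seed optional seed.
#' @return data.frame of class `null_ci_table`: one row per depth with
#'   `ci<level>_lo` / `ci<level>_hi` columns; design parameters as
#'   attributes.
#' @export
#' @examples
#' ci <- null_ci(depths = c(10, 30), reps = 2000, seed = 1)
#' ci
null_ci <- function(n_bulk = 30, depths = c(7:100, 120, 150, 200),
                    levels = c(0.95, 0.99), reps = 10000,
                    population = c("F2", "BC1"), seed = NULL) {
  population <- match.arg(population)
  if (reps < 1000) stop("reps must be >= 1000")
  if (any(depths < 1)) stop("depths must be >= 1")
  .maybe_seed(seed)
  depths <- sort(unique(as.integer(depths)))
  rows <- lapply(depths, function(d) {
    delta <- null_index_draws(n_bulk, d, reps, population) -
      null_index_draws(n_bulk, d, reps, population)
    qs <- lapply(levels, function(lv)
      quantile(delta, c((1 - lv) / 2, 1 - (1 - lv) / 2), names = FALSE))
    row <- data.frame(depth = d)
    for (i in seq_along(levels)) {
      row[[.lv_col(levels[i], "lo")]] <- qs[[i]][1]
      row[[.lv_col(levels[i], "hi")]] <- qs[[i]][2]
    }
    row
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("null_ci_table", "data.frame"),
            n_bulk = n_bulk, reps = reps, population = population,
            levels = levels, seed = seed)
}

#' @export
#' @method print null_ci_table
print.null_ci_table <- function(x, ...) {
  cat("Null delta(SNP-index) confidence bands (", attr(x, "population"),
      " design, ", attr(x, "n_bulk"), " per bulk, ", attr(x, "reps"),
      " reps)\n", sep = "")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

# per-site band bounds at the sites' effective depths, by linear
# interpolation between tabulated depths (clamped to the table range)
.site_bounds <- function(eff_depth, ci, level) {
  d <- pmin(pmax(eff_depth, min(ci$depth)), max(ci$depth))
  lo <- approx(ci$depth, ci[[.lv_col(level, "lo")]], xout = d, rule = 2)$y
  hi <- approx(ci$depth, ci[[.lv_col(level, "hi")]], xout = d, rule = 2)$y
  list(lo = lo, hi = hi)
}

# effective per-site depth for band lookup
.eff_depth <- function(records, depth_rule = c("min", "mean")) {
  depth_rule <- match.arg(depth_rule)
  if (depth_rule == "min") pmin(records$fr_depth, records$sm_depth)
  else (records$fr_depth + records$sm_depth) / 2
}

#' Attach null confidence bands to sliding windows
#'
#' Every member site gets band bounds at its own effective depth (by
#' default the smaller of its two bulk depths -- the conservative choice,
#' giving the wider band), linearly interpolated between tabulated depths
#' and clamped to the table range; a window's band is the arithmetic mean
#' of its member sites' bounds, mirroring how the window's delta is the
#' mean of the member deltas.
#'
#' @param windows output of [sliding_windows()].
#' @param records the same filtered site records the windows were built on.
#' @param ci a `null_ci_table` from [null_ci()].
#' @param depth_rule `"min"` (default) or `"mean"` of the two bulk depths.
#' @return `windows` with `ci<level>_lo` / `ci<level>_hi` columns appended.
#' @export
attach_ci <- function(windows, records, ci, depth_rule = c("min", "mean")) {
  if (is.null(ci) || nrow(ci) == 0L) stop("empty confidence-interval table")
  window <- attr(windows, "window"); step <- attr(windows, "step")
  if (is.null(window) || is.null(step))
    stop("windows must come from sliding_windows()")
  eff <- .eff_depth(records, depth_rule)
  levels <- attr(ci, "levels")
  per_site <- lapply(levels, function(lv) .site_bounds(eff, ci, lv))
  names(per_site) <- as.character(levels)
  for (lv in levels) {
    windows[[.lv_col(lv, "lo")]] <- NA_real_
    windows[[.lv_col(lv, "hi")]] <- NA_real_
  }
  for (ch in unique(windows$chrom)) {
    sel <- records$chrom == ch
    r_pos <- records$pos[sel]
    w <- windows$chrom == ch
    lo_i <- findInterval(windows$start[w], r_pos)
    hi_i <- findInterval(windows$end[w], r_pos)
    n <- hi_i - lo_i
    for (lv in levels) {
      b <- per_site[[as.character(lv)]]
      cs_lo <- c(0, cumsum(b$lo[sel])); cs_hi <- c(0, cumsum(b$hi[sel]))
      windows[[.lv_col(lv, "lo")]][w] <- (cs_lo[hi_i + 1L] - cs_lo[lo_i + 1L]) / n
      windows[[.lv_col(lv, "hi")]][w] <- (cs_hi[hi_i + 1L] - cs_hi[lo_i + 1L]) / n
    }
  }
  windows
}

#' Fraction of null sites falling outside their confidence band
#'
#' Calibration measure for the Monte-Carlo bands: the fraction of sites
#' whose delta lies outside the band at their own depth. Because delta is
#' discrete (a lattice of spacing 1/depth) and the empirical band lands on
#' lattice atoms, strictly-outside counting is systematically conservative;
#' the default mid-P convention counts sites exactly on the boundary with
#' weight 1/2, which restores the nominal rate in the continuum limit.
#'
#' @param delta per-site delta values.
#' @param eff_depth per-site effective depths (see [attach_ci()]).
#' @param ci a `null_ci_table`.
#' @param level band level to test.
#' @param ties `"half"` (mid-P, default), `"strict"`, or `"inclusive"`.
#' @return the exceedance fraction.
#' @export
ci_exceedance <- function(delta, eff_depth, ci, level = 0.95,
                          ties = c("half", "strict", "inclusive")) {
  ties <- match.arg(ties)
  b <- .site_bounds(eff_depth, ci, level)
  tol <- 1e-9
  outside <- delta > b$hi + tol | delta < b$lo - tol
  on_edge <- abs(delta - b$hi) <= tol | abs(delta - b$lo) <= tol
  switch(ties,
         strict = mean(outside),
         inclusive = mean(outside | on_edge),
         half = mean(outside) + 0.5 * mean(on_edge))
}

#' Extract candidate QTL regions from banded windows
#'
#' Windows whose mean delta(SNP-index) exceeds the band at the requested
#' level (upper tail for restorer-parent QTL; lower tail symmetric) are
#' merged into regions when overlapping or separated by at most `max_gap`;
#' regions shorter than `min_span` are discarded. The peak is the member
#' window with the largest absolute mean delta.
#'
#' @param windows banded windows from [attach_ci()].
#' @param level significance level of the band (default 0.95, i.e. P < 0.05).
#' @param tail `"upper"` or `"lower"`.
#' @param min_span minimum region span in bp (default 1 Mb).
#' @param max_gap maximum gap between merged windows (default: the window
#'   step).
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open),
#'   `peak_delta`, `peak_position`, `n_windows`, `level`.
#' @export
call_regions <- function(windows, level = 0.95, tail = c("upper", "lower"),
                         min_span = 1e6, max_gap = NULL) {
  tail <- match.arg(tail)
  if (is.null(max_gap)) max_gap <- attr(windows, "step")
  if (is.null(max_gap)) max_gap <- 1e4
  hi <- windows[[.lv_col(level, "hi")]]
  lo <- windows[[.lv_col(level, "lo")]]
  if (is.null(hi)) stop("windows carry no band at level ", level)
  sig <- if (tail == "upper") windows$mean_delta > hi
         else windows$mean_delta < lo
  sw <- windows[which(sig), , drop = FALSE]
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), peak_delta = numeric(0),
                      peak_position = numeric(0), n_windows = integer(0),
                      level = numeric(0))
  if (nrow(sw) == 0L) return(empty)
  out <- lapply(unique(sw$chrom), function(ch) {
    w <- sw[sw$chrom == ch, , drop = FALSE]
    w <- w[order(w$start), , drop = FALSE]
    grp <- cumsum(c(1, w$start[-1] > cummax(w$end[-nrow(w)]) + max_gap))
    do.call(rbind, lapply(split(w, grp), function(g) {
      peak <- g[which.max(abs(g$mean_delta)), ]
      data.frame(chrom = ch, start = min(g$start), end = max(g$end),
                 peak_delta = peak$mean_delta,
                 peak_position = (peak$start + peak$end) / 2,
                 n_windows = nrow(g), level = level,
                 stringsAsFactors = FALSE)
    }))
  })
  res <- do.call(rbind, out)
  res <- res[res$end - res$start >= min_span, , drop = FALSE]
  rownames(res) <- NULL
  res
}
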