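#' Bulked-segregant QTL-seq genome scan
#'
#' Fits the full QTL-seq analysis to a four-sample variant table (two inbred
#' parents, two extreme-phenotype bulks): selects informative parental SNPs,
#' computes per-site SNP-index for each bulk and delta(SNP-index) (the
#' trait-positive minus the trait-negative bulk), applies the locus filters
#' (read depth < `min_depth`, SNP-index < `index_low` or > `index_high` in
#' both bulks), averages in sliding windows, attaches Monte-Carlo confidence
#' bands for delta under the null hypothesis of no QTL at the observed read
#' depths, and extracts candidate regions whose window delta exceeds the
#' band.
#'
#' @param variants a file path (VCF or TSV; see [read_variants()]), a raw
#'   record table from [read_variants()], or a simulated/canonical site
#'   table.
#' @param sample_map VCF sample-name mapping, see [read_variants()].
#' @param min_parent_depth parental depth must exceed this (strict).
#' @param min_depth,index_low,index_high locus filters, see
#'   [apply_locus_filters()].
#' @param window,step sliding-window span and increment in bp.
#' @param bulk_size individuals per bulk used for the null bands.
#' @param population `"F2"` or `"BC1"` null design.
#' @param levels confidence levels for the bands.
#' @param ci optional precomputed [null_ci()] table (reused across runs);
#'   computed from `ci_reps` replicates when `NULL`.
#' @param ci_reps Monte-Carlo replicates per tabulated depth.
#' @param depth_rule per-site effective depth for band lookup, see
#'   [attach_ci()].
#' @param call_level band level at which regions are called (0.95 means
#'   P < 0.05).
#' @param tail `"upper"` calls QTL where the trait-positive bulk is enriched
#'   for the restorer-parent allele; `"lower"` is the symmetric case.
#' @param min_span,max_gap region merging parameters, see [call_regions()].
#' @param chrom_lengths optional named chromosome lengths for window tiling.
#' @param seed seed for the Monte-Carlo bands (ignored when `ci` is given).
#' @return an object of class `qtlseq` with components `sites` (retained
#'   per-SNP records), `windows` (with band columns), `regions`, `ci`,
#'   `filter_counts`, `discards`, `n_input`, `params`, `call`.
#' @seealso [summary.qtlseq()], [plot.qtlseq()], [run_qtlseq()]
#' @export
#' @examples
#' g <- genome_model(data.frame(name = "chr1", length = 20e6))
#' m <- restoration_model(rf4_locus = list(chrom = "chr1", pos = 2e6),
#'                        q_locus = list(chrom = "chr1", pos = 15e6))
#' d <- simulate_bsa_dataset(g, m, n_plants = 400, seed = 7)
#' fit <- qtlseq(d$variants, ci_reps = 1000, seed = 7)
#' fit
qtlseq <- function(variants,
                   sample_map = c(P1 = "P1", P2 = "P2", FR = "FR", SM = "SM"),
                   min_parent_depth = 5,
                   min_depth = 7, index_low = 0.3, index_high = 0.7,
                   window = 5e6, step = 1e4,
                   bulk_size = 30, population = c("F2", "BC1"),
                   levels = c(0.95, 0.99),
                   ci = NULL, ci_reps = 10000,
                   depth_rule = c("min", "mean"),
                   call_level = 0.95, tail = c("upper", "lower"),
                   min_span = 1e6, max_gap = step,
                   chrom_lengths = NULL, seed = NULL) {
  population <- match.arg(population)
  depth_rule <- match.arg(depth_rule)
  tail <- match.arg(tail)
  cl <- match.call()
  raw <- if (is.character(variants))
    read_variants(variants, sample_map = sample_map) else variants
  sites <- select_informative(raw, min_parent_depth = min_parent_depth)
  discards <- attr(sites, "discards")
  n_input <- attr(sites, "n_input")
  rec <- compute_snp_index(sites)
  rec <- apply_locus_filters(rec, min_depth = min_depth,
                             low = index_low, high = index_high)
  filter_counts <- attr(rec, "filter_counts")
  if (nrow(rec) == 0L)
    stop("no sites retained after filtering (input: ", n_input,
         "; informative: ", nrow(sites),
         "; removed by depth filter: ", filter_counts[["depth"]],
         ", low index: ", filter_counts[["low_index"]],
         ", high index: ", filter_counts[["high_index"]], ")")
  if (is.null(ci))
    ci <- null_ci(n_bulk = bulk_size, levels = levels, reps = ci_reps,
                  population = population, seed = seed)
  wins <- sliding_windows(rec, window = window, step = step,
                          chrom_lengths = chrom_lengths)
  wins <- attach_ci(wins, rec, ci, depth_rule = depth_rule)
  regions <- call_regions(wins, level = call_level, tail = tail,
                          min_span = min_span, max_gap = max_gap)
  structure(list(sites = rec, windows = wins, regions = regions, ci = ci,
                 filter_counts = filter_counts, discards = discards,
                 n_input = n_input,
                 params = list(min_parent_depth = min_parent_depth,
                               min_depth = min_depth, index_low = index_low,
                               index_high = index_high, window = window,
                               step = step, bulk_size = bulk_size,
                               population = population, levels = levels,
                               depth_rule = depth_rule,
                               call_level = call_level, tail = tail,
                               min_span = min_span, max_gap = max_gap,
                               seed = seed),
                 call = cl),
            class = "qtlseq")
}

#' @export
#' @method print qtlseq
print.qtlseq <- function(x, ...) {
  cat("QTL-seq bulked-segregant scan\n")
  cat("  sites retained:", nrow(x$sites), "of", x$n_input, "input records\n")
  cat("  windows:", nrow(x$windows), sprintf("(%.1f Mb span, %.0f kb step)\n",
      x$params$window / 1e6, x$params$step / 1e3))
  cat("  candidate regions at P <", format(1 - x$params$call_level), ":",
      nrow(x$regions), "\n")
  if (nrow(x$regions)) {
    r <- x$regions
    cat(sprintf("    %s:%.2f-%.2f Mb  peak delta = %.3f at %.2f Mb\n",
                r$chrom, r$start / 1e6, r$end / 1e6, r$peak_delta,
                r$peak_position / 1e6), sep = "")
  }
  invisible(x)
}

#' Summary of a QTL-seq scan
#'
#' @param object a `qtlseq` fit.
#' @param ... unused.
#' @return a `summary.qtlseq` list with filter accounting, per-chromosome
#'   window counts, and the region table.
#' @export
summary.qtlseq <- function(object, ...) {
  s <- list(
    n_input = object$n_input,
    discards = object$discards,
    filter_counts = object$filter_counts,
    n_sites = nrow(object$sites),
    mean_fr = mean(object$sites$fr_index),
    mean_sm = mean(object$sites$sm_index),
    mean_delta = mean(object$sites$delta),
    windows_per_chrom = table(object$windows$chrom),
    regions = object$regions,
    params = object$params
  )
  class(s) <- "summary.qtlseq"
  s
}

#' @export
#' @method print summary.qtlseq
print.summary.qtlseq <- function(x, ...) {
  cat("Input records:       ", x$n_input, "\n")
  cat("Informative discards:",
      paste(names(x$discards), x$discards, sep = "=", collapse = ", "), "\n")
  cat("Locus-filter removals:",
      paste(names(x$filter_counts), x$filter_counts, sep = "=",
            collapse = ", "), "\n")
  cat("Retained sites:      ", x$n_sites, "\n")
  cat(sprintf("Mean index: FR %.3f, SM %.3f, delta %.3f\n",
              x$mean_fr, x$mean_sm, x$mean_delta))
  cat("Windows per chromosome:\n")
  print(x$windows_per_chrom)
  cat("Candidate regions:\n")
  if (nrow(x$regions)) print(x$regions, row.names = FALSE)
  else cat("  none\n")
  invisible(x)
}

#' Per-site SNP-index records of a fit
#' @param object a `qtlseq` fit.
#' @param ... unused.
#' @return data.frame of retained sites.
#' @export
fitted.qtlseq <- function(object, ...) object$sites

#' Write the standard QTL-seq output files
#'
#' Runs [qtlseq()] (unless given an existing fit) and writes the per-SNP
#' site table and per-window table as TSV (1-based inclusive coordinates),
#' the candidate regions as BED (0-based half-open, score = 1000 x peak
#' delta), and the three-track index plot. Output is deterministic for a
#' fixed seed: no timestamps are written.
#'
#' @param variants input as in [qtlseq()], or a fitted `qtlseq` object.
#' @param outdir output directory (created if needed).
#' @param prefix file-name prefix.
#' @param plot_formats subset of `c("png", "svg", "pdf")`; formats whose
#'   device is unavailable are skipped with a message.
#' @param ... passed on to [qtlseq()].
#' @return the `qtlseq` fit, invisibly; file paths in attribute `files`.
#' @export
run_qtlseq <- function(variants, outdir = ".", prefix = "qtlseq",
                       plot_formats = c("png", "pdf"), ...) {
  fit <- if (inherits(variants, "qtlseq")) variants else qtlseq(variants, ...)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(ext) file.path(outdir, paste0(prefix, ext))
  files <- character(0)

  sites <- fit$sites
  sites$pos <- formatC(sites$pos, format = "d")
  write.table(sites, p("_sites.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  files <- c(files, p("_sites.tsv"))

  w1 <- fit$windows
  w1$start <- formatC(w1$start + 1, format = "d") # 1-based inclusive in TSV
  w1$end <- formatC(w1$end, format = "d")
  write.table(w1, p("_windows.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  files <- c(files, p("_windows.tsv"))

  r <- fit$regions
  bed <- data.frame(chrom = r$chrom, start = formatC(r$start, format = "d"),
                    end = formatC(r$end, format = "d"),
                    name = if (nrow(r)) paste0("region_", seq_len(nrow(r)))
                           else character(0),
                    score = round(1000 * r$peak_delta))
  writeLines(do.call(paste, c(bed, sep = "\t")), p("_regions.bed"))
  files <- c(files, p("_regions.bed"))

  has_cairo <- capabilities("cairo")
  for (fmt in plot_formats) {
    f <- p(paste0("_tracks.", fmt))
    ok <- TRUE
    if (fmt == "png" && has_cairo) grDevices::png(f, 1200, 900, type = "cairo")
    else if (fmt == "png" && capabilities("png")) grDevices::png(f, 1200, 900)
    else if (fmt == "svg" && has_cairo) grDevices::svg(f, 12, 9)
    else if (fmt == "pdf") grDevices::pdf(f, 12, 9)
    else { message("skipping unavailable plot device: ", fmt); ok <- FALSE }
    if (ok) {
      plot(fit)
      grDevices::dev.off()
      files <- c(files, f)
    }
  }
  attr(fit, "files") <- files
  invisible(fit)
}
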