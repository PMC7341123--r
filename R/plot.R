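#' Three-track SNP-index plot
#'
#' Draws, per chromosome, the sliding-window mean SNP-index of the
#' trait-positive bulk (top), of the trait-negative bulk (middle), and the
#' window mean delta(SNP-index) with the null confidence bands at both
#' configured levels (bottom; conventionally red for P < 0.05, green for
#' P < 0.01). Candidate regions, when supplied, are shaded on the delta
#' track. Chromosomes with no windows are omitted with a warning.
#'
#' @param windows banded window table from [attach_ci()] (or the `windows`
#'   component of a [qtlseq()] fit).
#' @param regions optional region table from [call_regions()].
#' @param levels band levels to draw (must be columns of `windows`).
#' @param band_cols line colours for the bands, one per level.
#' @param main overall title.
#' @return invisibly, the vector of chromosomes plotted.
#' @export
plot_index_tracks <- function(windows, regions = NULL,
                              levels = c(0.95, 0.99),
                              band_cols = c("red", "darkgreen"),
                              main = "QTL-seq scan") {
  chroms <- unique(windows$chrom)
  if (length(chroms) == 0L) {
    warning("no windows to plot")
    return(invisible(character(0)))
  }
  levels <- levels[vapply(levels, function(lv)
    .lv_col(lv, "hi") %in% names(windows), logical(1))]
  op <- graphics::par(mfrow = c(3, length(chroms)),
                      mar = c(3.5, 3.8, 2, 0.8), mgp = c(2.2, 0.7, 0))
  on.exit(graphics::par(op))
  track <- function(ycol, ylab, ylim, bands = FALSE) {
    for (ch in chroms) {
      w <- windows[windows$chrom == ch, , drop = FALSE]
      mb <- (w$start + w$end) / 2 / 1e6
      plot(mb, w[[ycol]], type = "l", ylim = ylim, xlab = paste(ch, "(Mb)"),
           ylab = ylab, col = "grey20")
      graphics::abline(h = if (bands) 0 else 0.5, lty = 3, col = "grey60")
      if (bands) {
        for (i in seq_along(levels)) {
          graphics::lines(mb, w[[.lv_col(levels[i], "hi")]],
                          col = band_cols[i], lwd = 1)
          graphics::lines(mb, w[[.lv_col(levels[i], "lo")]],
                          col = band_cols[i], lwd = 1)
        }
        if (!is.null(regions) && nrow(regions)) {
          rr <- regions[regions$chrom == ch, , drop = FALSE]
          if (nrow(rr))
            graphics::rect(rr$start / 1e6, -1, rr$end / 1e6, 1,
                           col = grDevices::adjustcolor("orange", 0.2),
                           border = NA)
        }
      }
      if (ch == chroms[1] && ycol == "mean_fr") graphics::title(main = main)
    }
  }
  track("mean_fr", "SNP-index (FR)", c(0, 1))
  track("mean_sm", "SNP-index (SM)", c(0, 1))
  track("mean_delta", expression(Delta * "(SNP-index)"), c(-1, 1),
        bands = TRUE)
  invisible(chroms)
}

#' Plot a QTL-seq fit
#'
#' @param x a [qtlseq()] fit.
#' @param ... passed to [plot_index_tracks()].
#' @return see [plot_index_tracks()].
#' @export
#' @method plot qtlseq
plot.qtlseq <- function(x, ...) {
  plot_index_tracks(x$windows, regions = x$regions,
                    levels = x$params$levels, ...)
}
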