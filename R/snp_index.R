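#' SNP-index: fraction of reads carrying the restorer-parent allele
#'
#' The SNP-index at a site is the proportion of a bulk's reads that carry
#' the designated (restorer) parent's allele: 0 when every read comes from
#' the maintainer parent, 1 when every read comes from the restorer parent,
#' and near 0.5 at sites unlinked to the trait in an F2 bulk.
#'
#' @param restorer_reads,other_reads non-negative read counts (vectorised).
#' @return `restorer_reads / (restorer_reads + other_reads)`; total depth
#'   must be positive (zero-depth sites are excluded upstream by the depth
#'   filter).
#' @export
#' @examples
#' snp_index(12, 0) # 1
#' snp_index(7, 3)  # 0.7
snp_index <- function(restorer_reads, other_reads) {
  if (any(restorer_reads < 0 | other_reads < 0)) stop("counts must be >= 0")
  tot <- restorer_reads + other_reads
  if (any(tot == 0)) stop("zero total depth: site must be filtered out upstream")
  restorer_reads / tot
}

#' Per-site SNP-index records for both bulks
#'
#' Adds per-bulk depth, SNP-index and delta(SNP-index) (FR minus SM) to a
#' canonical site table. Sites with zero depth in a bulk get `NA` indices;
#' they are removed by [apply_locus_filters()] (any reasonable `min_depth`
#' exceeds 0).
#'
#' @param sites canonical site table (see [select_informative()]), or the
#'   output of [simulate_reads()].
#' @return the table with columns `fr_depth`, `sm_depth`, `fr_index`,
#'   `sm_index`, `delta` appended.
#' @export
compute_snp_index <- function(sites) {
  s <- as_variant_sites(sites)
  s$fr_depth <- s$fr_restorer + s$fr_other
  s$sm_depth <- s$sm_restorer + s$sm_other
  s$fr_index <- ifelse(s$fr_depth > 0, s$fr_restorer / s$fr_depth, NA_real_)
  s$sm_index <- ifelse(s$sm_depth > 0, s$sm_restorer / s$sm_depth, NA_real_)
  s$delta <- s$fr_index - s$sm_index
  s
}

#' Locus filters for SNP-index records
#'
#' Removes false-positive-prone loci: a site is dropped when (a) either
#' bulk's read depth is below `min_depth` (default 7), or (b) both bulks'
#' SNP-indices lie below `low` (default 0.3), or (c) both lie above `high`
#' (default 0.7). Jointly extreme sites are typically mis-called or
#' monomorphic loci, while sites where the two bulks disagree are exactly
#' the signal of interest, so the index rule requires *both* bulks on the
#' same extreme side by default. Both the thresholds and the
#' either/both semantics are configurable.
#'
#' @param records output of [compute_snp_index()].
#' @param min_depth drop a site when a bulk's depth is `< min_depth`.
#' @param low,high SNP-index thresholds.
#' @param depth_rule `"either"` (default: one shallow bulk suffices to drop)
#'   or `"both"` (drop only when both bulks are shallow).
#' @param index_rule `"both"` (default) or `"either"` bulk beyond the
#'   threshold on the same side.
#' @return filtered records with attribute `filter_counts`, named counts of
#'   sites removed per rule (`depth`, `low_index`, `high_index`).
#' @export
apply_locus_filters <- function(records, min_depth = 7, low = 0.3, high = 0.7,
                                depth_rule = c("either", "both"),
                                index_rule = c("both", "either")) {
  depth_rule <- match.arg(depth_rule)
  index_rule <- match.arg(index_rule)
  shallow_fr <- records$fr_depth < min_depth
  shallow_sm <- records$sm_depth < min_depth
  depth_fail <- if (depth_rule == "either") shallow_fr | shallow_sm
                else shallow_fr & shallow_sm
  comb <- if (index_rule == "both") `&` else `|`
  low_fail <- !depth_fail &
    comb(records$fr_index < low, records$sm_index < low)
  high_fail <- !depth_fail & !low_fail &
    comb(records$fr_index > high, records$sm_index > high)
  keep <- !(depth_fail | low_fail | high_fail)
  keep[is.na(keep)] <- FALSE
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "filter_counts") <- c(depth = sum(depth_fail, na.rm = TRUE),
                                  low_index = sum(low_fail, na.rm = TRUE),
                                  high_index = sum(high_fail, na.rm = TRUE))
  out
}

#' Delta(SNP-index)
#'
#' The SNP-index of the trait-negative (SM) bulk subtracted from that of
#' the trait-positive (FR) bulk; near 0 under no linkage, pushed towards
#' +1 (restorer-parent QTL) or -1 near a causal locus.
#'
#' @param records output of [compute_snp_index()] (or anything with
#'   `fr_index`/`sm_index` columns).
#' @return numeric vector in `[-1, 1]`.
#' @export
delta_index <- function(records) {
  records$fr_index - records$sm_index
}
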