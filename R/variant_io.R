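# Canonical site table ("variant sites"): one row per biallelic SNP,
# oriented to the restorer-parent allele, with columns
#   chrom, pos, restorer_allele, other_allele, p1_depth, p2_depth,
#   fr_restorer, fr_other, sm_restorer, sm_other
# Coordinates are 1-based inclusive throughout (VCF convention);
# conversions to 0-based half-open live only in the BED writer.

.canon_cols <- c("chrom", "pos", "restorer_allele", "other_allele",
                 "p1_depth", "p2_depth",
                 "fr_restorer", "fr_other", "sm_restorer", "sm_other")

# simulate_reads() output -> canonical site table (parents collapse to depths)
as_variant_sites <- function(x) {
  if (all(.canon_cols %in% names(x))) return(x[, .canon_cols, drop = FALSE])
  stopifnot(all(c("p1_restorer", "fr_restorer") %in% names(x)))
  data.frame(chrom = x$chrom, pos = x$pos,
             restorer_allele = x$restorer_allele,
             other_allele = x$other_allele,
             p1_depth = x$p1_restorer + x$p1_other,
             p2_depth = x$p2_restorer + x$p2_other,
             fr_restorer = x$fr_restorer, fr_other = x$fr_other,
             sm_restorer = x$sm_restorer, sm_other = x$sm_other,
             stringsAsFactors = FALSE)
}

.check_sorted <- function(chrom, pos) {
  if (length(pos) < 2L) return(invisible(NULL))
  runs <- rle(as.character(chrom))
  if (anyDuplicated(runs$values))
    stop("input not sorted: chromosome '",
         runs$values[anyDuplicated(runs$values)],
         "' appears in more than one block")
  bad <- which(diff(pos) <= 0 & chrom[-1] == chrom[-length(chrom)])
  if (length(bad))
    stop("input not sorted: ", chrom[bad[1] + 1L], ":", pos[bad[1] + 1L],
         " follows position ", pos[bad[1]])
  invisible(NULL)
}

#' Write a variant table in the tab-separated dialect
#'
#' Columns: `chrom`, `pos` (1-based), `p1_allele` (restorer-parent allele),
#' `p2_allele`, `fr_restorer_depth`, `fr_other_depth`, `sm_restorer_depth`,
#' `sm_other_depth`, plus `p1_depth`/`p2_depth` so that the full site record
#' round-trips. The seed, when given, is recorded as a header comment.
#'
#' @param x variant table from [simulate_reads()] or a canonical site table.
#' @param path output file.
#' @param seed optional seed to record in the header.
#' @return `path`, invisibly.
#' @export
write_variants_tsv <- function(x, path, seed = NULL) {
  s <- as_variant_sites(x)
  out <- data.frame(chrom = s$chrom, pos = formatC(s$pos, format = "d"),
                    p1_allele = s$restorer_allele,
                    p2_allele = s$other_allele,
                    fr_restorer_depth = s$fr_restorer,
                    fr_other_depth = s$fr_other,
                    sm_restorer_depth = s$sm_restorer,
                    sm_other_depth = s$sm_other,
                    p1_depth = s$p1_depth, p2_depth = s$p2_depth)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#format=bsaqtl-variant-tsv-v1", con)
  if (!is.null(seed)) writeLines(paste0("#seed=", format(seed)), con)
  writeLines(paste(names(out), collapse = "\t"), con)
  write.table(out, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a variant table as VCF v4.2
#'
#' Emits samples `P1` (restorer parent), `P2`, `FR` and `SM` with `GT`,
#' `DP` and `AD` FORMAT fields. REF/ALT orientation follows the table's
#' `restorer_is_ref` column when present (random in simulated data, so the
#' reader's re-orientation is exercised), otherwise REF is the restorer
#' allele.
#'
#' @inheritParams write_variants_tsv
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(x, path, seed = NULL) {
  has_parent_ad <- all(c("p1_restorer", "p1_other") %in% names(x))
  s <- as_variant_sites(x)
  rr <- if ("restorer_is_ref" %in% names(x)) x$restorer_is_ref
        else rep(TRUE, nrow(s))
  p1r <- if (has_parent_ad) x$p1_restorer else s$p1_depth
  p1o <- if (has_parent_ad) x$p1_other else 0L
  p2r <- if (has_parent_ad) x$p2_restorer else 0L
  p2o <- if (has_parent_ad) x$p2_other else s$p2_depth
  ref <- ifelse(rr, s$restorer_allele, s$other_allele)
  alt <- ifelse(rr, s$other_allele, s$restorer_allele)
  fmt <- function(res, oth) {
    dp <- res + oth
    ad <- ifelse(rr, paste(res, oth, sep = ","), paste(oth, res, sep = ","))
    gt <- ifelse(res > oth, ifelse(rr, "0/0", "1/1"),
          ifelse(oth > res, ifelse(rr, "1/1", "0/0"), "0/1"))
    paste(gt, dp, ad, sep = ":")
  }
  bulk_fmt <- function(res, oth) {
    dp <- res + oth
    ad <- ifelse(rr, paste(res, oth, sep = ","), paste(oth, res, sep = ","))
    gt <- ifelse(res == 0 & oth > 0, ifelse(rr, "1/1", "0/0"),
          ifelse(oth == 0 & res > 0, ifelse(rr, "0/0", "1/1"), "0/1"))
    paste(gt, dp, ad, sep = ":")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=bsaqtl",
               if (!is.null(seed)) paste0("##bsaqtl_seed=", format(seed)),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
               '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", "P1", "P2", "FR", "SM", sep = "\t")),
             con)
  rows <- paste(s$chrom, formatC(s$pos, format = "d"), ".", ref, alt,
                ".", "PASS", ".", "GT:DP:AD",
                fmt(p1r, p1o), fmt(p2r, p2o),
                bulk_fmt(s$fr_restorer, s$fr_other),
                bulk_fmt(s$sm_restorer, s$sm_other), sep = "\t")
  writeLines(rows, con)
  invisible(path)
}

#' Read a four-sample variant table (VCF or TSV)
#'
#' Reads the two-parents/two-bulks variant table and returns a raw record
#' table in ascending (chrom, pos) order; unsorted input is a fatal error
#' naming the first out-of-order position. For VCF input, per-sample allele
#' depths come from the `AD` FORMAT field and parental calls from `GT`;
#' rows with missing bulk `AD` are counted as malformed (see
#' [select_informative()] accounting). Pass the result to
#' [select_informative()] to obtain oriented, informative sites.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"vcf"` or `"tsv"`.
#' @param sample_map named character vector mapping the roles `P1`
#'   (restorer parent), `P2`, `FR`, `SM` to VCF sample names.
#' @return a raw record data.frame with attribute `n_input` (rows read).
#' @export
read_variants <- function(path, format = c("auto", "vcf", "tsv"),
                          sample_map = c(P1 = "P1", P2 = "P2",
                                         FR = "FR", SM = "SM")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  if (format == "tsv") .read_variants_tsv(path) else
    .read_variants_vcf(path, sample_map)
}

.read_variants_tsv <- function(path) {
  x <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                  stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "p1_allele", "p2_allele",
            "fr_restorer_depth", "fr_other_depth",
            "sm_restorer_depth", "sm_other_depth")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("TSV is missing columns: ", paste(miss, collapse = ", "))
  .check_sorted(x$chrom, x$pos)
  raw <- data.frame(chrom = as.character(x$chrom), pos = x$pos,
                    ref = x$p1_allele, alt = x$p2_allele,
                    filter = "PASS", p1_gt = "0/0", p2_gt = "1/1",
                    p1_ref = if ("p1_depth" %in% names(x)) x$p1_depth else NA_integer_,
                    p1_alt = 0L,
                    p2_ref = 0L,
                    p2_alt = if ("p2_depth" %in% names(x)) x$p2_depth else NA_integer_,
                    fr_ref = x$fr_restorer_depth, fr_alt = x$fr_other_depth,
                    sm_ref = x$sm_restorer_depth, sm_alt = x$sm_other_depth,
                    stringsAsFactors = FALSE)
  attr(raw, "n_input") <- nrow(raw)
  attr(raw, "n_malformed") <- 0L
  raw
}

.read_variants_vcf <- function(path, sample_map) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(v@gt)[-1]
  roles <- c("P1", "P2", "FR", "SM")
  if (!all(roles %in% names(sample_map)))
    stop("sample_map must name all of P1, P2, FR, SM")
  unknown <- setdiff(sample_map[roles], samples)
  if (length(unknown))
    stop("sample(s) not present in VCF: ", paste(unknown, collapse = ", "))
  chrom <- vcfR::getCHROM(v)
  pos <- vcfR::getPOS(v)
  .check_sorted(chrom, pos)
  gt <- vcfR::extract.gt(v, element = "GT")
  ad <- vcfR::extract.gt(v, element = "AD")
  split_ad <- function(role) {
    a <- ad[, sample_map[[role]]]
    parts <- strsplit(ifelse(is.na(a), "", a), ",", fixed = TRUE)
    refd <- suppressWarnings(as.integer(vapply(parts, function(p)
      if (length(p) >= 1L) p[1] else NA_character_, character(1))))
    altd <- suppressWarnings(as.integer(vapply(parts, function(p)
      if (length(p) >= 2L) p[2] else NA_character_, character(1))))
    list(ref = refd, alt = altd)
  }
  p1 <- split_ad("P1"); p2 <- split_ad("P2")
  fr <- split_ad("FR"); sm <- split_ad("SM")
  raw <- data.frame(chrom = chrom, pos = pos,
                    ref = vcfR::getREF(v), alt = vcfR::getALT(v),
                    filter = vcfR::getFILTER(v),
                    p1_gt = unname(gt[, sample_map[["P1"]]]),
                    p2_gt = unname(gt[, sample_map[["P2"]]]),
                    p1_ref = p1$ref, p1_alt = p1$alt,
                    p2_ref = p2$ref, p2_alt = p2$alt,
                    fr_ref = fr$ref, fr_alt = fr$alt,
                    sm_ref = sm$ref, sm_alt = sm$alt,
                    stringsAsFactors = FALSE)
  n_input <- nrow(raw)
  # record-level errors: bulk allele depths absent
  bad <- is.na(raw$fr_ref) | is.na(raw$fr_alt) |
         is.na(raw$sm_ref) | is.na(raw$sm_alt)
  if (any(bad)) {
    message(sum(bad), " record(s) with missing bulk AD dropped (lines ",
            paste(utils::head(which(bad), 5L), collapse = ", "),
            if (sum(bad) > 5L) ", ..." else "", ")")
    raw <- raw[!bad, , drop = FALSE]
  }
  rownames(raw) <- NULL
  attr(raw, "n_input") <- n_input
  attr(raw, "n_malformed") <- sum(bad)
  raw
}

.is_hom <- function(gt, allele) gt %in% paste(allele, allele, sep = c("/")) |
  gt %in% paste(allele, allele, sep = "|")

#' Select informative parental SNPs and orient to the restorer allele
#'
#' Keeps only sites where both parents are called homozygous for different
#' alleles and each parent's read depth exceeds `min_parent_depth` (strict
#' `>`, default 5), then orients every record to the restorer parent's (P1)
#' allele: the reported counts are (restorer-allele reads, other-allele
#' reads) regardless of how REF/ALT were encoded. Discards are counted by
#' reason (`filter_fail`, `not_snp`, `het_parent`, `same_allele`,
#' `low_parent_depth`, plus `malformed` rows dropped at read time) and the
#' accounting satisfies input = retained + sum(discards).
#'
#' @param raw table from [read_variants()], or a canonical/simulated site
#'   table (then only the depth rule applies).
#' @param min_parent_depth retain only parents with depth strictly greater
#'   than this (default 5).
#' @param use_filter drop rows whose VCF FILTER is neither `PASS` nor `.`.
#' @param snps_only drop non-SNP or multiallelic records (default TRUE).
#' @return canonical site table with attribute `discards` (named counts)
#'   and `n_input`.
#' @export
select_informative <- function(raw, min_parent_depth = 5,
                               use_filter = TRUE, snps_only = TRUE) {
  if (all(.canon_cols %in% names(raw)) || "p1_restorer" %in% names(raw)) {
    s <- as_variant_sites(raw)
    low <- (!is.na(s$p1_depth) & s$p1_depth <= min_parent_depth) |
           (!is.na(s$p2_depth) & s$p2_depth <= min_parent_depth)
    out <- s[!low, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "n_input") <- nrow(s)
    attr(out, "discards") <- c(filter_fail = 0L, not_snp = 0L,
                               het_parent = 0L, same_allele = 0L,
                               low_parent_depth = sum(low), malformed = 0L)
    return(out)
  }
  n_input <- attr(raw, "n_input")
  if (is.null(n_input)) n_input <- nrow(raw)
  n_malformed <- attr(raw, "n_malformed")
  if (is.null(n_malformed)) n_malformed <- 0L
  reason <- rep(NA_character_, nrow(raw))
  if (use_filter)
    reason[is.na(reason) & !(raw$filter %in% c("PASS", "."))] <- "filter_fail"
  if (snps_only) {
    snp <- nchar(raw$ref) == 1L & nchar(raw$alt) == 1L &
      raw$ref %in% c("A", "C", "G", "T") & raw$alt %in% c("A", "C", "G", "T")
    reason[is.na(reason) & !snp] <- "not_snp"
  }
  p1_hom_ref <- .is_hom(raw$p1_gt, "0"); p1_hom_alt <- .is_hom(raw$p1_gt, "1")
  p2_hom_ref <- .is_hom(raw$p2_gt, "0"); p2_hom_alt <- .is_hom(raw$p2_gt, "1")
  reason[is.na(reason) & !((p1_hom_ref | p1_hom_alt) &
                           (p2_hom_ref | p2_hom_alt))] <- "het_parent"
  same <- (p1_hom_ref & p2_hom_ref) | (p1_hom_alt & p2_hom_alt)
  reason[is.na(reason) & same] <- "same_allele"
  p1_depth <- raw$p1_ref + raw$p1_alt
  p2_depth <- raw$p2_ref + raw$p2_alt
  reason[is.na(reason) & (is.na(p1_depth) | is.na(p2_depth) |
                          p1_depth <= min_parent_depth |
                          p2_depth <= min_parent_depth)] <- "low_parent_depth"
  keep <- is.na(reason)
  k <- raw[keep, , drop = FALSE]
  restorer_is_ref <- p1_hom_ref[keep]
  out <- data.frame(
    chrom = k$chrom, pos = k$pos,
    restorer_allele = ifelse(restorer_is_ref, k$ref, k$alt),
    other_allele = ifelse(restorer_is_ref, k$alt, k$ref),
    p1_depth = p1_depth[keep], p2_depth = p2_depth[keep],
    fr_restorer = ifelse(restorer_is_ref, k$fr_ref, k$fr_alt),
    fr_other = ifelse(restorer_is_ref, k$fr_alt, k$fr_ref),
    sm_restorer = ifelse(restorer_is_ref, k$sm_ref, k$sm_alt),
    sm_other = ifelse(restorer_is_ref, k$sm_alt, k$sm_ref),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  discards <- c(filter_fail = sum(reason == "filter_fail", na.rm = TRUE),
                not_snp = sum(reason == "not_snp", na.rm = TRUE),
                het_parent = sum(reason == "het_parent", na.rm = TRUE),
                same_allele = sum(reason == "same_allele", na.rm = TRUE),
                low_parent_depth = sum(reason == "low_parent_depth", na.rm = TRUE),
                malformed = n_malformed)
  attr(out, "n_input") <- n_input
  attr(out, "discards") <- discards
  out
}
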