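#' Genome model for the cross simulator
#'
#' Describes the physical genome on which a biparental cross is simulated:
#' chromosome names and lengths, the spacing of informative parental SNPs,
#' and the recombination model. Genetic length is derived from physical
#' length through a constant cM/Mb rate; crossovers are placed under the
#' Haldane (no-interference) model.
#'
#' The default is a scaled two-chromosome genome (2 x 150 Mb, one SNP every
#' 10 kb) so that a full simulate-and-scan run stays fast; a larger
#' multi-chromosome genome is just a different `chromosomes` table.
#'
#' @param chromosomes data.frame with columns `name` and `length` (bp).
#' @param snp_spacing distance in bp between informative parental SNPs.
#' @param cm_per_mb genetic map rate in centimorgan per megabase.
#' @param map_function recombination model; only `"haldane"` is implemented.
#' @return an object of class `genome_model`.
#' @export
#' @examples
#' g <- genome_model()
#' g$chromosomes
genome_model <- function(chromosomes = data.frame(name = c("chr1", "chr2"),
                                                  length = c(150e6, 150e6)),
                         snp_spacing = 1e4,
                         cm_per_mb = 1,
                         map_function = "haldane") {
  stopifnot(is.data.frame(chromosomes),
            all(c("name", "length") %in% names(chromosomes)))
  if (any(chromosomes$length <= 0)) stop("chromosome lengths must be > 0")
  if (snp_spacing <= 0) stop("snp_spacing must be > 0")
  if (cm_per_mb <= 0) stop("cm_per_mb must be > 0")
  map_function <- match.arg(map_function, "haldane")
  chromosomes$name <- as.character(chromosomes$name)
  structure(list(chromosomes = chromosomes,
                 snp_spacing = snp_spacing,
                 cm_per_mb = cm_per_mb,
                 map_function = map_function),
            class = "genome_model")
}

# informative SNP positions on one chromosome (1-based, within [1, length])
snp_positions <- function(genome, chrom) {
  len <- genome$chromosomes$length[match(chrom, genome$chromosomes$name)]
  if (is.na(len)) stop("unknown chromosome: ", chrom)
  seq(genome$snp_spacing, len, by = genome$snp_spacing)
}

#' Two-system fertility-restoration model
#'
#' Fertility in a CMS (cytoplasmic male sterility) cross is modelled by two
#' nuclear loci carried by the restorer parent: a dominant main restorer
#' (an *Rf4*-like gene) and a second, partially penetrant restorer QTL. The
#' joint genotype class determines a probability distribution over the five
#' fertility grades I-V (I-II sterile, III-V fertile).
#'
#' The penetrance table is free configuration, not biology the simulator
#' asserts: classes are `"Rf4_"` (at least one main-restorer allele) and
#' `"rf4rf4.qq"` / `"rf4rf4.Qq"` / `"rf4rf4.QQ"` (no main restorer, 0/1/2
#' copies of the second restorer allele). Each entry is a length-5
#' probability vector over grades I..V summing to 1.
#'
#' @param rf4_locus list/vector with `chrom` and `pos` of the main restorer.
#' @param q_locus list/vector with `chrom` and `pos` of the second restorer
#'   QTL (`NULL` for a single-gene model).
#' @param penetrance named list of grade distributions (see Details).
#' @return an object of class `restoration_model`.
#' @export
#' @examples
#' m <- restoration_model()
#' m$penetrance$rf4rf4.Qq
restoration_model <- function(rf4_locus = list(chrom = "chr1", pos = 25e6),
                              q_locus = list(chrom = "chr1", pos = 130e6),
                              penetrance = default_penetrance()) {
  pen <- penetrance
  needed <- if (is.null(q_locus)) c("Rf4_", "rf4rf4.qq")
            else c("Rf4_", "rf4rf4.qq", "rf4rf4.Qq", "rf4rf4.QQ")
  miss <- setdiff(needed, names(pen))
  if (length(miss)) stop("penetrance is missing classes: ",
                         paste(miss, collapse = ", "))
  for (cls in names(pen)) {
    p <- pen[[cls]]
    if (length(p) != 5L || any(p < 0) || abs(sum(p) - 1) > 1e-8)
      stop("penetrance for class ", cls,
           " must be 5 non-negative probabilities summing to 1")
  }
  structure(list(rf4_locus = rf4_locus, q_locus = q_locus, penetrance = pen),
            class = "restoration_model")
}

#' Default penetrance table
#'
#' Main restorer nearly fully penetrant for full fertility (grade V with
#' probability 0.997, rarely partial); plants without it are sterile when
#' they also lack the second restorer allele, and restored with probability
#' ~0.8 (grade V) when they carry it.
#'
#' @param q_penetrance probability that a `rf4rf4` plant carrying at least
#'   one second-restorer allele is fully fertile (grade V).
#' @return named list of grade-probability vectors.
#' @export
default_penetrance <- function(q_penetrance = 0.8) {
  stopifnot(q_penetrance >= 0, q_penetrance <= 1)
  rest <- 1 - q_penetrance
  qplus <- c(0.25 * rest, 0.25 * rest, 0.3 * rest, 0.2 * rest, q_penetrance)
  list(
    "Rf4_"      = c(0, 0, 0.0015, 0.0015, 0.997),
    "rf4rf4.qq" = c(0.5, 0.5, 0, 0, 0),
    "rf4rf4.Qq" = qplus,
    "rf4rf4.QQ" = qplus
  )
}

#' Short-read sampling model
#'
#' Per-sample sequencing depths are Poisson around the stated means (10x for
#' inbred parents, 30x per bulk is the usual QTL-seq design); sequencing
#' error is a symmetric per-read allele flip.
#'
#' @param parent_depth,bulk_depth mean depths.
#' @param error_rate probability a read reports the wrong allele.
#' @param depth_dist `"poisson"` (default) or `"fixed"` (every site at the
#'   mean depth exactly).
#' @return an object of class `read_model`.
#' @export
read_model <- function(parent_depth = 10, bulk_depth = 30,
                       error_rate = 0.001, depth_dist = c("poisson", "fixed")) {
  if (parent_depth < 0 || bulk_depth < 0) stop("depths must be >= 0")
  if (error_rate < 0 || error_rate >= 0.5) stop("error rate must be in [0, 0.5)")
  depth_dist <- match.arg(depth_dist)
  structure(list(parent_depth = parent_depth, bulk_depth = bulk_depth,
                 error_rate = error_rate, depth_dist = depth_dist),
            class = "read_model")
}

#' Bulk selection rule
#'
#' An extreme-phenotype bulk: individuals of a required marker genotype at
#' the main restorer locus and a required set of fertility grades. The usual
#' design contrasts 30 fully fertile (grade V) and 30 sterile (grade I/II)
#' `rf4rf4` plants.
#'
#' @param name bulk label, conventionally `"FR"` (fertility restored) or
#'   `"SM"` (sterility maintained).
#' @param genotype required genotype class at the main restorer locus,
#'   one of `"rf4rf4"`, `"Rf4rf4"`, `"Rf4Rf4"`, or `NA` for no requirement.
#' @param grades character vector of admissible fertility grades.
#' @param n bulk size.
#' @return an object of class `bulk_spec`.
#' @export
#' @examples
#' bulk_spec("FR", "rf4rf4", "V", 30)
bulk_spec <- function(name, genotype = "rf4rf4", grades, n = 30) {
  stopifnot(is.character(name), length(name) == 1L)
  if (n < 1) stop("bulk size n must be >= 1")
  if (!all(grades %in% GRADES)) stop("grades must be in I..V")
  if (!is.na(genotype) && !genotype %in% c("rf4rf4", "Rf4rf4", "Rf4Rf4"))
    stop("unknown genotype class: ", genotype)
  structure(list(name = name, genotype = genotype,
                 grades = grades, n = as.integer(n)),
            class = "bulk_spec")
}
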