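# Haplotypes are step functions of parental origin along one chromosome:
# `bp` holds segment right endpoints (ending at the chromosome length) and
# `origin` the parental origin of each segment (1 = restorer parent,
# 0 = maintainer parent). Segment i covers the half-open interval
# (bp[i-1], bp[i]].

new_haplotype <- function(bp, origin) list(bp = bp, origin = origin)

pure_haplotype <- function(length, origin) new_haplotype(length, origin)

# parental origin of a haplotype at position(s) pos
hap_at <- function(hap, pos) {
  hap$origin[findInterval(pos, hap$bp, left.open = TRUE) + 1L]
}

# one meiosis of a homolog pair under the Haldane model: crossover count is
# Poisson in the genetic length (Morgans), crossover positions uniform, no
# interference; the gamete alternates between the two parental haplotypes.
meiosis <- function(h1, h2, length, morgans) {
  ncx <- rpois(1L, morgans)
  start <- sample.int(2L, 1L)
  if (ncx == 0L) {
    hap <- if (start == 1L) h1 else h2
    return(hap)
  }
  cx <- sort(runif(ncx, 0, length))
  bounds <- sort(unique(c(cx, h1$bp, h2$bp)))
  mids <- (c(0, bounds[-length(bounds)]) + bounds) / 2
  active <- (start - 1L + findInterval(mids, cx)) %% 2L # 0 -> h1, 1 -> h2
  origin <- ifelse(active == 0L, hap_at(h1, mids), hap_at(h2, mids))
  # merge runs of equal origin
  keep <- c(origin[-1] != origin[-length(origin)], TRUE)
  new_haplotype(bounds[keep], origin[keep])
}

# genetic length of one chromosome in Morgans
chrom_morgans <- function(genome, length) length / 1e6 * genome$cm_per_mb / 100

.check_locus <- function(genome, locus, what) {
  if (is.null(locus)) return(invisible(NULL))
  i <- match(locus$chrom, genome$chromosomes$name)
  if (is.na(i)) stop(what, ": unknown chromosome '", locus$chrom, "'")
  if (locus$pos < 1 || locus$pos > genome$chromosomes$length[i])
    stop(what, ": position ", locus$pos, " outside chromosome bounds")
  invisible(NULL)
}

#' Restorer-allele dosage of one individual at a position
#'
#' @param ind an individual from [simulate_f2()] or [simulate_backcross()].
#' @param chrom,pos query position.
#' @return 0, 1 or 2 copies of the restorer-parent allele.
#' @export
genotype_at <- function(ind, chrom, pos) {
  pair <- ind$chrs[[chrom]]
  if (is.null(pair)) stop("unknown chromosome: ", chrom)
  hap_at(pair[[1]], pos) + hap_at(pair[[2]], pos)
}

# joint genotype class label used by the penetrance table
genotype_class <- function(rf4_geno, q_geno) {
  ifelse(rf4_geno >= 1L, "Rf4_",
         paste0("rf4rf4.", c("qq", "Qq", "QQ")[q_geno + 1L]))
}

# draw fertility grades for a vector of class labels
draw_grades <- function(classes, penetrance) {
  grades <- character(length(classes))
  for (cls in unique(classes)) {
    sel <- classes == cls
    grades[sel] <- sample(GRADES, sum(sel), replace = TRUE,
                          prob = penetrance[[cls]])
  }
  grades
}

# founder F1: one restorer-parent and one maintainer-parent haplotype per pair
make_f1 <- function(genome) {
  chrs <- lapply(genome$chromosomes$length, function(L)
    list(pure_haplotype(L, 1L), pure_haplotype(L, 0L)))
  names(chrs) <- genome$chromosomes$name
  list(pop = "F1", chrs = chrs)
}

.finish_individuals <- function(inds, genome, model, pop) {
  rf4 <- vapply(inds, genotype_at, integer(1),
                chrom = model$rf4_locus$chrom, pos = model$rf4_locus$pos)
  q <- if (is.null(model$q_locus)) rep(0L, length(inds))
       else vapply(inds, genotype_at, integer(1),
                   chrom = model$q_locus$chrom, pos = model$q_locus$pos)
  cls <- genotype_class(rf4, q)
  grades <- draw_grades(cls, model$penetrance)
  Map(function(ind, r, qq, g) {
    ind$pop <- pop; ind$rf4_geno <- r; ind$q_geno <- qq; ind$grade <- g
    ind
  }, inds, rf4, q, grades)
}

#' Simulate an F2 population
#'
#' Selfs the F1 of two fully homozygous parents: every F2 individual carries
#' two independent recombinant F1 gametes per chromosome, so single-locus
#' genotypes segregate 1:2:1. Fertility grades are drawn from the
#' restoration model's penetrance table given the joint genotype at the two
#' restorer loci.
#'
#' @param genome a [genome_model()].
#' @param model a [restoration_model()]; its loci must lie inside the genome.
#' @param n_plants number of F2 individuals (>= 1).
#' @param seed optional seed.
#' @return list of individuals; each has `pop`, `chrs` (per-chromosome
#'   haplotype pairs), `rf4_geno`, `q_geno` and `grade`.
#' @export
#' @examples
#' pop <- simulate_f2(genome_model(), restoration_model(), 50, seed = 1)
#' table(vapply(pop, `[[`, character(1), "grade"))
simulate_f2 <- function(genome, model, n_plants, seed = NULL) {
  if (n_plants < 1) stop("n_plants must be >= 1")
  .check_locus(genome, model$rf4_locus, "rf4_locus")
  .check_locus(genome, model$q_locus, "q_locus")
  .maybe_seed(seed)
  f1 <- make_f1(genome)
  lens <- genome$chromosomes$length
  morg <- chrom_morgans(genome, lens)
  cn <- genome$chromosomes$name
  inds <- vector("list", n_plants)
  for (i in seq_len(n_plants)) {
    chrs <- vector("list", length(cn))
    for (c in seq_along(cn)) {
      pair <- f1$chrs[[c]]
      chrs[[c]] <- list(meiosis(pair[[1]], pair[[2]], lens[c], morg[c]),
                        meiosis(pair[[1]], pair[[2]], lens[c], morg[c]))
    }
    names(chrs) <- cn
    inds[[i]] <- list(chrs = chrs)
  }
  .finish_individuals(inds, genome, model, "F2")
}

#' Simulate a backcross generation
#'
#' Each offspring receives one recombinant gamete from an individual sampled
#' (with replacement) from `parent_pop` and one non-recombinant gamete from
#' the recurrent inbred parent, so single-locus ratios converge to 1:1 when
#' backcrossing the F1.
#'
#' @param parent_pop non-empty list of individuals (e.g. `list(make_f1(g))`
#'   via [simulate_f2()] output, or F1s).
#' @param genome a [genome_model()].
#' @param model a [restoration_model()] used to grade the offspring.
#' @param recurrent `"P2"` (maintainer parent, the usual CMS design) or `"P1"`.
#' @param n_offspring number of offspring.
#' @param seed optional seed.
#' @return list of individuals as in [simulate_f2()], `pop = "BC1"`.
#' @export
simulate_backcross <- function(parent_pop, genome, model,
                               recurrent = c("P2", "P1"),
                               n_offspring, seed = NULL) {
  if (length(parent_pop) == 0L) stop("parent population is empty")
  recurrent <- match.arg(recurrent)
  if (n_offspring < 1) stop("n_offspring must be >= 1")
  .check_locus(genome, model$rf4_locus, "rf4_locus")
  .check_locus(genome, model$q_locus, "q_locus")
  .maybe_seed(seed)
  rec_origin <- if (recurrent == "P1") 1L else 0L
  lens <- genome$chromosomes$length
  morg <- chrom_morgans(genome, lens)
  cn <- genome$chromosomes$name
  pick <- sample.int(length(parent_pop), n_offspring, replace = TRUE)
  inds <- vector("list", n_offspring)
  for (i in seq_len(n_offspring)) {
    par <- parent_pop[[pick[i]]]
    chrs <- vector("list", length(cn))
    for (c in seq_along(cn)) {
      pair <- par$chrs[[cn[c]]]
      chrs[[c]] <- list(meiosis(pair[[1]], pair[[2]], lens[c], morg[c]),
                        pure_haplotype(lens[c], rec_origin))
    }
    names(chrs) <- cn
    inds[[i]] <- list(chrs = chrs)
  }
  .finish_individuals(inds, genome, model, "BC1")
}

# genotype class label at the main restorer locus for bulk selection
rf4_label <- function(ind) c("rf4rf4", "Rf4rf4", "Rf4Rf4")[ind$rf4_geno + 1L]

#' Construct extreme-phenotype bulks
#'
#' Samples the two bulks uniformly without replacement among qualifying
#' individuals (required restorer-locus genotype and fertility grades); the
#' bulks are guaranteed disjoint.
#'
#' @param pop population from [simulate_f2()] / [simulate_backcross()].
#' @param fr_spec,sm_spec [bulk_spec()] rules; defaults reproduce the usual
#'   contrast of 30 fully fertile vs 30 sterile `rf4rf4` plants.
#' @param seed optional seed.
#' @return list with elements `FR` and `SM` (lists of individuals) and
#'   `fr_idx`, `sm_idx` (indices into `pop`).
#' @export
build_bulks <- function(pop,
                        fr_spec = bulk_spec("FR", "rf4rf4", "V", 30),
                        sm_spec = bulk_spec("SM", "rf4rf4", c("I", "II"), 30),
                        seed = NULL) {
  .maybe_seed(seed)
  qualifies <- function(spec, exclude = integer(0)) {
    ok <- vapply(pop, function(ind) {
      (is.na(spec$genotype) || rf4_label(ind) == spec$genotype) &&
        ind$grade %in% spec$grades
    }, logical(1))
    setdiff(which(ok), exclude)
  }
  take <- function(spec, exclude = integer(0)) {
    q <- qualifies(spec, exclude)
    if (length(q) < spec$n)
      stop("bulk '", spec$name, "': only ", length(q),
           " qualifying individuals, ", spec$n, " required")
    sort(sample(q, spec$n))
  }
  fr_idx <- take(fr_spec)
  sm_idx <- take(sm_spec, exclude = fr_idx)
  list(FR = pop[fr_idx], SM = pop[sm_idx], fr_idx = fr_idx, sm_idx = sm_idx)
}

# restorer-allele frequency of a bulk at every informative SNP;
# returns data.frame(chrom, pos, freq)
bulk_allele_freq <- function(bulk, genome) {
  out <- lapply(genome$chromosomes$name, function(ch) {
    pos <- snp_positions(genome, ch)
    cnt <- numeric(length(pos))
    for (ind in bulk) {
      pair <- ind$chrs[[ch]]
      cnt <- cnt + hap_at(pair[[1]], pos) + hap_at(pair[[2]], pos)
    }
    data.frame(chrom = ch, pos = pos, freq = cnt / (2 * length(bulk)))
  })
  do.call(rbind, out)
}

#' Simulate short-read allele depths over a bulked-segregant design
#'
#' For each informative SNP and each bulk, sequencing depth is drawn from
#' the read model and the restorer-allele read count is Binomial(depth, p'),
#' where p' is the bulk's true restorer-allele frequency perturbed by the
#' symmetric sequencing-error rate. Parents are emitted as homozygous
#' opposite calls with their own sampled depths. Sites with zero depth in
#' every sample are dropped (uncovered).
#'
#' @param bulks result of [build_bulks()].
#' @param genome the [genome_model()] the population was simulated on.
#' @param rm a [read_model()].
#' @param seed optional seed.
#' @return a variant table `data.frame` (one row per covered SNP) with
#'   columns `chrom`, `pos`, `restorer_allele`, `other_allele`,
#'   `restorer_is_ref`, per-parent allele depths and per-bulk
#'   restorer/other read counts. Round-trips through [read_variants()].
#' @export
simulate_reads <- function(bulks, genome, rm = read_model(), seed = NULL) {
  if (length(bulks$FR) == 0L || length(bulks$SM) == 0L)
    stop("bulks must be nonempty")
  .maybe_seed(seed)
  fr <- bulk_allele_freq(bulks$FR, genome)
  sm <- bulk_allele_freq(bulks$SM, genome)
  m <- nrow(fr)
  e <- rm$error_rate
  draw_depth <- function(mean) {
    if (rm$depth_dist == "fixed") rep(as.integer(round(mean)), m)
    else rpois(m, mean)
  }
  perturb <- function(p) p * (1 - e) + (1 - p) * e
  fr_d <- draw_depth(rm$bulk_depth)
  sm_d <- draw_depth(rm$bulk_depth)
  p1_d <- draw_depth(rm$parent_depth)
  p2_d <- draw_depth(rm$parent_depth)
  fr_r <- rbinom(m, fr_d, perturb(fr$freq))
  sm_r <- rbinom(m, sm_d, perturb(sm$freq))
  p1_r <- rbinom(m, p1_d, 1 - e) # restorer parent, homozygous restorer allele
  p2_r <- rbinom(m, p2_d, e)     # maintainer parent
  # random allele bases and REF orientation so downstream orientation logic
  # is actually exercised
  bases <- c("A", "C", "G", "T")
  ra <- sample(bases, m, replace = TRUE)
  oa <- vapply(ra, function(b) sample(setdiff(bases, b), 1L), character(1))
  tab <- data.frame(
    chrom = fr$chrom, pos = fr$pos,
    restorer_allele = ra, other_allele = oa,
    restorer_is_ref = sample(c(TRUE, FALSE), m, replace = TRUE),
    p1_restorer = p1_r, p1_other = p1_d - p1_r,
    p2_restorer = p2_r, p2_other = p2_d - p2_r,
    fr_restorer = fr_r, fr_other = fr_d - fr_r,
    sm_restorer = sm_r, sm_other = sm_d - sm_r,
    stringsAsFactors = FALSE
  )
  covered <- (p1_d + p2_d + fr_d + sm_d) > 0
  tab <- tab[covered, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' One-call synthetic bulked-segregant dataset
#'
#' Convenience wrapper chaining [simulate_f2()], [build_bulks()] and
#' [simulate_reads()]. All stochastic stages draw from named substreams of
#' the single master seed (see [derive_seed()]), so each stage is
#' independently reproducible.
#'
#' @param genome,model,rm see the individual stages.
#' @param n_plants F2 population size.
#' @param fr_spec,sm_spec bulk rules.
#' @param seed master seed.
#' @return list with `variants` (the table from [simulate_reads()]), `pop`,
#'   and `bulks`.
#' @export
#' @examples
#' g <- genome_model(data.frame(name = "chr1", length = 2e6))
#' d <- simulate_bsa_dataset(g, restoration_model(rf4_locus =
#'        list(chrom = "chr1", pos = 5e5), q_locus = NULL),
#'        n_plants = 200, seed = 1)
#' head(d$variants)
simulate_bsa_dataset <- function(genome = genome_model(),
                                 model = restoration_model(),
                                 rm = read_model(),
                                 n_plants = 1000,
                                 fr_spec = bulk_spec("FR", "rf4rf4", "V", 30),
                                 sm_spec = bulk_spec("SM", "rf4rf4", c("I", "II"), 30),
                                 seed = NULL) {
  pop <- simulate_f2(genome, model, n_plants,
                     seed = if (is.null(seed)) NULL else derive_seed(seed, "cross"))
  bulks <- build_bulks(pop, fr_spec, sm_spec,
                       seed = if (is.null(seed)) NULL else derive_seed(seed, "bulks"))
  variants <- simulate_reads(bulks, genome, rm,
                             seed = if (is.null(seed)) NULL else derive_seed(seed, "reads"))
  list(variants = variants, pop = pop, bulks = bulks)
}
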