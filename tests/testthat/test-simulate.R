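test_that("F2 single-locus genotypes segregate 1:2:1 and a dominant restorer gives 3:1", {
  g <- tiny_genome(len = 50e6)
  m <- dominant_model(pos = 25e6)
  pop <- simulate_f2(g, m, 20000, seed = 101)
  geno <- vapply(pop, `[[`, integer(1), "rf4_geno")
  counts <- tabulate(geno + 1L, nbins = 3L) # rf4rf4, Rf4rf4, Rf4Rf4
  fit <- gof_chisq(counts, c(1, 2, 1))
  expect_gt(fit$p.value, 1e-4)
  # dominant fully penetrant single gene: sterile fraction 1/4
  se <- sqrt(0.25 * 0.75 / 20000)
  expect_lt(abs(sterile_frac(pop) - 0.25), 4 * se)
})

test_that("two independent dominant restorers leave 1/16 sterile in F2", {
  # oracle: enumerate the 9 joint genotype classes of two unlinked loci
  pr <- c(1, 2, 1) / 4
  joint <- outer(pr, pr)
  sterile_classes <- outer(0:2 == 0, 0:2 == 0) # rf4rf4 AND qq
  expected <- sum(joint[sterile_classes])
  expect_equal(expected, 1 / 16)

  g <- tiny_genome(nchrom = 2, len = 50e6)
  m <- two_gene_model(rf4 = list(chrom = "chr1", pos = 25e6),
                      q = list(chrom = "chr2", pos = 25e6))
  pop <- simulate_f2(g, m, 20000, seed = 202)
  se <- sqrt(expected * (1 - expected) / 20000)
  expect_lt(abs(sterile_frac(pop) - expected), 4 * se)
})

test_that("backcross offspring segregate 1:1 and dominant models give the enumerated fractions", {
  g <- tiny_genome(len = 50e6)
  m <- dominant_model(pos = 25e6)
  bc <- simulate_backcross(list(bsaqtl:::make_f1(g)), g, m,
                           recurrent = "P2", n_offspring = 20000, seed = 303)
  geno <- vapply(bc, `[[`, integer(1), "rf4_geno")
  expect_true(all(geno %in% 0:1)) # recurrent parent contributes rf4 only
  se <- sqrt(0.25 / 20000)
  expect_lt(abs(mean(geno) - 0.5), 4 * se)
  # dominant fully penetrant single gene: half the BC1 is fertile
  expect_lt(abs(sterile_frac(bc) - 0.5), 4 * se)

  # second dominant restorer, full penetrance: sterile = P(rf4rf4) * P(qq) = 1/4
  g2 <- tiny_genome(nchrom = 2, len = 50e6)
  m2 <- two_gene_model(rf4 = list(chrom = "chr1", pos = 25e6),
                       q = list(chrom = "chr2", pos = 25e6))
  bc2 <- simulate_backcross(list(bsaqtl:::make_f1(g2)), g2, m2,
                            recurrent = "P2", n_offspring = 20000, seed = 304)
  expect_lt(abs(sterile_frac(bc2) - 0.25), 4 * se)
})

test_that("degenerate simulator inputs error", {
  g <- tiny_genome()
  m <- dominant_model(pos = 1e6)
  expect_error(simulate_f2(g, m, 0), "n_plants")
  expect_error(simulate_backcross(list(), g, m, n_offspring = 10), "empty")
  bad <- restoration_model(rf4_locus = list(chrom = "chr9", pos = 1e6),
                           q_locus = NULL,
                           penetrance = dominant_model()$penetrance)
  expect_error(simulate_f2(g, bad, 5), "unknown chromosome")
  bad2 <- restoration_model(rf4_locus = list(chrom = "chr1", pos = 99e6),
                            q_locus = NULL,
                            penetrance = dominant_model()$penetrance)
  expect_error(simulate_f2(g, bad2, 5), "outside")
})

test_that("bulks are disjoint, satisfy their rules, and shortfalls name the bulk", {
  g <- tiny_genome(nchrom = 2, len = 20e6)
  m <- restoration_model(rf4_locus = list(chrom = "chr1", pos = 5e6),
                         q_locus = list(chrom = "chr2", pos = 15e6))
  pop <- simulate_f2(g, m, 800, seed = 11)
  b <- build_bulks(pop, seed = 12)
  expect_length(intersect(b$fr_idx, b$sm_idx), 0)
  expect_length(b$fr_idx, 30)
  for (ind in b$FR) {
    expect_identical(bsaqtl:::rf4_label(ind), "rf4rf4")
    expect_identical(ind$grade, "V")
  }
  for (ind in b$SM) {
    expect_identical(bsaqtl:::rf4_label(ind), "rf4rf4")
    expect_true(ind$grade %in% c("I", "II"))
  }
  expect_error(
    build_bulks(pop, sm_spec = bulk_spec("SM", "rf4rf4", c("I", "II"), 5000)),
    "bulk 'SM'")
})

test_that("identical seeds give byte-identical variant tables", {
  g <- tiny_genome(nchrom = 2, len = 5e6)
  m <- restoration_model(rf4_locus = list(chrom = "chr1", pos = 1e6),
                         q_locus = list(chrom = "chr2", pos = 4e6))
  d1 <- simulate_bsa_dataset(g, m, n_plants = 800, seed = 42)
  d2 <- simulate_bsa_dataset(g, m, n_plants = 800, seed = 42)
  expect_identical(d1$variants, d2$variants)
  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".tsv")
  write_variants_tsv(d1$variants, f1, seed = 42)
  write_variants_tsv(d2$variants, f2, seed = 42)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  d3 <- simulate_bsa_dataset(g, m, n_plants = 800, seed = 43)
  expect_false(identical(d1$variants, d3$variants))
})

test_that("a bulk fixed for the restorer allele yields SNP-index 1 everywhere (zero error)", {
  g <- tiny_genome(len = 1e6, spacing = 1e5)
  pure <- function(origin) {
    list(chrs = list(chr1 = list(bsaqtl:::pure_haplotype(1e6, origin),
                                 bsaqtl:::pure_haplotype(1e6, origin))),
         grade = if (origin == 1L) "V" else "I", pop = "F2",
         rf4_geno = 2L * origin, q_geno = 0L)
  }
  bulks <- list(FR = replicate(5, pure(1L), simplify = FALSE),
                SM = replicate(5, pure(0L), simplify = FALSE))
  tab <- simulate_reads(bulks, g, read_model(error_rate = 0), seed = 5)
  rec <- compute_snp_index(tab)
  covered <- rec$fr_depth > 0
  expect_true(all(rec$fr_index[covered] == 1))
  expect_true(all(rec$sm_index[rec$sm_depth > 0] == 0))
})

test_that("zero mean depth leaves every site uncovered", {
  g <- tiny_genome(len = 1e6, spacing = 1e5)
  m <- dominant_model(pos = 5e5)
  pop <- simulate_f2(g, m, 100, seed = 9)
  b <- build_bulks(pop, fr_spec = bulk_spec("FR", "Rf4Rf4", "V", 5),
                   sm_spec = bulk_spec("SM", "rf4rf4", c("I", "II"), 5),
                   seed = 9)
  tab <- simulate_reads(b, g, read_model(parent_depth = 0, bulk_depth = 0),
                        seed = 9)
  expect_identical(nrow(tab), 0L)
})

test_that("unlinked SNP-index averages 0.5 in both bulks (allele-frequency conservation)", {
  # null genome: restorer loci on their own chromosome, scan chromosome unlinked
  g <- genome_model(data.frame(name = c("chrQ1", "chrQ2", "chrN"),
                               length = c(10e6, 10e6, 120e6)),
                    snp_spacing = 1e4)
  m <- restoration_model(rf4_locus = list(chrom = "chrQ1", pos = 2e6),
                         q_locus = list(chrom = "chrQ2", pos = 8e6))
  d <- simulate_bsa_dataset(g, m, n_plants = 600,
                            rm = read_model(error_rate = 0), seed = 77)
  rec <- compute_snp_index(d$variants)
  rec <- rec[rec$chrom == "chrN" & rec$fr_depth > 0 & rec$sm_depth > 0, ]
  expect_gt(nrow(rec), 1e4)
  # SNPs on one chromosome are correlated through shared bulk haplotypes;
  # bound the standard error by the ~ 2 * n_bulk independent lineages
  se <- sqrt(0.25 / (4 * 30))
  expect_lt(abs(mean(rec$fr_index) - 0.5), 3 * se)
  expect_lt(abs(mean(rec$sm_index) - 0.5), 3 * se)
  expect_lt(abs(mean(rec$delta)), 3 * sqrt(2) * se)
})

test_that("delta(SNP-index) peaks at the causal locus and decays with distance", {
  g <- genome_model(data.frame(name = "chr1", length = 150e6), snp_spacing = 1e4)
  m <- restoration_model(rf4_locus = list(chrom = "chr1", pos = 25e6),
                         q_locus = list(chrom = "chr1", pos = 100e6))
  d <- simulate_bsa_dataset(g, m, n_plants = 1000,
                            rm = read_model(bulk_depth = 60), seed = 31)
  # true within-bulk allele frequencies, no read noise
  fr <- bsaqtl:::bulk_allele_freq(d$bulks$FR, g)
  sm <- bsaqtl:::bulk_allele_freq(d$bulks$SM, g)
  dl <- fr$freq - sm$freq
  at <- function(p) dl[fr$pos == p]
  expect_gt(at(100e6), at(60e6))
  expect_gt(at(100e6), at(140e6))
  expect_gt(at(100e6), 0.4)
})
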