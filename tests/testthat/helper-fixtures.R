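# small genomes and hand-built site tables shared across test files

tiny_genome <- function(nchrom = 1, len = 2e6, spacing = 1e4) {
  genome_model(data.frame(name = paste0("chr", seq_len(nchrom)),
                          length = rep(len, nchrom)),
               snp_spacing = spacing)
}

# single fully dominant restorer, fully penetrant (3:1 in F2)
dominant_model <- function(chrom = "chr1", pos = 1e6) {
  restoration_model(
    rf4_locus = list(chrom = chrom, pos = pos), q_locus = NULL,
    penetrance = list("Rf4_" = c(0, 0, 0, 0, 1),
                      "rf4rf4.qq" = c(0.5, 0.5, 0, 0, 0)))
}

# two independent fully dominant, fully penetrant restorers
two_gene_model <- function(rf4 = list(chrom = "chr1", pos = 1e6),
                           q = list(chrom = "chr2", pos = 1e6)) {
  restoration_model(
    rf4_locus = rf4, q_locus = q,
    penetrance = list("Rf4_" = c(0, 0, 0, 0, 1),
                      "rf4rf4.qq" = c(0.5, 0.5, 0, 0, 0),
                      "rf4rf4.Qq" = c(0, 0, 0, 0, 1),
                      "rf4rf4.QQ" = c(0, 0, 0, 0, 1)))
}

grade_of <- function(pop) vapply(pop, `[[`, character(1), "grade")
sterile_frac <- function(pop) mean(grade_of(pop) %in% c("I", "II"))

# canonical site table built directly from per-bulk counts
mk_sites <- function(pos, fr_r, fr_o, sm_r, sm_o, chrom = "chr1",
                     p1 = 10, p2 = 10) {
  data.frame(chrom = chrom, pos = pos,
             restorer_allele = "A", other_allele = "G",
             p1_depth = p1, p2_depth = p2,
             fr_restorer = fr_r, fr_other = fr_o,
             sm_restorer = sm_r, sm_other = sm_o,
             stringsAsFactors = FALSE)
}
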