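#' Default run configuration
#'
#' Flat named list of every tunable of the pipeline with its standard
#' QTL-seq default: parental depth > 5, locus filters depth < 7 and
#' SNP-index outside (0.3, 0.7) in both bulks, 5-Mb windows advanced by
#' 10 kb, bulks of 30, bands at the 95% and 99% levels from 10,000
#' Monte-Carlo replicates per depth, and the scaled simulator defaults
#' (2 x 150 Mb genome, SNP every 10 kb, 10x parents / 30x bulks).
#'
#' @return named list.
#' @export
default_config <- function() {
  list(
    # variant selection / locus filters
    min_parent_depth = 5, min_depth = 7,
    index_low = 0.3, index_high = 0.7,
    # windows and bands
    window = 5e6, step = 1e4,
    bulk_size = 30, population = "F2",
    levels = c(0.95, 0.99), ci_reps = 10000,
    depth_rule = "min", call_level = 0.95, tail = "upper",
    min_span = 1e6, max_gap = 1e4,
    # simulator
    n_plants = 1000, snp_spacing = 1e4, cm_per_mb = 1,
    chromosomes = list(chr1 = 150e6, chr2 = 150e6),
    rf4_chrom = "chr1", rf4_pos = 25e6,
    q_chrom = "chr1", q_pos = 130e6,
    q_penetrance = 0.8,
    parent_depth = 10, bulk_depth = 30, error_rate = 0.001,
    fr_size = 30, sm_size = 30,
    seed = 1
  )
}

#' Load a run configuration from YAML
#'
#' Reads a flat-key YAML file and merges it over [default_config()];
#' unknown keys are rejected so typos fail loudly. The merged
#' configuration round-trips through [save_config()].
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @param overrides named list applied after the file.
#' @return named list.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  apply_over <- function(cfg, new, src) {
    unknown <- setdiff(names(new), names(cfg))
    if (length(unknown))
      stop("unknown configuration key(s) in ", src, ": ",
           paste(unknown, collapse = ", "))
    modifyList(cfg, new)
  }
  if (!is.null(path)) {
    if (!file.exists(path)) stop("no such config file: ", path)
    cfg <- apply_over(cfg, yaml::read_yaml(path), path)
  }
  if (length(overrides)) cfg <- apply_over(cfg, overrides, "overrides")
  cfg
}

#' Save a run configuration as YAML
#'
#' @param cfg named list as from [load_config()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

# build the simulator objects described by a configuration
config_simulator <- function(cfg) {
  genome <- genome_model(
    chromosomes = data.frame(name = names(cfg$chromosomes),
                             length = unlist(cfg$chromosomes, use.names = FALSE)),
    snp_spacing = cfg$snp_spacing, cm_per_mb = cfg$cm_per_mb)
  model <- restoration_model(
    rf4_locus = list(chrom = cfg$rf4_chrom, pos = cfg$rf4_pos),
    q_locus = if (is.null(cfg$q_chrom)) NULL
              else list(chrom = cfg$q_chrom, pos = cfg$q_pos),
    penetrance = default_penetrance(cfg$q_penetrance))
  rm <- read_model(parent_depth = cfg$parent_depth,
                   bulk_depth = cfg$bulk_depth,
                   error_rate = cfg$error_rate)
  list(genome = genome, model = model, read_model = rm)
}
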