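#' Simulation configuration
#'
#' Builds the configuration object consumed by every generator in the
#' synthetic-data module. Defaults encode the study conditions of the
#' fine-mapping workflow: a case-control cohort of 465 cases and 5,200
#' controls carrying an 8-SNP high-LD risk haplotype at odds ratio 2.4 and
#' MAF 0.33; three ChIP-seq replicates of mean depth 150 with a planted
#' 1.7 non-risk:risk allelic read ratio; a 5 kb-binned contact matrix with a
#' distance-decaying background and a planted 2.7-fold loop; and a cohort of
#' 45 tumours, 65% trisomic for the locus chromosome, with a negative
#' expression effect per risk allele and a 21/31 probability that the risk
#' homologue is the duplicated one.
#'
#' @param seed integer seed from which every generator draws.
#' @param n_cases,n_controls cohort sizes for the case-control simulator.
#' @param haplotype_maf risk-haplotype frequency in (0,1).
#' @param odds_ratio per-allele odds ratio of the planted risk SNP (> 0).
#' @param n_haplotype_snps number of SNPs on the risk haplotype.
#' @param n_background unlinked background variants per simulated locus.
#' @param decoupling per-SNP probability that a haplotype SNP is redrawn
#'   independently of the founder allele; controls pairwise r-squared
#'   (approximately \code{(1 - decoupling)^4} between two non-lead SNPs).
#' @param read_depth mean reads per ChIP-seq replicate (Poisson mean).
#' @param allelic_ratio non-risk:risk read ratio planted at the test SNP.
#' @param n_replicates number of ChIP-seq replicates.
#' @param read_length read length in bp (>= 1).
#' @param error_rate flat per-base sequencing error probability.
#' @param n_bins number of contact-matrix bins (>= 3).
#' @param bin_size bin size in bp.
#' @param decay_exponent power-law decay exponent of expected contacts.
#' @param loop_fold fold enrichment planted at the loop anchor pair.
#' @param contact_scale expected count at bin distance 1; the default
#'   (NULL) keeps the mean count of every distance stratum at or above 50.
#' @param anchor_bin,target_bin 0-based bins of the planted loop; by
#'   default placed near the matrix centre 12 bins apart (60 kb at 5 kb
#'   resolution, the anchor-to-promoter separation emulated here).
#' @param n_tumours tumour cohort size.
#' @param trisomy_fraction probability a tumour is trisomic for the locus
#'   chromosome.
#' @param eqtl_effect log2-expression shift per risk allele (negative for a
#'   risk allele that lowers expression).
#' @param expr_baseline,expr_sd baseline log2 expression and residual SD.
#' @param baf_sd SD of the truncated-Gaussian B-allele-frequency noise.
#' @param duplication_bias probability that a heterozygous trisomic tumour
#'   duplicated the risk homologue.
#' @param locus_chrom,locus_offset chromosome name and bp offset of the
#'   simulated locus.
#' @return A validated list of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1L,
                       n_cases = 465L, n_controls = 5200L,
                       haplotype_maf = 0.33, odds_ratio = 2.4,
                       n_haplotype_snps = 8L, n_background = 50L,
                       decoupling = 0.01,
                       read_depth = 150, allelic_ratio = 1.7,
                       n_replicates = 3L, read_length = 36L,
                       error_rate = 0,
                       n_bins = 800L, bin_size = 5000L,
                       decay_exponent = 1, loop_fold = 2.7,
                       contact_scale = NULL,
                       anchor_bin = NULL, target_bin = NULL,
                       n_tumours = 45L, trisomy_fraction = 0.65,
                       eqtl_effect = -0.6, expr_baseline = 5,
                       expr_sd = 0.35, baf_sd = 0.04,
                       duplication_bias = 21 / 31,
                       locus_chrom = "chr10",
                       locus_offset = 63000000L) {
  n_bins <- as.integer(n_bins)
  if (is.null(contact_scale)) {
    # keep the sparsest distance stratum at a mean of >= 50 counts per pair
    contact_scale <- 50 * max(1L, n_bins - 1L)^decay_exponent
  }
  if (is.null(anchor_bin)) {
    # loop anchors near the matrix centre, 12 bins (60 kb at 5 kb bins)
    # apart: the anchor-to-promoter separation the workflow emulates
    anchor_bin <- max(0L, n_bins %/% 2L - 6L)
  }
  if (is.null(target_bin)) {
    target_bin <- min(n_bins - 1L, as.integer(anchor_bin) + 12L)
    if (target_bin == anchor_bin) anchor_bin <- max(0L, target_bin - 1L)
  }
  cfg <- list(
    seed = as.integer(seed),
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    haplotype_maf = haplotype_maf, odds_ratio = odds_ratio,
    n_haplotype_snps = as.integer(n_haplotype_snps),
    n_background = as.integer(n_background), decoupling = decoupling,
    read_depth = read_depth, allelic_ratio = allelic_ratio,
    n_replicates = as.integer(n_replicates),
    read_length = as.integer(read_length), error_rate = error_rate,
    n_bins = as.integer(n_bins), bin_size = as.integer(bin_size),
    decay_exponent = decay_exponent, loop_fold = loop_fold,
    contact_scale = contact_scale,
    anchor_bin = as.integer(anchor_bin), target_bin = as.integer(target_bin),
    n_tumours = as.integer(n_tumours), trisomy_fraction = trisomy_fraction,
    eqtl_effect = eqtl_effect, expr_baseline = expr_baseline,
    expr_sd = expr_sd, baf_sd = baf_sd,
    duplication_bias = duplication_bias,
    locus_chrom = locus_chrom, locus_offset = as.integer(locus_offset)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stop_cfg <- function(msg) {
    stop(errorCondition(msg, class = c("regulomap_config_error", "error")))
  }
  counts <- c("n_cases", "n_controls", "n_haplotype_snps", "n_replicates",
              "n_bins", "n_tumours", "read_length", "bin_size")
  for (f in counts) {
    if (!is.finite(cfg[[f]]) || cfg[[f]] < 1) {
      stop_cfg(sprintf("'%s' must be a positive count", f))
    }
  }
  if (cfg$n_bins < 3) stop_cfg("'n_bins' must be at least 3")
  if (!is.finite(cfg$odds_ratio) || cfg$odds_ratio <= 0) {
    stop_cfg("'odds_ratio' must be positive")
  }
  if (cfg$haplotype_maf <= 0 || cfg$haplotype_maf >= 1) {
    stop_cfg("'haplotype_maf' must lie in (0, 1)")
  }
  for (f in c("trisomy_fraction", "duplication_bias", "decoupling",
              "error_rate")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) {
      stop_cfg(sprintf("'%s' must lie in [0, 1]", f))
    }
  }
  if (cfg$read_depth <= 0) stop_cfg("'read_depth' must be positive")
  if (cfg$allelic_ratio <= 0) stop_cfg("'allelic_ratio' must be positive")
  if (cfg$decay_exponent <= 0) stop_cfg("'decay_exponent' must be positive")
  if (cfg$loop_fold <= 0) stop_cfg("'loop_fold' must be positive")
  if (cfg$anchor_bin == cfg$target_bin) {
    stop_cfg("loop anchors must be distinct bins")
  }
  if (cfg$anchor_bin < 0 || cfg$anchor_bin >= cfg$n_bins ||
      cfg$target_bin < 0 || cfg$target_bin >= cfg$n_bins) {
    stop_cfg("loop anchors must be valid 0-based bins")
  }
  invisible(cfg)
}

#' Read a pipeline configuration file
#'
#' A single YAML (or JSON) document with a versioned \code{schema} key holds
#' all thresholds, paths and the master seed. Unknown keys are rejected so
#' typos cannot silently change an analysis.
#'
#' @param path path to the YAML/JSON configuration file.
#' @return A named list of class \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    stop(errorCondition(sprintf("config file not found: %s", path),
                        class = c("regulomap_config_error", "error")))
  }
  raw <- yaml::read_yaml(path)
  as_pipeline_config(raw)
}

#' Build a pipeline configuration in code
#'
#' @param ... overrides of the default thresholds and simulation settings.
#' @return A named list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(...) {
  as_pipeline_config(utils::modifyList(default_pipeline_config(),
                                       list(...)))
}

default_pipeline_config <- function() {
  list(
    schema = 1L,
    seed = 1L,
    out_dir = "results",
    sim = list(),
    info_min = 0.80, maf_min = 0.01, p_max = 1e-10, or_min = 1.5,
    alpha = 0.001, control_alpha = 0.05,
    baf_tol = 0.08,
    kr_tol = 1e-8, kr_max_iter = 1000L, sparse_frac = 0.05
  )
}

as_pipeline_config <- function(raw) {
  defaults <- default_pipeline_config()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown) > 0) {
    stop(errorCondition(
      sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
      class = c("regulomap_config_error", "error")))
  }
  cfg <- utils::modifyList(defaults, raw)
  if (!identical(as.integer(cfg$schema), 1L)) {
    stop(errorCondition("unsupported config schema version",
                        class = c("regulomap_config_error", "error")))
  }
  sim_args <- cfg$sim
  sim_args$seed <- cfg$seed
  cfg$sim <- do.call(sim_config, sim_args)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write a pipeline configuration to YAML
#'
#' Round-trips losslessly through [read_pipeline_config()].
#'
#' @param cfg a \code{pipeline_config}.
#' @param path output path.
#' @export
write_pipeline_config <- function(cfg, path) {
  out <- unclass(cfg)
  out$sim <- out$sim[setdiff(names(out$sim), "seed")]
  out$sim <- unclass(out$sim)
  yaml::write_yaml(out, path)
  invisible(path)
}
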