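#' Run the full synthetic-data fine-mapping pipeline
#'
#' Executes, end to end and from a single seeded configuration: data
#' simulation; per-SNP additive logistic association and fixed-effects
#' inverse-variance meta-analysis of two half-cohorts; risk-haplotype
#' filtering on INFO/MAF/P/OR; regulatory-annotation prioritisation;
#' allele-specific binding testing with whole-genome-sequencing control;
#' Knight-Ruiz balancing and observed/expected loop enrichment with the
#' TAD-contained anchor profile; trisomy-restricted eQTL ANOVA;
#' duplicated-homologue classification and the preferential-retention
#' test; and cross-cohort Spearman correlation with weighted Fisher
#' combination. Per-stage tables are written as TSV, headline numbers into
#' a single JSON report, and a MANIFEST records which stages completed.
#' Every threshold actually applied is logged.
#'
#' @param config a \code{pipeline_config} (see [pipeline_config()] /
#'   [read_pipeline_config()]).
#' @param out_dir output directory (created if absent); overrides
#'   \code{config$out_dir}.
#' @param quiet suppress progress logging.
#' @return the report, invisibly (a named list mirroring report.json).
#' @export
run_full_pipeline <- function(config = pipeline_config(),
                              out_dir = config$out_dir, quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline.log")
  log_lines <- character()
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    if (!quiet) message(line)
  }
  manifest <- character()
  done <- function(stage) {
    manifest <<- c(manifest, sprintf("%s\tcomplete", stage))
    writeLines(manifest, file.path(out_dir, "MANIFEST"))
  }
  on.exit(writeLines(log_lines, log_path), add = TRUE)
  report <- list(seed = config$seed)
  sim <- config$sim

  say("seed=%d out_dir=%s", config$seed, out_dir)
  say("thresholds: info_min=%g maf_min=%g p_max=%g or_min=%g alpha=%g control_alpha=%g baf_tol=%g kr_tol=%g sparse_frac=%g",
      config$info_min, config$maf_min, config$p_max, config$or_min,
      config$alpha, config$control_alpha, config$baf_tol, config$kr_tol,
      config$sparse_frac)

  ## -- simulate ----------------------------------------------------------
  cc <- simulate_case_control(sim)
  chip_cfg <- sim
  chip <- simulate_chipseq_replicates(chip_cfg)
  wgs_cfg <- sim
  wgs_cfg$seed <- sim$seed + 1000L
  wgs <- simulate_chipseq_replicates(wgs_cfg, variant = chip$variant,
                                     allelic_ratio = 1)
  hic <- simulate_contact_matrix(sim)
  cohort <- simulate_trisomic_cohort(sim)
  write_truth(list(case_control = unclass(cc$truth),
                   chipseq = unclass(chip$truth),
                   contacts = unclass(hic$truth),
                   cohort = unclass(cohort$truth)),
              file.path(out_dir, "truth.json"))
  write_vcf(cc$variants, file.path(out_dir, "variants.vcf"))
  write_tsv(cohort$samples, file.path(out_dir, "cohort.tsv"))
  write_contact_matrix(hic$matrix, file.path(out_dir, "contacts.tsv"))
  say("simulated %d samples x %d variants; %d ChIP replicates; %dx%d contact matrix; %d tumours",
      nrow(cc$genotypes$dosages), ncol(cc$genotypes$dosages),
      length(chip$replicates), sim$n_bins, sim$n_bins, sim$n_tumours)
  done("simulate")

  ## -- association + meta of two half-cohorts ----------------------------
  assoc <- assoc_scan(cc$genotypes)
  write_tsv(assoc, file.path(out_dir, "association.tsv"))
  halves <- split_cohort(cc$genotypes)
  lead <- cc$truth$lead_snp
  half_fits <- lapply(halves, fit_additive_logistic, variant_id = lead)
  meta <- inverse_variance_meta(half_fits)
  write_tsv(meta, file.path(out_dir, "meta_lead.tsv"))
  say("association: lead SNP %s OR=%.3f p=%.3g; meta of 2 half-cohorts OR=%.3f",
      lead, assoc$or_[assoc$id == lead], assoc$p[assoc$id == lead],
      meta$or_)
  done("assoc_meta")

  ## -- filter + annotate -------------------------------------------------
  filtered <- filter_variants(cc$variants, assoc,
                              info_min = config$info_min,
                              maf_min = config$maf_min,
                              p_max = config$p_max,
                              or_min = config$or_min)
  say("filter(info>=%g, maf>%g, p<%g, or>%g): %d of %d variants survive",
      config$info_min, config$maf_min, config$p_max, config$or_min,
      nrow(filtered), nrow(cc$variants))
  tracks <- default_track_set(cc$variants, cc$truth$haplotype_snps,
                              seed = config$seed)
  annotated <- annotate_regulatory_overlap(
    if (nrow(filtered) > 0) filtered else cc$variants, tracks)
  write_tsv(annotated, file.path(out_dir, "annotated.tsv"))
  done("finemap_annotate")

  ## -- allele-specific binding -------------------------------------------
  asb <- asb_pipeline(chip$replicates, chip$variant,
                      wgs_alignments = wgs$replicates[[1]],
                      alpha = config$alpha,
                      control_alpha = config$control_alpha,
                      contigs = chip$contigs)
  write_tsv(data.frame(variant = asb$variant_id,
                       combined_p = asb$combined_p, fold = asb$fold,
                       favoured = asb$favoured_allele,
                       control_p = asb$control_p, verdict = asb$verdict),
            file.path(out_dir, "asb.tsv"))
  say("ASB: fold=%.2f combined_p=%.3g control_p=%.3g verdict=%s",
      asb$fold, asb$combined_p, asb$control_p, asb$verdict)
  done("asb")

  ## -- contact enrichment ------------------------------------------------
  bal <- kr_balance(hic$matrix, tol = config$kr_tol,
                    max_iter = config$kr_max_iter,
                    sparse_frac = config$sparse_frac)
  tads <- single_tad(hic$matrix)
  prof <- anchor_profile(bal, hic$truth$anchor_bin, tads,
                         check_target = hic$truth$target_bin)
  write_tsv(prof, file.path(out_dir, "contact_profile.tsv"))
  loop <- observed_expected_fold(bal, hic$truth$anchor_bin,
                                 hic$truth$target_bin)
  say("contacts: loop O/E fold=%.2f; planted partner ranks first: %s",
      loop$fold, attr(prof, "target_is_top"))
  done("contacts")

  ## -- eQTL + retention --------------------------------------------------
  eqtl <- eqtl_anova(cohort$samples, restrict_copy_number = 3)
  # on a trisomy, genotype 1 or 2 risk copies implies heterozygosity
  het_tri <- cohort$samples$chr_copy_number == 3 &
    cohort$samples$genotype %in% c(1, 2)
  calls <- classify_duplicated_allele(cohort$samples$baf[het_tri],
                                      baf_tol = config$baf_tol)
  retention <- retention_test(calls, risk_allele = "B")
  write_tsv(data.frame(
    group = eqtl$group_levels, n = eqtl$group_sizes,
    mean_expression = eqtl$group_means),
    file.path(out_dir, "eqtl_groups.tsv"))
  say("eQTL (trisomic n=%d): F=%.2f p=%.3g; retention %d:%d (amb %d) one-sided p=%.4f",
      eqtl$n, eqtl$F, eqtl$p, retention$n_risk_duplicated,
      retention$n_nonrisk_duplicated, retention$n_ambiguous, retention$p)
  done("eqtl_retention")

  ## -- cross-cohort correlation ------------------------------------------
  cohorts <- simulate_correlated_cohorts(c(154, 92, 139), rho = 0.3,
                                         seed = config$seed)
  cors <- lapply(seq_along(cohorts), function(i) {
    spearman_correlation(cohorts[[i]]$x, cohorts[[i]]$y,
                         cohort_id = sprintf("cohort%d", i),
                         alternative = "greater")
  })
  comb_p <- combine_cohort_correlations(cors)
  write_tsv(data.frame(
    cohort = vapply(cors, function(r) r$cohort_id, ""),
    n = vapply(cors, function(r) r$n, 0),
    rho = vapply(cors, function(r) r$rho, 0),
    p = vapply(cors, function(r) r$p, 0)),
    file.path(out_dir, "correlations.tsv"))
  say("correlation: combined weighted-Fisher p=%.3g", comb_p)
  done("correlate")

  ## -- report ------------------------------------------------------------
  report <- c(report, list(
    lead_snp = lead,
    lead_or = assoc$or_[assoc$id == lead],
    lead_p = assoc$p[assoc$id == lead],
    meta_or = meta$or_,
    n_filtered = nrow(filtered),
    top_ranked_snp = annotated$id[1],
    asb_verdict = asb$verdict,
    asb_fold = asb$fold,
    asb_combined_p = asb$combined_p,
    loop_fold = loop$fold,
    top_contact_is_planted = isTRUE(attr(prof, "target_is_top")),
    eqtl_p = eqtl$p,
    eqtl_group_means = eqtl$group_means,
    retention_counts = c(retention$n_risk_duplicated,
                         retention$n_nonrisk_duplicated),
    retention_p = retention$p,
    correlation_combined_p = comb_p
  ))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  done("report")
  invisible(report)
}

# deterministic split of a cohort into two studies (cases and controls
# alternating) for the meta-analysis stage
split_cohort <- function(genotypes) {
  n <- nrow(genotypes$dosages)
  first <- seq_len(n) %% 2 == 1
  lapply(list(first, !first), function(sel) {
    new_genotype_matrix(genotypes$dosages[sel, , drop = FALSE],
                        genotypes$phenotype[sel])
  })
}

# six regulatory tracks (enhancer histone marks, DNase, TF, conservation)
# constructed so the first two haplotype SNPs overlap five tracks each,
# remaining haplotype SNPs at most three
default_track_set <- function(variants, haplotype_snps, seed = 1L) {
  set.seed(seed + 17L)
  names6 <- c("H3K27ac", "H3K4me1", "H3K4me3", "DNase", "TFpeaks",
              "conservation")
  focal <- variants[variants$id %in% haplotype_snps[1:2], , drop = FALSE]
  rest <- variants[variants$id %in% haplotype_snps[-(1:2)], , drop = FALSE]
  tracks <- list()
  for (i in seq_along(names6)) {
    iv <- data.frame(chrom = focal$chrom, start = focal$pos - 50,
                     end = focal$pos + 50)
    if (i <= 3 && nrow(rest) > 0) {
      iv <- rbind(iv, data.frame(chrom = rest$chrom,
                                 start = rest$pos - 50,
                                 end = rest$pos + 50))
    }
    if (i == 6) iv <- iv[seq_len(min(1, nrow(iv))), , drop = FALSE]
    tracks[[names6[i]]] <- GenomicRanges::GRanges(
      iv$chrom, IRanges::IRanges(iv$start, iv$end))
  }
  tracks
}

# a single TAD of ~1 Mb (200 bins at 5 kb) centred on the matrix,
# containing both loop anchors; TADs are interior domains, so matrix edge
# bins never enter an anchor profile
single_tad <- function(cm, n_tad_bins = 200L) {
  n <- nrow(cm$counts)
  half <- min(n, n_tad_bins) %/% 2L
  lo <- max(0L, n %/% 2L - half)
  hi <- min(n, lo + min(n, n_tad_bins))
  GenomicRanges::GRanges(
    cm$chrom,
    IRanges::IRanges(cm$offset + lo * cm$bin_size + 1L,
                     cm$offset + hi * cm$bin_size))
}
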