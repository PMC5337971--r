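#!/usr/bin/env Rscript

# Stage 2 -- per-SNP additive logistic association, inverse-variance
# meta-analysis of two half-cohorts, LD to the lead SNP, threshold
# filtering (INFO/MAF/P/OR) and regulatory-annotation prioritisation.
# Reads the VCF written by stage 1; writes association, LD and annotation
# tables.

suppressMessages(library(regulomap))

sim_dir <- "results/sim"
out <- "results/association"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

vcf <- read_vcf(file.path(sim_dir, "variants.vcf"))
pheno <- read_tsv(file.path(sim_dir, "phenotypes.tsv"))
gm <- structure(list(samples = pheno$sample, phenotype = pheno$phenotype,
                     dosages = vcf$dosages), class = "genotype_matrix")
truth <- read_truth(file.path(sim_dir, "truth.json"))
lead <- truth$case_control$lead_snp

assoc <- assoc_scan(gm)
write_tsv(assoc, file.path(out, "association.tsv"))
cat(sprintf("lead SNP %s: OR %.3f, p %.3g\n", lead,
            assoc$or_[assoc$id == lead], assoc$p[assoc$id == lead]))

# fixed-effects inverse-variance meta of two deterministic half-cohorts
halves <- regulomap:::split_cohort(gm)
fits <- lapply(halves, fit_additive_logistic, variant_id = lead)
meta <- inverse_variance_meta(fits)
write_tsv(meta, file.path(out, "meta_lead.tsv"))
cat(sprintf("meta of 2 half-cohorts: OR %.3f, p %.3g\n", meta$or_, meta$p))

# LD of every haplotype SNP to the lead
hap <- unlist(truth$case_control$haplotype_snps)
ld <- data.frame(id = hap,
                 r2 = vapply(hap, function(v)
                   compute_ld_r2(gm, lead, v), 0))
write_tsv(ld, file.path(out, "ld_to_lead.tsv"))
cat(sprintf("LD to lead across the haplotype: r2 %.2f-%.2f\n",
            min(ld$r2), max(ld$r2)))

filtered <- filter_variants(vcf$variants, assoc, info_min = 0.80,
                            maf_min = 0.01, p_max = 1e-10, or_min = 1.5)
cat(sprintf("filter kept %d of %d variants (planted haplotype: %d)\n",
            nrow(filtered), nrow(vcf$variants), length(hap)))

tracks <- regulomap:::default_track_set(vcf$variants, hap, seed = 1L)
annotated <- annotate_regulatory_overlap(filtered, tracks)
write_tsv(annotated, file.path(out, "annotated.tsv"))
cat(sprintf("top prioritised SNP: %s (overlaps %d of %d tracks)\n",
            annotated$id[1], annotated$priority_score[1], length(tracks)))
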