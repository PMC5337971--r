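#!/usr/bin/env Rscript

# Stage 1 -- simulate every input of the fine-mapping workflow with a known
# truth ledger: the case-control cohort carrying the 8-SNP risk haplotype,
# ChIP-seq replicates with the planted 1.7 allelic read ratio plus an
# equal-ratio WGS control, the 5 kb contact matrix with the planted
# 2.7-fold loop, and the tumour cohort with trisomy, eQTL effect and BAF
# truth. Writes the on-disk formats downstream stages read.

suppressMessages(library(regulomap))

seed <- 1L
out <- "results/sim"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
cfg <- sim_config(seed = seed)

cc <- simulate_case_control(cfg)
write_vcf(cc$variants, file.path(out, "variants.vcf"),
          dosages = cc$genotypes$dosages)
write_tsv(data.frame(sample = cc$genotypes$samples,
                     phenotype = cc$genotypes$phenotype),
          file.path(out, "phenotypes.tsv"))

chip <- simulate_chipseq_replicates(cfg)
for (r in seq_along(chip$replicates)) {
  write_sam(chip$replicates[[r]], chip$contigs,
            file.path(out, sprintf("chip_rep%d.sam", r)))
}
wgs_cfg <- sim_config(seed = seed + 1000L)
wgs <- simulate_chipseq_replicates(wgs_cfg, variant = chip$variant,
                                   allelic_ratio = 1)
write_sam(wgs$replicates[[1]], wgs$contigs, file.path(out, "wgs.sam"))
Biostrings::writeXStringSet(chip$reference,
                            file.path(out, "reference.fa"))
write_vcf(cbind(chip$variant, maf = 0.33, info = 1.0),
          file.path(out, "test_snp.vcf"))

hic <- simulate_contact_matrix(cfg)
write_contact_matrix(hic$matrix, file.path(out, "contacts_dense.tsv"))
write_contact_matrix(hic$matrix, file.path(out, "contacts_coo.tsv"),
                     format = "coo")

cohort <- simulate_trisomic_cohort(cfg)
write_tsv(cohort$samples, file.path(out, "cohort.tsv"))

write_truth(list(case_control = unclass(cc$truth),
                 chipseq = unclass(chip$truth),
                 contacts = unclass(hic$truth),
                 cohort = unclass(cohort$truth)),
            file.path(out, "truth.json"))

cat(sprintf("simulated: %d samples x %d variants; %d ChIP replicates; %dx%d contact bins; %d tumours (%d trisomic)\n",
            nrow(cc$genotypes$dosages), ncol(cc$genotypes$dosages),
            length(chip$replicates), cfg$n_bins, cfg$n_bins,
            cfg$n_tumours, sum(cohort$samples$chr_copy_number == 3)))
cat(sprintf("truth ledger written to %s\n", file.path(out, "truth.json")))
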