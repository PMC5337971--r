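#!/usr/bin/env Rscript

# Stage 3 -- allele-specific binding at the candidate SNP: mask the
# reference at the test SNP, count alleles per ChIP-seq replicate from the
# SAM files, test each replicate with the exact binomial test, combine
# with depth-weighted Fisher (directional), and run the WGS copy-number
# control.

suppressMessages(library(regulomap))

sim_dir <- "results/sim"
out <- "results/asb"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

variant <- read_vcf(file.path(sim_dir, "test_snp.vcf"))$variants
reference <- Biostrings::readDNAStringSet(file.path(sim_dir, "reference.fa"))
masked <- mask_reference(reference, variant)
Biostrings::writeXStringSet(masked, file.path(out, "reference_masked.fa"))

reps <- list.files(sim_dir, pattern = "^chip_rep", full.names = TRUE)
res <- asb_pipeline(as.list(reps), variant,
                    wgs_alignments = file.path(sim_dir, "wgs.sam"),
                    alpha = 0.001, control_alpha = 0.05)

per_rep <- do.call(rbind, lapply(res$counts, function(ct)
  data.frame(replicate = ct$replicate_id, ref = ct$ref_count,
             alt = ct$alt_count, other = ct$other_count)))
per_rep$p_two_sided <- res$replicate_p
write_tsv(per_rep, file.path(out, "replicate_counts.tsv"))
write_tsv(data.frame(variant = res$variant_id, fold = res$fold,
                     favoured = res$favoured_allele,
                     combined_p = res$combined_p,
                     control_p = res$control_p, verdict = res$verdict),
          file.path(out, "asb_result.tsv"))

cat(sprintf("pooled fold %.2f favouring %s; combined p %.3g; WGS control p %.2f; verdict %s\n",
            res$fold, res$favoured_allele, res$combined_p, res$control_p,
            res$verdict))
truth <- read_truth(file.path(sim_dir, "truth.json"))
cat(sprintf("planted non-risk:risk ratio was %.2f\n",
            truth$chipseq$allelic_ratio))
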