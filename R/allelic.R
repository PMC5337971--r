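#' @title Allele-specific binding analysis
#' @description Mask a reference at known variants, count alleles at a
#'   heterozygous SNP from alignments, test per-replicate imbalance with an
#'   exact binomial test, combine replicates by (optionally weighted)
#'   Fisher's method, and run a whole-genome-sequencing copy-number
#'   control.
#' @name regulomap-allelic
NULL

asb_error <- function(msg, class = "regulomap_asb_error") {
  stop(errorCondition(msg, class = c(class, "error")))
}

#' Mask a reference sequence at variant positions
#'
#' Replaces each variant position with the ambiguity base \code{N}, the
#' standard mitigation of reference-mapping bias before allele counting.
#' All other bases are unchanged and sequence length is preserved.
#'
#' @param reference a \code{Biostrings::DNAStringSet} keyed by contig name.
#' @param variants data.frame with \code{id, chrom, pos} (1-based).
#' @return the masked \code{DNAStringSet}.
#' @export
mask_reference <- function(reference, variants) {
  if (nrow(variants) == 0) return(reference)
  out <- reference
  for (contig in unique(variants$chrom)) {
    if (!contig %in% names(out)) {
      asb_error(sprintf("contig '%s' absent from reference", contig))
    }
    vv <- variants[variants$chrom == contig, , drop = FALSE]
    too_far <- vv$pos > Biostrings::width(out[contig]) | vv$pos < 1
    if (any(too_far)) {
      asb_error(sprintf("variant '%s' position %d outside contig '%s'",
                        vv$id[too_far][1], vv$pos[too_far][1], contig))
    }
    at <- rep(FALSE, Biostrings::width(out[contig]))
    at[vv$pos] <- TRUE
    out[[contig]] <- Biostrings::replaceLetterAt(
      out[[contig]], at, rep.int("N", sum(at)))
  }
  out
}

#' Count alleles at a SNP from alignments
#'
#' Pileup-based enumeration of reads overlapping the variant position.
#' CIGAR operations are resolved (a read whose deletion spans the SNP
#' contributes to no category), unmapped reads and duplicates are excluded,
#' base and mapping quality floors are applied, and each read is counted at
#' most once. Input may be a SAM file path or an in-memory record
#' data.frame (as emitted by [simulate_chipseq_replicates()]), which is
#' converted through BAM internally.
#'
#' @param alignments SAM path, or a list with \code{records} and
#'   \code{contigs}, or a record data.frame plus \code{contigs}.
#' @param variant one-row data.frame: \code{id, chrom, pos, ref, alt}.
#' @param min_base_quality,min_mapping_quality quality floors.
#' @param contigs named contig lengths (required for in-memory records).
#' @return an \code{allele_count} list: \code{variant_id, replicate_id,
#'   ref_count, alt_count, other_count, depth}.
#' @export
count_alleles <- function(alignments, variant, min_base_quality = 20,
                          min_mapping_quality = 10, contigs = NULL) {
  sam_path <- NULL
  if (is.character(alignments)) {
    sam_path <- alignments
    if (!file.exists(sam_path)) {
      asb_error(sprintf("alignment file not found: %s", sam_path))
    }
  } else {
    records <- if (is.data.frame(alignments)) alignments else alignments$records
    if (is.null(contigs) && !is.data.frame(alignments)) {
      contigs <- alignments$contigs
    }
    if (is.null(contigs)) {
      asb_error("contig lengths required for in-memory records")
    }
    sam_path <- tempfile(fileext = ".sam")
    on.exit(unlink(sam_path), add = TRUE)
    write_sam(records, contigs, sam_path)
  }
  bam_prefix <- tempfile()
  bam <- Rsamtools::asBam(sam_path, bam_prefix, overwrite = TRUE,
                          indexDestination = TRUE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  which <- GenomicRanges::GRanges(variant$chrom,
                                  IRanges::IRanges(variant$pos,
                                                   variant$pos))
  sbp <- Rsamtools::ScanBamParam(
    which = which,
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isDuplicate = FALSE,
                                  isSecondaryAlignment = FALSE))
  pp <- Rsamtools::PileupParam(
    min_base_quality = as.integer(min_base_quality),
    min_mapq = as.integer(min_mapping_quality),
    min_nucleotide_depth = 0L, distinguish_strands = FALSE,
    distinguish_nucleotides = TRUE, include_deletions = TRUE,
    max_depth = 1000000L)
  pile <- Rsamtools::pileup(bam, scanBamParam = sbp, pileupParam = pp)
  counts <- stats::setNames(pile$count, as.character(pile$nucleotide))
  ref_count <- sum(counts[names(counts) == variant$ref])
  alt_count <- sum(counts[names(counts) == variant$alt])
  # deletions ('-') span the SNP without a base: skipped entirely
  other <- sum(counts[!names(counts) %in% c(variant$ref, variant$alt, "-")])
  structure(list(variant_id = variant$id,
                 replicate_id = basename(sam_path),
                 ref_count = as.integer(ref_count),
                 alt_count = as.integer(alt_count),
                 other_count = as.integer(other),
                 depth = as.integer(ref_count + alt_count + other)),
            class = "allele_count")
}

#' Exact binomial test of allelic imbalance
#'
#' Tests the reference-allele count against \code{ref + alt} trials at null
#' probability \code{p0}, assuming an equal distribution of reads between
#' alleles by default. The two-sided p-value uses the minimum-likelihood
#' method (sum of outcome probabilities no larger than the observed one),
#' the convention of \code{stats::binom.test}. "Other" bases never enter
#' the denominator.
#'
#' @param count an \code{allele_count}, or a length-2 numeric
#'   \code{c(ref, alt)}.
#' @param p0 null success probability.
#' @param alternative \code{"two.sided"}, \code{"greater"} or
#'   \code{"less"} (for the reference count).
#' @return the p-value.
#' @export
binomial_asb_test <- function(count, p0 = 0.5,
                              alternative = c("two.sided", "greater",
                                              "less")) {
  alternative <- match.arg(alternative)
  if (inherits(count, "allele_count")) {
    x <- count$ref_count
    n <- count$ref_count + count$alt_count
  } else {
    x <- count[1]
    n <- count[1] + count[2]
  }
  if (n < 1) {
    asb_error("binomial test undefined at zero informative depth",
              class = "regulomap_undefined_test")
  }
  stats::binom.test(x, n, p = p0, alternative = alternative)$p.value
}

#' Combine p-values by Fisher's or Lancaster's weighted method
#'
#' Unweighted: \code{X = -2 * sum(log(p))} referred to chi-squared with
#' \code{2k} degrees of freedom. Weighted (Lancaster's generalization):
#' each p-value is mapped through the upper quantile of a gamma with shape
#' \code{w_i * k / sum(w)} and scale 2, preserving the total \code{2k}
#' degrees of freedom, and the sum is referred to chi-squared \code{2k}.
#' Equal weights reduce exactly to the unweighted method.
#'
#' @param pvalues numeric vector in (0, 1].
#' @param weights optional positive weights, one per p-value.
#' @return the combined p-value.
#' @export
combine_fisher <- function(pvalues, weights = NULL) {
  if (length(pvalues) < 1) asb_error("need at least one p-value")
  if (any(pvalues <= 0)) {
    asb_error(paste("p-value of 0 cannot be combined;",
                    "floor inputs at the machine minimum explicitly"))
  }
  if (any(pvalues > 1)) asb_error("p-values must lie in (0, 1]")
  k <- length(pvalues)
  if (is.null(weights)) {
    x <- -2 * sum(log(pvalues))
    return(stats::pchisq(x, df = 2 * k, lower.tail = FALSE))
  }
  if (length(weights) != k || any(weights <= 0)) {
    asb_error("weights must be positive and match the p-values")
  }
  shape <- weights * k / sum(weights)  # per-study df = 2*shape, total 2k
  x <- sum(stats::qgamma(pvalues, shape = shape, scale = 2,
                         lower.tail = FALSE))
  stats::pchisq(x, df = 2 * k, lower.tail = FALSE)
}

#' Allele-specific binding pipeline for one SNP
#'
#' Counts alleles per replicate, tests each replicate with the exact
#' two-sided binomial test (reported per replicate), combines replicates
#' with depth-weighted Lancaster-Fisher (weights = informative depth; set
#' \code{weighted = FALSE} for plain Fisher), computes the pooled fold
#' \code{max(ref, alt) / min(ref, alt)}, and runs the whole-genome
#' sequencing copy-number control.
#'
#' Two combination conventions are provided. The default,
#' \code{"directional"}, combines the one-sided per-replicate p-values
#' separately in each direction and reports twice the smaller combined
#' value, capped at 1 (Pearson's directional variant of Fisher's method).
#' This is a valid two-sided combined test that rewards replicates
#' imbalanced in a consistent direction; naively combining two-sided
#' p-values (\code{combination = "naive"}) would declare replicates
#' imbalanced in opposite directions jointly significant. Verdicts:
#' \code{"ASB"} only when the
#' combined p is below \code{alpha} and the control shows no imbalance
#' (control p above \code{control_alpha}); \code{"control-failed"} when the
#' control itself is imbalanced; \code{"uncontrolled"} when significant but
#' no control was supplied; \code{"no-ASB"} otherwise.
#'
#' @param replicate_alignments list of SAM paths or record sets.
#' @param variant one-row data.frame: \code{id, chrom, pos, ref, alt}.
#' @param wgs_alignments optional control alignments.
#' @param alpha significance threshold on the combined p.
#' @param control_alpha threshold below which the control is failed.
#' @param weighted use depth-weighted Lancaster combination.
#' @param combination \code{"directional"} (default) or \code{"naive"}
#'   combination of replicate evidence (see Details).
#' @param contigs named contig lengths for in-memory records.
#' @param ... passed to [count_alleles()] (quality floors).
#' @return an \code{asb_result} list.
#' @export
asb_pipeline <- function(replicate_alignments, variant,
                         wgs_alignments = NULL, alpha = 0.001,
                         control_alpha = 0.05, weighted = TRUE,
                         combination = c("directional", "naive"),
                         contigs = NULL, ...) {
  combination <- match.arg(combination)
  if (length(replicate_alignments) < 1) {
    asb_error("need at least one replicate")
  }
  counts <- lapply(replicate_alignments, count_alleles, variant = variant,
                   contigs = contigs, ...)
  depths <- vapply(counts, function(ct) ct$ref_count + ct$alt_count, 0)
  if (all(depths == 0)) {
    return(structure(list(variant_id = variant$id, status = "undefined",
                          message = "all replicates have zero depth"),
                     class = "asb_result"))
  }
  usable <- depths > 0
  rep_p <- vapply(counts[usable], binomial_asb_test, 0)
  w <- if (weighted) depths[usable]
  if (combination == "directional") {
    p_hi <- vapply(counts[usable], binomial_asb_test, 0,
                   alternative = "greater")
    p_lo <- vapply(counts[usable], binomial_asb_test, 0,
                   alternative = "less")
    combined <- min(1, 2 * min(combine_fisher(p_hi, weights = w),
                               combine_fisher(p_lo, weights = w)))
  } else {
    combined <- combine_fisher(rep_p, weights = w)
  }
  pooled_ref <- sum(vapply(counts, function(ct) ct$ref_count, 0L))
  pooled_alt <- sum(vapply(counts, function(ct) ct$alt_count, 0L))
  fold <- max(pooled_ref, pooled_alt) / max(1L, min(pooled_ref, pooled_alt))
  favoured <- if (pooled_ref >= pooled_alt) variant$ref else variant$alt
  control_p <- NA_real_
  if (!is.null(wgs_alignments)) {
    wgs_count <- count_alleles(wgs_alignments, variant, contigs = contigs,
                               ...)
    control_p <- binomial_asb_test(wgs_count)
  }
  verdict <- if (combined >= alpha) {
    "no-ASB"
  } else if (is.na(control_p)) {
    "uncontrolled"
  } else if (control_p <= control_alpha) {
    "control-failed"
  } else {
    "ASB"
  }
  structure(list(variant_id = variant$id, counts = counts,
                 replicate_p = rep_p, combined_p = combined,
                 fold = fold, favoured_allele = favoured,
                 control_p = control_p, verdict = verdict,
                 status = "ok"),
            class = "asb_result")
}
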