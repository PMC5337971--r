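#' @title Association and fine-mapping
#' @description Per-SNP additive logistic association, fixed-effects
#'   inverse-variance meta-analysis, composite LD, threshold filtering of
#'   variants by imputation quality / MAF / P / OR, and regulatory
#'   annotation prioritisation.
#' @name regulomap-association
NULL

assoc_error <- function(msg) {
  stop(errorCondition(msg, class = c("regulomap_assoc_error", "error")))
}

#' Additive logistic association for one variant
#'
#' Fits \code{logit P(case) = a + b * dosage} by iteratively reweighted
#' least squares (the binomial GLM) and reports the Wald statistic
#' \code{z = b / se} with a two-sided normal p-value, the convention of
#' standard GWAS software. A monomorphic variant is returned with status
#' \code{"monomorphic"} and quasi-complete separation (|b| > 15) with
#' status \code{"separation"}; neither crashes the scan.
#'
#' @param genotypes a \code{genotype_matrix}.
#' @param variant_id column name of the variant to test.
#' @return one-row data.frame: \code{id, beta, se, z, p, or_, n, status}.
#' @export
fit_additive_logistic <- function(genotypes, variant_id) {
  if (!variant_id %in% colnames(genotypes$dosages)) {
    assoc_error(sprintf("unknown variant '%s'", variant_id))
  }
  dose <- genotypes$dosages[, variant_id]
  y <- genotypes$phenotype
  res <- data.frame(id = variant_id, beta = NA_real_, se = NA_real_,
                    z = NA_real_, p = NA_real_, or_ = NA_real_,
                    n = length(y), status = "ok",
                    stringsAsFactors = FALSE)
  if (stats::var(dose) == 0) {
    res$status <- "monomorphic"
    return(res)
  }
  fit <- suppressWarnings(
    stats::glm(y ~ dose, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-10, maxit = 50))
  )
  beta <- unname(stats::coef(fit)["dose"])
  se <- sqrt(stats::vcov(fit)["dose", "dose"])
  if (!is.finite(beta) || abs(beta) > 15) {
    res$status <- "separation"
    res$beta <- beta
    return(res)
  }
  z <- beta / se
  res$beta <- beta
  res$se <- se
  res$z <- z
  res$p <- 2 * stats::pnorm(-abs(z))
  res$or_ <- exp(beta)
  res
}

#' Association scan over all variants in a genotype matrix
#'
#' @param genotypes a \code{genotype_matrix}.
#' @param variant_ids variants to test (default: every column).
#' @return data.frame of per-variant association results.
#' @export
assoc_scan <- function(genotypes, variant_ids = colnames(genotypes$dosages)) {
  do.call(rbind, lapply(variant_ids,
                        function(v) fit_additive_logistic(genotypes, v)))
}

#' Fixed-effects inverse-variance meta-analysis
#'
#' Pools per-study log-odds with weights \code{w_i = 1 / se_i^2}:
#' pooled beta is the weighted mean, pooled se is \code{(sum w_i)^(-1/2)},
#' with a two-sided Wald p-value. Studies must report the effect for the
#' same ref/alt orientation; a flipped (ref/alt swapped) study has its sign
#' corrected, but strand-ambiguous A/T and C/G variants are refused rather
#' than auto-flipped.
#'
#' @param studies list of per-study one-row data.frames with \code{beta}
#'   and \code{se} (as produced by [fit_additive_logistic()]); optional
#'   \code{ref}/\code{alt} columns trigger orientation harmonisation.
#' @return data.frame: pooled \code{beta, se, z, p} plus per-study effects
#'   and weights in attributes \code{"studies"}.
#' @export
inverse_variance_meta <- function(studies) {
  if (length(studies) < 1) assoc_error("need at least one study")
  betas <- vapply(studies, function(s) s$beta, 0)
  ses <- vapply(studies, function(s) s$se, 0)
  if (any(!is.finite(ses)) || any(ses <= 0)) {
    assoc_error("all study standard errors must be positive and finite")
  }
  has_alleles <- all(vapply(studies, function(s)
    all(c("ref", "alt") %in% names(s)), TRUE))
  if (has_alleles && length(studies) > 1) {
    ref1 <- studies[[1]]$ref
    alt1 <- studies[[1]]$alt
    ambiguous <- function(r, a) {
      paste0(r, a) %in% c("AT", "TA", "CG", "GC")
    }
    for (i in seq_along(studies)[-1]) {
      r <- studies[[i]]$ref
      a <- studies[[i]]$alt
      if (r == ref1 && a == alt1) next
      if (r == alt1 && a == ref1) {
        if (ambiguous(r, a)) {
          assoc_error(sprintf(
            "strand-ambiguous alleles for variant '%s'; refusing to flip",
            studies[[i]]$id))
        }
        betas[i] <- -betas[i]
      } else {
        assoc_error(sprintf("allele mismatch for variant '%s'",
                            studies[[i]]$id))
      }
    }
  }
  w <- 1 / ses^2
  beta <- sum(w * betas) / sum(w)
  se <- 1 / sqrt(sum(w))
  z <- beta / se
  out <- data.frame(beta = beta, se = se, z = z,
                    p = 2 * stats::pnorm(-abs(z)),
                    or_ = exp(beta), n_studies = length(studies))
  attr(out, "studies") <- data.frame(beta = betas, se = ses, weight = w)
  out
}

#' Filter variants by imputation quality, MAF, P and OR
#'
#' Applies the fine-mapping filters: keep variants with
#' \code{info >= info_min} (poorly imputed variants, INFO strictly below
#' the floor, are excluded), \code{maf > maf_min}, \code{p < p_max} and
#' \code{or_ > or_min}. Input order is preserved; an empty result is legal.
#'
#' @param variants variant data.frame (\code{id, maf, info}, ...).
#' @param results association results covering every variant (\code{id, p,
#'   or_}).
#' @param info_min,maf_min,p_max,or_min thresholds.
#' @return the surviving rows of \code{variants}.
#' @export
filter_variants <- function(variants, results, info_min = 0.80,
                            maf_min = 0.01, p_max = 1, or_min = 0) {
  stopifnot(all(is.finite(c(info_min, maf_min, p_max, or_min))))
  idx <- match(variants$id, results$id)
  if (anyNA(idx)) {
    assoc_error(sprintf("no association result for variant '%s'",
                        variants$id[which(is.na(idx))[1]]))
  }
  p <- results$p[idx]
  or_ <- results$or_[idx]
  keep <- variants$info >= info_min &
    variants$maf > maf_min &
    !is.na(p) & p < p_max &
    !is.na(or_) & or_ > or_min
  variants[keep, , drop = FALSE]
}

#' Composite LD r-squared between two variants
#'
#' Squared Pearson correlation of the dosage vectors (composite LD). Phase
#' is not required, which matches case-control dosage data; for phased
#' haplotypes this equals the usual haplotype-based r-squared.
#'
#' @param genotypes a \code{genotype_matrix}.
#' @param variant_a,variant_b variant column names.
#' @return r-squared in [0, 1].
#' @export
compute_ld_r2 <- function(genotypes, variant_a, variant_b) {
  for (v in c(variant_a, variant_b)) {
    if (!v %in% colnames(genotypes$dosages)) {
      assoc_error(sprintf("unknown variant '%s'", v))
    }
    if (stats::var(genotypes$dosages[, v]) == 0) {
      stop(errorCondition(
        sprintf("LD undefined: variant '%s' is monomorphic", v),
        class = c("regulomap_monomorphic_error", "error")))
    }
  }
  stats::cor(genotypes$dosages[, variant_a],
             genotypes$dosages[, variant_b])^2
}

#' Prioritize variants by regulatory annotation overlap
#'
#' Scores each variant by the number of annotation tracks (enhancer
#' histone marks, DNase hypersensitivity, TF binding, conservation, ...)
#' whose intervals cover its position. Tracks use the 0-based half-open
#' BED convention; the 1-based VCF position is converted before the test,
#' so a variant at position 100 overlaps BED interval [99, 100) and not
#' [100, 101). Output is sorted by score descending, ties broken by
#' position.
#'
#' @param variants variant data.frame (\code{id, chrom, pos}).
#' @param tracks named list of \code{GRanges} (e.g. from [read_bed()]).
#' @return data.frame of annotated variants: per-track logical columns plus
#'   \code{priority_score}, sorted by score then position.
#' @export
annotate_regulatory_overlap <- function(variants, tracks) {
  v_gr <- GenomicRanges::GRanges(variants$chrom,
                                 IRanges::IRanges(variants$pos,
                                                  variants$pos))
  out <- variants
  score <- integer(nrow(variants))
  for (tn in names(tracks)) {
    hits <- GenomicRanges::countOverlaps(v_gr, tracks[[tn]]) > 0
    out[[paste0("track_", tn)]] <- hits
    score <- score + as.integer(hits)
  }
  out$priority_score <- score
  out[order(-out$priority_score, out$pos), , drop = FALSE]
}
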