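#' @title Expression genetics under trisomy
#' @description Trisomy-restricted eQTL ANOVA, B-allele-frequency
#'   classification of the duplicated homologue, the one-sided binomial
#'   preferential-retention test, and cross-cohort Spearman correlation
#'   with weighted Fisher combination.
#' @name regulomap-expression
NULL

expr_error <- function(msg, class = "regulomap_expr_error") {
  stop(errorCondition(msg, class = c(class, "error")))
}

#' log2(x + 1) transform
#'
#' @param values non-negative expression values (e.g. RSEM estimates).
#' @return elementwise \code{log2(values + 1)}.
#' @export
log2p1_transform <- function(values) {
  if (any(values < 0, na.rm = TRUE)) {
    expr_error("log2(x+1) transform requires non-negative input")
  }
  log2(values + 1)
}

#' One-way eQTL ANOVA restricted by chromosome copy number
#'
#' To control for gene dosage the analysis is restricted to samples at a
#' fixed chromosome copy number (default trisomic) before a one-way
#' fixed-effects ANOVA of expression on genotype class (count of risk
#' alleles among the homologues present). A linear-trend test on the
#' genotype count is available behind \code{trend = TRUE}.
#'
#' @param samples data.frame with \code{genotype, chr_copy_number} and the
#'   expression column.
#' @param expression_col name of the expression column.
#' @param restrict_copy_number copy number to keep (NULL for no
#'   restriction).
#' @param trend test a linear trend in genotype instead of class means.
#' @return an \code{eqtl_result} list: group means/sizes, F, df pair, p,
#'   status.
#' @export
eqtl_anova <- function(samples, expression_col = "expression",
                       restrict_copy_number = 3, trend = FALSE) {
  dat <- samples
  if (!is.null(restrict_copy_number)) {
    dat <- dat[dat$chr_copy_number == restrict_copy_number, , drop = FALSE]
  }
  expr <- dat[[expression_col]]
  geno <- dat$genotype
  tab <- table(geno)
  groups_ok <- sum(tab >= 2)
  out <- list(n = nrow(dat),
              group_levels = as.numeric(names(tab)),
              group_sizes = as.vector(tab),
              group_means = as.vector(tapply(expr, geno, mean)),
              F = NA_real_, df = c(NA_real_, NA_real_), p = NA_real_,
              status = "ok", trend = trend)
  class(out) <- "eqtl_result"
  if (length(tab) < 2 || groups_ok < 2) {
    out$status <- "underpowered"
    return(out)
  }
  fit <- if (trend) stats::lm(expr ~ geno) else
    stats::lm(expr ~ factor(geno))
  an <- suppressWarnings(stats::anova(fit))  # perfect fits handled below
  out$df <- c(an$Df[1], an$Df[2])
  sst <- sum(an$`Sum Sq`)
  scale0 <- nrow(dat) * (abs(mean(expr)) + 1)^2
  if (sst <= 1e-12 * scale0 || an$`Sum Sq`[1] <= 1e-12 * scale0) {
    # no between-group variation at all (degenerate zero-noise input)
    out$F <- 0
    out$p <- 1
  } else {
    out$F <- an$`F value`[1]
    out$p <- an$`Pr(>F)`[1]
  }
  out
}

#' Classify which homologue a trisomic heterozygote duplicated
#'
#' On a trisomic chromosome a heterozygous SNP shows a B-allele frequency
#' near 2/3 when the B homologue was duplicated and near 1/3 when the A
#' homologue was; values within \code{baf_tol} of neither centre are
#' ambiguous. Only applicable to heterozygous trisomic samples.
#'
#' @param baf B-allele frequency in [0, 1] (vectorised).
#' @param chr_copy_number copy number (must be 3).
#' @param heterozygous logical; must be TRUE.
#' @param baf_tol half-width of the acceptance window around 1/3 and 2/3.
#' @return character vector in \code{c("A", "B", "ambiguous")}.
#' @export
classify_duplicated_allele <- function(baf, chr_copy_number = 3,
                                       heterozygous = TRUE,
                                       baf_tol = 0.08) {
  if (any(chr_copy_number != 3) || !all(heterozygous)) {
    expr_error("classification applies only to heterozygous trisomic samples",
               class = "regulomap_inapplicable_error")
  }
  if (any(baf < 0 | baf > 1)) expr_error("BAF must lie in [0, 1]")
  out <- rep("ambiguous", length(baf))
  out[abs(baf - 2 / 3) <= baf_tol] <- "B"
  out[abs(baf - 1 / 3) <= baf_tol] <- "A"
  out
}

#' One-sided binomial test of preferential allele retention
#'
#' Among heterozygous trisomic tumours with an unambiguous
#' duplicated-homologue call, tests whether the risk homologue is
#' duplicated more often than the 50:50 null predicts:
#' \code{P(X >= n_risk | n, 1/2)}, one-sided. Ambiguous calls are excluded
#' from the denominator and reported.
#'
#' @param calls character vector of \code{"A"/"B"/"ambiguous"} calls.
#' @param risk_allele which allele (\code{"A"} or \code{"B"}) is the risk
#'   allele.
#' @return a \code{retention_result} list: the three counts, the excluded
#'   ambiguous count and the one-sided p.
#' @export
retention_test <- function(calls, risk_allele = "B") {
  stopifnot(risk_allele %in% c("A", "B"))
  other <- setdiff(c("A", "B"), risk_allele)
  n_risk <- sum(calls == risk_allele)
  n_nonrisk <- sum(calls == other)
  n_amb <- sum(calls == "ambiguous")
  n <- n_risk + n_nonrisk
  if (n == 0) {
    expr_error("no unambiguous duplicated-homologue calls",
               class = "regulomap_undefined_test")
  }
  p <- stats::binom.test(n_risk, n, p = 0.5,
                         alternative = "greater")$p.value
  structure(list(n_heterozygous_trisomic = n + n_amb,
                 n_risk_duplicated = n_risk,
                 n_nonrisk_duplicated = n_nonrisk,
                 n_ambiguous = n_amb, p = p),
            class = "retention_result")
}

#' Spearman correlation with t-approximation p-value
#'
#' Rank-based correlation with midranks for ties; the p-value uses the
#' t-approximation on \code{n - 2} degrees of freedom (the standard choice
#' at cohort sizes of tens to hundreds). An exact permutation p-value is
#' available for very small samples.
#'
#' @param x,y paired finite vectors, n >= 4.
#' @param cohort_id label carried into the result.
#' @param alternative \code{"two.sided"}, \code{"greater"} or
#'   \code{"less"}.
#' @param exact exact permutation p (only for n <= 10).
#' @return a \code{correlation_result} list: \code{cohort_id, rho, n, p}.
#' @export
spearman_correlation <- function(x, y, cohort_id = "cohort",
                                 alternative = "two.sided",
                                 exact = FALSE) {
  if (length(x) != length(y) || length(x) < 4) {
    expr_error("need paired vectors of length at least 4")
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    expr_error("non-finite values in correlation input")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    expr_error("correlation undefined for a constant vector",
               class = "regulomap_undefined_test")
  }
  n <- length(x)
  if (exact && n > 10) {
    expr_error("exact permutation p only supported for n <= 10")
  }
  rho <- stats::cor(x, y, method = "spearman")
  if (exact) {
    perms <- combinat_permutations(n)
    rx <- rank(x)
    ry <- rank(y)
    null_rho <- apply(perms, 1, function(idx) stats::cor(rx, ry[idx]))
    p <- switch(alternative,
                two.sided = mean(abs(null_rho) >= abs(rho) - 1e-12),
                greater = mean(null_rho >= rho - 1e-12),
                less = mean(null_rho <= rho + 1e-12))
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- switch(alternative,
                two.sided = 2 * stats::pt(-abs(tstat), df = n - 2),
                greater = stats::pt(tstat, df = n - 2, lower.tail = FALSE),
                less = stats::pt(tstat, df = n - 2))
  }
  structure(list(cohort_id = cohort_id, rho = rho, n = n, p = p,
                 alternative = alternative),
            class = "correlation_result")
}

combinat_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- combinat_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Combine per-cohort correlation p-values
#'
#' Delegates to [combine_fisher()] with cohort sample sizes as Lancaster
#' weights (the weighted Fisher's method); pass \code{weights = NULL} for
#' the unweighted combination. Cohort p-values should be one-sided toward
#' the common alternative (positive correlation).
#'
#' @param results list of \code{correlation_result}s.
#' @param weights \code{"n"} (default) or NULL.
#' @return the combined p-value.
#' @export
combine_cohort_correlations <- function(results, weights = "n") {
  if (length(results) < 1) expr_error("need at least one cohort result")
  p <- vapply(results, function(r) r$p, 0)
  w <- if (identical(weights, "n")) {
    vapply(results, function(r) as.numeric(r$n), 0)
  } else {
    NULL
  }
  combine_fisher(p, weights = w)
}
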