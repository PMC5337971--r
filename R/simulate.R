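#' @title Synthetic-data generators
#' @description Generators for every input the pipeline consumes, each with
#'   a known truth ledger: a case-control cohort carrying a high-LD risk
#'   haplotype, ChIP-seq replicates with a planted allelic read ratio at a
#'   heterozygous SNP, a distance-decaying contact matrix with a planted
#'   anchor-promoter loop, and a tumour cohort with genotype-dependent
#'   expression and a B-allele frequency that encodes which homologue was
#'   duplicated. All randomness flows from the configuration seed; the same
#'   configuration reproduces identical outputs.
#' @name regulomap-simulate
NULL

truth_record <- function(...) {
  structure(list(...), class = "truth_record")
}

new_genotype_matrix <- function(dosages, phenotype) {
  stopifnot(nrow(dosages) == length(phenotype))
  if (min(table(factor(phenotype, levels = 0:1))) == 0) {
    stop(errorCondition("need at least one case and one control",
                        class = c("regulomap_input_error", "error")))
  }
  if (any(dosages < 0 | dosages > 2)) {
    stop(errorCondition("dosages must lie in [0, 2]",
                        class = c("regulomap_input_error", "error")))
  }
  structure(list(samples = rownames(dosages), phenotype = phenotype,
                 dosages = dosages),
            class = "genotype_matrix")
}

#' Simulate a case-control cohort with a planted risk haplotype
#'
#' Haplotypes on the risk block are produced by copying a founder allele
#' with a per-SNP decoupling probability, which gives direct control of
#' pairwise LD: r-squared between block SNPs is approximately
#' \code{(1-decoupling)^4} (exactly 1 at decoupling 0). The lead SNP copies
#' the founder exactly and carries the causal effect. Case genotypes at the
#' causal SNP are drawn from the case-ascertained genotype distribution
#' implied by an additive logistic model at the configured odds ratio
#' (rare-disease limit), so a logistic regression of phenotype on dosage is
#' consistent for \code{log(odds_ratio)}. Unlinked background variants with
#' uniform MAF and imputation-quality scores are added to exercise
#' filtering.
#'
#' @param config a [sim_config()].
#' @return list with \code{genotypes} (a \code{genotype_matrix}),
#'   \code{variants} (data.frame of variant records) and \code{truth}
#'   (a \code{truth_record}).
#' @export
simulate_case_control <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n_case <- config$n_cases
  n_ctrl <- config$n_controls
  n <- n_case + n_ctrl
  p <- config$haplotype_maf
  beta <- log(config$odds_ratio)
  k <- config$n_haplotype_snps

  # causal genotype: controls ~ population HWE, cases ~ exp(beta*g)-tilted
  pop <- stats::dbinom(0:2, 2, p)
  case_probs <- pop * exp(beta * (0:2))
  case_probs <- case_probs / sum(case_probs)
  g_case <- sample(0:2, n_case, replace = TRUE, prob = case_probs)
  g_ctrl <- sample(0:2, n_ctrl, replace = TRUE, prob = pop)
  g <- c(g_case, g_ctrl)
  phenotype <- c(rep(1L, n_case), rep(0L, n_ctrl))

  # founder allele per haplotype, consistent with the causal genotype
  h1 <- as.integer(g == 2 | (g == 1 & stats::runif(n) < 0.5))
  h2 <- g - h1
  hap_dos <- matrix(0L, n, k)
  hap_dos[, 1] <- g  # lead SNP: copy-perfect
  if (k > 1) {
    for (j in 2:k) {
      a1 <- ifelse(stats::runif(n) < config$decoupling,
                   stats::rbinom(n, 1, p), h1)
      a2 <- ifelse(stats::runif(n) < config$decoupling,
                   stats::rbinom(n, 1, p), h2)
      hap_dos[, j] <- a1 + a2
    }
  }

  nb <- config$n_background
  bg_maf <- stats::runif(nb, 0.05, 0.5)
  bg_dos <- vapply(bg_maf, function(q) stats::rbinom(n, 2, q),
                   integer(n))

  hap_ids <- sprintf("hapSNP%02d", seq_len(k))
  bg_ids <- if (nb > 0) sprintf("bgSNP%02d", seq_len(nb)) else character()
  ids <- c(hap_ids, bg_ids)
  dosages <- cbind(hap_dos, bg_dos)
  colnames(dosages) <- ids
  rownames(dosages) <- c(sprintf("case%04d", seq_len(n_case)),
                         sprintf("ctrl%04d", seq_len(n_ctrl)))

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, k + nb, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")
  hap_pos <- config$locus_offset + 200000L + seq_len(k) * 1000L
  bg_pos <- sort(sample(config$locus_offset + seq_len(400000L), nb))
  obs_maf <- pmin(colMeans(dosages) / 2, 1 - colMeans(dosages) / 2)
  variants <- data.frame(
    id = ids, chrom = config$locus_chrom,
    pos = c(hap_pos, bg_pos), ref = ref, alt = alt,
    maf = obs_maf,
    info = c(rep(1, k), stats::runif(nb, 0.55, 1)),
    stringsAsFactors = FALSE
  )
  truth <- truth_record(
    kind = "case_control",
    lead_snp = hap_ids[1], haplotype_snps = hap_ids,
    odds_ratio = config$odds_ratio, haplotype_maf = p,
    decoupling = config$decoupling
  )
  list(genotypes = new_genotype_matrix(dosages, phenotype),
       variants = variants, truth = truth)
}

#' Simulate ChIP-seq replicates with a planted allelic read ratio
#'
#' Emits pre-aligned reads (SAM records) over a short reference contig.
#' Each replicate draws a Poisson number of reads covering the test SNP;
#' each read carries the non-risk (reference) allele with probability
#' \code{allelic_ratio / (1 + allelic_ratio)}. A flat per-base error rate
#' can corrupt bases. The reference sequence and an equal-ratio whole-genome
#' control can be generated from the same machinery.
#'
#' @param config a [sim_config()].
#' @param variant single-row data.frame with \code{chrom, pos, ref, alt}
#'   (defaults to a SNP mid-contig, non-risk ref "T", risk alt "C").
#' @param allelic_ratio non-risk:risk ratio; defaults to the configured one
#'   (pass 1 for a copy-number control).
#' @return list with \code{replicates} (list of SAM record data.frames),
#'   \code{reference} (a \code{DNAStringSet}), \code{contigs}, \code{variant}
#'   and \code{truth}.
#' @export
simulate_chipseq_replicates <- function(config, variant = NULL,
                                        allelic_ratio = config$allelic_ratio) {
  validate_sim_config(config)
  if (allelic_ratio <= 0) {
    stop(errorCondition("'allelic_ratio' must be positive",
                        class = c("regulomap_config_error", "error")))
  }
  set.seed(config$seed)
  contig_len <- 1000L
  L <- config$read_length
  ref_seq <- paste(sample(c("A", "C", "G", "T"), contig_len,
                          replace = TRUE), collapse = "")
  if (is.null(variant)) {
    variant <- data.frame(id = "testSNP", chrom = config$locus_chrom,
                          pos = 500L, ref = "T", alt = "C",
                          stringsAsFactors = FALSE)
  }
  substr(ref_seq, variant$pos, variant$pos) <- variant$ref
  p_ref <- allelic_ratio / (1 + allelic_ratio)
  reps <- vector("list", config$n_replicates)
  bases <- c("A", "C", "G", "T")
  for (r in seq_len(config$n_replicates)) {
    n_reads <- stats::rpois(1, config$read_depth)
    lo <- max(1L, variant$pos - L + 1L)
    hi <- min(contig_len - L + 1L, variant$pos)
    starts <- sample(lo:hi, n_reads, replace = TRUE)
    is_ref <- stats::runif(n_reads) < p_ref
    seqs <- vapply(seq_len(n_reads), function(i) {
      s <- substr(ref_seq, starts[i], starts[i] + L - 1L)
      allele <- if (is_ref[i]) variant$ref else variant$alt
      substr(s, variant$pos - starts[i] + 1L,
             variant$pos - starts[i] + 1L) <- allele
      if (config$error_rate > 0) {
        flip <- which(stats::runif(L) < config$error_rate)
        for (b in flip) {
          substr(s, b, b) <- sample(setdiff(bases, substr(s, b, b)), 1)
        }
      }
      s
    }, "")
    reps[[r]] <- data.frame(
      qname = sprintf("rep%d_read%05d", r, seq_len(n_reads)),
      flag = 0L, chrom = variant$chrom, pos = starts, mapq = 60L,
      cigar = sprintf("%dM", L), seq = seqs,
      qual = strrep("I", L), stringsAsFactors = FALSE
    )
    attr(reps[[r]], "true_ref_count") <- sum(is_ref)
    attr(reps[[r]], "true_alt_count") <- sum(!is_ref)
  }
  contigs <- stats::setNames(contig_len, variant$chrom)
  truth <- truth_record(
    kind = "chipseq", variant_id = variant$id,
    allelic_ratio = allelic_ratio,
    true_ref_counts = vapply(reps, attr, 0L, "true_ref_count"),
    true_alt_counts = vapply(reps, attr, 0L, "true_alt_count")
  )
  list(replicates = reps,
       reference = Biostrings::DNAStringSet(
         stats::setNames(ref_seq, variant$chrom)),
       contigs = contigs, variant = variant, truth = truth)
}

#' Construct a contact matrix object
#'
#' @param counts symmetric non-negative matrix of binned contact counts.
#' @param chrom chromosome name.
#' @param offset bp start of bin 0.
#' @param bin_size bin width in bp.
#' @return a \code{contact_matrix}.
#' @export
contact_matrix <- function(counts, chrom = "chr10", offset = 0L,
                           bin_size = 5000L) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts) ||
      !isTRUE(all.equal(counts, t(counts), tolerance = 1e-12))) {
    stop(errorCondition("contact counts must be a symmetric matrix",
                        class = c("regulomap_input_error", "error")))
  }
  if (any(counts < 0)) {
    stop(errorCondition("contact counts must be non-negative",
                        class = c("regulomap_input_error", "error")))
  }
  structure(list(chrom = chrom, offset = as.integer(offset),
                 bin_size = as.integer(bin_size), counts = counts),
            class = "contact_matrix")
}

#' Simulate a binned contact matrix with a planted loop
#'
#' Off-diagonal expectation follows the power-law decay
#' \code{contact_scale * |i - j|^(-decay_exponent)}; the anchor-target pair
#' is multiplied by \code{loop_fold}. With \code{noise = TRUE} (default)
#' counts are Poisson draws on the upper triangle mirrored to keep symmetry;
#' with \code{noise = FALSE} the exact expectations are returned, so the
#' observed/expected ratio at the loop against the constructed decay curve
#' is exactly \code{loop_fold}.
#'
#' @param config a [sim_config()].
#' @param noise draw Poisson counts (TRUE) or return exact expectations.
#' @return list with \code{matrix} (a \code{contact_matrix}) and
#'   \code{truth}.
#' @export
simulate_contact_matrix <- function(config, noise = TRUE) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_bins
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  mu <- config$contact_scale * ifelse(d == 0, 1, d^(-config$decay_exponent))
  a <- config$anchor_bin + 1L
  t <- config$target_bin + 1L
  mu[a, t] <- mu[a, t] * config$loop_fold
  mu[t, a] <- mu[t, a] * config$loop_fold
  if (noise) {
    counts <- matrix(0, n, n)
    up <- upper.tri(mu, diag = TRUE)
    counts[up] <- stats::rpois(sum(up), mu[up])
    counts <- counts + t(counts) - diag(diag(counts))
  } else {
    counts <- mu
  }
  truth <- truth_record(
    kind = "contacts", anchor_bin = config$anchor_bin,
    target_bin = config$target_bin, loop_fold = config$loop_fold,
    decay_exponent = config$decay_exponent,
    contact_scale = config$contact_scale
  )
  list(matrix = contact_matrix(counts, chrom = config$locus_chrom,
                               offset = config$locus_offset,
                               bin_size = config$bin_size),
       truth = truth)
}

#' Simulate a tumour cohort with trisomy, eQTL effect and BAF truth
#'
#' Each tumour is trisomic for the locus chromosome with probability
#' \code{trisomy_fraction}. The diploid genotype at the test SNP is drawn
#' under Hardy-Weinberg at the haplotype MAF, with the risk allele playing
#' the role of the B allele. A heterozygous trisomic tumour duplicates the
#' risk homologue with probability \code{duplication_bias}; homozygotes
#' duplicate their only homolog type. Expression is
#' \code{expr_baseline + eqtl_effect * (risk-allele copies) + noise};
#' BAF is (B copies)/(copy number) plus truncated-Gaussian noise in [0, 1].
#'
#' @param config a [sim_config()].
#' @param baf_noise set FALSE for noise-free BAF (deterministic limit).
#' @return list with \code{samples} (data.frame: sample, genotype,
#'   chr_copy_number, baf, expression) and \code{truth} (per-tumour
#'   duplicated-homologue labels).
#' @export
simulate_trisomic_cohort <- function(config, baf_noise = TRUE) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_tumours
  p <- config$haplotype_maf
  cn <- ifelse(stats::runif(n) < config$trisomy_fraction, 3L, 2L)
  g2 <- stats::rbinom(n, 2, p)  # risk-allele copies on two homologues
  dup_risk <- rep(NA, n)
  genotype <- g2
  tri <- cn == 3L
  het <- tri & g2 == 1L
  hom <- tri & g2 != 1L
  dup_risk[het] <- stats::runif(sum(het)) < config$duplication_bias
  dup_risk[hom] <- g2[hom] == 2L
  genotype[tri] <- g2[tri] + as.integer(dup_risk[tri])
  baf_true <- genotype / cn
  baf <- baf_true
  if (baf_noise && config$baf_sd > 0) {
    baf <- rtrunc_norm(n, baf_true, config$baf_sd)
  }
  expression <- config$expr_baseline + config$eqtl_effect * genotype +
    stats::rnorm(n, 0, config$expr_sd)
  samples <- data.frame(
    sample = sprintf("tumour%03d", seq_len(n)),
    genotype = genotype, chr_copy_number = cn,
    baf = baf, expression = expression,
    stringsAsFactors = FALSE
  )
  truth <- truth_record(
    kind = "trisomic_cohort", risk_allele = "B",
    eqtl_effect = config$eqtl_effect,
    duplication_bias = config$duplication_bias,
    duplicated_risk = dup_risk
  )
  list(samples = samples, truth = truth)
}

# truncated Gaussian on [0, 1] by inverse-CDF sampling
rtrunc_norm <- function(n, mean, sd) {
  lo <- stats::pnorm(0, mean, sd)
  hi <- stats::pnorm(1, mean, sd)
  stats::qnorm(lo + stats::runif(n) * (hi - lo), mean, sd)
}

#' Simulate expression cohorts with a planted cross-gene correlation
#'
#' Generates per-cohort paired expression values for two genes with a
#' planted Pearson/Spearman-scale correlation, used to exercise the
#' cross-cohort Spearman + weighted-Fisher combination stage at realistic
#' cohort sizes.
#'
#' @param ns integer vector of cohort sizes.
#' @param rho planted correlation.
#' @param seed integer seed.
#' @return list of data.frames with columns \code{x, y}, one per cohort.
#' @export
simulate_correlated_cohorts <- function(ns, rho, seed = 1L) {
  stopifnot(abs(rho) <= 1, all(ns >= 4))
  set.seed(seed)
  lapply(ns, function(n) {
    x <- stats::rnorm(n)
    y <- rho * x + sqrt(1 - rho^2) * stats::rnorm(n)
    data.frame(x = x, y = y)
  })
}
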