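make_gm <- function(dosages, phenotype) {
  rownames(dosages) <- sprintf("s%03d", seq_len(nrow(dosages)))
  regulomap:::new_genotype_matrix(dosages, phenotype)
}

test_that("logistic fit on a balanced table is null", {
  dose <- matrix(rep(c(0, 1, 2), each = 40), ncol = 1,
                 dimnames = list(NULL, "v1"))
  pheno <- rep(c(1L, 0L), 60)  # dosage independent of phenotype
  gm <- make_gm(dose, pheno)
  res <- fit_additive_logistic(gm, "v1")
  expect_lt(abs(res$beta), 1e-8)
  expect_gt(res$p, 0.999)
  expect_equal(res$or_, exp(res$beta))
})

test_that("binary-dosage logistic MLE equals the 2x2 cross-product ratio", {
  # cases: 30 exposed / 70 unexposed; controls: 10 / 90 -> OR 27/7
  dose <- matrix(c(rep(1, 30), rep(0, 70), rep(1, 10), rep(0, 90)),
                 ncol = 1, dimnames = list(NULL, "v1"))
  pheno <- c(rep(1L, 100), rep(0L, 100))
  res <- fit_additive_logistic(make_gm(dose, pheno), "v1")
  expect_equal(res$or_, (30 * 90) / (70 * 10), tolerance = 1e-6)
})

test_that("logistic fit matches a Newton-Raphson oracle to 1e-6", {
  for (s in 1:10) {
    set.seed(s)
    n <- 200
    dose <- matrix(stats::rbinom(n, 2, 0.3), ncol = 1,
                   dimnames = list(NULL, "v1"))
    pheno <- stats::rbinom(n, 1, stats::plogis(-0.5 + 0.6 * dose[, 1]))
    if (length(unique(pheno)) < 2 || stats::var(dose[, 1]) == 0) next
    res <- fit_additive_logistic(make_gm(dose, pheno), "v1")
    ora <- oracle_logistic(pheno, dose[, 1])
    expect_equal(res$beta, ora$beta, tolerance = 1e-6)
    expect_equal(res$se, ora$se, tolerance = 1e-6)
  }
})

test_that("monomorphic and separated variants are flagged, not fatal", {
  pheno <- c(rep(1L, 50), rep(0L, 50))
  dose <- cbind(mono = rep(1, 100),
                sep = ifelse(pheno == 1, 2, 0))  # complete separation
  gm <- make_gm(dose, pheno)
  expect_equal(fit_additive_logistic(gm, "mono")$status, "monomorphic")
  expect_equal(fit_additive_logistic(gm, "sep")$status, "separation")
})

test_that("inverse-variance meta: identity, closed form, oracle, pooling", {
  s1 <- data.frame(id = "v", beta = 0.7, se = 0.2)
  single <- inverse_variance_meta(list(s1))
  expect_equal(single$beta, 0.7)
  expect_equal(single$se, 0.2)

  two <- inverse_variance_meta(list(
    data.frame(id = "v", beta = 1, se = 0.5),
    data.frame(id = "v", beta = 2, se = 0.5)))
  expect_equal(two$beta, 1.5)
  expect_equal(two$se, 0.5 / sqrt(2), tolerance = 1e-12)

  for (s in 1:5) {
    set.seed(s)
    betas <- stats::rnorm(5)
    ses <- stats::runif(5, 0.1, 1)
    studies <- lapply(1:5, function(i)
      data.frame(id = "v", beta = betas[i], se = ses[i]))
    got <- inverse_variance_meta(studies)
    ora <- oracle_ivw(betas, ses)
    expect_equal(got$beta, ora$beta, tolerance = 1e-12)
    expect_equal(got$se, ora$se, tolerance = 1e-12)
    # pooled beta inside the study range, pooled se below the minimum
    expect_gte(got$beta, min(betas))
    expect_lte(got$beta, max(betas))
    expect_lte(got$se, min(ses))
  }

  # adding a study strictly shrinks the pooled se
  se3 <- inverse_variance_meta(list(s1, s1, s1))$se
  se2 <- inverse_variance_meta(list(s1, s1))$se
  expect_lt(se3, se2)
})

test_that("meta harmonizes flipped alleles and refuses ambiguous ones", {
  a <- data.frame(id = "v", beta = 0.5, se = 0.2, ref = "A", alt = "G")
  flipped <- data.frame(id = "v", beta = -0.5, se = 0.2, ref = "G",
                        alt = "A")
  got <- inverse_variance_meta(list(a, flipped))
  expect_equal(got$beta, 0.5)

  amb <- data.frame(id = "v", beta = -0.5, se = 0.2, ref = "T", alt = "A")
  a2 <- data.frame(id = "v", beta = 0.5, se = 0.2, ref = "A", alt = "T")
  expect_error(inverse_variance_meta(list(a2, amb)),
               class = "regulomap_assoc_error")
  mismatch <- data.frame(id = "v", beta = 0.5, se = 0.2, ref = "A",
                         alt = "C")
  expect_error(inverse_variance_meta(list(a, mismatch)),
               class = "regulomap_assoc_error")
  bad_se <- data.frame(id = "v", beta = 0.5, se = 0)
  expect_error(inverse_variance_meta(list(bad_se)),
               class = "regulomap_assoc_error")
})

test_that("variant filter applies the stated threshold conventions", {
  variants <- data.frame(
    id = c("a", "b", "c", "d"),
    maf = c(0.3, 0.3, 0.01, 0.3),
    info = c(1.0, 0.79, 1.0, 0.80),
    stringsAsFactors = FALSE)
  results <- data.frame(id = variants$id, p = c(1e-40, 1e-40, 1e-40, 0.5),
                        or_ = c(2.5, 2.5, 2.5, 2.5))
  # loosest thresholds return the input unchanged
  expect_identical(filter_variants(variants, results, info_min = 0,
                                   maf_min = 0, p_max = 1, or_min = 0),
                   variants)
  # INFO 0.79 is excluded (strictly below the 0.80 floor); 0.80 is kept
  kept <- filter_variants(variants, results, info_min = 0.80,
                          maf_min = 0, p_max = 1, or_min = 0)
  expect_identical(kept$id, c("a", "c", "d"))
  # MAF filter is strict: maf must exceed the floor
  kept <- filter_variants(variants, results, info_min = 0,
                          maf_min = 0.01, p_max = 1, or_min = 0)
  expect_false("c" %in% kept$id)
  # P and OR strict
  kept <- filter_variants(variants, results, info_min = 0, maf_min = 0,
                          p_max = 1e-35, or_min = 2.4)
  expect_identical(kept$id, c("a", "b", "c"))
})

test_that("variant filter is idempotent and order-preserving", {
  cfg <- sim_config(seed = 31, n_cases = 465, n_controls = 5200)
  cc <- simulate_case_control(cfg)
  res <- assoc_scan(cc$genotypes)
  kept <- filter_variants(cc$variants, res, info_min = 0.80,
                          maf_min = 0.01, p_max = 1e-10, or_min = 1.5)
  expect_identical(kept$id, sort(kept$id))  # input order was sorted ids
  again <- filter_variants(kept, res, info_min = 0.80, maf_min = 0.01,
                           p_max = 1e-10, or_min = 1.5)
  expect_identical(again, kept)
  # exactly the 8 planted haplotype SNPs survive among 50 background
  expect_identical(kept$id, cc$truth$haplotype_snps)
})

test_that("LD r2: identity, independence, symmetry, allele relabelling", {
  cfg <- sim_config(seed = 13, n_cases = 1000, n_controls = 1000,
                    n_background = 4)
  cc <- simulate_case_control(cfg)
  gm <- cc$genotypes
  expect_equal(compute_ld_r2(gm, "hapSNP01", "hapSNP01"), 1.0)
  expect_lt(compute_ld_r2(gm, "bgSNP01", "bgSNP02"), 0.05)
  expect_equal(compute_ld_r2(gm, "hapSNP01", "hapSNP02"),
               compute_ld_r2(gm, "hapSNP02", "hapSNP01"))
  # relabelling alleles (dosage -> 2 - dosage) leaves r2 unchanged
  gm2 <- gm
  gm2$dosages[, "hapSNP02"] <- 2 - gm2$dosages[, "hapSNP02"]
  expect_equal(compute_ld_r2(gm2, "hapSNP01", "hapSNP02"),
               compute_ld_r2(gm, "hapSNP01", "hapSNP02"))
  # monomorphic variant has undefined LD
  gm2$dosages[, "bgSNP03"] <- 1
  expect_error(compute_ld_r2(gm2, "hapSNP01", "bgSNP03"),
               class = "regulomap_monomorphic_error")
})

test_that("decoupled-copy LD matches the haplotype-frequency prediction", {
  # copy-with-decoupling at rate d: corr(SNP_j, founder) = 1 - d, so
  # r2 between lead (= founder) and a copied SNP is (1 - d)^2
  d <- 0.1
  r2s <- vapply(1:30, function(s) {
    cfg <- sim_config(seed = s, decoupling = d, n_cases = 2000,
                      n_controls = 2000, n_background = 0, odds_ratio = 1)
    cc <- simulate_case_control(cfg)
    compute_ld_r2(cc$genotypes, "hapSNP01", "hapSNP02")
  }, 0)
  expect_equal(mean(r2s), (1 - d)^2, tolerance = 0.02)
})

test_that("annotation overlap follows the BED coordinate convention", {
  variants <- data.frame(id = c("v1", "v2"), chrom = "chr1",
                         pos = c(100L, 101L), stringsAsFactors = FALSE)
  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t99\t100\tdnase", bed)
  tracks <- list(dnase = read_bed(bed))
  ann <- annotate_regulatory_overlap(variants, tracks)
  # 1-based position 100 overlaps [99, 100); 101 does not
  expect_true(ann$track_dnase[ann$id == "v1"])
  expect_false(ann$track_dnase[ann$id == "v2"])
})

test_that("annotation priority ranks densely-annotated variants first", {
  variants <- data.frame(id = sprintf("v%d", 1:8), chrom = "chr1",
                         pos = seq(1000L, 8000L, by = 1000L),
                         stringsAsFactors = FALSE)
  # empty track set: all scores zero, input order preserved
  ann0 <- annotate_regulatory_overlap(variants, list())
  expect_identical(ann0$id, variants$id)
  expect_true(all(ann0$priority_score == 0))
  # 6 tracks built so v3 and v7 hit >= 5 tracks, the rest at most 2
  mk <- function(pos) GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(pos - 10, pos + 10))
  focal <- c(3000L, 7000L)
  tracks <- list(
    H3K27ac = mk(focal), H3K4me1 = mk(focal), H3K4me3 = mk(focal),
    DNase = mk(focal), TF = mk(focal),
    cons = mk(c(1000L, 2000L)))
  ann <- annotate_regulatory_overlap(variants, tracks)
  expect_setequal(ann$id[1:2], c("v3", "v7"))
  expect_true(all(ann$priority_score[1:2] >= 5))
  expect_true(all(ann$priority_score[-(1:2)] <= 2))
})

test_that("95% Wald confidence intervals cover the planted odds ratio", {
  # small-scale coverage check; the full 300-seed version is in the
  # acceptance suite
  covered <- vapply(1:60, function(s) {
    cfg <- sim_config(seed = s + 500, n_background = 0)
    cc <- simulate_case_control(cfg)
    fit <- fit_additive_logistic(cc$genotypes, cc$truth$lead_snp)
    lo <- fit$beta - 1.959964 * fit$se
    hi <- fit$beta + 1.959964 * fit$se
    lo <= log(2.4) && log(2.4) <= hi
  }, TRUE)
  expect_gt(mean(covered), 0.85)
})
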