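test_that("reference masking replaces exactly the variant positions", {
  ref <- Biostrings::DNAStringSet(c(chrT = strrep("ACGT", 25)))
  variants <- data.frame(id = c("m1", "m2", "m3"), chrom = "chrT",
                         pos = c(10L, 50L, 99L), stringsAsFactors = FALSE)
  masked <- mask_reference(ref, variants)
  s0 <- strsplit(as.character(ref[[1]]), "")[[1]]
  s1 <- strsplit(as.character(masked[[1]]), "")[[1]]
  expect_equal(sum(s0 != s1), 3)
  expect_true(all(s1[c(10, 50, 99)] == "N"))
  expect_equal(length(s1), length(s0))
  # empty variant list: identity
  empty <- variants[0, ]
  expect_identical(mask_reference(ref, empty), ref)
  # out-of-bounds position names the variant
  bad <- data.frame(id = "far", chrom = "chrT", pos = 200L)
  expect_error(mask_reference(ref, bad), "far",
               class = "regulomap_asb_error")
  # FASTA round trip preserves masking
  fa <- tempfile(fileext = ".fa")
  Biostrings::writeXStringSet(masked, fa)
  back <- Biostrings::readDNAStringSet(fa)
  expect_equal(as.character(back[[1]]), as.character(masked[[1]]))
})

test_that("allele counting enumerates a constructed fixture exactly", {
  sam <- tempfile(fileext = ".sam")
  fixture_sam(c("C", "C", "T", "T", "T"), sam)
  ct <- count_alleles(sam, fixture_variant(ref = "C", alt = "T"))
  expect_equal(ct$ref_count, 2L)
  expect_equal(ct$alt_count, 3L)
  expect_equal(ct$other_count, 0L)
  expect_equal(ct$depth, 5L)
})

test_that("a read whose deletion spans the SNP is skipped entirely", {
  sam <- tempfile(fileext = ".sam")
  # two 10M reads with alleles, one read whose 2 bp deletion covers the SNP
  ref <- strrep("A", 60)
  records <- data.frame(
    qname = c("r1", "r2", "rdel"), flag = 0L, chrom = "chrT",
    pos = c(25L, 25L, 25L), mapq = 60L,
    cigar = c("10M", "10M", "4M3D6M"),
    seq = c("AAAAACAAAA", "AAAAATAAAA", "AAAAAAAAAA"),
    qual = strrep("I", 10), stringsAsFactors = FALSE)
  write_sam(records, c(chrT = 60L), sam)
  ct <- count_alleles(sam, fixture_variant(ref = "C", alt = "T"))
  expect_equal(ct$ref_count, 1L)
  expect_equal(ct$alt_count, 1L)
  expect_equal(ct$other_count, 0L)
})

test_that("quality floors exclude low-quality bases and mappings", {
  sam <- tempfile(fileext = ".sam")
  fixture_sam(c("C", "C", "T"), sam, qual_char = "#")  # base quality 2
  ct <- count_alleles(sam, fixture_variant(), min_base_quality = 20)
  expect_equal(ct$depth, 0L)
  sam2 <- tempfile(fileext = ".sam")
  fixture_sam(c("C", "T"), sam2, mapq = 3L)
  ct2 <- count_alleles(sam2, fixture_variant(), min_mapping_quality = 10)
  expect_equal(ct2$depth, 0L)
})

test_that("counts equal the simulator's emitted labels at zero error rate", {
  cfg <- sim_config(seed = 23)
  chip <- simulate_chipseq_replicates(cfg)
  for (r in seq_along(chip$replicates)) {
    ct <- count_alleles(chip$replicates[[r]], chip$variant,
                        contigs = chip$contigs)
    expect_equal(ct$ref_count, chip$truth$true_ref_counts[r])
    expect_equal(ct$alt_count, chip$truth$true_alt_counts[r])
    expect_equal(ct$other_count, 0L)
  }
})

test_that("counting is independent of record order", {
  cfg <- sim_config(seed = 29, n_replicates = 1)
  chip <- simulate_chipseq_replicates(cfg)
  recs <- chip$replicates[[1]]
  shuffled <- recs[rev(seq_len(nrow(recs))), ]
  a <- count_alleles(recs, chip$variant, contigs = chip$contigs)
  b <- count_alleles(shuffled, chip$variant, contigs = chip$contigs)
  expect_equal(a$ref_count, b$ref_count)
  expect_equal(a$alt_count, b$alt_count)
})

test_that("binomial imbalance test: centre, tails and symmetry", {
  # perfectly balanced counts: two-sided p = 1 (the copy-number control
  # convention)
  expect_equal(binomial_asb_test(c(25, 25)), 1.0)
  # one-sided 21 vs 10 equals the exact upper tail sum
  p21 <- binomial_asb_test(c(21, 10), alternative = "greater")
  expect_equal(p21, oracle_binom_upper(21, 31), tolerance = 1e-12)
  expect_equal(p21, 0.0354, tolerance = 1e-3)
  # extreme 0 vs n two-sided: 2 * (1/2)^n capped at 1
  for (n in c(5, 12)) {
    expect_equal(binomial_asb_test(c(0, n)), min(1, 2 * 0.5^n),
                 tolerance = 1e-12)
  }
  # two-sided symmetric under ref/alt swap
  expect_equal(binomial_asb_test(c(30, 12)), binomial_asb_test(c(12, 30)))
  # zero informative depth is an explicit error
  expect_error(binomial_asb_test(c(0, 0)),
               class = "regulomap_undefined_test")
})

test_that("Fisher combination: identity, closed form, weights, invariance", {
  expect_equal(combine_fisher(0.2), 0.2, tolerance = 1e-12)
  expect_equal(combine_fisher(0.2, weights = 5), 0.2, tolerance = 1e-10)
  # p = (0.5, 0.5): X = 2.7726, df 4, survival e^(-x/2) (1 + x/2)
  x <- -2 * (log(0.5) + log(0.5))
  expect_equal(combine_fisher(c(0.5, 0.5)), exp(-x / 2) * (1 + x / 2),
               tolerance = 1e-10)
  # equal weights degenerate to the unweighted method
  p <- c(0.01, 0.2, 0.6)
  expect_equal(combine_fisher(p, weights = c(2, 2, 2)),
               combine_fisher(p), tolerance = 1e-10)
  # permutation invariance
  expect_equal(combine_fisher(p[c(3, 1, 2)], weights = c(7, 1, 3)[c(3, 1, 2)]),
               combine_fisher(p, weights = c(7, 1, 3)), tolerance = 1e-12)
  # k identical p = 0.1 grows more significant as replicates accumulate
  ladder <- vapply(1:5, function(k) combine_fisher(rep(0.1, k)), 0)
  expect_true(all(diff(ladder) < 0))
  # p = 0 is refused with instructions
  expect_error(combine_fisher(c(0, 0.5)), "floor",
               class = "regulomap_asb_error")
  expect_error(combine_fisher(c(0.5, 1.5)), class = "regulomap_asb_error")
  expect_error(combine_fisher(c(0.5, 0.5), weights = c(1, -1)),
               class = "regulomap_asb_error")
})

test_that("asb pipeline: balanced replicates give a negative verdict", {
  alleles <- c(rep("C", 30), rep("T", 30))
  reps <- lapply(1:3, function(r) {
    sam <- tempfile(fileext = sprintf("_rep%d.sam", r))
    fixture_sam(alleles, sam)
  })
  res <- asb_pipeline(reps, fixture_variant())
  expect_equal(res$verdict, "no-ASB")
  expect_equal(res$fold, 1)
})

test_that("asb pipeline: planted imbalance is detected and controlled", {
  cfg <- sim_config(seed = 77)
  chip <- simulate_chipseq_replicates(cfg)
  wgs_cfg <- sim_config(seed = 78, read_depth = 200, n_replicates = 1)
  wgs <- simulate_chipseq_replicates(wgs_cfg, variant = chip$variant,
                                     allelic_ratio = 1)
  res <- asb_pipeline(chip$replicates, chip$variant,
                      wgs_alignments = wgs$replicates[[1]],
                      contigs = chip$contigs)
  expect_equal(res$verdict, "ASB")
  expect_lt(res$combined_p, 0.001)
  expect_gt(res$fold, 1.2)
  expect_equal(res$favoured_allele, chip$variant$ref)  # non-risk excess
  # without a control the verdict is downgraded
  res_nc <- asb_pipeline(chip$replicates, chip$variant,
                         contigs = chip$contigs)
  expect_equal(res_nc$verdict, "uncontrolled")
})

test_that("asb pipeline: imbalanced WGS control fails the verdict", {
  # a copy-number artifact: the same skew in ChIP and WGS
  cfg <- sim_config(seed = 79)
  chip <- simulate_chipseq_replicates(cfg)
  wgs_cfg <- sim_config(seed = 80, read_depth = 300, n_replicates = 1)
  wgs_skewed <- simulate_chipseq_replicates(wgs_cfg, variant = chip$variant,
                                            allelic_ratio = 1.7)
  res <- asb_pipeline(chip$replicates, chip$variant,
                      wgs_alignments = wgs_skewed$replicates[[1]],
                      contigs = chip$contigs)
  expect_equal(res$verdict, "control-failed")
})

test_that("estimated fold is a consistent estimator of the allelic ratio", {
  err <- vapply(c(100, 1000), function(depth) {
    folds <- vapply(1:25, function(s) {
      cfg <- sim_config(seed = s, read_depth = depth, n_replicates = 1)
      chip <- simulate_chipseq_replicates(cfg)
      tr <- chip$truth
      sum(tr$true_ref_counts) / sum(tr$true_alt_counts)
    }, 0)
    mean(abs(folds - 1.7))
  }, 0)
  expect_lt(err[2], err[1])  # error shrinks with depth
})

test_that("masked and unmasked references count error-free reads equally", {
  cfg <- sim_config(seed = 81, n_replicates = 1)
  chip <- simulate_chipseq_replicates(cfg)
  masked <- mask_reference(chip$reference,
                           data.frame(id = chip$variant$id,
                                      chrom = chip$variant$chrom,
                                      pos = chip$variant$pos))
  # counting uses only the reads' own bases, so the mask cannot change
  # the enumeration of error-free reads
  ct <- count_alleles(chip$replicates[[1]], chip$variant,
                      contigs = chip$contigs)
  expect_equal(ct$ref_count + ct$alt_count,
               chip$truth$true_ref_counts[1] + chip$truth$true_alt_counts[1])
  expect_equal(as.integer(Biostrings::width(masked)),
               as.integer(Biostrings::width(chip$reference)))
})
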