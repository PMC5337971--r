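# Independent oracles used to cross-check the implementation. Each is a
# deliberately different algorithm from the code path it checks.

# Newton-Raphson logistic regression (y ~ 1 + x), written directly from the
# score and Hessian of the binomial log-likelihood.
oracle_logistic <- function(y, x, tol = 1e-12, max_iter = 100) {
  X <- cbind(1, x)
  beta <- c(0, 0)
  for (i in seq_len(max_iter)) {
    eta <- as.vector(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    score <- t(X) %*% (y - mu)
    W <- mu * (1 - mu)
    H <- t(X) %*% (X * W)
    step <- solve(H, score)
    beta <- beta + as.vector(step)
    if (max(abs(step)) < tol) break
  }
  eta <- as.vector(X %*% beta)
  mu <- 1 / (1 + exp(-eta))
  H <- t(X) %*% (X * (mu * (1 - mu)))
  list(beta = beta[2], se = sqrt(solve(H)[2, 2]))
}

# Sinkhorn-Knopp alternating row/column scaling to a doubly-balanced form.
oracle_sinkhorn <- function(A, iters = 100000, tol = 1e-12) {
  r <- rep(1, nrow(A))
  for (i in seq_len(iters)) {
    c_ <- 1 / as.vector(t(A) %*% r)
    r_new <- 1 / as.vector(A %*% c_)
    if (max(abs(r_new - r)) < tol) {
      r <- r_new
      break
    }
    r <- r_new
  }
  # symmetrize: the balanced symmetric form uses sqrt(r * c)
  c_ <- 1 / as.vector(A %*% r)
  b <- sqrt(r * c_)
  A * outer(b, b)
}

# brute-force inverse-variance pooling
oracle_ivw <- function(betas, ses) {
  w <- 1 / ses^2
  list(beta = sum(w * betas) / sum(w), se = sqrt(1 / sum(w)))
}

# exact upper-tail binomial sum P(X >= k), written as a direct sum
oracle_binom_upper <- function(k, n, p = 0.5) {
  sum(vapply(k:n, function(i) choose(n, i) * p^i * (1 - p)^(n - i), 0))
}

# tiny SAM fixture builder: reads of given alleles over a 60 bp contig
# with the SNP at position 30
fixture_sam <- function(alleles, path, contig = "chrT", len = 60L,
                        snp_pos = 30L, read_len = 10L, mapq = 60L,
                        qual_char = "I", cigar = NULL) {
  ref <- strrep("A", len)
  n <- length(alleles)
  starts <- rep(snp_pos - 5L, n)
  seqs <- vapply(seq_len(n), function(i) {
    s <- strrep("G", read_len)
    substr(s, snp_pos - starts[i] + 1, snp_pos - starts[i] + 1) <- alleles[i]
    s
  }, "")
  records <- data.frame(
    qname = sprintf("fix%03d", seq_len(n)), flag = 0L, chrom = contig,
    pos = starts, mapq = mapq,
    cigar = if (is.null(cigar)) sprintf("%dM", read_len) else cigar,
    seq = seqs, qual = strrep(qual_char, read_len),
    stringsAsFactors = FALSE
  )
  write_sam(records, stats::setNames(len, contig), path)
  path
}

fixture_variant <- function(ref = "C", alt = "T") {
  data.frame(id = "fixSNP", chrom = "chrT", pos = 30L, ref = ref,
             alt = alt, stringsAsFactors = FALSE)
}

# random symmetric strictly-positive contact counts
random_symmetric_matrix <- function(n, seed) {
  set.seed(seed)
  M <- matrix(stats::runif(n * n, 1, 10), n, n)
  M <- M + t(M)
  M
}
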