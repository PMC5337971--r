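#' @title Chromatin contact analysis
#' @description Knight-Ruiz balancing of binned contact matrices, a
#'   per-distance expected model, observed/expected loop enrichment, bin
#'   assignment and TAD-contained anchor profiles.
#' @name regulomap-contact
NULL

hic_error <- function(msg, class = "regulomap_hic_error") {
  stop(errorCondition(msg, class = c(class, "error")))
}

#' Knight-Ruiz matrix balancing
#'
#' Computes the positive vector \code{b} such that
#' \code{diag(b) \%*\% counts \%*\% diag(b)} is doubly balanced (every
#' retained row sums to 1), using the Knight-Ruiz inner-outer Newton
#' iteration with a conjugate-gradient inner solve. Bins whose fraction of
#' nonzero entries falls below \code{sparse_frac} are masked before
#' balancing, since near-empty rows make the problem ill-posed.
#'
#' @param matrix a \code{contact_matrix} (or plain symmetric matrix).
#' @param tol convergence tolerance on the residual norm
#'   \code{||1 - b * (A b)||}.
#' @param max_iter maximum outer iterations.
#' @param sparse_frac minimum fraction of nonzero entries for a bin to be
#'   retained.
#' @return a \code{balanced_matrix}: the source, the balancing vector over
#'   retained bins, the balanced matrix (masked bins NA), the logical
#'   retention mask, and the iteration count.
#' @export
kr_balance <- function(matrix, tol = 1e-8, max_iter = 1000,
                       sparse_frac = 0.05) {
  cm <- if (inherits(matrix, "contact_matrix")) matrix else
    contact_matrix(matrix)
  counts <- cm$counts
  n <- nrow(counts)
  nonzero_frac <- rowSums(counts != 0) / n
  retained <- nonzero_frac >= sparse_frac
  if (sum(retained) < 2) {
    hic_error("fewer than 2 bins retained after sparse-bin filtering")
  }
  A <- counts[retained, retained, drop = FALSE]
  if (all(A == 0)) hic_error("matrix is entirely zero")
  b <- kr_vector(A, tol = tol, max_iter = max_iter)
  balanced <- matrix(NA_real_, n, n)
  balanced[retained, retained] <- A * outer(b, b)
  structure(list(source = cm, b = b, balanced = balanced,
                 retained = retained,
                 iterations = attr(b, "iterations"),
                 residual = attr(b, "residual")),
            class = "balanced_matrix")
}

# Knight-Ruiz bnewt: inexact Newton with CG inner iterations on the
# balancing equation x * (A x) = e, residual tracked in the 2-norm.
kr_vector <- function(A, tol = 1e-8, max_iter = 1000, delta = 0.1,
                      Delta = 3) {
  n <- nrow(A)
  e <- rep(1, n)
  x <- e
  g <- 0.9
  etamax <- 0.1
  eta <- etamax
  stop_tol <- tol * 0.5
  rt <- tol^2
  v <- x * as.vector(A %*% x)
  rk <- 1 - v
  rho_km1 <- sum(rk * rk)
  rout <- rho_km1
  rold <- rout
  outer_it <- 0
  total_inner <- 0
  while (rout > rt) {
    outer_it <- outer_it + 1
    if (outer_it > max_iter) {
      hic_error(sprintf(
        "Knight-Ruiz failed to converge in %d iterations (residual %.3g)",
        max_iter, sqrt(rout)), class = "regulomap_kr_nonconvergence")
    }
    k <- 0
    y <- e
    innertol <- max(eta^2 * rout, rt)
    rho_km2 <- rho_km1
    Z <- p <- NULL
    while (rho_km1 > innertol) {
      k <- k + 1
      if (k == 1) {
        Z <- rk / v
        p <- Z
        rho_km1 <- sum(rk * Z)
      } else {
        beta <- rho_km1 / rho_km2
        p <- Z + beta * p
      }
      w <- x * as.vector(A %*% (x * p)) + v * p
      alpha <- rho_km1 / sum(p * w)
      ap <- alpha * p
      ynew <- y + ap
      if (min(ynew) <= delta) {
        if (delta == 0) break
        ind <- ap < 0
        gamma <- min((delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      if (max(ynew) >= Delta) {
        ind <- ynew > Delta
        gamma <- min((Delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      y <- ynew
      rk <- rk - alpha * w
      rho_km2 <- rho_km1
      Z <- rk / v
      rho_km1 <- sum(rk * Z)
      if (k >= n) break
    }
    x <- x * y
    v <- x * as.vector(A %*% x)
    rk <- 1 - v
    rho_km1 <- sum(rk * rk)
    rout <- rho_km1
    total_inner <- total_inner + k + 1
    # adaptive forcing term (Eisenstat-Walker style)
    rat <- rout / rold
    rold <- rout
    res_norm <- sqrt(rout)
    eta_o <- eta
    eta <- g * rat
    if (g * eta_o^2 > 0.1) eta <- max(eta, g * eta_o^2)
    eta <- max(min(eta, etamax), stop_tol / res_norm)
  }
  attr(x, "iterations") <- total_inner
  attr(x, "residual") <- sqrt(rout)
  x
}

#' Per-distance expected contact model
#'
#' The expected value at bin distance \code{d} is the mean of the balanced
#' entries over all retained bin pairs at that distance, the standard
#' observed/expected construction. By construction the per-distance sums of
#' observed and expected values agree.
#'
#' @param balanced a \code{balanced_matrix}.
#' @return numeric vector indexed by distance 0..n-1 (NA where no retained
#'   pair exists).
#' @export
expected_by_distance <- function(balanced) {
  bal <- balanced$balanced
  n <- nrow(bal)
  expected <- rep(NA_real_, n)
  for (dist in 0:(n - 1)) {
    i <- seq_len(n - dist)
    vals <- bal[cbind(i, i + dist)]  # the dist-th superdiagonal
    vals <- vals[!is.na(vals)]
    if (length(vals) > 0) expected[dist + 1] <- mean(vals)
  }
  expected
}

#' Observed/expected fold at one bin pair
#'
#' @param balanced a \code{balanced_matrix}.
#' @param anchor_bin,target_bin 0-based bin indices; must be distinct and
#'   retained.
#' @param expected optional precomputed [expected_by_distance()] curve.
#' @return one-row data.frame: \code{anchor_bin, target_bin, observed,
#'   expected, fold} (fold NA-flagged when expected is 0).
#' @export
observed_expected_fold <- function(balanced, anchor_bin, target_bin,
                                   expected = NULL) {
  n <- nrow(balanced$balanced)
  for (b in c(anchor_bin, target_bin)) {
    if (b < 0 || b >= n) hic_error(sprintf("bin %d out of range", b))
    if (!balanced$retained[b + 1]) {
      hic_error(sprintf("bin %d was masked as sparse", b))
    }
  }
  if (anchor_bin == target_bin) {
    hic_error("anchor and target must be distinct bins (d = 0 diagonal)")
  }
  if (is.null(expected)) expected <- expected_by_distance(balanced)
  d <- abs(anchor_bin - target_bin)
  obs <- balanced$balanced[anchor_bin + 1, target_bin + 1]
  exp_d <- expected[d + 1]
  fold <- if (is.na(exp_d) || exp_d == 0) NA_real_ else obs / exp_d
  data.frame(anchor_bin = anchor_bin, target_bin = target_bin,
             observed = obs, expected = exp_d, fold = fold)
}

#' Assign a genomic position to a matrix bin
#'
#' Bins are half-open \code{[start, start + bin_size)} anchored at the
#' matrix offset: a position exactly on a boundary belongs to the higher
#' bin.
#'
#' @param position_bp 1-interpretation-free bp coordinate.
#' @param matrix a \code{contact_matrix} (or \code{balanced_matrix}).
#' @return 0-based bin index.
#' @export
assign_bin <- function(position_bp, matrix) {
  cm <- if (inherits(matrix, "balanced_matrix")) matrix$source else matrix
  idx <- floor((position_bp - cm$offset) / cm$bin_size)
  n <- nrow(cm$counts)
  if (any(idx < 0 | idx >= n)) {
    hic_error(sprintf("position %s outside the matrix span",
                      position_bp[which(idx < 0 | idx >= n)[1]]))
  }
  as.integer(idx)
}

#' Ranked enrichment profile of an anchor within its TAD
#'
#' Computes the observed/expected fold from the anchor to every retained
#' bin inside the TAD containing the anchor (excluding the anchor itself),
#' sorted by fold descending. Optionally reports whether a named target bin
#' ranks first.
#'
#' @param balanced a \code{balanced_matrix}.
#' @param anchor_bin 0-based anchor bin.
#' @param tads a \code{GRanges} of non-overlapping TAD intervals.
#' @param check_target optional 0-based bin; adds attribute
#'   \code{"target_is_top"}.
#' @return data.frame of [observed_expected_fold()] rows, sorted by fold.
#' @export
anchor_profile <- function(balanced, anchor_bin, tads,
                           check_target = NULL) {
  cm <- balanced$source
  n <- nrow(cm$counts)
  bin_starts <- cm$offset + (0:(n - 1)) * cm$bin_size
  bin_mid <- bin_starts + cm$bin_size / 2
  bins_gr <- GenomicRanges::GRanges(cm$chrom,
                                    IRanges::IRanges(bin_mid, bin_mid))
  hits <- GenomicRanges::findOverlaps(bins_gr, tads)
  tad_of <- rep(NA_integer_, n)
  tad_of[S4Vectors::queryHits(hits)] <- S4Vectors::subjectHits(hits)
  anchor_tad <- tad_of[anchor_bin + 1]
  if (is.na(anchor_tad)) hic_error("anchor bin falls outside all TADs")
  targets <- which(tad_of == anchor_tad & balanced$retained) - 1L
  targets <- setdiff(targets, anchor_bin)
  expected <- expected_by_distance(balanced)
  if (length(targets) == 0) {
    out <- data.frame(anchor_bin = integer(), target_bin = integer(),
                      observed = numeric(), expected = numeric(),
                      fold = numeric())
  } else {
    out <- do.call(rbind, lapply(targets, function(tb) {
      observed_expected_fold(balanced, anchor_bin, tb, expected = expected)
    }))
    out <- out[order(-out$fold), , drop = FALSE]
    rownames(out) <- NULL
  }
  if (!is.null(check_target)) {
    attr(out, "target_is_top") <-
      nrow(out) > 0 && out$target_bin[1] == check_target
  }
  out
}
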