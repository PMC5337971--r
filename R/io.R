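#' @title Format readers and writers
#' @description Strict readers/writers for the plain-text formats the
#'   pipeline exchanges: VCF v4.2, SAM, FASTA, BED, TSV tables, dense and
#'   COO contact matrices, and the JSON truth ledger. Coordinates are
#'   converted at these boundaries: VCF/SAM positions are 1-based, BED is
#'   0-based half-open, and all internal interval arithmetic is 0-based
#'   half-open.
#' @name regulomap-io
NULL

io_error <- function(msg, line = NULL) {
  if (!is.null(line)) msg <- sprintf("%s (line %d)", msg, line)
  stop(errorCondition(msg, class = c("regulomap_io_error", "error")))
}

# readLines with CRLF / trailing-whitespace tolerance
read_clean_lines <- function(path) {
  if (!file.exists(path)) io_error(sprintf("file not found: %s", path))
  sub("[ \t\r]+$", "", readLines(path, warn = FALSE))
}

#' Write variants (and optional dosages) as VCF v4.2
#'
#' MAF and imputation INFO scores are stored as \code{MAF=}/\code{INFO=}
#' keys in the INFO column. When a dosage matrix is supplied it is written
#' as a per-sample \code{DS} FORMAT field.
#'
#' @param variants data.frame with columns \code{id, chrom, pos, ref, alt,
#'   maf, info} (\code{pos} 1-based).
#' @param path output path.
#' @param dosages optional samples x variants matrix of dosages in [0, 2].
#' @export
write_vcf <- function(variants, path, dosages = NULL) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=MAF,Number=1,Type=Float,Description=\"Minor allele frequency\">",
    "##INFO=<ID=INFO,Number=1,Type=Float,Description=\"Imputation quality\">"
  )
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  info_col <- sprintf("MAF=%s;INFO=%s",
                      format(variants$maf, trim = TRUE, digits = 10),
                      format(variants$info, trim = TRUE, digits = 10))
  body_cols <- list(variants$chrom, variants$pos, variants$id,
                    variants$ref, variants$alt, ".", ".", info_col)
  if (!is.null(dosages)) {
    stopifnot(ncol(dosages) == nrow(variants))
    header <- c(header,
      "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">")
    cols <- c(cols, "FORMAT", rownames(dosages))
    body_cols <- c(body_cols, list("DS"))
    for (s in seq_len(nrow(dosages))) {
      body_cols <- c(body_cols,
                     list(format(dosages[s, ], trim = TRUE, digits = 10)))
    }
  }
  body <- do.call(paste, c(body_cols, sep = "\t"))
  writeLines(c(header, paste(cols, collapse = "\t"), body), path)
  invisible(path)
}

#' Read a VCF v4.2 file
#'
#' Returns the variant table and, when sample columns are present, a dosage
#' matrix taken from \code{DS} if available, otherwise from \code{GT}
#' (counting alternate alleles).
#'
#' @param path VCF path.
#' @return list with \code{variants} (data.frame) and \code{dosages}
#'   (matrix or NULL).
#' @export
read_vcf <- function(path) {
  lines <- read_clean_lines(path)
  hdr_idx <- grep("^#CHROM", lines)
  if (length(hdr_idx) != 1) io_error("missing #CHROM header line")
  cols <- strsplit(lines[hdr_idx], "\t", fixed = TRUE)[[1]]
  body_idx <- which(seq_along(lines) > hdr_idx & nzchar(lines))
  n <- length(body_idx)
  fields <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) != length(cols))
  if (length(bad) > 0) {
    io_error("wrong number of VCF columns", line = body_idx[bad[1]])
  }
  mat <- do.call(rbind, fields)
  info_get <- function(info, key) {
    m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]*"), info))
    out <- rep(NA_real_, length(info))
    hit <- vapply(m, length, 1L) == 1
    out[hit] <- as.numeric(sub(paste0(".*", key, "="), "", unlist(m[hit])))
    out
  }
  pos <- suppressWarnings(as.integer(mat[, 2]))
  if (anyNA(pos)) io_error("non-integer POS", line = body_idx[which(is.na(pos))[1]])
  variants <- data.frame(
    id = mat[, 3], chrom = mat[, 1], pos = pos,
    ref = mat[, 4], alt = mat[, 5],
    maf = info_get(mat[, 8], "MAF"),
    info = info_get(mat[, 8], "INFO"),
    stringsAsFactors = FALSE
  )
  dosages <- NULL
  if (length(cols) > 9) {
    fmt <- strsplit(mat[, 9], ":", fixed = TRUE)
    samples <- cols[10:length(cols)]
    dosages <- matrix(NA_real_, nrow = length(samples), ncol = n,
                      dimnames = list(samples, variants$id))
    for (v in seq_len(n)) {
      keys <- fmt[[v]]
      vals <- strsplit(mat[v, 10:length(cols)], ":", fixed = TRUE)
      pick <- function(key) vapply(vals, function(x) x[match(key, keys)], "")
      if ("DS" %in% keys) {
        dosages[, v] <- as.numeric(pick("DS"))
      } else if ("GT" %in% keys) {
        gt <- pick("GT")
        alleles <- strsplit(gt, "[/|]")
        dosages[, v] <- vapply(alleles, function(a) {
          a <- suppressWarnings(as.integer(a))
          if (anyNA(a)) NA_real_ else sum(a > 0)
        }, 0)
      } else {
        io_error("no DS or GT field in FORMAT", line = body_idx[v])
      }
    }
  }
  list(variants = variants, dosages = dosages)
}

#' Write alignment records as a SAM file
#'
#' @param records data.frame with columns \code{qname, flag, chrom, pos,
#'   mapq, cigar, seq, qual} (\code{pos} 1-based leftmost).
#' @param contigs named integer vector of contig lengths for the header.
#' @param path output path.
#' @export
write_sam <- function(records, contigs, path) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(contigs),
                      as.integer(contigs)))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                  records$qname, as.integer(records$flag), records$chrom,
                  as.integer(records$pos), as.integer(records$mapq),
                  records$cigar, records$seq, records$qual)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a BED file of genomic intervals
#'
#' Accepts 3-6 column BED (0-based half-open), tolerating CRLF line endings
#' and trailing whitespace. Returns a \code{GRanges} (1-based closed, the
#' Bioconductor convention), so a BED line \code{chr1 99 100} becomes the
#' single base 100.
#'
#' @param path BED path.
#' @return a \code{GenomicRanges::GRanges}, with \code{name}/\code{score}
#'   metadata columns when present.
#' @export
read_bed <- function(path) {
  lines <- read_clean_lines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                 !startsWith(lines, "track") & !startsWith(lines, "browser")]
  if (length(lines) == 0) {
    return(GenomicRanges::GRanges())
  }
  fields <- strsplit(lines, "[\t ]+")
  nf <- vapply(fields, length, 1L)
  if (any(nf < 3)) io_error("BED line with fewer than 3 fields",
                            line = which(nf < 3)[1])
  chrom <- vapply(fields, `[`, "", 1L)
  start0 <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
  end0 <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
  if (anyNA(start0) || anyNA(end0)) {
    io_error("non-integer BED coordinate",
             line = which(is.na(start0) | is.na(end0))[1])
  }
  bad <- which(start0 >= end0)
  if (length(bad) > 0) {
    io_error(sprintf("malformed interval: start %d >= end %d",
                     start0[bad[1]], end0[bad[1]]), line = bad[1])
  }
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start0 + 1L, end0))
  if (all(nf >= 4)) gr$name <- vapply(fields, `[`, "", 4L)
  if (all(nf >= 5)) {
    gr$score <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 5L)))
  }
  gr
}

#' Write a GRanges as BED (0-based half-open)
#'
#' @param gr a \code{GRanges}; \code{name} metadata column written when
#'   present.
#' @param path output path.
#' @export
write_bed <- function(gr, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
  if (!is.null(gr$name)) df$name <- gr$name
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write / read a contact matrix
#'
#' Dense TSV stores the full symmetric count matrix; COO stores one
#' \code{bin_i bin_j count} triplet per line for the upper triangle
#' (0-based bins). Metadata (chrom, offset, bin size) travels in comment
#' headers.
#'
#' @param cm a \code{contact_matrix}.
#' @param path output path.
#' @param format \code{"dense"} or \code{"coo"}.
#' @export
write_contact_matrix <- function(cm, path, format = c("dense", "coo")) {
  format <- match.arg(format)
  meta <- sprintf("#chrom=%s offset=%d bin_size=%d n_bins=%d",
                  cm$chrom, cm$offset, cm$bin_size, nrow(cm$counts))
  if (format == "dense") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(meta, con)
    utils::write.table(cm$counts, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    idx <- which(upper.tri(cm$counts, diag = TRUE) & cm$counts != 0,
                 arr.ind = TRUE)
    lines <- sprintf("%d\t%d\t%s", idx[, 1] - 1L, idx[, 2] - 1L,
                     format(cm$counts[idx], trim = TRUE, digits = 12))
    writeLines(c(meta, lines), path)
  }
  invisible(path)
}

#' @rdname write_contact_matrix
#' @param path path of a dense or COO contact-matrix file (auto-detected).
#' @export
read_contact_matrix <- function(path) {
  lines <- read_clean_lines(path)
  meta_line <- lines[startsWith(lines, "#")][1]
  if (is.na(meta_line)) io_error("missing contact-matrix metadata header")
  get_meta <- function(key) {
    m <- regmatches(meta_line, regexpr(paste0(key, "=[^ ]+"), meta_line))
    if (length(m) == 0) io_error(sprintf("missing metadata key '%s'", key))
    sub(paste0(key, "="), "", m)
  }
  chrom <- get_meta("chrom")
  offset <- as.integer(get_meta("offset"))
  bin_size <- as.integer(get_meta("bin_size"))
  n_bins <- as.integer(get_meta("n_bins"))
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  nfield <- length(strsplit(body[1], "\t", fixed = TRUE)[[1]])
  dense_ok <- FALSE
  if (length(body) == n_bins && nfield == n_bins) {
    counts <- as.matrix(utils::read.table(text = body, sep = "\t"))
    dimnames(counts) <- NULL
    # a tiny COO file can masquerade as dense; symmetry disambiguates
    dense_ok <- isTRUE(all.equal(counts, t(counts)))
  }
  if (!dense_ok && nfield == 3) {
    # COO upper-triangle triplets, 0-based bins
    trip <- utils::read.table(text = body, sep = "\t",
                              col.names = c("i", "j", "count"))
    if (any(trip$i < 0 | trip$j < 0 | trip$i >= n_bins |
            trip$j >= n_bins)) {
      io_error("COO bin index outside matrix")
    }
    counts <- matrix(0, n_bins, n_bins)
    counts[cbind(trip$i + 1L, trip$j + 1L)] <- trip$count
    counts[cbind(trip$j + 1L, trip$i + 1L)] <- trip$count
  } else if (!dense_ok) {
    io_error("contact matrix shape does not match metadata")
  }
  contact_matrix(counts, chrom = chrom, offset = offset,
                 bin_size = bin_size)
}

#' Write / read a plain TSV table with a header row
#'
#' @param df data.frame.
#' @param path file path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) io_error(sprintf("file not found: %s", path))
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

#' Serialize / restore a truth ledger
#'
#' Every generator attaches a \code{truth_record}: the planted parameters a
#' downstream test needs to score recovery. The ledger round-trips through
#' JSON losslessly.
#'
#' @param truth a \code{truth_record} list.
#' @param path JSON path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  truth <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(truth, class = "truth_record")
}
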