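#' Call SNPs per line from a pooled pileup
#'
#' Applies the read-count rule: a SNP is called at a position when at least
#' `threshold` reads carry a non-reference allele in at least one line's pool.
#' For each detected SNP, a per-line reference-agreement score is attached:
#' `S = ref_reads / (ref_reads + nonref_reads)` in a line where the SNP was
#' detected, and exactly `S = 1` in a line where it was not -- that line is
#' assumed fixed for the reference allele. Sites with no reference-supporting
#' read in either line are flagged `excluded`: they carry no information about
#' which line diverged from the reference and are left out of flanking-window
#' sums downstream (they still appear in variation-class tallies).
#'
#' @param pileup Data.frame with columns `chrom`, `pos`, `line` (`"high"` /
#'   `"low"`), `ref_reads`, `nonref_reads`, one row per (position, line);
#'   a missing line row is treated as zero depth.
#' @param threshold Minimum non-reference read count for detection (default 3).
#' @return A data.frame of SNP calls sorted by `chrom`, `pos` with columns
#'   `chrom`, `pos`, `detected_high`, `detected_low`, `S_high`, `S_low`,
#'   `depth_high`, `depth_low`, `ref_high`, `ref_low`, `nonref_high`,
#'   `nonref_low`, `variation_class`, `excluded`. Positions where neither line
#'   reaches the threshold are not emitted.
#' @examples
#' pu <- data.frame(chrom = "chr1", pos = c(100, 100, 200, 200),
#'                  line = c("high", "low", "high", "low"),
#'                  ref_reads = c(4, 6, 5, 5), nonref_reads = c(3, 0, 2, 2))
#' call_pool_snps(pu)
#' @export
call_pool_snps <- function(pileup, threshold = 3L) {
  stopifnot(threshold >= 1)
  check_pileup(pileup)
  wide <- pileup_to_wide(pileup)

  det_h <- wide$nonref_high >= threshold
  det_l <- wide$nonref_low >= threshold
  keep <- det_h | det_l
  wide <- wide[keep, , drop = FALSE]
  det_h <- det_h[keep]
  det_l <- det_l[keep]

  depth_h <- wide$ref_high + wide$nonref_high
  depth_l <- wide$ref_low + wide$nonref_low
  S_h <- ifelse(det_h, wide$ref_high / depth_h, 1)
  S_l <- ifelse(det_l, wide$ref_low / depth_l, 1)

  calls <- data.frame(
    chrom = wide$chrom, pos = wide$pos,
    detected_high = det_h, detected_low = det_l,
    S_high = S_h, S_low = S_l,
    depth_high = depth_h, depth_low = depth_l,
    ref_high = wide$ref_high, ref_low = wide$ref_low,
    nonref_high = wide$nonref_high, nonref_low = wide$nonref_low,
    stringsAsFactors = FALSE
  )
  calls$variation_class <- classify_variation(calls, threshold = threshold)
  calls$excluded <- calls$ref_high == 0 & calls$ref_low == 0
  calls <- calls[order(calls$chrom, calls$pos), , drop = FALSE]
  rownames(calls) <- NULL
  calls
}

#' Call a single site from its two per-line pileup records
#'
#' Convenience wrapper around [call_pool_snps()] for one position. Both
#' records must share the same coordinates.
#'
#' @param rec_high,rec_low One-row data.frames (or named lists) with `chrom`,
#'   `pos`, `ref_reads`, `nonref_reads`. Pass `NULL` for a line with no reads
#'   at the position.
#' @param threshold Minimum non-reference read count for detection.
#' @return A one-row call data.frame as in [call_pool_snps()], or `NULL` when
#'   neither line reaches the threshold (no call).
#' @export
call_site <- function(rec_high, rec_low, threshold = 3L) {
  recs <- list(high = rec_high, low = rec_low)
  recs <- recs[!vapply(recs, is.null, logical(1))]
  if (length(recs) == 0) stop("both line records missing", call. = FALSE)
  coords <- unique(do.call(rbind, lapply(recs, function(r) {
    data.frame(chrom = r$chrom, pos = r$pos, stringsAsFactors = FALSE)
  })))
  if (nrow(coords) != 1) {
    stop("rec_high and rec_low have mismatched coordinates", call. = FALSE)
  }
  pu <- do.call(rbind, lapply(names(recs), function(ln) {
    r <- recs[[ln]]
    data.frame(chrom = r$chrom, pos = r$pos, line = ln,
               ref_reads = r$ref_reads, nonref_reads = r$nonref_reads,
               stringsAsFactors = FALSE)
  }))
  out <- call_pool_snps(pu, threshold = threshold)
  if (nrow(out) == 0) NULL else out
}

#' Classify within-line variation of detected SNPs
#'
#' Assigns each detected call to one of four classes describing how the two
#' line pools vary against the reference:
#' \describe{
#'   \item{both_all_nonref}{no reference-supporting read in either line;}
#'   \item{one_all_nonref}{all reads differ from the reference in exactly one
#'     line and the other line shows no above-threshold non-reference
#'     evidence;}
#'   \item{one_biallelic}{exactly one line carries both reference reads and
#'     an above-threshold non-reference count;}
#'   \item{both_biallelic}{both lines do.}
#' }
#' The four classes partition the detected call set.
#'
#' @param calls A call data.frame from [call_pool_snps()] (the per-line read
#'   count columns are used).
#' @param threshold The detection threshold the calls were made with.
#' @return Character vector of class labels, one per row of `calls`.
#' @export
classify_variation <- function(calls, threshold = 3L) {
  det_h <- calls$nonref_high >= threshold
  det_l <- calls$nonref_low >= threshold
  if (any(!det_h & !det_l)) {
    stop("classify_variation() requires calls detected in at least one line",
         call. = FALSE)
  }
  bi_h <- det_h & calls$ref_high > 0
  bi_l <- det_l & calls$ref_low > 0
  n_bi <- bi_h + bi_l
  ifelse(calls$ref_high == 0 & calls$ref_low == 0, "both_all_nonref",
         ifelse(n_bi == 2, "both_biallelic",
                ifelse(n_bi == 1, "one_biallelic", "one_all_nonref")))
}

#' Detected SNP density per kb, overall and per chromosome class
#'
#' @param calls Call data.frame from [call_pool_snps()].
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp.
#' @param class_map Named character vector mapping chromosome to
#'   `"macro"` / `"intermediate"` / `"micro"`; optional.
#' @return Data.frame with columns `scope` (`"overall"` or a class name),
#'   `n_snps`, `length_kb`, `snps_per_kb`. Classes with no sequence in
#'   `chrom_lengths` are reported with density 0 and a warning.
#' @examples
#' calls <- data.frame(chrom = "chr1", pos = 1:370)
#' snp_density(calls, c(chr1 = 1e5))
#' @export
snp_density <- function(calls, chrom_lengths, class_map = NULL) {
  if (nrow(calls) == 0) stop("empty call set", call. = FALSE)
  if (sum(chrom_lengths) <= 0) stop("zero-length genome", call. = FALSE)
  out <- data.frame(scope = "overall", n_snps = nrow(calls),
                    length_kb = sum(chrom_lengths) / 1000,
                    stringsAsFactors = FALSE)
  if (!is.null(class_map)) {
    for (cls in intersect(c("macro", "intermediate", "micro"), class_map)) {
      chroms <- names(class_map)[class_map == cls]
      len <- sum(chrom_lengths[names(chrom_lengths) %in% chroms])
      n <- sum(calls$chrom %in% chroms)
      if (len == 0) {
        warning(sprintf("chromosome class '%s' has no sequence; density 0", cls))
        out <- rbind(out, data.frame(scope = cls, n_snps = n, length_kb = 0,
                                     stringsAsFactors = FALSE))
      } else {
        out <- rbind(out, data.frame(scope = cls, n_snps = n,
                                     length_kb = len / 1000,
                                     stringsAsFactors = FALSE))
      }
    }
  }
  out$snps_per_kb <- ifelse(out$length_kb > 0, out$n_snps / out$length_kb, 0)
  out
}

#' Tabulate variation classes of a call set
#'
#' Counts and fractions per variation class, in the style of a per-class SNP
#' variation summary table.
#'
#' @param calls Call data.frame from [call_pool_snps()].
#' @return Data.frame with `variation_class`, `n_snps`, `fraction`.
#' @export
variation_table <- function(calls) {
  lv <- c("both_all_nonref", "one_all_nonref", "one_biallelic",
          "both_biallelic")
  tab <- table(factor(calls$variation_class, levels = lv))
  data.frame(variation_class = lv, n_snps = as.integer(tab),
             fraction = as.numeric(tab) / max(1, nrow(calls)),
             stringsAsFactors = FALSE)
}

check_pileup <- function(pileup) {
  need <- c("chrom", "pos", "line", "ref_reads", "nonref_reads")
  miss <- setdiff(need, names(pileup))
  if (length(miss) > 0) {
    stop("pileup is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(pileup$ref_reads < 0) || any(pileup$nonref_reads < 0)) {
    stop("negative read counts in pileup", call. = FALSE)
  }
  if (!all(pileup$line %in% c("high", "low"))) {
    stop("pileup line must be 'high' or 'low'", call. = FALSE)
  }
  key <- paste(pileup$chrom, pileup$pos, pileup$line)
  if (anyDuplicated(key)) {
    stop("duplicated (chrom, pos, line) in pileup", call. = FALSE)
  }
  invisible(pileup)
}

# long (chrom,pos,line) pileup -> one row per position with per-line counts;
# a missing line record means zero depth in that line
pileup_to_wide <- function(pileup) {
  h <- pileup[pileup$line == "high", c("chrom", "pos", "ref_reads", "nonref_reads")]
  l <- pileup[pileup$line == "low", c("chrom", "pos", "ref_reads", "nonref_reads")]
  names(h)[3:4] <- c("ref_high", "nonref_high")
  names(l)[3:4] <- c("ref_low", "nonref_low")
  wide <- merge(h, l, by = c("chrom", "pos"), all = TRUE)
  for (col in c("ref_high", "nonref_high", "ref_low", "nonref_low")) {
    wide[[col]][is.na(wide[[col]])] <- 0L
  }
  wide
}
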