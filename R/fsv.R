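#' The standard flanking-window grid
#'
#' Total flanking-window widths (bp) conventionally scanned when searching for
#' the window size that best predicts between-line SNP variability:
#' 2, 8, 14, 20, 26, 32, 38, 44, 50, 56, 62, 68, 74 and 128 kb.
#'
#' @return Integer vector of 14 total window widths in bp, ascending.
#' @export
fsv_window_grid <- function() {
  as.integer(c(2, 8, 14, 20, 26, 32, 38, 44, 50, 56, 62, 68, 74, 128) * 1000)
}

#' Flanking SNPs Value at a single focal position
#'
#' Direct evaluation of the flanking SNPs value (FSV). The flanking set is
#' every detected, non-excluded SNP call whose position lies within
#' `window_total / 2` bp of the focal position on the same chromosome (closed
#' interval, boundary ties included), excluding the focal position itself.
#' With `S_high`, `S_low` the per-line reference-agreement scores,
#'
#' \deqn{FSV = \frac{\sum_{i \in H} |S_{i,H} - S_{i,L}|}{N_H} \times
#'             \frac{\sum_{j \in L} |S_{j,L} - S_{j,H}|}{N_L}}
#'
#' where `H` and `L` are the flanking SNPs detected in the high and low line
#' respectively (a SNP detected in both lines contributes one term to each
#' sum) and `N_H`, `N_L` are their counts. Scores equal 1 in a line where a
#' SNP was not detected (fixation assumption, applied at calling time). The
#' value is undefined (not an error) when either flanking set is empty.
#'
#' @param calls Call data.frame from [call_pool_snps()], sorted by position
#'   within the chromosome.
#' @param chrom Chromosome of the focal position.
#' @param focal_pos Focal position (bp, 1-based).
#' @param window_total Total flanking window width in bp (even, positive);
#'   half extends each side of the focal SNP. Windows overhanging a chromosome
#'   end are implicitly truncated at the end.
#' @return One-row data.frame: `chrom`, `pos`, `window_total`, `N_H`, `N_L`,
#'   `mean_absdiff_H`, `mean_absdiff_L`, `fsv`, `defined`, `density_pass`.
#' @examples
#' calls <- data.frame(chrom = "chr1", pos = c(900L, 1100L),
#'                     detected_high = c(TRUE, FALSE),
#'                     detected_low = c(FALSE, TRUE),
#'                     S_high = c(0, 1), S_low = c(1, 0),
#'                     excluded = FALSE)
#' compute_fsv(calls, "chr1", 1000L, 2000L)  # maximal divergence: FSV = 1
#' @export
compute_fsv <- function(calls, chrom, focal_pos, window_total) {
  stopifnot(window_total > 0, window_total %% 2 == 0)
  cc <- calls[calls$chrom == chrom, , drop = FALSE]
  if (is.unsorted(cc$pos)) {
    stop("calls must be sorted by position within chromosome", call. = FALSE)
  }
  half <- window_total / 2
  fl <- cc[cc$pos >= focal_pos - half & cc$pos <= focal_pos + half &
             cc$pos != focal_pos & !cc$excluded, , drop = FALSE]
  absdiff <- abs(fl$S_high - fl$S_low)
  n_h <- sum(fl$detected_high)
  n_l <- sum(fl$detected_low)
  mean_h <- if (n_h > 0) sum(absdiff[fl$detected_high]) / n_h else NA_real_
  mean_l <- if (n_l > 0) sum(absdiff[fl$detected_low]) / n_l else NA_real_
  defined <- n_h >= 1 && n_l >= 1
  data.frame(
    chrom = chrom, pos = focal_pos, window_total = window_total,
    N_H = n_h, N_L = n_l,
    mean_absdiff_H = mean_h, mean_absdiff_L = mean_l,
    fsv = if (defined) mean_h * mean_l else NA_real_,
    defined = defined,
    density_pass = defined && density_filter(n_h, n_l, window_total),
    stringsAsFactors = FALSE
  )
}

#' Flanking-SNP density filter
#'
#' A flanking window is informative only when each line contributes strictly
#' more than 1 scored SNP per kb of total window; sparser windows usually
#' indicate locally poor depth coverage rather than low divergence.
#'
#' @param n_h,n_l Counts of flanking SNPs detected in the high / low line.
#' @param window_total Total window width in bp.
#' @return Logical: `TRUE` when both per-line densities exceed 1 SNP/kb.
#' @examples
#' density_filter(63, 70, 62000)  # TRUE
#' density_filter(62, 70, 62000)  # FALSE: not strictly greater
#' @export
density_filter <- function(n_h, n_l, window_total) {
  kb <- window_total / 1000
  n_h / kb > 1 & n_l / kb > 1
}

#' Flanking SNPs Values for many focal positions and window sizes
#'
#' Computes one FSV per (focal position, window width) with a single sorted
#' sweep per chromosome (cumulative sums over the eligible call set). Output
#' is identical to calling [compute_fsv()] per focal position.
#'
#' @param focal Data.frame of focal positions with columns `chrom`, `pos`.
#'   Focal positions need not themselves be called SNPs.
#' @param calls Call data.frame from [call_pool_snps()].
#' @param windows Integer vector of total window widths in bp, ascending
#'   (default [fsv_window_grid()]).
#' @return Data.frame with the columns of [compute_fsv()], one row per
#'   (focal, window), ordered by window within focal.
#' @export
fsv_scan <- function(focal, calls, windows = fsv_window_grid()) {
  stopifnot(all(windows > 0), all(windows %% 2 == 0))
  if (is.unsorted(windows)) {
    stop("windows must be sorted ascending", call. = FALSE)
  }
  if (nrow(focal) == 0) {
    return(data.frame(
      chrom = character(0), pos = integer(0), window_total = integer(0),
      N_H = integer(0), N_L = integer(0),
      mean_absdiff_H = numeric(0), mean_absdiff_L = numeric(0),
      fsv = numeric(0), defined = logical(0), density_pass = logical(0),
      stringsAsFactors = FALSE
    ))
  }
  out <- vector("list", length(unique(focal$chrom)))
  names(out) <- unique(focal$chrom)
  for (chr in unique(focal$chrom)) {
    cc <- calls[calls$chrom == chr & !calls$excluded, , drop = FALSE]
    if (is.unsorted(cc$pos)) {
      stop("calls must be sorted by position within chromosome", call. = FALSE)
    }
    fp <- focal$pos[focal$chrom == chr]
    pos <- cc$pos
    absdiff <- abs(cc$S_high - cc$S_low)
    c_nh <- c(0, cumsum(cc$detected_high))
    c_nl <- c(0, cumsum(cc$detected_low))
    c_sh <- c(0, cumsum(absdiff * cc$detected_high))
    c_sl <- c(0, cumsum(absdiff * cc$detected_low))
    # a call sitting exactly at a focal position is excluded from its own sums
    self <- match(fp, pos)
    self_nh <- ifelse(is.na(self), 0, cc$detected_high[self])
    self_nl <- ifelse(is.na(self), 0, cc$detected_low[self])
    self_sh <- ifelse(is.na(self), 0, absdiff[self] * cc$detected_high[self])
    self_sl <- ifelse(is.na(self), 0, absdiff[self] * cc$detected_low[self])

    per_win <- vector("list", length(windows))
    for (w in seq_along(windows)) {
      half <- windows[w] / 2
      i_lo <- findInterval(fp - half - 0.5, pos)
      i_hi <- findInterval(fp + half + 0.5, pos)
      n_h <- as.integer(c_nh[i_hi + 1] - c_nh[i_lo + 1] - self_nh)
      n_l <- as.integer(c_nl[i_hi + 1] - c_nl[i_lo + 1] - self_nl)
      s_h <- c_sh[i_hi + 1] - c_sh[i_lo + 1] - self_sh
      s_l <- c_sl[i_hi + 1] - c_sl[i_lo + 1] - self_sl
      mean_h <- ifelse(n_h > 0, s_h / n_h, NA_real_)
      mean_l <- ifelse(n_l > 0, s_l / n_l, NA_real_)
      defined <- n_h >= 1 & n_l >= 1
      per_win[[w]] <- data.frame(
        chrom = chr, pos = fp, window_total = windows[w],
        N_H = n_h, N_L = n_l,
        mean_absdiff_H = mean_h, mean_absdiff_L = mean_l,
        fsv = ifelse(defined, mean_h * mean_l, NA_real_),
        defined = defined,
        density_pass = defined & density_filter(n_h, n_l, windows[w]),
        stringsAsFactors = FALSE
      )
    }
    out[[chr]] <- do.call(rbind, per_win)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$pos, res$window_total), , drop = FALSE]
  rownames(res) <- NULL
  res
}
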