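#' Summarize chip genotypes per SNP
#'
#' Computes per-line non-reference allele frequencies, the joint call
#' frequency, polymorphism status, and the between-line allele-frequency
#' difference from the individual genotype matrices of the two lines.
#'
#' @param chip An `fsv_chip` object from [simulate_chip()], or any list with
#'   `sites` (data.frame `chrom`, `pos`) and dosage matrices `high`, `low`
#'   (rows = SNPs, values 0/1/2 with `NA` for no-calls).
#' @param min_call_freq SNPs must have a call frequency (fraction of
#'   non-missing genotypes across both lines jointly) strictly above this to
#'   be usable downstream (default 0.95).
#' @return Data.frame with one row per SNP: `chrom`, `pos`, `freq_high`,
#'   `freq_low`, `call_freq`, `polymorphic`, `delta_p`, `usable`. A SNP with
#'   zero non-missing calls in a line gets `NA` frequencies and
#'   `usable = FALSE` rather than an error. `polymorphic` is `FALSE` only when
#'   every non-missing dosage across both lines is the same homozygote.
#'   `delta_p = |freq_high - freq_low|`.
#' @examples
#' chip <- list(sites = data.frame(chrom = "chr1", pos = c(10L, 20L)),
#'              high = rbind(c(2L, 2L), c(0L, 0L)),
#'              low = rbind(c(0L, 0L), c(0L, 0L)))
#' summarize_chip(chip)
#' @export
summarize_chip <- function(chip, min_call_freq = 0.95) {
  g_h <- chip$high
  g_l <- chip$low
  stopifnot(nrow(g_h) == nrow(chip$sites), nrow(g_l) == nrow(chip$sites))
  n_h <- rowSums(!is.na(g_h))
  n_l <- rowSums(!is.na(g_l))
  freq_h <- ifelse(n_h > 0, rowSums(g_h, na.rm = TRUE) / (2 * n_h), NA_real_)
  freq_l <- ifelse(n_l > 0, rowSums(g_l, na.rm = TRUE) / (2 * n_l), NA_real_)
  call_freq <- (n_h + n_l) / (ncol(g_h) + ncol(g_l))

  # monomorphic only if all non-missing dosages are one homozygote class
  all_joint <- cbind(g_h, g_l)
  rng_min <- suppressWarnings(apply(all_joint, 1, min, na.rm = TRUE))
  rng_max <- suppressWarnings(apply(all_joint, 1, max, na.rm = TRUE))
  mono <- is.finite(rng_min) & rng_min == rng_max & rng_min %in% c(0L, 2L)

  out <- data.frame(
    chrom = chip$sites$chrom, pos = chip$sites$pos,
    freq_high = freq_h, freq_low = freq_l,
    call_freq = call_freq,
    polymorphic = !mono,
    delta_p = abs(freq_h - freq_l),
    stringsAsFactors = FALSE
  )
  out$usable <- out$call_freq > min_call_freq & n_h > 0 & n_l > 0
  out
}

#' Assign a non-reference allele frequency to a 10%-wide bin
#'
#' Bins span `[0, 0.1), [0.1, 0.2), ..., [0.9, 1.0]`; the top bin is closed on
#' the right so a frequency of exactly 1 belongs to `0.9-1.0`.
#'
#' @param freq Numeric vector of non-reference allele frequencies in `[0, 1]`.
#' @param bin_width Bin width (default 0.1).
#' @return Factor of bin labels of the form `"0.5-0.6"`, ordered by frequency.
#' @examples
#' nonref_frequency_bin(c(0.55, 1.0))
#' @export
nonref_frequency_bin <- function(freq, bin_width = 0.1) {
  if (any(!is.na(freq) & (freq < 0 | freq > 1))) {
    stop("frequencies must lie in [0, 1]", call. = FALSE)
  }
  n_bins <- ceiling(1 / bin_width)
  idx <- pmin(floor(freq / bin_width), n_bins - 1)
  lo <- (seq_len(n_bins) - 1) * bin_width
  labels <- sprintf("%.1f-%.1f", lo, lo + bin_width)
  factor(labels[idx + 1], levels = labels)
}
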