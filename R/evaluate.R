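#' Closed-form SNP detection power under Poisson depth
#'
#' Probability that a pooled site with non-reference pool frequency `q`
#' accumulates at least `threshold` non-reference reads when depth is
#' `Poisson(mean_depth)` and each read miscalls with probability `error`.
#' By Poisson thinning the non-reference read count is
#' `Poisson(mean_depth * q')` with `q' = q(1-e) + (1-q)e`, so the power is
#' the upper tail `1 - P(X < threshold)`.
#'
#' @param mean_depth Expected reads per site (lambda), > 0. Vectorized.
#' @param q Non-reference allele frequency in the pool, in `[0, 1]`.
#' @param threshold Minimum non-reference read count for detection
#'   (default 3, must be >= 1).
#' @param error Per-read miscall probability (default 0).
#' @return Numeric vector of detection probabilities.
#' @examples
#' detection_power(5.19, 1)          # ~0.890
#' detection_power(5.19, seq(0, 1, 0.1))
#' @export
detection_power <- function(mean_depth, q, threshold = 3L, error = 0) {
  if (any(threshold < 1)) stop("threshold must be >= 1", call. = FALSE)
  stopifnot(all(mean_depth > 0), all(q >= 0 & q <= 1),
            all(error >= 0 & error <= 1))
  q_eff <- q * (1 - error) + (1 - q) * error
  1 - stats::ppois(threshold - 1, mean_depth * q_eff)
}

#' Detection sensitivity by non-reference allele frequency bin
#'
#' Joins chip SNP summaries to the pooled SNP calls by position and reports,
#' per frequency bin, the fraction of chip SNPs at which pooled resequencing
#' detected a SNP in the corresponding line. Each line contributes one
#' observation per chip SNP (binned by that line's own chip frequency);
#' `"pooled"` rows aggregate both lines' observations.
#'
#' @param chip_summary Data.frame from [summarize_chip()]. Only usable,
#'   polymorphic SNPs enter the table.
#' @param calls Call data.frame from [call_pool_snps()]. Chip SNPs absent
#'   from the call table count as undetected.
#' @param bin_width Frequency bin width (default 0.1).
#' @return Data.frame with `line` (`"high"`, `"low"`, `"pooled"`), `bin`,
#'   `n_chip_snps`, `n_detected`, `fraction_detected`.
#' @export
sensitivity <- function(chip_summary, calls, bin_width = 0.1) {
  cs <- chip_summary[chip_summary$usable & chip_summary$polymorphic, ,
                     drop = FALSE]
  if (nrow(cs) == 0) stop("no usable polymorphic chip SNPs", call. = FALSE)
  key_calls <- paste(calls$chrom, calls$pos)
  idx <- match(paste(cs$chrom, cs$pos), key_calls)
  if (all(is.na(idx)) && nrow(calls) > 0) {
    stop("no chip positions overlap the call table", call. = FALSE)
  }
  det_h <- !is.na(idx) & calls$detected_high[ifelse(is.na(idx), 1L, idx)]
  det_l <- !is.na(idx) & calls$detected_low[ifelse(is.na(idx), 1L, idx)]

  obs <- rbind(
    data.frame(line = "high", freq = cs$freq_high, detected = det_h,
               stringsAsFactors = FALSE),
    data.frame(line = "low", freq = cs$freq_low, detected = det_l,
               stringsAsFactors = FALSE)
  )
  obs$bin <- nonref_frequency_bin(obs$freq, bin_width)
  tab_line <- function(o, label) {
    n <- tapply(o$detected, o$bin, length)
    d <- tapply(o$detected, o$bin, sum)
    n[is.na(n)] <- 0
    d[is.na(d)] <- 0
    data.frame(line = label, bin = factor(levels(o$bin), levels = levels(o$bin)),
               n_chip_snps = as.integer(n), n_detected = as.integer(d),
               fraction_detected = ifelse(n > 0, d / n, NA_real_),
               stringsAsFactors = FALSE)
  }
  out <- rbind(tab_line(obs[obs$line == "high", ], "high"),
               tab_line(obs[obs$line == "low", ], "low"),
               tab_line(obs, "pooled"))
  rownames(out) <- NULL
  out
}

#' Mean FSV stratified by between-line allele-frequency difference
#'
#' Joins chip summaries to FSV results on (chromosome, position) and reports
#' mean FSV with its standard error per `delta_p` bin, using only rows with a
#' defined FSV that pass the flanking-density filter.
#'
#' @param chip_summary Data.frame from [summarize_chip()].
#' @param fsv_results FSV table from [fsv_scan()]; if several window sizes are
#'   present, supply `window_total` to pick one.
#' @param bin_width Width of the `delta_p` bins (default 0.1).
#' @param window_total Optional window width (bp) to restrict `fsv_results` to.
#' @return Data.frame with `bin`, `n`, `mean_fsv`, `se_fsv` (empty bins keep
#'   `n = 0` and `NA` statistics).
#' @export
fsv_by_delta_bins <- function(chip_summary, fsv_results, bin_width = 0.1,
                              window_total = NULL) {
  if (!is.null(window_total)) {
    fsv_results <- fsv_results[fsv_results$window_total == window_total, ,
                               drop = FALSE]
  }
  joined <- join_chip_fsv(chip_summary, fsv_results)
  joined$bin <- nonref_frequency_bin(joined$delta_p, bin_width)
  n <- tapply(joined$fsv, joined$bin, length)
  m <- tapply(joined$fsv, joined$bin, mean)
  se <- tapply(joined$fsv, joined$bin, function(x) {
    if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
  })
  n[is.na(n)] <- 0
  data.frame(bin = factor(levels(joined$bin), levels = levels(joined$bin)),
             n = as.integer(n), mean_fsv = as.numeric(m),
             se_fsv = as.numeric(se), stringsAsFactors = FALSE)
}

#' Pearson correlation between FSV and chip allele-frequency difference
#'
#' For each chromosome size class (and all chromosomes jointly) and each
#' window width present in the FSV table, computes the Pearson
#' product-moment correlation between FSV and `delta_p` over chip SNPs whose
#' between-line difference exceeds `delta_min`, restricted to defined,
#' density-passing FSV rows. Also reports, per class, the window with the
#' strongest correlation.
#'
#' @param chip_summary Data.frame from [summarize_chip()].
#' @param fsv_results Multi-window FSV table from [fsv_scan()].
#' @param delta_min Strict lower bound on `delta_p` (default 0.4). Use `NULL`
#'   (or a negative value) to include all SNPs.
#' @param class_map Named character vector mapping chromosome to
#'   `"macro"` / `"intermediate"` / `"micro"`; `NULL` gives only the joint
#'   `"all"` stratum.
#' @return List of class `fsv_corr_scan` with `scan` (data.frame: `class`,
#'   `window_total`, `n`, `pearson_r`, `p_value`; strata with fewer than 3
#'   rows or zero variance keep `NA` statistics) and `best` (per-class argmax
#'   window, `NA` where no stratum was defined).
#' @export
correlation_scan <- function(chip_summary, fsv_results, delta_min = 0.4,
                             class_map = NULL) {
  joined <- join_chip_fsv(chip_summary, fsv_results)
  if (!is.null(delta_min)) {
    joined <- joined[joined$delta_p > delta_min, , drop = FALSE]
  }
  joined$class <- if (is.null(class_map)) rep("all", nrow(joined)) else
    unname(class_map[joined$chrom])
  classes <- unique(c("all", stats::na.omit(joined$class)))
  windows <- sort(unique(fsv_results$window_total))

  rows <- list()
  for (cls in classes) {
    sub_c <- if (cls == "all") joined else
      joined[!is.na(joined$class) & joined$class == cls, , drop = FALSE]
    for (w in windows) {
      sub <- sub_c[sub_c$window_total == w, , drop = FALSE]
      r <- p <- NA_real_
      if (nrow(sub) >= 3 && stats::sd(sub$fsv) > 0 &&
          stats::sd(sub$delta_p) > 0) {
        ct <- stats::cor.test(sub$fsv, sub$delta_p, method = "pearson")
        r <- unname(ct$estimate)
        p <- ct$p.value
      }
      rows[[length(rows) + 1]] <- data.frame(
        class = cls, window_total = w, n = nrow(sub),
        pearson_r = r, p_value = p, stringsAsFactors = FALSE
      )
    }
  }
  scan <- do.call(rbind, rows)
  best <- do.call(rbind, lapply(classes, function(cls) {
    s <- scan[scan$class == cls & !is.na(scan$pearson_r), , drop = FALSE]
    if (nrow(s) == 0) {
      data.frame(class = cls, window_total = NA_integer_,
                 pearson_r = NA_real_, stringsAsFactors = FALSE)
    } else {
      s[which.max(s$pearson_r), c("class", "window_total", "pearson_r")]
    }
  }))
  rownames(best) <- NULL
  out <- list(scan = scan, best = best, delta_min = delta_min)
  class(out) <- "fsv_corr_scan"
  out
}

#' @export
print.fsv_corr_scan <- function(x, ...) {
  cat(sprintf("FSV / delta_p Pearson correlation scan (delta_p > %s)\n",
              if (is.null(x$delta_min)) "none" else format(x$delta_min)))
  cat("strongest window per stratum:\n")
  b <- x$best
  for (i in seq_len(nrow(b))) {
    cat(sprintf("  %-12s r = %.3f at %s kb\n", b$class[i], b$pearson_r[i],
                format(b$window_total[i] / 1000)))
  }
  invisible(x)
}

# inner join of chip summaries and FSV rows on (chrom, pos), with the
# usable / polymorphic / defined / density filters applied
join_chip_fsv <- function(chip_summary, fsv_results) {
  cs <- chip_summary[chip_summary$usable & chip_summary$polymorphic &
                       !is.na(chip_summary$delta_p),
                     c("chrom", "pos", "delta_p"), drop = FALSE]
  fr <- fsv_results[fsv_results$defined & fsv_results$density_pass, ,
                    drop = FALSE]
  merge(fr, cs, by = c("chrom", "pos"))
}
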