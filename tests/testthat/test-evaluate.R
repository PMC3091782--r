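test_that("closed-form detection power is correct at its anchors", {
  expect_equal(detection_power(5.19, 0, error = 0), 0)
  # frozen against 1 - e^-l (1 + l + l^2/2) at l = 5.19
  expect_equal(detection_power(5.19, 1), 0.8904652, tolerance = 1e-6)
  # non-decreasing in q
  pw <- detection_power(5.19, seq(0, 1, 0.1))
  expect_false(is.unsorted(pw))
  # sequencing error lifts power off zero at q = 0
  expect_gt(detection_power(5.19, 0, error = 0.01), 0)
  expect_error(detection_power(5.19, 0.5, threshold = 0), ">= 1")
})

test_that("analytic power agrees with Monte-Carlo thinning on a grid", {
  set.seed(11)
  n <- 20000
  for (lam in c(2, 5.19)) {
    for (q in c(0.2, 0.6, 1.0)) {
      depth <- rpois(n, lam)
      nonref <- rbinom(n, depth, q)
      mc <- mean(nonref >= 3)
      an <- detection_power(lam, q)
      expect_lt(abs(mc - an), 3 * sqrt(max(an * (1 - an), 1e-6) / n))
    }
  }
})

test_that("sensitivity bins chip SNPs per line and partitions the set", {
  cfg <- tiny_config(len = 2e6, seed = 23, chip_fraction = 0.2)
  tr <- simulate_truth(cfg)
  calls <- call_pool_snps(simulate_pools(tr, cfg))
  cs <- summarize_chip(simulate_chip(tr, cfg))
  sens <- sensitivity(cs, calls)
  expect_setequal(unique(sens$line), c("high", "low", "pooled"))
  n_poly <- sum(cs$usable & cs$polymorphic)
  for (ln in c("high", "low", "pooled")) {
    sub <- sens[sens$line == ln, ]
    expect_true(all(sub$n_detected <= sub$n_chip_snps))
    ok <- !is.na(sub$fraction_detected)
    expect_true(all(sub$fraction_detected[ok] >= 0 &
                      sub$fraction_detected[ok] <= 1))
  }
  # per-line observations partition: each line sees every usable polymorphic SNP
  expect_identical(sum(sens$n_chip_snps[sens$line == "high"]), n_poly)
  expect_identical(sum(sens$n_chip_snps[sens$line == "pooled"]), 2L * n_poly)
})

test_that("chip SNPs absent from the line's pool reads are never 'detected'", {
  # all SNPs fixed reference in the low line, fixed non-reference in the high
  cfg <- tiny_config(seed = 29, seq_error_rate = 0, chip_fraction = 1,
                     missing_rate = 0)
  tr <- constant_truth(1, 0, 4000, cfg)
  calls <- call_pool_snps(simulate_pools(tr, cfg))
  cs <- summarize_chip(simulate_chip(tr, cfg))
  sens <- sensitivity(cs, calls)
  low <- sens[sens$line == "low", ]
  expect_true(all(low$n_detected[low$n_chip_snps > 0] == 0))
  high <- sens[sens$line == "high", ]
  top <- high[high$bin == "0.9-1.0", ]
  # detection in the top bin tracks the analytic power at fixation
  expect_lt(abs(top$fraction_detected - detection_power(5.19, 1)), 0.03)
})

test_that("FSV means by delta_p bin report n, mean and SE per stratum", {
  fsv <- data.frame(
    chrom = "chr1", pos = c(10L, 20L, 30L, 40L), window_total = 2000L,
    N_H = 5L, N_L = 5L, mean_absdiff_H = 0.5, mean_absdiff_L = 0.5,
    fsv = c(0.25, 0.25, 0.25, 0.25), defined = TRUE, density_pass = TRUE,
    stringsAsFactors = FALSE
  )
  cs <- data.frame(
    chrom = "chr1", pos = c(10L, 20L, 30L, 40L),
    freq_high = 1, freq_low = 1, call_freq = 1, polymorphic = TRUE,
    delta_p = c(0.05, 0.05, 0.55, 0.95), usable = TRUE,
    stringsAsFactors = FALSE
  )
  out <- fsv_by_delta_bins(cs, fsv)
  expect_identical(sum(out$n), 4L)
  # identical FSVs give zero standard error wherever it is estimable
  expect_true(all(out$se_fsv[out$n > 1] == 0))
  expect_true(all(is.na(out$mean_fsv[out$n == 0])))
})

test_that("correlation scan recovers exact and null relationships", {
  set.seed(31)
  n <- 60
  dp <- runif(n, 0.41, 1)
  base <- data.frame(
    chrom = "chr1", pos = seq_len(n), window_total = 2000L,
    N_H = 5L, N_L = 5L, mean_absdiff_H = 0.5, mean_absdiff_L = 0.5,
    defined = TRUE, density_pass = TRUE, stringsAsFactors = FALSE
  )
  cs <- data.frame(chrom = "chr1", pos = seq_len(n), freq_high = 1,
                   freq_low = 0, call_freq = 1, polymorphic = TRUE,
                   delta_p = dp, usable = TRUE, stringsAsFactors = FALSE)
  # FSV identically equal to delta_p: r = 1
  perfect <- transform(base, fsv = dp)
  scan <- correlation_scan(cs, perfect)
  expect_equal(scan$scan$pearson_r, 1)
  expect_identical(scan$best$window_total, 2000L)
  # independently shuffled FSVs: r within 3 SE of zero
  shuffled <- transform(base, fsv = sample(dp))
  r0 <- correlation_scan(cs, shuffled)$scan$pearson_r
  expect_lt(abs(r0), 3 / sqrt(n))
  # zero-variance FSV: flagged undefined, not an error
  flat <- transform(base, fsv = 0.5)
  expect_true(is.na(correlation_scan(cs, flat)$scan$pearson_r))
  # strata with < 3 rows are undefined
  tiny <- correlation_scan(cs[1:2, ], perfect[1:2, ])
  expect_true(is.na(tiny$scan$pearson_r))
})

test_that("the strict delta_p filter and class strata are honoured", {
  set.seed(37)
  n <- 200
  dp <- runif(n)
  fsv <- data.frame(
    chrom = rep(c("chr1", "chr2"), each = n / 2), pos = rep(1:(n / 2), 2),
    window_total = 2000L, N_H = 5L, N_L = 5L,
    mean_absdiff_H = 0.5, mean_absdiff_L = 0.5,
    fsv = pmin(pmax(dp + rnorm(n, 0, 0.1), 0), 1),
    defined = TRUE, density_pass = TRUE, stringsAsFactors = FALSE
  )
  cs <- data.frame(chrom = fsv$chrom, pos = fsv$pos, freq_high = 1,
                   freq_low = 0, call_freq = 1, polymorphic = TRUE,
                   delta_p = dp, usable = TRUE, stringsAsFactors = FALSE)
  scan <- correlation_scan(cs, fsv, delta_min = 0.4,
                           class_map = c(chr1 = "macro", chr2 = "micro"))
  expect_setequal(unique(scan$scan$class), c("all", "macro", "micro"))
  expect_identical(scan$scan$n[scan$scan$class == "all"],
                   sum(dp > 0.4))
  # strictness: delta_p exactly at the cutoff is excluded
  cs2 <- cs
  cs2$delta_p[] <- 0.4
  expect_identical(correlation_scan(cs2, fsv)$scan$n, 0L)
})
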