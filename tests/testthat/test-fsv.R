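test_that("FSV matches hand evaluation of the flanking-window formula", {
  # two high-line SNPs with |S_H - S_L| = 0.8 and 0.4; one low-line SNP
  # with |S_L - S_H| = 1.0: FSV = ((0.8 + 0.4)/2) * (1.0/1) = 0.6
  calls <- data.frame(
    chrom = "chr1", pos = c(900L, 1050L, 1100L),
    detected_high = c(TRUE, TRUE, FALSE),
    detected_low = c(FALSE, FALSE, TRUE),
    S_high = c(0.2, 0.5, 1.0),
    S_low = c(1.0, 0.9, 0.0),
    excluded = FALSE, stringsAsFactors = FALSE
  )
  res <- compute_fsv(calls, "chr1", 1000L, 2000L)
  expect_identical(res$N_H, 2L)
  expect_identical(res$N_L, 1L)
  expect_equal(res$fsv, 0.6)
  expect_true(res$defined)

  # maximal divergence in both directions gives FSV = 1
  calls1 <- data.frame(
    chrom = "chr1", pos = c(900L, 1100L),
    detected_high = c(TRUE, FALSE), detected_low = c(FALSE, TRUE),
    S_high = c(0, 1), S_low = c(1, 0), excluded = FALSE,
    stringsAsFactors = FALSE
  )
  expect_equal(compute_fsv(calls1, "chr1", 1000L, 2000L)$fsv, 1)

  # no score differences at all: FSV = 0
  calls0 <- transform(calls1, S_low = S_high, detected_low = TRUE)
  expect_equal(compute_fsv(calls0, "chr1", 1000L, 2000L)$fsv, 0)
})

test_that("FSV handles edge rules: focal exclusion, excluded SNPs, undefined windows", {
  calls <- data.frame(
    chrom = "chr1", pos = c(980L, 1000L, 1020L),
    detected_high = TRUE, detected_low = c(TRUE, TRUE, FALSE),
    S_high = c(0.2, 0.0, 0.3), S_low = c(0.9, 1.0, 1.0),
    excluded = c(FALSE, FALSE, FALSE), stringsAsFactors = FALSE
  )
  # the focal SNP's own scores never enter the sums
  res <- compute_fsv(calls, "chr1", 1000L, 2000L)
  expect_identical(res$N_H, 2L)
  expect_equal(res$mean_absdiff_H, (0.7 + 0.7) / 2)
  # flagged-excluded flanking SNPs are dropped from both sums
  calls$excluded[1] <- TRUE
  res2 <- compute_fsv(calls, "chr1", 1000L, 2000L)
  expect_identical(res2$N_H, 1L)
  # a window with no low-line SNPs is undefined, not an error
  calls3 <- data.frame(chrom = "chr1", pos = 900L, detected_high = TRUE,
                       detected_low = FALSE, S_high = 0.5, S_low = 1,
                       excluded = FALSE, stringsAsFactors = FALSE)
  res3 <- compute_fsv(calls3, "chr1", 1000L, 2000L)
  expect_false(res3$defined)
  expect_true(is.na(res3$fsv))
  expect_false(res3$density_pass)
  # unsorted calls are an error
  expect_error(compute_fsv(calls[c(2, 1, 3), ], "chr1", 1000L, 2000L),
               "sorted")
})

test_that("boundary ties are inside the closed window", {
  calls <- data.frame(
    chrom = "chr1", pos = c(0L, 2000L),
    detected_high = TRUE, detected_low = TRUE,
    S_high = 0, S_low = 1, excluded = FALSE, stringsAsFactors = FALSE
  )
  res <- compute_fsv(calls, "chr1", 1000L, 2000L)
  expect_identical(res$N_H, 2L)
  sc <- fsv_scan(data.frame(chrom = "chr1", pos = 1000L), calls,
                 windows = 2000L)
  expect_identical(sc$N_H, 2L)
})

test_that("density filter requires strictly more than 1 SNP/kb per line", {
  expect_true(density_filter(63, 70, 62000))
  expect_false(density_filter(62, 70, 62000))
  expect_true(density_filter(3, 3, 2000))
  expect_false(density_filter(2, 3, 2000))
})

test_that("windowed sweep equals direct evaluation on randomized instances", {
  set.seed(123)
  for (rep in 1:5) {
    calls <- random_calls(300, span = 50000L)
    focal <- data.frame(
      chrom = "chrZ",
      pos = sort(unique(c(sample.int(50000L, 80),
                          sample(calls$pos, 20)))),
      stringsAsFactors = FALSE
    )
    windows <- c(2000L, 8000L, 14000L)
    sc <- fsv_scan(focal, calls, windows)
    for (w in windows) {
      direct <- do.call(rbind, lapply(focal$pos, function(p) {
        compute_fsv(calls, "chrZ", p, w)
      }))
      got <- sc[sc$window_total == w, , drop = FALSE]
      rownames(got) <- rownames(direct) <- NULL
      expect_equal(got$N_H, direct$N_H)
      expect_equal(got$N_L, direct$N_L)
      expect_equal(got$fsv, direct$fsv, tolerance = 1e-12)
      expect_equal(got$defined, direct$defined)
      expect_equal(got$density_pass, direct$density_pass)
    }
  }
})

test_that("FSV is bounded in [0,1] and symmetric under line relabeling", {
  set.seed(321)
  calls <- random_calls(500, span = 40000L)
  focal <- data.frame(chrom = "chrZ", pos = sample.int(40000L, 100))
  sc <- fsv_scan(focal, calls, windows = c(4000L, 20000L))
  ok <- !is.na(sc$fsv)
  expect_true(all(sc$fsv[ok] >= 0 & sc$fsv[ok] <= 1))
  sc_swapped <- fsv_scan(focal, swap_lines(calls), windows = c(4000L, 20000L))
  expect_equal(sc$fsv, sc_swapped$fsv)
  expect_identical(sc$N_H, sc_swapped$N_L)
})

test_that("flanking sets are nested across window sizes", {
  set.seed(55)
  calls <- random_calls(400, span = 30000L)
  focal <- data.frame(chrom = "chrZ", pos = sample.int(30000L, 50))
  sc <- fsv_scan(focal, calls, windows = c(8000L, 14000L, 28000L))
  for (p in focal$pos) {
    nh <- sc$N_H[sc$pos == p]
    nl <- sc$N_L[sc$pos == p]
    expect_false(is.unsorted(nh))
    expect_false(is.unsorted(nl))
  }
})

test_that("a flanking SNP at the current mean difference leaves the factor unchanged", {
  calls <- data.frame(
    chrom = "chr1", pos = c(900L, 950L),
    detected_high = TRUE, detected_low = FALSE,
    S_high = c(0.4, 0.8), S_low = 1, excluded = FALSE,
    stringsAsFactors = FALSE
  )
  before <- compute_fsv(calls, "chr1", 1000L, 2000L)$mean_absdiff_H
  # add a SNP whose |S_H - S_L| equals the current mean (0.4)
  extra <- data.frame(chrom = "chr1", pos = 1050L, detected_high = TRUE,
                      detected_low = FALSE, S_high = 0.6, S_low = 1,
                      excluded = FALSE, stringsAsFactors = FALSE)
  after <- compute_fsv(rbind(calls, extra), "chr1", 1000L, 2000L)$mean_absdiff_H
  expect_equal(after, before)
})

test_that("an empty focal set yields an empty table", {
  sc <- fsv_scan(data.frame(chrom = character(0), pos = integer(0)),
                 random_calls(10))
  expect_identical(nrow(sc), 0L)
  expect_true(all(c("fsv", "defined", "density_pass") %in% names(sc)))
})
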