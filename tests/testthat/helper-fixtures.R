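# shared fixture builders: everything is generated in code at test time

tiny_config <- function(len = 5e5, seed = 1L, ...) {
  sim_config(chromosome_lengths = c(chrT = len), rng_seed = seed, ...)
}

# a random but invariant-respecting call table on one chromosome:
# every row detected in >= 1 line, S = 1 exactly in undetected lines
random_calls <- function(n, chrom = "chrZ", span = 20000L) {
  pos <- sort(sample.int(span, n))
  det_h <- runif(n) < 0.6
  det_l <- runif(n) < 0.6
  neither <- !det_h & !det_l
  det_h[neither] <- TRUE
  s_h <- ifelse(det_h, runif(n), 1)
  s_l <- ifelse(det_l, runif(n), 1)
  data.frame(
    chrom = chrom, pos = pos,
    detected_high = det_h, detected_low = det_l,
    S_high = s_h, S_low = s_l,
    excluded = runif(n) < 0.05,
    stringsAsFactors = FALSE
  )
}

# relabel the two lines throughout a call table
swap_lines <- function(calls) {
  out <- calls
  out$detected_high <- calls$detected_low
  out$detected_low <- calls$detected_high
  out$S_high <- calls$S_low
  out$S_low <- calls$S_high
  out
}

# one-row pileup record
rec <- function(chrom, pos, ref, nonref) {
  data.frame(chrom = chrom, pos = pos, ref_reads = ref, nonref_reads = nonref,
             stringsAsFactors = FALSE)
}

# hand-built truth object with constant line frequencies
constant_truth <- function(p_high, p_low, n_snps, config) {
  snps <- data.frame(
    chrom = names(config$chromosome_lengths)[1],
    pos = seq_len(n_snps), block = 1L,
    p_high = rep(p_high, n_snps), p_low = rep(p_low, n_snps),
    on_chip = TRUE, stringsAsFactors = FALSE
  )
  structure(list(snps = snps, blocks = NULL, config = config),
            class = "fsv_truth")
}
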