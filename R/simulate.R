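#' Simulation configuration for a two-line pooled resequencing study
#'
#' Builds and validates the configuration object consumed by
#' [simulate_truth()], [simulate_chip()] and [simulate_pools()]. The defaults
#' emulate a study design of two lines divergently selected for a quantitative
#' trait: pools of 7 males + 4 females sequenced at ~5X mean depth
#' (5.19X high line, 5.53X low line), 20 individuals per line genotyped on a
#' sparse chip panel, and a true SNP density of 5 SNPs/kb.
#'
#' @param chromosome_lengths Numeric vector of chromosome lengths in bp; names
#'   are used as chromosome identifiers (defaults to `chr1`, `chr2`, ...).
#' @param chromosome_classes Character vector, one of `"macro"`,
#'   `"intermediate"`, `"micro"` per chromosome. Defaults to macro for the
#'   first chromosome(s), then intermediate, then micro, mirroring avian
#'   karyotype structure on a small simulated genome.
#' @param snp_density True segregating sites per kb (default 5.0).
#' @param chip_fraction Fraction of true SNPs placed on the chip panel.
#'   The default 0.012 yields ~0.06 chip SNPs/kb, the density of a 60K panel
#'   spread over a ~1 Gb genome.
#' @param n_individuals_chip Genotyped individuals per line (default 20).
#' @param pool_males,pool_females Pool composition per line (defaults 7 and 4).
#' @param mean_depth_high,mean_depth_low Expected reads per site for the high
#'   and low line pools (defaults 5.19 and 5.53).
#' @param fst_within_block Balding-Nichols divergence intensity applied per
#'   block; 0 means the two lines share identical frequencies.
#' @param block_length_mean Mean divergence-block length in bp (exponential
#'   law). Loosely plays the role of the typical LD block size.
#' @param ancestral_freq_shape Length-2 numeric: Beta shape parameters of the
#'   ancestral non-reference allele frequency distribution.
#' @param snp_jitter Standard deviation of the per-SNP frequency perturbation
#'   shared by both lines within a block (keeps neighbouring SNPs correlated
#'   but not identical).
#' @param seq_error_rate Per-read miscall probability.
#' @param missing_rate Chip no-call probability per genotype.
#' @param rng_seed Integer seed from which all stage seeds are derived.
#'
#' @return An object of class `fsv_sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(chromosome_lengths = c(chrA = 2e6), rng_seed = 1)
#' cfg$snp_density
#' @export
sim_config <- function(chromosome_lengths = c(chr1 = 10e6, chr2 = 6e6, chr3 = 4e6),
                       chromosome_classes = NULL,
                       snp_density = 5.0,
                       chip_fraction = 0.012,
                       n_individuals_chip = 20L,
                       pool_males = 7L,
                       pool_females = 4L,
                       mean_depth_high = 5.19,
                       mean_depth_low = 5.53,
                       fst_within_block = 0.35,
                       block_length_mean = 30000,
                       ancestral_freq_shape = c(1, 1),
                       snp_jitter = 0.02,
                       seq_error_rate = 0.001,
                       missing_rate = 0.01,
                       rng_seed = 1L) {
  if (is.null(names(chromosome_lengths))) {
    names(chromosome_lengths) <- paste0("chr", seq_along(chromosome_lengths))
  }
  n_chr <- length(chromosome_lengths)
  if (is.null(chromosome_classes)) {
    # small genomes get one chromosome per class where possible
    cls <- rep("micro", n_chr)
    cls[seq_len(min(n_chr, 1))] <- "macro"
    if (n_chr >= 2) cls[2] <- "intermediate"
    if (n_chr > 3) {
      third <- ceiling(n_chr / 3)
      cls <- rep(c("macro", "intermediate", "micro"),
                 c(third, third, n_chr - 2 * third))
    }
    chromosome_classes <- cls
  }
  cfg <- list(
    chromosome_lengths = chromosome_lengths,
    chromosome_classes = stats::setNames(chromosome_classes,
                                         names(chromosome_lengths)),
    snp_density = snp_density,
    chip_fraction = chip_fraction,
    n_individuals_chip = as.integer(n_individuals_chip),
    pool_males = as.integer(pool_males),
    pool_females = as.integer(pool_females),
    mean_depth_high = mean_depth_high,
    mean_depth_low = mean_depth_low,
    fst_within_block = fst_within_block,
    block_length_mean = block_length_mean,
    ancestral_freq_shape = ancestral_freq_shape,
    snp_jitter = snp_jitter,
    seq_error_rate = seq_error_rate,
    missing_rate = missing_rate,
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "fsv_sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "fsv_sim_config"))
  with(cfg, {
    if (length(chromosome_lengths) < 1 || any(chromosome_lengths <= 0)) {
      stop("chromosome_lengths must be positive", call. = FALSE)
    }
    if (!all(chromosome_classes %in% c("macro", "intermediate", "micro"))) {
      stop("chromosome_classes must be macro/intermediate/micro", call. = FALSE)
    }
    if (length(chromosome_classes) != length(chromosome_lengths)) {
      stop("one class per chromosome required", call. = FALSE)
    }
    stopifnot(
      snp_density > 0, chip_fraction >= 0, chip_fraction <= 1,
      n_individuals_chip >= 1, pool_males + pool_females >= 1,
      mean_depth_high > 0, mean_depth_low > 0,
      fst_within_block >= 0, fst_within_block < 1,
      block_length_mean > 0,
      length(ancestral_freq_shape) == 2, all(ancestral_freq_shape > 0),
      snp_jitter >= 0,
      seq_error_rate >= 0, seq_error_rate <= 1,
      missing_rate >= 0, missing_rate <= 1
    )
  })
  invisible(cfg)
}

#' @export
print.fsv_sim_config <- function(x, ...) {
  cat("Two-line pooled resequencing simulation config\n")
  cat(sprintf("  genome: %d chromosome(s), %.1f Mb total\n",
              length(x$chromosome_lengths),
              sum(x$chromosome_lengths) / 1e6))
  cat(sprintf("  true SNP density: %.2f /kb; chip fraction: %.3f\n",
              x$snp_density, x$chip_fraction))
  cat(sprintf("  pools: %d male + %d female per line; depths %.2fX / %.2fX\n",
              x$pool_males, x$pool_females,
              x$mean_depth_high, x$mean_depth_low))
  cat(sprintf("  divergence: Fst %.2f per block, mean block %.0f bp\n",
              x$fst_within_block, x$block_length_mean))
  cat(sprintf("  seed: %d\n", x$rng_seed))
  invisible(x)
}

# Stage seeds are derived from the single manifest seed so each stage is
# reproducible in isolation; offsets are fixed constants.
stage_seed <- function(cfg, stage) {
  offset <- c(truth = 101L, chip = 211L, pool = 307L)[[stage]]
  (cfg$rng_seed + offset) %% .Machine$integer.max
}

#' Simulate ground-truth allele frequencies for two diverged lines
#'
#' Places SNPs by a homogeneous point process along each chromosome, partitions
#' each chromosome into blocks with exponentially distributed lengths, and
#' assigns allele frequencies by a block-shared Balding-Nichols draw: each
#' block draws one ancestral frequency `p0 ~ Beta(a, b)` and, per line, one
#' divergent frequency from `Beta(p0 (1-F)/F, (1-p0)(1-F)/F)` with
#' `F = fst_within_block`. All SNPs in a block share the two line frequencies
#' up to a small per-SNP perturbation applied identically to both lines, so
#' the between-line difference is spatially correlated on the block scale --
#' the structure the Flanking SNPs Value statistic exploits.
#'
#' @param config An [sim_config()] object.
#' @return An object of class `fsv_truth`: a list with `snps` (data.frame:
#'   `chrom`, `pos`, `block`, `p_high`, `p_low`, `on_chip`), `blocks`
#'   (data.frame of block intervals per chromosome) and the `config`.
#' @examples
#' tr <- simulate_truth(sim_config(chromosome_lengths = c(chr1 = 5e5)))
#' head(tr$snps)
#' @export
simulate_truth <- function(config) {
  validate_sim_config(config)
  set.seed(stage_seed(config, "truth"))
  F <- config$fst_within_block
  a <- config$ancestral_freq_shape[1]
  b <- config$ancestral_freq_shape[2]

  snp_list <- vector("list", length(config$chromosome_lengths))
  block_list <- vector("list", length(config$chromosome_lengths))
  for (i in seq_along(config$chromosome_lengths)) {
    chrom <- names(config$chromosome_lengths)[i]
    len <- config$chromosome_lengths[[i]]

    # homogeneous point process at snp_density per kb
    n_snp <- stats::rpois(1, config$snp_density * len / 1000)
    pos <- sort(sample.int(len, min(n_snp, len)))

    # exponential block tiling
    n_guess <- max(16, ceiling(3 * len / config$block_length_mean) + 8)
    gaps <- stats::rexp(n_guess, rate = 1 / config$block_length_mean)
    while (sum(gaps) < len) {
      gaps <- c(gaps, stats::rexp(n_guess, rate = 1 / config$block_length_mean))
    }
    bounds <- cumsum(gaps)
    bounds <- c(0, bounds[bounds < len], len)
    if (length(bounds) < 2) {
      stop(sprintf("chromosome %s is shorter than a single block", chrom),
           call. = FALSE)
    }
    n_block <- length(bounds) - 1

    # one ancestral frequency and one per-line divergence draw per block
    p0 <- stats::rbeta(n_block, a, b)
    if (F > 0) {
      k <- (1 - F) / F
      ph <- stats::rbeta(n_block, p0 * k, (1 - p0) * k)
      pl <- stats::rbeta(n_block, p0 * k, (1 - p0) * k)
    } else {
      ph <- p0
      pl <- p0
    }

    blk <- findInterval(pos, bounds, rightmost.closed = TRUE,
                        left.open = TRUE)
    blk[blk < 1] <- 1L
    # per-SNP jitter shared by the two lines: F = 0 keeps p_high == p_low
    jit <- stats::rnorm(length(pos), 0, config$snp_jitter)
    p_high <- pmin(pmax(ph[blk] + jit, 0), 1)
    p_low <- pmin(pmax(pl[blk] + jit, 0), 1)

    snp_list[[i]] <- data.frame(
      chrom = rep(chrom, length(pos)), pos = as.integer(pos),
      block = as.integer(blk), p_high = p_high, p_low = p_low,
      stringsAsFactors = FALSE
    )
    block_list[[i]] <- data.frame(
      chrom = chrom, block = seq_len(n_block),
      start = as.integer(floor(bounds[-length(bounds)]) + 1),
      end = as.integer(floor(bounds[-1])),
      p0 = p0, p_high_block = ph, p_low_block = pl,
      stringsAsFactors = FALSE
    )
  }
  snps <- do.call(rbind, snp_list)
  rownames(snps) <- NULL
  snps$on_chip <- stats::runif(nrow(snps)) < config$chip_fraction

  out <- list(snps = snps, blocks = do.call(rbind, block_list),
              config = config)
  class(out) <- "fsv_truth"
  out
}

#' @export
print.fsv_truth <- function(x, ...) {
  cat(sprintf("Simulated truth: %d SNPs on %d chromosome(s); %d on chip panel\n",
              nrow(x$snps), length(unique(x$snps$chrom)), sum(x$snps$on_chip)))
  cat(sprintf("  mean |p_high - p_low| = %.3f\n",
              mean(abs(x$snps$p_high - x$snps$p_low))))
  invisible(x)
}

#' Simulate individual chip genotypes for both lines
#'
#' For every chip-panel SNP and each genotyped individual, draws a
#' non-reference allele dosage from `Binomial(2, p_line)` and masks it as
#' missing with probability `missing_rate`.
#'
#' @param truth An `fsv_truth` object from [simulate_truth()].
#' @param config The same configuration used to build `truth` (defaults to the
#'   config stored in `truth`).
#' @return A list of class `fsv_chip` with `sites` (data.frame `chrom`, `pos`),
#'   and integer matrices `high` and `low` (rows = chip SNPs, columns =
#'   individuals, values 0/1/2 with `NA` for no-calls).
#' @export
simulate_chip <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "fsv_truth"))
  validate_sim_config(config)
  chip <- truth$snps[truth$snps$on_chip, , drop = FALSE]
  if (nrow(chip) == 0) stop("no SNPs on the chip panel", call. = FALSE)
  set.seed(stage_seed(config, "chip"))
  n <- config$n_individuals_chip
  draw <- function(p) {
    g <- matrix(stats::rbinom(length(p) * n, 2, rep(p, n)),
                nrow = length(p), ncol = n)
    g[matrix(stats::runif(length(g)) < config$missing_rate, nrow = nrow(g))] <- NA_integer_
    g
  }
  out <- list(
    sites = data.frame(chrom = chip$chrom, pos = chip$pos,
                       stringsAsFactors = FALSE),
    high = draw(chip$p_high),
    low = draw(chip$p_low)
  )
  class(out) <- "fsv_chip"
  out
}

#' Simulate pooled-pileup read counts for both lines
#'
#' Per line, a finite pool of `pool_males + pool_females` diploid individuals
#' is drawn from the line's true frequencies, giving a pool allele frequency
#' `q = (non-reference chromosome count) / (2 * pool size)`. Per SNP, sequencing
#' depth is `Poisson(mean_depth_line)` and the non-reference read count is
#' `Binomial(depth, q(1-e) + (1-q)e)` with `e = seq_error_rate`.
#'
#' @inheritParams simulate_chip
#' @return A data.frame pileup with columns `chrom`, `pos`, `line`
#'   (`"high"`/`"low"`), `ref_reads`, `nonref_reads`, sorted by chromosome,
#'   position, line.
#' @export
simulate_pools <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "fsv_truth"))
  validate_sim_config(config)
  set.seed(stage_seed(config, "pool"))
  n_chrom_copies <- 2L * (config$pool_males + config$pool_females)
  e <- config$seq_error_rate
  snps <- truth$snps
  one_line <- function(p, lambda, line) {
    q <- stats::rbinom(length(p), n_chrom_copies, p) / n_chrom_copies
    depth <- stats::rpois(length(p), lambda)
    qe <- q * (1 - e) + (1 - q) * e
    nonref <- stats::rbinom(length(p), depth, qe)
    data.frame(chrom = snps$chrom, pos = snps$pos, line = line,
               ref_reads = depth - nonref, nonref_reads = nonref,
               stringsAsFactors = FALSE)
  }
  out <- rbind(one_line(snps$p_high, config$mean_depth_high, "high"),
               one_line(snps$p_low, config$mean_depth_low, "low"))
  out <- out[order(out$chrom, out$pos, out$line), , drop = FALSE]
  rownames(out) <- NULL
  out
}
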