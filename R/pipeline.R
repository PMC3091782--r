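#' Run the full simulate -> call -> chip -> FSV -> evaluate pipeline
#'
#' Executes every stage in order under the single seed carried by the
#' configuration: simulate ground truth, chip genotypes and pooled pileups;
#' call SNPs from the pools; summarize the chip; compute FSVs at every usable
#' polymorphic chip SNP over the window grid; and evaluate detection
#' sensitivity, delta-p-stratified FSV means and the window/class correlation
#' scan. Record counts are logged after each stage and after each filter.
#' Re-running with the same configuration reproduces identical outputs.
#'
#' @param config An [sim_config()] object.
#' @param out_dir Optional directory; when given, every stage table plus a
#'   run manifest (`manifest.yaml`: config snapshot, seed, package version,
#'   timestamps, file digests) is written there as TSV/YAML.
#' @param windows Total FSV window widths in bp (default [fsv_window_grid()]).
#' @param threshold Non-reference read calling threshold (default 3).
#' @param delta_min Strict `delta_p` cutoff for the correlation scan
#'   (default 0.4).
#' @param quiet Suppress progress messages.
#' @return List of class `fsv_run`: `truth`, `pileup`, `calls`, `chip`,
#'   `chip_summary`, `fsv`, `sensitivity`, `delta_bins`, `corr`, `corr_all`
#'   (unfiltered-delta variant), `density`, `variation`, `manifest`.
#' @examples
#' \donttest{
#' cfg <- sim_config(chromosome_lengths = c(chr1 = 1e6), rng_seed = 7)
#' run <- run_pipeline(cfg, quiet = TRUE)
#' run$corr$best
#' }
#' @export
run_pipeline <- function(config, out_dir = NULL, windows = fsv_window_grid(),
                         threshold = 3L, delta_min = 0.4, quiet = FALSE) {
  validate_sim_config(config)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  truth <- stage("simulate", simulate_truth(config))
  say("simulate: %d true SNPs (%d on chip)", nrow(truth$snps),
      sum(truth$snps$on_chip))
  chip <- stage("simulate", simulate_chip(truth, config))
  pileup <- stage("simulate", simulate_pools(truth, config))
  say("simulate: %d pileup records", nrow(pileup))

  calls <- stage("call", call_pool_snps(pileup, threshold = threshold))
  say("call: %d SNPs detected (threshold %d), %d excluded (no ref read)",
      nrow(calls), threshold, sum(calls$excluded))
  density <- stage("call", snp_density(calls, config$chromosome_lengths,
                                       config$chromosome_classes))
  variation <- stage("call", variation_table(calls))

  chip_summary <- stage("chip", summarize_chip(chip))
  say("chip: %d SNPs assayed, %d pass call-frequency filter, %d polymorphic",
      nrow(chip_summary), sum(chip_summary$usable),
      sum(chip_summary$usable & chip_summary$polymorphic))

  focal <- chip_summary[chip_summary$usable & chip_summary$polymorphic,
                        c("chrom", "pos"), drop = FALSE]
  fsv <- stage("fsv", fsv_scan(focal, calls, windows))
  say("fsv: %d (focal, window) values; %d defined and density-passing",
      nrow(fsv), sum(fsv$defined & fsv$density_pass))

  sens <- stage("evaluate", sensitivity(chip_summary, calls))
  corr <- stage("evaluate",
                correlation_scan(chip_summary, fsv, delta_min = delta_min,
                                 class_map = config$chromosome_classes))
  corr_all <- stage("evaluate",
                    correlation_scan(chip_summary, fsv, delta_min = NULL,
                                     class_map = config$chromosome_classes))
  best_w <- corr$best$window_total[corr$best$class == "all"]
  if (is.na(best_w)) best_w <- windows[[1]]
  delta_bins <- stage("evaluate",
                      fsv_by_delta_bins(chip_summary, fsv,
                                        window_total = best_w))
  say("evaluate: best overall window %s kb (r = %.3f over delta_p > %s)",
      format(best_w / 1000),
      corr$best$pearson_r[corr$best$class == "all"], format(delta_min))

  out <- list(truth = truth, pileup = pileup, calls = calls, chip = chip,
              chip_summary = chip_summary, fsv = fsv, sensitivity = sens,
              delta_bins = delta_bins, corr = corr, corr_all = corr_all,
              density = density, variation = variation, manifest = NULL)
  class(out) <- "fsv_run"

  if (!is.null(out_dir)) {
    out$manifest <- stage("write", write_run(out, config, out_dir))
  }
  out
}

# write all stage tables plus the run manifest
write_run <- function(run, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$rng_seed
  paths <- c(
    truth_snps = "truth_snps.tsv", pileup = "pileup.tsv",
    calls = "calls.tsv", chip_summary = "chip_summary.tsv",
    fsv = "fsv.tsv", sensitivity = "sensitivity.tsv",
    delta_bins = "fsv_delta_bins.tsv", correlation = "correlation_scan.tsv",
    density = "snp_density.tsv", variation = "variation_classes.tsv"
  )
  full <- file.path(out_dir, paths)
  names(full) <- names(paths)
  write_fsv_tsv(run$truth$snps, full[["truth_snps"]], seed)
  write_fsv_tsv(run$pileup, full[["pileup"]], seed)
  write_fsv_tsv(run$calls, full[["calls"]], seed)
  write_fsv_tsv(run$chip_summary, full[["chip_summary"]], seed)
  write_fsv_tsv(run$fsv, full[["fsv"]], seed)
  write_fsv_tsv(run$sensitivity, full[["sensitivity"]], seed)
  write_fsv_tsv(run$delta_bins, full[["delta_bins"]], seed)
  write_fsv_tsv(run$corr$scan, full[["correlation"]], seed)
  write_fsv_tsv(run$density, full[["density"]], seed)
  write_fsv_tsv(run$variation, full[["variation"]], seed)

  manifest <- list(
    package = "fsvkit",
    version = as.character(utils::packageVersion("fsvkit")),
    seed = seed,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(within(unclass(config), {
      chromosome_lengths <- as.list(chromosome_lengths)
      chromosome_classes <- as.list(chromosome_classes)
    })),
    outputs = as.list(stats::setNames(unname(tools::md5sum(full)),
                                      sub("[.]tsv$", "", unname(paths))))
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  manifest
}

#' @export
print.fsv_run <- function(x, ...) {
  cat("fsvkit pipeline run\n")
  cat(sprintf("  %d true SNPs, %d called, %d chip SNPs\n",
              nrow(x$truth$snps), nrow(x$calls), nrow(x$chip_summary)))
  cat(sprintf("  overall called density: %.2f SNPs/kb\n",
              x$density$snps_per_kb[x$density$scope == "overall"]))
  b <- x$corr$best
  cat(sprintf("  best window (all chromosomes): %s kb, r = %.3f\n",
              format(b$window_total[b$class == "all"] / 1000),
              b$pearson_r[b$class == "all"]))
  invisible(x)
}
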