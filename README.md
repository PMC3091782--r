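# fsvkit

Low-coverage resequencing of pooled DNA is a cheap way to survey SNPs in two
populations at once, but at ~5X depth many segregating sites are missed and a
single site's read counts say little about how informative that SNP is for
telling the populations apart. `fsvkit` implements an analysis of this design
for two divergently selected lines:

- **Pool-based SNP calling.** At every position, each line's pool contributes
  reference and non-reference read counts; a SNP is called when at least
  *k* = 3 non-reference reads appear in at least one pool. Each detected SNP
  gets a per-line reference-agreement score *S* = (reference reads) / (total
  reads); a line where the SNP was not detected is assumed fixed for the
  reference allele (*S* = 1). Detected SNPs are classified by within-line
  variation (both lines all non-reference / one line all non-reference / one
  line biallelic / both biallelic), and SNPs with no reference-supporting read
  in either pool are flagged and excluded from window statistics.
- **The Flanking SNPs Value (FSV).** For a focal position and a total flanking
  window *W* (centred, *W*/2 each side), with *H* and *L* the flanking SNPs
  detected in the high and low line,

  FSV = ( Σ_{i∈H} |S_iH − S_iL| / N_H ) × ( Σ_{j∈L} |S_jL − S_jH| / N_L )

  an FSV near 1 means the two pools disagree consistently across the whole
  window — a proxy for local between-population divergence and hence for the
  focal SNP's informativity. Windows where either line contributes ≤ 1 SNP/kb
  are flagged by a density filter.
- **Evaluation layer.** Detection sensitivity by non-reference allele-frequency
  bin (against individual chip genotypes of 20 birds/line), closed-form
  detection power under Poisson depth, mean FSV stratified by the between-line
  allele-frequency difference Δp, and Pearson correlation scans of FSV vs Δp
  over a 14-window grid (2–128 kb) and chromosome size classes
  (macro / intermediate / micro).
- **Synthetic data generator.** Block-structured Balding–Nichols divergence:
  chromosomes are tiled with exponential blocks; each block draws one
  ancestral frequency and one per-line divergent frequency, shared by the
  block's SNPs, so Δp is spatially correlated on the block scale. Chip
  genotypes are Binomial(2, p) with missingness; pool pileups resample a
  finite pool (7♂ + 4♀ per line), then Poisson depth and binomial read
  sampling with a per-read error rate. All stages are seeded and
  byte-reproducible.

## Worked example

```r
library(fsvkit)
cfg <- sim_config(
  chromosome_lengths = c(chr1 = 10e6, chr2 = 6e6, chr3 = 4e6),
  chromosome_classes = c("macro", "intermediate", "micro"),
  snp_density = 5, chip_fraction = 0.1,
  fst_within_block = 0.5, block_length_mean = 30000,
  rng_seed = 1
)
run <- run_pipeline(cfg, quiet = TRUE)
run
#> fsvkit pipeline run
#>   100050 true SNPs, 64305 called, 10028 chip SNPs
#>   overall called density: 3.22 SNPs/kb
#>   best window (all chromosomes): 62 kb, r = 0.627
detection_power(5.19, 1)
#> [1] 0.8904652
```

Reading the output: of ~100k simulated SNPs (5/kb over 20 Mb), the 3-read
rule at ~5X recovers ~64k (3.2/kb) — detection is lossy, and most misses are
low-frequency alleles. `detection_power(5.19, 1)` is the closed-form chance
of seeing ≥ 3 non-reference reads at a site fixed for the non-reference
allele: even there, ~11% of sites are missed at 5.19X. The correlation scan
finds FSV most predictive of the chip-measured Δp (r ≈ 0.63 among SNPs with
Δp > 0.4) at a 62 kb total window, matching the ~30 kb divergence-block scale
of the simulation (a window of roughly twice the block length keeps the focal
block dominant in both flanks).

Per-stage functions (`simulate_truth()`, `simulate_pools()`,
`call_pool_snps()`, `summarize_chip()`, `fsv_scan()`, `sensitivity()`,
`correlation_scan()`) expose every intermediate table, and
`run_pipeline(cfg, out_dir = ...)` writes all of them as headered TSV plus a
YAML run manifest with seed and file digests.

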