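---
title: "Predicting SNP informativity from pooled resequencing: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting SNP informativity from pooled resequencing: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fsvkit)
```

## The problem

Two lines divergently selected for a quantitative trait accumulate
allele-frequency differences, strongest around selected loci and — because of
linkage — in the chromosomal neighbourhoods of those loci. Sequencing one
pooled DNA sample per line at low depth (~5X) is an inexpensive way to survey
variants genome-wide, but individual sites are unreliable at that depth: a
site covered by five reads cannot distinguish a frequency of 0.6 from 1.0,
and many true SNPs produce fewer than the minimum number of non-reference
reads needed to be called at all. `fsvkit` implements the two-part answer to
this: a transparent read-count calling rule, and a flanking-window statistic
that pools evidence across neighbouring SNPs to predict how informative a
focal SNP is about between-line divergence.

## Calling model

Each line's pool gives, per position, a reference and a non-reference read
count (the pileup is biallelic by construction: every non-reference base is
pooled; multi-allelic resolution is out of scope). A SNP is detected in a
line when its pool shows at least `threshold = 3` non-reference reads; the
rule is applied per line independently. Each detected SNP carries a per-line
reference-agreement score

$$S = \frac{\text{ref reads}}{\text{ref reads} + \text{nonref reads}},$$

and a line in which the SNP was *not* detected is assumed fixed for the
reference allele, i.e. $S = 1$ exactly. That fixation assumption is applied
once, at calling time (`call_pool_snps()`), never downstream. Detected SNPs
with no reference-supporting read in either line are flagged `excluded`:
both pools disagree with the reference in the same direction, so the site
carries no between-line signal, and a diverged-from-reference site inflates
window statistics if left in. Excluded SNPs still appear in the
variation-class table, which partitions all detected SNPs into
`both_all_nonref`, `one_all_nonref`, `one_biallelic` and `both_biallelic`.

The closed-form companion `detection_power()` gives the probability of
calling a site whose pool non-reference frequency is $q$: depth is
$\mathrm{Poisson}(\lambda)$ and each read reports non-reference with
probability $q' = q(1-e) + (1-q)e$, so by Poisson thinning the non-reference
count is $\mathrm{Poisson}(\lambda q')$ and the power is
$1 - \sum_{j<k} e^{-\lambda q'}(\lambda q')^j / j!$. At $\lambda = 5.19$,
$q = 1$, $k = 3$ this is `r round(detection_power(5.19, 1), 4)` — even fixed
differences are missed ~11% of the time at 5X, which is why single-site
scores are a weak guide to informativity.

## The Flanking SNPs Value

For a focal position and a total window of $W$ bp ($W/2$ on each side,
closed interval, boundary ties included), let $H$ and $L$ be the flanking
SNPs detected in the high and low line (the sets overlap where a SNP is
detected in both). Then

$$\mathrm{FSV} = \frac{\sum_{i\in H} |S_{iH}-S_{iL}|}{N_H}
 \times \frac{\sum_{j\in L} |S_{jL}-S_{jH}|}{N_L}.$$

Both factors are means of absolute score differences, so
$\mathrm{FSV} \in [0,1]$, and the product is symmetric under relabelling the
lines. The focal SNP's own scores never enter the sums, and `excluded` calls
are omitted. When either $N$ is zero the value is undefined (flagged, not an
error). A separate density filter requires each line to contribute strictly
more than 1 flanking SNP per kb of total window; sparse windows usually
reflect locally poor coverage rather than low divergence, and they are
flagged `density_pass = FALSE` and dropped from correlation tests only.

Interpretation choices the formula itself leaves open, decided here and
tested as stated: "total flanking region $W$" means a single centred window
of total width $W$; the focal SNP is excluded from both sums; windows
overhanging a chromosome end are truncated (the flanking set is simply
smaller) rather than the focal SNP being dropped.

`fsv_scan()` computes all (focal, window) pairs with one cumulative-sum sweep
per chromosome; its contract — identical output to direct per-focal
evaluation by `compute_fsv()` — is enforced by randomized equivalence tests.

## Evaluation layer

Against individual chip genotypes (dosage 0/1/2 per SNP and bird),
`summarize_chip()` computes per-line frequencies, the joint call frequency
(SNPs at or below 0.95 are dropped), polymorphism status and
$\Delta p = |p_{high} - p_{low}|$. A SNP is monomorphic only when every
non-missing dosage across both lines is the same homozygote — a SNP fixed
for the same non-reference allele in both lines shows no within- or
between-line variation, so it is treated as monomorphic for the chip
analyses even though it differs from the reference. Frequency bins are
$[0,0.1), \dots, [0.9,1.0]$ with a right-closed top bin. For the Figure-style
sensitivity table each line contributes one observation per chip SNP, binned
by that line's own frequency; the alternative (binning by the larger of the
two frequencies) compresses the low bins and was not used.

`correlation_scan()` reports the Pearson product-moment correlation between
FSV and $\Delta p$ per window and chromosome size class, restricted to
defined, density-passing windows and (by default) to SNPs with
$\Delta p > 0.4$ strictly; the unfiltered variant is also computed because
the overall correlation is a quantity of interest in its own right. Raw $r$
and two-sided $p$ from the $t$ transform are reported without
multiple-testing correction; strata with fewer than 3 rows or zero variance
are reported as undefined rather than dropped.

## Synthetic data generator

The generator emulates the study design the package targets: two lines of a
41-generation divergent selection experiment, pools of 7 males + 4 females
per line at 5.19X/5.53X, 20 chip-genotyped individuals per line, ~5 true
SNPs/kb, and a chip panel that is a uniform random subset of true SNPs
(default `chip_fraction = 0.012`, i.e. ~0.06 chip SNPs/kb — a 60K-scale
panel over a ~1 Gb genome).

Divergence is modelled with block-shared Balding–Nichols draws rather than
forward simulation: chromosomes are tiled with exponentially distributed
blocks (`block_length_mean`, default 30 kb), each block draws an ancestral
frequency $p_0 \sim \mathrm{Beta}(1,1)$ and one frequency per line from
$\mathrm{Beta}(p_0\frac{1-F}{F},\,(1-p_0)\frac{1-F}{F})$ with
$F$ = `fst_within_block`. All SNPs in a block share the two line frequencies
up to a small normal perturbation, clamped to $[0,1]$ (`snp_jitter`,
default sd 0.02)
applied *identically* to both lines — so $F = 0$ gives exactly equal
frequencies, and $\Delta p$ is constant within a block and decorrelates
between blocks. The pairwise correlation of $\Delta p$ therefore decays like
the probability that two positions share a block,
$e^{-d/\text{block length}}$, which the distance-decay test verifies
empirically. No quantitative LD-block length is available for these lines;
the 30 kb default sits inside the 38–62 kb range where flanking windows are
most predictive in this kind of data, and it is an exposed parameter, not a
calibrated constant.

Pool pileups resample a finite pool: the 22 chromosomes of the 11 pooled
birds are drawn binomially from the line frequency, giving the pool frequency
$q$; depth is Poisson, and the non-reference read count is binomial in depth
with error-perturbed $q'$. Chip genotypes are $\mathrm{Binomial}(2, p)$
dosages with i.i.d. missingness (default 0.01, so nearly all SNPs clear the
0.95 call-frequency filter, as on a real well-behaved panel).

What the generator deliberately does **not** model: read-level sequence or
colour-space errors, alignment and mappability, GC or gene-density effects on
coverage, ascertainment bias of chip panels, sex chromosomes, linkage within
the chip sample (individual genotypes are drawn independently), or selection
itself (divergence is exchangeable across blocks rather than concentrated at
trait loci). Consequently the tests show that the statistics behave correctly
under the stated sampling model — not that real chicken data would reproduce
any particular correlation value, which also depends on recombination-rate
and gene-density variation the generator omits.

## Numerical and design choices

- Coordinates are 1-based and intervals fully closed throughout.
- All randomness flows from `rng_seed`; the three simulation stages use
  fixed offsets from it so each stage is independently reproducible, and the
  whole pipeline is byte-reproducible under one seed.
- Within-block clamping of jittered frequencies to $[0,1]$ can create small
  within-block $\Delta p$ variation near the boundaries; this is harmless
  (it only attenuates block correlation slightly).
- Undefined FSVs and density-filter failures are distinct flags; only
  `defined & density_pass` rows enter correlation tests.
- Ties at window boundaries are included; the sweep and the direct
  evaluation implement the same closed-interval rule, enforced by test.
- Degenerate inputs: a line with no reads at a site is depth 0 (detection
  impossible there); a chip SNP with no calls in a line is flagged unusable
  rather than erroring; an empty focal set yields an empty FSV table.

## Problem sizes

The test-suite simulations use 0.5–2 Mb genomes for unit properties and a
20 Mb genome (three chromosome size classes, 5 SNPs/kb) for the end-to-end
sensitivity and correlation-recovery checks, with the chip fraction raised
above the 60K-emulating default (0.1–0.25) so every frequency and $\Delta p$
stratum holds enough SNPs for the checks to reflect expectations rather than
bin noise. These sizes recover the qualitative results stably — monotone
sensitivity, positive FSV/$\Delta p$ correlation concentrated in high-$\Delta p$
SNPs, and an interior optimum window tracking the block scale — in a few
seconds each.

## Limitations

FSV is a window statistic: it predicts neighbourhood divergence, not the
focal SNP's own genotype, and it inherits the calling rule's asymmetries —
under low coverage, a line that is genuinely polymorphic can appear fixed for
the reference, inflating score differences and hence FSV for weakly diverged
regions; this is why the correlation with $\Delta p$ is concentrated among
SNPs that are already divergent, and why low-$\Delta p$ strata show
essentially none. The density filter mitigates, but does not remove, the
dependence of FSV on local coverage.
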