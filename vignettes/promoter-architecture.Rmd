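---
title: "Core promoter architecture from TSS-seq: methods and design notes"
author: "promarch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Core promoter architecture from TSS-seq: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promarch)
```

This vignette is the package's own account of the method: the model each
stage implements, the tunable parameters and why their defaults are what
they are, what the synthetic-data generator does and does not emulate,
the numerical choices, and the places where the underlying procedure is
genuinely open to interpretation and a decision had to be made.

## 1. From mapped reads to tag clusters

TSS-seq reads mark mRNA 5' ends, so the biological signal is the
distribution of read *start* positions (interval start on `+`, interval
end on `-`). `merge_reads()` groups reads into **tag clusters**: two
reads belong to the same cluster iff they are connected by a chain of
pairwise, same-scaffold, same-strand overlaps of at least one base.

* `merge_gap` (default `-1`, meaning a true overlap is required): the
  classical implementation of this step with `bedtools merge -d 1` also
  joins intervals separated by one base. The stated biology — "at least
  one overlapping base" — wins as the default; `merge_gap = 1`
  reproduces the bedtools behaviour for comparison. Both are supported
  because the two readings cannot be distinguished from the published
  description.
* `min_tags` (default 100): clusters supported by fewer tags are treated
  as noise. The threshold trades sensitivity for specificity in the
  absence of orthogonal evidence (full-length cDNAs, ESTs); with
  supporting evidence a much lower threshold (10) is customary.

`annotate_clusters()` classifies clusters with the precedence
five_prime > other_genic > geneless_scaffold > periphery > intergenic.
The five_prime zone of a gene is the union of its 5'UTR, its first
coding exon and an upstream allowance (`utr_upstream`, default 300 bp —
a typical mean 5'UTR length); when the annotated 5'UTR is missing or
<= 10 bp the upstream allowance anchors on the first coding exon
instead, since such UTR stubs usually reflect annotation artifacts. The
periphery rule marks unassigned clusters within `periphery_margin`
(default: the median gene length of the annotation) of a scaffold end:
in a fragmented assembly such clusters may belong to a gene that fell
off the scaffold, so they are reported separately rather than called
intergenic. All gene-relative tests are same-strand; antisense clusters
over a gene are *not* assigned to it.

## 2. Promoter shape

For a cluster *g* with TSS histogram *h*, `peakedness()` computes

$$S_g = \frac{m}{n\,w}$$

with \(m = \max h\) (modal tag count), \(n = \sum h\), and \(w\) the
width of the TSS distribution. Two readings of "width" are possible: the
span of distinct read 5'-end positions (max − min + 1) or the width of
the merged cluster interval, which is inflated by the read length. The
package uses the former (`width_mode = "tss"`): a cluster whose reads
all start at one position then reaches the documented maximum
\(S_g = 1\), which is impossible under the interval reading (a 36-bp
read makes the interval 36 bp wide). `width_mode = "interval"` is kept
for comparison.

`classify_shape()` applies two cutoffs: **narrow** means <= 10 distinct
TSS positions (`narrow_max`); broader clusters are **broad_with_peak**
when the mode carries >= 50 % of tags (`peak_fraction`), else
**broad_without_peak**. Ties at the thresholds are inclusive (exactly
10 positions is narrow; exactly 50 % is a peak).

`dominant_tss()` takes the histogram argmax; ties break toward the most
upstream position in transcript orientation, a deterministic choice that
favours the longest transcript interpretation. `select_gene_cluster()`
resolves genes with several candidate clusters toward the one with most
tags, ties again upstream.

## 3. Core promoters and composition

`extract_core_promoters()` returns the 100-nt window −50…−1, +1…+50 in
transcript orientation. There is no position 0: +1 is the TSS base, so
the window is exactly 100 nt. Windows reaching past a scaffold end are
N-padded with a warning rather than dropped, so the promoter set stays
aligned. A promoter whose genomic window intersects a transposon
interval by >= 1 bp is flagged and excluded from motif annotation
(repeat-derived matches would otherwise dominate the statistics);
flagged promoters are retained in the output so the exclusion is
auditable. Composition profiling (`composition_profile()`,
−200/+100 by default) and the −1/+1 initiator dinucleotide table use the
same coordinate convention; ambiguous bases are excluded from both
numerator and denominator, so every informative position sums to 1.

## 4. Motif annotation

The six canonical core promoter motifs are scanned in transcript
orientation only — their function is orientation-specific, so the
reverse strand is deliberately not scanned.

* **PWM scores.** A position frequency matrix is smoothed with a
  pseudocount of 0.8 per cell (a common smoothing choice; changing it
  shifts scores continuously), column-normalized, and turned into
  log2-odds against a mononucleotide background estimated from the
  scanned promoters themselves (zero frequencies floored at 1e-4 and
  renormalized).
* **Exact p-values.** Per-column scores are discretized to a 1e-3-bit
  grid and the distribution of the total score under the background is
  obtained by exact dynamic-programming convolution of the per-column
  4-point distributions. The p-value of a hit is the upper tail of that
  distribution at the hit's (identically discretized) score, so the
  p-value is exact on the grid rather than approximated. The default
  per-position threshold is p <= 1e-2.
* **Functional windows.** A hit is only retained when its start lies in
  the motif's functional window extended by +/- 5 bp of elasticity:
  BREu [−38,−32], TATA [−31,−24], BREd [−23,−17], INR [−2,+4],
  MTE [+18,+27], DPE [+28,+32]. These are canonical literature
  placements shipped as configurable defaults, not measured quantities;
  any window table can be attached via `read_jaspar(windows = ...)`.
* Multiple hits of one motif in one promoter collapse to a single
  presence flag — all downstream statistics are per-promoter occurrence.
* Promoters containing ambiguous bases are skipped by the scanner with a
  warning (they still contribute to composition profiles).

The bundled matrices under `inst/extdata/pfm/` are *synthetic*
consensus-derived count matrices (85/5/5/5 per column), present so the
pipeline runs out of the box and so planted-motif recovery is a sharp
test; curated database matrices should replace them in real analyses.

## 5. Statistics

**Real vs random enrichment.** `shuffle_promoters()` permutes each
promoter independently, preserving its exact base multiset — a
composition-matched null preferable to coding or intergenic background.
`binomial_enrichment()` then compares the number of true promoters
carrying a motif with the shuffled count: the shuffled count defines a
null proportion with a continuity pseudocount,
\(\hat p = (r + 0.5)/(n + 1)\), and the p-value is the exact binomial
upper tail \(P(X \ge t)\), \(X \sim \mathrm{Bin}(n, \hat p)\). One
property of this construction should be understood before interpreting
its p-values as strict error rates: the random count is itself a noisy
draw, and conditioning on it as if it were the true null proportion
understates the variance of the comparison by roughly a factor of two.
Under a strict null (true and random counts drawn from the same
binomial) the test therefore rejects at about 9–12 % at a nominal 5 %
for realistic promoter-class sizes. The test is best read as a
screening statistic — in practice the interesting enrichments (planted
or biological) sit many orders of magnitude below the threshold, where
this miscalibration is immaterial.

**Co-occurrence.** For each pair (15 combinations) or triple (20) of
motifs and each shape class, the observed percent of promoters carrying
the full set is compared with the independence expectation — the product
of the class marginals. The published description ("a 95 % confidence
interval of each combination with respect to the sample size") does not
fix the interval construction, so the package makes a documented choice:
the default band is a delta-method interval for the *difference* between
the observed proportion and the plug-in expectation under independence,

$$\mathrm{Var}(\mathrm{obs} - e) \approx
  \frac{e(1-e) - e^2 \sum_i (1-p_i)/p_i}{N},$$

which accounts for the covariance between the observed count and the
estimated marginals and consequently flags at the nominal two-sided rate
(measured 3.5–5 % under simulated independence at N = 500). The simpler
band \(e \pm z\sqrt{e(1-e)/N}\) — which ignores that covariance and
therefore under-fires (≈1–3 %) — is available as `ci_method = "wald"`,
and binomial quantiles as `ci_method = "exact"`. Flags are `over`/
`under` when the observed percent falls outside the band.

**TATA partition.** `tata_partition_table()` reports per-motif percent
occurrence separately for TATA-containing and TATA-less promoters; by
construction TATA is 100 % in the first column and 0 in the second.

**GO over-representation.** Per shape class, term counts are summed and
a term is reported when its count reaches the nearest-rank 75th
percentile of the class's count distribution. Nearest-rank is used
because it is deterministic and well-defined for the short, tied count
vectors typical of sparse annotations. No multiple-testing correction is
applied anywhere in this layer — the procedures are reported as-is, as
descriptive screens.

## 6. The synthetic-data generator

`sim_config()` defaults describe the emulated study conditions, chosen
once and not revisited:

| parameter | default | rationale |
|---|---|---|
| `at_fraction` | 0.70 | insect promoters are AT-rich |
| `shape_mix` | 0.05 / 0.23 / 0.72 | observed narrow / broad-with-peak / broad-without-peak proportions |
| `reads_per_gene_range` | 150–250 | ~200 tags per gene; validation runs use exactly 200 |
| `read_length` | 36 | Illumina-era tag length |
| `motif_plant_rates` | .21/.29/.32/.34/.33/.30 | observed occurrence of BREu/BREd/TATA/INR/MTE/DPE |
| `utr_length_range` | 50–300 | upper bound = the 300-bp mean 5'UTR allowance |
| `n_genes`, scaffolds | 150 on 10 × 120 kb | large enough for class-level statistics, small enough for test-time generation |

Initiation archetypes: **narrow** draws from a point mass with a
geometric tail truncated to <= 10 positions; **broad_with_peak** is a
discretized Gaussian over a 60–150 bp window plus a modal spike carrying
55–70 % of reads; **broad_without_peak** is the Gaussian alone, with the
post-conditions (>= 11 distinct positions; modal fraction below/above
50 %) enforced by resampling. The true dispersion of broad initiation is
not known — these widths are tunable archetypes, not calibrated fits.
Motif consensi (TATAAA, TCAGTT, AGACGT, CGAACGGA, GGGCGCC, GTTTGTT) are
written at the centers of the functional windows; the INR consensus
spans −2…+4, which places C at −1 and A at +1 and makes CA the expected
modal initiator dinucleotide in planted data. Transposon intervals are
placed in intergenic space >= 500 bp from every TSS, so the
transposon-exclusion filter is exercised by explicit test cases rather
than by random collisions that would contaminate motif-recovery
measurements. A low rate of scattered background reads
(`background_read_rate`, 0.05/kb) adds sub-threshold noise clusters.

What the generator does **not** emulate: sequencing error, adapter
contamination, multi-mapping, realistic scaffold-length distributions,
correlated motif placement, or expression-dependent tag depth. Passing
tests on synthetic data therefore demonstrate the correctness of the
computation — clustering, scoring, window logic, statistics — not the
biological fidelity of any particular threshold on real libraries.

A note on validation anchoring: promoter-shape recovery is measured
through the full calling chain (reads → clusters → dominant TSS →
classification), while planted-motif recovery is measured on promoters
anchored at the generator's *true* TSS. For broad-without-peak genes the
dominant tag position is dispersed by construction, so a called-TSS
anchor would shift the functional windows by more than the +/- 5 bp
elasticity for many genes no matter how good the scanner is; anchoring
at the true TSS isolates the extraction + scanning + window-filter chain
that the motif-recovery check is meant to validate.

## 7. Numerical choices and degenerate inputs

* Score grid 1e-3 bits; DP p-values are exact on the grid, and the test
  suite checks them against full 4^L enumeration up to L = 8.
* Background flooring at 1e-4 keeps log-odds finite on degenerate
  (e.g. all-A) inputs.
* Ties: dominant TSS and cluster selection break upstream; shape
  thresholds are inclusive (<= 10, >= 50 %).
* Empty inputs error early with explicit messages (no genes, no
  sequences, empty candidate lists); empty shape classes are omitted
  from class-wise statistics with warnings.
* All generator outputs are byte-deterministic functions of
  `sim_config()$seed`; the reads and GO maps derive their streams from
  fixed offsets of the same seed, so regeneration of any single artifact
  is reproducible in isolation.

## 8. Problem sizes used in validation

The shipped validation suite runs the clustering oracle on 1,000 random
read sets (<= 200 reads each), shape recovery and motif recovery on a
150-gene / 200-reads-per-gene study, p-value enumeration up to 4^8
words, and statistical calibration with 2,000 binomial replicates and
60 × 500-promoter independence simulations — sizes at which every
distributional property of interest is measurable while the whole suite
completes in a few minutes on one CPU.

## 9. Known limitations

* One promoter per gene: alternative promoters are deliberately out of
  scope; only the strongest five_prime cluster is kept.
* The mononucleotide background ignores dinucleotide structure; an
  AT-rich genome makes TATA-like false positives comparatively cheap,
  which is precisely why the functional-window restriction and the
  shuffled-background comparison are part of the method.
* Functional windows are literature defaults, not fitted to any genome.
* The real-vs-random binomial p-value is anti-conservative under a
  strict null (see section 5); treat marginal significances near the
  threshold with caution.
* GO analysis performs no term-ancestry propagation and no
  multiple-testing correction; it is a descriptive percentile screen.
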