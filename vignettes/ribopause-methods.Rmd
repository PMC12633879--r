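---
title: "Methods: codon-level differential ribosome pausing and aneuploidy screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: codon-level differential ribosome pausing and aneuploidy screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`ribopause` analyses how an extra chromosome changes translation in yeast
entering quiescence. It covers four connected analyses plus the simulator
that feeds them for testing:

1. **Codon-level differential ribosome pausing** from ribosome-profiling
   footprints: P-site assignment, gene-body occupancy normalization,
   per-codon Fisher exact tests with FDR control, replicate combination,
   and positional/chromosomal summaries of the called pause sites.
2. **Stall-site motif enrichment**: the amino acids decoded at and around
   differential pause sites, scored against proteome background
   frequencies.
3. **Spike-in transcriptome-silencing analysis**: per-cell normalization
   via foreign spike-in cells and a selection rule for genes that fail
   quiescence silencing in every aneuploid strain.
4. **Pooled barcode-screen hit selection**: TMM normalization, enrichment
   at day 1 / day 28 of chronological aging versus the starting pool, an
   aneuploid-versus-euploid 2-fold specificity rule, and classification
   of hits as early-benefit versus life-span-specific.

All user-facing functions take data frames (long tibbles) and return
tibbles; fitted objects support `tidy()`/`glance()` and there are
`plot_*()`/`autoplot()` displays for each result type.

# The occupancy model

Footprint 5' ends are converted to P sites with a fixed 12-nt offset
(`assign_psites()`): on the plus strand the P site is `pos5 + 12`, on the
minus strand `pos5 - 12`. Each P site maps to an *extended codon index*
relative to the gene's ATG: codon 1 is the ATG, codons −24..−1 cover the
72 nt upstream, and 20 codons (60 nt) follow the stop. Only CDS codons are
ever tested for differential pausing; the window codons are kept for
display. A single offset for all read lengths is used; it is a function
argument for libraries calling for a different offset.

Occupancy for gene *g*, codon *c*, is

$$\mathrm{occ}(c) = \frac{n_c + 1}{\overline{(n + 1)}_{\mathrm{body}}},$$

where the *gene body* is CDS codons 21 to $L - 20$ ($L$ counts the stop
codon). The +1 pseudocount stabilizes sparse codons; by construction the
mean occupancy over body codons is exactly 1. Whether the body bounds are
inclusive is a convention; we fix codons 21 and $L-20$ as included and
expose no alternative, since the choice moves two codons at most. Genes
shorter than 41 codons have an empty body and are skipped. Genes need at
least 50 raw body reads per sample to enter the analysis
(`filter_genes()`), and a euploid/aneuploid comparison uses the
intersection of the per-sample retained sets.

# Differential pause calling

For each replicate pair and every CDS codon of every retained gene we form
the 2×2 table

|            | reads at codon | body reads excluding the codon |
|------------|----------------|--------------------------------|
| euploid    | $n_c^{(e)}$    | $N^{(e)} - n_c^{(e)}$          |
| aneuploid  | $n_c^{(a)}$    | $N^{(a)} - n_c^{(a)}$          |

and compute the two-sided Fisher exact p-value by the standard
sum-of-probabilities rule (all hypergeometric outcomes no more probable
than the observed one). Excluding the tested codon from the body column
keeps the columns disjoint; with bodies of hundreds of reads the
difference from including it is negligible, and a flag restores the
inclusive variant. The implementation enumerates the hypergeometric
support directly (vectorized over all codons), which makes testing every
codon of a transcriptome cheap; it agrees with `stats::fisher.test()` to
10⁻⁹ and is verified in the tests against an independent
log-binomial-coefficient enumeration.

Benjamini–Hochberg correction is applied over **all codons tested within
one replicate** (one family per comparison, not per gene). Codons with
FDR < 0.05 are labelled by direction using the pseudocounted occupancy
ratio (aneuploid / euploid). Replicate-level calls are **combined by
union**; sites significant in opposite directions in different replicates
are contradictory and are discarded with a report. Union rather than
intersection was chosen because the per-replicate FDR already controls
false positives and intersection would throw away sites lost to coverage
in one replicate; the choice is a documented convention of this package.

Positional shifts between euploid-higher and aneuploid-higher sites use a
two-sided Wilcoxon rank-sum test on relative positions (codon / length):
exact null distribution when both groups have ≤ 20 sites without ties,
normal approximation with tie correction otherwise. Chromosome
enrichment of peak-bearing transcripts against measured transcripts is an
upper-tail hypergeometric test.

Per-transcript similarity of euploid and aneuploid traces is summarized
by the uncentered Pearson correlation (cosine similarity) of the CDS
occupancy vectors, paired by replicate — scale-invariant, so it compares
pause *shape*, not expression level.

# Motif enrichment

For pause sites of one direction (by default the aneuploid-higher sites),
residues at positions −10..+10 around the pause codon (position 0 = P
site, +1 = A site) are read from the proteins; the terminal stop symbol
counts as a residue, and positions running off a protein end contribute
nothing to that position's denominator — denominators are therefore
per-position, which is the only consistent reading when peaks sit near
protein ends. Each (position, residue) cell is tested two-sided against
the proteome background (occurrences out of total residues) with the
same Fisher machinery, BH-corrected over the whole matrix, and reported
as log2(observed frequency / background frequency). The background
defaults to all included genes; a measured-genes-only background is
available because either scope is defensible.

# Spike-in normalization and the silencing rule

With a fixed number of foreign cells spiked into each sample before RNA
extraction, spike-gene counts should differ between samples only by a
global scale. `spike_slope_factors()` fits a through-origin regression of
each sample's spike counts against a reference sample and returns
1/slope. The default fit is on the log scale (the geometric mean of
per-gene ratios), which is the maximum-likelihood slope under
multiplicative log-normal noise — the noise structure spike-ins actually
show — and has the smallest variance of the fits offered;
least-absolute-deviations and ordinary least squares on the raw counts
are provided as alternatives. Applying the factors and re-fitting yields
slopes of 1 (idempotence), which the tests assert to 10⁻⁶. With 50 spike
genes at 10% observation noise, any through-origin estimator has a
standard error near 2% (the information bound is $\sqrt{2}\,\mathrm{cv}/\sqrt{n}$,
both samples being noisy), so recovery is validated on the typical
(median) error across samples and replicate simulations.

The silencing-defect rule is pure set logic over per-gene contrast
statistics: a gene qualifies iff it is significantly repressed
(negative log2FC, FDR < 0.05) in the euploid at some quiescent timepoint
*and* significantly higher than the euploid (positive log2FC,
FDR < 0.05) in **every** aneuploid strain at at least one timepoint. The
statistics themselves are pluggable: `builtin_contrast_test()` provides a
moderated two-sample test on log2 normalized counts (limma's
empirical-Bayes pooled variance), and externally computed per-gene tables
in the same layout are accepted unchanged.

# Screen analysis

`tmm_factors()` implements trimmed-mean-of-M-values normalization
natively: reference = the sample whose upper-quartile scaled count is
closest to the mean; per sample, gene-wise log-ratios trimmed 30% and
log-abundances trimmed 5% (two-sided), precision-weighted mean of the
surviving log-ratios, factors rescaled to geometric mean 1. It matches
edgeR's implementation to 10⁻⁹ on random tables (asserted in the tests,
where edgeR serves as the independent oracle).

Enrichment at day 1 or day 28 versus the starting pool is the difference
of mean log2 TMM-normalized abundances, with a moderated p-value across
replicates and BH correction across genes. The selection cascade is then:
significant positive day-28 enrichment in the aneuploid pool
(FDR < 0.1 by default; 0.05 is the strict alternative) **and** linear
enrichment at least 2-fold above the euploid's
($2^{\Delta \log_2}\!\ge\!2$ — the "linear difference" is a ratio of
fold-changes; a subtractive reading is not exposed because it is not
scale-free). Hits are classified *life-span-specific* when day-28
enrichment exceeds day-1 enrichment more than 2-fold, else
*early-benefit*.

# The synthetic-data generator

The generator produces data with exactly the statistical structure the
analyses assume, plus ground truth for recovery scoring. Its defaults are
the package's study conditions and are not tuned per test:

* **Genome** — 200 single-exon genes of 150–450 codons (stop included)
  over 16 chromosomes, round-robin, random strand, 500-nt spacers;
  background codons uniform over the 61 sense codons. Chromosome XII is
  duplicated with dosage 2.0 (a true duplication; the attenuated 1.7
  observed in vivo is a configurable alternative). Stop codons belong to
  the CDS; introns are never generated, so the intron-exclusion path is
  exercised with hand-written GFF3 fixtures instead.
* **Stalls** — planted at body codons with ≥ 10-codon flanks; occupancy
  multiplied 8-fold in the affected condition; P-site residues drawn
  K/N, A-site G/E (the stall chemistry reported for quiescent aneuploid
  yeast); placement uniform by default or Beta-skewed toward the 5' end
  to reproduce the positional shift of aneuploid-enhanced peaks.
* **Footprints** — per-gene expression log-normal (log2 sd 1); shared
  across samples so conditions differ only by dosage and stalls. Within
  genes, Dirichlet-multinomial allocation with per-codon concentration
  10 (≈ 30% biological CV per codon, comparable to codon-level
  replicate noise in real profiling data); flanking window codons carry
  a 0.1 relative weight. Totals are multinomial at the configured depth,
  so library totals are conserved. Read-start records, when requested,
  place 5' ends exactly 12 nt from the true P site (a single 28-nt read
  length is assumed, since only 5' ends matter downstream).
* **Spike-in RNA-seq** — per-sample global scales (the quantity to
  recover), spike counts with independent log-normal observation noise,
  host genes with quiescence repression (−3 log2 by default) and a
  planted defect set that fails to repress in aneuploids only.
* **Screen** — log-normal library proportions, negative-binomial counts
  (dispersion 0.1, triplicate, 2 × 10⁶ reads), planted early hits
  boosted $2^3$-fold at day 1 and 28, late hits at day 28 only, euploid
  pools untouched.

Generators restore the caller's RNG state; a fixed `seed` gives
byte-identical output. Sub-generators use fixed offsets from the seed so
their streams are distinct.

What the simulation does **not** emulate: sequence-dependent ligation and
nuclease bias, rRNA contamination, UTR biology, multimapping, codon-level
dwell-time structure beyond planted stalls, and the colony-bottleneck of
the screen beyond NB dispersion. Passing recovery tests therefore shows
the statistical machinery is correct under the stated noise model, not
that real libraries meet that model.

# Numerical choices and problem sizes

* Two-sided Fisher p-values use the `relErr = 1 + 10^{-7}` probability
  comparison, matching `stats::fisher.test()`; an all-zero table gives
  p = 1.
* All-zero traces get correlation 0 with a warning.
* `chromosome_dosage()` divides per-gene proportion ratios by the
  genome-wide median ratio before summarizing (like median-of-ratios
  size-factor normalization). Raw proportion ratios are compositionally
  shifted by the duplicated chromosome itself — every unaffected gene's
  share shrinks by the factor $1/(1+\varphi)$, with $\varphi$ the
  duplicated chromosome's expression share — so without recentring a
  clean 2-fold duplication reads as < 2 on the duplicated chromosome and
  < 1 everywhere else. `rescale = "none"` gives the raw ratios.
* Recovery simulations run at ~6 reads per body codon (the regime where
  the 50-read gene filter retains nearly all genes and per-codon Fisher
  tests are count-limited), null calibrations at the default depth of
  10⁶ footprints over 200 genes (~120,000 tested codons across two
  replicate pairs); correlation contrasts use 500 genes. These sizes
  make the whole test suite and the acceptance script run in a few
  minutes on one CPU while keeping every estimate comfortably inside its
  acceptance band.

# Known limitations

* The per-codon Fisher test assumes multinomial counting noise; with
  strong biological overdispersion and deep coverage it becomes
  anti-conservative. The empirical false-call fraction is measured in
  the acceptance suite at the default overdispersion and stays well
  under 10% at FDR < 0.05, but very deep libraries would need a
  count-model test instead.
* The built-in contrast and enrichment engines are deliberately simple
  moderated two-sample tests; for real data, statistics from a dedicated
  count GLM can be imported, and the selection rules consume them
  unchanged.
* Reads overlapping two gene windows are counted for both genes; with
  yeast-like spacing this duplicated mass is negligible, and the
  assignment report includes the multi-assignment count.
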