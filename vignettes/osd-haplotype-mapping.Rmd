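---
title: "Mapping divergent haplotype blocks from observed strain differences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping divergent haplotype blocks from observed strain differences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Two inbred strains bred out of the same founder colony inherit each
genomic segment either from the same founder haplotype — identity by
descent (IBD) — or from different founder haplotypes fixed during
selective inbreeding. Within IBD segments the only differences are
mutations that arose after the strains separated, a rate of order
10⁻⁶–10⁻⁵ per bp; within divergent segments the strains differ at the
founder population's polymorphism rate, order 10⁻³ per bp. The genome is
modelled as an alternating mosaic of these two regimes.

The observable is the Observed Strain Difference of each fixed
non-overlapping window (100 kb by default):

$$\mathrm{OSD}_w = S_w / C_w,$$

with $S_w$ the homozygous SNV differences in the window and $C_w$ its
callable bases (outside the union of both strains' zero-coverage gaps).
Using $C_w$ rather than the window length as denominator keeps
gap-rich windows comparable to fully covered ones. Only sites where both
strains carry homozygous, non-missing, mutually different calls are
counted: in fully inbred lines residual heterozygous calls are almost
always artifacts, and a site with a missing call in either strain is not
a difference that can be asserted.

Because the two regimes differ by more than two orders of magnitude, the
genome-wide OSD distribution is bimodal. The pipeline:

1. smooths the OSD values with a binned Gaussian kernel density estimate
   on 401 equally spaced grid points spanning $[0, \max(\mathrm{OSD})]$;
2. locates the Polymorphism Enrichment Threshold (PET): the OSD value at
   the first local density minimum after the first local maximum,
   scanning from 0;
3. merges maximal runs of adjacent windows with
   $\mathrm{OSD} \ge \mathrm{PET}$ into divergent haplotype blocks;
4. summarizes the comparison (windows above PET, block count and length
   moments, mean OSD on each side of the PET, SNVs contained in blocks).

The key assumptions are that the strains are fully inbred (homozygous),
that divergent segments are long relative to the window (so most windows
are cleanly one regime), and that enough of the genome is in each regime
for both density peaks to be populated.

## Tunable parameters

* `window_size` (bp, default 100,000). Smaller windows raise resolution
  but push IBD windows deeper into count-Poisson noise; at 100 kb an IBD
  window carries on the order of 0.5 expected SNVs while a divergent
  window carries ~150, a separation of three orders of magnitude.
* `grid_points` (default 401). Grid resolution of the density estimate;
  the PET is always reported at a grid point.
* `bandwidth` (OSD units, default: Wand–Jones oversmoothed selector for
  the Gaussian kernel, $h = 1.144\,\hat\sigma\,n^{-1/5}$, the default of
  the standard binned-KDE implementation in R). Oversmoothing is
  deliberate: the PET definition needs one clean valley, not fine
  structure. An explicit override is available for degenerate inputs or
  sensitivity analysis.
* `min_callable_frac` (default 0.10). Windows with fewer callable bases
  than this fraction of the window size get an undefined OSD and are
  excluded from density estimation and block membership: with a tiny
  denominator a single SNV can exceed any plausible PET.
* `pet` override. Skips valley detection; useful to propagate a PET
  between closely related comparisons or to probe sensitivity.

## The simulator, and what passing tests do and do not show

`simulate_mosaic()` generates the structure the analysis assumes:
alternating shared/divergent segments per strain pair, with divergent
segment lengths exponential (optionally shifted by a minimum length)
around a 0.9-Mb mean, divergent fraction 0.15, and per-pair SNVs as
Poisson processes at 5×10⁻⁶ and 1.5×10⁻³ per bp — the two regimes
observed between closely related inbred rat strains. Zero-coverage gaps
are placed per strain from an independent RNG substream (5% of the
genome, 20-kb mean length — typical short-read coverage dropout; the gap
process is a design choice, as gap statistics are platform-dependent).
One global seed drives deterministic per-chromosome/per-pair/per-strain
substreams, so chromosome order cannot change results.

The exponential segment-length law is the minimal-assumption choice for
a Poisson-process mosaic; block-length summaries of real comparisons
report only means and SDs, not a generative law, so this choice is ours.
The simulator does not model linkage phase, residual heterozygosity,
mutation spectra, multi-strain consistency of segments (each pair's
mosaic is drawn independently), or read-level error — so green recovery
tests demonstrate the windowing/density/valley/merging machinery, not
robustness to calling artifacts in real data.

Validation runs use 50-Mb genomes (500 windows) and 10 seeds: large
enough to populate both density modes and keep Poisson noise in check,
small enough that the full suite runs in seconds.

## Numerical choices

* **Grid range `[0, max]`.** Starting at 0 keeps the spike of zero-OSD
  (fully IBD) windows inside the first peak, which the PET definition
  requires.
* **Linear binning.** Each value splits its mass between the two
  bracketing grid points before convolution with the kernel; tests tie
  the result to the exact direct-sum estimate within 1% at every grid
  point, and to the reference FFT-based binned implementation.
* **Extremum detection.** Plateau runs of exactly equal density collapse
  to their first grid index. The grid boundary may host a *maximum* (the
  IBD peak can sit at 0) but never a *minimum*: a valley is by
  definition interior, so a monotone decreasing density is correctly
  classified as having no valley.
* **No-valley condition.** Signalled as a typed condition
  (`osd_no_valley`), not a plain error: the pipeline completes with an
  empty block list and a flagged summary.
* **Partial trailing windows** are retained (flagged) and enter OSD with
  their smaller denominator, but blocks containing them are excluded
  from block-length moments by default, since their length is not a
  multiple of the window size.
* **Multi-allelic records** are decomposed into biallelic sites; at a
  given biallelic site a homozygous call for a *different* alternate
  allele is treated as missing rather than as reference, so a position
  never counts twice.
* **Degenerate inputs.** All-identical OSD values make the bandwidth
  collapse; the error suggests an explicit bandwidth. All-zero OSD
  values make the grid degenerate and error out.

## Downstream conventions

* **QTL intersection** uses union semantics genome-wide (overlapping QTL
  are merged before computing totals) and keeps per-trait rows separate;
  `% narrowing = 100 − % covered`.
* **Genotyping-panel blocks** span from the nearest flanking monomorphic
  SNP on each side of a run of polymorphic SNPs (chromosome bounds at
  edges). The comparison labels — concordant / novel / refined /
  extended — are this package's total classification; "novel" (no
  overlapping panel block) is the only one with an external definition.
* **Mean OSD per peak** is reported as the arithmetic mean of window OSD
  on each side of the PET. Density mode locations are exposed separately
  (`density_modes()`) as an alternative statistic; which of the two a
  given published table used is not always stated, so both are
  available.
* **Fisher enrichment** uses the common two-tailed convention (sum of
  probabilities of all same-margin tables no more probable than the
  observed one), via the standard exact-test implementation. Carriers
  are strains homozygous for the minor allele; heterozygous or missing
  strains are dropped from that variant's table with a logged count. No
  multiple-testing correction is applied by default — published strain
  panel scans report raw p-values — but `p.adjust`-style correction can
  be layered on the output.

## Known limitations

* **Valley position scales with sample size.** The oversmoothed
  bandwidth shrinks only as $n^{-1/5}$, so with a few hundred windows
  the bandwidth is 2–3× larger than at genome scale and the detected
  valley sits higher in the OSD range. Segment-edge windows with partial
  divergent overlap then fall below the PET, trimming roughly one window
  per block edge. Desk-scale block sets therefore slightly under-cover
  true divergent bases; this is quantified by the recovery metrics the
  acceptance script computes.
* **Count discreteness at the IBD rate.** With ~0.5 expected SNVs per
  window, IBD windows have OSD values on a lattice (k / callable). When
  there is no divergent class at all, the sample SD — and with it the
  bandwidth — is small relative to the lattice spacing, so the smoothed
  density is genuinely multimodal and a valley is found between the
  0-count and 1-count modes. A fully IBD comparison thus yields a PET
  near 1/window-size with scattered single-window "blocks" rather than
  the no-valley condition. Inspecting the PET magnitude (orders of
  magnitude below the divergent regime) exposes such cases; the
  continuous-unimodal case does raise the condition.
* **Window-grid resolution.** Block boundaries are window-aligned; a
  true segment boundary is located no better than ±1 window.
* The method identifies *candidate* regions: phenotype-driven selection
  of divergent haplotypes is an assumption, and post-separation
  mutations with phenotypic effect are invisible to it.
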