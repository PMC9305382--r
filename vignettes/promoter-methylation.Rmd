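---
title: "Quantifying promoter methylation from direct bisulfite Sanger traces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying promoter methylation from direct bisulfite Sanger traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sangermeth)
```

## The measurement model

Direct bisulfite sequencing reads a *pooled* PCR product on a Sanger
instrument. Bisulfite converts unmethylated cytosine to uracil (amplified
and read as T) while 5-methylcytosine stays C, so at every cytosine
position the chromatogram superimposes the C and T signals of thousands
of template molecules. The population methylation fraction *m* of a
plus-strand cytosine is therefore estimated from the two peak heights:

$$\hat m = \frac{C}{C + T} \times 100 \ (\text{forward reads}), \qquad
  \hat m = \frac{G}{G + A} \times 100 \ (\text{reverse reads}).$$

The package's orientation convention: traces are stored at plus-strand
coordinates with plus-strand base labels; forward reads quantify
plus-strand cytosines (C/T peaks), reverse reads quantify minus-strand
cytosines (G/A peaks at the plus-strand G position). Under this
convention the two members of a symmetric CG pair — which share one
methylation state through maintenance methylation — are measured
independently by the two read directions, and their estimates coincide on
noiseless data; this is a tested invariant.

Key assumptions, and when they fail:

* **Mixture proportionality.** Peak height is proportional to the
  template fraction carrying that base. Real chromatograms deviate
  (dye-dependent incorporation, local context effects); the estimator is
  exactly scale-invariant, so only *differential* channel distortion
  biases it.
* **Complete conversion.** An unmethylated cytosine that escapes
  conversion reads as C and inflates $\hat m$: with conversion
  efficiency $e$ the expected read-out at a site with true fraction $m$
  is $m + (1-m)(1-e)$, so a fully unmethylated site reports
  $100(1-e)$ percent (5% at $e = 0.95$). This closed form is verified by
  simulation, and the demethylated PCR control estimates $e$ as
  $100 - \overline{\hat m}_{\text{control}}$, with a warning below 95%
  and a hard abort below 90%.
* **No-data is not zero.** A site whose two formula-relevant channels are
  both zero carries no information. It is flagged `no_data`, excluded
  from every denominator, and counted in QC; coding it as 0% would
  deflate general-methylation percentages.

## Statistics

A cytosine is **called** methylated when its specific percent is strictly
greater than 50 — exactly 50 is unmethylated. Per context (CG, CHG, CHH)
and pooled (Total): *general* methylation is the percentage of called
sites, *specific* methylation the mean per-site percent. The Total row
pools sites rather than averaging the three context percentages, so the
Total tracks the dominant context by site count; a context with no
measured sites prints "-", never 0.

Lines are compared per context with Welch's unequal-variance t-test on
per-site percents (sites are the units; site counts and variances differ
between lines, so the pooled-variance test is not appropriate). No
multiple-testing correction is applied across the four context rows,
matching standard practice for this table layout. Degenerate inputs are
resolved explicitly, since `t.test()` refuses constant data: both groups
constant and equal means gives p = 1; constant groups with unequal means
gives the smallest positive representable p, flagged `zero_variance`.
Star codes are `*` p < 0.05, `**` p < 0.005, `***` p < 0.001.

**Hotspots** are maximal runs of at least `min_run = 4` consecutive
methylated cytosines in site order (irrespective of nucleotide gaps);
the default reflects the clustered groups of 4–5 methylated cytosines
observed in heavily methylated promoter stretches. No-data sites break
runs: bridging them would fabricate contiguity the data does not show.

## Promoter anatomy and %Y profiling

Coordinates are 1-based closed intervals; BED export converts to 0-based
half-open at the boundary only. The core promoter is TSS ± 35 nt; the
proximal promoter is the 200 nt upstream of the core, i.e. [−200, −36]
relative to the TSS; the distal promoter is everything further upstream.
The literature definition of the proximal region is stated inconsistently
(its boundaries cannot simultaneously be "200" and "−100"), so the
package adopts the reading that tiles the upstream sequence without gaps
and leaves both extents configurable.

Pyrimidine content (%Y = %C+T) is profiled in 30 bp windows at step 1
(decimation is presentation-only). The **Y-region** detector merges
windows at or above 55 %Y, bridges sub-threshold gaps of up to 10 nt, and
accepts the widest merged block spanning at least 100 nt whose 3′ end
lies within 50 nt of the CDS start — the Y-patch region involves at least
100 nt immediately upstream of the CDS. The threshold and merge gap are
explicit package choices (the source analyses only say "selected
accumulations of %Y"); they are configurable and logged in the run
manifest.

The package bundles the published single-nucleotide composition counts of
the three taxane-pathway promoters
(`published_composition_counts()`). Four printed rows disagree with
their own counts (all three proximal-promoter rows and the TXS core row,
plus one purine percentage); these are flagged `self_consistent = FALSE`
and excluded from numeric reproduction rather than silently accepted.

## Motif scanning and methylation overlap

Cis-elements are matched as exact IUPAC consensus strings — the upstream
predictions these analyses compare against come from consensus-style
tools, and a position-weight score would invent information the consensus
does not carry. Low-affinity variants are separate catalog entries. The
MYC (CACATG), LHY (AAAATATCT) and AP2/ERF (GCCGGC) consensi are documented
assumptions, overridable through a YAML catalog that merges with the
built-ins by name. A TFBS counts as *affected by methylation* when at
least one methylated cytosine lies within its span (the minimal reading
of overlap marks in published figures).

Matching is delegated to `Biostrings::matchPattern(fixed = "subject")`;
the test suite cross-checks every hit set against an independent
position-by-position IUPAC matcher.

## The bisulfite-aware aligner

Reads are aligned to the *unconverted* reference with a global affine-gap
aligner (match 2, mismatch −3, gap open 10, extend 1) whose substitution
rule is asymmetric: in forward orientation read T matches reference C
(conversion) but read C does not match reference T; in reverse
orientation read A matches reference G. Off-the-shelf aligners require
symmetric substitution matrices and cannot express this one-directional
tolerance, hence the built-in implementation. Reads below 80% alignment
identity are rejected as unmappable. In the packaged pipeline the
trace_tsv format already carries reference coordinates, so the aligner
serves base-called sequence input and QC rather than the hot path.

## Primer and amplicon design

Direct bisulfite PCR needs primers that anneal regardless of template
methylation: every C in the forward primer becomes Y (C/T) and every G in
the reverse primer becomes R (A/G). Targets are tiled with amplicons of
150–300 bp overlapping by ≥ 30 bp (overlap and primer length 25 are
package defaults; the source protocol does not state them). Within a
±10 nt jitter window each primer minimises its degenerate-base count,
then the distance of its non-degenerate GC fraction from 0.5 (a crude
melting-temperature proxy); the jitter budget is reserved out of the
length bound so tiled products can never exceed 300 bp.

## What the simulator emulates — and what it does not

`simulation_config()` encodes the study conditions: a 2,000 nt promoter
at GC 0.40 with TSS at 1,689 and CDS start at 1,891 (the ~200 nt
TSS–CDS spacing of the *DBTNBT* promoter); a planted cytosine-poor core
(≤ 2 C in 71 nt, the *GGPPS* anomaly), a planted 130 nt pyrimidine- and
cytosine-rich block upstream of the CDS (C 35%, T 35%), planted motif
instances inside and outside the hotspot; and two lines whose per-context
true means are the published specific-methylation levels of the most
heavily methylated promoter — old line CG 0.92 / CHG 0.96 / CHH 0.60, new
line CG 0.60 / CHG 0.53 / CHH 0.14, sd 0.05 — plus a fully methylated
200 bp hotspot in the old line only. Conversion efficiency defaults to
0.99 (modern kit performance), channel noise to an additive truncated
Gaussian of sd 5 intensity units on a 300-unit total signal. Symmetric
CG pairs share one true *m* per line; CHG/CHH strands are independent.

Intensities are mixture-proportional, not read-count based, matching
pooled-template Sanger physics. The simulator does **not** model
base-calling errors, dye blobs, mobility shifts, primer bias, or
spatially correlated noise — so passing recovery tests demonstrates the
estimator and pipeline logic, not robustness to every chromatogram
artifact. Clipping noisy channels at zero slightly inflates estimates
near 0% (visible as control efficiencies of ~98.7% under a simulated
99%); this mirrors the real-data behaviour that incomplete conversion
and baseline noise can only inflate, never deflate, apparent methylation.

All draws are seeded; reference, methylome and trace generation use
offset seed streams so each stage is independently reproducible, and the
whole bundle is byte-identical under a fixed seed.

## Numerical and degenerate-input choices

* Threshold comparisons are strict (`> 50`), per the calling definition.
* Percentages are kept at full precision internally; reports round to
  1 decimal (composition) or 2 decimals (methylation summary).
* Cytosines whose 2 nt context window runs off the sequence end are kept
  and flagged `truncated` (dropping them would change denominators);
  the undeterminable cases default to CHH, the majority class.
* Ambiguity codes are rejected at ingest with the offending position —
  context classification and composition are undefined on them.
* Replicate measurements of one site are merged by unweighted mean
  (each read is one measurement of the same template population);
  forward/reverse averaging is the default orientation policy, with
  single-orientation policies available.

## Problem sizes used in validation

The packaged checks use a 700 nt promoter (≈ 280 cytosine sites) for
end-to-end runs, 100 independent 420 nt datasets for noisy parameter
recovery (mean absolute error of per-context specific percent < 2
points), a 3,000 nt reference (> 1,200 sites) for the
incomplete-conversion closed form, and 10,000 null replicates (n = 20
sites per group) for Welch type-I-error calibration — sizes chosen so the
whole suite exercises every stage in well under the patience of a desk
check while keeping Monte-Carlo error far below the tested tolerances.

## Known limitations

* AB1 binary chromatograms are not parsed; peak heights must be exported
  to the documented `trace_tsv` dialect upstream.
* Consensus matching cannot rank partial or low-affinity sites; the
  catalog approach trades sensitivity for transparency.
* The published numeric methylation table for the original promoters is
  not reproducible from first principles (its raw traces are not
  public); validation is by parameter recovery on synthetic data plus
  the self-consistent published composition rows.
* TSS prediction is out of scope: the TSS and CDS start are user-supplied
  configuration.
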