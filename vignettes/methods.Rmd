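---
title: "Automated microsatellite genotyping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated microsatellite genotyping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(msatools)
```

# The assay and what this package automates

msatools implements the data-analysis half of a high-throughput
microsatellite assay: eleven loci amplified in two multiplexed PCR
reactions (group 1: Bat25, Bat26, D3S3623, D5S346, D6S262, D7S481;
group 2: D2S123, D3S1262, D9S171, D17S250, D18S61), labelled with three
dyes (FAM, HEX, NED) and separated by capillary electrophoresis
alongside a ROX-labelled internal size standard spanning 35–500 nt.
Same-dye amplicons are placed at least 40 nt apart by design so that
population variation and instability never collide;
`validate_panel()` checks this rule on either the expected product
ranges or the wider marker windows (the Bat26/D6S262 *windows* are only
25 nt apart — the rule holds for products, and the validator reports
both bases rather than guessing which was intended).

The pipeline is: detect peaks per dye channel, match the ROX ladder,
convert scans to base pairs by Local Southern sizing, remove
between-marker artifacts with per-dye range filters, and call alleles
per marker — a stutter-aware two-allele rule for dinucleotide repeats
and the 0.95 mono cut-off rule for the quasimonomorphic mononucleotide
markers.  Downstream, the package computes process QC (per-allele
sizing %CV across replicate runs, percent deviation from expected
genotypes, control charts), MSI classification, LOH allele ratios, and
Mendelian lineage checks.

# Fragment sizing

Electrophoretic mobility is reciprocal in fragment length: scan
position follows $m(L) = m_0 + c/(L - L_0)$.  Local Southern sizing
inverts this locally: for a query scan the four nearest matched
standards $p_1 < p_2 \le m \le p_3 < p_4$ define two exact three-point
reciprocal curves (through $p_1 p_2 p_3$ and $p_2 p_3 p_4$, solved in
closed form), and the reported size is the mean of the two predictions.
Because each curve interpolates its standards exactly, a query on a
matched standard returns that standard's size, and data generated from
any reciprocal law are recovered to machine precision.  Queries with
fewer than two standards on a side are flagged unsized, never
extrapolated — extrapolation silently degrades precision, and the
usable interval (50–490 nt for the GS500 list) comfortably covers every
marker window (70–240 nt).

Two comparators are included because they are the standard
alternatives: a single least-squares reciprocal curve over all
standards (Global Southern) and a third-order polynomial
(`cubic_ls`).  On reciprocal-law data the cubic has a systematic
lack-of-fit that Local Southern does not; the test suite demonstrates
both the bias gap and comparable replicate-to-replicate precision.

Ladder matching assigns the known fragment sizes to a monotone subset
of detected ROX apexes by minimizing the RMS residual of one reciprocal
fit; up to three surplus candidates are resolved exhaustively, beyond
that the shortest candidates are thinned first (ladder fragments run at
similar signal).  A fit worse than 2 bp RMS is a ladder failure and the
run is unusable — `genotype_run()` converts this into a run-level
no-call rather than an error, since one failed capillary should not
abort a plate.

# Peak detection

The advanced detection algorithm of the original instrument software is
proprietary; the detector here is a documented stand-in built from
standard pieces: a running-minimum baseline (wide centred window,
interpolated and smoothed), candidate maxima on a 5-point moving
average, sub-scan apex localization by quadratic interpolation of log
intensity (exact for Gaussian pulses), and apex height as the 3-point
median around the apex so that a one-scan electrical impulse riding on
a real peak cannot inflate its measured height.  Isolated spikes are
rejected by the minimum peak half-width (half width at half height):
4 points for group 1, 2 points for group 2, matching the assay's tuned
parameters; the default height floor is 50 fluorescence units, a
typical genotyping threshold.

# Allele calling

Fragments are assigned to integer bins with a maximum offset of
±0.5 bp; an exact tie between centers breaks toward the lower center.
With the full-adenylation default (below), apparent sizes sit on a
+1-shifted lattice, which the default bin centers absorb
(`window_min + 1`, stepping by the repeat unit).

For dinucleotide markers, a peak one repeat unit below a taller peak
with height ratio ≤ 0.8 is discarded as stutter; comparisons use
original heights so whole stutter ladders cascade away while true
heterozygotes one repeat apart (ratio near 1) survive.  Among binned
survivors the two tallest become alleles 1 and 2.  The 0.8 threshold is
a documented, configurable default: the source assay specifies bins and
range filters but not its dinucleotide peak-selection rule.

For the mononucleotide markers the tallest in-window peak is allele 1
and every peak whose ratio to it is *strictly* greater than the mono
cut-off (0.95) is an additional allele — the strict reading of
">95% of the maximum peak height"; a ratio of exactly 0.95 is not
called.  Height ties break toward the smaller size.

Range filters deserve a note because their semantics are easy to
misread.  The configured intervals (group 1: FAM 146–194, HEX 136–159,
NED 116–174; group 2: FAM 181–250, HEX 151–199, NED 131–174) are
*exclusion* windows: each spans exactly the gap between the two
same-dye marker windows of its group, disjoint from every window.
Peaks inside them — notably HEX→FAM bleed-through images of Bat26/D6S262
and D2S123 — are removed before marker assignment; anything outside a
marker window is additionally excluded at assignment.  Read as
retain-intervals they would delete every true allele, which settles the
interpretation.

# The synthetic-data generator

No raw traces are published for this assay, so validation rests on a
ground-truthed simulator that emulates the statistical structure of the
real data.  Per marker it draws genotypes from allele frequency tables
(dinucleotide: a uniform ladder on the repeat lattice well inside the
window; Bat25/Bat26: quasimonomorphic with modal probability 0.96 and
modal apparent sizes 127 and 122 nt, the assay's control values), then
expands each allele into a main peak plus a geometric stutter ladder
and renders Gaussian pulses on a four-channel trace with the ROX ladder,
HEX→FAM spectral bleed, one-scan spikes, broad nonspecific products,
baseline and white noise.  All randomness flows through explicit seeds.

Parameter defaults, with the reasoning:

* **Adenylation fraction 1.0.**  The assay's GTGTCTT primer tails were
  chosen to drive essentially complete +A addition, so apparent sizes
  sit one nucleotide above the template lattice.  Partial adenylation
  (split ±0/+1 peaks) is available for robustness experiments.
* **Stutter ratios**: adjacent-stutter ratio drawn per allele,
  Uniform(0.30, 0.60) for dinucleotide and Uniform(0.85, 0.90) for
  mononucleotide repeats; the k-th stutter is the adjacent ratio to the
  k-th power, truncated below 1% of the main peak.  These are simulator
  choices, not measured values.  The mononucleotide upper bound is set
  with the rendering physics in mind: 1-nt-spaced pulses overlap, which
  inflates each measured apex by a factor ≈ $1 + g(r + 1/r)$ with
  $g = e^{-d^2/2\sigma^2}$ for spacing $d$ and pulse width $\sigma$; the
  bound keeps every overlap-inflated secondary ratio below the 0.95
  cut-off, reproducing the assay's tuned at-most-two-alleles behaviour
  for stable samples.
* **Mobility** $m(L) = -9500 - 9{\times}10^6/(L - 900)$: strictly
  increasing and invertible on 35–500 nt, about 14 scans per nucleotide
  at 120 nt — enough to resolve mononucleotide stutter combs against
  the 4-point pulse width, comparable to a capillary instrument.
* **Migration noise 0.08 bp SD per fragment species** (not per allele
  copy: identical-length fragments co-migrate, so a homozygote's two
  copies render as one coherent pulse).  The co-electrophoresed ladder
  defines the size axis and cancels common-mode migration variation by
  construction, so ladder fragments carry only a small residual jitter
  (`ladder_sd`, 0.02 bp).
* **Bleed coefficient 0.05** (HEX into FAM), spikes at rate 2 per
  trace, nonspecific products at rate 1.5 placed outside same-dye
  marker windows, baseline 20 units with white noise SD 5, pulse
  sigma 4 scans (half-width at half height 4.7 points, clearing the
  group 1 minimum of 4).

What the simulator does *not* model: physically accurate
electrokinetics, instrument spectral calibration matrices, saturation
and off-scale peaks, inter-run mobility drift, and sample-matrix
effects.  Passing tests therefore show that the algorithms are correct
under the stated statistical structure, not that the pipeline is
validated on any particular instrument's raw files.

# Quality-control statistics

`sizing_cv()` reports, per (marker, bin), the percent coefficient of
variation of sized lengths across replicate runs, using the sample
(n−1) standard deviation — the small-n convention for replicate series;
single observations are reported as missing, not zero.
`percent_deviation()` scores each expected genotype as two alleles per
marker (a homozygote's single observed call covers both); a spurious
called allele counts every expected allele of that marker as miscalled,
the conservative convention for nonspecific signals identified as
alleles.  For the mononucleotide markers a deviation of one nucleotide
is accepted as normal polymerase slippage and applied symmetrically
(|observed − expected| ≤ 1 nt): which side of the modal allele the
slippage product lands on depends only on how allele 1 is anchored, so
a one-sided tolerance would score the same biology differently in
different runs.  The statistic is additive over day partitions, and
`control_chart()` attributes deviations to process (control failed) or
sample integrity (control passed).

On simulated replicate series (23 runs, group 1 control, 0.08 bp
migration noise) the pipeline's per-allele %CV falls in the
0.03–0.09% range, inside the 0.05–0.12% precision envelope the assay
reports, and `scripts/acceptance.R` recomputes this end to end.

# Downstream analyses

MSI classification compares a sample profile to a reference profile:
mononucleotide markers are unstable only at shifts of ≥3 bp (Bat25) or
≥4 bp (Bat26) — the published convention for true somatic alteration of
these markers — while ±1 nt stays normal; dinucleotide markers are
unstable on any novel bin.  The overall call uses the five-marker NCI
panel (Bat25, Bat26, D2S123, D5S346, D17S250): MSI-H at ≥2 unstable,
MSI-L at 1, MSS at 0.  The per-marker stability table is the primary
output; the overall label follows the workshop convention, which the
source assay references but does not restate.

LOH uses the community-standard ratio
$R = (T_1/T_2)/(N_1/N_2)$ on bin-matched allele heights with strict
bounds 0.5 and 2.0 (configurable); markers with a homozygous normal are
uninformative, and relabelling alleles maps $R \to 1/R$ without
changing the call.  `lineage_check()` tests per marker whether a
child's allele pair can be drawn one-from-each-parent, records the
parent of origin when unambiguous, and flags children with identical
bins at every marker as possible monozygotic twins.

# Numerical and degenerate-input conventions

* Closed-form three-point reciprocal solves reject collinear
  configurations (vanishing denominator) as fit errors.
* The Global Southern fit seeds `nls` from an exact three-point solve;
  `scaleOffset` makes its convergence test valid on zero-residual data.
* Empty traces, empty peak sets and all-constant channels yield empty
  results or no-call profiles, never errors; ladder failure is an error
  at `match_ladder()` level and a flagged no-call at run level.
* Sizes are reported to 0.01 bp in files; bins are integers; scan
  indices are the trace's own axis.

# Problem sizes used in validation

The bundled validation suite runs entirely on simulated data sized for
a laptop-class machine: a 100-sample end-to-end concordance study (both
multiplex groups, ~2,200 alleles, mirroring the scale at which the
assay reports 0.63%/0.77% deviation), 23-run replicate precision
series, 12–15-run sizing-method comparisons, and small families for
lineage checks.  These sizes were chosen so the full suite completes in
about a minute while keeping every statistic's sampling error an order
of magnitude below the thresholds being tested.

# Known limitations

* The peak detector is a documented substitute for an undocumented
  proprietary algorithm; parameters match the assay's, internals do not.
* Bin calibration from a reference cohort is emulated
  (`default_bins()` covers the full +1-shifted lattice) rather than
  learned from the unpublished 5,508-allele reference dataset.
* Saturated/off-scale peaks are not modelled; no claim of fidelity is
  made for them.
* ABIF ingestion (`read_abif()`) is a best-effort adapter with a fixed
  channel-order heuristic; the canonical interchange format is the
  plain TSV trace.
* No inter-run size correction factor is applied before binning (the
  assay deliberately measured total variation without it); a hook
  exists but is off by default.
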