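---
title: "Models and methods behind mitosense"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mitosense}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

mitosense packages the quantitative procedures used to study the
PINK1–Parkin mitophagy pathway with reporter assays: a FACS-bin CRISPRi
screen read out by MFN2-Halo fluorescence, single-cell flow-cytometry
statistics for several reporters, mask-based quantification of confocal
images, and downstream proteomics statistics. This vignette explains each
model, the tunable parameters, and the design choices made where the
published procedure leaves the design open. All empirical statements below
are reproduced by the package's test suite or by `scripts/acceptance.R`;
nothing here is asserted beyond what those compute.

## Screen scoring

The screen sorts cells into the top 30% and bottom 30% of reporter
fluorescence and sequences guide abundance in each bin, in duplicate.
Scoring proceeds guide-by-guide:

1. **Zero-count filter.** A guide is dropped if any replicate of either bin
   has a read count of 0.
2. **Guide differential** (`guide_differential()`). Counts are
   size-normalized per replicate by median-of-ratios across guides (the
   median taken in log space, the DESeq convention), and the guide log2
   fold change is
   $\log_2\frac{\bar h + c}{\bar l + c}$ with pseudocount $c = 0.5$.
   This stage is a transparent stand-in for an external guide-ranking
   pipeline: the published analysis consumed another tool's guide-level
   summary, and what matters downstream — the gene score and the
   six-screen classifier — only needs a sanely calibrated guide test.
   The default two-sided test standardizes each guide's mean replicate
   log-ratio by the variance pooled across all guides. The pooling is
   deliberate: with two replicates a per-guide Student t has one degree of
   freedom, whose heavy tails make Bonferroni-corrected significance over
   thousands of guides unreachable at any effect size, while under the
   near-homoscedastic noise of equal-coverage count data the pooled z is
   both calibrated (null rate of $p<0.05$ sits in the 3–7% band) and
   powerful. A per-guide t (`test = "t"`) and a guide-label permutation
   null (automatic with a single replicate) are also available.
3. **Bonferroni correction.** Default is the standard `min(1, p * m)` over
   the `m` surviving guides. Some reports describe the correction as
   *dividing* p by the number of tests, which moves p the wrong way; that
   variant is exposed as `mode = "as_printed"` strictly for reproducing
   such a pipeline and is never the default.
4. **Gene score.** $(-\log_{10} p_{\mathrm{adj}}) \times \mathrm{log2fc}$,
   so the sign tracks the direction of regulation. An adjusted p of
   exactly 0 (floating-point underflow) is clamped to the smallest
   positive double, with a warning.
5. **Guide-to-gene aggregation.** The published analysis names guide-level
   values but plots gene-level points without stating the aggregation, so
   the method is a flag, not a claim: the default `best_guide_pair` takes
   the two largest-|score| guides agreeing in sign (gene log2fc = their
   mean, gene p = their max — requiring *both* top guides to clear the
   bar, a phenotype-consistency requirement in the spirit of dual-guide
   designs), with plain means as the alternative. Ties break by
   lexicographic guide id for reproducibility. Gene significance is
   Bonferroni-corrected p < 0.05; the hit definitions say only
   "significant", and gene-level Bonferroni matches the correction used in
   the same analysis paragraph.

**Hit classification** uses the published thresholds verbatim across the
six screens (HeLa ± Parkin, HEK293; untreated vs OXPHOS-inhibited):
activators are significant with log2fc < −1 in untreated HeLa + Parkin
and a difference < −1.25 versus untreated HeLa without Parkin;
facilitators are significant with log2fc > 1 in treated HeLa + Parkin
exceeding both comparators by > 1 (the "at least greater than 1 compared
to" sentence is read as a difference rule, parallel to the activator's);
MFN2 down/up-regulators are significant with |log2fc| > 1 in both
Parkin-free untreated screens and are excluded if already called
activator/facilitator. Symbol harmonization (TIMM23B→TIMM23,
HSPE1-MOB4→HSPE1, PARK2→PRKN) is applied before MitoCarta-style
annotation.

## The screen simulator

`simulate_screen()` is first-class, tested code: it is the ground truth
against which scoring is validated. Per cell, the reporter value on the
log2 scale is the guide's knockdown effect plus Gaussian noise
(`reporter_sd`, default 1 log2 unit — a wide single-cell reporter
distribution, as FACS histograms of such reporters show); bin membership
follows the empirical top/bottom `sort_fraction` (default 0.30) of the
pooled mixture, mirroring gating without modelling optics. A guide's
expected read count in a bin is proportional to its reporter mass beyond
the cutoff, scaled so a null guide averages `baseline_mean` reads
(default 500, a typical genome-wide coverage per bin), and counts are
negative binomial with variance $\mu + \mu^2/\phi$ (dispersion
$\phi = 10$, typical screen-count overdispersion). Guides within a gene
get multiplicative efficacies 1.0, 0.8, 0.6, … (floored at 0.2), so gene
aggregation is stressed by heterogeneous potency. The simulator does not
model sequencing error, guide cross-reactivity, or growth effects during
culture; passing recovery tests shows the scoring machinery is correct
and calibrated under the declared noise model, not that real screens are
free of those artifacts.

## Flow-cytometry statistics

All population summaries are arithmetic means of raw intensities
(medians are an option). The degradation statistic is computed exactly as
printed,
$$100 \cdot \frac{\mathrm{normint}^{+} - \mathrm{normint}^{-}}
                  {\mathrm{normint}^{+}},$$
with each population's mean divided by its control-guide mean. As
printed, the value is *negative* when the Parkin-positive population
loses reporter signal; the sign convention is preserved and documented
rather than silently flipped. The flow simulator plants
`true_degradation_pct` as the fixed point of this formula (the
marker-negative subpopulation's reporter mean is scaled by $1 - d/100$),
so recovery tests compare against the formula's own ground truth.

mt-Keima gating first corrects the neutral-excitation channel for a 10%
spillover from the YFP channel, flooring at 0 (negative corrected
intensities are non-physical for gating), then counts events inside a
polygon gate on the (corrected neutral, acidic) plane. The published
gate's vertices are never printed, so the gate is required config; the
boundary of the polygon is exclusive (a measure-zero choice).

The quadrant analysis normalizes each sample's MMP-dye (MitoLite)
intensity by the "normalization factor" — the mean dye intensity of that
sample's guide-negative reference population (PINK1-low, BFP-low events)
divided by the control sample's — and partitions events by fixed cutoffs,
boundary events counting as "high". The cutoff values are never printed
and are required config; the PINK1 cutoff is in raw channel units (PINK1
values are not modified by the normalization), while the MMP cutoff is
specified in control-relative units (1.0 = the control's guide-negative
reference mean). That unit choice makes the high/low split algebraically
equal to `raw / sample_reference_mean >= cut`, so the quadrant fractions
are invariant to detector gain — a fixed raw cutoff would silently change
meaning between instruments, and with the normalization as printed could
not be rescale-invariant.

The BFP threshold separating guide-positive from guide-negative cells is
likewise config (the published gating names no number); the suggested
default is the 95th percentile of a no-guide control.

## Image quantification

Channels are cropped to a user-supplied cell polygon (outside set to 0,
as the published macro sets the background color to black), linearly
rescaled per channel to 8 bits (min→0, max→255 — the reproducible reading
of a display-range-dependent bit-depth downgrade), and thresholded
inclusively at (80, 255). The mask algebra follows the macro verbatim:
the mitochondrial mask is the union of the MTS and MMP-dye masks;
`partition_a` is the mitochondrial mask minus the dye mask and
`partition_b` the remainder. The macro labels `partition_a` "high MMP",
yet the dye accumulates in *polarized* mitochondria, so dye-negative
objects are the ones that lost membrane potential; the partition is
computed as printed and the macro's labels are carried in the `labels`
field rather than silently corrected. Connected components use
8-connectivity (the default particle behavior of common tools),
implemented as iterative minimum-label propagation; ROI means are taken
from the raw, pre-quantization intensities, since quantization exists
only to build masks.

"R over background" is the in-ROI Pearson coefficient minus the mean
coefficient over 20 control images in which the second channel is
randomized. The published plugin's randomization kernel is unspecified;
the default here transposes square pixel blocks (5 px, the scale of an
object's width), which preserves local texture and is the conservative
Costes-style null; a per-pixel shuffle is a flag. Pearson is computed so
that perfectly collinear inputs return exactly ±1 (plain `cor()` can be
one ulp off). Constant channels raise a statistic-undefined error.

The image simulator draws random-walk skeletons dilated to 3–5 px,
placed without mutual contact so each connected component corresponds to
one planted object; it renders matrix marker, MMP dye (high-MMP objects
only) and PINK1 channels with additive clipped Gaussian noise. It does
not model depth, point-spread blur, or uneven illumination.

## Proteomics post-processing

Differential abundance uses a two-sided t-test on log2 abundances
(classical equal-variance by default, matching the published wording
"Student's t tests"; Welch is an option), fold change as the log2 ratio
of linear condition means, BH FDR across all tested proteins, and the
joint flag FDR < 0.05 with |log2fc| above the per-experiment cut (1.0,
or 0.5 where so designed). Proteins with fewer than two observed
replicates, or over half missing, in either condition are excluded rather
than imputed — distribution-based imputation belongs to the upstream
search platform and is out of scope here. Per-sample normalization to the
non-mitochondrial protein median and the strong-presequence rule
(mitochondrial, not primarily outer-membrane, MTS score ≥ 2, MTS start
< 20 residues) are pure arithmetic on the annotation fields, with the
boundary conventions exactly as printed (≥ 2, < 20).

## Numerical and scale choices

Every stochastic operation takes an explicit seed; there is no silent
default randomness, and identical configuration plus seed reproduces
outputs byte for byte. Validation problem sizes were chosen once as
realistic desk-scale conditions: screens of 1,000 genes × 5 guides × 2
replicates with 50 planted hits at reporter shift −3; flow samples of
50,000 events; 256×256 noise fields and ~20-object images for the
colocalization and partition checks. The exactness checks (worked BH
example, non-mitochondrial median of 1) use an odd count of
non-mitochondrial proteins so the median is a datum and the
post-condition holds exactly in floating point.

## Known limitations

The guide test is a calibrated stand-in, not a reimplementation of the
published ranking tool; absolute p-values differ even where ranks agree.
Gates and cutoffs that the published analysis applied by eye are inputs
here, so results depend on them exactly as the original analysis did.
The simulators are deliberately minimal and should not be mistaken for
instrument models; they exist to plant known truth under a declared noise
model.
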