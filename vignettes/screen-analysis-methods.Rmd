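---
title: "Morphometric screen analysis: models, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphometric screen analysis: models, statistics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuritescreen)
```

## The analysis problem

`neuritescreen` implements the statistical pipeline of a high-content siRNA
screen for early neuronal morphogenesis. The experimental design it models:
P19 stem cells in 384-well plates are co-transfected with a neurogenic
transcription factor (driving neuronal differentiation), a cytosolic EGFP
reporter, and siRNA against one gene per well, in triplicate plates with
4-point dose titrations (0.5–4 pmol). Each plate carries 20 positive-control
wells (differentiated, no siRNA) and 20 negative-control wells (not
differentiated). Six microscopic fields per well are imaged in a neuronal
marker channel (β-III tubulin) and the reporter channel, and summarized into
four per-field totals: total neurite length (px), total neuronal cell-body
area (px), total marker intensity and total reporter intensity
(background-corrected counts).

Three biological readouts are derived from these totals:

* **growth** — proliferation of transfected precursors, read from the
  reporter intensity;
* **differentiation** — how much neuronal cell-body area is produced per
  unit of reporter signal;
* **outgrowth** — how much neurite length is produced per unit of cell-body
  area.

## The regression-deviation statistic

Raw well means are first transformed to percent of the plate's controls:
the reporter uses the two-point transform
$100\,(v - \bar{v}_{neg})/(\bar{v}_{pos} - \bar{v}_{neg})$, while the
marker-derived area and length use percent of the positive-control mean
only, because undifferentiated negative controls carry no neuronal marker
(their area and length are zero by definition, not by measurement).

Growth is scored as the percent-scale z-score of the reporter against the
positive controls. Differentiation and outgrowth are ratio readouts and are
deliberately not scored as plain ratios: a well with half the cells has half
the reporter *and* half the area, and should score zero for
differentiation. Instead, for each plate an ordinary least-squares
regression line is fitted through the 20 positive-control points — area%
against reporter% for differentiation, length% against area% for outgrowth —
and each well is scored by its signed orthogonal deviation from that line:

$$d = \frac{m x - y + b}{\sqrt{m^2 + 1}}$$

with $m$, $b$ the slope and intercept. $|d|$ is the Euclidean point-to-line
distance; $d > 0$ means the point lies *below* the line (less area per
reporter, or shorter neurites per area). Because a pure change in cell
number moves a well *along* the control line, the deviation isolates the
specific phenotype from the proliferation phenotype. The OLS fit uses
vertical residuals while $d$ is orthogonal; these are two separate choices,
both stated parts of the procedure, not an inconsistency.

Each well's $d$ is divided by the standard deviation of the positive
controls' own $d$ values on the same plate, so scores are in units of the
control SD of the same statistic — this is what makes the 3-SD hit
threshold calibrated. A consequence worth keeping in mind: the
standardizing SD is estimated from 20 wells and includes measurement noise,
so recovered effect sizes shrink slightly (a percent or two at the default
noise level) relative to the injected truth.

Replicate plates are combined as an unweighted mean ± SEM
(SD/$\sqrt{n}$) over the (default 3) replicate scores. Deviations are
computed per well from well-mean measurements by default; a per-field mode
(`phenotype_scores(per_field = TRUE)`) computes deviations per field and
averages within the well first — because $d$ is linear in the percent
coordinates the two agree exactly when the same control statistics are
used, and the per-well default is the simpler description.

## Hit calling

A (gene, measure) combination is a hit when the replicate-mean score
exceeds 3 control SDs in magnitude; it is graded **stringent** when
$|\text{mean}| - \text{SEM} > 3$ and **marginal** otherwise. Calls are made
at the maximal dose by default (`dose_policy = "max"`), with the full
titration available upstream. Direction labels map the sign convention to
biology: positive outgrowth scores mean *shorter* neurites (a decrease),
negative scores longer neurites. Genes whose growth score shows more than a
3-SD *reduction* are flagged excluded for the differentiation and outgrowth
categories — with strongly impaired precursor growth too few cells remain
for those ratio readouts to be reliable — while their growth call is
retained.

No multiple-testing correction is applied: the procedure is a fixed 3-SD
cut, and the pipeline instead logs the implied per-gene normal-theory
false-positive rate ($2\Phi(-3\sqrt{n_{rep}})$, about $2\times10^{-5}$% for
3 replicates) for transparency.

Secondary screens re-test pooled-siRNA hits with the individual oligos; a
phenotype is reproduced when at least one oligo passes the criterion in the
primary direction, reproduced-by-multiple with at least two, and an
opposite-direction significant oligo raises a flag without changing the
status. Functional-class composition of hits is reported as raw
percentages against the library composition, without a hypergeometric
test, matching how such over-representation is usually quoted for these
screens.

## Field morphometry

`measure_field()` reproduces the measurement concept, not any specific
tool's internals: the marker image is background-corrected (background =
mean of pixels below a global Otsu threshold; corrected values clipped at
0), thresholded and binarized; a morphological opening with a disc of the
soma scale (default radius 6 px) retains the thick, compact cell bodies;
the thin remainder of the mask is the neurite compartment, which is
skeletonized (Zhang–Suen thinning, implemented in-package) and measured as
link-weighted skeleton length: orthogonal neighbour links count 1 px,
diagonal links $\sqrt 2$, diagonal links that duplicate an orthogonal
connection are skipped. This estimator is unbiased for straight lines at
arbitrary angles to within a few percent; junctions from crossing neurites
bias it mildly downward after thinning. Intensities are integrated over the
whole corrected image; at high read noise the clipping at zero biases
integrated totals upward, which is why the measurement examples keep
objects dominant over the background area. `masked_mean_intensity()`
implements the masked-channel readout (e.g. EB1 signal within neurites):
mean of the raw signal inside the binarized marker mask, with an explicit
error — not a silent zero — on an empty mask.

Coordinates are (row, col), 0-based pixel units internally; images read and
written as single-channel 16-bit TIFF with a JSON ground-truth sidecar.

## The synthetic screen generator

The generator is the package's ground-truth instrument: every downstream
stage is validated against effects it injects. Two variance sources are
deliberately separated:

* **Control scatter** is *deterministic*. Positive-control wells come in
  quadruples sharing a growth level (5 levels across 20 wells), with ±1
  differentiation and outgrowth contrasts inside each quadruple, scaled to
  sample SD 1 and to the configured relative magnitudes. Because each
  contrast is orthogonal to every function of the coarser levels, the
  fitted control regressions coincide exactly with the proportional-scaling
  lines, plate control statistics are well defined even at zero noise, and
  a pure proliferation effect provably leaves differentiation and outgrowth
  scores at zero — the decoupling is an emergent property of the statistic,
  not forced per gene.
* **Field noise** is stochastic: each per-field value is the well mean
  times a log-normal factor with the configured CV (mean exactly 1), the
  natural model for positive totals proportional to cell number.

Treatment wells are placed by inverting the normalization chain against the
noise-free control statistics: a target shift of $s$ control SDs at the
maximal dose (linear in dose/max-dose by default) is converted to raw
channel values such that the standardized score downstream equals $s$
exactly at zero noise and in expectation otherwise. Proliferation effects
scale all channels together; differentiation effects re-place the area at
the prescribed deviation with length and marker following proportionally;
outgrowth effects re-place the length given the well's area. Axes with a
zero target are left at the proportional baseline. Optional `growth` /
`differentiation` / `outgrowth` columns in the effect table co-inject
additional shifts, e.g. an outgrowth gene whose knockdown also impairs
precursor growth.

Default anchors emulate the study scale: ~167 neurons per field (1000 per
well over 6 fields), 78 px soma area and 60 px neurite per neuron.
Negative-control wells keep the reporter at 30% of the positive anchor
(undifferentiated cells keep dividing and dilute the reporter plasmid; the
paper quantity is not published, and any value below the positive anchor
keeps the percent scale oriented so negative growth scores mean reduced
growth) and the neuronal marker at background.

**Control-scatter calibration.** The scatter magnitudes define the SD unit
of the whole analysis; the design rule used for the defaults is that the
control SD must be a *biological* unit, not a technical one: at the default
field-noise CV of 2% (0.8% at well level after 6-field averaging), field
noise must contribute less than 2% of the control-deviation variance and
the plate-level fluctuation of the estimated control SD must stay below 4%.
This gives growth scatter 0.10 and differentiation/outgrowth scatter 0.08 —
also a realistic well-to-well CV for cell-based assays. With weaker control
scatter the SD unit becomes noise-dominated and the 3-SD threshold loses
its meaning as a biological effect size.

What the generator does **not** emulate: spatial plate artifacts
(row/column gradients — the analysis has no spatial correction, so the
generator injects none), cell-cycle structure, photorealistic optics (PSF,
vignetting), or non-monotone dose–response. Passing tests therefore show
that the statistics recover what they are defined to recover under the
stated noise model — not that segmentation of real micrographs is solved.

## Epistasis statistics

Combined-knockdown designs hold the total siRNA at 4 pmol per well, padding
with non-targeting oligo; `validate_design()` enforces the dose arithmetic
per arm. Arm comparisons use one-way ANOVA followed by Dunnett many-to-one
comparisons against the non-targeting control arm. The familywise-adjusted
two-sided p-values are computed from the joint multivariate-t distribution
of the simultaneous t statistics via its one-factor representation
$T_i = (a_i Z_i - b_i Z_0)/S$, integrating numerically over the shared
control deviate $Z_0$ and the pooled scale $S$ (nested
`stats::integrate`, exact correlation structure for unbalanced arms). A
label-permutation fallback (`compare_arms_permutation()`) provides a
distribution-free check. The test suite cross-validates adjusted p-values
against `multcomp::glht` and the critical value against the equicorrelated
multivariate-t quantile; the familywise type-I error is verified by
simulation to sit at the nominal 5%. Knockdown-phenotype relationships use
the sample Pearson correlation (knockdown fractions are pipeline inputs
from e.g. western blots, never computed from blot images); masked-intensity
group comparisons use the equal-variance two-sided Student t-test, as named
in the original design, rather than the Welch variant.

## Numerical choices and degenerate inputs

* Plates need ≥3 positive controls with non-constant percent coordinates;
  degenerate controls (equal positive and negative means, zero control SD,
  constant x) raise errors rather than producing infinities.
* `to_percent` never clips: treatment values below 0% or above 100% are
  meaningful.
* Positive-control counts must be multiples of 4 (≥8) because of the
  quadruple contrast layout.
* Effect placement clamps raw channel targets at a small positive floor;
  injected magnitudes beyond ~±12 SD at default scatter would otherwise
  demand negative lengths.
* The Zhang–Suen thinning operates on zero-padded shifts, so structures
  touching the border are handled; an isolated pixel has skeleton length 0.
* All generation is keyed by a single integer seed; identical configuration
  and seed give byte-identical tables (RNG state is saved and restored, so
  the generator does not disturb the caller's stream).

## Problem sizes used in the checks

The packaged checks run the full design (20/20 controls, 6 fields, 3
replicates) at: 100–200 genes for standardization and recovery properties
(20 independent seeds for the recovery rates), a 50,000-gene single-dose
screen for null calibration, 10,000 simulated 4-arm experiments (n = 6
wells) for the Dunnett familywise error, and drawn scenes with 50–200 px
neurites for morphometry accuracy. The image-level pipeline mode is
demonstrated on miniature screens (a few genes, reduced anchors) — it runs
the identical normalization and calling code, only the measurement stage
differs.

## Known limitations

* The morphometry module measures field totals only — no per-neuron
  tracing, branch statistics, or neurite-to-soma assignment.
* Integrated intensities inherit a small positive bias from clipping the
  background-corrected image at zero; negligible at the default noise
  levels, visible at high read noise on sparse fields.
* Effect-size recovery shrinks by the ratio of true control scatter to
  realized control SD (which includes measurement noise); about 1–2% under
  default settings.
* The Dunnett integration assumes the one-factor correlation structure of
  many-to-one contrasts with a shared pooled variance; it does not cover
  general contrast matrices.
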