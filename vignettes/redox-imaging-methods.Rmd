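---
title: "Quantifying subcellular redox state from ratiometric roGFP imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying subcellular redox state from ratiometric roGFP imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement model

roGFP2-family sensors interconvert between two spectral forms with the state
of an engineered disulfide. The fully oxidized form has a bimodal excitation
spectrum with its major peak near 395 nm; the fully reduced form is monomodal
with its major peak near 470 nm. At any intermediate degree of oxidation
(OxD), the excitation spectrum is the linear two-state mixture, so the
background-subtracted excitation ratio

$$R_{395/470} = \frac{I_{395} - b_{395}}{I_{470} - b_{470}}$$

is a strictly increasing function of OxD and — because the sensor amount
cancels between numerator and denominator — independent of probe
concentration. That concentration invariance is what makes diffuse cytosolic
signal comparable with bright subcellular puncta. Fusing the sensor to
glutaredoxin couples it specifically to the glutathione redox pool; fusing it
to the large subunit of Rubisco targets it to carboxysomes (or, in shell-less
mutants, procarboxysomes).

`redoxim` implements this measurement end to end: a synthetic image generator
with per-object ground truth, threshold-plus-watershed segmentation with
rule-based curation, puncta detection with a minimum-area filter, wild-type
background subtraction, the clipped ratio above, and population-level
statistics (time series with standard errors, burn-in exclusion, bimodality
detection, hysteresis assessment, two-sample comparisons), plus the parallel
bulk spectrofluorometer workflow.

Backgrounds $b_{395}, b_{470}$ are the averaged intensities of wild-type
(sensor-free) objects, which share autofluorescence and camera offset with
sensor strains but carry no probe. Because the 470-nm channel can run close
to background, any object-mean falling below zero after subtraction is
brought to zero; if the denominator is zero the ratio is undefined, and such
objects are excluded from every aggregate and counted in the QC report
rather than imputed as 0 or infinity.

## What the synthetic generator emulates

No public imaging dataset accompanies this analysis, so the generator is a
first-class module whose defaults define the study conditions:

* Rod-shaped (capsule) cells placed without overlap on a pad, imaged every
  20 minutes in four channels (395-nm excitation, 470-nm excitation,
  chlorophyll autofluorescence, brightfield with dark cells), 30 frames per
  field, four fields per study, ~26 cells per sensor strain per field plus
  wild-type cells.
* Four strain classes: cytosolic sensor (diffuse), carboxysomal sensor
  (3 bright puncta per cell), procarboxysomal sensor (2 large puncta;
  high-CO2-requiring), and wild type.
* Pixel intensities: camera offset 100 counts, autofluorescence bleed-through
  40 counts (cell-to-cell pigment CV 0.2), probe term
  $\text{gain}\cdot\text{probe}\cdot(\text{OxD}\,s^{ox}_c +
  (1-\text{OxD})\,s^{red}_c)$ with gain 1500 and a 3x concentration factor in
  puncta; Poisson shot noise plus Gaussian read noise (sd 2), digitized to
  integer counts as an sCMOS camera would.
* Excitation endmembers are smooth Gaussian composites with the two-state
  shape above, evaluated at 395/470 nm for imaging, and on the full
  350--480 nm grid (131 points) for bulk spectra, so image-based and
  spectrum-based ratios agree exactly in the noise-free limit.

The biological facts the defaults encode are orderings and shifts, not
absolute values (none are published): carboxysomes more oxidized than cytosol
and procarboxysomes in air; every compartment more reduced under 3% CO2; a
reduced, procarboxysome-like carboxysome subpopulation (35% of puncta,
OxD 0.30) appearing only under 3% CO2; and a hysteretic return to air
(air target lowered by 0.05). The chosen OxD means — cytosol 0.35/0.20
(air/3% CO2), carboxysome 0.90/0.70, procarboxysome 0.45/0.25 — are one-time
modeling choices consistent with a strongly oxidizing carboxysome lumen and a
reducing cytosol.

Oxidation dynamics are intentionally minimal: after a CO2 switch the latent
per-object mean relaxes exponentially toward the condition target with a
150-minute time constant (the population shift plays out over ~8 hours);
an initial +0.08 offset decaying with a 45-minute time constant emulates the
settling transient in the first 2--3 hours of acquisition, which is why
condition statistics exclude a 3-hour burn-in by default. Per-object
deviations are mean-reverting (OU) with stationary sd 0.05 and a 2-hour
decorrelation time: daughters inherit their mother's state at division but
lineages decorrelate, so a single extreme cell cannot found a spurious
subpopulation. Draws are kept inside [0, 1] by reflection rather than
truncation, which would otherwise create a point mass at the boundary that
a mixture fit would misread as a second mode.

Division is modeled as label replacement — the mother's footprint splits
into two daughters with new identities; there is no lineage tracking, no
photobleaching, no focus drift, no PSF beyond an optional Gaussian blur, and
no illumination gradients. Passing tests on these scenes therefore
demonstrates correctness of the measurement and statistics chain under the
stated noise model, not robustness to every artifact of real microscopy.

## Segmentation choices

Cells are segmented on the (inverted) brightfield channel by a per-image
Otsu threshold — reproducible and parameter-free, with a fixed-threshold
override — followed by a watershed on the Euclidean distance transform to
split touching rods. Connectivity is 8 for cells (thick objects) and 4 for
puncta (small, compact). Objects under 100 px and objects touching the image
border are dropped (partial cells bias per-object means). Manual mask
correction is replaced by two logged rules: objects whose mean chlorophyll
falls below half the frame's median object chlorophyll are removed as dead,
and objects with convex solidity below 0.8 (or above an area cap) as
overlapped/merged; externally edited masks can be supplied instead.

Puncta are detected inside cell masks on the summed excitation channels;
each punctum is assigned the cell containing its centroid, falling back to
majority pixel overlap (ties to the lower label). Puncta strictly smaller
than 62 px are excluded — the size filter is scoped, per its motivation of
suppressing misidentified background puncta, to the procarboxysome strain
class by default and is configurable per strain. The cutoff applies to the
final labeled area.

In simulation mode, strain identity (done visually in a real experiment) and
object identity across frames come from matching segmented labels to the
generator's ground-truth maps by maximal overlap (IoU >= 0.3); condition
comparisons then use per-object time-averaged ratios after burn-in, so the
unit of replication is the object, not the object-frame.

## Population statistics

Time series report mean, SEM ($s/\sqrt{n}$, undefined for $n<2$) and $n$ per
group per frame, with $n$ varying as cells divide. Histograms use fixed bins
with explicit under/overflow buckets and a count of undefined ratios.

Bimodality is decided by fitting 1- and 2-component Gaussian mixtures
(deterministic model-based initialization) and declaring two modes only when
ΔBIC = BIC₁ − BIC₂ > 10 *and* the fitted modes are separated by Ashman's
D ≥ 2. The fits run on the log-ratio scale: OxD maps to the ratio through a
convex function, so even a symmetric unimodal population is right-skewed on
the ratio scale, and a Gaussian mixture would otherwise report the skew as a
second component; the log transform is monotone (mode counts are preserved)
and near-linearizing, and the D gate then suppresses the residual
skew-splits that BIC alone would accept. Zero ratios produced by the clip
rule cannot enter the log fit; they are excluded and counted. Reported
component means are geometric means back on the ratio scale. A dip-style
unimodality statistic with a Monte-Carlo null is available as an alternative
decision rule. Samples below 50 observations return an explicit
insufficient-data result.

Hysteresis is assessed by comparing the mean ratio over a pre-shift window
against an equal-length window ending the series after the return, as
pre-minus-post (positive = the population stayed more reduced than before
the perturbation), with a two-tailed Welch test across per-frame means — the
window variances differ by construction, unlike the equal-variance group
comparisons. Group comparisons elsewhere use the classical unpaired
two-tailed Student's t-test; star annotations default to * p < 0.05,
** p < 0.001, *** p < 0.0001 (an alternative convention with ** at p < 0.01
exists in the literature; the thresholds are configurable). No
multiple-testing correction is applied by default, matching common practice
for these panel-style comparisons; Holm-adjusted p-values can be obtained by
passing the comparison table through `p.adjust`.

## Bulk assays

Chlorophyll a is quantified from methanol-extract absorbance as
$16.29 \times A_{665}$ µg/mL, with the dilution factor to the 3 µg/mL
working concentration; the formula's reference optical density is metadata
and is not applied as a correction. Bulk ratios subtract the cross-replicate
mean wild-type emission at 395/470 nm from each sensor replicate, divide,
and then average the per-replicate ratios (mean-of-ratios; the text order of
operations), with ratio-of-means available as an option. Replicates with
non-positive denominators are flagged and excluded. The redox-agent panel
(100 µM DTT, 30 mM H2O2) models compartment-specific agent sensitivity as a
pull of OxD toward 0.02 (DTT) or 0.95 (H2O2) scaled by a per-compartment
permeability factor: the cytosol responds to both, carboxysomes respond to
the reductant but barely to the oxidant, and procarboxysomes — already
reduced in their permissive high-CO2 condition — respond to neither
appreciably. Biological replicates draw their own OxD around the strain mean
(sd 0.05), which is what gives the t-tests realistic replicate variance.

## Numerical choices and degenerate inputs

* Otsu on a constant image is a degenerate threshold and raises an error; an
  all-background image yields an empty label map, which is not an error.
* A scene too crowded to place all requested cells fails with an explicit
  placement error after a bounded number of rejection-sampling attempts —
  never a silent truncation of the cell count.
* Zero WT objects make background estimation an error (never a silent zero
  background).
* Negative raw intensities are treated as corrupt input.
* Stored datasets quantize intensities to integer counts (16-bit); the
  default noise models already produce integers, so round trips are exact.
  Channel layout, spec, optical model and seed go into a JSON manifest from
  which the dataset can be regenerated bit-identically.
* All randomness flows through R's RNG from a single scene/study seed; field
  seeds are derived deterministically from the study seed.

## Problem sizes

The shipped test suite and the worked examples run the full synthetic study
at 4 fields x 512x512 px x 30 frames per condition (~104 cells per sensor
strain, ~5000 carboxysome punctum-frames pooled per condition), which this
package's statistics resolve with wide margins; the bulk study uses 4
replicates per group. Exact-recovery checks run on single noise-free frames,
where the pipeline reproduces ground-truth ratios to floating-point
precision.

## Known limitations

Segmentation is classical (threshold + watershed), not learned; heavily
clumped or low-contrast real images will need externally provided masks,
which every quantification function accepts. Absolute redox potentials
(Nernst/OxD calibration) are out of scope — all outputs are relative ratios.
The generator's realism limits are listed above; in particular the noise
model does not include spatial illumination structure, so flat-field
correction is deliberately absent from the pipeline.

The function-level API (`generate_scene()`, `segment_cells()`,
`compute_ratio()`, `run_timelapse_study()`, ...) is the intended interface;
scripts wrapping it are one-liners, and `scripts/acceptance.R` in the source
repository shows the pattern.
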