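---
title: "Quantifying direction-selective circuit structure and function"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying direction-selective circuit structure and function}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dscircuit)
```

## The measurement problem

The retinal direction-selectivity (DS) circuit couples starburst amacrine
cells (SACs) to ON-OFF direction-selective ganglion cells (ooDSGCs).
Assessing whether a genetic perturbation degrades this circuit requires
three very different kinds of quantification, which this package
implements as one tested toolkit:

1. **Spike-train physiology** — how sharply and strongly individual
   ooDSGCs are tuned to motion direction, and how well their ON (bright
   edge) and OFF (dark edge) responses agree.
2. **Mosaic regularity** — how evenly SAC cell bodies tile the retina,
   measured against what a random arrangement of the same cells would
   produce.
3. **Anatomy** — where dendrites point and stratify in the inner
   plexiform layer (IPL), how much territory arbors cover, and how often
   homotypic arbors touch.

Recorded and imaged data of this kind are rarely redistributable, so the
package pairs every analysis with a synthetic-data generator whose ground
truth is known. Every stage is then verifiable by parameter recovery and
closed-form oracles, and an end-to-end "wild-type vs mutant" experiment
can be simulated and analyzed with two function calls.

## Direction-tuning statistics

A cell's tuning curve is the spike count $n_i$ summed over trials for
each of 12 equally spaced motion directions $\theta_i$. All downstream
statistics treat the curve as a count-weighted distribution on the circle.

**Direction selectivity index.** With unit vectors
$\hat u(\theta_i)$,
$$\mathrm{DSI} = \frac{\lVert \sum_i n_i \hat u(\theta_i)\rVert}{\sum_i n_i},$$
0 for an untuned cell and 1 when all spikes share one direction. Adding a
direction-independent count to every bin strictly decreases the DSI,
which is why elevated null-direction spiking registers as degraded
selectivity.

**Tuning width.** The circular standard deviation
$\sigma_{circ} = \sqrt{-2\ln \bar R}$, where $\bar R$ is the mean
resultant length of the count-weighted distribution. For counts sampled
from a von Mises density with concentration $\kappa$,
$\bar R \to I_1(\kappa)/I_0(\kappa)$, which the tests verify to within
1%. The width is computed on the raw counts (a nonparametric estimate);
the von Mises fit is kept for display and for recovering $\mu$ and
$\kappa$. Note that $\sigma_{circ}$ includes the square root of the
standard circular-SD definition; implementations that omit it report the
squared width.

**Tuning strength.** Because the preferred direction
$\theta_{PD}$ (the resultant-vector angle) generally falls between the
30°-spaced sampled directions, the preferred response is a cosine-weighted
sum over the two sampled directions nearest $\theta_{PD}$, and likewise
for the null direction $\theta_{ND} = \theta_{PD} + 180°$; the strength
is their normalized difference $(P - N)/(P + N)$. A perfectly balanced
curve has no resultant direction; its strength is reported as 0 rather
than `NaN` so population pipelines proceed.

**ON/OFF segmentation.** A bright bar crossing the receptive field
drives two temporal response lobes. The boundary between them is set
halfway between the two largest peaks of the direction-pooled,
Gaussian-smoothed PSTH at high contrast, and the same boundary is reused
at every contrast. Peaks must rise above their flanking minima by at
least 10% of the tallest peak (the prominence floor), so ripples on a
single lobe's flank are not mistaken for a second lobe. The ON-OFF
preferred-direction difference $\Delta\phi$ is the minimal circular
difference between the phase-specific resultant angles, in [0°, 180°].

Defaults that matter: spike times are binned at 1 ms; the PSTH smoothing
kernel is Gaussian with $\sigma$ = 25 ms (the bin width is standard for
this preparation, the kernel width is this package's choice — narrow
enough to keep two lobes 1 s apart well separated, wide enough to
suppress single-trial noise); candidate peaks must be at least 0.5 s
apart. All are arguments of `split_on_off()`.

## Population gating and comparison

The DSI histogram of a full recorded RGC population is bimodal. DS cells
are gated by fitting a two-component Gaussian mixture (`mclust`) and
thresholding at the density crossing between components; when the fit is
not convincingly bimodal (component means closer than the pooled SD), a
fixed threshold of 0.25 is used instead — the value that reliably
separates the modes in practice. ooDSGCs are isolated from ON DSGCs by
requiring a bilobed response whose smaller lobe reaches at least 20% of
the larger (this ratio is a formalization of a qualitative criterion, and
is configurable). Subtypes are assigned by k-means on the circle with
seeds at the four cardinal directions, minimal-angular-difference
assignment, and circular-mean center updates; empty clusters keep their
seed. Genotype populations are compared metric-by-metric with the
two-sample Kolmogorov–Smirnov test; with unequal group sizes a literal
pairing is impossible, so the two-sample test is the operative
interpretation.

Quality control mirrors standard MEA practice: units with more than 10%
of inter-spike intervals inside the refractory window, or with mean rate
below 1 Hz, are excluded. The refractory window defaults to 1.5 ms (a
typical RGC value; the exclusion rule states the percentage, not the
window).

## Mosaic regularity

Each cell of a field receives its Voronoi domain; domains touching the
field boundary are excluded (their true extent is unknown), and the
Voronoi domain regularity index is
$$\mathrm{VDRI} = \frac{\mathrm{mean}(\text{domain areas})}{\mathrm{SD}(\text{domain areas})}.$$
The tessellation is computed by clipping the field rectangle against the
perpendicular bisectors toward neighboring points (exact for planar
Voronoi cells, with nearest-first pruning). Two built-in invariants guard
it: the clipped domains tile the rectangle exactly, and areas match a
nearest-neighbor pixel-assignment oracle. A perfect lattice has zero
area spread; its VDRI is reported as a capped sentinel (10^6) with a
`degenerate` flag.

The reference for a measured VDRI is a **density-matched random null**:
hard-core random arrays (sequential placement with an exclusion radius)
at the same density, scored identically. The exclusion radius defaults to
8 µm — an approximate SAC soma diameter, since two somata cannot overlap;
it is configurable because published nulls rarely print it. Per-animal
summaries average the fields imaged from one animal, and genotype effects
are tested by one-way ANOVA on the per-animal means.

`territory_bin_analysis()` relates per-cell Voronoi ("territory") area to
a binary outcome in 100 µm² bins with open-ended first (<200 µm²) and
last (>1100 µm²) bins, reporting exact binomial confidence intervals and
omitting empty bins rather than scoring them zero.

## Anatomy

* **Dendrite orientation**: absolute angles in [0°, 180°] with 0° toward
  the IPL are partitioned at 45°/135° into IPL / tangential / ONBL
  classes. The cuts reconstruct quadrants that are drawn rather than
  printed, and are configurable.
* **IPL profiles**: a 12.5 µm-wide ROI perpendicular to the strata is
  width-averaged, background-(minimum-)subtracted, and normalized to its
  maximum; depth runs 0% at the INL border to 100% at the GCL border.
  The pipeline is therefore invariant to affine intensity rescaling.
  Peaks are local maxima above a prominence floor; a plateau of equal
  maxima counts once, at its center. Band distance is the difference of
  dominant peak depths in % IPL.
* **Territory area**: the polygon through a cell's dendritic tips,
  ordered by polar angle about their centroid (a deterministic
  approximation to manual nearest-neighbor tracing), measured by the
  shoelace formula.
* **Plexus coverage**: Otsu thresholding (or a fixed cut) of the en-face
  image, then the foreground percentage.
* **Homotypic contacts**: a tip counts as contacting if its voxel lies in
  the target mask (optionally within one voxel, emulating confocal
  resolution). The chance control flips the target channel about both
  in-plane axes and recounts — geometry and density are preserved while
  true contacts are scrambled.

## The synthetic generators

`generate_population()` draws spikes from an inhomogeneous Poisson
process with two Gaussian temporal lobes. Per trial, the expected lobe
count at direction $\theta$ is
$$\lambda(\theta) = \max\!\big(g\, e^{\kappa(\cos(\theta-\mu)-1)},\ r_0\big)\, s(c),$$
with gain $g$, concentration $\kappa$, preferred direction $\mu$, null
floor $r_0$, and a Naka–Rushton contrast response $s(c) = c/(c+c_{50})$
normalized to 1 at the protocol's top contrast, so that $g$ is the
expected preferred-direction count per trial at maximum contrast. The
protocol defaults are the standard ones for this preparation: 12
directions, Weber contrasts {5, 10, 20, 40, 80, 150, 300}%, 8 trials,
a 1200 µm bar at 400 µm/s — which also fixes the ON-to-OFF lobe interval
at 3 s (bar width over speed). Lobe peaks default to 0.8 s and 3.8 s with
$\sigma$ = 0.15 s in a 5 s trial. Poisson spiking was chosen for
analytic tractability: the rate law above is exactly the oracle that
`expected_counts()` exposes and the tests check. What it deliberately
does **not** emulate: refractoriness (real trains cannot violate it, so
the contamination filter is exercised more strictly on synthetic data at
high gains), adaptation across trials, and correlated noise between
cells. Passing tests therefore demonstrate correctness of the analysis
chain, not biological realism of the spike trains.

`generate_mosaic()` provides three point processes of decreasing
regularity — jittered hexagonal lattice, hard-core, and Poisson — whose
VDRI ordering (lattice > hard-core > Poisson, in distribution over
seeds) is itself a tested invariant. The anatomy fixtures
(`generate_ipl_profile()`, `generate_plexus_image()`,
`generate_contact_volume()`) build inputs whose true peak positions,
coverage, and contact counts are known by construction; contact placement
is integer-exact, so fixture recovery is exact rather than statistical.

All generators draw from one explicit seed through a scoped RNG; global
RNG state is never touched, and identical parameters plus seed give
byte-identical output.

## End-to-end experiments

`run_physiology_experiment()` chains generation → QC → DSI gating →
ooDSGC isolation → tuning metrics → subtype assignment → KS comparisons
for a named set of genotypes, logging cell counts into and out of every
filter. The default configuration contrasts a wild-type-like genotype
(null rate 0.5 spikes/trial, ON-OFF misalignment SD 5°) with a
mutant-like genotype (null rate 3, misalignment SD 20°): elevated
null-direction spiking is the mechanism by which the mutant population's
width distribution shifts right and its strength distribution shifts
left. At the recorded population sizes (about 80 cells per genotype)
this shift is detected by the KS test at $\alpha = 0.01$ in virtually
every repetition. `run_mosaic_experiment()` does the same for fields ×
animals × genotypes against the random-null envelope.

## Numerical choices and degenerate inputs

* All-zero tuning curves yield `NaN` metrics with a warning (not an
  error), so population loops continue; `fit_von_mises()` requires at
  least three nonzero directions and falls back to its initialization
  (flagged) on non-convergence.
* $\bar R$ below $10^{-12}$ is treated as exact cancellation: width
  reports an `Inf` sentinel, strength reports 0.
* The concentration initializer inverts
  $\bar R = I_1(\kappa)/I_0(\kappa)$ by Fisher's piecewise approximation
  polished with bisection to $10^{-10}$.
* Voronoi edge detection uses an absolute vertex-on-boundary tolerance of
  $10^{-7}$ µm; hard-core placement retries 500 times per point before
  declaring the packing infeasible.
* Angular differences are always reduced to minimal circular form;
  $\Delta\phi$ lives in [0°, 180°].

## Problem sizes used in the tests

The shipped suite exercises: recovery on 200 synthetic ooDSGCs (8 trials
× 12 directions, gains of 30); 100 repetitions of the two-genotype
width/strength comparison at recorded-population sizes (80 vs 74 cells);
100 seeds of the three mosaic processes at 600 cells/mm² in 400 µm
fields plus a 99-simulation null envelope. These sizes give stable
statistics while keeping a full run in minutes; all are parameters, so
larger studies only change arguments.

## Known limitations

* The Poisson spiking model understates ISI regularity; QC contamination
  on synthetic data is an upper bound on what clean recorded units show.
* The tip-polygon territory is one formalization of manual tracing;
  strongly non-star-shaped arbors can be ordered differently by a human.
* The mixture-crossing DSI gate assumes two Gaussian modes; heavily
  skewed non-DS modes may shift the crossing, which is why the 0.25
  fallback exists.
* Stratification calls for single cells (peak within ±10% of the
  reference band, ≥60% of signal in band) formalize a qualitative
  criterion; both knobs are exposed and should be reported with results.
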