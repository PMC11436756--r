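---
title: "Quantifying compartmentalized fluorescence in neurons with punctate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying compartmentalized fluorescence in neurons with punctate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(punctate)
```

## The measurement problem

Adenylyl cyclase (AC) isoforms, dopamine receptors, and PKA biosensors
occupy distinct subcellular territories in striatal neurons: the primary
cilium, the extraciliary plasma membrane, and endosomes. `punctate`
implements the quantifications used to characterize such distributions
from fluorescence microscopy:

1. **Compartment enrichment indices** for the cilium and for
   marker-defined endosomes (fixed cells);
2. **Puncta counting** and population positivity classification;
3. **Receptor accumulation kinetics** at endosomes in live-cell movies;
4. **Biosensor time-course summaries** (dF/F0, two-phase AUC, peak,
   plateau, Fsk/IBMX endpoint normalization);
5. **Distance-based colocalization** of spots with a reference
   compartment;
6. **Replicate-level statistics** (mean ± s.e.m. over biological
   replicates, Student's t).

Because the raw neuron images behind such studies are rarely deposited,
every stage is validated against a synthetic-microscopy generator whose
ground truth is known exactly.

## Enrichment index: model and conventions

For a protein channel $I$, compartment mask $C$ and cell mask $W$
(with $C \subseteq W$), after background subtraction the package computes

$$E_{\mathrm{mean}} = \frac{\operatorname{mean}_{p \in C} I_p}
{\operatorname{mean}_{p \in W} I_p}, \qquad
E_{\mathrm{int}} = \frac{\sum_{p \in C} I_p}{\sum_{p \in W} I_p}.$$

The phrase "compartment fluorescence divided by total cell fluorescence"
admits both readings, and the original descriptions do not disambiguate.
We default to the **mean-ratio** because it behaves like a concentration
enrichment: a uniformly distributed protein scores exactly 1 regardless
of compartment size, and the score does not change when the compartment
grows at constant brightness. The integrated-ratio (the fraction of
total cellular signal in the compartment) is retained as an option, and
every result row records the convention used. Pixels that go negative
after background subtraction are clipped to zero before either ratio, to
avoid sign pathologies in dim cells.

Background defaults to the mean intensity outside the cell mask; a
dedicated background ROI or a low-percentile estimate are available when
the field of view is crowded.

## Segmentation conventions

The mask-building primitives follow the conventions of the ImageJ
ecosystem in which these pipelines are usually assembled:

* **Thresholding is strict** (`> threshold`), matching upper
  thresholding in ImageJ. Manual thresholds are accepted verbatim;
  Otsu's method on a 256-bin histogram (`auto_threshold()`) is the
  reproducible default where the original protocol says "set manually".
* **Connectivity defaults to 8** (the Analyze Particles default);
  4-connectivity is available.
* **The size filter** removes components below 3 px before counting,
  and `smooth_mask()` applies a dilation of 1 px followed by an erosion
  of 1 px. The structuring element is a 3×3 cross ("1 pixel" radius); a
  3×3 square is available by flag. Closing is computed on a
  background-padded frame so border pixels behave as in an unbounded
  image, which preserves the extensivity guarantee (output ⊇ input).
* **Projections**: z-max first, then (for live-cell ROI refinement)
  temporal max — the order is fixed and recorded in mask provenance.
* The exact smoothing applied to the refined cell ROI in the original
  live-cell pipeline is unspecified; we reuse the same 1-px closing as
  for the endosome mask and flag this as an assumption.

Cell-ROI refinement thresholds the temporal maximum projection with Otsu
computed on log-intensities. On microscopy histograms dominated by a
large background mode, linear Otsu tends to split bright structures from
everything else; the log transform makes it split background from cell,
which is what ROI refinement needs. Background for the live-cell trace
is estimated outside the union of the drawn ROI and the convex hull of
the refined ROI — the hull covers dim cytoplasm even when refinement
kept only the bright membrane and endosomes.

## Live-cell accumulation traces

`puncti_accumulation_trace()` re-implements the endosomal accumulation
measurement: per frame, the endosomal marker channel is thresholded
inside the refined cell ROI, components under 3 px are discarded, the
mask is closed by 1 px, and the mean receptor fluorescence under the
mask is background-subtracted. The whole trace is then normalized to the
mean of the pre-agonist baseline (F/F0 by default; dF/F0 available).
Whether the original code recomputed the mask per frame or used a single
projection-derived mask is not stated; both modes are provided
(`mask_mode`), and on stable-marker simulations they agree to within the
noise. Frames whose marker mask comes out empty are recorded as missing
(`NA`), never as zero; linear interpolation is used only inside AUC
integration, never in stored traces.

## Biosensor summaries

Traces are summarized exactly as the published analyses specify: dF/F0
relative to the 1-min pre-agonist baseline; optional division by the
mean of the terminal Fsk/IBMX saturation epoch (applied to cytosolic
cAMP and non-targeted PKA sensors); trapezoidal AUC over the early
(0–5 min] and late (5–30 min] phases with the boundary interpolated
exactly so the two phases sum to the total; the peak as the maximum
sample in (0, 30] (pre-agonist frames excluded, ties resolved to the
earliest time); and the plateau as the mean over [20, 30] min,
inclusive. Boundary-membership conventions are a package choice — the
source texts do not state them — and are fixed here once. At 20 s
sampling the trapezoidal rule is within 1% of closed forms for the
relevant time constants, so the quadrature choice is immaterial.
Condition-level normalization divides each statistic by its mean in a
reference condition, which therefore maps to 1. No exclusion rule is
applied to saturating or bleaching cells; none was described.

## Colocalization rule

A spot colocalizes with a reference compartment when its centre lies
within **1 µm or less** (inclusive) of the nearest reference-mask pixel,
with distances taken from an exact Euclidean distance transform in
physical units. The reference mask here is a thresholded marker mask —
a stated proxy for surface renderings whose creation parameters are not
documented. Distances are computed on 2-D projections by default, since
that is where the published counts were quantified; spot positions are
rounded to the nearest pixel for the lookup, with bilinear interpolation
available. Spot detection (local maxima above threshold, greedily pruned
brightest-first to a minimum separation) stands in for interactive spot
placement; its parameters are recorded in the output.

## The synthetic-microscopy generator

`simulate_static_scene()` paints a two-channel neuron: an elliptical
soma with radiating processes, a 3-px-wide, 3-µm-long cilium extending
from the soma, 12 endosomal disks of 2–3 px radius, and a 1-px membrane
rim, at 0.1 µm/px over a 160×160 field. The protein channel paints
`base_cell` photons/px across the cell, multiplied per compartment by
configurable enrichment factors; the marker channel emulates an
endosomal stain. Camera noise is Poisson on signal + background followed
by Gaussian read noise (σ = 2 photons), clipped at zero — the standard
shot + read model. Intensity defaults (base 100, background 10) give
SNR ≈ 10 on the cell body, comparable to a well-exposed spinning-disk
frame.

Compartments are **hard-edged**: a pixel belongs to a compartment when
its centre falls inside the ideal shape. Since the generator models no
point-spread function (by design), soft edges would add a boundary
blur with no optical meaning while making ground-truth masks ambiguous;
hard edges keep the true masks exact, so noiseless recovery tests can
demand exact agreement. Endosomes are placed by rejection sampling with
a ≥3 px boundary gap so that the 1-px closing cannot merge neighbours —
touching endosomes in real images would be segmented as one particle,
a known limitation of the particle-counting approach itself.

`simulate_trafficking_movie()` moves receptor fluorescence from the
membrane rim to the endosome disks following
$f(t) = f_{\mathrm{mobile}}\,(1 - e^{-k t})$ (zero before agonist),
conserving total fluorescence frame by frame. A dim cytosolic receptor
pool (20% of `base_cell`) gives endosome pixels a nonzero pre-agonist
baseline, as out-of-focus light does in real movies — without it the
baseline normalization would divide by zero. The published experiments
report no internalization rate; the default $k = 0.2\,\mathrm{min}^{-1}$
with 80% mobile fraction reproduces the qualitative time course
(accumulation beginning within ~1 min and continuing over tens of
minutes) and is a free parameter, not a claim about the biology.

`simulate_biosensor_trace()` uses
$r(t) = A\,(1 - e^{-t/\tau_r})(p + (1 - p)e^{-t/\tau_d})$ — a saturating
rise times a partial decay to a plateau fraction $p$ — followed by a
2-min saturation epoch at level $S$. The functional form is an artifact
choice; the source observations are qualitative (fast rise within
~2 min, partial decay, sustained plateau). Defaults
($A = 1$, $\tau_r = 1.2$ min, $\tau_d = 4$ min, $p = 0.4$,
$\sigma_{\mathrm{noise}} = 0.05$ dF/F0 per frame, 10% cell-to-cell
amplitude CV, $S = 2.5$) put the noiseless peak at ~2.7 min and give
traces that look like published cADDis/ExRai responses. After Fsk/IBMX
normalization the plateau recovers $pA/S$.

Timing defaults everywhere follow the acquisition protocol: 20 s
frames, 1 min baseline, 30 min of agonist, t = 0 at agonist addition.
Seconds are used for acquisition metadata and minutes at reporting
boundaries. All indices are 1-based, R's native convention; frame 1 is
the first acquired frame and the agonist frame is the first frame at or
after t = 0.

### What the simulations do and do not establish

Passing recovery tests on these scenes shows the *computations* are
faithful: masks, ratios, traces and summaries do what their definitions
say, exactly where exactness is possible and within stated bounds under
camera noise. The scenes deliberately omit point-spread blur, focal
drift, photobleaching, cell motion, autofluorescence and segmentation
ambiguity from touching organelles. Agreement on synthetic data
therefore does not certify accuracy on any particular real data set,
and the published per-neuron index values cannot be reproduced here at
all, since the underlying images are not public. The validation surface
is parameter recovery, not replication of printed numbers.

## Statistics

Group summaries average cells within each biological replicate (an
independent culture or dish) first and report mean ± s.e.m. over
replicate means — the replicate, not the cell, is the unit of analysis,
matching the reporting convention of the experiments. Comparisons use
the classical pooled-variance Student's t (two-tailed), as named in the
original methods, with Welch's available in `stats::t.test` for users
who prefer it; paired tests operate on within-pair differences. Two
groups with zero variance and equal means return t = 0, p = 1 by
convention. No multiple-testing correction is applied (none was in the
source analyses).

A discrimination property ties the pieces together: two simulated
conditions programmed with equal peaks but plateau fractions in ratio
0.5, at n = 9 traces per condition under default noise, separate on the
late-phase AUC and plateau (p < 0.05 in ≥ 90% of repetitions) while the
early-phase AUC stays at the nominal false-positive rate. This mirrors
the logic of distinguishing a sustained-signaling deficit from an
initial-response deficit, without claiming any published effect size.

## Worked example

```{r example}
scene <- scene_config(endosome_factor = 4, seed = 1)
sim <- simulate_static_scene(scene)
res <- endosome_enrichment(sim$stack, region_mask(sim$truth$masks$cell))
res$index                                  # measured, Otsu mask
sim$truth$enrichment$endosome$index[1]     # ground truth
```

```{r example2}
kin <- kinetic_config(seed = 2)
trace <- simulate_biosensor_trace(kin)$trace
summarize_phases(fskibmx_normalize(trace))
```

## Numerical choices and degenerate inputs

* Tolerances: noiseless recovery asserts ≤ 1e-6 (ground-truth masks) or
  exact equality where the arithmetic is closed; AUC additivity holds to
  1e-9 by construction of the shared interpolated boundary.
* Problem sizes in the test-suite simulations (160×160 px scenes, 94- to
  97-frame movies, 100-fixture oracle sweeps, 100-repetition power
  estimates) were chosen as the smallest sizes at which every quantity
  is still well-resolved.
* Degenerate inputs are contracts, not crashes: empty compartment masks
  yield index 0 with a flag; empty reference masks yield infinite
  distances with a warning; empty per-frame marker masks become missing
  values; constant images cannot be auto-thresholded; baseline or
  Fsk means that are nonpositive are errors.
* Determinism: every simulator takes an explicit seed, restores the
  caller's RNG state, and identical (config, seed) pairs give
  bit-identical output. `run_pipeline()` writes a manifest with every
  parameter and convention flag it consumed, and identical configs give
  bit-identical output files.

## Known limitations

* 2-D only: all quantification happens on projections, as in the
  original pipelines; the optional 3-D colocalization mode supports
  anisotropic spacing but the simulator does not render 3-D scenes.
* No watershed: touching puncta count as one particle.
* The ROI JSON schema is this package's own (documented in the README);
  ImageJ `.roi` files are not parsed.
* TIFF intensities are stored as 16-bit integers with a power-of-two
  scale recorded in a JSON sidecar; arbitrary doubles are quantized at
  ~1/65535 of full scale on write.
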