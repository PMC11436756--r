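# punctate

Quantification of compartmentalized fluorescence in neurons: compartment
enrichment indices, puncta classification, live-cell trafficking
kinetics, biosensor time-course summaries, and distance-based
colocalization — with a synthetic-microscopy generator that makes every
stage testable against exact ground truth.

## Who this is for

Cell biologists and imaging analysts quantifying where a protein lives
in a neuron and how signaling follows from that localization: adenylyl
cyclase isoforms restricted to the primary cilium or concentrated on
endosomes, GPCRs internalizing after agonist, cAMP/PKA biosensor
responses whose late plateau depends on endosomal signaling. The package
re-implements, as tested and scriptable R, the measurements such studies
typically assemble interactively in ImageJ/MATLAB/Imaris.

## The core quantities

**Enrichment index.** For protein image $I$, compartment mask
$C \subseteq W$ (cell mask), after background subtraction:

- mean-ratio (default): $E = \mathrm{mean}_C(I) / \mathrm{mean}_W(I)$ —
  a concentration enrichment, 1 for a uniformly distributed protein;
- integrated-ratio: $E = \sum_C I / \sum_W I$ — the fraction of total
  cell fluorescence in the compartment.

**Puncta classification.** Threshold → connected components
(8-connectivity) → drop particles < 3 px → count; a cell with ≥ 10
internal puncta is "positive", and populations are summarized as the
percentage of positive cells.

**Trafficking kinetics.** Per movie frame, the endosomal marker channel
is thresholded inside a refined cell ROI, size-filtered, closed by 1 px
(dilate then erode), and the mean receptor fluorescence under the mask
is background-subtracted; the trace is normalized to the pre-agonist
baseline (F/F0).

**Biosensor summaries.** dF/F0 traces (optionally divided by the mean of
a terminal Fsk/IBMX saturation epoch) are reduced to: AUC over (0, 5]
and (5, 30] min (trapezoidal, boundary interpolated so the phases sum
exactly), peak = max over (0, 30], plateau = mean over [20, 30], each
optionally normalized to a reference condition's mean.

**Colocalization.** A spot colocalizes with a reference compartment if
its centre lies within 1 µm or less (inclusive) of the nearest mask
pixel, using an exact Euclidean distance transform in physical units.

**Statistics.** Mean ± s.e.m. over biological replicates (cells averaged
within replicate first) and two-tailed pooled-variance Student's t.

## Worked example

```r
library(punctate)

# a synthetic neuron with 4-fold endosomal enrichment of the AC channel
scene <- scene_config(endosome_factor = 4, seed = 1)
sim   <- simulate_static_scene(scene)

res <- endosome_enrichment(sim$stack, region_mask(sim$truth$masks$cell))
res$index                               # 3.162984
sim$truth$enrichment$endosome$index[1]  # 3.170114
```

The measured mean-ratio index (Otsu-derived endosome mask, estimated
background, full camera noise) is 3.16 against a ground truth of 3.17 —
a 0.2% error. The truth is below the nominal factor 4 because the
painted cell also contains membrane and cilium signal that enters the
whole-cell mean.

```r
kin   <- kinetic_config(seed = 2)
trace <- simulate_biosensor_trace(kin)$trace
summarize_phases(fskibmx_normalize(trace))
#   auc_early auc_late auc_total      peak peak_time_min   plateau
#    1.001439  3.84804   4.84948 0.2609831      3.333333 0.1409742
```

After Fsk/IBMX normalization the trace is on a fraction-of-maximum
scale: the response peaks at 26% of the saturated level around 3.3 min
and sustains a 14% plateau over 20–30 min (the programmed plateau is
p·A/S = 0.4/2.5 = 0.16; this cell drew a below-average amplitude).
AUC units are dF/F0·min.

ROI JSON schema, for importing hand-drawn polygons:

```json
{"rois": [{"id": "cell1", "kind": "polygon",
           "vertices": [[y1, x1], [y2, x2], ...], "channel": 2}]}
```

A command-line wrapper over the same pipeline lives at
`inst/cli/punctate.R`:

```sh
Rscript inst/cli/punctate.R pipeline --config analysis.yaml --seed 1 \
        --out-dir results/
```

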