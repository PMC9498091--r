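---
title: "Hybrid-imaging risk stratification: models, phantoms, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid-imaging risk stratification: models, phantoms, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(melrisk)
```

## Scope

melrisk implements a quantitative workflow for baseline whole-body
PET/CT + PET/MR imaging of metastasized melanoma before systemic
treatment (checkpoint inhibition and/or BRAF/MEK inhibition):

1. **Imaging I/O** — NIfTI volumes and binary lesion masks on a common
   grid, plus a cohort table; the published 37-patient baseline table is
   embedded (`table1_fixture()`).
2. **Handcrafted lesion markers** — SUL conversion, SULpeak, the
   42%-isocontour metabolic tumor volume (MTV), total lesion glycolysis
   (TLG), axial diameters with the sub-centimetre rule, ADC means,
   patient-level aggregation, organ involvement, and the spleen–liver
   (SLR) and bone-marrow–liver (BLR) reference ratios.
3. **Survival screening** — Kaplan–Meier curves, marker dichotomization
   by constrained one-dimensional clustering, Gehan–Breslow–Wilcoxon OS
   tests, Welch *t*-tests on responder status, and Holm–Bonferroni
   correction per outcome family.
4. **A multistream CNN** that classifies patients into low/high risk
   from lesion patches of co-registered modality pairs, evaluated by
   leave-one-patient-out cross-validation (LOOCV).
5. **A synthetic multimodal phantom cohort** so that every stage is
   exercisable without patient data.

Low risk is defined as overall survival beyond 548 days *and* treatment
response (CR/PR/SD); everything else is high risk.

## Quantification conventions

Several operational definitions are not fully pinned down by common
reporting practice; the package fixes them as follows.

* **Lean body mass** uses the sex-specific Janmahasatian formula,
  `9270 W / (6680 + 216 BMI)` for males and `9270 W / (8780 + 244 BMI)`
  for females. SUL is activity concentration divided by dose per kg LBM.
* **SULpeak** is the EANM-style peak: the mean SUL in a 1 cm^3 sphere
  (radius 6.2 mm) placed on the mask voxel that maximizes the mean,
  clipped at volume borders. Masks smaller than the sphere support fall
  back to the mask mean (flagged).
* **MTV** is the volume of mask voxels at or above 42% of the lesion
  maximum that are 26-connected to the maximum voxel; the connectivity
  constraint keeps disconnected satellite voxels from inflating the MTV.
  TLG is MTV times the mean SUL inside the MTV submask.
* **Axial diameter** is the largest in-plane physical extent over axial
  slices (centre-to-centre distance widened by one in-plane voxel).
  Lesions under 10 mm are recorded at 5 mm with functional parameters
  suppressed (partial-volume protection); brain lesions keep only the
  diameter.
* **ADC ROI**: the free-hand ROI placed at the largest diameter while
  avoiding organ borders is operationalized as the largest-diameter
  axial slice eroded in-plane by one voxel (4-neighbourhood); if erosion
  empties the slice the un-eroded slice is used and flagged. ADC values
  are stored in 1e-6 mm^2/s; printed thresholds such as "600" are in
  the same unit.
* **Reference VOIs**: SLR = spleen/liver mean SUL in 2 cm spherical
  VOIs, classified along the published cutoff sweep 1.1 → 0.9 in steps
  of 0.05; BLR averages up to four 1.5 cm vertebral VOIs (excluded
  vertebrae dropped) over the liver VOI.
* **Target lesion**: highest SULpeak wins; SULpeak ties within a 5%
  relative tolerance go to the larger diameter; brain lesions are never
  target lesions.

## Survival statistics

Markers are dichotomized by exhaustive search over all cut points
between consecutive sorted values, maximizing the between-group sum of
squares subject to at least 10 patients per group — for two groups in
one dimension this is exactly the Ward's-criterion split, computed
deterministically so it can be verified against enumeration. The OS
comparison uses the Gehan–Breslow–Wilcoxon weighted log-rank statistic
(weight = number at risk), the survival-platform "Wilcoxon test" of
classical biostatistics packages; a seeded label-permutation mode
provides an assumption-free reference p-value. Response comparisons use
Welch *t*-tests. Holm–Bonferroni is applied separately per outcome
family (one OS family, one response family), each of the size of the
set of markers actually tested. The Kaplan–Meier median convention is
the smallest event time with survival at or below one half.

The published cohort's summary, "median OS 429 (120–1266) days", does
not equal the median of the 21 deceased patients' OS values in the
embedded table (277 days) but matches their arithmetic mean (428.7
days); the package's `fixture_report()` therefore reports the mean of
the deceased, which reproduces the printed value.

## The phantom cohort

`simulate_cohort()` draws a latent aggressiveness `a ~ U(0,1)` per
patient. Overall survival is exponential with hazard
`h0 * exp(beta * a)` (defaults `h0 = 1/900` per day, `beta = 1.4`),
censored administratively at 1800 days; response is Bernoulli with
`P(responder) = plogis(0.5 - 2a)`. These defaults give death and
responder fractions comparable to the embedded cohort. The risk label
is then derived by the OS/response rule, and the *risk class* (not `a`
directly) sets the lesion appearance: texture amplitude
`h = hetero_lo + hetero_effect * (class == high)`, and the per-class
ADC model (lower mean, larger between-lesion spread in high-risk
patients — the latter plants the "intraindividual ADC range" marker).

Lesions are ellipsoids with a seeded multi-octave texture field `T` in
[0,1] (three octaves of trilinearly upsampled uniform noise at voxel
scales 8/4/2, fine octave weighted highest so the texture is visible to
3x3 filters). Voxel models per modality:

* PET: `SULmax * (1 - h * (T - 0.5))` — the texture is centred so the
  class amplitude changes the voxel spread but not the mean uptake
  (otherwise the mean-uptake shift, not heterogeneity, would separate
  the classes);
* CT: soft-tissue HU plus `120 h (T - 0.5)`;
* VIBE: hyperintense with a `0.8 h (T - 0.5)` relative modulation;
* ADC: Gaussian voxels around the lesion's drawn ADC mean.

Lesions blend into the background over a configurable rim
(`lesion_edge_mm`, default 4 mm phantom-wide; a point-spread-function
analogue). Without this taper the binary lesion edge dominates all
high-frequency content and masks the planted texture. Lesions never
overlap each other or the organ reference regions (liver, spleen,
L1–L4), which are rendered as uniform spheres with configurable uptake
so SLR/BLR are computable by construction.

What the phantom does **not** model: PET noise texture and PSF
(beyond the rim taper), MR artifacts (the ADC artifact flag is drawn at
random rather than arising from any image content), respiratory motion,
anatomy (organ regions are labels, not spatial context), and any
correlation structure between markers beyond what the risk class
induces. Passing tests on phantoms therefore demonstrate that the
algorithms recover what was planted — not that the markers or the
network would perform comparably on patients.

## The multistream network

The network follows the published topology: two branches (PET;
anatomical CT/MR), each with three per-orientation feature extractors
(two sequential squeeze-and-excitation blocks: two 3x3 convolutions
with batch norm and ReLU, gated by a channel-attention path of global
average pooling and two fully connected layers with a sigmoid), the
orientation feature maps concatenated into three wide residual blocks
with increasing widths, global average pooling per branch, fusion with
three standardized anthropometric scalars (height, weight,
target-lesion diameter), and a three-layer dense head with softmax over
the two risk classes. One training sample is a co-indexed
(axial, coronal, sagittal) slice triple of one 32^3 patch for one
modality pair; the three pairs (PET_MR+VIBE, PET_MR+ADC, PET_CT+CT)
form separate samples sharing position and label, which is what makes
single-modality ablation possible without architecture changes. Lesions
whose diffusion data carry artifacts drop their PET_MR+ADC pair.

The default configuration freezes extractor width 8, attention
reduction 2, wide-residual widths 48/96/192 and dense head 96/48/2,
giving 1,800,818 trainable parameters (1.8 M; the count is independent
of the seed). Patches are 32^3 voxels on a 2 mm isotropic working grid
cropped from a 132 x 160 x 250 mm lesion field of view (zero-padded
outside the volume). The crop lattice snaps onto the source lattice so
that, when the source grid already matches the working grid, the
resampling is exact — sub-voxel trilinear shifts otherwise low-pass
filter exactly the fine texture the network is supposed to see.
Training uses Adam (default learning rate 5e-4, batch 32, 150 epochs,
categorical cross-entropy, 384 random patches per training patient).
Deterministic stride-16 tiling provides validation/test patches: the
validation lesion is the second-highest-SULpeak lesion of at least
10 mm (fallback to the highest, flagged), the test lesion is the
held-out patient's target lesion. A patient's prediction is the mean
softmax probability over all patch samples; exact ties go to high risk.

Implementation notes: the engine is hand-written on BLAS matrix algebra
with an explicit backward pass per layer (verified against finite
differences to 1e-8); the 3x3 convolution and the fused
batch-norm+ReLU run in compiled code. Inverse-class-frequency loss
weights compensate the mild class imbalance of leave-one-out folds.
Batch-norm inference defaults to the statistics of the presented
patient's own patch samples ("transductive" inference) rather than
exponential running statistics — with the short desk-scale schedules
the running estimates are formed from too few updates to be reliable,
and per-patient statistics also remove patient-level intensity offsets.
Two further short-schedule aids are available and default off: Gaussian
jitter on the standardized anthropometric inputs (the phantom's
anthropometrics carry no class signal, so with a dozen patients they
act as patient fingerprints that invite memorization), and a *head
warm-up*: branch features of all training samples are extracted once
under the same per-patient normalization used at prediction time, and
the dense head alone is optimized by full-batch Adam steps before
end-to-end training begins. The warm-up substitutes for the hundreds of
epochs the full-scale protocol spends bringing the head to its
operating point, at a tiny fraction of the cost.

## Desk-scale evaluation protocol

`planted_signal_protocol()` freezes the configuration used by the test
suite and the acceptance script to exercise the full LOOCV loop on one
CPU: a 12-patient balanced cohort on 48^3 grids at 2 mm with one
geometrically matched target lesion per patient (40–44 mm, near-sphere,
fixed SULmax 6, 8 mm rim), texture amplitude 0 vs 0.8 as the only
systematic class difference, no background noise; and a narrow network
(extractor width 2, widths 3/4/5, head 16/8/2) on the PET_CT+CT pair
with 4 patches x 3 interior triples per patient, trained by a
3000-step full-batch head-only schedule (cached branch features,
anthropometric jitter 2, no end-to-end minibatch epochs). The matched
lesion geometry is deliberate: with a dozen patients the lesion-edge
energy otherwise varies more between patients than the planted texture
differs between classes, and the experiment would measure geometry, not
heterogeneity. The head-only schedule is equally deliberate: at this
sample size (about 130 slice triples from eleven lesions) a handful of
minibatch Adam steps cannot reach the operating point of a converged
readout — and, once the head has converged, further end-to-end steps
measurably degrade it — so the reduced protocol trains the fusion head
to convergence over fixed convolutional features (the classic
random-features regime) and leaves end-to-end optimization to the
full-scale configuration. Under this protocol the planted texture is
recoverable while permuted labels stay at chance, which is the
property the acceptance suite asserts.

Problem sizes throughout the test suite (grid sizes, patch counts,
epochs, permutation counts, replicate counts) are chosen as the
smallest sizes at which the respective statistical property is stable;
the full-scale defaults remain the study configuration.

## Known limitations

* The phantom's texture family is an explicit stand-in; no claim of
  radiological realism is made, and the published real-cohort CNN
  performance (96/92/92/95% specificity/sensitivity/PPV/accuracy) is
  not reproducible without the patient images.
* The patch-to-patient aggregation (mean softmax) and the
  validation/test tiling are package-defined conventions where the
  published description is silent.
* BLR vertebra exclusions are random flags in the phantom; real
  exclusions (osteoarthritis, fractures, hemangiomas, surgery) would
  correlate with age and disease.
* `resample_to_grid` and the field-of-view crop use trilinear/nearest
  interpolation without anti-alias prefiltering; strong downsampling of
  textured volumes aliases accordingly.
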