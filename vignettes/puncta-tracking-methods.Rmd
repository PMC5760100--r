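---
title: "Methods: segmentation, tracking-by-assignment and kinematics of photoreceptor puncta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmentation, tracking-by-assignment and kinematics of photoreceptor puncta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(punctatrack)
```

## What the pipeline measures

The package quantifies the motion of fluorescent puncta — vesicle-associated
particles such as Rab8-coated opsin carriers — in 2-D time-lapse recordings
of polarized cells, typically zebrafish photoreceptors imaged live at
1 frame/s for 10 minutes with 210 nm pixels. Channel 1 carries the moving
puncta; channel 2 a static basal-body (BB) marker (tagged centrin) used as
the cell's immobile reference point. Five per-particle statistics are
computed on each track, averaged per photoreceptor, and compared between
groups. The per-photoreceptor mean is the experimental unit throughout:
one cell contributes one value per statistic regardless of how many puncta
it contains, which keeps pseudo-replication out of the group tests.

## The measurement model

**Segmentation.** Each frame is blurred (Gaussian, σ = 0.1 px — effectively
no smoothing, retained because it is the configuration the protocol states),
min–max normalized to [0, 1], thresholded at 0.30 (working range
0.29–0.31), and labelled into 4-connected components; components smaller
than 2 px are discarded. A detection's position is the *unweighted*
centroid of its pixel set; using the mask rather than intensity weights
makes the position robust to the normalization constant. The threshold here
operates on normalized intensity; interactive pixel-classification tools
threshold a probability map instead, which raw intensity approximates well
for high-contrast puncta. Both the threshold and the blur are exposed in
`segmentation_config()`.

**Tracking.** Because mergers are capped at one object and divisions are
disabled in the emulated configuration, the global tracking model
factorizes over consecutive frame pairs, and each pair reduces to a
minimum-cost bipartite assignment with unmatched costs: matching
detections $i \to j$ costs $w\,d_{ij}^2$ (transition weight $w = 3$,
$d_{ij}$ in pixels), an unmatched earlier detection pays the disappearance
cost 47, an unmatched later detection the appearance cost 9. The squared
distance is the conventional assignment energy; the unmatch costs then act
as a distance gate at $\sqrt{(9+47)/3} \approx 4.32$ px — steps larger than
that are cheaper to explain as one disappearance plus one appearance.
A hard gating radius (8 px) additionally forbids distant matches. The
assignment is solved exactly by a shortest-augmenting-path (Hungarian)
solver on the $(n+m)\times(n+m)$ padded cost matrix; the test suite checks
the objective and the track decomposition against exhaustive enumeration
over all partial matchings on hundreds of random instances. There is no
gap closing: a particle lost for one frame restarts as a new track, which
is exactly what the appearance/disappearance semantics imply.

One consequence worth knowing: at 210 nm pixels the 4.32 px gate caps the
step lengths that can remain inside a track at roughly 0.9 μm/frame, so
within-track maximum speeds saturate just below 1 μm/s. Faster events
fragment the track instead.

**Eligibility.** Only tracks present in ≥ 10 frames enter the statistics
(`filter_tracks()`), mirroring the analysis protocol. Tracks with
undefined metrics (single frame, zero apico-basal span) are excluded from
the per-cell means and counted in the summary's `n_undefined` attribute so
the filtering is auditable.

**Kinematics.** With barycenters $p_1,\dots,p_n$ (nm) and the cell's axis
angle $\theta$ (between the apico-basal axis and the image vertical):

- displacement $= \lVert p_n - p_1 \rVert$ (nm);
- trajectory $= \sum_t \lVert p_{t+1} - p_t \rVert$ (μm);
- maximum speed $= \max_t \lVert p_{t+1} - p_t \rVert / \Delta t$ (nm/s,
  $\Delta t = 1$ s);
- directionality $=$ (span of $x'$) / (span of $y'$) after the rotation
  $x' = x\cos\theta + y\sin\theta$, $y' = y\cos\theta - x\sin\theta$;
  values < 1 mean predominantly apico-basal motion. "Span" is max − min;
  the alternative reading (summed absolute excursion) is not used.
- area $=$ mean pixel count × (0.21 μm)² = 0.0441 μm² per pixel, averaged
  over the track's frames (10 px ⇒ 0.441 μm², printed as 0.44);
- a BB contact is a frame whose barycenter lies within 3 px = 630 nm of
  the BB barycenter. The boundary is inclusive ("within a 3 pixel radius"
  is ambiguous; ≤ was chosen and is tested at exactly 3.0 px).

$\theta$ is an input annotation per cell — in practice drawn through the BB
and the synapse; the geometry generator records it exactly.

**Statistics.** Pairwise kinetic comparisons use the classical
equal-variance Student's *t* (Welch via a flag); contact parameters are
not normally distributed, so they use the Mann–Whitney *U* test, exact by
enumeration of all $\binom{n_1+n_2}{n_1}$ labelings when the combined
sample is ≤ 16 (ties handled through midranks), otherwise the normal
approximation with tie and continuity correction. Multi-group kinetic
comparisons use one-way fixed-effects ANOVA (`stats::oneway.test`,
equal-variance). All p-values are two-sided, and no multiple-testing
correction is applied, matching the per-parameter reporting convention of
the emulated protocol. Degenerate inputs are defined rather than fatal:
two zero-variance samples with equal means give p = 1; identical groups
give F = 0, p = 1.

## The synthetic-data generator

The generator exists so that every stage has a ground-truth oracle. It
emulates, per cell:

- a rectangular cell footprint of configurable length × width (defaults
  60 × 12 px ≈ 12.6 × 2.5 μm), rotated by $\theta$, with the BB near the
  apical end and compartment boundaries partitioning the axis into an
  apical (BB) region, the inner segment, and the basal region;
- puncta performing a confined anisotropic Gaussian walk in the cell frame
  (defaults: axial σ = 400 nm/frame, lateral σ = 150 nm/frame), reflected
  at the inner-segment boundaries — reflection, not absorption, so path
  length is conserved under confinement;
- rare directed excursions to the BB and back (Poisson-triggered,
  p = 0.003/frame, 800 nm/s), producing the transient BB approaches seen
  in such recordings. 800 nm/s keeps approach steps near 1 μm/s while
  remaining below the linker's 4.32 px gate, so an excursion stays inside
  one track and registers as a contact; at faster speeds the approach
  fragments into ineligible one-frame tracks and contacts become
  systematically unobservable — a measurement-model interaction, not a
  biological statement;
- geometric lifetimes (mean 400 frames) and Poisson births
  (0.01/frame);
- rendering as isotropic Gaussian blobs (PSF σ = 250 nm ≈ the diffraction
  limit at the emulated magnification, convolved with the finite particle
  radius), a static BB blob in channel 2, a weak static cytoplasmic
  autofluorescence inside the cell mask (5% of peak), optional Poisson
  shot and Gaussian read noise, and optional stage drift;
- a mutant mode: fewer puncta (3 vs 4), a diffuse cytoplasmic signal
  fraction (0.3) and doubled lateral σ, emulating the qualitative
  mutant phenotype (partial cytoplasmic mislocalization, more lateral
  movement) without claiming parameter values.

**Density calibration.** The number of puncta per cell is not stated in
the emulated study; it was fixed at 4 (wild type) because (a) a handful of
well-individualizable puncta per cell is what such recordings show, and
(b) the generator must satisfy its stated calibration: on noiseless
renders with the default anisotropy, the *measured* directionality is < 1
for ≥ 90% of eligible tracks (the acceptance suite computes this). At
higher densities blob mergers fragment tracks into short segments whose
span ratios are noisy, and the calibration fails even though the
ground-truth motion is unchanged — a useful reminder that the pipeline
measures tracks, not particles.

**What the generator does not emulate:** 3-D motion and focal-plane loss,
photobleaching and blinking, motion blur within a frame, neighbouring
cells and tissue background, non-rigid tissue movement, and any
nucleus/synapse structure. Passing tests on synthetic data therefore
validate the measurement chain, not the biology of real recordings.

## Numerical choices

- **Coordinates:** 0-based pixel indices, x = column, y = row; the apical
  end of an unrotated cell is at low y. Physical units are px × 210 nm;
  displacement and speed are reported in nm and nm/s, trajectory and area
  in μm and μm², matching the usual plotting conventions.
- **Registration** estimates integer shifts by FFT cross-correlation.
  The default correlates consecutive frames and accumulates, because a
  distant reference frame no longer shares particle positions and the
  correlation locks onto spurious punctum alignments. On synthetic videos
  whose channel 1 contains *only* moving puncta, even per-step estimates
  can wander by ±1 px; `register_stack(..., channel = 2)` anchors the
  estimate on the static BB channel instead — precisely the role of an
  immobile reference marker. Sub-pixel refinement is not implemented;
  drifted-noisy recovery is within 1 px by construction.
- **Assignment ties** are broken deterministically by the solver's
  augmenting order (lowest detection index first); forbidden pairs carry a
  finite cost of appearance + disappearance + 1, which is provably never
  chosen.
- **Constant frames** (normalization undefined) yield zero detections
  rather than an error; empty frames are legal everywhere in the linker.
- **TIFF I/O** writes 32-bit float samples scaled to [0, 1] with the
  intensity scale and calibration (pixel size, frame interval) in a JSON
  sidecar, because the baseline TIFF writer exposes no free-form
  calibration tag; `read_stack()` restores both exactly.
- **Determinism:** every stochastic component (motion, births/deaths,
  noise, selection) takes an explicit integer seed; identical
  configuration + seed reproduces bit-identical tracks, videos and output
  files. The pipeline stamps an MD5 hash of its configuration and the
  seeds into every CSV it writes.

## Problem sizes used in validation

The shipped validation runs use: 600-frame videos for tracking-recovery
and calibration checks (3 particles / 3 cells), 200 random instances of
≤ 4 detections × ≤ 5 frames for the enumeration oracle of the linker,
50 tracks × 600 frames for the closed-form (Rayleigh step mean) estimator
check, and the full replicated design — 13 photoreceptors × 5 conditions,
600 frames each — in the acceptance script, which completes in a few
minutes on one CPU. These sizes were chosen so each check is statistically
decisive (e.g. the Rayleigh check is asserted within three standard
errors) while the whole suite stays quick to run.

## Known limitations

- Translation-only registration; rotation or non-rigid drift is out of
  scope (the emulated protocol also used translation registration).
- No gap closing and no merger resolution: occlusions and crossings
  fragment tracks, biasing per-track statistics toward shorter, slower
  tracks. This is faithful to the emulated configuration, but it means
  trajectory totals depend strongly on track length, and within-track
  speeds are capped by the assignment gate (≈ 0.9 μm/frame at 210 nm
  pixels).
- Measured areas depend on the threshold and blob model: with the default
  PSF and threshold, rendered puncta segment to masks a few pixels across,
  and the resulting areas are systematically larger than the physical
  particle cross-section. Area comparisons are therefore meaningful
  within a configuration, not across configurations.
- The exact Mann–Whitney enumeration is combinatorial; above a combined
  sample of 16 the implementation switches to the corrected normal
  approximation.
- Geometry masks are convex rectangles; real photoreceptor
  footprints are not, and the confinement model ignores organelle
  exclusion volumes such as the mitochondrial cluster.
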