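---
title: "Methods: synapse detection, classification and subtype discovery from multiplexed images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synapse detection, classification and subtype discovery from multiplexed images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analysis problem

Multiplexed immunofluorescence of cultured neurons images the same field
over many rounds, each round carrying a few channels, so that ten or more
synaptic proteins can be measured at every synapse. `synaptopipe`
implements the full computational path from the raw per-round images to
population statistics:

1. **Registration.** Every round includes a MAP2 (dendrite) channel; the
   translation of each round relative to the first is estimated from MAP2
   by normalized cross-correlation and undone on all channels of that
   round. Registration is restricted to integer translations: the
   generator injects integer shifts, translation is the dominant error
   mode of repeated-wash imaging, and subpixel interpolation would alter
   the intensity statistics measured later.
2. **Illumination correction.** A smooth background (grayscale
   morphological opening with a disc, default radius 30 px) is subtracted
   from each channel and the result clipped at zero. The disc must be
   larger than any foreground structure to be preserved; 30 px clears the
   largest nuclei while broad gradients survive into the background
   estimate and are removed.
3. **Spot enhancement.** A white top-hat (image minus opening, disc
   radius 4 px) suppresses everything wider than a diffraction-limited
   punctum (puncta are at most 15 px across; the 9-px-diameter element
   retains them while flattening dendritic and nuclear signal).
4. **Thresholding.** The robust-background rule: per image, discard the
   dimmest and brightest 5% of pixels and take mean + 2 sd of the rest.
   Thresholds are computed on untreated-group images only, averaged into
   a single per-target threshold, and applied to every group, so that
   treatment comparisons cannot be confounded by segmentation.
5. **Declumping.** Catchment basins of the 1-px-Gaussian-smoothed image
   are computed by watershed flooding over the *whole* field -- every
   punctum's pixels drain to the punctum's own intensity maximum, maxima
   closer than 3 px merge (the flooding window is a chessboard radius of
   `min_peak_distance - 1`, matching the Euclidean 3-px rule), and maxima
   whose prominence is below half the image's MAD-based noise floor are
   absorbed (`tolerance_k = 0.5`; sub-noise bumps otherwise both
   fragment puncta and dominate the flooding cost). Foreground pixels
   (strictly above threshold) then inherit their basin label, so the
   threshold only selects pixels and the object count is monotone
   non-increasing in the threshold by construction. Labeling uses
   8-connectivity.
6. **Compartments.** Nuclei from Otsu's threshold on smoothed DAPI with
   hole filling; dendrites from the robust-background threshold on MAP2;
   small objects removed from both.
7. **Synapse assembly.** Puncta with equivalent diameter outside
   [3, 15] px (inclusive) are discarded. A punctum is non-synaptic if it
   touches the nuclei mask or lies farther than 8 px (Euclidean distance
   transform, edge-based, inclusive) from the dendrite mask. Every
   surviving synapsin1 punctum anchors one synapse; every other punctum
   joins the anchor with which it shares the largest fraction of its own
   area, provided that fraction is at least 50% for presynaptic targets
   (vGlut1, vGAT, bassoon) and at least 6.25% -- one pixel of a 16-px
   punctum -- for postsynaptic targets. The overlap denominator is the
   child's area: it makes the 6.25% rule exact in pixels and is the
   conventional parent-child colocalization score. Ties go to the lowest
   anchor id so repeated runs agree exactly; a child joins at most one
   synapse. Anchors themselves must pass the location rules.
8. **Classification.** Only vGlut1 children: excitatory. Only vGAT:
   inhibitory. Both: dual. Neither: unknown. Dual and unknown synapses
   are kept in the feature table but excluded from embedding and
   downstream group statistics, which operate on confidently classified
   synapses.
9. **Features.** A CellProfiler-style battery per synapse: anchor shape
   (area, equivalent diameter, perimeter, form factor, extent, solidity,
   Euler number, eccentricity, axis lengths, orientation, mean/maximum
   radius, compactness), anchor-region intensity statistics measured on
   every channel (integrated/min/max, population sd, median absolute
   deviation, type-7 quartiles, edge statistics over pixels with a
   4-neighbour outside the region, mass displacement), per-target child
   counts and distances, and same-source child intensity statistics.
   `reduced_feature_set()` lists the 107 metric-source-target combinations
   used as embedding input.
10. **Subtype discovery.** Classified synapses are subsampled to at most
    2000 per replicate (so each replicate contributes equally), columns
    containing missing values are removed, features with pairwise
    |Pearson r| > 0.90 are pruned greedily (drop the member with the
    larger mean absolute correlation, repeat), columns are centred and
    scaled, a 2D UMAP is fitted (neighbourhood size 15, minimum distance
    0.1, Euclidean metric, fixed random state) and HDBSCAN with
    `min_cluster_size = 100` labels the embedding; low-density points are
    noise (cluster -1) and excluded from profiles. Clusters are
    renumbered by descending size.
11. **Statistics.** All group comparisons operate on *replicate means* --
    the culture replicate is the exchangeable unit, not the synapse.
    Two-tailed permutation tests on the mean difference are computed by
    exhaustive enumeration whenever `choose(n1+n2, n1)` does not exceed
    the shuffle budget (the default 6-vs-5 design has only 462
    relabelings, so its p values are exact); otherwise 5000 random
    relabelings with the identity included in numerator and denominator,
    so p is never zero. Effect sizes are Cohen's d with pooled sd;
    intervals are bias-corrected and accelerated bootstrap (5000
    resamples; bias correction from the midrank fraction of resamples
    below the estimate, acceleration from jackknife skewness); power uses
    the noncentral t distribution with `ncp = d*sqrt(n1*n2/(n1+n2))`.
    Per-cluster correlation matrices are computed per replicate, averaged
    element-wise, and entries with |r| < 0.4 are masked (|r| = 0.4 is
    displayed; the bound is exclusive). A Benjamini-Hochberg column is
    emitted for information only; reported p values are raw.

# The synthetic-data generator

No raw images accompany the study conditions this package targets, so the
generator is a first-class module: it renders cohorts whose statistical
structure matches what the analysis assumes, with complete ground truth.

**Scene.** Each field contains a dendrite arbor (two smoothed random
walks of unit steps, rendered 5 px wide; the analytic walk length is the
true dendrite length), DAPI nuclei (disks of radius 12 px placed away
from the dendrite so that the nuclei-exclusion rule removes decoys rather
than real synapses), and synapses placed along the walk with
perpendicular jitter (sd 2.5 px, truncated at 6 px, keeping everything
within the 8-px dendrite rule).

**Synapses.** Class first: 22% unknown (synapsin1 only), 12% dual (both
markers), the remaining 66% split excitatory:inhibitory at 5:1. Subtypes
within a class follow six profiles -- five excitatory (one complete
high-intensity profile at weight 0.55, three each missing a different
postsynaptic/cytoskeletal group, one sparse low-intensity profile) and
one inhibitory (vGAT/gephyrin positive) -- with per-target presence
probabilities, log-normal intensities (sd 0.3) and a 4% cross-reactivity
floor for nominally absent targets. Every punctum is a 2D Gaussian
truncated at 3 sigma and renormalized so the discrete kernel sums exactly
to the true integrated intensity; at zero noise the rendered image is an
exact sum of kernels, which the tests exploit. Punctum sd is drawn once
per synapse from 0.9-1.4 px (the diffraction-limited spot size at
187 nm/pixel) and shared across the synapse's puncta (+-10% presynaptic,
+-20% postsynaptic): markers of one synapse label the same structure, and
this is what makes the 50% presynaptic overlap rule satisfiable at all.
Child offsets from the anchor centre are Gaussian (sd 0.8 px presynaptic,
1.8 px postsynaptic).

**Densities.** Defaults are 56 excitatory and 15.8 inhibitory synapses
per 100 um of dendrite; anchors are placed at
`(56+15.8)/100/0.66` per um so that the *classified* density matches
those figures after the dual/unknown fraction is accounted for.

**Nuisance structure.** Per-round integer shifts up to +-4 px; a
multiplicative planar illumination gradient of relative amplitude 0.15
with random orientation per round; an additive baseline of 50 counts;
Poisson shot noise plus Gaussian read noise (sd 3). Replicates carry
independent log-normal per-target intensity factors (sd 0.1) emulating
culture/staining variability -- these, not synapse-level variance, set
the power of replicate-level tests. Treated replicates additionally
multiply per-target intensities by configurable treatment effects.
Decoy puncta (including deliberately over- and under-sized ones) exercise
the size and location filters. One master seed drives everything;
per-field substreams are derived from (replicate, field) so any field can
be regenerated in isolation, byte-identically.

**What the generator does not emulate** -- and therefore what passing
tests do not establish about real data: Airy/PSF optics beyond an
isotropic Gaussian, z-projection artifacts, photobleaching or
round-to-round signal decay, rotational/non-rigid drift, structured
antibody cross-reactivity, axons and non-neuronal cells, and spatial
clustering of subtypes along dendrites. Results on real images depend on
those factors; the synthetic cohort validates the *bookkeeping and
statistics* of the pipeline, not its robustness to every imaging
pathology.

# Crowding and the resolvable regime

A corollary worth stating explicitly: the generator draws class labels at
the configured rates (12% dual, 22% unknown, E:I = 5 among the rest), but
the *detected* composition differs, because resolution-limited
cross-assignment converts classes into one another -- an inhibitory
anchor that captures a vGlut1 punctum from the five-fold denser
excitatory neighbourhood is reported dual, an excitatory anchor whose
merged vGlut1 blob fails the 50% rule is reported unknown. At the default
density the detected cohort runs at roughly 15-20% dual and 30-35%
unknown, and the detected E:I ratio sits a few percent below the
generative 5:1. This mirrors real data, where the published dual/unknown
fractions are also post-detection quantities.

At the default densities the mean anchor spacing along the dendrite
(~0.9 um, under 5 px) is comparable to the diffraction-limited punctum
footprint, so nearby synapses genuinely merge: at full density roughly
half of true anchors are recovered as single objects, and a matched-pair
analysis shows the remainder merge with a neighbour (the same physics
that produces "dual" synapses in real data). Merging affects excitatory
and inhibitory synapses nearly proportionally, so the classified E:I
*ratio* is preserved within a few percent even where one-to-one recovery
is impossible. One-to-one recovery itself (>= 95% of true synapses found
within 2 px, >= 95% classified correctly) is therefore validated in a
sparse, minimum-separation configuration (`min_separation_px = 7`, about
one eighth of the default density, zero noise) where the spots are
resolvable by construction; the full-density regime is validated through
the ratio, density and statistical checks instead.

# Numerical choices

- **Perimeter** is the chain length of the Moore-traced boundary with
  step weights 0.948 (orthogonal) and 1.340 (diagonal), the standard
  bias-corrected chain-code estimator; it makes the form factor of
  rasterized disks approach 1 with radius, which the plain crack-length
  count does not. Hole boundaries are included; an isolated pixel
  contributes 4.
- **Second moments** include the 1/12 unit-pixel variance term, so a
  one-pixel-wide line has positive minor axis and eccentricity strictly
  below 1.
- **Solidity** divides the pixel count by the size of the rasterized
  convex hull (pixels whose centre falls in the hull of the region's
  pixel centres), the regionprops convention, so it never exceeds 1 on
  rasterized shapes.
- **Euler number** counts 8-connected components minus 4-connected holes.
- **Radii** are Euclidean distances to the nearest background pixel
  (boundary pixels have radius 1).
- **Quartiles** interpolate linearly between order statistics (R type 7);
  intensity spreads use the population sd; MAD is unscaled.
- **Minimum distance** of a child is measured from its centroid to the
  anchor's boundary pixels, 0 if the centroid lies inside the anchor;
  with several children per target, distances are averaged and
  intensities are computed over the union of child pixels.
- **Dendrite length** is measured on the Zhang-Suen skeleton after a
  sequential simple-point cleanup pass (parallel thinning leaves 2-px
  staircase residue that would inflate path length by ~40%) and pruning
  of spur branches shorter than 8 px running from an endpoint to a
  junction (mask-edge noise artifacts; unbranched chains are never
  touched). Length is orthogonal steps + sqrt(2) x diagonal steps + 1
  per component, so a straight run of k pixels measures exactly k. On
  generated fields the measured length agrees with the analytic walk
  length within ~6%.
- **Embedding/clustering back end.** UMAP and HDBSCAN run in the bundled
  Python helper (`inst/python/embed_cluster.py`) on top of the reference
  implementations (umap-learn; scikit-learn's HDBSCAN), exchanged with R
  as CSV. Density clustering in this field is routinely done through the
  Python implementation, and a fixed `random_state` with a single worker
  makes the embedding deterministic. The fitted model is pickled next to
  the run output so held-out rows can be transformed later.

# Test and simulation sizes

The shipped tests validate ground-truth statistics on cohorts of 11
replicates x 5 fields at the default 256-px field (about 7000 synapses);
image-path checks run on 128-256-px fields, up to 6 replicates x 15
fields for the E:I-ratio recovery; subtype recovery embeds ~4700
classified synapses;
BCa coverage uses 400 simulations of 400 resamples; null calibration
uses 200 replicate-level comparisons from 20 simulated cohorts. These
sizes were chosen to give each check useful statistical resolution
(binomial/Poisson error well inside the asserted bands) at desk scale.

# Known limitations

- Registration is translation-only; rotation or scale drift would
  degrade alignment silently (the QC shift table is the guard).
- The robust-background threshold assumes mostly-background images; on a
  noise-free synthetic field it can fall to zero, making footprints as
  wide as the rendered kernels. With any realistic noise floor it
  behaves as intended.
- HDBSCAN cluster counts depend on embedding hyperparameters; the
  defaults are logged in the provenance file, and the acceptance check is
  subtype recovery on synthetic data, not any particular count on real
  data.
- A child punctum overlapping two anchors equally is assigned by anchor
  id; no probabilistic splitting is attempted.
- Statistics treat replicates as exchangeable; plate or batch structure
  beyond the replicate factor is not modelled.
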