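# synaptopipe

Single-synapse analysis of multiplexed immunofluorescence images of
cultured neurons. Multi-round imaging measures ten or more synaptic
proteins on the same field; `synaptopipe` turns the raw per-round images
into classified synapses, per-synapse feature profiles, phenotypic
subtypes and replicate-level statistics:

- **Registration** of every imaging round on its MAP2 (dendrite) channel
  by normalized cross-correlation (integer translation).
- **Illumination correction** (background subtraction by grayscale
  morphological opening) and **white top-hat** spot enhancement.
- **Robust-background thresholding** (trimmed mean + 2 sd, averaged over
  untreated-group images and applied identically to all groups) and
  **watershed declumping** of puncta by intensity peaks.
- **Synapse assembly**: each synapsin1 punctum anchors one synapse;
  puncta with equivalent diameter outside [3, 15] px, touching nuclei, or
  more than 8 px from the dendrite mask are non-synaptic; other puncta
  join the anchor they overlap most, requiring at least 50% of their own
  area for presynaptic targets (vGlut1, vGAT, bassoon) and at least
  6.25% for postsynaptic ones.
- **Classification**: vGlut1 only → excitatory; vGAT only → inhibitory;
  both → dual; neither → unknown.
- **Feature battery**: CellProfiler-style shape and intensity statistics
  per synapse across all channels (`reduced_feature_set()` lists the 107
  combinations used for embedding).
- **Subtype discovery**: replicate-balanced subsampling (2000 synapses
  per replicate), correlation pruning (|r| > 0.9), centring/scaling, 2D
  UMAP, HDBSCAN (`min_cluster_size = 100`) with noise removal, and
  per-cluster intensity/composition profiles.
- **Statistics** on replicate means: two-tailed permutation t tests
  (exact by enumeration for the default 6-vs-5 design), Cohen's d with
  BCa bootstrap intervals, noncentral-t power, per-cluster correlation
  matrices masked at |r| < 0.4, and synapse densities per 100 µm of
  skeletonized dendrite (0.187 µm/px).

Because raw multiplexed cohorts are rarely shareable, the package ships a
**synthetic-data generator** (`synth_config()`, `generate_field()`,
`generate_cohort()`) that renders multi-round 16-bit TIFF cohorts --
dendrite arbor, nuclei, subtype-structured synapses, misalignment, uneven
illumination, Poisson + Gaussian noise, replicate and treatment effects --
with complete ground truth, so every stage is testable end to end.

## Worked example

Simulate a small cohort, process one field, and assemble synapses:

```r
library(synaptopipe)

cfg <- synth_config(seed = 7, n_replicates_untreated = 1L,
                    n_replicates_treated = 0L, fields_per_replicate = 1L,
                    noise_model = list(poisson_scale = 1, gaussian_sd = 1),
                    illumination_gradient_amplitude = 0.05)
gf   <- generate_field(cfg, "UT1", 1)
proc <- process_field(gf$field)          # align, correct, enhance
thr  <- vapply(proc$enhanced, function(e)
  robust_background_threshold(list(e)), numeric(1))
res  <- segment_and_assemble(proc, thr, pixel_size_um = cfg$pixel_size_um)

table(res$synapses$class)
#>       dual excitatory inhibitory    unknown
#>         14         30         10         29
round(res$dendrite_length_um, 1)
#> [1] 124.3
synapse_density(res$synapses, res$masks$dendrite)[1:3, c(1, 2, 4)]
#>        scope count density_per_100um
#> 1        all    83         66.786298
#> 2 excitatory    30         24.139626
#> 3 inhibitory    10          8.046542
```

One field of ~124 µm dendrite yields 83 synapsin1-anchored synapses, 30
excitatory and 10 inhibitory. Detected counts undercount the simulated
ground truth (the generator renders synapses at the full study density,
where neighbouring diffraction-limited puncta genuinely merge -- the
methods vignette quantifies this), and one field is far too small to
estimate the excitatory:inhibitory ratio; the acceptance script below
measures it on >5000 anchors. The recorded shifts (`proc$shifts`)
reproduce the generator's injected round-to-round misalignment exactly.

The full pipeline -- thresholds from the untreated group, all fields,
feature table, embedding, clustering, statistics, provenance YAML -- is
one call (or the `inst/scripts/synaptopipe` command-line wrapper):

```r
run_pipeline(synth_config(seed = 7), "results/run1")
```

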