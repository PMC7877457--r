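# Shared small configurations and cached expensive fixtures.

# small, fast field: quarter-size image, fewer rounds of the same layout
small_config <- function(...) {
  args <- utils::modifyList(
    list(image_shape = c(128L, 128L), dendrite_path_px = 320,
         fields_per_replicate = 2L, n_nuclei = 2L, decoys_per_field = 6L),
    list(...))
  do.call(synth_config, args)
}

# resolvable regime: sparse, well-separated, noise-free synapses for
# one-to-one recovery checks
resolvable_config <- function(...) {
  synth_config(
    noise_model = list(poisson_scale = 0, gaussian_sd = 0),
    illumination_gradient_amplitude = 0,
    shift_range_px = 0L,
    decoys_per_field = 0L,
    synapse_density_per_100um = c(excitatory = 8, inhibitory = 2.3),
    min_separation_px = 7,
    ...
  )
}

# build puncta tables directly from 0-based pixel coordinate sets
make_puncta <- function(regions, targets, dim = c(64L, 64L)) {
  rows <- lapply(seq_along(regions), function(i) {
    rc <- regions[[i]]
    idx <- as.integer(rc[, 1] + 1L + rc[, 2] * dim[1])
    data.frame(id = i, target = targets[i], role = role_of(targets[i]),
               area = nrow(rc), eq_diameter = 2 * sqrt(nrow(rc) / pi),
               centroid_r = mean(rc[, 1]), centroid_c = mean(rc[, 2]),
               pixels = I(list(idx)), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

rect_region <- function(r0, r1, c0, c1) {
  as.matrix(expand.grid(r = r0:r1, c = c0:c1))
}

# cache one processed default-ish field across tests in a session
.fixture_env <- new.env()

processed_small_field <- function() {
  if (is.null(.fixture_env$psf)) {
    cfg <- small_config(seed = 42)
    gf <- generate_field(cfg, "UT1", 1)
    proc <- process_field(gf$field)
    thr <- vapply(proc$enhanced, function(e)
      robust_background_threshold(list(e)), numeric(1))
    .fixture_env$psf <- list(cfg = cfg, gf = gf, proc = proc, thr = thr)
  }
  .fixture_env$psf
}
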