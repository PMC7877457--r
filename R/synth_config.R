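#' Default synaptic subtype profiles
#'
#' Six phenotypic profiles drive the generator: five excitatory subtypes and
#' one inhibitory subtype. Profiles differ in which targets are present and
#' how bright they are, in the style of per-cluster relative-intensity
#' heatmaps from multiplexed synapse studies: one "full" excitatory subtype
#' carrying every excitatory-side target at high intensity, three subtypes
#' each missing a different group of postsynaptic/cytoskeletal proteins, one
#' sparse low-intensity subtype, and an inhibitory subtype defined by
#' vGAT/gephyrin. Values are arbitrary intensity units (only relative
#' effects are meaningful); presence is a per-target Bernoulli probability.
#'
#' @return A list of profiles. Each profile is a list with fields `name`,
#'   `weight` (mixture weight within its class), `class` (`"excitatory"` or
#'   `"inhibitory"`), `presence` (named probability vector over synaptic
#'   targets), `mean_log` and `sd_log` (named, log integrated intensity),
#'   `sigma_range` (px, punctum Gaussian sd), `offset_sd_pre` and
#'   `offset_sd_post` (px, child offset from the anchor centroid).
#' @export
default_subtype_profiles <- function() {
  tg <- synaptic_targets()
  base_presence <- c(
    Synapsin1 = 1, vGlut1 = 0, vGAT = 0, Bassoon = 0.9,
    PSD95 = 0.9, SHANK3 = 0.9, Homer1bc = 0.9, NR2B = 0.85,
    Gephyrin = 0.04, Actin = 0.85, Cortactin = 0.85
  )[tg]
  hi <- log(2500)
  mid <- log(1400)
  lo <- log(800)
  mk_mean <- function(level) stats::setNames(rep(level, length(tg)), tg)
  profile <- function(name, class, weight, presence, mean_log,
                      sigma_range = c(0.9, 1.4)) {
    list(name = name, class = class, weight = weight,
         presence = presence, mean_log = mean_log,
         sd_log = stats::setNames(rep(0.3, length(tg)), tg),
         sigma_range = sigma_range,
         offset_sd_pre = 0.8, offset_sd_post = 1.8)
  }

  p1 <- base_presence; p1["vGlut1"] <- 1
  m1 <- mk_mean(hi)

  p2 <- p1; p2[c("Homer1bc", "NR2B")] <- 0.04
  m2 <- mk_mean(mid)

  p3 <- p1; p3[c("Actin", "Cortactin")] <- 0.04
  m3 <- mk_mean(mid); m3[c("Synapsin1", "vGlut1")] <- hi

  p4 <- p1; p4[c("PSD95", "SHANK3")] <- 0.04
  m4 <- mk_mean(mid)

  p5 <- p1
  p5[setdiff(tg, c("Synapsin1", "vGlut1", "Bassoon"))] <- 0.05
  p5["Bassoon"] <- 0.6
  m5 <- mk_mean(lo); m5[c("Synapsin1", "vGlut1")] <- mid

  p6 <- c(
    Synapsin1 = 1, vGlut1 = 0, vGAT = 1, Bassoon = 0.6,
    PSD95 = 0.12, SHANK3 = 0.12, Homer1bc = 0.25, NR2B = 0.05,
    Gephyrin = 0.9, Actin = 0.6, Cortactin = 0.5
  )[tg]
  m6 <- mk_mean(mid)
  m6[c("Synapsin1", "vGAT", "Gephyrin")] <- hi

  list(
    profile("exc_full",        "excitatory", 0.55, p1, m1),
    profile("exc_low_nmda",    "excitatory", 0.13, p2, m2),
    profile("exc_low_cyto",    "excitatory", 0.12, p3, m3),
    profile("exc_low_scaffold","excitatory", 0.10, p4, m4),
    profile("exc_sparse",      "excitatory", 0.10, p5, m5),
    profile("inhibitory",      "inhibitory", 1.00, p6, m6)
  )
}

#' Configuration for the synthetic multiplexed-image generator
#'
#' Builds and validates the full parameter set for simulating a cohort of
#' multi-round, multi-channel fluorescence fields of cultured neurons:
#' a MAP2 dendrite arbor, DAPI nuclei, synapsin1-anchored synapses whose
#' per-target content follows configurable subtype profiles, plus
#' round-to-round misalignment, uneven illumination, and Poisson + Gaussian
#' noise. The same configuration and seed always produce identical output.
#'
#' @param image_shape integer (rows, cols) of each field, pixels.
#' @param pixel_size_um micrometres per pixel; default 0.187.
#' @param n_rounds number of imaging rounds; default 10. Every round carries
#'   a MAP2 channel used for registration.
#' @param channels_per_round channels per round; default 4.
#' @param n_replicates_untreated,n_replicates_treated replicate counts
#'   (defaults 6 and 5).
#' @param fields_per_replicate fields of view per replicate; default 5.
#' @param synapse_density_per_100um named vector with elements `excitatory`
#'   and `inhibitory`: classified synapses per 100 um of dendrite (defaults
#'   56 and 15.8).
#' @param ei_ratio expected excitatory:inhibitory count ratio among
#'   classified synapses; default 5.
#' @param dual_rate,unknown_rate fraction of anchors rendered with both
#'   markers / with no marker (defaults 0.12 and 0.22).
#' @param subtype_profiles list of subtype profiles; see
#'   [default_subtype_profiles()].
#' @param shift_range_px maximum absolute integer round-to-round shift
#'   (rows and cols); default 4.
#' @param illumination_gradient_amplitude relative amplitude of the smooth
#'   multiplicative illumination field; default 0.15.
#' @param noise_model list with `poisson_scale` (photon counts per intensity
#'   unit; 0 disables shot noise) and `gaussian_sd` (read noise, counts).
#' @param treatment_effects named per-target multiplicative intensity
#'   factors applied to treated replicates; unnamed targets default to 1.
#' @param replicate_effect_sd sd of the per-replicate, per-target log-normal
#'   intensity factor (between-replicate biological/staining variability).
#' @param dendrite_path_px total dendrite path length per field in pixels;
#'   default `2.5 * min(image_shape)`.
#' @param dendrite_width_px rendered dendrite width, pixels; default 5.
#' @param n_nuclei,nucleus_radius_px DAPI nuclei per field and radius.
#' @param decoys_per_field non-synaptic decoy puncta per field (placed
#'   anywhere, including off-dendrite and on nuclei); default 12.
#' @param min_separation_px minimum 2D distance between synapse centres
#'   (rejection sampling; 0 = none, the default). Real cultures have
#'   near-coincident synapses, so this is off by default; validation of
#'   one-to-one recovery uses it to construct a resolvable field.
#' @param background_level additive baseline intensity, counts.
#' @param seed integer master seed; per-field substreams are derived
#'   deterministically from (replicate, field).
#' @return An object of class `synth_config` (a validated list).
#' @export
synth_config <- function(image_shape = c(256L, 256L),
                         pixel_size_um = 0.187,
                         n_rounds = 10L,
                         channels_per_round = 4L,
                         n_replicates_untreated = 6L,
                         n_replicates_treated = 5L,
                         fields_per_replicate = 5L,
                         synapse_density_per_100um = c(excitatory = 56,
                                                       inhibitory = 15.8),
                         ei_ratio = 5,
                         dual_rate = 0.12,
                         unknown_rate = 0.22,
                         subtype_profiles = default_subtype_profiles(),
                         shift_range_px = 4L,
                         illumination_gradient_amplitude = 0.15,
                         noise_model = list(poisson_scale = 1,
                                            gaussian_sd = 3),
                         treatment_effects = NULL,
                         replicate_effect_sd = 0.1,
                         dendrite_path_px = NULL,
                         dendrite_width_px = 5,
                         n_nuclei = 3L,
                         nucleus_radius_px = 12,
                         decoys_per_field = 12L,
                         min_separation_px = 0,
                         background_level = 50,
                         seed = 1L) {
  tg <- synaptic_targets()
  te <- stats::setNames(rep(1, length(tg)), tg)
  if (!is.null(treatment_effects)) {
    bad <- setdiff(names(treatment_effects), tg)
    if (length(bad)) stop("treatment_effects for unknown target(s): ",
                          paste(bad, collapse = ", "))
    te[names(treatment_effects)] <- treatment_effects
  }
  cfg <- list(
    image_shape = as.integer(image_shape),
    pixel_size_um = pixel_size_um,
    n_rounds = as.integer(n_rounds),
    channels_per_round = as.integer(channels_per_round),
    target_list = c(tg, "MAP2", "DAPI"),
    n_replicates_untreated = as.integer(n_replicates_untreated),
    n_replicates_treated = as.integer(n_replicates_treated),
    fields_per_replicate = as.integer(fields_per_replicate),
    synapse_density_per_100um = synapse_density_per_100um,
    ei_ratio = ei_ratio,
    dual_rate = dual_rate,
    unknown_rate = unknown_rate,
    subtype_profiles = subtype_profiles,
    shift_range_px = as.integer(shift_range_px),
    illumination_gradient_amplitude = illumination_gradient_amplitude,
    noise_model = noise_model,
    treatment_effects = te,
    replicate_effect_sd = replicate_effect_sd,
    dendrite_path_px = dendrite_path_px %||% (2.5 * min(image_shape)),
    dendrite_width_px = dendrite_width_px,
    n_nuclei = as.integer(n_nuclei),
    nucleus_radius_px = nucleus_radius_px,
    decoys_per_field = as.integer(decoys_per_field),
    min_separation_px = min_separation_px,
    background_level = background_level,
    seed = as.integer(seed)
  )
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  stopifnot(length(cfg$image_shape) == 2L, all(cfg$image_shape >= 32L))
  if (cfg$pixel_size_um <= 0) stop("pixel_size_um must be > 0")
  if (cfg$ei_ratio <= 0) stop("ei_ratio must be > 0")
  if (cfg$dual_rate < 0 || cfg$unknown_rate < 0 ||
      cfg$dual_rate + cfg$unknown_rate >= 1) {
    stop("dual_rate + unknown_rate must lie in [0, 1)")
  }
  for (cls in c("excitatory", "inhibitory")) {
    w <- vapply(Filter(function(p) p$class == cls, cfg$subtype_profiles),
                function(p) p$weight, numeric(1))
    if (!length(w)) stop("no subtype profile of class ", cls)
    if (abs(sum(w) - 1) > 1e-8) {
      stop("subtype profile weights for class ", cls, " must sum to 1")
    }
  }
  for (p in cfg$subtype_profiles) {
    if (any(p$presence < 0 | p$presence > 1)) {
      stop("presence probabilities must lie in [0, 1] (profile ", p$name, ")")
    }
  }
  n_slots <- (cfg$channels_per_round - 1L) * cfg$n_rounds
  n_nonmap2 <- length(cfg$target_list) - 1L
  if (n_slots < n_nonmap2) {
    stop("channel layout too small: ", n_nonmap2, " non-MAP2 targets need ",
         n_nonmap2, " slots but only ", n_slots, " are available")
  }
  # sizing: the rendered puncta must plausibly fit into the field
  exp_anchors <- expected_anchor_count(cfg)
  if (exp_anchors * 9 > 0.5 * prod(cfg$image_shape)) {
    stop("image too small to hold the requested synapse density: ",
         "expected ", round(exp_anchors), " anchors in a ",
         paste(cfg$image_shape, collapse = "x"), " field")
  }
  invisible(cfg)
}

#' @keywords internal
expected_anchor_count <- function(cfg) {
  classified_frac <- 1 - cfg$dual_rate - cfg$unknown_rate
  dens <- sum(cfg$synapse_density_per_100um) / 100 / classified_frac
  len_um <- cfg$dendrite_path_px * cfg$pixel_size_um
  dens * len_um
}

#' Per-round channel-to-target map
#'
#' MAP2 occupies channel 1 of every round (it is the registration
#' reference); DAPI and the synaptic targets fill the remaining channels
#' round-major, starting with DAPI and synapsin1 in round 1. Unused slots
#' are left out of the map.
#'
#' @param cfg a [synth_config()].
#' @return data.frame with columns `round`, `channel`, `target`.
#' @export
channel_map <- function(cfg) {
  others <- c("DAPI", setdiff(cfg$target_list, c("MAP2", "DAPI")))
  rows <- data.frame(round = seq_len(cfg$n_rounds), channel = 1L,
                     target = "MAP2", stringsAsFactors = FALSE)
  slots <- expand.grid(channel = seq(2L, cfg$channels_per_round),
                       round = seq_len(cfg$n_rounds))
  slots <- slots[order(slots$round, slots$channel), ]
  n <- length(others)
  rows <- rbind(rows, data.frame(round = slots$round[seq_len(n)],
                                 channel = slots$channel[seq_len(n)],
                                 target = others, stringsAsFactors = FALSE))
  rows <- rows[order(rows$round, rows$channel), ]
  rownames(rows) <- NULL
  rows
}

#' Read or write a generator configuration as YAML
#'
#' Subtype profiles are serialized field-by-field so a round trip restores
#' an identical configuration.
#'
#' @param cfg a [synth_config()].
#' @param path file path.
#' @return `read_synth_config` returns a `synth_config`.
#' @export
write_synth_config <- function(cfg, path) {
  ## yaml drops the names of named atomic vectors; convert them to maps
  named_to_list <- function(x) {
    if (is.list(x)) {
      lapply(x, named_to_list)
    } else if (is.atomic(x) && !is.null(names(x))) {
      as.list(x)
    } else x
  }
  ## precision 17 makes the double round trip exact, so a reloaded
  ## configuration reproduces cohorts byte-identically
  yaml::write_yaml(named_to_list(unclass(cfg)), path, precision = 17)
  invisible(path)
}

#' @rdname write_synth_config
#' @export
read_synth_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$subtype_profiles <- lapply(x$subtype_profiles, function(p) {
    for (f in c("presence", "mean_log", "sd_log")) p[[f]] <- unlist(p[[f]])
    p$sigma_range <- as.numeric(unlist(p$sigma_range))
    p
  })
  args <- x[setdiff(names(x), "target_list")]
  te <- unlist(args$treatment_effects)
  args$treatment_effects <- te
  args$synapse_density_per_100um <- unlist(args$synapse_density_per_100um)
  do.call(synth_config, args)
}
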