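## Synthetic multiplexed-field generator.
##
## A field is sampled in two steps: (1) `sample_field_truth()` draws the
## dendrite arbor, nuclei, synapse positions, classes, subtypes and
## per-target punctum parameters (the ground truth); (2) `render_field()`
## turns the truth into per-round, per-channel images with shifts,
## illumination and noise. Both are deterministic given (config, replicate,
## field): every source of randomness runs under a seed derived from the
## master seed and the replicate/field indices.

#' Replicate layout of a synthetic cohort
#'
#' @param cfg a [synth_config()].
#' @return data.frame with columns `replicate` (e.g. `"UT1"`, `"TTX2"`) and
#'   `treatment` (`"untreated"` / `"treated"`).
#' @export
cohort_replicates <- function(cfg) {
  n_u <- cfg$n_replicates_untreated
  n_t <- cfg$n_replicates_treated
  if (n_u + n_t < 1L) stop("cohort must contain at least one replicate")
  data.frame(
    replicate = c(if (n_u) paste0("UT", seq_len(n_u)),
                  if (n_t) paste0("TTX", seq_len(n_t))),
    treatment = c(rep("untreated", n_u), rep("treated", n_t)),
    stringsAsFactors = FALSE
  )
}

field_seed <- function(cfg, replicate_idx, field_id) {
  as.integer((as.double(cfg$seed) * 10007 + replicate_idx * 1009 +
                field_id * 101) %% 2147483629)
}

#' Per-replicate intensity factors
#'
#' Each replicate carries an independent log-normal multiplicative factor
#' per target, emulating between-culture/staining variability. Factors are
#' derived from the master seed and the replicate index only, so any field
#' of a replicate can be regenerated in isolation.
#'
#' @param cfg a [synth_config()].
#' @return matrix (replicates x targets) of multiplicative factors.
#' @export
replicate_factors <- function(cfg) {
  reps <- cohort_replicates(cfg)
  tg <- synaptic_targets()
  out <- matrix(1, nrow(reps), length(tg),
                dimnames = list(reps$replicate, tg))
  for (i in seq_len(nrow(reps))) {
    set.seed(field_seed(cfg, i, 0L))
    out[i, ] <- exp(stats::rnorm(length(tg), 0, cfg$replicate_effect_sd))
  }
  out
}

## -- truth sampling ---------------------------------------------------------

sample_dendrite <- function(cfg) {
  nr <- cfg$image_shape[1]; nc <- cfg$image_shape[2]
  margin <- 16
  n_seg <- 2L
  steps_per_seg <- ceiling(cfg$dendrite_path_px / n_seg)
  pts <- vector("list", n_seg)
  for (s in seq_len(n_seg)) {
    r <- stats::runif(1, margin, nr - margin)
    c <- stats::runif(1, margin, nc - margin)
    th <- stats::runif(1, 0, 2 * pi)
    p <- matrix(NA_real_, steps_per_seg + 1L, 2)
    p[1, ] <- c(r, c)
    for (k in seq_len(steps_per_seg)) {
      th <- th + stats::rnorm(1, 0, 0.10)
      rn <- r + sin(th); cn <- c + cos(th)
      if (rn < margin || rn > nr - margin) { th <- -th; rn <- r + sin(th) }
      if (cn < margin || cn > nc - margin) { th <- pi - th; cn <- c + cos(th) }
      r <- min(max(rn, margin), nr - margin)
      c <- min(max(cn, margin), nc - margin)
      p[k + 1L, ] <- c(r, c)
    }
    pts[[s]] <- p
  }
  list(points = pts, length_px = n_seg * steps_per_seg,
       length_um = n_seg * steps_per_seg * cfg$pixel_size_um)
}

sample_nuclei <- function(cfg, dendrite) {
  nr <- cfg$image_shape[1]; nc <- cfg$image_shape[2]
  allp <- do.call(rbind, dendrite$points)
  sub <- allp[seq(1, nrow(allp), by = 4L), , drop = FALSE]
  min_d <- cfg$nucleus_radius_px + cfg$dendrite_width_px / 2 + 10
  centers <- matrix(NA_real_, 0, 2)
  tries <- 0L
  while (nrow(centers) < cfg$n_nuclei && tries < 300L) {
    tries <- tries + 1L
    cand <- c(stats::runif(1, cfg$nucleus_radius_px + 2,
                           nr - cfg$nucleus_radius_px - 2),
              stats::runif(1, cfg$nucleus_radius_px + 2,
                           nc - cfg$nucleus_radius_px - 2))
    d2 <- (sub[, 1] - cand[1])^2 + (sub[, 2] - cand[2])^2
    if (min(d2) > min_d^2) centers <- rbind(centers, cand)
  }
  centers
}

sample_class <- function(cfg) {
  u <- stats::runif(1)
  if (u < cfg$unknown_rate) return("unknown")
  if (u < cfg$unknown_rate + cfg$dual_rate) return("dual")
  p_exc <- cfg$ei_ratio / (cfg$ei_ratio + 1)
  if (stats::runif(1) < p_exc) "excitatory" else "inhibitory"
}

pick_profile <- function(cfg, class) {
  pool_class <- if (class == "inhibitory") "inhibitory" else "excitatory"
  pool <- Filter(function(p) p$class == pool_class, cfg$subtype_profiles)
  w <- vapply(pool, function(p) p$weight, numeric(1))
  pool[[sample.int(length(pool), 1, prob = w)]]
}

#' Sample the ground truth of one field (no rendering)
#'
#' @param cfg a [synth_config()].
#' @param replicate_id replicate label from [cohort_replicates()].
#' @param field_id integer field index (1-based).
#' @return list with `synapses` (one row per anchor: ids, class, subtype,
#'   centroid in 0-based pixel coordinates, per-target true integrated
#'   intensity), `puncta` (every rendered punctum incl. decoys), `field`
#'   (true shifts as a rounds x 2 matrix, dendrite length), `dendrite`,
#'   `nuclei`.
#' @export
sample_field_truth <- function(cfg, replicate_id, field_id) {
  reps <- cohort_replicates(cfg)
  ri <- match(replicate_id, reps$replicate)
  if (is.na(ri)) stop("unknown replicate id: ", replicate_id)
  treatment <- reps$treatment[ri]
  rf <- replicate_factors(cfg)[replicate_id, ]
  set.seed(field_seed(cfg, ri, field_id))

  dend <- sample_dendrite(cfg)
  nuc <- sample_nuclei(cfg, dend)
  tg <- synaptic_targets()
  te <- if (treatment == "treated") cfg$treatment_effects else
    stats::setNames(rep(1, length(tg)), tg)

  classified_frac <- 1 - cfg$dual_rate - cfg$unknown_rate
  dens_per_um <- sum(cfg$synapse_density_per_100um) / 100 / classified_frac
  n_syn <- stats::rpois(1, dens_per_um * dend$length_um)

  allp <- do.call(rbind, dend$points)
  n_path <- nrow(allp)

  syn_rows <- vector("list", n_syn)
  pun_rows <- vector("list", n_syn)
  placed <- matrix(NA_real_, n_syn, 2)
  for (i in seq_len(n_syn)) {
    for (try in 1:50) {
      k <- sample.int(n_path - 1L, 1)
      step <- allp[k + 1L, ] - allp[k, ]
      perp <- c(-step[2], step[1]) / sqrt(sum(step^2))
      off <- max(min(stats::rnorm(1, 0, 2.5), 6), -6)
      center <- allp[k, ] + perp * off
      if (cfg$min_separation_px <= 0 || i == 1L) break
      d2 <- (placed[seq_len(i - 1L), 1] - center[1])^2 +
        (placed[seq_len(i - 1L), 2] - center[2])^2
      if (min(d2, na.rm = TRUE) >= cfg$min_separation_px^2) break
    }
    placed[i, ] <- center
    class <- sample_class(cfg)
    prof <- pick_profile(cfg, class)
    subtype <- switch(class, dual = "dual", unknown = "unknown", prof$name)

    present <- stats::runif(length(tg)) < prof$presence[tg]
    names(present) <- tg
    present["Synapsin1"] <- TRUE
    if (class == "excitatory") { present["vGlut1"] <- TRUE; present["vGAT"] <- FALSE }
    if (class == "inhibitory") { present["vGAT"] <- TRUE; present["vGlut1"] <- FALSE }
    if (class == "dual")       { present["vGlut1"] <- TRUE; present["vGAT"] <- TRUE }
    if (class == "unknown")    present[setdiff(tg, "Synapsin1")] <- FALSE

    mean_log <- prof$mean_log
    if (class == "dual" && present["vGAT"]) {
      inh <- Filter(function(p) p$class == "inhibitory", cfg$subtype_profiles)[[1]]
      mean_log["vGAT"] <- inh$mean_log["vGAT"]
    }
    pt <- tg[present]
    inten <- exp(stats::rnorm(length(pt), mean_log[pt], prof$sd_log[pt])) *
      rf[pt] * te[pt]
    ## puncta of one synapse share its physical scale: presynaptic partners
    ## closely (they mark the same bouton), postsynaptic ones more loosely
    sigma_base <- stats::runif(1, prof$sigma_range[1], prof$sigma_range[2])
    role <- role_of(pt)
    sigma <- sigma_base * ifelse(role == "anchor", 1,
                                 ifelse(role == "presynaptic",
                                        stats::runif(length(pt), 0.9, 1.1),
                                        stats::runif(length(pt), 0.8, 1.2)))
    osd <- ifelse(role == "presynaptic", prof$offset_sd_pre,
                  ifelse(role == "anchor", 0, prof$offset_sd_post))
    dr <- stats::rnorm(length(pt), 0, osd)
    dc <- stats::rnorm(length(pt), 0, osd)

    syn_rows[[i]] <- data.frame(
      replicate = replicate_id, treatment = treatment, field = field_id,
      synapse = i, class = class, subtype = subtype,
      row = center[1] - 1, col = center[2] - 1,
      stringsAsFactors = FALSE
    )
    iv <- stats::setNames(rep(0, length(tg)), tg)
    iv[pt] <- inten
    syn_rows[[i]] <- cbind(syn_rows[[i]],
                           as.data.frame(as.list(iv),
                                         col.names = paste0("intensity_", tg)))
    pun_rows[[i]] <- data.frame(
      synapse = i, target = pt, row = center[1] + dr, col = center[2] + dc,
      sigma = sigma, intensity = inten, decoy = FALSE,
      stringsAsFactors = FALSE
    )
  }

  ## decoys: off-pipeline clutter, including over/under-sized puncta
  n_dec <- cfg$decoys_per_field
  dec <- NULL
  if (n_dec > 0) {
    kind <- sample(c("normal", "big", "tiny"), n_dec, replace = TRUE,
                   prob = c(0.5, 0.25, 0.25))
    dec <- data.frame(
      synapse = NA_integer_,
      target = sample(tg, n_dec, replace = TRUE),
      row = stats::runif(n_dec, 4, cfg$image_shape[1] - 4),
      col = stats::runif(n_dec, 4, cfg$image_shape[2] - 4),
      sigma = ifelse(kind == "big", stats::runif(n_dec, 4.5, 6),
                     ifelse(kind == "tiny", stats::runif(n_dec, 0.35, 0.5),
                            stats::runif(n_dec, 1.0, 1.8))),
      intensity = exp(stats::rnorm(n_dec, log(1500), 0.4)) *
        ifelse(kind == "big", 8, 1),
      decoy = TRUE, stringsAsFactors = FALSE
    )
  }

  shifts <- matrix(0L, cfg$n_rounds, 2,
                   dimnames = list(NULL, c("row", "col")))
  if (cfg$n_rounds > 1L && cfg$shift_range_px > 0L) {
    shifts[-1L, ] <- matrix(
      sample.int(2L * cfg$shift_range_px + 1L,
                 2L * (cfg$n_rounds - 1L), replace = TRUE) -
        cfg$shift_range_px - 1L,
      ncol = 2)
  }

  syn <- if (n_syn) do.call(rbind, syn_rows) else NULL
  pun <- do.call(rbind, c(pun_rows, list(dec)))
  list(
    synapses = syn,
    puncta = pun,
    field = data.frame(replicate = replicate_id, treatment = treatment,
                       field = field_id,
                       dendrite_length_um = dend$length_um,
                       stringsAsFactors = FALSE),
    shifts = shifts,
    dendrite = dend,
    nuclei = nuc
  )
}

## -- rendering --------------------------------------------------------------

stamp_gaussian <- function(img, r0, c0, sigma, intensity) {
  R <- ceiling(3 * sigma)
  rs <- floor(r0 - R):ceiling(r0 + R)
  cs <- floor(c0 - R):ceiling(c0 + R)
  w <- outer(rs, cs, function(r, c) {
    d2 <- (r - r0)^2 + (c - c0)^2
    ifelse(d2 <= (3 * sigma)^2, exp(-d2 / (2 * sigma^2)), 0)
  })
  sw <- sum(w)
  if (sw == 0) return(img)
  kern <- intensity * w / sw
  keep_r <- rs >= 1 & rs <= nrow(img)
  keep_c <- cs >= 1 & cs <= ncol(img)
  img[rs[keep_r], cs[keep_c]] <- img[rs[keep_r], cs[keep_c]] +
    kern[keep_r, keep_c]
  img
}

render_dendrite_mask <- function(cfg, dendrite) {
  m <- matrix(FALSE, cfg$image_shape[1], cfg$image_shape[2])
  rad <- cfg$dendrite_width_px / 2
  R <- ceiling(rad)
  offs <- expand.grid(dr = -R:R, dc = -R:R)
  offs <- offs[offs$dr^2 + offs$dc^2 <= rad^2, ]
  allp <- do.call(rbind, dendrite$points)
  pr <- round(allp[, 1]); pc <- round(allp[, 2])
  for (k in seq_len(nrow(offs))) {
    r <- pr + offs$dr[k]; c <- pc + offs$dc[k]
    ok <- r >= 1 & r <= nrow(m) & c >= 1 & c <= ncol(m)
    m[cbind(r[ok], c[ok])] <- TRUE
  }
  m
}

render_nuclei_image <- function(cfg, nuclei, intensity = 180) {
  img <- matrix(0, cfg$image_shape[1], cfg$image_shape[2])
  if (is.null(nuclei) || nrow(nuclei) == 0) return(img)
  R <- ceiling(cfg$nucleus_radius_px)
  for (i in seq_len(nrow(nuclei))) {
    rs <- pmax(1, round(nuclei[i, 1]) - R):pmin(nrow(img), round(nuclei[i, 1]) + R)
    cs <- pmax(1, round(nuclei[i, 2]) - R):pmin(ncol(img), round(nuclei[i, 2]) + R)
    d2 <- outer(rs, cs, function(r, c) (r - nuclei[i, 1])^2 + (c - nuclei[i, 2])^2)
    img[rs, cs] <- img[rs, cs] + intensity * (d2 <= cfg$nucleus_radius_px^2)
  }
  as.matrix(EBImage::gblur(img, sigma = 2))
}

shift_int <- function(img, dr, dc) {
  out <- matrix(0, nrow(img), ncol(img))
  nr <- nrow(img); nc <- ncol(img)
  src_r <- max(1, 1 - dr):min(nr, nr - dr)
  src_c <- max(1, 1 - dc):min(nc, nc - dc)
  if (!length(src_r) || !length(src_c)) return(out)
  out[src_r + dr, src_c + dc] <- img[src_r, src_c]
  out
}

illumination_field <- function(shape, amplitude) {
  if (amplitude == 0) return(matrix(1, shape[1], shape[2]))
  th <- stats::runif(1, 0, 2 * pi)
  r <- (seq_len(shape[1]) - (shape[1] + 1) / 2) / shape[1]
  c <- (seq_len(shape[2]) - (shape[2] + 1) / 2) / shape[2]
  plane <- outer(r, c, function(r, c) r * sin(th) + c * cos(th)) * 2
  1 + amplitude * plane
}

#' Generate one multiplexed field and its ground truth
#'
#' Renders the per-round, per-channel images of a single field of view:
#' puncta as 2D Gaussian kernels truncated at 3 sigma (normalized so the
#' discrete kernel sums exactly to the true integrated intensity), the MAP2
#' dendrite, DAPI nuclei, the per-round true shift, a smooth multiplicative
#' illumination gradient, an additive background, and Poisson + Gaussian
#' noise (applied after shifting). Images are kept as un-quantized numeric
#' matrices; 16-bit quantization happens only when TIFFs are written.
#'
#' @inheritParams sample_field_truth
#' @return list with `field` (a `multiplexed_field`: named image list,
#'   channel map, replicate/treatment/field ids) and `truth` (see
#'   [sample_field_truth()], plus the rendered dendrite/nuclei masks).
#' @export
generate_field <- function(cfg, replicate_id, field_id) {
  truth <- sample_field_truth(cfg, replicate_id, field_id)
  cm <- channel_map(cfg)
  dmask <- render_dendrite_mask(cfg, truth$dendrite)

  base <- list()
  for (t in cfg$target_list) {
    img <- matrix(0, cfg$image_shape[1], cfg$image_shape[2])
    if (t == "MAP2") {
      img <- as.matrix(EBImage::gblur(dmask * 120, sigma = 1))
    } else if (t == "DAPI") {
      img <- render_nuclei_image(cfg, truth$nuclei)
    }
    pp <- truth$puncta
    if (!is.null(pp)) {
      pp <- pp[pp$target == t, , drop = FALSE]
      for (i in seq_len(nrow(pp))) {
        img <- stamp_gaussian(img, pp$row[i], pp$col[i], pp$sigma[i],
                              pp$intensity[i])
      }
    }
    base[[t]] <- img
  }

  ps <- cfg$noise_model$poisson_scale %||% 0
  gs <- cfg$noise_model$gaussian_sd %||% 0
  images <- list()
  for (i in seq_len(nrow(cm))) {
    rd <- cm$round[i]; ch <- cm$channel[i]; t <- cm$target[i]
    img <- shift_int(base[[t]], truth$shifts[rd, 1], truth$shifts[rd, 2])
    img <- img + cfg$background_level
    ill <- illumination_field(cfg$image_shape,
                              cfg$illumination_gradient_amplitude)
    img <- img * ill
    if (ps > 0) img <- stats::rpois(length(img), img * ps) / ps
    if (gs > 0) img <- img + stats::rnorm(length(img), 0, gs)
    img <- matrix(pmax(img, 0), cfg$image_shape[1], cfg$image_shape[2])
    images[[sprintf("r%02d_c%d", rd, ch)]] <- img
  }

  field <- structure(list(
    images = images, map = cm,
    replicate = replicate_id,
    treatment = truth$field$treatment,
    field_id = field_id,
    pixel_size_um = cfg$pixel_size_um,
    shifts = NULL, aligned = FALSE
  ), class = "multiplexed_field")

  truth$dendrite_mask <- dmask
  list(field = field, truth = truth)
}

#' Generate a full synthetic cohort
#'
#' Loops over the configured replicates and fields. With `out_dir` set,
#' each field's images are written as one 16-bit grayscale TIFF per
#' round/channel and dropped from memory; otherwise all fields are returned
#' in memory (only sensible for small configurations).
#'
#' @param cfg a [synth_config()].
#' @param out_dir optional output directory for TIFFs and CSVs.
#' @return list with `manifest` (one row per image file, or per field when
#'   kept in memory), `truth` (cohort-level ground-truth synapse table),
#'   `field_truth` (per-field dendrite lengths and shift matrices),
#'   `fields` (list of `multiplexed_field`, NULL when writing to disk).
#' @export
generate_cohort <- function(cfg, out_dir = NULL) {
  reps <- cohort_replicates(cfg)
  fields <- list(); man <- list(); syn <- list(); ft <- list(); shifts <- list()
  for (ri in seq_len(nrow(reps))) {
    for (fi in seq_len(cfg$fields_per_replicate)) {
      gf <- generate_field(cfg, reps$replicate[ri], fi)
      key <- sprintf("%s_f%02d", reps$replicate[ri], fi)
      syn[[key]] <- gf$truth$synapses
      ft[[key]] <- gf$truth$field
      shifts[[key]] <- gf$truth$shifts
      if (is.null(out_dir)) {
        fields[[key]] <- gf$field
        man[[key]] <- data.frame(replicate = reps$replicate[ri],
                                 treatment = reps$treatment[ri],
                                 field = fi, path = NA_character_,
                                 stringsAsFactors = FALSE)
      } else {
        man[[key]] <- write_field_tiffs(gf$field, out_dir)
      }
    }
  }
  truth <- do.call(rbind, unname(syn))
  field_truth <- do.call(rbind, unname(ft))
  rownames(field_truth) <- NULL
  manifest <- do.call(rbind, unname(man))
  rownames(manifest) <- NULL
  if (!is.null(out_dir)) {
    utils::write.csv(truth, file.path(out_dir, "ground_truth_synapses.csv"),
                     row.names = FALSE)
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  }
  list(manifest = manifest, truth = truth, field_truth = field_truth,
       shifts = shifts,
       fields = if (is.null(out_dir)) fields else NULL)
}

#' Ground-truth cohort without rendering
#'
#' Fast path for validating the statistical stages: samples every field's
#' ground truth (positions, classes, true intensities under replicate and
#' treatment effects) without rendering pixels.
#'
#' @param cfg a [synth_config()].
#' @return list with `truth` and `field_truth` as in [generate_cohort()].
#' @export
simulate_cohort_truth <- function(cfg) {
  reps <- cohort_replicates(cfg)
  syn <- list(); ft <- list()
  for (ri in seq_len(nrow(reps))) {
    for (fi in seq_len(cfg$fields_per_replicate)) {
      tr <- sample_field_truth(cfg, reps$replicate[ri], fi)
      key <- sprintf("%s_f%02d", reps$replicate[ri], fi)
      syn[[key]] <- tr$synapses
      ft[[key]] <- tr$field
    }
  }
  ft <- do.call(rbind, unname(ft)); rownames(ft) <- NULL
  list(truth = do.call(rbind, unname(syn)), field_truth = ft)
}

#' Feature table built from ground-truth intensities
#'
#' Turns a ground-truth synapse table into the intensity block of a
#' feature table (columns `IntegratedIntensity__Synapsin1__<target>`), with
#' optional log-normal measurement noise. Used to exercise the
#' normalization/clustering/statistics stages directly against the
#' generator's truth.
#'
#' @param truth ground-truth synapse table from [generate_cohort()] or
#'   [simulate_cohort_truth()].
#' @param measurement_sd sd of multiplicative log-normal measurement noise
#'   (0 = exact truth).
#' @return data.frame with metadata columns (`replicate`, `treatment`,
#'   `field`, `class`, `subtype`) and one intensity column per target.
#' @export
ground_truth_features <- function(truth, measurement_sd = 0) {
  tg <- synaptic_targets()
  out <- truth[, c("replicate", "treatment", "field", "class", "subtype")]
  for (t in tg) {
    v <- truth[[paste0("intensity_", t)]]
    if (measurement_sd > 0) {
      v <- v * exp(stats::rnorm(length(v), 0, measurement_sd))
    }
    out[[paste0("IntegratedIntensity__Synapsin1__", t)]] <- v
  }
  out
}

## -- TIFF i/o ---------------------------------------------------------------

#' Write one field as 16-bit TIFFs
#'
#' One file per round/channel, named
#' `<replicate>_f<field>_r<round>_c<channel>_<target>.tif`. Intensities are
#' rounded to integer counts and clipped to the 16-bit range.
#'
#' @param field a `multiplexed_field`.
#' @param dir output directory (created if needed).
#' @return manifest data.frame (one row per file).
#' @export
write_field_tiffs <- function(field, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (i in seq_len(nrow(field$map))) {
    rd <- field$map$round[i]; ch <- field$map$channel[i]
    t <- field$map$target[i]
    key <- sprintf("r%02d_c%d", rd, ch)
    fn <- sprintf("%s_f%02d_%s_%s.tif", field$replicate, field$field_id,
                  key, t)
    img <- round(pmin(pmax(field$images[[key]], 0), 65535))
    tiff::writeTIFF(img / 65535, file.path(dir, fn),
                    bits.per.sample = 16, compression = "none")
    rows[[i]] <- data.frame(replicate = field$replicate,
                            treatment = field$treatment,
                            field = field$field_id, round = rd, channel = ch,
                            target = t, path = file.path(dir, fn),
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Read one field back from a TIFF manifest
#'
#' @param manifest manifest rows (single replicate/field) as written by
#'   [write_field_tiffs()].
#' @param pixel_size_um micrometres per pixel to record on the field.
#' @return a `multiplexed_field` with intensities in counts.
#' @export
read_field_tiffs <- function(manifest, pixel_size_um = 0.187) {
  stopifnot(nrow(manifest) > 0)
  if (length(unique(paste(manifest$replicate, manifest$field))) != 1L) {
    stop("manifest must describe exactly one field")
  }
  images <- list()
  for (i in seq_len(nrow(manifest))) {
    if (!file.exists(manifest$path[i])) {
      stop("missing image for round ", manifest$round[i], " channel ",
           manifest$channel[i], ": ", manifest$path[i])
    }
    img <- tiff::readTIFF(manifest$path[i]) * 65535
    images[[sprintf("r%02d_c%d", manifest$round[i], manifest$channel[i])]] <-
      img
  }
  structure(list(
    images = images,
    map = manifest[, c("round", "channel", "target")],
    replicate = manifest$replicate[1], treatment = manifest$treatment[1],
    field_id = manifest$field[1], pixel_size_um = pixel_size_um,
    shifts = NULL, aligned = FALSE
  ), class = "multiplexed_field")
}
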