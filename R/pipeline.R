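## End-to-end orchestration: simulate (or read) fields, process images,
## assemble and classify synapses, build the feature table, embed and
## cluster, and run the statistics battery. Re-running with the same
## configuration reproduces all CSV outputs byte-identically.

#' Pipeline stage parameters
#'
#' All tunables of the processing/assembly/clustering stages in one
#' place; echoed into the run's provenance file.
#'
#' @param illumination_radius disc radius (px) for background opening.
#' @param tophat_radius white top-hat disc radius (px), default 4.
#' @param trim_lo,trim_hi,k_sd robust-background threshold parameters.
#' @param min_peak_distance,smooth_sigma declumping parameters (px).
#' @param d_min,d_max size filter bounds (px, inclusive).
#' @param overlap_presynaptic,overlap_postsynaptic assignment thresholds.
#' @param max_dendrite_distance px, inclusive.
#' @param subsample_quota synapses per replicate for clustering input.
#' @param cor_cutoff correlation-pruning cutoff.
#' @param n_neighbors,min_dist UMAP hyperparameters.
#' @param min_cluster_size HDBSCAN minimum cluster size.
#' @param n_shuffles,n_boot resampling budgets for the statistics stage.
#' @return list of class `pipeline_params`.
#' @export
pipeline_params <- function(illumination_radius = 30,
                            tophat_radius = 4,
                            trim_lo = 0.05, trim_hi = 0.05, k_sd = 2,
                            min_peak_distance = 3, smooth_sigma = 1,
                            d_min = 3, d_max = 15,
                            overlap_presynaptic = 0.5,
                            overlap_postsynaptic = 0.0625,
                            max_dendrite_distance = 8,
                            subsample_quota = 2000,
                            cor_cutoff = 0.90,
                            n_neighbors = 15, min_dist = 0.1,
                            min_cluster_size = 100,
                            n_shuffles = 5000, n_boot = 5000) {
  p <- as.list(environment())
  class(p) <- "pipeline_params"
  p
}

#' Process one field: align, correct illumination, enhance puncta
#'
#' @param field a `multiplexed_field`.
#' @param params a [pipeline_params()].
#' @return list with `corrected` (per-target illumination-corrected
#'   images), `enhanced` (white top-hat images for puncta targets),
#'   `shifts` (estimated per-round shifts).
#' @export
process_field <- function(field, params = pipeline_params()) {
  field <- align_rounds(field)
  imgs <- target_images(field)
  corrected <- lapply(imgs, correct_illumination,
                      radius = params$illumination_radius)
  puncta_targets <- intersect(synaptic_targets(), names(imgs))
  enhanced <- lapply(corrected[puncta_targets], white_tophat,
                     se_radius = params$tophat_radius)
  list(corrected = corrected, enhanced = enhanced, shifts = field$shifts)
}

#' Segment and assemble one processed field
#'
#' @param processed output of [process_field()].
#' @param thresholds named per-target intensity thresholds (from the
#'   untreated group).
#' @param params a [pipeline_params()].
#' @param pixel_size_um micrometres per pixel for the dendrite length.
#' @return list with `synapses`, `assignments`, `puncta`, `masks`,
#'   `features`, `dendrite_length_um`.
#' @export
segment_and_assemble <- function(processed, thresholds,
                                 params = pipeline_params(),
                                 pixel_size_um = 0.187) {
  comp <- segment_compartments(processed$corrected[["DAPI"]],
                               processed$corrected[["MAP2"]],
                               trim_lo = params$trim_lo,
                               trim_hi = params$trim_hi, k_sd = params$k_sd)
  puncta <- list()
  offset <- 0L
  for (t in names(processed$enhanced)) {
    seg <- segment_puncta(processed$enhanced[[t]], thresholds[[t]],
                          min_peak_distance = params$min_peak_distance,
                          smooth_sigma = params$smooth_sigma)
    pp <- puncta_from_labels(seg$labels, t, id_offset = offset)
    offset <- offset + max(0L, seg$n)
    puncta[[t]] <- pp
  }
  puncta <- do.call(rbind, unname(puncta))
  rownames(puncta) <- NULL
  puncta <- size_filter(puncta, params$d_min, params$d_max)
  asm <- assemble_synapses(puncta, comp$nuclei, comp$dendrite,
                           targets = names(processed$enhanced),
                           overlap_presynaptic = params$overlap_presynaptic,
                           overlap_postsynaptic = params$overlap_postsynaptic,
                           max_dendrite_distance = params$max_dendrite_distance)
  feats <- compute_synapse_features(asm, puncta, processed$corrected)
  skel <- prune_spurs(skeletonize(comp$dendrite))
  len_um <- skeleton_length_px(skel) * pixel_size_um
  list(synapses = asm$synapses, assignments = asm$assignments,
       puncta = puncta, masks = comp, features = feats,
       dendrite_length_um = len_um)
}

#' Per-target thresholds from the untreated group
#'
#' Renders/loads every untreated field, processes it, and computes the
#' robust-background threshold of each puncta target on the enhanced
#' image; per-image thresholds are averaged into one threshold per target,
#' later applied to both groups so all images are segmented identically.
#'
#' @param field_source function(replicate, field_id) returning a
#'   `multiplexed_field`.
#' @param replicates data.frame from [cohort_replicates()] (untreated rows
#'   are used).
#' @param fields_per_replicate fields per replicate.
#' @param params a [pipeline_params()].
#' @return named numeric vector of thresholds.
#' @export
untreated_thresholds <- function(field_source, replicates,
                                 fields_per_replicate,
                                 params = pipeline_params()) {
  ut <- replicates$replicate[replicates$treatment == "untreated"]
  if (!length(ut)) stop("no untreated replicates to derive thresholds from")
  acc <- list()
  for (r in ut) {
    for (fi in seq_len(fields_per_replicate)) {
      proc <- process_field(field_source(r, fi), params)
      for (t in names(proc$enhanced)) {
        thr <- robust_background_threshold(list(proc$enhanced[[t]]),
                                           params$trim_lo, params$trim_hi,
                                           params$k_sd)
        acc[[t]] <- c(acc[[t]], thr)
      }
    }
  }
  vapply(acc, mean, numeric(1))
}

#' Run the full pipeline on a synthetic cohort
#'
#' Stages: simulate fields (deterministically re-rendered where needed),
#' derive per-target thresholds from the untreated group, process and
#' assemble every field, build and normalize the feature table, embed and
#' cluster the classified synapses, and run the statistics battery.
#' All CSV outputs and a provenance YAML are written under `out_dir`.
#'
#' @param cfg a [synth_config()] describing the cohort.
#' @param out_dir output directory.
#' @param params a [pipeline_params()].
#' @param stages character subset of `c("cluster", "stats")`; dropping
#'   `"cluster"` restricts statistics to class-level comparisons.
#' @param verbose print stage-level progress with object counts.
#' @return invisible list with the main tables (`features`, `synapses`,
#'   `embedding`, `clusters`, `statistics`, `densities`, `thresholds`).
#' @export
run_pipeline <- function(cfg, out_dir, params = pipeline_params(),
                         stages = c("cluster", "stats"),
                         verbose = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(...)
  reps <- cohort_replicates(cfg)
  src <- function(r, fi) generate_field(cfg, r, fi)$field

  say("deriving per-target thresholds from ",
      sum(reps$treatment == "untreated"), " untreated replicate(s)")
  thresholds <- untreated_thresholds(src, reps, cfg$fields_per_replicate,
                                     params)

  feats <- list(); dens <- list(); counts <- list()
  for (ri in seq_len(nrow(reps))) {
    r <- reps$replicate[ri]
    for (fi in seq_len(cfg$fields_per_replicate)) {
      proc <- process_field(src(r, fi), params)
      res <- segment_and_assemble(proc, thresholds, params,
                                  pixel_size_um = cfg$pixel_size_um)
      key <- sprintf("%s_f%02d", r, fi)
      f <- res$features
      if (nrow(f)) {
        f <- cbind(data.frame(replicate = r,
                              treatment = reps$treatment[ri],
                              field = fi, stringsAsFactors = FALSE), f)
        feats[[key]] <- f
      }
      dens[[key]] <- data.frame(replicate = r, treatment = reps$treatment[ri],
                                field = fi,
                                dendrite_length_um = res$dendrite_length_um,
                                n_synapses = nrow(res$synapses),
                                stringsAsFactors = FALSE)
      counts[[key]] <- table(factor(res$synapses$class,
                                    c("excitatory", "inhibitory", "dual",
                                      "unknown")))
    }
    say(r, ": ", sum(vapply(feats[grep(paste0("^", r, "_"), names(feats))],
                            nrow, integer(1))), " synapses")
  }
  features <- do.call(rbind, unname(feats))
  rownames(features) <- NULL
  densities <- do.call(rbind, unname(dens))
  rownames(densities) <- NULL

  table <- build_feature_table(features, mode = "reduced")
  table <- normalize_to_untreated(table)
  utils::write.csv(table, file.path(out_dir, "feature_table.csv"),
                   row.names = FALSE)
  utils::write.csv(densities, file.path(out_dir, "field_summary.csv"),
                   row.names = FALSE)
  syn_out <- features[, c("replicate", "treatment", "field", "anchor_id",
                          "class")]
  utils::write.csv(syn_out, file.path(out_dir, "synapses.csv"),
                   row.names = FALSE)

  embedding <- NULL; clusters <- NULL; profiles <- NULL
  assignment_full <- NULL
  if ("cluster" %in% stages) {
    ei <- which(table$class %in% c("excitatory", "inhibitory"))
    sub <- subsample_replicates(table[ei, , drop = FALSE],
                                quota = params$subsample_quota,
                                seed = cfg$seed)
    meta <- c("replicate", "treatment", "field", "anchor_id", "class",
              "subtype")
    num <- sub[, setdiff(names(sub), meta), drop = FALSE]
    ## the published procedure removes columns containing missing values
    has_na <- vapply(num, anyNA, logical(1))
    num <- num[, !has_na, drop = FALSE]
    if (nrow(num) >= max(10, params$min_cluster_size)) {
      say("clustering ", nrow(num), " classified synapses on ",
          ncol(num), " features")
      pruned <- prune_correlated_features(num, cutoff = params$cor_cutoff)
      scaled <- center_scale(pruned$table)
      emb <- fit_embedding(scaled$table, seed = cfg$seed,
                           n_neighbors = params$n_neighbors,
                           min_dist = params$min_dist,
                           model_dir = file.path(out_dir, "umap_model"))
      clusters <- cluster_embedding(emb$coords,
                                    min_cluster_size = params$min_cluster_size)
      embedding <- cbind(sub[, intersect(meta, names(sub))],
                         as.data.frame(emb$coords))
      embedding$cluster <- clusters$cluster
      utils::write.csv(embedding, file.path(out_dir, "embedding.csv"),
                       row.names = FALSE)
      profiles <- cluster_profiles(sub, clusters)
      utils::write.csv(profiles, file.path(out_dir, "cluster_profiles.csv"),
                       row.names = FALSE)
      ## map cluster ids back onto the full table rows used
      assignment_full <- rep(NA_integer_, nrow(table))
      assignment_full[match(rownames(sub), rownames(table))] <-
        clusters$cluster
      say("found ", clusters$k, " clusters (",
          sum(clusters$cluster == -1L), " noise points)")
    } else {
      say("too few classified synapses for clustering; skipping")
    }
  }

  statistics <- NULL
  if ("stats" %in% stages) {
    if (length(unique(table$treatment)) == 2) {
      sub_assign <- NULL
      stat_table <- table
      if (!is.null(clusters)) {
        ## statistics on the clustered subsample, plus class scopes
        keep <- !is.na(assignment_full)
        stat_table <- table[keep, , drop = FALSE]
        sub_assign <- assignment_full[keep]
      }
      statistics <- compare_conditions(stat_table, sub_assign,
                                       dendrite_lengths = densities,
                                       n_shuffles = params$n_shuffles,
                                       n_boot = params$n_boot,
                                       seed = cfg$seed)
      utils::write.csv(statistics, file.path(out_dir, "statistics.csv"),
                       row.names = FALSE)
      if (!is.null(clusters)) {
        cors <- cluster_correlation_matrices(stat_table, sub_assign)
        for (k in names(cors)) {
          utils::write.csv(cors[[k]]$masked,
                           file.path(out_dir,
                                     paste0("correlation_cluster", k, ".csv")))
        }
      }
    } else {
      say("single condition; skipping treated-vs-untreated statistics")
    }
  }

  prov <- list(config = unclass(cfg)[setdiff(names(cfg), "subtype_profiles")],
               params = unclass(params),
               thresholds = as.list(thresholds))
  yaml::write_yaml(prov, file.path(out_dir, "provenance.yaml"))

  invisible(list(features = table, synapses = syn_out,
                 embedding = embedding, clusters = clusters,
                 profiles = profiles, statistics = statistics,
                 densities = densities, thresholds = thresholds))
}
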