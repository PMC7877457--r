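## Assembly of per-target puncta into synapsin1-anchored synapses.
##
## Rules: a punctum is non-synaptic if it touches the nuclei mask, lies
## farther than 8 px from the dendrite mask, or fails its role's overlap
## rule with a synapsin1 anchor (presynaptic: at least 50% of its own area;
## postsynaptic: at least 6.25% -- one pixel of a 16-px punctum).

#' Build a punctum table from a label image
#'
#' @param labels integer label matrix from [segment_puncta()].
#' @param target canonical target name (fixes the punctum role).
#' @param id_offset added to the label to form the punctum id.
#' @return data.frame, one row per object: `id`, `target`, `role`, `area`
#'   (px), `eq_diameter` (px), `centroid_r`/`centroid_c` (0-based), and a
#'   `pixels` list-column of linear pixel indices into the image matrix.
#' @export
puncta_from_labels <- function(labels, target, id_offset = 0L) {
  idx <- which(labels > 0L)
  role <- role_of(target)
  if (!length(idx)) {
    return(data.frame(id = integer(), target = character(),
                      role = character(), area = integer(),
                      eq_diameter = numeric(), centroid_r = numeric(),
                      centroid_c = numeric(),
                      pixels = I(list()), stringsAsFactors = FALSE))
  }
  nr <- nrow(labels)
  lab <- labels[idx]
  pix <- split(idx, lab)
  area <- lengths(pix)
  cr <- vapply(pix, function(p) mean((p - 1L) %% nr), numeric(1))
  cc <- vapply(pix, function(p) mean((p - 1L) %/% nr), numeric(1))
  data.frame(
    id = as.integer(names(pix)) + as.integer(id_offset),
    target = target, role = role,
    area = as.integer(area),
    eq_diameter = 2 * sqrt(area / pi),
    centroid_r = cr, centroid_c = cc,
    pixels = I(unname(pix)), stringsAsFactors = FALSE
  )
}

#' Fraction of a child punctum overlapping an anchor
#'
#' @param child,anchor puncta (one-row data.frames or lists with a `pixels`
#'   element of linear indices on the same pixel grid).
#' @return `|child  n  anchor| / |child|` in `[0, 1]`.
#' @export
overlap_fraction <- function(child, anchor) {
  cp <- punctum_pixels(child)
  ap <- punctum_pixels(anchor)
  if (!length(cp)) stop("child punctum has an empty pixel set")
  length(intersect(cp, ap)) / length(cp)
}

punctum_pixels <- function(p) {
  px <- if (is.data.frame(p)) p$pixels[[1]] else p$pixels
  as.integer(unlist(px))
}

#' Keep puncta with equivalent diameter in a closed interval
#'
#' @param puncta punctum table from [puncta_from_labels()].
#' @param d_min,d_max inclusive bounds in pixels (defaults 3 and 15).
#' @return filtered punctum table.
#' @export
size_filter <- function(puncta, d_min = 3, d_max = 15) {
  if (d_min > d_max) stop("d_min must not exceed d_max")
  puncta[puncta$eq_diameter >= d_min & puncta$eq_diameter <= d_max, ,
         drop = FALSE]
}

#' Assemble puncta into synapsin1-anchored synapses
#'
#' Applies the location rules (nuclei exclusion; within
#' `max_dendrite_distance` px of the dendrite mask, edge-based by Euclidean
#' distance transform, inclusive), then assigns every surviving non-anchor
#' punctum to the anchor with maximal overlap fraction, provided the
#' fraction meets its role's threshold. Ties are broken toward the lowest
#' anchor id; a child joins at most one synapse. Each surviving anchor
#' seeds one synapse, classified by its vGlut1/vGAT children.
#'
#' @param puncta size-filtered punctum table (all targets).
#' @param nuclei_mask,dendrite_mask logical matrices on the punctum grid.
#' @param targets channels present (default: targets occurring in
#'   `puncta`); must include `"Synapsin1"`.
#' @param overlap_presynaptic,overlap_postsynaptic assignment thresholds
#'   (defaults 0.5 and 0.0625, both inclusive).
#' @param max_dendrite_distance pixels (default 8, inclusive).
#' @return list with `synapses` (anchor id, centroid, class, `children`
#'   list-column mapping target to child ids) and `assignments` (per
#'   punctum: status, assigned anchor, overlap fraction).
#' @export
assemble_synapses <- function(puncta, nuclei_mask, dendrite_mask,
                              targets = NULL,
                              overlap_presynaptic = 0.5,
                              overlap_postsynaptic = 0.0625,
                              max_dendrite_distance = 8) {
  targets <- targets %||% unique(puncta$target)
  if (!"Synapsin1" %in% targets) {
    stop("missing synapsin1 channel: cannot anchor synapses")
  }
  n <- nrow(puncta)
  status <- rep("assigned", n)
  anchor_of <- rep(NA_integer_, n)
  ovl <- rep(NA_real_, n)

  if (n) {
    if (any(dendrite_mask)) {
      dmap <- as.matrix(EBImage::distmap(!dendrite_mask))
    } else {
      dmap <- matrix(Inf, nrow(dendrite_mask), ncol(dendrite_mask))
    }
    for (i in seq_len(n)) {
      px <- puncta$pixels[[i]]
      if (any(nuclei_mask[px])) {
        status[i] <- "in_nuclei"
      } else if (min(dmap[px]) > max_dendrite_distance) {
        status[i] <- "off_dendrite"
      }
    }
  }

  ok <- status == "assigned"
  is_anchor <- puncta$role == "anchor"
  anchors <- which(ok & is_anchor)

  alab <- matrix(0L, nrow(nuclei_mask), ncol(nuclei_mask))
  for (i in anchors) alab[puncta$pixels[[i]]] <- puncta$id[i]

  for (i in which(ok & !is_anchor)) {
    px <- puncta$pixels[[i]]
    hits <- alab[px]
    hits <- hits[hits > 0L]
    if (!length(hits)) {
      status[i] <- "no_anchor_overlap"
      next
    }
    cnt <- table(hits)
    frac <- as.numeric(cnt) / length(px)
    ids <- as.integer(names(cnt))
    best <- order(-frac, ids)[1]
    thr <- if (puncta$role[i] == "presynaptic") overlap_presynaptic
           else overlap_postsynaptic
    if (frac[best] >= thr) {
      anchor_of[i] <- ids[best]
      ovl[i] <- frac[best]
    } else {
      status[i] <- "below_overlap_threshold"
      ovl[i] <- frac[best]
    }
  }
  status[!is.na(anchor_of)] <- "assigned"
  status[ok & !is_anchor & is.na(anchor_of) & status == "assigned"] <-
    "no_anchor_overlap"

  syn <- puncta[anchors, c("id", "area", "eq_diameter",
                           "centroid_r", "centroid_c"), drop = FALSE]
  names(syn)[1] <- "anchor_id"
  rownames(syn) <- NULL
  children <- vector("list", nrow(syn))
  child_targets <- setdiff(targets, "Synapsin1")
  for (k in seq_len(nrow(syn))) {
    aid <- syn$anchor_id[k]
    kids <- which(anchor_of == aid)
    children[[k]] <- lapply(stats::setNames(child_targets, child_targets),
                            function(t) puncta$id[kids[puncta$target[kids] == t]])
  }
  syn$children <- I(children)
  syn$class <- vapply(children, function(ch) {
    classify_synapse(list(children = ch))
  }, character(1))

  assignments <- data.frame(
    id = puncta$id, target = puncta$target, role = puncta$role,
    status = status, anchor_id = anchor_of, overlap = ovl,
    stringsAsFactors = FALSE
  )
  list(synapses = syn, assignments = assignments)
}

#' Classify an assembled synapse
#'
#' Only vGlut1 children: excitatory. Only vGAT children: inhibitory.
#' Both: dual. Neither: unknown.
#'
#' @param synapse list with a `children` element mapping target names to
#'   child punctum ids.
#' @return one of `"excitatory"`, `"inhibitory"`, `"dual"`, `"unknown"`.
#' @export
classify_synapse <- function(synapse) {
  ch <- synapse$children
  has_glut <- length(ch[["vGlut1"]]) > 0
  has_gat <- length(ch[["vGAT"]]) > 0
  if (has_glut && has_gat) "dual"
  else if (has_glut) "excitatory"
  else if (has_gat) "inhibitory"
  else "unknown"
}
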