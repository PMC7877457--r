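## CellProfiler-style measurement battery. All geometry is computed on
## 0-based (row, col) pixel-center coordinates; pixel sets are linear
## indices into the image matrix.

idx_to_rc <- function(idx, nr) {
  cbind(r = (idx - 1L) %% nr, c = (idx - 1L) %/% nr)
}

INTENSITY_METRICS <- c("IntegratedIntensity", "IntegratedIntensityEdge",
                       "MaxIntensity", "MinIntensity", "MinIntensityEdge",
                       "StdIntensity", "StdIntensityEdge", "MADIntensity",
                       "LowerQuartileIntensity", "UpperQuartileIntensity")

#' Shape features of a punctum
#'
#' Area, equivalent diameter, perimeter (weighted boundary chain walk:
#' 0.948 per orthogonal and 1.340 per diagonal step, so rasterized disks
#' approach the true circle perimeter), form factor `4*pi*A/P^2`, extent
#' (area over bounding box), solidity (area over convex-hull area, hull
#' taken over pixel corners so solidity never exceeds 1), Euler number
#' (8-connected components minus 4-connected holes), eccentricity, axis
#' lengths and orientation from second central moments with the 1/12
#' unit-pixel correction, mean/maximum radius from the interior Euclidean
#' distance transform, and compactness (mean squared distance from the
#' centroid over `A/(2*pi)`; 1 for an ideal disk).
#'
#' @param punctum one-row punctum table or list with `pixels`.
#' @param dim image dimensions `c(nrow, ncol)`.
#' @return named list of shape features.
#' @export
shape_features <- function(punctum, dim) {
  px <- punctum_pixels(punctum)
  if (!length(px)) stop("empty pixel set")
  nr <- dim[1]
  rc <- idx_to_rc(px, nr)
  A <- nrow(rc)
  cen <- colMeans(rc)

  bbox_r <- range(rc[, 1]); bbox_c <- range(rc[, 2])
  extent <- A / ((diff(bbox_r) + 1) * (diff(bbox_c) + 1))

  ## solidity: area over the rasterized convex hull (pixels whose centre
  ## lies in the hull of the region's pixel centres), the regionprops
  ## convention -- guarantees solidity <= 1 on rasterized shapes
  hull_px <- rasterized_hull_size(rc)
  solidity <- A / max(hull_px, A)

  ## second central moments, 1/12 pixel correction
  dr <- rc[, 1] - cen[1]; dc <- rc[, 2] - cen[2]
  mu20 <- mean(dr^2) + 1 / 12
  mu02 <- mean(dc^2) + 1 / 12
  mu11 <- mean(dr * dc)
  common <- (mu20 + mu02) / 2
  delta <- sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
  l1 <- common + delta; l2 <- common - delta
  major <- 4 * sqrt(l1); minor <- 4 * sqrt(max(l2, 0))
  ecc <- sqrt(max(1 - l2 / l1, 0))
  orientation <- 0.5 * atan2(2 * mu11, mu20 - mu02)

  euler <- euler_number(rc)
  P <- region_perimeter(rc)
  radii <- interior_radii(rc)
  compact <- mean(dr^2 + dc^2) / (A / (2 * pi))

  list(
    Area = A,
    EquivalentDiameter = 2 * sqrt(A / pi),
    Perimeter = P,
    FormFactor = 4 * pi * A / P^2,
    Extent = extent,
    Solidity = min(solidity, 1),
    EulerNumber = euler,
    Eccentricity = ecc,
    MajorAxisLength = major,
    MinorAxisLength = minor,
    Orientation = orientation,
    MeanRadius = mean(radii),
    MaximumRadius = max(radii),
    Compactness = compact
  )
}

## number of pixels whose centre lies inside (or on) the convex hull of
## the region's pixel centres
rasterized_hull_size <- function(rc) {
  h <- grDevices::chull(rc)
  hp <- rc[h, , drop = FALSE]
  if (nrow(hp) <= 2) return(nrow(rc))
  g <- expand.grid(r = min(rc[, 1]):max(rc[, 1]),
                   c = min(rc[, 2]):max(rc[, 2]))
  ## a point is inside a convex polygon iff all edge cross-products share
  ## one sign (orientation-agnostic: test both senses)
  all_le <- rep(TRUE, nrow(g)); all_ge <- rep(TRUE, nrow(g))
  n <- nrow(hp)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    cross <- (hp[j, 1] - hp[i, 1]) * (g$c - hp[i, 2]) -
      (hp[j, 2] - hp[i, 2]) * (g$r - hp[i, 1])
    all_le <- all_le & cross <= 1e-9
    all_ge <- all_ge & cross >= -1e-9
  }
  sum(all_le | all_ge)
}

## local binary mask of a region, padded by one background pixel
region_mask <- function(rc) {
  r0 <- min(rc[, 1]) - 1L; c0 <- min(rc[, 2]) - 1L
  m <- matrix(FALSE, max(rc[, 1]) - r0 + 2L, max(rc[, 2]) - c0 + 2L)
  m[cbind(rc[, 1] - r0 + 1L, rc[, 2] - c0 + 1L)] <- TRUE
  m
}

euler_number <- function(rc) {
  m <- region_mask(rc)
  n_comp <- max(label_components8(m))
  bg <- label_components4(!m)
  border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  n_holes <- length(setdiff(unique(bg[bg > 0]), border))
  n_comp - n_holes
}

label_components4 <- function(mask) {
  ## EBImage::bwlabel is 4-connected
  matrix(as.integer(EBImage::bwlabel(mask)), nrow(mask), ncol(mask))
}

## perimeter: sum of weighted chain steps along the 8-connected boundary
## of each component (plus hole boundaries), traced Moore-style.
region_perimeter <- function(rc) {
  m <- region_mask(rc)
  lab <- label_components8(m)
  total <- 0
  for (k in seq_len(max(lab))) {
    total <- total + trace_perimeter(lab == k)
  }
  ## hole boundaries contribute too: trace complement components (holes)
  bg <- label_components4(!m)
  border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  holes <- setdiff(unique(bg[bg > 0]), border)
  for (k in holes) {
    total <- total + trace_perimeter(bg == k)
  }
  total
}

## chain length of the outer boundary of a single 8-connected component.
## Moore-neighbour tracing expressed as a deterministic map on
## (pixel, incoming direction) states; the boundary chain is the cycle of
## that map, detected exactly by state repetition.
trace_perimeter <- function(m) {
  idx <- which(m)
  if (length(idx) == 1L) return(4)
  nr <- nrow(m)
  start <- idx[1]  # first foreground pixel in scan order is on the boundary
  sr <- (start - 1L) %% nr + 1L; sc <- (start - 1L) %/% nr + 1L
  dirs <- rbind(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
                c(1, 0), c(1, -1), c(0, -1), c(-1, -1))  # clockwise
  step_len <- ifelse(dirs[, 1] != 0 & dirs[, 2] != 0, 1.340, 0.948)
  advance <- function(r, c, prev_dir) {
    ## sweep clockwise starting just past the backtrack direction
    for (s in 1:8) {
      d <- ((prev_dir + 3L + s) %% 8L) + 1L
      rr <- r + dirs[d, 1]; cc <- c + dirs[d, 2]
      if (rr >= 1 && rr <= nrow(m) && cc >= 1 && cc <= ncol(m) && m[rr, cc]) {
        return(c(rr, cc, d))
      }
    }
    NULL
  }
  ## fictitious downward entry into the start pixel (pixel above is bg)
  st <- advance(sr, sc, 5L)
  if (is.null(st)) return(4)
  seen <- new.env(hash = TRUE)
  lens <- numeric(0)
  k <- 0L
  repeat {
    key <- paste(st, collapse = ",")
    if (!is.null(seen[[key]])) {
      first <- seen[[key]]
      return(sum(lens[first:k]))
    }
    k <- k + 1L
    seen[[key]] <- k
    nxt <- advance(st[1], st[2], st[3])
    lens[k] <- step_len[nxt[3]]
    st <- nxt
    if (k > 8L * length(idx) + 16L) return(sum(lens))  # safety
  }
}

boundary_pixels <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  inner <- pad[2:(nr + 1), 3:(nc + 2)] & pad[2:(nr + 1), 1:nc] &
    pad[3:(nr + 2), 2:(nc + 1)] & pad[1:nr, 2:(nc + 1)]
  m & !inner
}

## Euclidean distance of each region pixel to the nearest non-region pixel
interior_radii <- function(rc) {
  m <- region_mask(rc)
  nr <- nrow(m)
  fg <- which(m); bg <- which(!m)
  frc <- idx_to_rc(fg, nr); brc <- idx_to_rc(bg, nr)
  vapply(seq_along(fg), function(i) {
    sqrt(min((brc[, 1] - frc[i, 1])^2 + (brc[, 2] - frc[i, 2])^2))
  }, numeric(1))
}

#' Intensity features of a region on an image
#'
#' Integrated (summed) intensity, min/max, population standard deviation,
#' median absolute deviation, lower/upper quartiles (linear interpolation
#' between order statistics), the same statistics over the region edge
#' (pixels with at least one 4-neighbour outside the region), and mass
#' displacement: the Euclidean distance between the intensity-weighted and
#' the unweighted centroid.
#'
#' @param pixels linear pixel indices (or a punctum row/list).
#' @param image numeric matrix covering the region.
#' @return named list of intensity features.
#' @export
intensity_features <- function(pixels, image) {
  px <- if (is.numeric(pixels)) as.integer(pixels) else punctum_pixels(pixels)
  if (!length(px)) stop("empty region")
  if (any(px < 1L | px > length(image))) stop("region outside image")
  nr <- nrow(image)
  x <- image[px]
  rc <- idx_to_rc(px, nr)
  m <- region_mask(rc)
  bd <- boundary_pixels(m)
  r0 <- min(rc[, 1]) - 1L; c0 <- min(rc[, 2]) - 1L
  is_edge <- bd[cbind(rc[, 1] - r0 + 1L, rc[, 2] - c0 + 1L)]
  xe <- x[is_edge]
  pop_sd <- function(v) if (length(v) > 0) sqrt(mean((v - mean(v))^2)) else 0
  q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  wsum <- sum(x)
  if (wsum > 0) {
    wc <- c(sum(rc[, 1] * x), sum(rc[, 2] * x)) / wsum
  } else {
    wc <- colMeans(rc)
  }
  gc <- colMeans(rc)
  list(
    IntegratedIntensity = sum(x),
    MaxIntensity = max(x),
    MinIntensity = min(x),
    StdIntensity = pop_sd(x),
    MADIntensity = stats::median(abs(x - stats::median(x))),
    LowerQuartileIntensity = q[1],
    UpperQuartileIntensity = q[2],
    IntegratedIntensityEdge = sum(xe),
    MinIntensityEdge = if (length(xe)) min(xe) else 0,
    StdIntensityEdge = pop_sd(xe),
    MassDisplacement = sqrt(sum((wc - gc)^2))
  )
}

#' Relational features of an assembled synapse
#'
#' Per child target: number of assigned children, mean Euclidean distance
#' between child and anchor centroids, mean distance from child centroids
#' to the anchor boundary (0 for a centroid inside the anchor), and the
#' intensity features of the union of child pixels measured on the
#' target's own image. Targets with no child yield 0 counts/intensities
#' and NA distances.
#'
#' @param synapse one row of the `synapses` table from
#'   [assemble_synapses()].
#' @param puncta the punctum table the synapse was assembled from.
#' @param images named list of per-target images.
#' @return named list of features, `Metric__Source__Target` style.
#' @export
relational_features <- function(synapse, puncta, images) {
  ch <- synapse$children[[1]]
  anchor <- puncta[puncta$id == synapse$anchor_id, ]
  arc <- idx_to_rc(anchor$pixels[[1]], nrow(images[[1]]))
  am <- region_mask(arc)
  abd <- boundary_pixels(am)
  bd_rc <- which(abd, arr.ind = TRUE)
  r0 <- min(arc[, 1]) - 1L; c0 <- min(arc[, 2]) - 1L
  bd_rc <- cbind(bd_rc[, 1] + r0 - 1L, bd_rc[, 2] + c0 - 1L)  # 0-based
  acen <- c(synapse$centroid_r, synapse$centroid_c)
  anchor_set <- anchor$pixels[[1]]
  nr <- nrow(images[[1]])

  out <- list()
  for (t in names(ch)) {
    ids <- ch[[t]]
    out[[paste0("PunctaNumber__Synapsin1__", t)]] <- length(ids)
    if (!length(ids)) {
      out[[paste0("DistanceCentroid__", t, "__", t)]] <- NA_real_
      out[[paste0("DistanceMinimum__", t, "__", t)]] <- NA_real_
      for (mtr in INTENSITY_METRICS) {
        out[[paste0(mtr, "__", t, "__", t)]] <- 0
      }
      out[[paste0("MassDisplacement__", t, "__", t)]] <- 0
      next
    }
    rows <- puncta[match(ids, puncta$id), ]
    dc <- sqrt((rows$centroid_r - acen[1])^2 + (rows$centroid_c - acen[2])^2)
    dmin <- vapply(seq_len(nrow(rows)), function(i) {
      cr <- rows$centroid_r[i]; cc <- rows$centroid_c[i]
      pix <- round(cr) + 1L + round(cc) * nr
      if (pix %in% anchor_set) return(0)
      sqrt(min((bd_rc[, 1] - cr)^2 + (bd_rc[, 2] - cc)^2))
    }, numeric(1))
    out[[paste0("DistanceCentroid__", t, "__", t)]] <- mean(dc)
    out[[paste0("DistanceMinimum__", t, "__", t)]] <- mean(dmin)
    upx <- sort(unique(unlist(rows$pixels)))
    fx <- intensity_features(upx, images[[t]])
    for (mtr in names(fx)) {
      out[[paste0(mtr, "__", t, "__", t)]] <- fx[[mtr]]
    }
  }
  out
}

#' Full measurement battery for every synapse of a field
#'
#' Anchor shape features, anchor-region intensity features on every
#' target image, and the relational/child block.
#'
#' @param assembly result of [assemble_synapses()].
#' @param puncta punctum table.
#' @param images named list of per-target images (must include all
#'   measured targets).
#' @return data.frame, one row per synapse.
#' @export
compute_synapse_features <- function(assembly, puncta, images) {
  syn <- assembly$synapses
  n <- nrow(syn)
  rows <- vector("list", n)
  dimg <- dim(images[[1]])
  for (k in seq_len(n)) {
    anchor <- puncta[puncta$id == syn$anchor_id[k], ]
    sf <- shape_features(anchor, dimg)
    names(sf) <- paste0(names(sf), "__Synapsin1__Synapsin1")
    fx <- list()
    for (t in names(images)) {
      f <- intensity_features(anchor$pixels[[1]], images[[t]])
      names(f) <- paste0(names(f), "__Synapsin1__", t)
      fx <- c(fx, f)
    }
    rel <- relational_features(syn[k, ], puncta, images)
    rows[[k]] <- c(list(anchor_id = syn$anchor_id[k], class = syn$class[k]),
                   sf, fx, rel)
  }
  if (!n) return(data.frame(anchor_id = integer(), class = character()))
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, check.names = FALSE)))
}

#' The reduced feature set used for embedding
#'
#' The 107 unique `Metric x Source x Target` combinations retained after
#' feature reduction and used as clustering input: the full anchor shape
#' block, anchor-region intensity statistics measured on selected target
#' images, per-target puncta counts, and same-source child statistics.
#'
#' @return data.frame with columns `metric`, `source`, `target`, `column`.
#' @export
reduced_feature_set <- function() {
  syn <- function(metric, targets) {
    data.frame(metric = metric, source = "Synapsin1", target = targets,
               stringsAsFactors = FALSE)
  }
  own <- function(target, metrics) {
    data.frame(metric = metrics, source = target, target = target,
               stringsAsFactors = FALSE)
  }
  x <- rbind(
    syn(c("Compactness", "Eccentricity", "EulerNumber", "Extent",
          "FormFactor", "MajorAxisLength", "MaximumRadius", "MeanRadius",
          "MinorAxisLength", "Orientation", "Perimeter", "Solidity"),
        "Synapsin1"),
    syn("PunctaNumber", c("Homer1bc", "NR2B", "PSD95", "SHANK3", "Actin",
                          "Cortactin", "vGlut1")),
    syn("IntegratedIntensityEdge", c("DAPI", "Gephyrin")),
    syn("IntegratedIntensity", c("NR2B", "PSD95", "SHANK3", "Actin",
                                 "Synapsin1", "vGlut1")),
    syn("LowerQuartileIntensity", "Synapsin1"),
    syn("MADIntensity", c("DAPI", "Gephyrin", "Homer1bc", "MAP2", "PSD95",
                          "SHANK3", "Actin", "Bassoon", "Cortactin",
                          "Synapsin1", "vGAT")),
    syn("MassDisplacement", c("DAPI", "Gephyrin", "Homer1bc", "MAP2",
                              "NR2B", "PSD95", "SHANK3", "Actin", "Bassoon",
                              "Cortactin", "Synapsin1", "vGlut1", "vGAT")),
    syn("MinIntensityEdge", c("Homer1bc", "NR2B", "PSD95", "SHANK3",
                              "Actin", "Bassoon", "Cortactin", "vGlut1")),
    syn("MinIntensity", c("Gephyrin", "MAP2", "Synapsin1", "vGAT")),
    syn("StdIntensity", c("Gephyrin", "NR2B", "vGlut1")),
    syn("UpperQuartileIntensity", "DAPI"),
    own("Gephyrin", c("DistanceCentroid", "IntegratedIntensity",
                      "MassDisplacement", "StdIntensity")),
    own("Homer1bc", c("DistanceCentroid", "IntegratedIntensity",
                      "MADIntensity", "MassDisplacement", "MinIntensityEdge")),
    own("NR2B", c("DistanceMinimum", "IntegratedIntensity", "MADIntensity",
                  "MassDisplacement")),
    own("PSD95", c("DistanceMinimum", "IntegratedIntensity", "MADIntensity",
                   "MassDisplacement", "MinIntensity")),
    own("SHANK3", c("DistanceMinimum", "IntegratedIntensity",
                    "MADIntensity")),
    own("Actin", c("DistanceCentroid", "IntegratedIntensity", "MADIntensity",
                   "MassDisplacement")),
    own("Bassoon", c("DistanceCentroid", "MADIntensity",
                     "MassDisplacement")),
    own("Cortactin", c("DistanceCentroid", "IntegratedIntensity",
                       "MADIntensity", "MassDisplacement", "MinIntensity")),
    own("vGlut1", c("MADIntensity", "MassDisplacement", "MinIntensityEdge")),
    own("vGAT", c("MassDisplacement", "MinIntensity", "StdIntensityEdge"))
  )
  x$column <- paste0(x$metric, "__", x$source, "__", x$target)
  x
}

#' Assemble the analysis feature table
#'
#' Binds per-field feature rows, selects the published reduced column set (default
#' mode) or everything (full mode), and removes all-NA columns, recording
#' what was dropped.
#'
#' @param features data.frame from [compute_synapse_features()] (with
#'   metadata columns `replicate`, `treatment`, `field`, `anchor_id`,
#'   `class` added by the caller or pipeline).
#' @param mode `"reduced"` (the published embedding set) or `"full"`.
#' @return data.frame with attribute `dropped_columns`.
#' @export
build_feature_table <- function(features, mode = c("reduced", "full")) {
  mode <- match.arg(mode)
  meta <- intersect(c("replicate", "treatment", "field", "anchor_id",
                      "class", "subtype"), names(features))
  if (mode == "reduced") {
    want <- reduced_feature_set()$column
    missing <- setdiff(want, names(features))
    if (length(missing)) {
      stop("feature columns missing from input: ",
           paste(utils::head(missing, 5), collapse = ", "))
    }
    out <- features[, c(meta, want), drop = FALSE]
  } else {
    out <- features
  }
  if (anyDuplicated(names(out))) {
    stop("duplicated column names: ",
         paste(unique(names(out)[duplicated(names(out))]), collapse = ", "))
  }
  num <- setdiff(names(out), meta)
  all_na <- if (nrow(out) == 0) character(0) else
    num[vapply(out[num], function(v) all(is.na(v)), logical(1))]
  if (length(all_na)) out <- out[, setdiff(names(out), all_na), drop = FALSE]
  attr(out, "dropped_columns") <- all_na
  out
}

#' Normalize intensity features to the untreated-group mean
#'
#' Every intensity-type column (integrated/min/max/std/MAD/quartile
#' intensities, edge variants) is divided by its mean over untreated
#' synapses; shape, distance and count columns are left untouched. After
#' the call the untreated mean of each normalized column is 1.
#'
#' @param table feature table with a `treatment` column.
#' @return normalized table.
#' @export
normalize_to_untreated <- function(table) {
  if (!any(table$treatment == "untreated")) {
    stop("no untreated synapses to normalize to")
  }
  metric_of <- function(cols) sub("__.*$", "", cols)
  cols <- names(table)[metric_of(names(table)) %in% INTENSITY_METRICS]
  ut <- table$treatment == "untreated"
  for (cl in cols) {
    m <- mean(table[[cl]][ut], na.rm = TRUE)
    if (is.na(m)) next
    if (m == 0) stop("untreated mean is zero for column ", cl)
    table[[cl]] <- table[[cl]] / m
  }
  table
}
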