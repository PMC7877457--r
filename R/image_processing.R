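## Stage 1-2 of the pipeline: registration of imaging rounds on the MAP2
## channel, illumination correction, white top-hat spot enhancement,
## robust-background thresholding, watershed declumping of puncta, and
## nuclei/dendrite compartment masks.

#' Fetch an image from a multiplexed field by target
#'
#' @param field a `multiplexed_field`.
#' @param target canonical target name.
#' @param round optional round; defaults to the first round carrying the
#'   target.
#' @return numeric matrix.
#' @export
field_image <- function(field, target, round = NULL) {
  m <- field$map
  hit <- if (is.null(round)) m[m$target == target, , drop = FALSE]
         else m[m$target == target & m$round == round, , drop = FALSE]
  if (!nrow(hit)) stop("field has no image for target ", target)
  field$images[[sprintf("r%02d_c%d", hit$round[1], hit$channel[1])]]
}

#' Estimate the integer translation between two images
#'
#' Normalized cross-correlation computed via FFT; the argmax over circular
#' lags gives the shift of `img` relative to `ref` (i.e. `img` is `ref`
#' translated by the returned (row, col) offset).
#'
#' @param ref,img numeric matrices of identical shape.
#' @return integer vector (row, col).
#' @export
estimate_shift <- function(ref, img) {
  stopifnot(all(dim(ref) == dim(img)))
  if (stats::sd(ref) == 0 || stats::sd(img) == 0) {
    stop("featureless image: zero variance, cannot estimate shift")
  }
  a <- ref - mean(ref)
  b <- img - mean(img)
  cc <- Re(stats::fft(stats::fft(b) * Conj(stats::fft(a)), inverse = TRUE))
  k <- which.max(cc)
  nr <- nrow(ref); nc <- ncol(ref)
  dr <- (k - 1) %% nr
  dc <- (k - 1) %/% nr
  if (dr > nr / 2) dr <- dr - nr
  if (dc > nc / 2) dc <- dc - nc
  c(row = as.integer(dr), col = as.integer(dc))
}

#' Align all imaging rounds of a field on the MAP2 channel
#'
#' Round 1 is the reference. The translation of every later round is
#' estimated from its MAP2 image by normalized cross-correlation and undone
#' on all channels of that round. Estimated shifts are recorded on the
#' returned field.
#'
#' @param field a `multiplexed_field` in which every round carries a MAP2
#'   channel.
#' @return the aligned `multiplexed_field` (with `$shifts`, a rounds x 2
#'   matrix, and `$aligned = TRUE`).
#' @export
align_rounds <- function(field) {
  m <- field$map
  rounds <- sort(unique(m$round))
  map2 <- m[m$target == "MAP2", ]
  if (!all(rounds %in% map2$round)) {
    stop("round(s) without MAP2 channel: ",
         paste(setdiff(rounds, map2$round), collapse = ", "))
  }
  ref <- field_image(field, "MAP2", round = rounds[1])
  shifts <- matrix(0L, length(rounds), 2,
                   dimnames = list(NULL, c("row", "col")))
  for (i in seq_along(rounds)) {
    rd <- rounds[i]
    if (i > 1L) {
      img <- field_image(field, "MAP2", round = rd)
      s <- tryCatch(estimate_shift(ref, img), error = function(e) {
        stop("alignment failed for round ", rd, ": ", conditionMessage(e))
      })
      shifts[i, ] <- s
    }
    if (any(shifts[i, ] != 0L)) {
      for (j in which(m$round == rd)) {
        key <- sprintf("r%02d_c%d", m$round[j], m$channel[j])
        field$images[[key]] <- shift_int(field$images[[key]],
                                         -shifts[i, 1], -shifts[i, 2])
      }
    }
  }
  field$shifts <- shifts
  field$aligned <- TRUE
  field
}

## Grayscale min/max morphology. EBImage's dilate() is a correct grayscale
## maximum filter, but erode() binarizes its input, so grayscale erosion is
## built from dilation via min-max duality: erode(x) = M - dilate(M - x).
gray_dilate <- function(image, brush) {
  as.matrix(EBImage::dilate(image, brush))
}

gray_erode <- function(image, brush) {
  M <- max(image)
  M - as.matrix(EBImage::dilate(M - image, brush))
}

gray_opening <- function(image, brush) {
  gray_dilate(gray_erode(image, brush), brush)
}

#' Subtract a smooth background estimated by morphological opening
#'
#' The background is the grayscale opening of the image with a large disc;
#' anything too small to contain the disc (puncta, dendrites, but not
#' broad gradients) survives the subtraction. Output is clipped at zero.
#'
#' @param image nonnegative numeric matrix.
#' @param radius disc radius in pixels (default 30; must exceed the largest
#'   foreground structure to be preserved).
#' @return numeric matrix, same shape.
#' @export
correct_illumination <- function(image, radius = 30) {
  bg <- gray_opening(image, EBImage::makeBrush(2 * radius + 1, "disc"))
  pmax(image - bg, 0)
}

#' White top-hat spot enhancement
#'
#' Image minus its morphological opening with a disc: structures larger
#' than the disc are suppressed, diffraction-limited spots are enhanced.
#'
#' @param image numeric matrix.
#' @param se_radius disc radius in pixels (>= 1); default 4.
#' @return nonnegative numeric matrix.
#' @export
white_tophat <- function(image, se_radius = 4) {
  stopifnot(se_radius >= 1)
  pmax(image - gray_opening(image,
                            EBImage::makeBrush(2 * se_radius + 1, "disc")), 0)
}

#' Robust-background threshold averaged over images
#'
#' Per image, the dimmest `trim_lo` and brightest `trim_hi` pixel fractions
#' are discarded and the threshold is mean + `k_sd` x sd of the remaining
#' pixels; the returned value is the mean of the per-image thresholds.
#' By the pipeline contract the images are the untreated group only and the
#' resulting single threshold is applied to all groups, so that every image
#' is segmented identically.
#'
#' @param images list of numeric matrices (or one matrix).
#' @param trim_lo,trim_hi trimmed fractions (defaults 0.05 each).
#' @param k_sd sd multiplier (default 2).
#' @return scalar threshold.
#' @export
robust_background_threshold <- function(images, trim_lo = 0.05,
                                        trim_hi = 0.05, k_sd = 2) {
  if (is.matrix(images)) images <- list(images)
  stopifnot(length(images) >= 1, trim_lo >= 0, trim_hi >= 0,
            trim_lo + trim_hi < 1)
  per <- vapply(images, function(img) {
    x <- sort(as.numeric(img))
    n <- length(x)
    lo <- floor(n * trim_lo)
    hi <- floor(n * trim_hi)
    x <- x[seq.int(lo + 1L, n - hi)]
    if (!length(x)) stop("no pixels left after trimming")
    if (length(x) == 1L) return(x)
    mean(x) + k_sd * stats::sd(x)
  }, numeric(1))
  mean(per)
}

#' 8-connected component labeling
#'
#' @param mask logical matrix.
#' @return integer matrix; background 0, objects labeled 1..K in order of
#'   their first pixel (column-major).
#' @export
label_components8 <- function(mask) {
  idx <- which(mask)
  out <- matrix(0L, nrow(mask), ncol(mask))
  if (!length(idx)) return(out)
  nr <- nrow(mask)
  pos <- integer(length(mask)); pos[idx] <- seq_along(idx)
  r <- (idx - 1L) %% nr + 1L
  c <- (idx - 1L) %/% nr + 1L
  edges <- list()
  k <- 1L
  for (d in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))) {
    r2 <- r + d[1]; c2 <- c + d[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= ncol(mask)
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- mask[nb]
    if (any(hit)) {
      edges[[k]] <- rbind(pos[idx[ok][hit]], pos[nb[hit]])
      k <- k + 1L
    }
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges)) {
    g <- igraph::add_edges(g, as.vector(do.call(cbind, edges)))
  }
  memb <- igraph::components(g)$membership
  relab <- match(memb, unique(memb))  # order of first pixel, column-major
  out[idx] <- relab
  out
}

local_peaks <- function(img, min_distance) {
  brush <- EBImage::makeBrush(2 * min_distance + 1, "disc")
  dil <- as.matrix(EBImage::dilate(img, brush))
  img >= dil & img > 0
}

#' Segment puncta by thresholding and intensity-peak declumping
#'
#' Foreground pixels are those strictly above `threshold` on the enhanced
#' image. Connected regions (8-connectivity) are split into one object per
#' local intensity maximum of the Gaussian-smoothed image, by seeded
#' region growing (seeded watershed on the inverted intensity).
#'
#' @param enhanced numeric matrix (typically top-hat enhanced).
#' @param threshold intensity threshold (>= 0).
#' @param min_peak_distance minimum separation of intensity peaks, pixels
#'   (default 3).
#' @param smooth_sigma Gaussian pre-smoothing before maxima detection
#'   (default 1 px).
#' @param tolerance_k prominence tolerance for declumping, in multiples of
#'   the image's MAD-based noise floor: maxima rising less than this above
#'   the point of contact with a neighbouring object are merged into it.
#'   The default 0.5 absorbs sub-noise maxima (which otherwise dominate
#'   the flooding cost) while splitting at every resolvable real peak;
#'   larger values merge adjacent markers and are rarely appropriate.
#' @return list with `labels` (integer matrix, 0 = background) and `n`
#'   (object count).
#' @export
segment_puncta <- function(enhanced, threshold, min_peak_distance = 3,
                           smooth_sigma = 1, tolerance_k = 0.5) {
  stopifnot(threshold >= 0)
  mask <- enhanced > threshold
  if (!any(mask)) {
    return(list(labels = matrix(0L, nrow(enhanced), ncol(enhanced)), n = 0L))
  }
  sm <- if (smooth_sigma > 0) {
    as.matrix(EBImage::gblur(enhanced, sigma = smooth_sigma))
  } else enhanced
  ## catchment basins are computed on the full smoothed image,
  ## independent of the mask: the threshold only selects which pixels
  ## survive, so raising it can only remove objects (object count
  ## monotone non-increasing in the threshold). Flooding guarantees that
  ## every punctum's pixels drain to the punctum's own intensity maximum.
  ## Maxima whose prominence is within the image's noise floor (MAD-based,
  ## also mask-independent) are merged, so noise bumps on a punctum's
  ## flank do not fragment it; at zero noise the tolerance falls back to
  ## the numerical floor that absorbs FFT ripple of the smoothing.
  noise_sd <- stats::mad(sm)
  tol <- max(tolerance_k * noise_sd, max(sm) * 1e-6) / max(sm)
  ## ext is a chessboard radius: ext = d-1 merges maxima strictly closer
  ## than d pixels (Euclidean) while keeping pairs at d or more apart
  basins <- EBImage::watershed(sm / max(sm), tolerance = tol,
                               ext = max(1, min_peak_distance - 1))
  basins <- matrix(as.integer(basins), nrow(basins), ncol(basins))
  lab <- basins * mask
  relab <- match(lab, sort(unique(lab[lab > 0])))
  out <- matrix(0L, nrow(lab), ncol(lab))
  out[lab > 0] <- relab[lab > 0]
  list(labels = out, n = max(out, 0L))
}

#' Nuclei and dendrite compartment masks
#'
#' Nuclei: Otsu threshold on the smoothed DAPI image, hole filling, removal
#' of small objects. Dendrites: robust-background threshold on MAP2,
#' removal of small objects.
#'
#' @param dapi_image,map2_image aligned numeric matrices.
#' @param nucleus_sigma Gaussian smoothing of DAPI before Otsu (default 2).
#' @param min_nucleus_area,min_dendrite_area smallest retained object, px.
#' @param trim_lo,trim_hi,k_sd robust-background parameters for MAP2.
#' @return list with logical matrices `nuclei` and `dendrite`.
#' @export
segment_compartments <- function(dapi_image, map2_image,
                                 nucleus_sigma = 2,
                                 min_nucleus_area = 60,
                                 min_dendrite_area = 100,
                                 trim_lo = 0.05, trim_hi = 0.05, k_sd = 2) {
  stopifnot(all(dim(dapi_image) == dim(map2_image)))
  nuclei <- matrix(FALSE, nrow(dapi_image), ncol(dapi_image))
  rng <- range(dapi_image)
  if (diff(rng) > 0) {
    sm <- as.matrix(EBImage::gblur(dapi_image, sigma = nucleus_sigma))
    sm01 <- (sm - min(sm)) / (max(sm) - min(sm))
    thr <- EBImage::otsu(EBImage::Image(sm01))
    m <- sm01 > thr
    m <- as.matrix(EBImage::fillHull(m)) > 0
    nuclei <- drop_small_objects(m, min_nucleus_area)
  }
  thr <- robust_background_threshold(list(map2_image), trim_lo, trim_hi, k_sd)
  dm <- map2_image > thr
  dendrite <- drop_small_objects(dm, min_dendrite_area)
  list(nuclei = nuclei, dendrite = dendrite)
}

drop_small_objects <- function(mask, min_area) {
  if (!any(mask)) return(mask)
  lab <- label_components8(mask)
  sz <- tabulate(lab[lab > 0])
  keep <- which(sz >= min_area)
  matrix(lab %in% keep, nrow(mask)) & mask
}

#' Aligned per-target images of a field
#'
#' @param field an aligned `multiplexed_field`.
#' @return named list of matrices, one per target (first round carrying the
#'   target).
#' @export
target_images <- function(field) {
  tg <- unique(field$map$target)
  out <- lapply(tg, function(t) field_image(field, t))
  names(out) <- tg
  out
}
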