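test_that("integer shifts are recovered exactly over the full range", {
  cfg <- small_config(seed = 3, shift_range_px = 4L)
  gf <- generate_field(cfg, "UT1", 1)
  ref <- field_image(gf$field, "MAP2", round = 1)
  ## exhaustive sweep of every |shift| <= shift_range
  for (dr in -4:4) {
    for (dc in -4:4) {
      est <- estimate_shift(ref, synaptopipe:::shift_int(ref, dr, dc))
      expect_identical(unname(est), c(dr, dc))
    }
  }
})

test_that("align_rounds undoes the generator's per-round shifts", {
  cfg <- small_config(seed = 6, shift_range_px = 3L)
  gf <- generate_field(cfg, "UT1", 1)
  aligned <- align_rounds(gf$field)
  expect_identical(unname(aligned$shifts), unname(gf$truth$shifts))
  expect_true(aligned$aligned)
  ## zero injected shift -> zero estimates
  cfg0 <- small_config(seed = 6, shift_range_px = 0L)
  gf0 <- generate_field(cfg0, "UT1", 1)
  expect_true(all(align_rounds(gf0$field)$shifts == 0L))
})

test_that("featureless reference image fails alignment with round named", {
  f <- processed_small_field()$gf$field
  key <- "r02_c1"  # MAP2 of round 2
  f$images[[key]] <- matrix(7, nrow(f$images[[key]]), ncol(f$images[[key]]))
  expect_error(align_rounds(f), "round 2")
})

test_that("illumination correction removes flat/gradient background", {
  expect_equal(max(abs(correct_illumination(matrix(5, 80, 80)))), 0)
  ## a pure linear gradient much broader than the kernel: residual (a
  ## border-strip effect of width = disc radius) stays under 10% of the
  ## gradient amplitude
  ramp <- outer(seq(0, 10, length.out = 400), rep(1, 60))
  expect_lt(max(correct_illumination(ramp + 100)), 0.1 * 10)
  ## an isolated Gaussian spot survives within 5% integrated intensity
  img <- matrix(20, 120, 120)
  spot <- matrix(0, 120, 120)
  spot <- synaptopipe:::stamp_gaussian(spot, 60, 60, 2, 5000)
  out <- correct_illumination(img + spot)
  expect_equal(sum(out), 5000, tolerance = 0.05)
})

test_that("white top-hat obeys its morphological contracts", {
  expect_equal(max(abs(white_tophat(matrix(3, 50, 50)))), 0)
  ## bright disk smaller than the element is retained at full contrast
  img <- matrix(10, 60, 60)
  dsk <- disk_region(3, c(30, 30))
  img[dsk + 1] <- 50
  th <- white_tophat(img, se_radius = 5)
  expect_equal(max(th), 40)
  expect_equal(sum(th > 35), nrow(dsk))
  ## plateau larger than the element is suppressed in its interior
  img2 <- matrix(10, 80, 80)
  big <- disk_region(12, c(40, 40))
  img2[big + 1] <- 50
  th2 <- white_tophat(img2, se_radius = 5)
  expect_lt(th2[41, 41], 1e-9)
  ## tophat <= input, nonnegative
  x <- processed_small_field()$proc$corrected[["Synapsin1"]]
  w <- white_tophat(x)
  expect_true(all(w <= x + 1e-9))
  expect_true(all(w >= 0))
})

test_that("robust background threshold matches the trimmed-moment oracle", {
  ## constant image: threshold = c for any k (sd = 0)
  expect_equal(robust_background_threshold(matrix(7, 10, 10), k_sd = 2), 7)
  ## uniform pixel sets, trim 5%/5%, k = 2: brute-force agreement
  i1 <- matrix(0:99, 10, 10)
  i2 <- matrix(0:199, 20, 10)
  got <- robust_background_threshold(list(i1, i2), 0.05, 0.05, 2)
  want <- mean(c(oracle_robust_threshold(i1, 0.05, 0.05, 2),
                 oracle_robust_threshold(i2, 0.05, 0.05, 2)))
  expect_equal(got, want, tolerance = 1e-9)
  ## no trimming, k = 0: mean of image means
  expect_equal(robust_background_threshold(list(i1, i2), 0, 0, 0),
               mean(c(mean(i1), mean(i2))))
  ## random images against the oracle
  set.seed(1)
  imgs <- replicate(5, matrix(rgamma(400, 2, 0.1), 20, 20), simplify = FALSE)
  expect_equal(robust_background_threshold(imgs, 0.1, 0.02, 1.5),
               mean(vapply(imgs, oracle_robust_threshold, numeric(1),
                           0.1, 0.02, 1.5)),
               tolerance = 1e-9)
  expect_error(robust_background_threshold(list(i1), 0.5, 0.5, 2))
})

test_that("puncta segmentation thresholds, declumps and stays monotone", {
  empty <- segment_puncta(matrix(1, 30, 30), threshold = 5)
  expect_equal(empty$n, 0)
  ## two well-separated spots -> two objects with accurate centroids
  img <- matrix(0, 60, 60)
  img <- synaptopipe:::stamp_gaussian(img, 20, 20, 1.5, 3000)
  img <- synaptopipe:::stamp_gaussian(img, 40, 45, 1.5, 3000)
  seg <- segment_puncta(img, threshold = 5)
  expect_equal(seg$n, 2)
  pp <- puncta_from_labels(seg$labels, "Synapsin1")
  cen <- pp[order(pp$centroid_r), c("centroid_r", "centroid_c")]
  expect_lt(max(abs(unlist(cen) - c(19, 39, 19, 44))), 1)
  ## two overlapping spots with peaks >= min_peak_distance apart -> split
  img2 <- matrix(0, 40, 40)
  img2 <- synaptopipe:::stamp_gaussian(img2, 20, 18, 1.2, 3000)
  img2 <- synaptopipe:::stamp_gaussian(img2, 20, 23, 1.2, 3000)
  expect_equal(segment_puncta(img2, 5, min_peak_distance = 3)$n, 2)
  ## object count is monotone non-increasing in the threshold
  enh <- processed_small_field()$proc$enhanced[["Synapsin1"]]
  thr0 <- robust_background_threshold(list(enh))
  counts <- vapply(thr0 * c(0.5, 1, 2, 4, 8), function(th)
    segment_puncta(enh, th)$n, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("compartment masks behave on blank, single-nucleus and real input", {
  blank <- segment_compartments(matrix(0, 64, 64), matrix(5, 64, 64))
  expect_false(any(blank$nuclei))
  ## one rendered nucleus -> one connected nuclear component
  dapi <- matrix(0, 100, 100)
  dsk <- disk_region(10, c(50, 50))
  dapi[dsk + 1] <- 200
  comp1 <- segment_compartments(dapi, matrix(5, 100, 100))
  expect_equal(max(label_components8(comp1$nuclei)), 1)
  ## generated field: dendrite mask overlaps the rendered footprint
  psf <- processed_small_field()
  comp <- segment_compartments(psf$proc$corrected[["DAPI"]],
                               psf$proc$corrected[["MAP2"]])
  truth_mask <- psf$gf$truth$dendrite_mask
  jac <- sum(comp$dendrite & truth_mask) / sum(comp$dendrite | truth_mask)
  expect_gte(jac, 0.7)
})

test_that("component labeling is 8-connected with contiguous labels", {
  m <- matrix(FALSE, 8, 8)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE  # diagonal touch: one object
  m[6, 6] <- TRUE                   # separate object
  lab <- label_components8(m)
  expect_equal(max(lab), 2)
  expect_equal(lab[2, 2], lab[3, 3])
  expect_true(all(sort(unique(lab[lab > 0])) == 1:2))
})
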