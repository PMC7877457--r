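test_that("intensity and basic shape features match pixel-loop oracles", {
  set.seed(101)
  dim <- c(40L, 40L)
  img <- matrix(rgamma(prod(dim), 2, 0.05), dim[1], dim[2])
  for (i in 1:250) {
    rc <- random_region(sample(3:25, 1))
    pun <- region_to_punctum(rc, dim)
    want <- oracle_region_stats(rc, img[rc + 1])
    fx <- intensity_features(pun$pixels, img)
    expect_equal(fx$IntegratedIntensity, want$integrated, tolerance = 1e-9)
    expect_equal(fx$MaxIntensity, want$max, tolerance = 1e-9)
    expect_equal(fx$MinIntensity, want$min, tolerance = 1e-9)
    expect_equal(fx$StdIntensity, want$std, tolerance = 1e-9)
    expect_equal(fx$MADIntensity, want$mad, tolerance = 1e-9)
    expect_equal(fx$LowerQuartileIntensity, want$q25, tolerance = 1e-9)
    expect_equal(fx$UpperQuartileIntensity, want$q75, tolerance = 1e-9)
    expect_equal(fx$IntegratedIntensityEdge, want$integrated_edge,
                 tolerance = 1e-9)
    expect_equal(fx$MinIntensityEdge, want$min_edge, tolerance = 1e-9)
    expect_equal(fx$StdIntensityEdge, want$std_edge, tolerance = 1e-9)
    expect_equal(fx$MassDisplacement, want$mass_displacement,
                 tolerance = 1e-9)
    sf <- shape_features(pun, dim)
    expect_equal(sf$Area, want$area)
    expect_equal(sf$EquivalentDiameter, want$eq_diameter, tolerance = 1e-9)
    expect_equal(sf$Extent, want$extent, tolerance = 1e-9)
    expect_equal(sf$Compactness, want$compactness, tolerance = 1e-9)
    expect_equal(sf$MeanRadius, want$mean_radius, tolerance = 1e-9)
    expect_equal(sf$MaximumRadius, want$max_radius, tolerance = 1e-9)
    mo <- oracle_moments(rc)
    expect_equal(sf$MajorAxisLength, mo$major, tolerance = 1e-9)
    expect_equal(sf$MinorAxisLength, mo$minor, tolerance = 1e-9)
    expect_equal(sf$Eccentricity, mo$ecc, tolerance = 1e-9)
    expect_equal(sf$Orientation, mo$orientation, tolerance = 1e-9)
  }
})

test_that("shape features on canonical geometries", {
  dim <- c(40L, 40L)
  ## 1 x 10 line
  line <- cbind(10, 5:14)
  sf <- shape_features(region_to_punctum(line, dim), dim)
  expect_equal(sf$Extent, 1)
  expect_lt(sf$MinorAxisLength, sf$MajorAxisLength / 5)
  expect_equal(sf$EulerNumber, 1)
  expect_lt(sf$Eccentricity, 1)
  ## digital disk radius 5 (81 px)
  dsk <- disk_region(5, c(20, 20))
  expect_equal(nrow(dsk), 81)
  sfd <- shape_features(region_to_punctum(dsk, dim), dim)
  expect_equal(sfd$Solidity, 1, tolerance = 0.05)
  expect_lte(sfd$Eccentricity, 0.2)
  expect_lt(abs(sfd$FormFactor - 1), 0.15)
  ## 3 x 3 square with the center removed: one hole
  ring <- as.matrix(expand.grid(r = 10:12, c = 10:12))
  ring <- ring[!(ring[, 1] == 11 & ring[, 2] == 11), ]
  expect_equal(shape_features(region_to_punctum(ring, dim), dim)$EulerNumber,
               0)
})

test_that("form factor of rasterized disks approaches 1 with radius", {
  dim <- c(100L, 100L)
  err <- vapply(c(5, 10, 20), function(r) {
    sf <- shape_features(region_to_punctum(disk_region(r, c(50, 50)), dim),
                         dim)
    abs(sf$FormFactor - 1)
  }, numeric(1))
  expect_true(all(diff(err) < 0))
  expect_lt(err[3], 0.05)
})

test_that("intensity features on hand-computable regions", {
  dim <- c(20L, 20L)
  ## uniform region: no dispersion, no mass displacement
  rc <- as.matrix(expand.grid(r = 5:8, c = 5:8))
  img <- matrix(0, dim[1], dim[2]); img[rc + 1] <- 7
  fx <- intensity_features(region_to_punctum(rc, dim)$pixels, img)
  expect_equal(fx$MassDisplacement, 0)
  expect_equal(fx$StdIntensity, 0)
  expect_equal(fx$MADIntensity, 0)
  ## two pixels {1, 3}
  rc2 <- cbind(c(5, 5), c(5, 6))
  img2 <- matrix(0, dim[1], dim[2]); img2[rc2 + 1] <- c(1, 3)
  fx2 <- intensity_features(region_to_punctum(rc2, dim)$pixels, img2)
  expect_equal(fx2$IntegratedIntensity, 4)
  expect_equal(fx2$MADIntensity, 1)
  expect_equal(fx2$LowerQuartileIntensity, 1.5)
  expect_equal(fx2$UpperQuartileIntensity, 2.5)
  ## all intensity in one corner: displacement = corner-to-centroid distance
  rc3 <- as.matrix(expand.grid(r = 5:7, c = 5:7))
  img3 <- matrix(0, dim[1], dim[2]); img3[6, 6] <- 10   # 0-based (5, 5)
  fx3 <- intensity_features(region_to_punctum(rc3, dim)$pixels, img3)
  expect_equal(fx3$MassDisplacement, sqrt(2), tolerance = 1e-12)
  ## integrated intensity is additive under region partition
  set.seed(3)
  imgr <- matrix(runif(prod(dim)), dim[1], dim[2])
  whole <- random_region(20, dim[1], dim[2])
  part1 <- whole[1:8, , drop = FALSE]
  part2 <- whole[9:20, , drop = FALSE]
  s <- function(rc) intensity_features(region_to_punctum(rc, dim)$pixels,
                                       imgr)$IntegratedIntensity
  expect_equal(s(whole), s(part1) + s(part2), tolerance = 1e-12)
  ## region outside the image errors
  expect_error(intensity_features(c(1L, 100000L), img), "outside")
})

test_that("relational features measure counts and distances per target", {
  dim <- c(64L, 64L)
  anchor <- disk_region(4, c(30, 30))
  childA <- disk_region(2, c(33, 34))       # centroid (33, 34): d = 5
  childB <- disk_region(1, c(30, 30))       # centroid inside anchor
  puncta <- make_puncta(list(anchor, childA, childB),
                        c("Synapsin1", "PSD95", "SHANK3"), dim)
  nuc <- matrix(FALSE, dim[1], dim[2]); den <- matrix(TRUE, dim[1], dim[2])
  asm <- assemble_synapses(puncta, nuc, den,
                           targets = c("Synapsin1", "PSD95", "SHANK3",
                                       "vGAT"))
  images <- list(Synapsin1 = matrix(1, dim[1], dim[2]),
                 PSD95 = matrix(2, dim[1], dim[2]),
                 SHANK3 = matrix(3, dim[1], dim[2]),
                 vGAT = matrix(4, dim[1], dim[2]))
  rel <- relational_features(asm$synapses[1, ], puncta, images)
  expect_equal(rel$PunctaNumber__Synapsin1__PSD95, 1)
  expect_equal(rel$DistanceCentroid__PSD95__PSD95, 5)
  expect_equal(rel$DistanceMinimum__SHANK3__SHANK3, 0)
  expect_equal(rel$IntegratedIntensity__PSD95__PSD95,
               2 * nrow(childA))
  ## a target with no child: zero count/intensity, NA distances
  expect_equal(rel$PunctaNumber__Synapsin1__vGAT, 0)
  expect_equal(rel$IntegratedIntensity__vGAT__vGAT, 0)
  expect_true(is.na(rel$DistanceCentroid__vGAT__vGAT))
})

test_that("the published feature set is selected exactly in reduced mode", {
  pfs <- reduced_feature_set()
  expect_equal(nrow(pfs), 107)
  expect_false(anyDuplicated(pfs$column) > 0)
  psf <- processed_small_field()
  comp <- segment_compartments(psf$proc$corrected[["DAPI"]],
                               psf$proc$corrected[["MAP2"]])
  res <- segment_and_assemble(psf$proc, psf$thr)
  feats <- cbind(data.frame(replicate = "UT1", treatment = "untreated",
                            field = 1L), res$features)
  tab <- build_feature_table(feats, mode = "reduced")
  kept <- setdiff(names(tab), c("replicate", "treatment", "field",
                                "anchor_id", "class"))
  dropped <- attr(tab, "dropped_columns")
  expect_setequal(c(kept, dropped), pfs$column)
  ## dropped columns are exactly the all-NA ones (absent-target distances)
  expect_true(all(grepl("^Distance", dropped)))
  ## zero synapses: empty table with the full header
  empty <- feats[0, , drop = FALSE]
  tab0 <- build_feature_table(empty, mode = "reduced")
  expect_equal(nrow(tab0), 0)
  expect_true(all(pfs$column %in% names(tab0)))
})

test_that("normalization to the untreated mean behaves and is idempotent", {
  t0 <- data.frame(
    replicate = rep(c("UT1", "UT2", "TTX1"), each = 4),
    treatment = rep(c("untreated", "untreated", "treated"), each = 4),
    class = "excitatory",
    IntegratedIntensity__Synapsin1__vGAT = c(1, 2, 3, 4, 2, 3, 4, 5,
                                             6, 6, 6, 6),
    Perimeter__Synapsin1__Synapsin1 = 10,
    check.names = FALSE
  )
  n1 <- normalize_to_untreated(t0)
  ut <- n1$treatment == "untreated"
  expect_equal(mean(n1$IntegratedIntensity__Synapsin1__vGAT[ut]), 1)
  expect_equal(unique(n1$IntegratedIntensity__Synapsin1__vGAT[!ut]), 2)
  ## shape columns untouched
  expect_equal(unique(n1$Perimeter__Synapsin1__Synapsin1), 10)
  ## idempotence
  n2 <- normalize_to_untreated(n1)
  expect_equal(n2, n1, tolerance = 1e-12)
  ## zero untreated mean names the column
  t0$IntegratedIntensity__Synapsin1__vGAT[t0$treatment == "untreated"] <- 0
  expect_error(normalize_to_untreated(t0), "vGAT")
})
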