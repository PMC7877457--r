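test_that("overlap fraction is child-normalized with exact boundaries", {
  dim <- c(64L, 64L)
  anchor <- rect_region(10, 19, 10, 19)             # 100 px
  child16 <- rect_region(19, 22, 19, 22)            # 16 px, 1 px shared
  p <- make_puncta(list(anchor, child16), c("Synapsin1", "PSD95"), dim)
  expect_equal(overlap_fraction(p[2, ], p[1, ]), 1 / 16)
  ## disjoint and nested
  far <- rect_region(40, 43, 40, 43)
  inside <- rect_region(12, 13, 12, 13)
  p2 <- make_puncta(list(anchor, far, inside),
                    c("Synapsin1", "PSD95", "PSD95"), dim)
  expect_equal(overlap_fraction(p2[2, ], p2[1, ]), 0)
  expect_equal(overlap_fraction(p2[3, ], p2[1, ]), 1)
  expect_error(overlap_fraction(list(pixels = integer()), p2[1, ]), "empty")
})

test_that("size filter keeps equivalent diameters in [3, 15] inclusive", {
  areas <- c(7L, 78L, 177L)   # diameters 2.99, 9.97, 15.01
  regions <- lapply(areas, function(a) {
    g <- disk_region(8, c(20, 20))
    g[seq_len(a), , drop = FALSE]
  })
  p <- make_puncta(regions, rep("Synapsin1", 3), c(64L, 64L))
  kept <- size_filter(p)
  expect_equal(kept$area, 78L)
  ## boundary areas: d exactly >= 3 at area 8 (d = 3.19); area 176 keeps
  ## d = 14.97
  p2 <- make_puncta(lapply(c(8L, 176L), function(a)
    disk_region(9, c(20, 20))[seq_len(a), , drop = FALSE]),
    rep("Synapsin1", 2), c(64L, 64L))
  expect_equal(nrow(size_filter(p2)), 2)
  expect_error(size_filter(p, d_min = 10, d_max = 3), "d_min")
})

test_that("assembly applies the overlap rules with inclusive thresholds", {
  dim <- c(220L, 220L)
  nuc <- matrix(FALSE, dim[1], dim[2])
  den <- matrix(TRUE, dim[1], dim[2])
  ## postsynaptic: child of 10000 px sharing 624 px -> 0.0624 rejected;
  ## sharing 625 px -> 0.0625 assigned
  anchor <- rect_region(100, 147, 95, 107)          # 48 x 13 = 624 in child
  child <- rect_region(48, 147, 50, 149)            # 100 x 100 = 10000 px
  p <- make_puncta(list(anchor, child), c("Synapsin1", "PSD95"), dim)
  ov <- overlap_fraction(p[2, ], p[1, ])
  expect_equal(ov, 0.0624)
  asm <- assemble_synapses(p, nuc, den)
  expect_equal(asm$assignments$status[2], "below_overlap_threshold")
  anchor2 <- rbind(anchor, c(100, 108))             # 625 shared px
  p2 <- make_puncta(list(anchor2, child), c("Synapsin1", "PSD95"), dim)
  expect_equal(overlap_fraction(p2[2, ], p2[1, ]), 0.0625)
  asm2 <- assemble_synapses(p2, nuc, den)
  expect_equal(asm2$assignments$status[2], "assigned")
  ## presynaptic: 49/100 rejected, 50/100 assigned
  childp <- rect_region(100, 109, 98, 107)          # 100 px
  anchor49 <- rect_region(100, 106, 101, 107)       # 7 x 7 = 49 shared
  p3 <- make_puncta(list(anchor49, childp), c("Synapsin1", "vGlut1"), dim)
  expect_equal(overlap_fraction(p3[2, ], p3[1, ]), 0.49)
  expect_equal(assemble_synapses(p3, nuc, den)$assignments$status[2],
               "below_overlap_threshold")
  anchor50 <- rect_region(100, 109, 103, 107)       # 10 x 5 = 50 shared
  p4 <- make_puncta(list(anchor50, childp), c("Synapsin1", "vGlut1"), dim)
  expect_equal(overlap_fraction(p4[2, ], p4[1, ]), 0.50)
  expect_equal(assemble_synapses(p4, nuc, den)$assignments$status[2],
               "assigned")
})

test_that("location rules: nuclei exclusion and 8-px dendrite proximity", {
  dim <- c(64L, 64L)
  nuc <- matrix(FALSE, dim[1], dim[2])
  den <- matrix(FALSE, dim[1], dim[2])
  den[32, ] <- TRUE                                  # horizontal dendrite
  ## single-pixel anchors at distances 8 and 9 from the dendrite row
  a8 <- matrix(c(32 + 8 - 1, 20), 1, 2)              # 0-based row 39 -> dist 8
  a9 <- matrix(c(32 + 9 - 1, 40), 1, 2)              # dist 9
  p <- make_puncta(list(a8, a9), c("Synapsin1", "Synapsin1"), dim)
  asm <- assemble_synapses(p, nuc, den)
  expect_equal(nrow(asm$synapses), 1)
  expect_equal(asm$assignments$status, c("assigned", "off_dendrite"))
  ## anchor touching a nucleus is excluded
  nuc2 <- nuc; nuc2[39:41, 19:21] <- TRUE
  asm2 <- assemble_synapses(p, nuc2, den)
  expect_equal(asm2$assignments$status[1], "in_nuclei")
  ## missing synapsin channel errors
  pc <- make_puncta(list(a8), "PSD95", dim)
  expect_error(assemble_synapses(pc, nuc, den), "synapsin1")
})

test_that("classification follows the marker taxonomy", {
  expect_equal(classify_synapse(list(children = list(vGlut1 = 1L))),
               "excitatory")
  expect_equal(classify_synapse(list(children = list(vGAT = 2L))),
               "inhibitory")
  expect_equal(classify_synapse(list(children = list(vGlut1 = 1L,
                                                     vGAT = 2L))), "dual")
  expect_equal(classify_synapse(list(children = list(PSD95 = 3L))),
               "unknown")
})

test_that("assignments match a brute-force all-pairs oracle on a field", {
  psf <- processed_small_field()
  comp <- segment_compartments(psf$proc$corrected[["DAPI"]],
                               psf$proc$corrected[["MAP2"]])
  puncta <- list(); offset <- 0L
  for (t in names(psf$proc$enhanced)) {
    seg <- segment_puncta(psf$proc$enhanced[[t]], psf$thr[[t]])
    pp <- puncta_from_labels(seg$labels, t, id_offset = offset)
    offset <- offset + max(0L, seg$n)
    puncta[[t]] <- pp
  }
  puncta <- size_filter(do.call(rbind, unname(puncta)))
  asm <- assemble_synapses(puncta, comp$nuclei, comp$dendrite)
  ## oracle: for every child that passed location rules, recompute all
  ## overlap fractions against all anchors directly
  a <- asm$assignments
  anchors <- puncta[puncta$role == "anchor" &
                      a$status[match(puncta$id, a$id)] != "in_nuclei" &
                      a$status[match(puncta$id, a$id)] != "off_dendrite", ]
  for (i in which(puncta$role != "anchor")) {
    st <- a$status[a$id == puncta$id[i]]
    if (st %in% c("in_nuclei", "off_dendrite")) next
    fr <- vapply(seq_len(nrow(anchors)), function(k)
      overlap_fraction(puncta[i, ], anchors[k, ]), numeric(1))
    if (!length(fr) || max(fr) == 0) {
      expect_equal(st, "no_anchor_overlap")
      next
    }
    best <- which(fr == max(fr))
    best <- best[which.min(anchors$id[best])]
    thr <- if (puncta$role[i] == "presynaptic") 0.5 else 0.0625
    if (max(fr) >= thr) {
      expect_equal(st, "assigned")
      expect_equal(a$anchor_id[a$id == puncta$id[i]], anchors$id[best])
    } else {
      expect_equal(st, "below_overlap_threshold")
    }
  }
  ## class labels partition the anchors
  expect_equal(sum(table(asm$synapses$class)), nrow(asm$synapses))
  ## determinism: repeated assembly agrees exactly
  asm2 <- assemble_synapses(puncta, comp$nuclei, comp$dendrite)
  expect_identical(asm$assignments, asm2$assignments)
  expect_identical(asm$synapses$class, asm2$synapses$class)
})

test_that("resolvable-regime recovery and classification are near-perfect", {
  ## sparse, well-separated, noise-free synapses: the pipeline must find
  ## nearly all of them within 2 px and classify them correctly
  rec <- c(); acc <- c()
  cfg <- resolvable_config(seed = 11)
  for (fi in 1:4) {
    gf <- generate_field(cfg, "UT1", fi)
    proc <- process_field(gf$field)
    thr <- vapply(proc$enhanced, function(e)
      robust_background_threshold(list(e)), numeric(1))
    res <- segment_and_assemble(proc, thr, pixel_size_um = cfg$pixel_size_um)
    tr <- gf$truth$synapses
    d2 <- outer(tr$row, res$synapses$centroid_r, "-")^2 +
      outer(tr$col, res$synapses$centroid_c, "-")^2
    nn <- apply(d2, 1, which.min)
    ok <- apply(d2, 1, min) <= 4
    rec <- c(rec, ok)
    acc <- c(acc, res$synapses$class[nn[ok]] == tr$class[ok])
  }
  expect_gte(mean(rec), 0.95)
  expect_gte(mean(acc), 0.95)
})
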