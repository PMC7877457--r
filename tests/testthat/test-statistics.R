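test_that("permutation t test is exact by enumeration for small designs", {
  ## identical groups: zero difference, p = 1
  r0 <- permutation_t_test(c(1, 2, 3), c(1, 2, 3), seed = 1)
  expect_equal(r0$observed, 0)
  expect_equal(r0$p, 1)
  ## separated groups: p equals the exhaustive enumeration over C(6,3)
  a <- c(10, 11, 12); b <- c(0, 1, 2)
  r <- permutation_t_test(a, b, seed = 1)
  expect_true(r$exact)
  expect_equal(r$p, oracle_perm_p(a, b))
  expect_equal(r$p, 2 / 20)
  ## default 6-vs-5 design is enumerated exactly (C(11,5) = 462 <= 5000)
  set.seed(2)
  a6 <- rnorm(6); b5 <- rnorm(5, 1)
  r2 <- permutation_t_test(a6, b5, seed = 1)
  expect_true(r2$exact)
  expect_equal(r2$p, oracle_perm_p(a6, b5))
  ## the two-tailed p is symmetric in the group order, and invariant to
  ## the within-group ordering of values (exchangeability of the pool)
  r3 <- permutation_t_test(b5, a6, seed = 1)
  expect_equal(r3$p, r2$p)
  r4 <- permutation_t_test(rev(a6), sample(b5), seed = 1)
  expect_equal(r4$p, r2$p)
  ## degenerate input warns and returns p = 1
  expect_warning(rd <- permutation_t_test(c(2, 2), c(2, 2)), "identical")
  expect_equal(rd$p, 1)
  ## CI brackets the observed difference
  expect_true(r2$ci[1] <= r2$observed && r2$observed <= r2$ci[2])
})

test_that("Cohen's d uses the pooled standard deviation", {
  expect_equal(cohens_d(c(1, 2), c(1, 2)), 0)
  expect_equal(cohens_d(c(0, 2), c(2, 4)), -2 / sqrt(2), tolerance = 1e-12)
  set.seed(3)
  a <- rnorm(6); b <- rnorm(5)
  expect_equal(cohens_d(a, b), -cohens_d(b, a))
  expect_error(cohens_d(c(1, 1), c(1, 1)), "zero")
})

test_that("BCa interval reduces to percentile under a symmetric null", {
  expect_warning(ci0 <- bca_ci(rep(5, 8), mean, n_boot = 200, seed = 1),
                 "degenerate")
  expect_equal(ci0, c(5, 5))
  ## symmetric data, mean statistic: BCa ~ percentile within MC error
  set.seed(4)
  x <- rnorm(40)
  bca <- bca_ci(x, mean, n_boot = 4000, seed = 9)
  pct <- oracle_percentile_ci(x, mean, n_boot = 4000, seed = 9)
  expect_lt(max(abs(bca - pct)), 0.1 * stats::sd(x))
  ## agreement with the reference implementation on the same data
  if (requireNamespace("boot", quietly = TRUE)) {
    set.seed(11)
    bo <- boot::boot(x, function(d, i) mean(d[i]), R = 4000)
    ref <- boot::boot.ci(bo, type = "bca")$bca[4:5]
    expect_lt(max(abs(bca - ref)), 0.15 * stats::sd(x))
  }
  ## two-sample form runs and brackets the estimate for a clear effect
  set.seed(5)
  g1 <- rnorm(6, 2); g2 <- rnorm(5)
  dd <- cohens_d(g1, g2)
  ci <- bca_ci(list(g1, g2), cohens_d, n_boot = 1000, seed = 2)
  expect_true(ci[1] <= dd && dd <= ci[2])
})

test_that("BCa coverage of the normal mean is near nominal", {
  set.seed(6)
  hits <- vapply(1:400, function(i) {
    x <- rnorm(20)
    ci <- bca_ci(x, mean, n_boot = 400, seed = i)
    ci[1] <= 0 && 0 <= ci[2]
  }, logical(1))
  expect_gte(mean(hits), 0.90)
  expect_lte(mean(hits), 0.98)
})

test_that("power of the unequal-n t test matches quadrature", {
  expect_equal(power_t2n(0, 6, 5), 0.05, tolerance = 1e-12)
  expect_gt(power_t2n(10, 6, 5), 0.999)
  expect_equal(power_t2n(1, 6, 5), oracle_power_t2n(1, 6, 5),
               tolerance = 1e-4)
  expect_equal(power_t2n(-1.7, 8, 4), oracle_power_t2n(-1.7, 8, 4),
               tolerance = 1e-4)
  ## more samples, more power
  expect_gt(power_t2n(1, 12, 10), power_t2n(1, 6, 5))
})

test_that("per-cluster correlation matrices average, mask and order", {
  set.seed(7)
  n <- 120
  tab <- data.frame(replicate = rep(c("UT1", "UT2", "UT3"), each = n / 3))
  base <- rnorm(n)
  tab$IntegratedIntensity__Synapsin1__Synapsin1 <- exp(base)
  tab$IntegratedIntensity__Synapsin1__vGlut1 <- 2 * exp(base)   # proportional
  tab$IntegratedIntensity__Synapsin1__Gephyrin <- exp(rnorm(n)) # independent
  cs <- cluster_correlation_matrices(tab, rep(1L, n), mask_bound = 0.4)
  m <- cs[["1"]]
  expect_equal(m$n_replicates, 3)
  expect_equal(unname(diag(m$average)), rep(1, 3))
  expect_false(anyNA(diag(m$masked)))
  expect_equal(m$average["Synapsin1", "vGlut1"], 1, tolerance = 1e-9)
  expect_false(is.na(m$masked["Synapsin1", "vGlut1"]))
  ## independent target: weak correlation masked
  expect_true(is.na(m$masked["Synapsin1", "Gephyrin"]))
  expect_length(m$order, 3)
})

test_that("synapse density uses the skeleton path length", {
  ## straight dendrite of 107 px at 0.187 um/px -> 20.009 um
  mask <- matrix(FALSE, 20, 120)
  mask[10, 5:111] <- TRUE
  syn <- data.frame(class = rep(c("excitatory", "inhibitory"), c(8, 2)))
  d <- synapse_density(syn, mask, pixel_size_um = 0.187)
  expect_equal(d$dendrite_length_um[1], 107 * 0.187, tolerance = 1e-9)
  expect_equal(d$density_per_100um[d$scope == "all"], 100 * 10 / 20.009,
               tolerance = 1e-3)
  expect_equal(d$density_per_100um[d$scope == "excitatory"],
               100 * 8 / 20.009, tolerance = 1e-3)
  ## 10 synapses on 20 um -> 50 per 100 um
  mask2 <- matrix(FALSE, 20, 120)
  mask2[10, 5:(5 + round(20 / 0.187) - 1)] <- TRUE
  d2 <- synapse_density(syn, mask2, pixel_size_um = 0.187)
  expect_equal(d2$density_per_100um[1], 50, tolerance = 0.01)
  ## tiling invariance: two half-fields preserve total length exactly
  left <- mask[, 1:60]; right <- mask[, 61:120]
  len <- function(m) synapse_density(syn[1, , drop = FALSE], m,
                                     0.187)$dendrite_length_um[1]
  expect_equal(len(left) + len(right), d$dendrite_length_um[1],
               tolerance = 1e-9)
  expect_error(synapse_density(syn, matrix(FALSE, 5, 5)), "empty")
  ## generator field at default geometry: measured skeleton length within
  ## 10% of the true walk length (small crowded fields self-overlap and
  ## are genuinely under-measured, so the default 256-px field is used)
  cfg <- synth_config(seed = 42)
  gf <- generate_field(cfg, "UT1", 1)
  proc <- process_field(gf$field)
  comp <- segment_compartments(proc$corrected[["DAPI"]],
                               proc$corrected[["MAP2"]])
  dmeas <- synapse_density(syn, comp$dendrite,
                           pixel_size_um = cfg$pixel_size_um)
  expect_equal(dmeas$dendrite_length_um[1],
               gf$truth$field$dendrite_length_um, tolerance = 0.1)
})

test_that("condition comparison runs the full battery per target and scope", {
  set.seed(8)
  cfg <- synth_config(seed = 51, fields_per_replicate = 1L,
                      treatment_effects = c(vGAT = 1.6))
  sim <- simulate_cohort_truth(cfg)
  ft <- normalize_to_untreated(ground_truth_features(sim$truth,
                                                     measurement_sd = 0.05))
  res <- compare_conditions(ft, n_shuffles = 1000, n_boot = 400, seed = 3)
  expect_setequal(unique(res$scope), c("excitatory", "inhibitory"))
  expect_equal(nrow(res), 2 * length(synaptic_targets()))
  expect_true(all(res$p >= 0 & res$p <= 1))
  ok <- !is.na(res$cohens_d)   # markers absent from a scope yield NA d
  expect_true(all(res$d_ci_lo[ok] <= res$cohens_d[ok] + 1e-9 &
                    res$cohens_d[ok] <= res$d_ci_hi[ok] + 1e-9))
  expect_true(all(c("power", "p_bh") %in% names(res)))
  ## the injected inhibitory-marker effect is detected where it acts
  hit <- res[res$target == "vGAT" & res$scope == "inhibitory", ]
  expect_lt(hit$p, 0.05)
  expect_lt(hit$cohens_d, 0)  # untreated minus treated is negative
})
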