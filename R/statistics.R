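## Replicate-level statistics: permutation t tests (exact by enumeration
## whenever feasible), Cohen's d with BCa bootstrap intervals, power for
## unequal group sizes, per-cluster correlation structure, and synapse
## densities per dendrite length.

#' Two-tailed permutation t test on replicate means
#'
#' The observed statistic is `mean(a) - mean(b)`. Group labels are
#' reshuffled and the p value is the fraction of relabelings whose
#' absolute mean difference is at least the observed one. When the number
#' of distinct relabelings `choose(n1+n2, n1)` does not exceed
#' `n_shuffles`, all of them are enumerated and the p value is exact;
#' otherwise `n_shuffles` random relabelings are drawn and the identity
#' relabeling is included in numerator and denominator, so p is never 0.
#' The confidence interval on the difference comes from a percentile
#' bootstrap (resampling replicates within each group).
#'
#' @param a,b numeric vectors of replicate means (each length >= 2).
#' @param n_shuffles reshuffle budget (default 5000).
#' @param seed integer seed.
#' @param level confidence level for the difference CI (default 0.95).
#' @return list with `observed`, `p`, `ci` (length-2), `exact` (logical).
#' @export
permutation_t_test <- function(a, b, n_shuffles = 5000, seed = 1L,
                               level = 0.95) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  pool <- c(a, b)
  n1 <- length(a)
  n <- length(pool)
  obs <- mean(a) - mean(b)
  if (all(pool == pool[1])) {
    warning("all values identical across both groups; p = 1")
    return(list(observed = 0, p = 1, ci = c(0, 0), exact = TRUE))
  }
  set.seed(seed)
  n_exact <- choose(n, n1)
  if (n_exact <= n_shuffles) {
    combs <- utils::combn(n, n1)
    diffs <- apply(combs, 2, function(ix) {
      mean(pool[ix]) - mean(pool[-ix])
    })
    p <- mean(abs(diffs) >= abs(obs) - 1e-12)
    exact <- TRUE
  } else {
    diffs <- replicate(n_shuffles - 1L, {
      ix <- sample.int(n, n1)
      mean(pool[ix]) - mean(pool[-ix])
    })
    p <- (sum(abs(diffs) >= abs(obs) - 1e-12) + 1) / n_shuffles
    exact <- FALSE
  }
  boot_diff <- replicate(n_shuffles, {
    mean(sample(a, n1, replace = TRUE)) -
      mean(sample(b, length(b), replace = TRUE))
  })
  alpha <- (1 - level) / 2
  ci <- unname(stats::quantile(boot_diff, c(alpha, 1 - alpha), type = 7))
  list(observed = obs, p = p, ci = ci, exact = exact)
}

#' Cohen's d with pooled standard deviation
#'
#' `d = (mean(a) - mean(b)) / s_p` with
#' `s_p = sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1+n2-2))`.
#'
#' @param a,b numeric vectors (each length >= 2).
#' @return scalar effect size.
#' @export
cohens_d <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) /
    (n1 + n2 - 2)
  if (sp2 <= 0) stop("pooled standard deviation is zero")
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' Bias-corrected and accelerated bootstrap interval
#'
#' One-sample form: `values` is a numeric vector and `statistic(values)`
#' a scalar. Two-sample form: `values` is a list of two vectors and
#' `statistic(a, b)` a scalar (resampling and jackknife run within each
#' group). Bias correction z0 comes from the fraction of bootstrap
#' replicates below the point estimate; acceleration from the jackknife
#' skewness.
#'
#' @param values numeric vector or list of two numeric vectors.
#' @param statistic function of the data returning a scalar.
#' @param n_boot bootstrap resamples (default 5000).
#' @param seed integer seed.
#' @param level confidence level (default 0.95).
#' @return length-2 vector (lower, upper).
#' @export
bca_ci <- function(values, statistic, n_boot = 5000, seed = 1L,
                   level = 0.95) {
  set.seed(seed)
  two <- is.list(values)
  est <- if (two) statistic(values[[1]], values[[2]]) else statistic(values)
  safe_stat <- function(...) {
    tryCatch(statistic(...), error = function(e) NA_real_)
  }
  boots <- if (two) {
    a <- values[[1]]; b <- values[[2]]
    stopifnot(length(a) >= 2, length(b) >= 2)
    replicate(n_boot, safe_stat(sample(a, replace = TRUE),
                                sample(b, replace = TRUE)))
  } else {
    stopifnot(length(values) >= 2)
    replicate(n_boot, safe_stat(sample(values, replace = TRUE)))
  }
  ## resamples where the statistic is undefined (e.g. zero spread in a
  ## tiny resampled group) are dropped
  boots <- boots[is.finite(boots)]
  if (!length(boots)) {
    warning("statistic undefined on every bootstrap resample")
    return(c(est, est))
  }
  if (max(boots) - min(boots) < .Machine$double.eps * max(1, abs(est))) {
    warning("degenerate bootstrap distribution; returning point interval")
    return(c(est, est))
  }
  ## bias correction (midrank convention for ties at the estimate)
  frac <- (sum(boots < est) + 0.5 * sum(boots == est)) / length(boots)
  frac <- min(max(frac, 1 / (2 * length(boots))),
              1 - 1 / (2 * length(boots)))
  z0 <- stats::qnorm(frac)
  ## acceleration from the jackknife (0 when too few usable leave-one-out
  ## values, e.g. two-observation groups)
  jack <- if (two) {
    a <- values[[1]]; b <- values[[2]]
    c(vapply(seq_along(a), function(i) safe_stat(a[-i], b), numeric(1)),
      vapply(seq_along(b), function(i) safe_stat(a, b[-i]), numeric(1)))
  } else {
    vapply(seq_along(values), function(i) safe_stat(values[-i]), numeric(1))
  }
  jack <- jack[is.finite(jack)]
  acc <- 0
  if (length(jack) >= 2) {
    jm <- mean(jack)
    denom <- sum((jm - jack)^2)^1.5
    if (denom > 0) acc <- sum((jm - jack)^3) / (6 * denom)
  }
  alpha <- (1 - level) / 2
  adj <- function(a_) {
    z <- z0 + stats::qnorm(a_)
    stats::pnorm(z0 + z / (1 - acc * z))
  }
  unname(stats::quantile(boots, c(adj(alpha), adj(1 - alpha)), type = 7))
}

#' Power of the two-sample t test with unequal group sizes
#'
#' Two-sided test at level `alpha`; noncentrality
#' `d * sqrt(n1 n2 / (n1 + n2))`, `n1 + n2 - 2` degrees of freedom.
#'
#' @param d Cohen's d.
#' @param n1,n2 group sizes (>= 2).
#' @param alpha significance level (default 0.05).
#' @return power in `[0, 1]`.
#' @export
power_t2n <- function(d, n1, n2, alpha = 0.05) {
  stopifnot(n1 >= 2, n2 >= 2)
  df <- n1 + n2 - 2
  ncp <- d * sqrt(n1 * n2 / (n1 + n2))
  tc <- stats::qt(1 - alpha / 2, df)
  ## beyond |ncp| ~ 20 the power is 1 to within 1e-12; below that,
  ## stats::pt may still note reduced far-tail precision for large ncp --
  ## irrelevant at the 1e-4 accuracy this function is validated to
  if (abs(ncp) > 20) return(1)
  suppressWarnings(stats::pt(-tc, df, ncp) + 1 - stats::pt(tc, df, ncp))
}

#' Per-cluster correlation structure of synaptic protein levels
#'
#' Within each cluster, a Pearson correlation matrix of per-synapse
#' normalized integrated intensities across targets is computed for every
#' replicate with enough synapses, the matrices are averaged element-wise,
#' weak entries (|r| < `mask_bound`) are masked to NA, and a hierarchical
#' leaf order (average linkage on 1 - r of the unmasked average) is
#' attached.
#'
#' @param table feature table with `replicate` and intensity columns.
#' @param assignment `cluster_assignment` or integer vector (-1 = noise).
#' @param mask_bound masking threshold (default 0.4; entries with
#'   |r| >= 0.4 are displayed).
#' @param min_synapses minimum synapses per replicate-cluster for the
#'   replicate to contribute (default 3).
#' @return named list (one element per cluster) with `average`, `masked`,
#'   `order` (leaf order), `n_replicates`.
#' @export
cluster_correlation_matrices <- function(table, assignment, mask_bound = 0.4,
                                         min_synapses = 3) {
  cl <- if (inherits(assignment, "cluster_assignment")) assignment$cluster
        else as.integer(assignment)
  stopifnot(length(cl) == nrow(table))
  icols <- grep("^IntegratedIntensity__Synapsin1__", names(table),
                value = TRUE)
  targets <- sub("^IntegratedIntensity__Synapsin1__", "", icols)
  out <- list()
  for (k in sort(unique(cl[cl > 0]))) {
    rows <- which(cl == k)
    mats <- list()
    for (r in unique(table$replicate[rows])) {
      rr <- rows[table$replicate[rows] == r]
      if (length(rr) < min_synapses) next
      x <- as.matrix(table[rr, icols, drop = FALSE])
      colnames(x) <- targets
      ## constant targets give NA correlations; excluded from the average
      m <- suppressWarnings(stats::cor(x))
      mats[[r]] <- m
    }
    if (!length(mats)) next
    arr <- array(unlist(mats), dim = c(length(targets), length(targets),
                                       length(mats)))
    avg <- apply(arr, c(1, 2), mean, na.rm = TRUE)
    dimnames(avg) <- list(targets, targets)
    masked <- avg
    masked[abs(masked) < mask_bound] <- NA
    diag(masked) <- 1
    d <- stats::as.dist(1 - avg)
    ord <- if (all(is.finite(d))) {
      stats::hclust(d, method = "average")$order
    } else {
      seq_along(targets)
    }
    out[[as.character(k)]] <- list(average = avg, masked = masked,
                                   order = ord,
                                   n_replicates = length(mats))
  }
  out
}

## -- dendrite skeleton ------------------------------------------------------

#' Morphological skeleton of a binary mask (Zhang-Suen thinning)
#'
#' @param mask logical matrix.
#' @return logical matrix of the same shape.
#' @export
skeletonize <- function(mask) {
  m <- mask
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  nbr <- function(p) {
    ## neighbours P2..P9 clockwise from north, as shifted matrices
    list(p[1:nr, 2:(nc + 1)],          # P2 north
         p[1:nr, 3:(nc + 2)],          # P3 north-east
         p[2:(nr + 1), 3:(nc + 2)],    # P4 east
         p[3:(nr + 2), 3:(nc + 2)],    # P5 south-east
         p[3:(nr + 2), 2:(nc + 1)],    # P6 south
         p[3:(nr + 2), 1:nc],          # P7 south-west
         p[2:(nr + 1), 1:nc],          # P8 west
         p[1:nr, 1:nc])                # P9 north-west
  }
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      pad[2:(nr + 1), 2:(nc + 1)] <- m
      nb <- nbr(pad)
      B <- Reduce(`+`, nb)
      A <- matrix(0L, nr, nc)
      for (i in 1:8) {
        j <- if (i == 8) 1 else i + 1
        A <- A + (!nb[[i]] & nb[[j]])
      }
      if (phase == 1) {
        c1 <- !(nb[[1]] & nb[[3]] & nb[[5]])
        c2 <- !(nb[[3]] & nb[[5]] & nb[[7]])
      } else {
        c1 <- !(nb[[1]] & nb[[3]] & nb[[7]])
        c2 <- !(nb[[1]] & nb[[5]] & nb[[7]])
      }
      del <- m & B >= 2 & B <= 6 & A == 1 & c1 & c2
      if (any(del)) {
        m[del] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  thin_residue(m)
}

## sequential cleanup after the parallel pass: remove pixels whose
## foreground neighbours stay mutually 8-connected without them (simple
## points with degree >= 2). Eliminates the 2-px staircase residue that
## parallel thinning leaves, so path-length counting sees clean chains.
thin_residue <- function(m) {
  nbr_offsets <- cbind(
    dr = c(-1, -1, 0, 1, 1, 1, 0, -1),
    dc = c(0, 1, 1, 1, 0, -1, -1, -1)
  )
  ## adjacency among the 8 neighbour slots (8-connectivity in the 3x3 ring)
  slot_adj <- outer(1:8, 1:8, function(i, j) {
    abs(nbr_offsets[i, 1] - nbr_offsets[j, 1]) <= 1 &
      abs(nbr_offsets[i, 2] - nbr_offsets[j, 2]) <= 1
  }) & !diag(8)
  nr <- nrow(m); nc <- ncol(m)
  repeat {
    changed <- FALSE
    for (px in which(m)) {
      r <- (px - 1L) %% nr + 1L
      c <- (px - 1L) %/% nr + 1L
      rr <- r + nbr_offsets[, 1]; cc <- c + nbr_offsets[, 2]
      ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
      fg <- logical(8)
      fg[ok] <- m[(cc[ok] - 1L) * nr + rr[ok]]
      B <- sum(fg)
      if (B < 2L) next
      ## component count among foreground neighbour slots
      slots <- which(fg)
      seen <- logical(8)
      ncomp <- 0L
      for (s in slots) {
        if (seen[s]) next
        ncomp <- ncomp + 1L
        queue <- s
        while (length(queue)) {
          q <- queue[1]; queue <- queue[-1]
          if (seen[q]) next
          seen[q] <- TRUE
          queue <- c(queue, slots[slot_adj[q, slots] & !seen[slots]])
        }
      }
      if (ncomp == 1L) {
        m[px] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

#' Remove short spur branches from a skeleton
#'
#' Deletes branches that run from an endpoint to a junction in fewer than
#' `max_len` steps -- the staircase artifacts that mask-edge noise leaves
#' on a thinned dendrite. Unbranched chains (no junction) are never
#' touched, so straight skeletons keep their exact length.
#'
#' @param skeleton logical matrix (thin skeleton).
#' @param max_len longest branch treated as a spur (default 8 px).
#' @return pruned logical matrix.
#' @export
prune_spurs <- function(skeleton, max_len = 8) {
  nbr_off <- cbind(dr = c(-1, -1, 0, 1, 1, 1, 0, -1),
                   dc = c(0, 1, 1, 1, 0, -1, -1, -1))
  nr <- nrow(skeleton); nc <- ncol(skeleton)
  nbrs <- function(r, c) {
    rr <- r + nbr_off[, 1]; cc <- c + nbr_off[, 2]
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    cbind(rr[ok], cc[ok])[skeleton[cbind(rr[ok], cc[ok])], , drop = FALSE]
  }
  repeat {
    changed <- FALSE
    deg <- matrix(0L, nr, nc)
    idx <- which(skeleton, arr.ind = TRUE)
    for (i in seq_len(nrow(idx))) {
      deg[idx[i, 1], idx[i, 2]] <- nrow(nbrs(idx[i, 1], idx[i, 2]))
    }
    ends <- idx[deg[idx] == 1L, , drop = FALSE]
    for (e in seq_len(nrow(ends))) {
      r <- ends[e, 1]; c <- ends[e, 2]
      if (!skeleton[r, c]) next
      path <- matrix(c(r, c), 1)
      prev <- c(NA_integer_, NA_integer_)
      is_spur <- FALSE
      while (nrow(path) <= max_len) {
        nb <- nbrs(r, c)
        if (!is.na(prev[1])) {
          nb <- nb[!(nb[, 1] == prev[1] & nb[, 2] == prev[2]), ,
                   drop = FALSE]
        }
        if (nrow(nb) == 0L) break            # isolated chain: keep
        if (nrow(nb) > 1L || deg[nb[1, 1], nb[1, 2]] >= 3L) {
          is_spur <- TRUE                    # reached a junction
          break
        }
        prev <- c(r, c)
        r <- nb[1, 1]; c <- nb[1, 2]
        path <- rbind(path, c(r, c))
      }
      if (is_spur) {
        skeleton[path] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  skeleton
}

#' Path length of a skeleton in pixels
#'
#' Sum over adjacent skeleton-pixel pairs: 1 per orthogonal and sqrt(2)
#' per diagonal link, plus 1 per connected component (so an unbranched
#' straight run of k pixels has length k).
#'
#' @param skeleton logical matrix.
#' @return length in pixel units.
#' @export
skeleton_length_px <- function(skeleton) {
  idx <- which(skeleton)
  if (!length(idx)) return(0)
  nr <- nrow(skeleton)
  r <- (idx - 1L) %% nr + 1L
  c <- (idx - 1L) %/% nr + 1L
  n_orth <- 0L; n_diag <- 0L
  for (d in list(c(1L, 0L), c(0L, 1L))) {
    r2 <- r + d[1]; c2 <- c + d[2]
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= ncol(skeleton)
    n_orth <- n_orth + sum(skeleton[(c2[ok] - 1L) * nr + r2[ok]])
  }
  for (d in list(c(1L, 1L), c(1L, -1L))) {
    r2 <- r + d[1]; c2 <- c + d[2]
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= ncol(skeleton)
    n_diag <- n_diag + sum(skeleton[(c2[ok] - 1L) * nr + r2[ok]])
  }
  n_comp <- max(label_components8(skeleton))
  n_orth + sqrt(2) * n_diag + n_comp
}

#' Synapse density per 100 um of dendrite
#'
#' Dendrite length is the skeleton path length of the dendrite mask times
#' the pixel size; the density is `100 * count / length_um`, reported
#' overall and per class (and per cluster if given).
#'
#' @param synapses synapse table with a `class` column (and optionally
#'   `cluster`).
#' @param dendrite_mask logical matrix (non-empty).
#' @param pixel_size_um micrometres per pixel (default 0.187).
#' @param per_class split by class (default TRUE).
#' @return data.frame with `scope`, `count`, `dendrite_length_um`,
#'   `density_per_100um`.
#' @export
synapse_density <- function(synapses, dendrite_mask, pixel_size_um = 0.187,
                            per_class = TRUE) {
  if (!any(dendrite_mask)) stop("empty dendrite mask")
  skel <- prune_spurs(skeletonize(dendrite_mask))
  len_px <- skeleton_length_px(skel)
  if (len_px == 0) stop("zero-length dendrite skeleton")
  len_um <- len_px * pixel_size_um
  dens <- function(n) 100 * n / len_um
  out <- data.frame(scope = "all", count = nrow(synapses),
                    dendrite_length_um = len_um,
                    density_per_100um = dens(nrow(synapses)),
                    stringsAsFactors = FALSE)
  if (per_class && nrow(synapses)) {
    for (cls in c("excitatory", "inhibitory", "dual", "unknown")) {
      n <- sum(synapses$class == cls)
      out <- rbind(out, data.frame(scope = cls, count = n,
                                   dendrite_length_um = len_um,
                                   density_per_100um = dens(n)))
    }
    if ("cluster" %in% names(synapses)) {
      for (k in sort(unique(synapses$cluster[synapses$cluster > 0]))) {
        n <- sum(synapses$cluster == k, na.rm = TRUE)
        out <- rbind(out, data.frame(scope = paste0("cluster", k), count = n,
                                     dendrite_length_um = len_um,
                                     density_per_100um = dens(n)))
      }
    }
  }
  out
}

#' Untreated-vs-treated comparison battery
#'
#' For each target and scope (all excitatory synapses, all inhibitory
#' synapses, and each cluster if an assignment is given), the per-replicate
#' mean normalized integrated intensity is compared between conditions
#' with a permutation t test, Cohen's d, a BCa interval on d, and the
#' power of the corresponding t test. With per-replicate dendrite lengths,
#' per-cluster densities relative to the untreated mean get the same
#' battery. A Benjamini-Hochberg column is appended for information; the
#' reported p values are the raw permutation p values.
#'
#' @param table normalized feature table with `replicate`, `treatment`,
#'   `class` and intensity columns.
#' @param assignment optional `cluster_assignment` aligned with `table`.
#' @param dendrite_lengths optional data.frame with `replicate`,
#'   `treatment`, `dendrite_length_um` (one row per replicate or field).
#' @param n_shuffles,n_boot resampling budgets (defaults 5000).
#' @param seed integer seed.
#' @return data.frame, one row per target x scope comparison.
#' @export
compare_conditions <- function(table, assignment = NULL,
                               dendrite_lengths = NULL,
                               n_shuffles = 5000, n_boot = 5000, seed = 1L) {
  cl <- if (is.null(assignment)) NULL
        else if (inherits(assignment, "cluster_assignment")) assignment$cluster
        else as.integer(assignment)
  icols <- grep("^IntegratedIntensity__Synapsin1__", names(table),
                value = TRUE)
  targets <- sub("^IntegratedIntensity__Synapsin1__", "", icols)
  scopes <- list(excitatory = table$class == "excitatory",
                 inhibitory = table$class == "inhibitory")
  if (!is.null(cl)) {
    for (k in sort(unique(cl[cl > 0]))) {
      scopes[[paste0("cluster", k)]] <- cl == k
    }
  }
  rep_table <- unique(table[, c("replicate", "treatment")])
  rows <- list()
  ridx <- 0L
  battery <- function(target, scope_name, ut, tt, seed_i) {
    if (stats::sd(c(ut, tt)) == 0) {
      ## e.g. a marker absent from every synapse of the scope: no
      ## evidence either way
      return(data.frame(target = target, scope = scope_name,
                        n_untreated = length(ut), n_treated = length(tt),
                        mean_untreated = mean(ut), mean_treated = mean(tt),
                        difference = 0, p = 1,
                        diff_ci_lo = 0, diff_ci_hi = 0,
                        cohens_d = NA_real_, d_ci_lo = NA_real_,
                        d_ci_hi = NA_real_, power = NA_real_,
                        stringsAsFactors = FALSE))
    }
    pt <- permutation_t_test(ut, tt, n_shuffles, seed = seed_i)
    d <- cohens_d(ut, tt)
    dci <- bca_ci(list(ut, tt), cohens_d, n_boot, seed = seed_i)
    data.frame(target = target, scope = scope_name,
               n_untreated = length(ut), n_treated = length(tt),
               mean_untreated = mean(ut), mean_treated = mean(tt),
               difference = pt$observed, p = pt$p,
               diff_ci_lo = pt$ci[1], diff_ci_hi = pt$ci[2],
               cohens_d = d, d_ci_lo = dci[1], d_ci_hi = dci[2],
               power = power_t2n(d, length(ut), length(tt)),
               stringsAsFactors = FALSE)
  }
  for (si in seq_along(scopes)) {
    sel <- scopes[[si]]
    for (ti in seq_along(targets)) {
      v <- table[[icols[ti]]]
      means <- vapply(seq_len(nrow(rep_table)), function(i) {
        use <- sel & table$replicate == rep_table$replicate[i]
        if (!sum(use)) return(NA_real_)
        mean(v[use], na.rm = TRUE)
      }, numeric(1))
      ut <- means[rep_table$treatment == "untreated" & !is.na(means)]
      tt <- means[rep_table$treatment == "treated" & !is.na(means)]
      if (length(ut) < 2 || length(tt) < 2) {
        warning("scope ", names(scopes)[si], ", target ", targets[ti],
                ": fewer than 2 replicates per condition; skipped")
        next
      }
      ridx <- ridx + 1L
      rows[[ridx]] <- battery(targets[ti], names(scopes)[si], ut, tt,
                              seed_i = seed + ridx)
    }
  }
  ## per-cluster synapse density relative to the untreated mean
  if (!is.null(cl) && !is.null(dendrite_lengths)) {
    lens <- stats::aggregate(dendrite_length_um ~ replicate + treatment,
                             data = dendrite_lengths, FUN = sum)
    for (k in sort(unique(cl[cl > 0]))) {
      dens <- vapply(seq_len(nrow(lens)), function(i) {
        n <- sum(cl == k & table$replicate == lens$replicate[i])
        100 * n / lens$dendrite_length_um[i]
      }, numeric(1))
      ut <- dens[lens$treatment == "untreated"]
      tt <- dens[lens$treatment == "treated"]
      if (length(ut) < 2 || length(tt) < 2) next
      base <- mean(ut)
      if (base == 0) next
      ridx <- ridx + 1L
      rows[[ridx]] <- battery("synapse_density",
                              paste0("cluster", k, "_density"),
                              ut / base, tt / base, seed_i = seed + ridx)
    }
  }
  if (!length(rows)) {
    return(data.frame(target = character(), scope = character()))
  }
  res <- do.call(rbind, rows)
  res$p_bh <- stats::p.adjust(res$p, method = "BH")
  rownames(res) <- NULL
  res
}
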