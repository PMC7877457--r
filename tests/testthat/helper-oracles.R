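# Independent brute-force oracles. These re-derive every quantity with
# direct pixel loops / enumeration, sharing no code with the package
# implementation beyond base R.

# trimmed-moments threshold, one image
oracle_robust_threshold <- function(img, trim_lo, trim_hi, k_sd) {
  x <- sort(as.numeric(img))
  n <- length(x)
  x <- x[(floor(n * trim_lo) + 1):(n - floor(n * trim_hi))]
  if (length(x) == 1) return(x)
  mean(x) + k_sd * stats::sd(x)
}

# shape/intensity oracle on a pixel set given as 0-based (row, col) matrix
oracle_region_stats <- function(rc, values) {
  n <- nrow(rc)
  cen <- colMeans(rc)
  in_region <- function(r, c) any(rc[, 1] == r & rc[, 2] == c)
  is_edge <- vapply(seq_len(n), function(i) {
    r <- rc[i, 1]; c <- rc[i, 2]
    !(in_region(r - 1, c) && in_region(r + 1, c) &&
        in_region(r, c - 1) && in_region(r, c + 1))
  }, logical(1))
  xe <- values[is_edge]
  wsum <- sum(values)
  wc <- if (wsum > 0) {
    c(sum(rc[, 1] * values), sum(rc[, 2] * values)) / wsum
  } else cen
  list(
    area = n,
    eq_diameter = 2 * sqrt(n / pi),
    integrated = sum(values),
    max = max(values), min = min(values),
    std = sqrt(mean((values - mean(values))^2)),
    mad = stats::median(abs(values - stats::median(values))),
    q25 = stats::quantile(values, 0.25, type = 7, names = FALSE),
    q75 = stats::quantile(values, 0.75, type = 7, names = FALSE),
    integrated_edge = sum(xe),
    min_edge = if (length(xe)) min(xe) else 0,
    std_edge = if (length(xe)) sqrt(mean((xe - mean(xe))^2)) else 0,
    mass_displacement = sqrt(sum((wc - cen)^2)),
    extent = n / ((diff(range(rc[, 1])) + 1) * (diff(range(rc[, 2])) + 1)),
    compactness = mean((rc[, 1] - cen[1])^2 + (rc[, 2] - cen[2])^2) /
      (n / (2 * pi)),
    mean_radius = mean(oracle_radii(rc)),
    max_radius = max(oracle_radii(rc))
  )
}

# distance of every region pixel to the nearest background pixel,
# brute force over a padded bounding box
oracle_radii <- function(rc) {
  rr <- (min(rc[, 1]) - 1):(max(rc[, 1]) + 1)
  cc <- (min(rc[, 2]) - 1):(max(rc[, 2]) + 1)
  grid <- expand.grid(r = rr, c = cc)
  fg <- mapply(function(r, c) any(rc[, 1] == r & rc[, 2] == c),
               grid$r, grid$c)
  bg <- grid[!fg, ]
  vapply(seq_len(nrow(rc)), function(i) {
    sqrt(min((bg$r - rc[i, 1])^2 + (bg$c - rc[i, 2])^2))
  }, numeric(1))
}

# second-moment ellipse quantities with the 1/12 unit-pixel term
oracle_moments <- function(rc) {
  cen <- colMeans(rc)
  dr <- rc[, 1] - cen[1]; dc <- rc[, 2] - cen[2]
  mu20 <- mean(dr^2) + 1 / 12
  mu02 <- mean(dc^2) + 1 / 12
  mu11 <- mean(dr * dc)
  common <- (mu20 + mu02) / 2
  delta <- sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
  l1 <- common + delta; l2 <- max(common - delta, 0)
  list(major = 4 * sqrt(l1), minor = 4 * sqrt(l2),
       ecc = sqrt(max(1 - l2 / l1, 0)),
       orientation = 0.5 * atan2(2 * mu11, mu20 - mu02))
}

# exhaustive two-sample permutation p value (mean difference statistic)
oracle_perm_p <- function(a, b) {
  pool <- c(a, b)
  n1 <- length(a)
  obs <- mean(a) - mean(b)
  combs <- utils::combn(length(pool), n1)
  diffs <- apply(combs, 2, function(ix) mean(pool[ix]) - mean(pool[-ix]))
  mean(abs(diffs) >= abs(obs) - 1e-12)
}

# noncentral-t tail quadrature: P(T <= t) with df and noncentrality delta,
# via conditioning on the chi-square denominator (uses only pnorm/dchisq)
oracle_pt_ncp <- function(t, df, delta) {
  f <- function(v) stats::pnorm(t * sqrt(v / df) - delta) * stats::dchisq(v, df)
  stats::integrate(f, 0, Inf, rel.tol = 1e-10)$value
}

oracle_power_t2n <- function(d, n1, n2, alpha = 0.05) {
  df <- n1 + n2 - 2
  ncp <- d * sqrt(n1 * n2 / (n1 + n2))
  tc <- stats::qt(1 - alpha / 2, df)
  oracle_pt_ncp(-tc, df, ncp) + 1 - oracle_pt_ncp(tc, df, ncp)
}

# percentile bootstrap interval (shares only base R with the BCa code)
oracle_percentile_ci <- function(values, statistic, n_boot, seed,
                                 level = 0.95) {
  set.seed(seed)
  boots <- replicate(n_boot, statistic(sample(values, replace = TRUE)))
  alpha <- (1 - level) / 2
  unname(stats::quantile(boots, c(alpha, 1 - alpha), type = 7))
}

# iterative correlation-pruning re-check: greedy rule applied from scratch
oracle_prune <- function(x, cutoff) {
  repeat {
    cm <- abs(stats::cor(x))
    diag(cm) <- 0
    if (max(cm) <= cutoff) return(names(x))
    idx <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    mean_abs <- colMeans(abs(stats::cor(x)))
    drop <- if (mean_abs[idx[1]] > mean_abs[idx[2]]) idx[1] else idx[2]
    x <- x[, -drop, drop = FALSE]
  }
}

# random connected pixel region grown from a seed (0-based coords)
random_region <- function(n_pix, nr = 40, nc = 40) {
  r <- sample(5:(nr - 5), 1); c <- sample(5:(nc - 5), 1)
  cells <- matrix(c(r, c), 1, 2)
  while (nrow(cells) < n_pix) {
    i <- sample(nrow(cells), 1)
    step <- sample(list(c(0, 1), c(0, -1), c(1, 0), c(-1, 0)), 1)[[1]]
    cand <- cells[i, ] + step
    if (cand[1] < 1 || cand[1] > nr - 2 || cand[2] < 1 || cand[2] > nc - 2) next
    if (!any(cells[, 1] == cand[1] & cells[, 2] == cand[2])) {
      cells <- rbind(cells, cand)
    }
  }
  cells
}

# rasterized disk as a 0-based pixel coordinate matrix
disk_region <- function(radius, center = c(20, 20)) {
  rr <- (center[1] - radius - 1):(center[1] + radius + 1)
  cc <- (center[2] - radius - 1):(center[2] + radius + 1)
  g <- expand.grid(r = rr, c = cc)
  g <- g[(g$r - center[1])^2 + (g$c - center[2])^2 <= radius^2, ]
  as.matrix(g)
}

# pixel coordinate matrix -> punctum-style list on an image grid
region_to_punctum <- function(rc, dim = c(40, 40), target = "Synapsin1") {
  idx <- rc[, 1] + 1L + rc[, 2] * dim[1]
  list(pixels = as.integer(idx), target = target)
}
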