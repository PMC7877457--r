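## Subtype discovery: replicate-balanced subsampling, correlation-based
## feature pruning, centering/scaling, 2D UMAP embedding and HDBSCAN
## density clustering. The embedding and clustering themselves run in the
## bundled Python backend (umap-learn and scikit-learn's HDBSCAN), driven
## through CSV round trips; everything else is R.

python_backend <- function() {
  py <- Sys.which("python")
  if (py == "") py <- Sys.which("python3")
  if (py == "") stop("no python interpreter on PATH (needed for UMAP/HDBSCAN)")
  script <- system.file("python", "embed_cluster.py", package = "synaptopipe")
  if (script == "") stop("bundled python backend not found")
  list(python = py, script = script)
}

run_backend <- function(args) {
  be <- python_backend()
  out <- system2(be$python, c(be$script, args), stdout = TRUE, stderr = TRUE)
  status <- attr(out, "status") %||% 0L
  if (status != 0L) {
    stop("python backend failed (", args[1], "): ",
         paste(utils::tail(out, 5), collapse = "\n"))
  }
  invisible(out)
}

#' Replicate-balanced subsampling
#'
#' Uniform sampling without replacement of at most `quota` rows per
#' replicate, so every replicate contributes equally to the clustering
#' input. Replicates smaller than the quota are kept whole with a warning.
#'
#' @param table feature table with a `replicate` column.
#' @param quota rows per replicate (default 2000).
#' @param seed integer seed; the selection is deterministic given the seed.
#' @return subsampled table (row order: replicates in first-appearance
#'   order, sampled rows in sampled order).
#' @export
subsample_replicates <- function(table, quota = 2000, seed = 1L) {
  reps <- unique(table$replicate)
  set.seed(seed)
  keep <- integer(0)
  for (r in reps) {
    idx <- which(table$replicate == r)
    if (length(idx) <= quota) {
      if (length(idx) < quota) {
        warning("replicate ", r, " has only ", length(idx),
                " synapses (quota ", quota, "); keeping all")
      }
      keep <- c(keep, idx)
    } else {
      keep <- c(keep, sample(idx, quota))
    }
  }
  table[keep, , drop = FALSE]
}

#' Correlation-based feature pruning
#'
#' Drops, from every pair of columns with absolute Pearson correlation
#' above `cutoff`, the member with the larger mean absolute correlation to
#' all other columns, repeating until no pair exceeds the cutoff
#' (`caret::findCorrelation` with `exact = TRUE`). Zero-variance columns
#' are removed first with a warning.
#'
#' @param table data.frame of numeric columns (no NA columns).
#' @param cutoff absolute correlation threshold (default 0.90).
#' @return list with `table` (pruned) and `dropped` (column names).
#' @export
prune_correlated_features <- function(table, cutoff = 0.90) {
  num <- vapply(table, is.numeric, logical(1))
  stopifnot(all(num))
  sds <- vapply(table, stats::sd, numeric(1))
  const <- names(table)[sds == 0 | is.na(sds)]
  if (length(const)) {
    warning("dropping zero-variance column(s): ",
            paste(const, collapse = ", "))
    table <- table[, setdiff(names(table), const), drop = FALSE]
  }
  dropped <- const
  if (ncol(table) >= 2) {
    cm <- stats::cor(table)
    bad <- caret::findCorrelation(cm, cutoff = cutoff, exact = TRUE,
                                  names = TRUE)
    dropped <- c(dropped, bad)
    table <- table[, setdiff(names(table), bad), drop = FALSE]
  }
  list(table = table, dropped = dropped)
}

#' Center and scale feature columns
#'
#' Each column is transformed to `(x - mean) / sd`; the parameters are
#' stored so that held-out rows can be transformed identically.
#'
#' @param table data.frame of numeric columns.
#' @return list with `table` (scaled), `center`, `scale` (named vectors).
#' @export
center_scale <- function(table) {
  m <- vapply(table, mean, numeric(1))
  s <- vapply(table, stats::sd, numeric(1))
  if (any(s == 0 | is.na(s))) {
    stop("zero-variance column(s): ",
         paste(names(table)[s == 0 | is.na(s)], collapse = ", "),
         " (prune before scaling)")
  }
  scaled <- as.data.frame(mapply(function(x, mu, sd) (x - mu) / sd,
                                 table, m, s, SIMPLIFY = FALSE),
                          check.names = FALSE)
  list(table = scaled, center = m, scale = s)
}

#' Apply stored scaling parameters to new rows
#'
#' @param table data.frame with the columns used at fit time.
#' @param center,scale named vectors from [center_scale()].
#' @return scaled data.frame.
#' @export
apply_scaling <- function(table, center, scale) {
  missing <- setdiff(names(center), names(table))
  if (length(missing)) {
    stop("column mismatch: missing ", paste(missing, collapse = ", "))
  }
  table <- table[, names(center), drop = FALSE]
  as.data.frame(mapply(function(x, mu, sd) (x - mu) / sd,
                       table, center, scale, SIMPLIFY = FALSE),
                check.names = FALSE)
}

#' Fit a 2D UMAP embedding
#'
#' Fits UMAP (Euclidean metric, fixed random state, hence deterministic)
#' on scaled feature rows and returns the fitted model for transforming
#' held-out rows.
#'
#' @param table scaled numeric data.frame (>= 10 rows).
#' @param seed integer random state.
#' @param n_neighbors,min_dist UMAP hyperparameters (defaults 15 and 0.1).
#' @param model_dir directory to keep the fitted model state in (defaults
#'   to a session temp dir; pass a run directory to persist it).
#' @return object of class `synapse_embedding`: `coords` (n x 2 matrix),
#'   `columns`, `model_file`, and the hyperparameters.
#' @export
fit_embedding <- function(table, seed = 42L, n_neighbors = 15,
                          min_dist = 0.1, model_dir = NULL) {
  if (nrow(table) < 10) stop("need at least 10 rows to fit an embedding")
  num <- vapply(table, is.numeric, logical(1))
  stopifnot(all(num))
  model_dir <- model_dir %||% tempfile("umap_model_")
  dir.create(model_dir, recursive = TRUE, showWarnings = FALSE)
  infile <- tempfile(fileext = ".csv")
  outfile <- tempfile(fileext = ".csv")
  model_file <- file.path(model_dir, "umap_model.pkl")
  utils::write.table(table, infile, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  run_backend(c("fit", "--in", infile, "--out", outfile,
                "--model", model_file,
                "--n-neighbors", n_neighbors, "--min-dist", min_dist,
                "--seed", as.integer(seed)))
  coords <- as.matrix(utils::read.csv(outfile, header = FALSE))
  dimnames(coords) <- list(NULL, c("umap1", "umap2"))
  unlink(c(infile, outfile))
  structure(list(coords = coords, columns = names(table),
                 model_file = model_file, seed = as.integer(seed),
                 n_neighbors = n_neighbors, min_dist = min_dist),
            class = "synapse_embedding")
}

#' Transform rows with a fitted embedding
#'
#' @param object a `synapse_embedding` from [fit_embedding()].
#' @param newdata data.frame with the columns the model was fit on (same
#'   scaling applied by the caller).
#' @param ... unused.
#' @return n x 2 coordinate matrix.
#' @export
predict.synapse_embedding <- function(object, newdata, ...) {
  missing <- setdiff(object$columns, names(newdata))
  if (length(missing)) {
    stop("column mismatch on transform: missing ",
         paste(missing, collapse = ", "))
  }
  newdata <- newdata[, object$columns, drop = FALSE]
  infile <- tempfile(fileext = ".csv")
  outfile <- tempfile(fileext = ".csv")
  utils::write.table(newdata, infile, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  run_backend(c("transform", "--in", infile, "--out", outfile,
                "--model", object$model_file))
  coords <- as.matrix(utils::read.csv(outfile, header = FALSE))
  dimnames(coords) <- list(NULL, c("umap1", "umap2"))
  unlink(c(infile, outfile))
  coords
}

#' Density-based clustering of embedding coordinates
#'
#' HDBSCAN with a minimum cluster size; low-density points are flagged as
#' noise (cluster id -1) and excluded from profiles and downstream
#' statistics. Clusters are renumbered 1..K by descending size.
#'
#' @param coords n x 2 coordinate matrix.
#' @param min_cluster_size smallest reported cluster (default 100).
#' @return list of class `cluster_assignment`: `cluster` (integer vector,
#'   -1 = noise), `k`, `min_cluster_size`.
#' @export
cluster_embedding <- function(coords, min_cluster_size = 100) {
  stopifnot(is.matrix(coords), ncol(coords) == 2)
  infile <- tempfile(fileext = ".csv")
  outfile <- tempfile(fileext = ".csv")
  utils::write.table(coords, infile, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  run_backend(c("hdbscan", "--in", infile, "--out", outfile,
                "--min-cluster-size", as.integer(min_cluster_size)))
  raw <- as.integer(utils::read.csv(outfile, header = FALSE)[[1]])
  unlink(c(infile, outfile))
  cl <- rep(-1L, length(raw))
  pos <- raw >= 0L
  if (any(pos)) {
    sizes <- sort(table(raw[pos]), decreasing = TRUE)
    remap <- stats::setNames(seq_along(sizes), names(sizes))
    cl[pos] <- remap[as.character(raw[pos])]
  }
  structure(list(cluster = cl, k = max(0L, max(cl)),
                 min_cluster_size = as.integer(min_cluster_size)),
            class = "cluster_assignment")
}

#' Per-cluster intensity and composition profiles
#'
#' For every non-noise cluster: mean normalized integrated intensity per
#' target (anchor region), the fraction of synapses with detectable
#' (nonzero) signal per target, cluster size, and the share of excitatory
#' and inhibitory synapses.
#'
#' @param table feature table aligned with the assignment (one row per
#'   embedded synapse; needs `IntegratedIntensity__Synapsin1__<target>`
#'   columns and a `class` column).
#' @param assignment a `cluster_assignment` (or integer vector).
#' @return data.frame, one row per cluster.
#' @export
cluster_profiles <- function(table, assignment) {
  cl <- if (inherits(assignment, "cluster_assignment")) assignment$cluster
        else as.integer(assignment)
  stopifnot(length(cl) == nrow(table))
  icols <- grep("^IntegratedIntensity__Synapsin1__", names(table),
                value = TRUE)
  targets <- sub("^IntegratedIntensity__Synapsin1__", "", icols)
  out <- list()
  for (k in sort(unique(cl[cl > 0]))) {
    rows <- which(cl == k)
    if (!length(rows)) {
      warning("cluster ", k, " is empty; skipped")
      next
    }
    prof <- data.frame(cluster = k, n = length(rows),
                       frac_excitatory = mean(table$class[rows] == "excitatory"),
                       frac_inhibitory = mean(table$class[rows] == "inhibitory"))
    for (i in seq_along(icols)) {
      v <- table[[icols[i]]][rows]
      prof[[paste0("mean_intensity_", targets[i])]] <- mean(v, na.rm = TRUE)
      prof[[paste0("detectable_", targets[i])]] <- mean(v > 0, na.rm = TRUE)
    }
    out[[as.character(k)]] <- prof
  }
  if (!length(out)) {
    return(data.frame(cluster = integer(), n = integer()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
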