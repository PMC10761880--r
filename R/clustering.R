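#' Build the clustering feature matrix
#'
#' Transforms raw per-cell marker intensities into the feature space used
#' for clustering and embedding: `log(x + 1)` per marker, then a
#' per-marker z-score across the cohort. Markers with zero variance are
#' set to 0 rather than producing NaNs. Row order is preserved; the
#' per-marker centers and scales are stored as attributes so the
#' transform can be inverted.
#'
#' @param cells cell table containing the marker columns.
#' @param markers marker names to use.
#' @return numeric matrix (cells x markers) with attributes `center`,
#'   `scale` and `markers`.
#' @seealso [inverse_features()]
#' @export
build_features <- function(cells, markers) {
  missing_m <- setdiff(markers, names(cells))
  if (length(missing_m)) {
    stop_("missing marker column(s): %s", paste(missing_m, collapse = ", "))
  }
  m <- as.matrix(cells[markers])
  if (!is.numeric(m) || any(!is.finite(m))) {
    stop_("marker intensities must be finite numbers")
  }
  lg <- log1p(m)
  ctr <- colMeans(lg)
  scl <- apply(lg, 2, sd)
  z <- sweep(lg, 2, ctr)
  ok <- scl > 0
  z[, ok] <- sweep(z[, ok, drop = FALSE], 2, scl[ok], "/")
  z[, !ok] <- 0
  attr(z, "center") <- ctr
  attr(z, "scale") <- scl
  attr(z, "markers") <- markers
  z
}

#' Invert the feature transform back to raw intensities
#'
#' @param features matrix from [build_features()] (attributes required).
#' @return matrix of raw intensities (AU).
#' @export
inverse_features <- function(features) {
  ctr <- attr(features, "center"); scl <- attr(features, "scale")
  if (is.null(ctr) || is.null(scl)) {
    stop_("'features' must carry the center/scale attributes from build_features()")
  }
  scl0 <- ifelse(scl > 0, scl, 0)
  expm1(sweep(sweep(unclass(features)[, , drop = FALSE], 2, scl0, "*"), 2, ctr, "+"))
}

#' Fit a k-component Gaussian mixture over marker feature space
#'
#' Model-based clustering of single cells with full (unconstrained)
#' covariance per component, fitted by EM. Initialization uses
#' model-based hierarchical clustering on a random subset; `n_init`
#' differently-seeded initializations are run and the fit with the best
#' log-likelihood kept, so the result is deterministic given `seed`.
#' Near-singular covariances are handled by refitting under mclust's
#' conjugate prior.
#'
#' @param features matrix from [build_features()].
#' @param k number of components (>= 2; 7 is the conventional default for
#'   this panel).
#' @param seed integer seed.
#' @param n_init number of initializations.
#' @param init_subset size of the random subset used to initialize EM.
#' @return list with `model` (class `cluster_model`: component means
#'   `k x d`, covariances, weights, log-likelihood, seed, markers) and
#'   `labels` (integer per-cell hard assignments by maximum posterior,
#'   ties to the lower component index).
#' @export
fit_clusters <- function(features, k = 7, seed = 1L, n_init = 3,
                         init_subset = 2000) {
  if (!is.numeric(k) || length(k) != 1L || k < 2) {
    stop_("'k' must be an integer >= 2")
  }
  k <- as.integer(k)
  x <- unclass(features)
  if (nrow(x) < k) stop_("need at least k rows to fit k components")
  best <- NULL
  for (i in seq_len(n_init)) {
    set.seed(seed + i - 1L)
    sub <- sample.int(nrow(x), min(init_subset, nrow(x)))
    fit <- tryCatch(
      mclust::Mclust(x, G = k, modelNames = "VVV", verbose = FALSE,
                     initialization = list(subset = sub)),
      error = function(e) NULL)
    if (is.null(fit)) {
      fit <- tryCatch(
        mclust::Mclust(x, G = k, modelNames = "VVV", verbose = FALSE,
                       prior = mclust::priorControl(),
                       initialization = list(subset = sub)),
        error = function(e) NULL)
    }
    if (!is.null(fit) && (is.null(best) || fit$loglik > best$loglik)) best <- fit
  }
  if (is.null(best)) stop_("Gaussian mixture fit failed for k = %d", k)
  labels <- max.col(best$z, ties.method = "first")
  model <- structure(list(
    k = k,
    markers = colnames(x),
    means = t(best$parameters$mean),
    covariances = best$parameters$variance$sigma,
    weights = as.numeric(best$parameters$pro),
    loglik = best$loglik,
    model_name = best$modelName,
    parameters = best$parameters,
    seed = seed
  ), class = "cluster_model")
  list(model = model, labels = as.integer(labels))
}

#' Assign cells to the components of a fitted cluster model
#'
#' @param model a `cluster_model` from [fit_clusters()].
#' @param features feature matrix in the same space the model was fit in.
#' @return integer labels (maximum posterior, ties to lower index).
#' @export
predict_clusters <- function(model, features) {
  if (!inherits(model, "cluster_model")) stop_("'model' must be a cluster_model")
  dens <- mclust::cdens(data = unclass(features), modelName = model$model_name,
                        parameters = model$parameters, logarithm = TRUE)
  post <- sweep(dens, 2, log(model$weights), "+")
  as.integer(max.col(post, ties.method = "first"))
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("Gaussian mixture cluster model: k = %d, %d markers (%s), logLik = %.1f\n",
              x$k, length(x$markers), x$model_name, x$loglik))
  invisible(x)
}

#' Profile clusters by median marker expression
#'
#' Per-cluster median of `log1p` marker intensities and per-cluster cell
#' fractions. Empty clusters get fraction 0 and `NA` medians, flagged in
#' the `empty` field.
#'
#' @param cells cell table with the marker columns.
#' @param labels integer per-cell cluster labels (aligned with `cells`).
#' @param markers marker names to profile (default: attribute-free guess
#'   is not attempted; pass explicitly).
#' @param k number of clusters (default `max(labels)`).
#' @return object of class `cluster_profile`: `medians` (`k x m` matrix,
#'   log AU), `fractions`, `n` (per-cluster counts), `empty`, `k`,
#'   `markers`.
#' @export
profile_clusters <- function(cells, labels, markers, k = max(labels)) {
  if (length(labels) != nrow(cells)) {
    stop_("'labels' must align with 'cells' (one per row)")
  }
  missing_m <- setdiff(markers, names(cells))
  if (length(missing_m)) {
    stop_("missing marker column(s): %s", paste(missing_m, collapse = ", "))
  }
  k <- as.integer(k)
  n <- tabulate(labels, nbins = k)
  med <- matrix(NA_real_, k, length(markers),
                dimnames = list(paste0("cluster", seq_len(k)), markers))
  lg <- log1p(as.matrix(cells[markers]))
  for (cl in which(n > 0)) {
    med[cl, ] <- apply(lg[labels == cl, , drop = FALSE], 2, median)
  }
  structure(list(medians = med,
                 fractions = n / sum(n),
                 n = n,
                 empty = n == 0,
                 k = k, markers = markers),
            class = "cluster_profile")
}

#' @export
print.cluster_profile <- function(x, ...) {
  cat(sprintf("Cluster profile: k = %d over %d markers\n", x$k, length(x$markers)))
  print(round(cbind(fraction = x$fractions, x$medians), 3))
  invisible(x)
}

#' Annotate clusters as tumor or immune-stromal by lineage markers
#'
#' Labels each cluster from its median expression of an epithelial
#' (tumor) lineage marker and a leukocyte marker: `"tumor"` when the
#' tumor-marker median exceeds its cohort gating threshold while the
#' immune marker does not, `"immune-stromal"` for the converse, and
#' `"mixed"` otherwise (clusters with heterogeneous expression of both
#' lineages). If either lineage marker is missing from the profile, all
#' clusters are `"unannotated"`.
#'
#' Thresholds are cohort-level gate thresholds on the `log1p` scale,
#' either supplied directly or computed from `cells` with
#' [gate_marker()].
#'
#' @param profile a [profile_clusters()] result.
#' @param cells optional cell table used to derive thresholds.
#' @param tumor_marker,immune_marker lineage marker names.
#' @param tumor_threshold,immune_threshold gate thresholds (log AU);
#'   computed from `cells` when omitted.
#' @param seed gating seed when thresholds are derived from `cells`.
#' @return character vector of length `k`.
#' @export
annotate_clusters <- function(profile, cells = NULL,
                              tumor_marker = "Keratin", immune_marker = "CD45",
                              tumor_threshold = NULL, immune_threshold = NULL,
                              seed = 1L) {
  if (!inherits(profile, "cluster_profile")) {
    stop_("'profile' must come from profile_clusters()")
  }
  have <- c(tumor_marker, immune_marker) %in% profile$markers
  if (!all(have)) {
    warn_("lineage marker(s) %s missing from the profile; clusters left unannotated",
          paste(c(tumor_marker, immune_marker)[!have], collapse = ", "))
    return(rep("unannotated", profile$k))
  }
  if (is.null(tumor_threshold)) {
    if (is.null(cells)) stop_("supply 'tumor_threshold' or 'cells' to derive it")
    tumor_threshold <- gate_marker(cells[[tumor_marker]], seed = seed,
                                   marker = tumor_marker)$threshold
  }
  if (is.null(immune_threshold)) {
    if (is.null(cells)) stop_("supply 'immune_threshold' or 'cells' to derive it")
    immune_threshold <- gate_marker(cells[[immune_marker]], seed = seed,
                                    marker = immune_marker)$threshold
  }
  mt <- profile$medians[, tumor_marker]
  mi <- profile$medians[, immune_marker]
  out <- rep("mixed", profile$k)
  out[!is.na(mt) & !is.na(mi) & mt > tumor_threshold & mi <= immune_threshold] <- "tumor"
  out[!is.na(mt) & !is.na(mi) & mi > immune_threshold & mt <= tumor_threshold] <- "immune-stromal"
  out[profile$empty] <- "unannotated"
  out
}

#' Embed cells in two dimensions with t-SNE
#'
#' Computes a 2-D t-distributed stochastic neighbor embedding of a seeded
#' random subsample of cells (50,000 by convention for visualization) on
#' the same z-scored feature space used for clustering, and stores the
#' cohort means of the two embedding coordinates for downstream
#' dispersion scoring.
#'
#' @param features matrix from [build_features()].
#' @param subsample number of cells to embed (all cells if the table is
#'   smaller).
#' @param seed RNG seed (subsampling and the embedding itself).
#' @param perplexity t-SNE perplexity; must satisfy
#'   `3 * perplexity < n_embedded - 1`.
#' @param theta Barnes-Hut accuracy/speed trade-off (0 = exact).
#' @param max_iter gradient-descent iterations.
#' @return object of class `cell_embedding`: `coords` (data frame `row`
#'   (index into `features`), `tsne1`, `tsne2`), cohort means `mean1`,
#'   `mean2`, and the `seed`, `perplexity` and `n_total` used.
#' @export
embed_cells <- function(features, subsample = 50000, seed = 1L,
                        perplexity = 30, theta = 0.5, max_iter = 500) {
  x <- unclass(features)
  n <- nrow(x)
  subsample <- check_count(subsample, "subsample", min = 4)
  set.seed(seed)
  idx <- if (n > subsample) sort(sample.int(n, subsample)) else seq_len(n)
  if (perplexity >= length(idx)) {
    stop_("perplexity (%s) must be smaller than the number of embedded cells (%d)",
          format(perplexity), length(idx))
  }
  if (3 * perplexity >= length(idx) - 1) {
    stop_("perplexity too large for %d cells: need 3*perplexity < n - 1",
          length(idx))
  }
  set.seed(seed)
  ts <- Rtsne::Rtsne(x[idx, , drop = FALSE], dims = 2,
                     perplexity = perplexity, theta = theta,
                     max_iter = max_iter, check_duplicates = FALSE,
                     pca = FALSE, verbose = FALSE, num_threads = 1)
  coords <- data.frame(row = idx, tsne1 = ts$Y[, 1], tsne2 = ts$Y[, 2])
  structure(list(coords = coords,
                 mean1 = mean(coords$tsne1), mean2 = mean(coords$tsne2),
                 seed = seed, perplexity = perplexity, n_total = n),
            class = "cell_embedding")
}

#' @export
print.cell_embedding <- function(x, ...) {
  cat(sprintf("t-SNE embedding: %d of %d cells (perplexity %.0f, seed %d); cohort means (%.2f, %.2f)\n",
              nrow(x$coords), x$n_total, x$perplexity, x$seed, x$mean1, x$mean2))
  invisible(x)
}
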