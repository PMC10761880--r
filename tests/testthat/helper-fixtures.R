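# small cohorts and feature fixtures shared across test files

tiny_cohort <- function(n_patients = 8, mean_cells = 60, k = 4,
                        markers = c("HER2", "ER", "Ki67", "Keratin", "CD45", "CD68"),
                        seed = 11, ...) {
  generate_cohort(cohort_config(
    n_patients = n_patients,
    cells_per_core = list(mean = mean_cells, dispersion = 0.1),
    markers = markers, k_true = k, seed = seed, ...))
}

# two well-separated Gaussian blobs in 2-D feature space
two_blob_features <- function(n_per = 150, sep = 8, seed = 5) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(2 * n_per), ncol = 2),
             matrix(rnorm(2 * n_per, mean = sep), ncol = 2))
  colnames(x) <- c("f1", "f2")
  list(features = x, labels = rep(1:2, each = n_per))
}

rdirichlet_test <- function(k) {
  x <- rgamma(k, 1)
  x / sum(x)
}

# hand-built embedding object for score tests
manual_embedding <- function(tsne1, tsne2, rows = seq_along(tsne1),
                             n_total = max(rows)) {
  structure(list(coords = data.frame(row = rows, tsne1 = tsne1, tsne2 = tsne2),
                 mean1 = mean(tsne1), mean2 = mean(tsne2),
                 seed = 0L, perplexity = NA_real_, n_total = n_total),
            class = "cell_embedding")
}
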