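test_that("feature building z-scores log intensities and is invertible", {
  coh <- tiny_cohort(n_patients = 4, mean_cells = 40)
  mk <- c("HER2", "ER", "Ki67")
  f <- build_features(coh$cells, mk)
  expect_equal(unname(colMeans(f)), rep(0, 3), tolerance = 1e-9)
  expect_equal(unname(apply(f, 2, sd)), rep(1, 3), tolerance = 1e-9)
  raw <- inverse_features(f)
  expect_equal(unname(raw), unname(as.matrix(coh$cells[mk])), tolerance = 1e-8)
  expect_error(build_features(coh$cells, c("HER2", "missing")), "missing")
})

test_that("zero-variance markers become zero features, not NaN", {
  cells <- data.frame(a = rep(3, 5), b = c(1, 2, 3, 4, 5))
  f <- build_features(cells, c("a", "b"))
  expect_equal(unname(f[, "a"]), rep(0, 5))
  expect_true(all(is.finite(f)))
})

test_that("the mixture recovers separated phenotype clusters", {
  coh <- tiny_cohort(n_patients = 10, mean_cells = 60, seed = 2)
  f <- build_features(coh$cells, c("HER2", "ER", "Ki67", "Keratin", "CD45", "CD68"))
  cl <- fit_clusters(f, k = 4, seed = 1, n_init = 2)
  expect_gte(mclust::adjustedRandIndex(cl$labels, coh$truth$cell_labels), 0.9)
  expect_equal(sum(cl$model$weights), 1, tolerance = 1e-9)
  expect_error(fit_clusters(f, k = 1), ">= 2")

  # more initializations can only improve the kept log-likelihood
  cl1 <- fit_clusters(f, k = 4, seed = 1, n_init = 1)
  expect_gte(cl$model$loglik, cl1$model$loglik - 1e-6)

  # duplicated rows get identical labels
  lab2 <- predict_clusters(cl$model, rbind(f, f))
  n <- nrow(f)
  expect_equal(lab2[seq_len(n)], lab2[n + seq_len(n)])
})

test_that("a two-blob fixture is split exactly up to label permutation", {
  tb <- two_blob_features()
  cl <- fit_clusters(tb$features, k = 2, seed = 3, n_init = 1)
  tab <- table(cl$labels, tb$labels)
  expect_equal(sum(apply(tab, 1, max)), length(tb$labels))
})

test_that("cluster profiles report median expression and fractions", {
  set.seed(8)
  n <- 5000
  cells <- data.frame(M = c(exp(rnorm(n, 1, 0.3)), exp(rnorm(n, 4, 0.3))),
                      C = 2)
  labels <- rep(1:2, each = n)
  pr <- profile_clusters(cells, labels, c("M", "C"))
  expect_equal(sum(pr$fractions), 1, tolerance = 1e-9)
  # medians of log1p(x) near log1p(exp(mu)) for log-normal clusters
  expect_lt(abs(pr$medians[1, "M"] - log1p(exp(1))), 0.05)
  expect_lt(abs(pr$medians[2, "M"] - log1p(exp(4))), 0.05)
  expect_equal(pr$medians[1, "C"], pr$medians[2, "C"])

  one <- profile_clusters(cells, rep(1L, 2 * n), "M", k = 1)
  expect_equal(one$fractions, 1)

  holes <- profile_clusters(cells[1:10, ], rep(1L, 10), "M", k = 3)
  expect_true(all(holes$empty[2:3]))
  expect_true(all(is.na(holes$medians[2:3, ])))
  expect_equal(holes$fractions[2:3], c(0, 0))
})

test_that("lineage annotation separates tumor from immune-stromal clusters", {
  med <- rbind(c(Keratin = 5, CD45 = 0.5),
               c(Keratin = 0.5, CD45 = 5),
               c(Keratin = 0.5, CD45 = 0.5))
  pr <- structure(list(medians = med, fractions = rep(1 / 3, 3),
                       n = c(5L, 5L, 5L), empty = rep(FALSE, 3), k = 3L,
                       markers = c("Keratin", "CD45")),
                  class = "cluster_profile")
  ann <- annotate_clusters(pr, tumor_threshold = 2, immune_threshold = 2)
  expect_equal(ann, c("tumor", "immune-stromal", "mixed"))
  pr$markers <- c("Keratin", "CD3")
  expect_warning(ann2 <- annotate_clusters(pr, tumor_threshold = 2,
                                           immune_threshold = 2),
                 "unannotated")
  expect_equal(ann2, rep("unannotated", 3))
})

test_that("the embedding is deterministic, definitionally centered and separates blobs", {
  tb <- two_blob_features(n_per = 120)
  e1 <- embed_cells(tb$features, subsample = 240, seed = 9, perplexity = 20)
  e2 <- embed_cells(tb$features, subsample = 240, seed = 9, perplexity = 20)
  expect_identical(e1$coords, e2$coords)
  expect_equal(e1$mean1, mean(e1$coords$tsne1))
  expect_equal(e1$mean2, mean(e1$coords$tsne2))

  sil <- cluster::silhouette(tb$labels,
                             dist(as.matrix(e1$coords[c("tsne1", "tsne2")])))
  expect_gt(mean(sil[, "sil_width"]), 0.5)

  sub <- embed_cells(tb$features, subsample = 100, seed = 1, perplexity = 15)
  expect_equal(nrow(sub$coords), 100)
  expect_error(embed_cells(tb$features, subsample = 50, perplexity = 60),
               "perplexity")
})

test_that("relabeling clusters leaves composition scores unchanged", {
  coh <- tiny_cohort(n_patients = 6, mean_cells = 50, seed = 4)
  lab <- coh$truth$cell_labels
  cs <- compositions(lab, coh$cells$patient_id, k = 4)
  s <- gmm_score(cs)
  perm <- c(3L, 1L, 4L, 2L)
  cs_p <- compositions(perm[lab], coh$cells$patient_id, k = 4)
  s_p <- gmm_score(cs_p)
  expect_equal(s$gmm_score, s_p$gmm_score, tolerance = 1e-12)
})
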