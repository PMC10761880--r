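test_that("cohort size and structure follow the configuration and are deterministic", {
  cfg <- cohort_config(n_patients = 3, cores_per_patient = 3,
                       cells_per_core = list(mean = 200, dispersion = 0),
                       seed = 4)
  coh <- generate_cohort(cfg)
  expect_equal(length(unique(coh$cells$core_id)), 9)
  expect_equal(nrow(coh$cells), 3 * 3 * 200)
  expect_equal(nrow(coh$clinical), 3)
  expect_true(all(cfg$markers %in% names(coh$cells)))
  expect_true(all(coh$truth$cell_labels %in% seq_len(cfg$k_true)))
  expect_equal(unname(rowSums(coh$truth$patient_composition)), rep(1, 3),
               tolerance = 1e-9)
  # identical configuration => bit-identical tables
  coh2 <- generate_cohort(cfg)
  expect_identical(coh$cells, coh2$cells)
  expect_identical(coh$clinical, coh2$clinical)
})

test_that("invalid configuration fields are rejected by name", {
  expect_error(cohort_config(n_patients = 0), "n_patients")
  expect_error(cohort_config(k_true = 1), "k_true")
  expect_error(cohort_config(composition_alpha = 0), "composition_alpha")
  expect_error(cohort_config(censor_rate = 1.5), "censor_rate")
  expect_error(cohort_config(cluster_means = matrix(0, 2, 2)), "cluster_means")
  expect_error(cohort_config(global_weights = c(0.5, 0.5)), "global_weights")
})

test_that("the concentration limit pins patient compositions to the cohort weights", {
  coh <- generate_cohort(cohort_config(
    n_patients = 10, cells_per_core = list(mean = 10, dispersion = 0),
    composition_alpha = 1e6, seed = 2))
  dev <- sweep(coh$truth$patient_composition, 2,
               coh$truth$cohort_weights)
  expect_lt(max(abs(dev)), 1e-2)
})

test_that("raising composition_alpha lowers mean divergence-from-cohort heterogeneity", {
  mean_het <- function(alpha) {
    mean(sapply(1:20, function(s) {
      coh <- generate_cohort(cohort_config(
        n_patients = 15, cells_per_core = list(mean = 5, dispersion = 0),
        composition_alpha = alpha, seed = s))
      mean(coh$truth$heterogeneity)
    }))
  }
  h <- c(mean_het(1), mean_het(5), mean_het(25), mean_het(125))
  expect_true(all(diff(h) < 0))
})

test_that("with hazard_coupling = 0 recurrence carries no heterogeneity signal", {
  pvals <- sapply(1:50, function(s) {
    coh <- generate_cohort(cohort_config(
      n_patients = 40, cells_per_core = list(mean = 5, dispersion = 0),
      hazard_coupling = 0, seed = s))
    d <- coh$clinical
    f <- survival::coxph(survival::Surv(time_months, recurrence) ~ het,
                         data = cbind(d, het = coh$truth$heterogeneity))
    summary(f)$coefficients[1, "Pr(>|z|)"]
  })
  # nominal behavior: about 5% of null replicates reach p < 0.05
  expect_lte(sum(pvals < 0.05), 8)
  expect_gt(mean(pvals), 0.3)
})

test_that("pixel pairs hit the requested correlation and edge cases", {
  pp <- generate_pixel_pairs(100, rho = 1, noise_sd = 0, seed = 3)
  expect_equal(pp$reference, pp$candidate)
  expect_equal(cor(log1p(pp$reference), log1p(pp$candidate)), 1)
  expect_equal(nrow(generate_pixel_pairs(2, rho = 0.5)), 2)
  expect_error(generate_pixel_pairs(100, rho = 1.2), "\\[-1, 1\\]")
  pp <- generate_pixel_pairs(5000, rho = 0.8, seed = 7)
  expect_lt(abs(cor(log1p(pp$reference), log1p(pp$candidate)) - 0.8), 0.02)
  # extra log-scale noise attenuates the attained correlation as recorded
  ppn <- generate_pixel_pairs(20000, rho = 0.8, noise_sd = 0.5, seed = 8)
  expect_lt(abs(cor(log1p(ppn$reference), log1p(ppn$candidate)) -
                  attr(ppn, "rho_attained")), 0.02)
})

test_that("image fixtures deliver the requested cell count or fail as infeasible", {
  fx <- generate_image_fixture(10, image_size = 256, seed = 0)
  expect_equal(sort(unique(as.vector(fx$mask[fx$mask > 0]))), 1:10)
  expect_equal(nrow(fx$truth), 10)
  fx0 <- generate_image_fixture(0)
  expect_true(all(fx0$mask == 0))
  expect_true(all(fx0$image == 0))
  expect_error(generate_image_fixture(500, image_size = 64), "capacity")
})
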