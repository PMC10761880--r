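test_that("concordance handles identity, anti-identity and degenerate inputs", {
  x <- rlnorm(500, 3, 1)
  expect_equal(concordance(x, x, seed = 1), 1)
  # y with log1p(y) = c - log1p(x): exact anti-correlation on the log scale
  y <- expm1(10 - log1p(x))
  expect_equal(concordance(x, y, seed = 1), -1)
  expect_equal(concordance(x, y, seed = 1), concordance(y, x, seed = 1))
  expect_error(concordance(x, rep(2, 500), seed = 1), "zero variance")
  expect_error(concordance(x, x[-1]), "equal length")
})

test_that("sampled concordance recovers the generative correlation and stabilizes over seeds", {
  pp <- generate_pixel_pairs(5000, rho = 0.85, seed = 2)
  r <- concordance(pp$reference, pp$candidate, n_sample = 5000, seed = 2)
  expect_lt(abs(r - 0.85), 0.02)

  pool <- generate_pixel_pairs(20000, rho = 0.8, seed = 1)
  rs <- sapply(1:20, function(s) {
    concordance(pool$reference, pool$candidate, n_sample = 5000, seed = s)
  })
  expect_lt(sd(rs), 0.01)
  expect_equal(concordance(pool$reference, pool$candidate, seed = 4),
               concordance(pool$reference, pool$candidate, seed = 4))
})

test_that("core summaries report mean log intensity and gated positivity per core", {
  set.seed(12)
  cells <- data.frame(
    core_id = rep(c("neg", "pos"), each = 400),
    M = c(rlnorm(400, 1, 0.15), rlnorm(400, 4, 0.15)))
  cs <- core_summaries(cells, "M", seed = 1)
  cs <- cs[match(c("neg", "pos"), cs$core_id), ]
  expect_equal(cs$positivity_ratio, c(0, 1))
  expect_equal(cs$mean_log_intensity,
               c(mean(log1p(cells$M[1:400])), mean(log1p(cells$M[401:800]))))
  const <- data.frame(core_id = rep(c("a", "b"), each = 200),
                      M = rep(c(2, 20), each = 200))
  expect_equal(core_summaries(const, "M", seed = 1)$mean_log_intensity,
               log(c(3, 21)))
  expect_error(core_summaries(cells, "nope"), "unknown marker")
})

test_that("core-level concordance is high when the candidate tracks the reference", {
  set.seed(3)
  cells <- data.frame(core_id = rep(sprintf("c%02d", 1:30), each = 100))
  base <- rep(runif(30, 0.5, 5), each = 100)
  cells$REF <- exp(base + rnorm(3000, 0, 0.3))
  cells$CAND <- exp(base + rnorm(3000, 0, 0.1) + 0.2)
  a <- core_summaries(cells, "REF", seed = 1)
  b <- core_summaries(cells, "CAND", seed = 1)
  expect_gte(cor(a$mean_log_intensity, b$mean_log_intensity), 0.95)
})

test_that("stratified comparison bins cores into the four standard strata", {
  sc <- stratified_comparison(c(10, 30, 60, 90), c(1, 2, 3, 4))
  expect_equal(sc$n, rep(1L, 4))
  expect_equal(sc$median, 1:4)
  # boundary 25 goes to the second (left-closed) bin; 100 to the last
  sc2 <- stratified_comparison(c(25, 100), c(7, 9))
  expect_equal(sc2$n, c(0L, 1L, 0L, 1L))
  # every core lands in exactly one bin
  set.seed(2)
  ref <- runif(200, 0, 100)
  expect_equal(sum(stratified_comparison(ref, ref)$n), 200L)
  # monotone candidate => non-decreasing bin medians
  expect_true(all(diff(na.omit(stratified_comparison(ref, 2 * ref + 1)$median)) >= 0))
  expect_error(stratified_comparison(c(-2, 50), c(1, 2)), "\\[0, 100\\]")
})

test_that("qualification verdicts rank antibody pairs from the metric ladder", {
  perfect <- qualify(pixel_r = 1, cell_r = 1, core_r = 1,
                     core_positivity_r = 1, dynamic_range = 4)
  expect_equal(perfect$stars, 3L)
  nosig <- qualify(pixel_r = NA, dynamic_range = 0)
  expect_equal(nosig$stars, 1L)
  expect_match(paste(nosig$notes, collapse = " "), "no signal")
  poor <- qualify(pixel_r = 0.1, cell_r = 0.5, dynamic_range = 3)
  expect_equal(poor$stars, 1L)
  # strong correlation but compressed dynamic range: flagged down to 2 stars
  narrow <- qualify(pixel_r = 0.9, cell_r = 0.9, core_r = 0.9,
                    core_positivity_r = 0.9, dynamic_range = 0.4)
  expect_equal(narrow$stars, 2L)
  partial <- qualify(pixel_r = 0.95, dynamic_range = 3)
  expect_setequal(partial$absent, c("cell_r", "core_r", "core_positivity_r"))
  expect_match(paste(partial$notes, collapse = " "), "partial")
})

test_that("dynamic range is the robust log-intensity spread", {
  expect_equal(dynamic_range(rep(5, 100)), 0)
  x <- exp(seq(0, 6, length.out = 1001))
  expect_gt(dynamic_range(x), 5)
  expect_gte(dynamic_range(rlnorm(100, 2, 1)), 0)
})
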