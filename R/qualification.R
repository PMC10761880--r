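#' Pixel/cell-level concordance between two antibodies
#'
#' Pearson correlation of log-transformed paired intensities on a seeded
#' uniform subsample of at most `n_sample` pairs (pixel-level concordance
#' conventionally uses 5000 sampled pixels; the same operation serves
#' cell-level concordance on paired per-cell means).
#'
#' @param x,y paired nonnegative intensities of equal length.
#' @param n_sample maximum number of pairs to sample (default 5000).
#' @param seed RNG seed for the subsample.
#' @return Pearson correlation of `log1p(x)` vs `log1p(y)` on the
#'   subsample.
#' @export
concordance <- function(x, y, n_sample = 5000, seed = 1L) {
  if (length(x) != length(y)) stop_("'x' and 'y' must be paired (equal length)")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop_("values must be finite")
  n_sample <- check_count(n_sample, "n_sample", min = 3)
  set.seed(seed)
  idx <- if (length(x) > n_sample) sample.int(length(x), n_sample) else seq_along(x)
  if (length(idx) < 3L) stop_("need at least 3 pairs after sampling")
  lx <- log1p(x[idx]); ly <- log1p(y[idx])
  if (sd(lx) == 0 || sd(ly) == 0) {
    stop_("undefined correlation: zero variance in one of the vectors")
  }
  cor(lx, ly)
}

#' Dynamic range of an antibody's signal
#'
#' Spread of log intensities between the 1st and 99th percentile,
#' a robust measure of how well an antibody separates low- from
#' high-expressing cells.
#'
#' @param x nonnegative intensities (AU).
#' @return `P99 - P1` of `log1p(x)` (log AU, >= 0).
#' @export
dynamic_range <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x))) stop_("'x' must be finite")
  q <- quantile(log1p(x), c(0.01, 0.99), names = FALSE, type = 7)
  q[2] - q[1]
}

#' Per-core summary of a marker
#'
#' Core-level concordance inputs: per core, the mean log intensity
#' (`mean(log1p(x))`) and the positivity ratio after binary gating of the
#' whole table with [gate_marker()].
#'
#' @param cells cell table with a `core_id` column and the marker column.
#' @param marker marker name.
#' @param method gating method passed to [gate_marker()].
#' @param seed gating seed.
#' @return data frame: `core_id`, `n_cells`, `mean_log_intensity`,
#'   `positivity_ratio`.
#' @export
core_summaries <- function(cells, marker, method = "gmm2", seed = 1L) {
  if (!marker %in% names(cells)) {
    stop_("unknown marker '%s': not a column of the cell table", marker)
  }
  if (!"core_id" %in% names(cells)) stop_("cell table needs a 'core_id' column")
  gate <- gate_marker(cells[[marker]], method = method, seed = seed, marker = marker)
  pr <- positivity_ratio(gate$calls, cells$core_id)
  mli <- tapply(log1p(cells[[marker]]), factor(cells$core_id), mean)
  out <- data.frame(core_id = pr$sample_id,
                    n_cells = pr$n_cells,
                    mean_log_intensity = as.numeric(mli[pr$sample_id]),
                    positivity_ratio = pr$ratio,
                    stringsAsFactors = FALSE)
  attr(out, "threshold") <- gate$threshold
  out
}

#' Stratified cross-assay comparison
#'
#' Bins cores by a reference percent-positive score into the standard
#' quartile strata 0-24, 25-49, 50-74 and 75-100 and summarizes a
#' candidate per-core measurement within each stratum. Bins are
#' left-closed/right-open except the last, which includes 100 (so a
#' score of exactly 25 falls in the second bin).
#'
#' @param reference_scores per-core percent positive, in `[0, 100]`.
#' @param candidate_values per-core candidate measurements (same length).
#' @return data frame with one row per bin: `bin`, `n`, `median`, `q1`,
#'   `q3` (quartiles of the candidate values; `NA` for empty bins).
#' @export
stratified_comparison <- function(reference_scores, candidate_values) {
  if (length(reference_scores) != length(candidate_values)) {
    stop_("inputs must have equal length")
  }
  if (any(!is.finite(reference_scores)) ||
      any(reference_scores < 0 | reference_scores > 100)) {
    stop_("reference scores must lie in [0, 100]")
  }
  labs <- c("0-24", "25-49", "50-74", "75-100")
  bin <- findInterval(reference_scores, c(0, 25, 50, 75), rightmost.closed = FALSE)
  bin[reference_scores >= 75] <- 4L   # last bin closed at 100
  out <- data.frame(bin = labs, n = 0L, median = NA_real_,
                    q1 = NA_real_, q3 = NA_real_, stringsAsFactors = FALSE)
  for (b in 1:4) {
    v <- candidate_values[bin == b]
    out$n[b] <- length(v)
    if (length(v) > 0) {
      q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
      out$q1[b] <- q[1]; out$median[b] <- q[2]; out$q3[b] <- q[3]
    }
  }
  out
}

#' Qualify an antibody pair from multi-level concordance metrics
#'
#' Combines pixel-, cell- and core-level correlations and the dynamic
#' range into a 1-3 star verdict for a candidate antibody against its
#' clinical reference: 3 stars when every available correlation reaches
#' `r_high` and the dynamic range reaches `d_min`; 1 star when the
#' pixel-level correlation falls below `r_low`, any correlation is
#' undefined (`NA`, e.g. a constant candidate with no signal), or the
#' dynamic range is degenerate; 2 stars otherwise. Missing levels yield a
#' partial report with the absent fields recorded.
#'
#' @param pixel_r,cell_r,core_r,core_positivity_r Pearson correlations at
#'   each validation level (`NULL` if the level was not measured, `NA` if
#'   measured but undefined).
#' @param dynamic_range candidate dynamic range (log AU), see
#'   [dynamic_range()].
#' @param r_high,r_low star thresholds on the correlations.
#' @param d_min minimum dynamic range for 3 stars (log AU).
#' @param pair optional label ("reference vs candidate").
#' @return object of class `qualification_report`: the metrics, `stars`
#'   (1, 2 or 3), `absent` (character vector of missing levels) and
#'   `notes`.
#' @export
qualify <- function(pixel_r = NULL, cell_r = NULL, core_r = NULL,
                    core_positivity_r = NULL, dynamic_range = NULL,
                    r_high = 0.7, r_low = 0.3, d_min = 1, pair = NULL) {
  metrics <- list(pixel_r = pixel_r, cell_r = cell_r, core_r = core_r,
                  core_positivity_r = core_positivity_r,
                  dynamic_range = dynamic_range)
  absent <- names(metrics)[vapply(metrics, is.null, logical(1))]
  rs <- unlist(metrics[setdiff(names(metrics)[1:4], absent)])
  notes <- character(0)
  if (length(absent)) {
    notes <- c(notes, sprintf("partial report; absent: %s",
                              paste(absent, collapse = ", ")))
  }
  bad <- any(is.na(rs)) ||
    (!is.null(pixel_r) && !is.na(pixel_r) && pixel_r < r_low) ||
    (!is.null(dynamic_range) && !is.na(dynamic_range) && dynamic_range < 1e-6)
  if (any(is.na(rs))) notes <- c(notes, "no signal: undefined correlation")
  stars <- if (bad) {
    1L
  } else if (length(rs) > 0 && all(rs >= r_high) &&
             !is.null(dynamic_range) && !is.na(dynamic_range) &&
             dynamic_range >= d_min) {
    3L
  } else {
    2L
  }
  structure(c(metrics,
              list(stars = stars, absent = absent, notes = notes, pair = pair,
                   thresholds = c(r_high = r_high, r_low = r_low, d_min = d_min))),
            class = "qualification_report")
}

#' @export
print.qualification_report <- function(x, ...) {
  fmt <- function(v) if (is.null(v)) "-" else sprintf("%.3f", v)
  cat(sprintf("Antibody qualification%s: %s\n",
              if (is.null(x$pair)) "" else paste0(" (", x$pair, ")"),
              strrep("*", x$stars)))
  cat(sprintf("  pixel r = %s, cell r = %s, core r = %s, core positivity r = %s, dynamic range = %s\n",
              fmt(x$pixel_r), fmt(x$cell_r), fmt(x$core_r),
              fmt(x$core_positivity_r), fmt(x$dynamic_range)))
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}
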