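#' Generate paired-antibody pixel intensities with known correlation
#'
#' Simulates the paired per-pixel intensities used for pixel-level
#' antibody concordance: two log-normal intensity columns whose latent
#' log intensities have population Pearson correlation `rho`. With
#' `noise_sd = 0` (the default) the log-scale correlation equals `rho`
#' exactly in population; additional log-scale measurement noise on the
#' candidate channel attenuates it to `rho / sqrt(1 + noise_sd^2)`,
#' recorded in the `rho_attained` attribute.
#'
#' @param n_pixels number of pixel pairs (>= 2).
#' @param rho target latent log-scale Pearson correlation, in `[-1, 1]`.
#' @param noise_sd SD of extra log-scale noise on the candidate channel.
#' @param seed RNG seed.
#' @return data frame with columns `reference` and `candidate`
#'   (nonnegative intensities, AU), with attributes `rho` (generative)
#'   and `rho_attained` (population log-scale correlation after noise).
#' @examples
#' pp <- generate_pixel_pairs(1000, rho = 0.8, seed = 1)
#' cor(log1p(pp$reference), log1p(pp$candidate))
#' @export
generate_pixel_pairs <- function(n_pixels, rho, noise_sd = 0, seed = 1L) {
  n_pixels <- check_count(n_pixels, "n_pixels", min = 2)
  if (!is.numeric(rho) || length(rho) != 1L || !is.finite(rho) || abs(rho) > 1) {
    stop_("'rho' must be a correlation in [-1, 1]")
  }
  noise_sd <- check_number(noise_sd, "noise_sd", min = 0)
  seed <- check_count(seed, "seed", min = 0)
  set.seed(seed)
  z1 <- rnorm(n_pixels)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n_pixels)
  if (noise_sd > 0) z2 <- z2 + rnorm(n_pixels, 0, noise_sd)
  out <- data.frame(reference = exp(4 + z1), candidate = exp(4 + z2))
  attr(out, "rho") <- rho
  attr(out, "rho_attained") <- rho / sqrt(1 + noise_sd^2)
  out
}

#' Generate a multi-channel nuclear image fixture with ground truth
#'
#' Draws `n_cells` non-overlapping nuclei as Gaussian blobs in a square
#' image. The first channel is the nuclear (Hoechst) channel; each of the
#' `n_markers` additional channels is constant within each cell's true
#' disc at a known per-cell mean intensity, so downstream quantification
#' can be checked exactly. Centers are placed by rejection sampling with a
#' minimum separation; if the requested count cannot be packed, a
#' capacity error is raised.
#'
#' @param n_cells number of nuclei (0 allowed: empty image and mask).
#' @param image_size side length in pixels.
#' @param n_markers number of marker channels besides the nuclear one.
#' @param blob_sigma Gaussian SD of the nuclear blobs, pixels.
#' @param min_separation minimum center-to-center distance, pixels
#'   (default `5 * blob_sigma`, which keeps expanded cells disjoint).
#' @param seed RNG seed.
#' @return list with `image` (`image_size x image_size x (1 + n_markers)`
#'   array in `[0, 1]` for the nuclear channel, AU for markers; channel
#'   names `Hoechst`, `M1`, ...), `mask` (integer true label mask, discs
#'   of radius `2 * blob_sigma`), and `truth` (data frame: `cell_id`,
#'   0-based centroid `x` (column) and `y` (row), and the true per-cell
#'   mean of each marker channel).
#' @export
generate_image_fixture <- function(n_cells, image_size = 256, n_markers = 2,
                                   blob_sigma = 3, min_separation = 5 * blob_sigma,
                                   seed = 1L) {
  n_cells <- check_count(n_cells, "n_cells", min = 0)
  image_size <- check_count(image_size, "image_size", min = 16)
  n_markers <- check_count(n_markers, "n_markers", min = 0)
  seed <- check_count(seed, "seed", min = 0)
  radius <- 2 * blob_sigma
  margin <- ceiling(radius + 4)
  ch_names <- c("Hoechst", if (n_markers > 0) paste0("M", seq_len(n_markers)))
  img <- array(0, dim = c(image_size, image_size, 1 + n_markers),
               dimnames = list(NULL, NULL, ch_names))
  mask <- matrix(0L, image_size, image_size)
  truth <- data.frame(cell_id = integer(0), x = numeric(0), y = numeric(0))
  for (m in seq_len(n_markers)) truth[[paste0("M", m)]] <- numeric(0)
  if (n_cells == 0L) {
    return(list(image = img, mask = mask, truth = truth))
  }
  set.seed(seed)
  lo <- margin; hi <- image_size - margin
  if (hi <= lo) stop_("cannot place %d cells: image too small", n_cells)
  centers <- matrix(NA_real_, n_cells, 2)
  placed <- 0L
  tries <- 0L
  max_tries <- 2000L * n_cells
  while (placed < n_cells && tries < max_tries) {
    tries <- tries + 1L
    cand <- runif(2, lo, hi)
    if (placed == 0L ||
        min((centers[seq_len(placed), 1] - cand[1])^2 +
            (centers[seq_len(placed), 2] - cand[2])^2) >= min_separation^2) {
      placed <- placed + 1L
      centers[placed, ] <- cand
    }
  }
  if (placed < n_cells) {
    stop_("cannot place %d non-overlapping cells of separation %.1f px in a %d px image (capacity exceeded)",
          n_cells, min_separation, image_size)
  }
  amp <- runif(n_cells, 0.6, 1.0)
  marker_means <- matrix(rlnorm(n_cells * max(1L, n_markers), 4, 0.7),
                         n_cells, max(1L, n_markers))
  rw <- row(mask); cl <- col(mask)
  for (i in seq_len(n_cells)) {
    cy <- centers[i, 1]; cx <- centers[i, 2]   # row, col
    d2 <- (rw - cy)^2 + (cl - cx)^2
    img[, , 1] <- img[, , 1] + amp[i] * exp(-d2 / (2 * blob_sigma^2))
    disc <- d2 <= radius^2
    mask[disc] <- i
    for (m in seq_len(n_markers)) {
      ch <- img[, , m + 1]
      ch[disc] <- marker_means[i, m]
      img[, , m + 1] <- ch
    }
  }
  img[, , 1] <- pmin(img[, , 1], 1)
  truth <- data.frame(cell_id = seq_len(n_cells),
                      x = centers[, 2] - 1,  # 0-based column
                      y = centers[, 1] - 1)  # 0-based row
  for (m in seq_len(n_markers)) truth[[paste0("M", m)]] <- marker_means[, m]
  list(image = img, mask = mask, truth = truth)
}
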