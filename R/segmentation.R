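#' Watershed nuclear segmentation
#'
#' Segments nuclei from a 2-D nuclear-stain (Hoechst) channel: the image
#' is Gaussian-smoothed, foreground is selected by Otsu's threshold, and
#' an intensity watershed seeded at local maxima of the smoothed channel
#' splits touching nuclei. Objects smaller than `min_area` are removed
#' and labels are renumbered consecutively. The result is deterministic
#' for a fixed input.
#'
#' @param nuclear_channel 2-D nonnegative numeric matrix.
#' @param smoothing_sigma Gaussian smoothing SD in pixels (0 disables).
#' @param min_area minimum object area in pixels^2.
#' @param tolerance watershed tolerance (minimum height, on the
#'   max-normalized intensity scale, by which a seed must stand out to
#'   form its own object).
#' @return integer label mask of the same dimensions; 0 is background,
#'   labels are `1..n`. An empty or signal-free image yields an all-zero
#'   mask.
#' @export
segment_nuclei <- function(nuclear_channel, smoothing_sigma = 2,
                           min_area = 20, tolerance = 0.1) {
  if (!is.matrix(nuclear_channel) || !is.numeric(nuclear_channel)) {
    stop_("'nuclear_channel' must be a 2-D numeric matrix")
  }
  if (any(nuclear_channel < 0, na.rm = TRUE)) {
    stop_("'nuclear_channel' must be nonnegative")
  }
  empty <- matrix(0L, nrow(nuclear_channel), ncol(nuclear_channel))
  mx <- suppressWarnings(max(nuclear_channel, na.rm = TRUE))
  if (!is.finite(mx) || mx <= 0) return(empty)
  img <- nuclear_channel / mx
  sm <- if (smoothing_sigma > 0) {
    as.matrix(EBImage::gblur(img, sigma = smoothing_sigma))
  } else {
    img
  }
  sm <- pmax(sm, 0)
  th <- EBImage::otsu(EBImage::Image(sm), range = c(0, 1))
  fg <- sm > th
  if (!any(fg)) return(empty)
  ws <- EBImage::watershed(EBImage::Image(sm * fg), tolerance = tolerance, ext = 1)
  lab <- EBImage::imageData(ws)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area)
  if (length(keep) == 0L) return(empty)
  remap <- integer(length(sizes))
  remap[keep] <- seq_along(keep)
  out <- empty
  nz <- lab > 0
  out[nz] <- remap[lab[nz]]
  storage.mode(out) <- "integer"
  out
}

#' Expand a label mask by a fixed Euclidean distance
#'
#' Dilates every label by Euclidean distance `distance` (the cell
#' boundary around a nuclear mask; 3 px in the standard CyCIF
#' quantification convention). Contested background pixels go to the
#' nearest label, with ties broken deterministically in favour of the
#' lower label ID; original label pixels are never reassigned, so
#' expansion is a partition and label sets stay disjoint.
#'
#' @param mask integer label mask (0 background).
#' @param distance expansion radius in pixels (>= 0).
#' @return expanded label mask of the same dimensions.
#' @export
expand_labels <- function(mask, distance = 3) {
  if (!is.matrix(mask) || !is.numeric(mask)) stop_("'mask' must be a 2-D matrix")
  if (!is.numeric(distance) || length(distance) != 1L || !is.finite(distance) ||
      distance < 0) {
    stop_("'distance' must be a nonnegative number")
  }
  out <- mask
  storage.mode(out) <- "integer"
  if (distance == 0 || !any(mask > 0)) return(out)
  # distance of each background pixel to the nearest labeled pixel
  dm <- EBImage::imageData(EBImage::distmap(EBImage::Image((mask == 0) * 1)))
  cand <- which(mask == 0 & dm <= distance + 1e-9)
  if (length(cand) == 0L) return(out)
  lab_idx <- which(mask > 0)
  lab_coord <- cbind(((lab_idx - 1L) %% nrow(mask)) + 1L,
                     ((lab_idx - 1L) %/% nrow(mask)) + 1L)
  cand_coord <- cbind(((cand - 1L) %% nrow(mask)) + 1L,
                      ((cand - 1L) %/% nrow(mask)) + 1L)
  k <- min(8L, nrow(lab_coord))
  nn <- FNN::get.knnx(lab_coord, cand_coord, k = k)
  labs <- matrix(out[lab_idx][nn$nn.index], nrow = nrow(nn$nn.index))
  within <- nn$nn.dist[, 1] <= distance + 1e-9
  # ties: every neighbour at (numerically) the minimal distance competes;
  # the smallest label ID wins
  tie <- nn$nn.dist <= nn$nn.dist[, 1] + 1e-6
  labs[!tie] <- .Machine$integer.max
  assigned <- do.call(pmin, as.data.frame(labs))
  out[cand[within]] <- assigned[within]
  out
}

#' Quantify per-cell marker intensities from a label mask
#'
#' Computes one record per segmented cell: centroid and nuclear area from
#' the nuclear (pre-expansion) mask, and the mean intensity of every
#' marker channel over the mask expanded by `expand_distance` pixels (so
#' membrane/cytoplasmic signal around the nucleus is captured).
#' Coordinates are 0-based with `x` the column index.
#'
#' @param mask nuclear label mask (see [segment_nuclei()]).
#' @param channels multi-channel image: `h x w x c` array, a single
#'   matrix, or a list of matrices; spatial dimensions must match `mask`.
#' @param marker_names one name per channel.
#' @param expand_distance boundary expansion in pixels (default 3).
#' @return data frame with columns `cell_id`, `x`, `y`, `area` and one
#'   mean-intensity column per marker. Empty mask gives a 0-row table
#'   with the full header.
#' @export
quantify_cells <- function(mask, channels, marker_names, expand_distance = 3) {
  if (!is.matrix(mask)) stop_("'mask' must be a 2-D matrix")
  if (is.list(channels)) channels <- simplify2array(channels)
  if (is.matrix(channels)) channels <- array(channels, dim = c(dim(channels), 1L))
  if (length(dim(channels)) != 3L ||
      !identical(dim(channels)[1:2], dim(mask))) {
    stop_("'channels' must share the 2-D shape of 'mask'")
  }
  if (missing(marker_names) || is.null(marker_names) ||
      length(marker_names) != dim(channels)[3] || anyNA(marker_names) ||
      any(marker_names == "")) {
    stop_("'marker_names' must name every channel")
  }
  n <- max(mask)
  header <- c("cell_id", "x", "y", "area", marker_names)
  if (n == 0L) {
    out <- as.data.frame(setNames(rep(list(numeric(0)), length(header)), header))
    out$cell_id <- integer(0)
    return(out)
  }
  idx <- which(mask > 0)
  lab <- mask[idx]
  rr <- ((idx - 1L) %% nrow(mask)) + 1L
  cc <- ((idx - 1L) %/% nrow(mask)) + 1L
  area <- tabulate(lab, nbins = n)
  cx <- rowsum(cc - 1, lab)[, 1] / area   # 0-based, x = column
  cy <- rowsum(rr - 1, lab)[, 1] / area
  emask <- expand_labels(mask, expand_distance)
  eidx <- which(emask > 0)
  elab <- emask[eidx]
  earea <- tabulate(elab, nbins = n)
  out <- data.frame(cell_id = seq_len(n), x = cx, y = cy, area = area)
  for (ch in seq_along(marker_names)) {
    v <- channels[, , ch]
    out[[marker_names[ch]]] <- rowsum(v[eidx], elab)[, 1] / earea
  }
  rownames(out) <- NULL
  out
}
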