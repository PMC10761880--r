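#' Read a per-cell intensity table from CSV
#'
#' Reads the interchange format for segmented single-cell data: one row
#' per cell with the required columns `cell_id`, `patient_id`, `core_id`,
#' `x`, `y`, `area` plus at least one marker intensity column. Unknown
#' columns are preserved and row order is kept stable. Numeric columns
#' are validated; a non-numeric intensity raises a parse error naming the
#' first offending row.
#'
#' @param path CSV file with a header.
#' @return data frame; marker column names are recorded in the
#'   `"markers"` attribute.
#' @export
read_cell_table <- function(path) {
  d <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  required <- c("cell_id", "patient_id", "core_id", "x", "y", "area")
  miss <- setdiff(required, names(d))
  if (length(miss)) {
    stop_("cell table schema error: missing required column(s) %s",
          paste(sQuote(miss), collapse = ", "))
  }
  # candidate marker columns: every extra column that is numeric or mostly
  # numeric (a mostly-numeric column with stray non-numeric entries is a
  # corrupt intensity column and raises a parse error; a fully non-numeric
  # column is preserved as metadata)
  markers <- character(0)
  for (colname in setdiff(names(d), required)) {
    v <- d[[colname]]
    if (is.numeric(v)) {
      markers <- c(markers, colname)
      next
    }
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) & !is.na(v) & v != "")
    if (length(bad) == 0L) {
      d[[colname]] <- num
      markers <- c(markers, colname)
    } else if (length(bad) <= 0.5 * sum(!is.na(v))) {
      stop_("parse error in column '%s': non-numeric value '%s' at row %d",
            colname, v[bad[1]], bad[1])
    }
  }
  if (length(markers) == 0L) {
    stop_("cell table schema error: need at least one numeric marker column")
  }
  for (colname in c("x", "y", "area")) {
    v <- d[[colname]]
    if (!is.numeric(v)) {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad)) {
        stop_("parse error in column '%s': non-numeric value '%s' at row %d",
              colname, v[bad[1]], bad[1])
      }
      d[[colname]] <- num
    }
  }
  attr(d, "markers") <- markers
  d
}

#' Write a per-cell intensity table to CSV
#'
#' @param cells cell table data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(cells, path) {
  write.csv(cells, path, row.names = FALSE)
  invisible(path)
}

#' Read a clinical table from CSV
#'
#' @param path CSV with a header; a `patient_id` column is required.
#' @return data frame.
#' @export
read_clinical_table <- function(path) {
  d <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"patient_id" %in% names(d)) {
    stop_("clinical table schema error: missing required column 'patient_id'")
  }
  d
}

#' Write a label mask as a 16-bit TIFF
#'
#' @param mask integer label mask (labels up to 65535).
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_mask_tiff <- function(mask, path) {
  if (max(mask) > 65535) stop_("mask labels exceed the 16-bit range")
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a label mask written by [write_mask_tiff()]
#'
#' @param path TIFF path.
#' @return integer label mask.
#' @export
read_mask_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  out <- matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
  out
}

#' Write a multi-channel image as a multi-page 16-bit TIFF
#'
#' Intensities are stored on a linear 16-bit scale; values are clipped to
#' the `[0, max_value]` range.
#'
#' @param image `h x w x c` array (or matrix).
#' @param path output TIFF path.
#' @param max_value intensity mapped to the top of the 16-bit range.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(image, path, max_value = max(image)) {
  if (is.matrix(image)) image <- array(image, c(dim(image), 1L))
  if (max_value <= 0) max_value <- 1
  pages <- lapply(seq_len(dim(image)[3]), function(ch) {
    pmin(pmax(image[, , ch] / max_value, 0), 1)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a single- or multi-page TIFF as an image array
#'
#' @param path TIFF path.
#' @return `h x w x c` numeric array in `[0, 1]`.
#' @export
read_image_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3L) p[, , 1] else p)
  simplify2array(pages)
}
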