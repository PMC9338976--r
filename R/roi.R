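#' Rectangular region of interest
#'
#' ROIs use 0-based, row-major, half-open coordinates: the rectangle covers
#' rows `[row0, row0 + height)` and columns `[col0, col0 + width)` of the
#' image. The default size is a 10 x 10 pixel square, the sampling unit used
#' for segment quantification.
#'
#' @param row0,col0 Top-left corner (0-based).
#' @param height,width Extent in pixels (each at least 1).
#' @param id Optional identifier carried through reports.
#' @return An object of class `icg_roi`.
#' @export
roi <- function(row0, col0, height = 10L, width = 10L, id = NULL) {
  vals <- c(row0 = row0, col0 = col0, height = height, width = width)
  if (anyNA(vals) || any(vals != round(vals)) || row0 < 0 || col0 < 0 ||
      height < 1 || width < 1) {
    abort("ROI needs integer row0, col0 >= 0 and height, width >= 1.",
          class = "icgquant_bad_roi")
  }
  structure(list(row0 = as.integer(row0), col0 = as.integer(col0),
                 height = as.integer(height), width = as.integer(width),
                 id = id),
            class = "icg_roi")
}

#' @export
print.icg_roi <- function(x, ...) {
  cat(sprintf("<roi%s> rows [%d, %d) x cols [%d, %d)\n",
              if (is.null(x$id)) "" else paste0(" ", x$id),
              x$row0, x$row0 + x$height, x$col0, x$col0 + x$width))
  invisible(x)
}

check_roi_bounds <- function(img, r) {
  h <- nrow(img$G); w <- ncol(img$G)
  if (r$row0 + r$height > h || r$col0 + r$width > w) {
    abort(sprintf(
      "ROI%s out of bounds: rows [%d, %d) x cols [%d, %d) exceeds %d x %d image.",
      if (is.null(r$id)) "" else paste0(" '", r$id, "'"),
      r$row0, r$row0 + r$height, r$col0, r$col0 + r$width, h, w),
      class = "icgquant_roi_bounds")
  }
  invisible(TRUE)
}

roi_index_rows <- function(r) (r$row0 + 1L):(r$row0 + r$height)
roi_index_cols <- function(r) (r$col0 + 1L):(r$col0 + r$width)

#' Read an ROI specification file
#'
#' Plain-text CSV with columns `roi_id,row0,col0,height,width` (0-based
#' half-open convention as in [roi()]).
#'
#' @param path CSV path.
#' @return A list of [roi()] objects.
#' @export
read_roi_csv <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("ROI file not found: %s", path), class = "icgquant_io_error")
  }
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("roi_id", "row0", "col0", "height", "width")
  if (!all(need %in% names(df))) {
    abort(sprintf("ROI file %s must have columns %s.", path,
                  paste(need, collapse = ",")),
          class = "icgquant_io_error")
  }
  lapply(seq_len(nrow(df)), function(i) {
    roi(df$row0[i], df$col0[i], df$height[i], df$width[i], id = df$roi_id[i])
  })
}

#' Extract retained green intensities inside an ROI
#'
#' Returns the green-channel values of exactly those pixels inside the
#' rectangle that pass the green-dominance mask, in row-major order.
#'
#' @param img An [rgb_image].
#' @param r An [roi()].
#' @param mask Logical retain matrix, by default computed from `img`.
#' @return Integer vector of length `n_retained` (possibly empty).
#' @export
extract_roi_values <- function(img, r, mask = green_dominance_mask(img)) {
  stopifnot(inherits(img, "rgb_image"), inherits(r, "icg_roi"))
  if (!identical(dim(mask), dim(img$G))) {
    abort("Mask dimensions must match the image.", class = "icgquant_bad_image")
  }
  check_roi_bounds(img, r)
  g <- img$G[roi_index_rows(r), roi_index_cols(r), drop = FALSE]
  m <- mask[roi_index_rows(r), roi_index_cols(r), drop = FALSE]
  # matrices are column-major; transpose to honour the row-major contract
  as.integer(t(g)[t(m)])
}

#' Central-tendency statistics of retained ROI pixels
#'
#' All statistics are computed over the retained (green-dominant) pixels
#' only. The standard deviation uses the n-1 denominator; the median and
#' quartiles use linear interpolation between order statistics
#' (`stats::quantile()` type 7), a convention recorded in report metadata.
#' The histogram has 256 bins indexed by green value 0..255.
#'
#' @param values Integer green intensities of the retained pixels.
#' @param n_total Number of pixels in the rectangle (retained or not).
#' @return An object of class `roi_stats`: list with `n_total`, `n_retained`,
#'   `mean`, `sd`, `median`, `q1`, `q3`, `min`, `max`, `histogram`.
#' @export
roi_statistics <- function(values, n_total) {
  if (length(n_total) != 1L || is.na(n_total) || n_total < 1) {
    abort("`n_total` must be a positive count.", class = "icgquant_bad_roi")
  }
  if (length(values) == 0L) {
    abort("Empty ROI: no retained green-dominant pixels.",
          class = "icgquant_empty_roi")
  }
  if (length(values) > n_total) {
    abort("More retained values than pixels in the rectangle.",
          class = "icgquant_bad_roi")
  }
  if (anyNA(values) || any(values < 0) || any(values > 255)) {
    abort("Green values must lie in [0, 255].", class = "icgquant_bad_roi")
  }
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  structure(list(
    n_total = as.integer(n_total),
    n_retained = length(values),
    mean = mean(values),
    sd = if (length(values) > 1L) sd(values) else 0,
    median = q[2], q1 = q[1], q3 = q[3],
    min = min(values), max = max(values),
    histogram = tabulate(values + 1L, nbins = 256L)
  ), class = "roi_stats")
}

#' @export
print.roi_stats <- function(x, ...) {
  cat(sprintf(
    "<roi_stats> %d/%d pixels retained | mean %.2f sd %.2f | median %.1f [q1 %.1f, q3 %.1f] | range [%d, %d]\n",
    x$n_retained, x$n_total, x$mean, x$sd, x$median, x$q1, x$q3, x$min, x$max))
  invisible(x)
}

#' Quantify a tissue segment over multiple ROIs
#'
#' Computes per-ROI statistics and the pooled segment mean. Pooling is
#' pixel-weighted: the mean of the union of all retained pixel values across
#' all ROIs, never a mean of ROI means, so sparser ROIs contribute in
#' proportion to their retained pixel count. ROIs whose retained fraction
#' falls below `min_retained_fraction` are flagged (`valid = FALSE`) but
#' still pooled; fully masked ROIs contribute nothing.
#'
#' @param img An [rgb_image].
#' @param rois List of [roi()] objects (at least one).
#' @param mask Retain matrix, default [green_dominance_mask()] of `img`.
#' @param min_retained_fraction Minimum fraction of retained pixels for an
#'   ROI to be considered representative (default 0.5).
#' @return A list of class `segment_summary` with elements
#'   `per_roi` (tibble of per-ROI statistics), `pooled_mean`,
#'   `pooled_values`, `n_retained`, `n_total`.
#' @export
quantify_segment <- function(img, rois, mask = green_dominance_mask(img),
                             min_retained_fraction = 0.5) {
  stopifnot(inherits(img, "rgb_image"))
  if (!is.list(rois) || length(rois) == 0L) {
    abort("Provide at least one ROI.", class = "icgquant_bad_roi")
  }
  if (inherits(rois, "icg_roi")) rois <- list(rois)
  per <- vector("list", length(rois))
  pooled <- integer(0)
  for (i in seq_along(rois)) {
    r <- rois[[i]]
    vals <- extract_roi_values(img, r, mask)
    n_tot <- r$height * r$width
    id <- if (is.null(r$id)) paste0("roi", i) else as.character(r$id)
    if (length(vals) == 0L) {
      per[[i]] <- tibble(
        roi_id = id, row0 = r$row0, col0 = r$col0,
        height = r$height, width = r$width,
        n_total = n_tot, n_retained = 0L, retained_fraction = 0,
        valid = FALSE, mean = NA_real_, sd = NA_real_, median = NA_real_,
        q1 = NA_real_, q3 = NA_real_, min = NA_integer_, max = NA_integer_)
      next
    }
    st <- roi_statistics(vals, n_tot)
    per[[i]] <- tibble(
      roi_id = id, row0 = r$row0, col0 = r$col0,
      height = r$height, width = r$width,
      n_total = st$n_total, n_retained = st$n_retained,
      retained_fraction = st$n_retained / st$n_total,
      valid = st$n_retained / st$n_total >= min_retained_fraction,
      mean = st$mean, sd = st$sd, median = st$median,
      q1 = st$q1, q3 = st$q3, min = st$min, max = st$max)
    pooled <- c(pooled, vals)
  }
  if (length(pooled) == 0L) {
    abort("Quantification failed: all ROIs are empty after green-dominance masking.",
          class = "icgquant_empty_roi")
  }
  structure(list(
    per_roi = dplyr::bind_rows(per),
    pooled_mean = mean(pooled),
    pooled_values = pooled,
    n_retained = length(pooled),
    n_total = sum(vapply(rois, function(r) r$height * r$width, integer(1)))
  ), class = "segment_summary")
}

#' @export
print.segment_summary <- function(x, ...) {
  cat(sprintf("<segment_summary> %d ROIs | pooled mean %.4f over %d/%d retained pixels\n",
              nrow(x$per_roi), x$pooled_mean, x$n_retained, x$n_total))
  invisible(x)
}

#' Automatically place non-overlapping sampling squares
#'
#' Emulates the manual placement of sampling squares over areas of uniform
#' vascularization: rejection-samples `n` non-overlapping `size x size`
#' rectangles that (a) avoid near-saturated vessel pixels (any retained
#' pixel with green >= `vessel_cutoff`, default 250, close to the 255
#' ceiling that distorts readings; white specular reflections are already
#' discarded by the mask and are governed by the retained-fraction rule
#' instead) and (b) keep a retained-pixel fraction of at least
#' `min_retained_fraction` under the green-dominance mask. Placement is
#' deterministic for a given seed.
#'
#' @inheritParams quantify_segment
#' @param n Number of ROIs to place.
#' @param size Side length of each square ROI in pixels.
#' @param seed Integer seed controlling placement.
#' @param vessel_cutoff Green level at or above which a pixel is treated as a
#'   saturated vessel and excludes the candidate rectangle.
#' @param max_attempts Total rejection-sampling budget.
#' @return List of `n` [roi()] objects.
#' @export
auto_sample_rois <- function(img, mask = green_dominance_mask(img), n = 10L,
                             size = 10L, seed = 1L,
                             min_retained_fraction = 0.5,
                             vessel_cutoff = 250L,
                             max_attempts = 1000L * n) {
  stopifnot(inherits(img, "rgb_image"))
  h <- nrow(img$G); w <- ncol(img$G)
  if (n < 1 || size < 1) {
    abort("`n` and `size` must be positive.", class = "icgquant_bad_roi")
  }
  if (size > h || size > w) {
    abort(sprintf("Image (%d x %d) too small for %d x %d ROIs.", h, w, size, size),
          class = "icgquant_bad_roi")
  }
  accepted <- list()
  with_seed(seed, {
    attempts <- 0L
    while (length(accepted) < n && attempts < max_attempts) {
      attempts <- attempts + 1L
      r0 <- sample.int(h - size + 1L, 1L) - 1L
      c0 <- sample.int(w - size + 1L, 1L) - 1L
      cand <- roi(r0, c0, size, size, id = paste0("auto", length(accepted) + 1L))
      overlaps <- any(vapply(accepted, function(a) {
        r0 < a$row0 + a$height && a$row0 < r0 + size &&
          c0 < a$col0 + a$width && a$col0 < c0 + size
      }, logical(1)))
      if (overlaps) next
      g <- img$G[roi_index_rows(cand), roi_index_cols(cand)]
      m <- mask[roi_index_rows(cand), roi_index_cols(cand)]
      # saturation cutoff applies to retained pixels: white reflections are
      # already discarded by the mask, vessels (green, near-255) are not
      if (any(g[m] >= vessel_cutoff)) next
      if (mean(m) < min_retained_fraction) next
      accepted[[length(accepted) + 1L]] <- cand
    }
  })
  if (length(accepted) < n) {
    abort(sprintf(
      "ROI sampling failed: placed %d of %d requested ROIs within %d attempts.",
      length(accepted), n, max_attempts),
      class = "icgquant_sampling_failure")
  }
  accepted
}
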