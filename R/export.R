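#' Export retained pixels to CSV
#'
#' One row per retained pixel inside the given ROIs, with 0-based image
#' coordinates: header `row,col,green`. A summary block of central-tendency
#' values is appended as `#`-prefixed comment lines so the data section
#' re-parses losslessly with any CSV reader that honours comments
#' (see [read_pixel_export()]).
#'
#' @inheritParams quantify_segment
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_pixels <- function(img, rois, path, mask = green_dominance_mask(img)) {
  stopifnot(inherits(img, "rgb_image"))
  if (inherits(rois, "icg_roi")) rois <- list(rois)
  rows <- integer(0); cols <- integer(0); greens <- integer(0)
  for (r in rois) {
    check_roi_bounds(img, r)
    m <- mask[roi_index_rows(r), roi_index_cols(r), drop = FALSE]
    g <- img$G[roi_index_rows(r), roi_index_cols(r), drop = FALSE]
    idx <- which(t(m))                       # row-major within the rectangle
    if (length(idx) == 0L) next
    rr <- (idx - 1L) %/% r$width             # local 0-based row
    cc <- (idx - 1L) %% r$width
    rows <- c(rows, r$row0 + rr)
    cols <- c(cols, r$col0 + cc)
    greens <- c(greens, t(g)[idx])
  }
  if (length(greens) == 0L) {
    abort("Nothing to export: no retained pixels in the given ROIs.",
          class = "icgquant_empty_roi")
  }
  con <- tryCatch(file(path, "w"),
                  error = function(e) abort(
                    sprintf("Cannot write pixel export to %s: %s", path,
                            conditionMessage(e)),
                    class = "icgquant_io_error"))
  on.exit(close(con))
  writeLines("row,col,green", con)
  writeLines(paste(rows, cols, greens, sep = ","), con)
  st <- roi_statistics(greens, sum(vapply(rois, function(r) r$height * r$width,
                                          integer(1))))
  writeLines(c(
    sprintf("# n_total,%d", st$n_total),
    sprintf("# n_retained,%d", st$n_retained),
    sprintf("# mean,%.10g", st$mean),
    sprintf("# sd,%.10g", st$sd),
    sprintf("# median,%.10g", st$median),
    sprintf("# q1,%.10g", st$q1),
    sprintf("# q3,%.10g", st$q3),
    sprintf("# min,%d", st$min),
    sprintf("# max,%d", st$max),
    "# quartile_convention,linear interpolation (type 7)"
  ), con)
  invisible(path)
}

#' Re-read a pixel export written by [export_pixels()]
#'
#' @param path CSV path.
#' @return Tibble with integer columns `row`, `col`, `green`.
#' @export
read_pixel_export <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Pixel export not found: %s", path), class = "icgquant_io_error")
  }
  as_tibble(read.csv(path, comment.char = "#"))
}

roi_overlay <- function(img, rois, colour = c(255L, 255L, 0L)) {
  out <- img
  for (r in rois) {
    rows <- roi_index_rows(r); cols <- roi_index_cols(r)
    border_r <- c(rep(rows[1], length(cols)), rep(rows[length(rows)], length(cols)),
                  rows, rows)
    border_c <- c(cols, cols, rep(cols[1], length(rows)),
                  rep(cols[length(cols)], length(rows)))
    idx <- cbind(border_r, border_c)
    out$R[idx] <- colour[1]; out$G[idx] <- colour[2]; out$B[idx] <- colour[3]
  }
  out
}

#' Render a quantification report bundle
#'
#' Writes, into `out_dir`: `overlay.png` (the image with ROI rectangles
#' drawn on it, same dimensions as the input), `boxplot.png` (per-ROI
#' distribution of retained green values), `histogram.png` (pooled retained
#' values), and `summary.json` (central-tendency values plus the statistical
#' conventions used).
#'
#' @inheritParams quantify_segment
#' @param summary A `segment_summary` from [quantify_segment()]; computed if
#'   omitted.
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of the four file paths, invisibly.
#' @export
render_report <- function(img, rois, out_dir,
                          mask = green_dominance_mask(img),
                          summary = quantify_segment(img, rois, mask)) {
  stopifnot(inherits(img, "rgb_image"), inherits(summary, "segment_summary"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("Cannot create output directory %s.", out_dir),
                   class = "icgquant_io_error")
  }
  if (inherits(rois, "icg_roi")) rois <- list(rois)
  paths <- c(overlay = file.path(out_dir, "overlay.png"),
             boxplot = file.path(out_dir, "boxplot.png"),
             histogram = file.path(out_dir, "histogram.png"),
             summary = file.path(out_dir, "summary.json"))

  write_image(roi_overlay(img, rois), paths[["overlay"]])

  per_pixel <- dplyr::bind_rows(lapply(seq_along(rois), function(i) {
    vals <- extract_roi_values(img, rois[[i]], mask)
    if (length(vals) == 0L) return(NULL)
    id <- if (is.null(rois[[i]]$id)) paste0("roi", i) else as.character(rois[[i]]$id)
    tibble(roi_id = id, green = vals)
  }))
  p_box <- ggplot2::ggplot(per_pixel, ggplot2::aes(x = .data$roi_id, y = .data$green)) +
    ggplot2::geom_boxplot(fill = "darkseagreen") +
    ggplot2::labs(x = "ROI", y = "Green intensity (0-255)",
                  title = "Retained green intensity per ROI") +
    ggplot2::theme_minimal()
  ggplot2::ggsave(paths[["boxplot"]], p_box, width = 6, height = 4, dpi = 120)

  p_hist <- ggplot2::ggplot(tibble(green = summary$pooled_values),
                            ggplot2::aes(x = .data$green)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "darkgreen") +
    ggplot2::labs(x = "Green intensity (0-255)", y = "Pixel count",
                  title = "Pooled retained green intensities") +
    ggplot2::theme_minimal()
  ggplot2::ggsave(paths[["histogram"]], p_hist, width = 6, height = 4, dpi = 120)

  pooled_stats <- roi_statistics(summary$pooled_values, summary$n_total)
  jsonlite::write_json(list(
    pooled_mean = summary$pooled_mean,
    n_retained = summary$n_retained,
    n_total = summary$n_total,
    median = pooled_stats$median, q1 = pooled_stats$q1, q3 = pooled_stats$q3,
    sd = pooled_stats$sd, min = pooled_stats$min, max = pooled_stats$max,
    conventions = list(
      dominance_rule = "G strictly greater than R and B; ties discarded",
      quartiles = "linear interpolation (type 7)",
      sd = "sample (n-1)",
      pooling = "pixel-weighted union across ROIs",
      coordinates = "0-based, row-major, half-open rectangles"
    ),
    per_roi = summary$per_roi
  ), paths[["summary"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(paths)
}
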