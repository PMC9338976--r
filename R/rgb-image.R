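#' 8-bit RGB image container
#'
#' An `rgb_image` holds the three colour channels of an 8-bit RGB raster as
#' integer matrices on the 0--255 decimal scale, one value per pixel per
#' channel. Row 1 is the top of the image; column 1 is the left edge.
#'
#' @param R,G,B Integer matrices of identical dimensions with values in
#'   \[0, 255\].
#'
#' @return An object of class `rgb_image`: a list with elements `R`, `G`, `B`.
#' @examples
#' img <- rgb_image(
#'   R = matrix(0L, 2, 2), G = matrix(255L, 2, 2), B = matrix(0L, 2, 2)
#' )
#' dim(img)
#' @export
rgb_image <- function(R, G, B) {
  chans <- list(R = R, G = G, B = B)
  for (nm in names(chans)) {
    ch <- chans[[nm]]
    if (!is.matrix(ch) || !is.numeric(ch)) {
      abort(sprintf("Channel %s must be a numeric matrix.", nm),
            class = "icgquant_bad_image")
    }
    if (anyNA(ch) || any(ch < 0) || any(ch > 255) || any(ch != round(ch))) {
      abort(sprintf("Channel %s must contain integers in [0, 255].", nm),
            class = "icgquant_bad_image")
    }
  }
  if (!identical(dim(R), dim(G)) || !identical(dim(G), dim(B))) {
    abort("All three channel matrices must have identical dimensions.",
          class = "icgquant_bad_image")
  }
  if (nrow(R) < 1L || ncol(R) < 1L) {
    abort("Image must have at least one row and one column.",
          class = "icgquant_bad_image")
  }
  structure(
    list(R = matrix(as.integer(R), nrow(R)),
         G = matrix(as.integer(G), nrow(G)),
         B = matrix(as.integer(B), nrow(B))),
    class = "rgb_image"
  )
}

#' @export
dim.rgb_image <- function(x) dim(x$G)

#' @export
print.rgb_image <- function(x, ...) {
  cat(sprintf("<rgb_image> %d x %d pixels, 8-bit RGB\n", nrow(x$G), ncol(x$G)))
  invisible(x)
}

#' Load an 8-bit RGB image from PNG or JPEG
#'
#' Decodes the file and splits it into its red, green and blue channel
#' matrices on the 0--255 scale. An alpha channel, if present, is dropped
#' with a warning. Greyscale rasters and bit depths other than 8 per channel
#' are rejected. JPEG support requires the optional \pkg{jpeg} package;
#' lossless PNG is recommended for any quantitative workflow.
#'
#' @param path Path to a `.png`, `.jpg` or `.jpeg` file.
#' @return An [rgb_image].
#' @export
load_image <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    abort(sprintf("Cannot read image: file not found: %s", path),
          class = "icgquant_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  arr <- if (ext == "png") {
    dat <- tryCatch(png::readPNG(path, info = TRUE),
                    error = function(e) abort(
                      sprintf("Failed to decode PNG at %s: %s", path, conditionMessage(e)),
                      class = "icgquant_io_error"))
    info <- attr(dat, "info")
    if (!is.null(info$bit.depth) && info$bit.depth != 8L) {
      abort(sprintf("Unsupported bit depth %d in %s: only 8 bits per channel supported.",
                    info$bit.depth, path),
            class = "icgquant_unsupported_format")
    }
    dat
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("jpeg", quietly = TRUE)) {
      abort("JPEG support requires the 'jpeg' package.",
            class = "icgquant_unsupported_format")
    }
    tryCatch(jpeg::readJPEG(path),
             error = function(e) abort(
               sprintf("Failed to decode JPEG at %s: %s", path, conditionMessage(e)),
               class = "icgquant_io_error"))
  } else {
    abort(sprintf("Unsupported image format '.%s' (%s): use PNG or JPEG.", ext, path),
          class = "icgquant_unsupported_format")
  }

  if (length(dim(arr)) == 2L) {
    abort(sprintf("Greyscale image not supported (%s): an RGB raster is required.", path),
          class = "icgquant_unsupported_format")
  }
  nch <- dim(arr)[3]
  if (nch == 4L) {
    warn(sprintf("Alpha channel in %s dropped.", path))
  } else if (nch != 3L) {
    abort(sprintf("Expected 3 or 4 channels, found %d in %s.", nch, path),
          class = "icgquant_unsupported_format")
  }
  to255 <- function(k) matrix(as.integer(round(arr[, , k] * 255)),
                              dim(arr)[1], dim(arr)[2])
  rgb_image(to255(1), to255(2), to255(3))
}

#' Write an [rgb_image] to a PNG file
#'
#' Lossless round trip: reloading the file with [load_image()] reproduces the
#' channel matrices exactly.
#'
#' @param img An [rgb_image].
#' @param path Output path ending in `.png`.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  stopifnot(inherits(img, "rgb_image"))
  arr <- array(0, dim = c(nrow(img$G), ncol(img$G), 3))
  arr[, , 1] <- img$R / 255
  arr[, , 2] <- img$G / 255
  arr[, , 3] <- img$B / 255
  tryCatch(png::writePNG(arr, target = path),
           error = function(e) abort(
             sprintf("Failed to write PNG to %s: %s", path, conditionMessage(e)),
             class = "icgquant_io_error"))
  invisible(path)
}
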