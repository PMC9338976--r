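#' Green-dominance pixel filter
#'
#' Classifies each pixel by its predominant colour and retains only those
#' whose green channel strictly exceeds both the red and the blue channel.
#' Ties are discarded, so neutral greys and pure white specular reflections
#' (R = G = B = 255) are never retained; this is what protects the ICG
#' intensity readout from false readings caused by reflections of the light
#' source on wet tissue.
#'
#' @param img An [rgb_image].
#' @return A logical matrix with the image's dimensions; `TRUE` marks a
#'   retained (green-dominant) pixel.
#' @examples
#' img <- rgb_image(matrix(10L), matrix(200L), matrix(30L))
#' green_dominance_mask(img)
#' @export
green_dominance_mask <- function(img) {
  if (!inherits(img, "rgb_image")) {
    abort("`img` must be an rgb_image.", class = "icgquant_bad_image")
  }
  img$G > img$R & img$G > img$B
}
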