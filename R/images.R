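#' Load a grayscale image as a \[0, 1\] intensity matrix
#'
#' Reads an 8-bit grayscale PNG or JPEG and returns a numeric matrix with
#' intensities in \[0, 1\] (8-bit values divided by 255). Multi-channel
#' images are collapsed by averaging the channels.
#'
#' @param path path to a PNG or JPEG file.
#' @return numeric matrix, rows = image rows.
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop_decreg("image file not found: %s", path)
  img <- EBImage::readImage(path)
  px <- EBImage::imageData(img)
  if (length(dim(px)) == 3) px <- apply(px, c(1, 2), mean)
  # EBImage stores the x axis first; transpose to row-major matrix convention
  t(px)
}

#' Write an intensity matrix as an 8-bit grayscale PNG
#'
#' @param pixels numeric matrix in \[0, 1\].
#' @param path output path (extension selects PNG/JPEG).
#' @return `path`, invisibly.
#' @export
save_image <- function(pixels, path) {
  type <- if (grepl("\\.jpe?g$", path, ignore.case = TRUE)) "jpeg" else "png"
  EBImage::writeImage(t(pixels), path, type = type, bits.per.sample = 8L)
  invisible(path)
}

# round-half-away-from-zero; base round() rounds half to even
#' @noRd
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Resize and center-crop an image
#'
#' Standard preprocessing for decision-region analysis: bilinear resize so the
#' shortest image dimension equals `short_side` (the other dimension scales by
#' the same factor, rounded half away from zero), followed by a centered crop
#' to `crop` x `crop` pixels. With the defaults every image becomes 320 x 320.
#' On odd crop remainders the offset is `floor((dim - crop)/2)`, i.e. the crop
#' window sits one pixel closer to the top/left edge.
#'
#' @param pixels numeric matrix (2-D).
#' @param short_side target length of the shortest dimension after resizing.
#' @param crop side length of the final square crop; must not exceed
#'   `short_side`.
#' @return a `crop` x `crop` numeric matrix.
#' @examples
#' dim(preprocess_image(matrix(0.5, 480, 640)))  # 320 320
#' @export
preprocess_image <- function(pixels, short_side = 320L, crop = 320L) {
  if (!is.matrix(pixels)) stop_decreg("pixels must be a 2-D matrix")
  if (crop > short_side) stop_decreg("crop (%d) exceeds short_side (%d)",
                                     crop, short_side)
  h <- nrow(pixels); w <- ncol(pixels)
  if (min(h, w) != short_side) {
    scale <- short_side / min(h, w)
    if (h <= w) {
      nh <- as.integer(short_side)
      nw <- as.integer(round_half_away(w * scale))
    } else {
      nw <- as.integer(short_side)
      nh <- as.integer(round_half_away(h * scale))
    }
    # EBImage's first dimension is x; our matrices are [row, col], so w maps
    # to rows here. Bilinear is the default filter.
    pixels <- EBImage::resize(pixels, w = nh, h = nw, filter = "bilinear")
  }
  h <- nrow(pixels); w <- ncol(pixels)
  r0 <- (h - crop) %/% 2L
  c0 <- (w - crop) %/% 2L
  pixels[(r0 + 1L):(r0 + crop), (c0 + 1L):(c0 + crop), drop = FALSE]
}
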