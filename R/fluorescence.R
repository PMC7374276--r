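#' Convert an image to grayscale
#'
#' RGB images are converted with the ITU-R BT.601 luma weights
#' `0.299 R + 0.587 G + 0.114 B`, rounded to the nearest integer; grayscale
#' images are returned unchanged.
#'
#' @param img A [raster_image()].
#' @return A 1-channel [raster_image()].
#' @export
to_grayscale <- function(img) {
  stopifnot(inherits(img, "raster_image"))
  if (img$channels == 1L) return(img)
  g <- round(0.299 * img$pixels[, , 1] + 0.587 * img$pixels[, , 2] +
             0.114 * img$pixels[, , 3])
  raster_image(matrix(as.integer(g), img$height, img$width),
               source_path = img$source_path)
}

#' Binarize the red channel at an intensity threshold
#'
#' The mask is `red >= threshold` (inclusive comparison; set
#' `inclusive = FALSE` for a strict `>`). Fluorescent-positive cells are
#' counted by applying this mask to the grayscale image and running the
#' ordinary counting model on the result.
#'
#' @param img An RGB [raster_image()] (grayscale input is an error: there is
#'   no red channel to threshold).
#' @param threshold Integer in `[0, 255]`.
#' @param inclusive Use `>=` (default) rather than `>`.
#' @return Logical `H x W` matrix.
#' @export
red_mask <- function(img, threshold, inclusive = TRUE) {
  stopifnot(inherits(img, "raster_image"))
  if (img$channels != 3L)
    stop("red_mask requires an RGB image (grayscale has no red channel)")
  threshold <- as.integer(threshold)
  if (is.na(threshold) || threshold < 0L || threshold > 255L)
    stop("red threshold must be an integer in [0, 255], got ", threshold)
  red <- matrix(img$pixels[, , 1], img$height, img$width)
  if (inclusive) red >= threshold else red > threshold
}

#' Apply a binary mask to a grayscale image
#'
#' Pixels outside the mask are set to 0, the background value of
#' phase-contrast-dark frames.
#'
#' @param img A 1-channel [raster_image()].
#' @param mask Logical `H x W` matrix.
#' @return A masked 1-channel [raster_image()].
#' @export
apply_mask <- function(img, mask) {
  stopifnot(inherits(img, "raster_image"), img$channels == 1L,
            is.logical(mask), all(dim(mask) == c(img$height, img$width)))
  px <- img$pixels
  ch <- matrix(px[, , 1], img$height, img$width)
  ch[!mask] <- 0L
  px[, , 1] <- ch
  raster_image(px)
}

#' Count red-fluorescent cells
#'
#' Binarizes the red channel at `threshold`, applies the mask to the
#' grayscale image (masked-out pixels set to 0), then tiles, pads and counts
#' exactly as [count_frame()]. At threshold 0 the mask passes everything and
#' the result equals `count_frame` on the grayscale image.
#'
#' @param model Trained model.
#' @param img An RGB [raster_image()].
#' @param threshold Red intensity threshold in `[0, 255]`; the service
#'   default is 100.
#' @param spec Optional [count_map_spec()] override.
#' @return Numeric scalar count of red-positive cells (unrounded).
#' @export
count_red <- function(model, img, threshold = 100L, spec = NULL) {
  stopifnot(inherits(img, "raster_image"))
  mask <- red_mask(img, threshold)
  masked <- apply_mask(to_grayscale(img), mask)
  count_frame(model, masked, spec)
}

#' Percentage of red-fluorescent cells
#'
#' @param total Total cell count (must be positive).
#' @param red Red-positive cell count.
#' @return `100 * red / total`.
#' @export
percent_red <- function(total, red) {
  if (!is.finite(total) || total <= 0)
    stop("percentage undefined: total count must be positive, got ", total)
  100 * red / total
}
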