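#' Raster image container
#'
#' An 8-bit raster image held as an integer array of shape
#' `height x width x channels` with intensities in `[0, 255]`. Channel order
#' is red-green-blue for colour images regardless of the file dialect, so
#' "red channel" always means channel 1.
#'
#' @param pixels Integer matrix (`H x W`) or array (`H x W x C`) with values
#'   in `[0, 255]`; `C` must be 1 or 3.
#' @param source_path Optional provenance string.
#'
#' @return An object of class `raster_image` with fields `pixels`
#'   (`H x W x C` integer array), `height`, `width`, `channels`,
#'   `source_path`.
#' @export
raster_image <- function(pixels, source_path = NULL) {
  if (is.matrix(pixels)) dim(pixels) <- c(dim(pixels), 1L)
  if (!is.array(pixels) || length(dim(pixels)) != 3L)
    stop("`pixels` must be an H x W or H x W x C array")
  d <- dim(pixels)
  if (!d[3] %in% c(1L, 3L))
    stop("channels must be 1 (grayscale) or 3 (RGB), got ", d[3])
  if (d[1] < 1L || d[2] < 1L) stop("image extents must be at least 1 x 1")
  storage.mode(pixels) <- "integer"
  if (anyNA(pixels) || min(pixels) < 0L || max(pixels) > 255L)
    stop("intensities must be integers in [0, 255]")
  structure(
    list(pixels = pixels, height = d[1], width = d[2], channels = d[3],
         source_path = source_path),
    class = "raster_image"
  )
}

#' @export
print.raster_image <- function(x, ...) {
  cat(sprintf("<raster_image %d x %d x %d (8-bit)%s>\n",
              x$height, x$width, x$channels,
              if (is.null(x$source_path)) "" else paste0(" ", x$source_path)))
  invisible(x)
}

#' @export
dim.raster_image <- function(x) dim(x$pixels)

#' Test two images for pixel-identical content
#' @param a,b `raster_image` objects.
#' @return Logical scalar.
#' @export
images_identical <- function(a, b) {
  identical(dim(a$pixels), dim(b$pixels)) && all(a$pixels == b$pixels)
}

## tiff/png work in [0,1] doubles; files are 8-bit so the scale factor is 255.
.from_unit <- function(x) {
  x <- round(x * 255)
  storage.mode(x) <- "integer"
  x
}

#' Read an 8-bit TIFF or PNG image
#'
#' Only 8-bit files are accepted: the fluorescence thresholds used downstream
#' are defined on the 0-255 scale, so deeper files are rejected rather than
#' silently rescaled. RGBA alpha channels are likewise rejected.
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file, or a raw vector
#'   holding the encoded bytes of one (the format is then sniffed from the
#'   magic number).
#' @return A [raster_image()].
#' @export
read_image <- function(path) {
  if (is.raw(path)) {
    bytes <- path
    src <- NULL
  } else {
    if (!file.exists(path)) stop("file not found: ", path)
    bytes <- readBin(path, "raw", file.info(path)$size)
    src <- path
  }
  if (length(bytes) < 8L) stop("not a readable TIFF or PNG file")
  is_png  <- identical(as.integer(bytes[1:4]), c(137L, 80L, 78L, 71L))
  is_tiff <- identical(as.integer(bytes[1:2]), c(73L, 73L)) ||
             identical(as.integer(bytes[1:2]), c(77L, 77L))
  if (is_png) {
    ## read as native to inspect true bit depth before decoding to doubles
    meta <- attr(png::readPNG(bytes, info = TRUE), "info")
    if (!is.null(meta$bit.depth) && meta$bit.depth != 8)
      stop("unsupported bit depth: ", meta$bit.depth, " (only 8-bit supported)")
    arr <- png::readPNG(bytes)
  } else if (is_tiff) {
    arr <- tiff::readTIFF(bytes, info = TRUE)
    info <- attributes(arr)
    depth <- info$bits.per.sample
    if (!is.null(depth) && any(depth != 8))
      stop("unsupported bit depth: ", paste(depth, collapse = "/"),
           " (only 8-bit supported)")
  } else {
    stop("not a readable TIFF or PNG file")
  }
  if (is.matrix(arr)) dim(arr) <- c(dim(arr), 1L)
  nc <- dim(arr)[3]
  if (nc == 4L) stop("alpha channels are not supported (got RGBA)")
  if (nc == 2L) stop("gray+alpha images are not supported")
  raster_image(.from_unit(arr), source_path = src)
}

#' Write an image losslessly as 8-bit TIFF or PNG
#'
#' The format is chosen from the file extension. Writing then reading back
#' reproduces the pixel grid bit-exactly.
#'
#' @param img A [raster_image()].
#' @param path Output path ending in `.tif`, `.tiff` or `.png`.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  stopifnot(inherits(img, "raster_image"))
  if (!dir.exists(dirname(path))) stop("directory does not exist: ", dirname(path))
  arr <- img$pixels / 255
  if (dim(arr)[3] == 1L) dim(arr) <- dim(arr)[1:2]
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(arr, path, bits.per.sample = 8L, compression = "none")
  } else if (ext == "png") {
    png::writePNG(arr, path)
  } else {
    stop("unsupported extension: .", ext, " (use .tif/.tiff/.png)")
  }
  invisible(path)
}

#' Point annotations: one-pixel cell marks
#'
#' Cells are annotated by a single pixel each, as `(row, col)` pairs,
#' 0-based, row increasing downward. Duplicate marks are permitted (two
#' cells may share a pixel) but flagged with a warning.
#'
#' @param points Integer matrix with columns `row`, `col` (0 or more rows),
#'   or a data.frame with those columns.
#' @param frame_height,frame_width Extents of the frame the points refer to.
#' @return An object of class `point_annotations` with fields `points`
#'   (n x 2 integer matrix, columns `row`, `col`), `frame_height`,
#'   `frame_width`.
#' @export
point_annotations <- function(points, frame_height, frame_width) {
  if (is.data.frame(points)) points <- as.matrix(points[, c("row", "col")])
  if (is.null(points) || length(points) == 0L)
    points <- matrix(integer(), ncol = 2L)
  if (ncol(points) != 2L) stop("`points` must have two columns (row, col)")
  storage.mode(points) <- "integer"
  colnames(points) <- c("row", "col")
  frame_height <- as.integer(frame_height); frame_width <- as.integer(frame_width)
  if (nrow(points) > 0L) {
    bad <- which(points[, 1] < 0L | points[, 1] >= frame_height |
                 points[, 2] < 0L | points[, 2] >= frame_width)
    if (length(bad) > 0L)
      stop(sprintf("annotation %d at (%d, %d) is outside the %d x %d frame",
                   bad[1], points[bad[1], 1], points[bad[1], 2],
                   frame_height, frame_width))
    if (anyDuplicated(points))
      warning("duplicate annotation pixels present (cells sharing a mark)")
  }
  structure(list(points = points, frame_height = frame_height,
                 frame_width = frame_width),
            class = "point_annotations")
}

#' @export
print.point_annotations <- function(x, ...) {
  cat(sprintf("<point_annotations: %d cells on a %d x %d frame>\n",
              nrow(x$points), x$frame_height, x$frame_width))
  invisible(x)
}

#' Number of annotated cells
#' @param ann A [point_annotations()].
#' @return Integer count.
#' @export
n_cells <- function(ann) nrow(ann$points)

#' Read point annotations from CSV
#'
#' Expects a header `row,col` and one record per cell, 0-based coordinates.
#' Every point is validated against the frame extents; the upper bound is
#' exclusive (a point at `row == frame_height` is an error).
#'
#' @param path CSV path.
#' @param frame_height,frame_width Frame extents the points must fall in.
#' @return A [point_annotations()].
#' @export
read_annotations <- function(path, frame_height, frame_width) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path)
  if (!all(c("row", "col") %in% names(df)))
    stop("annotation CSV must have a header with columns `row,col`")
  point_annotations(df, frame_height, frame_width)
}

#' Write point annotations to CSV
#' @param ann A [point_annotations()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  stopifnot(inherits(ann, "point_annotations"))
  utils::write.csv(as.data.frame(ann$points), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
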