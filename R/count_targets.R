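#' Count-map specification
#'
#' Fixes the square kernel of ones that defines the redundant count map: an
#' annotated cell contributes 1 to every map pixel whose k x k window covers
#' its mark, i.e. to exactly `k^2` pixels. The pad `p = (k - 1) / 2` is the
#' zero border added to images so that cells near the frame border are seen
#' by a full window.
#'
#' @param kernel_size Odd positive integer `k`; default 65.
#' @return An object of class `count_map_spec` with fields `kernel_size`,
#'   `pad` (`(k-1)/2`) and `kernel_area` (`k^2`).
#' @export
count_map_spec <- function(kernel_size = 65L) {
  k <- as.integer(kernel_size)
  if (is.na(k) || k < 1L || k %% 2L == 0L)
    stop("kernel_size must be an odd positive integer, got ", kernel_size)
  structure(list(kernel_size = k, pad = (k - 1L) %/% 2L,
                 kernel_area = k * k),
            class = "count_map_spec")
}

#' @export
print.count_map_spec <- function(x, ...) {
  cat(sprintf("<count_map_spec: kernel %d x %d = %d, pad %d>\n",
              x$kernel_size, x$kernel_size, x$kernel_area, x$pad))
  invisible(x)
}

#' Redundant count map
#'
#' A non-negative real grid of shape `(H + 2p) x (W + 2p)` for a source
#' frame `H x W`. Target maps (built from annotations) are integer-valued;
#' prediction maps (network output) are arbitrary non-negative reals.
#'
#' @param values Numeric matrix, all values `>= 0`.
#' @param spec A [count_map_spec()].
#' @param kind `"target"` or `"prediction"`.
#' @return An object of class `count_map`.
#' @export
count_map <- function(values, spec, kind = c("target", "prediction")) {
  kind <- match.arg(kind)
  stopifnot(inherits(spec, "count_map_spec"), is.matrix(values))
  if (any(values < 0)) stop("count-map values must be non-negative")
  if (kind == "target" && any(abs(values - round(values)) > 1e-9))
    stop("target count maps must be integer-valued")
  structure(list(values = values, spec = spec, kind = kind),
            class = "count_map")
}

#' @export
print.count_map <- function(x, ...) {
  cat(sprintf("<count_map (%s) %d x %d, kernel %d, sum %.1f -> count %.2f>\n",
              x$kind, nrow(x$values), ncol(x$values), x$spec$kernel_size,
              sum(x$values), infer_count(x)))
  invisible(x)
}

#' Pad an image with a zero border
#'
#' Adds `p` zero pixels on every side in every channel, so an `H x W` image
#' becomes `(H + 2p) x (W + 2p)`. Applied before prediction so border cells
#' fall inside full receptive fields.
#'
#' @param img A [raster_image()].
#' @param p Non-negative integer border width.
#' @return A padded [raster_image()].
#' @export
pad_image <- function(img, p) {
  stopifnot(inherits(img, "raster_image"))
  p <- as.integer(p)
  if (is.na(p) || p < 0L) stop("pad must be a non-negative integer")
  if (p == 0L) return(img)
  out <- array(0L, dim = c(img$height + 2L * p, img$width + 2L * p,
                           img$channels))
  out[(p + 1L):(p + img$height), (p + 1L):(p + img$width), ] <- img$pixels
  raster_image(out, source_path = img$source_path)
}

#' Build the redundant count-map target from point annotations
#'
#' Output pixel `(i, j)` of the `(H + 2p) x (W + 2p)` grid counts the
#' annotated points `(r, c)` with `|r + p - i| <= p` and `|c + p - j| <= p`
#' (full-convolution extent), so every point contributes to exactly `k^2`
#' pixels and `sum(values) = k^2 * n_points`. Computed with a separable
#' box filter over the point-mass image.
#'
#' @param ann A [point_annotations()].
#' @param spec A [count_map_spec()].
#' @return A [count_map()] of kind `"target"`.
#' @export
make_count_target <- function(ann, spec) {
  stopifnot(inherits(ann, "point_annotations"), inherits(spec, "count_map_spec"))
  p <- spec$pad; k <- spec$kernel_size
  H <- ann$frame_height; W <- ann$frame_width
  Hp <- H + 2L * p; Wp <- W + 2L * p
  ## point masses on the padded grid (1-based: point (r,c) -> (r+p+1, c+p+1))
  mass <- matrix(0, Hp, Wp)
  if (n_cells(ann) > 0L) {
    idx <- cbind(ann$points[, 1] + p + 1L, ann$points[, 2] + p + 1L)
    for (i in seq_len(nrow(idx))) mass[idx[i, 1], idx[i, 2]] <-
      mass[idx[i, 1], idx[i, 2]] + 1
  }
  vals <- .box_filter(mass, p)
  count_map(vals, spec, kind = "target")
}

## same-extent box sum of half-width p via separable running sums
.box_filter <- function(m, p) {
  if (p == 0L) return(m)
  m <- apply(m, 2L, .running_sum, p = p)
  t(apply(m, 1L, .running_sum, p = p))
}

.running_sum <- function(v, p) {
  n <- length(v)
  cs <- cumsum(c(0, v))
  hi <- pmin(n, seq_len(n) + p)
  lo <- pmax(0L, seq_len(n) - p - 1L)
  cs[hi + 1L] - cs[lo + 1L]
}

#' Infer the cell count from a count map
#'
#' The redundant map counts every cell once per covering pixel (`k^2`
#' times), so the count is the map sum divided by the kernel area. The
#' result is an unrounded real; rounding is presentation-only because
#' fractional per-pixel errors cancel across images.
#'
#' @param cm A [count_map()].
#' @return Numeric scalar count.
#' @export
infer_count <- function(cm) {
  stopifnot(inherits(cm, "count_map"))
  sum(cm$values) / cm$spec$kernel_area
}

#' Rotate an image together with its annotations
#'
#' Counter-clockwise rotation by 90, 180 or 270 degrees, the augmentation
#' applied to training tiles. A point `(r, c)` on an `H x W` frame maps to
#' `(W - 1 - c, r)` for 90, `(H - 1 - r, W - 1 - c)` for 180 and
#' `(c, H - 1 - r)` for 270 degrees; frame extents swap for 90/270.
#'
#' @param img A [raster_image()].
#' @param ann A [point_annotations()] on the same frame.
#' @param angle One of 90, 180, 270.
#' @return List with rotated `image` and `annotations`.
#' @export
rotate_with_annotations <- function(img, ann, angle) {
  stopifnot(inherits(img, "raster_image"), inherits(ann, "point_annotations"))
  if (!angle %in% c(90, 180, 270))
    stop("angle must be 90, 180 or 270, got ", angle)
  if (img$height != ann$frame_height || img$width != ann$frame_width)
    stop("image and annotation frame extents differ")
  H <- img$height; W <- img$width
  rot90 <- function(a) {  # counter-clockwise: (r, c) -> (W - 1 - c, r)
    out <- array(0L, dim = c(dim(a)[2], dim(a)[1], dim(a)[3]))
    for (ch in seq_len(dim(a)[3])) out[, , ch] <- t(a[, , ch])[rev(seq_len(dim(a)[2])), ]
    out
  }
  px <- img$pixels
  n_turns <- angle / 90
  for (i in seq_len(n_turns)) px <- rot90(px)
  pts <- ann$points
  if (nrow(pts) > 0L) {
    r <- pts[, 1]; c <- pts[, 2]
    pts <- switch(as.character(angle),
      "90"  = cbind(row = W - 1L - c, col = r),
      "180" = cbind(row = H - 1L - r, col = W - 1L - c),
      "270" = cbind(row = c, col = H - 1L - r))
  }
  new_h <- if (angle == 180) H else W
  new_w <- if (angle == 180) W else H
  list(image = raster_image(px),
       annotations = point_annotations(pts, new_h, new_w))
}

#' Export a count map as a 32-bit float TIFF for inspection
#'
#' @param cm A [count_map()].
#' @param path Output `.tif`/`.tiff` path.
#' @return `path`, invisibly.
#' @export
write_count_map <- function(cm, path) {
  stopifnot(inherits(cm, "count_map"))
  tiff::writeTIFF(cm$values / max(1, max(cm$values)), path,
                  bits.per.sample = 32L, compression = "none")
  invisible(path)
}
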