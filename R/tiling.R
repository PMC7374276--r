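#' Quadrant tiling plan
#'
#' Full microscope frames are split into four quadrants before prediction to
#' bound the memory used by the fully convolutional network; quadrant counts
#' are summed to the frame count. Rows split at `floor(H / 2)` and columns
#' at `floor(W / 2)`; the boxes are half-open `[row0, row1) x [col0, col1)`
#' in 0-based coordinates and partition the frame exactly.
#'
#' @param H,W Frame extents, both at least 2.
#' @return An object of class `tiling_plan` with fields `H`, `W` and `boxes`
#'   (4 x 4 integer matrix, columns `row0,row1,col0,col1`).
#' @export
tiling_plan <- function(H, W) {
  H <- as.integer(H); W <- as.integer(W)
  if (H < 2L || W < 2L) stop("frame must be at least 2 x 2 to quarter")
  rs <- H %/% 2L; cs <- W %/% 2L
  boxes <- rbind(
    c(0L, rs, 0L, cs), c(0L, rs, cs, W),
    c(rs, H, 0L, cs), c(rs, H, cs, W))
  colnames(boxes) <- c("row0", "row1", "col0", "col1")
  structure(list(H = H, W = W, boxes = boxes), class = "tiling_plan")
}

#' Split a frame into four quadrants
#'
#' @param img A [raster_image()] with `H >= 2`, `W >= 2`.
#' @return List with `quadrants` (list of four [raster_image()]s, order:
#'   top-left, top-right, bottom-left, bottom-right) and `plan`
#'   (the [tiling_plan()]).
#' @export
split_quadrants <- function(img) {
  stopifnot(inherits(img, "raster_image"))
  plan <- tiling_plan(img$height, img$width)
  quads <- lapply(seq_len(4L), function(i) {
    b <- plan$boxes[i, ]
    raster_image(img$pixels[(b["row0"] + 1L):b["row1"],
                            (b["col0"] + 1L):b["col1"], , drop = FALSE])
  })
  list(quadrants = quads, plan = plan)
}

#' Reassemble quadrants into the original frame
#'
#' @param quadrants List of four [raster_image()]s as produced by
#'   [split_quadrants()].
#' @param plan The matching [tiling_plan()].
#' @return A [raster_image()] equal to the original frame.
#' @export
reassemble_quadrants <- function(quadrants, plan) {
  stopifnot(inherits(plan, "tiling_plan"), length(quadrants) == 4L)
  ch <- quadrants[[1]]$channels
  out <- array(0L, dim = c(plan$H, plan$W, ch))
  for (i in seq_len(4L)) {
    b <- plan$boxes[i, ]
    out[(b["row0"] + 1L):b["row1"], (b["col0"] + 1L):b["col1"], ] <-
      quadrants[[i]]$pixels
  }
  raster_image(out)
}

#' Restrict annotations to one tiling box
#'
#' Keeps the points falling in the half-open box and re-expresses them in
#' quadrant-local coordinates. Used to build per-quadrant training targets;
#' every frame annotation lands in exactly one quadrant.
#'
#' @param ann A [point_annotations()].
#' @param box Length-4 integer vector `(row0, row1, col0, col1)`, half-open.
#' @return A [point_annotations()] on the box extents.
#' @export
crop_annotations <- function(ann, box) {
  stopifnot(inherits(ann, "point_annotations"))
  pts <- ann$points
  keep <- pts[, 1] >= box[1] & pts[, 1] < box[2] &
          pts[, 2] >= box[3] & pts[, 2] < box[4]
  pts <- pts[keep, , drop = FALSE]
  pts[, 1] <- pts[, 1] - box[1]
  pts[, 2] <- pts[, 2] - box[3]
  point_annotations(pts, box[2] - box[1], box[4] - box[3])
}

#' Prepare training tiles from annotated frames
#'
#' Converts annotated frames (e.g. synthetic scenes) into the training
#' items consumed by [train_model()]: each frame is converted to grayscale
#' and split into its four quadrants, with annotations cropped to each
#' quadrant. With `red_masked = TRUE` (and scenes carrying `red_flags`),
#' each frame additionally contributes its red-channel-masked grayscale
#' quadrants annotated with the red cells only, so the counting model also
#' learns the mostly-dark masked inputs used for fluorescent counting.
#'
#' @param scenes List of items with `image` ([raster_image()]) and
#'   `annotations` ([point_annotations()]); `synthetic_scene`s qualify.
#' @param red_masked Also emit red-masked tiles (requires RGB images and
#'   `red_flags`).
#' @param red_threshold Threshold for the red mask; default 100.
#' @param masked_weight Loss weight attached to masked tiles (default 4).
#'   Masked targets are sparse, so their unweighted loss contribution is an
#'   order of magnitude below the plain tiles' and the optimiser would
#'   otherwise neglect them.
#' @return List of `list(image =, annotations =, weight =)` training items.
#' @export
prepare_training_tiles <- function(scenes, red_masked = FALSE,
                                   red_threshold = 100L,
                                   masked_weight = 4) {
  items <- list()
  add_quads <- function(img, ann, w) {
    sp <- split_quadrants(img)
    for (i in seq_len(4L)) {
      items[[length(items) + 1L]] <<- list(
        image = sp$quadrants[[i]],
        annotations = crop_annotations(ann, sp$plan$boxes[i, ]),
        weight = w)
    }
  }
  for (sc in scenes) {
    gray <- to_grayscale(sc$image)
    add_quads(gray, sc$annotations, 1)
    if (red_masked) {
      if (sc$image$channels != 3L || is.null(sc$red_flags))
        stop("red_masked tiles require RGB images with red_flags")
      masked <- apply_mask(gray, red_mask(sc$image, red_threshold))
      red_ann <- point_annotations(
        sc$annotations$points[sc$red_flags, , drop = FALSE],
        sc$annotations$frame_height, sc$annotations$frame_width)
      add_quads(masked, red_ann, masked_weight)
    }
  }
  items
}

#' Count the cells on a whole frame
#'
#' Splits the frame into quadrants, pads each by `p`, predicts a count map
#' per quadrant and sums the four inferred counts. RGB frames are converted
#' to grayscale first (the counting model is trained on grayscale tiles).
#'
#' @param model A trained model from [train_model()], or any predictor
#'   accepted by [predict_count_map()].
#' @param img A [raster_image()].
#' @param spec A [count_map_spec()]; defaults to the model's spec.
#' @return Numeric scalar count (unrounded).
#' @export
count_frame <- function(model, img, spec = NULL) {
  stopifnot(inherits(img, "raster_image"))
  if (is.null(spec)) spec <- model_count_spec(model)
  if (img$channels == 3L) img <- to_grayscale(img)
  sp <- split_quadrants(img)
  counts <- vapply(sp$quadrants, function(q) {
    infer_count(predict_count_map(model, q, spec))
  }, numeric(1))
  sum(counts)
}

#' Batch-count a directory of frames
#'
#' Counts every TIFF/PNG frame in a directory and, for RGB frames, also the
#' red-fluorescent cells above a threshold. Grayscale frames get `NA` red
#' counts.
#'
#' @param model Trained model.
#' @param dir Directory of `.tif`/`.tiff`/`.png` frames.
#' @param red_threshold Red intensity threshold in `[0, 255]` (default 100).
#' @param spec Optional [count_map_spec()] override.
#' @return Data frame with columns `path`, `cell_count`, `red_count`,
#'   `threshold`, one row per frame (sorted by path).
#' @export
count_directory <- function(model, dir, red_threshold = 100L, spec = NULL) {
  files <- sort(list.files(dir, pattern = "\\.(tif|tiff|png)$",
                           ignore.case = TRUE, full.names = TRUE))
  rows <- lapply(files, function(f) {
    img <- read_image(f)
    total <- count_frame(model, img, spec)
    red <- if (img$channels == 3L)
      count_red(model, img, red_threshold, spec) else NA_real_
    data.frame(path = f, cell_count = total, red_count = red,
               threshold = red_threshold)
  })
  if (length(rows) == 0L)
    return(data.frame(path = character(), cell_count = numeric(),
                      red_count = numeric(), threshold = integer()))
  do.call(rbind, rows)
}
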