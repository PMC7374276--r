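# shared fixtures and independent oracles

# carries state between acceptance blocks (trained model reuse)
.acceptance_env <- new.env(parent = emptyenv())

# fresh scratch directory per test
withr_like_tempdir <- function() {
  d <- tempfile("cellcountr-test-")
  dir.create(d)
  d
}

# random point annotations on an H x W frame (0-based, distinct pixels)
random_annotations <- function(n, H, W) {
  idx <- sample.int(H * W, n)
  point_annotations(cbind((idx - 1L) %% H, (idx - 1L) %/% H), H, W)
}

# brute-force count-map oracle: scatter a k x k block of ones per point on
# the full-convolution (H+2p) x (W+2p) grid — a direct transcription of the
# definition, independent of the box-filter implementation
brute_force_target <- function(ann, spec) {
  p <- spec$pad; k <- spec$kernel_size
  out <- matrix(0, ann$frame_height + 2L * p, ann$frame_width + 2L * p)
  if (n_cells(ann) > 0L) {
    for (i in seq_len(n_cells(ann))) {
      r <- ann$points[i, 1] + 1L  # 1-based top-left of the k x k block
      c <- ann$points[i, 2] + 1L
      out[r:(r + k - 1L), c:(c + k - 1L)] <-
        out[r:(r + k - 1L), c:(c + k - 1L)] + 1
    }
  }
  out
}

# exact-target mock predictor: matches the incoming image against a stored
# list of (image, annotations) items and returns the true count map
make_exact_predictor <- function(items) {
  function(img, spec) {
    if (img$channels == 3L) img <- to_grayscale(img)
    for (it in items) {
      ref <- it$image
      if (ref$channels == 3L) ref <- to_grayscale(ref)
      if (images_identical(ref, img))
        return(make_count_target(it$annotations, spec))
    }
    stop("mock predictor: unknown image")
  }
}

# flat mid-gray test frame with annotations scattered on it
flat_frame <- function(H, W, level = 128L, channels = 1L) {
  raster_image(array(as.integer(level), dim = c(H, W, channels)))
}

# small standard scene config for fast tests
tiny_scene_config <- function(seed = 1L, ...) {
  synthetic_config(height = 64L, width = 64L, n_cells = 12L, seed = seed, ...)
}

# tiny trainable model (k = 9) for interface/pipeline tests
tiny_model <- function(seed = 3L) {
  ms <- model_spec(kernel_size = 9L, n_inception_blocks = 1L,
                   stem_kernel = 3L, stem_channels = 3L,
                   incep_channels1 = 2L, incep_channels3 = 2L,
                   large_channels = 2L)
  build_model(ms, count_map_spec(9L), seed = seed)
}

# U statistic by direct pair counting (independent of the rank formula)
u_by_pairs <- function(a, b) {
  ua <- 0
  for (x in a) ua <- ua + sum(x > b) + 0.5 * sum(x == b)
  min(ua, length(a) * length(b) - ua)
}

# exact two-sided permutation p-value by enumeration over group assignments
p_by_enumeration <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  combs <- utils::combn(length(pooled), na)
  obs <- u_by_pairs(a, b)
  stats <- apply(combs, 2L, function(ia)
    u_by_pairs(pooled[ia], pooled[-ia]))
  mean(stats <= obs + 1e-12)
}
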