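test_that("count_map_spec derives pad and area and rejects even kernels", {
  sp <- count_map_spec(65)
  expect_equal(sp$pad, 32L)
  expect_equal(sp$kernel_area, 4225L)
  expect_error(count_map_spec(64), "odd")
  expect_error(count_map_spec(-3), "odd")
  expect_equal(count_map_spec(1)$pad, 0L)
})

test_that("padding adds a zero border and preserves the interior", {
  img520 <- flat_frame(520, 696, 7L, channels = 3L)
  padded <- pad_image(img520, 32)
  expect_equal(c(padded$height, padded$width), c(584L, 760L))

  img <- raster_image(array(255L, dim = c(10, 10, 1)))
  out <- pad_image(img, 32)
  expect_equal(dim(out$pixels)[1:2], c(74L, 74L))
  expect_true(all(out$pixels[33:42, 33:42, 1] == 255L))
  interior <- matrix(FALSE, 74, 74); interior[33:42, 33:42] <- TRUE
  expect_true(all(out$pixels[, , 1][!interior] == 0L))

  expect_true(images_identical(pad_image(img, 0), img))
  expect_error(pad_image(img, -1), "non-negative")
})

test_that("a single centred point yields target sum k^2", {
  ann <- point_annotations(cbind(50L, 50L), 100, 100)
  tg <- make_count_target(ann, count_map_spec(65))
  expect_equal(sum(tg$values), 4225)
  expect_equal(infer_count(tg), 1)
})

test_that("empty annotations yield an all-zero full-extent map", {
  ann <- point_annotations(NULL, 100, 150)
  tg <- make_count_target(ann, count_map_spec(65))
  expect_equal(dim(tg$values), c(164L, 214L))
  expect_equal(sum(tg$values), 0)
  expect_equal(infer_count(tg), 0)
})

test_that("target equals the brute-force window count pixelwise", {
  set.seed(101)
  for (k in c(5L, 33L)) {
    spec <- count_map_spec(k)
    for (rep in 1:5) {
      H <- sample(20:60, 1); W <- sample(20:60, 1)
      n <- sample(0:15, 1)
      ann <- random_annotations(n, H, W)
      tg <- make_count_target(ann, spec)
      expect_equal(tg$values, brute_force_target(ann, spec))
      expect_equal(infer_count(tg), n)
    }
  }
  ## the documented 7-point case
  set.seed(7)
  ann <- random_annotations(7, 200, 200)
  tg <- make_count_target(ann, count_map_spec(33))
  expect_equal(sum(tg$values), 7 * 1089)
})

test_that("count conservation, additivity and translation covariance hold", {
  set.seed(55)
  spec <- count_map_spec(17)
  H <- 50L; W <- 40L
  a1 <- random_annotations(8, H, W)
  ## disjoint second set
  repeat {
    a2 <- random_annotations(6, H, W)
    key <- function(a) paste(a$points[, 1], a$points[, 2])
    if (!any(key(a2) %in% key(a1))) break
  }
  both <- point_annotations(rbind(a1$points, a2$points), H, W)
  t1 <- make_count_target(a1, spec)
  t2 <- make_count_target(a2, spec)
  tb <- make_count_target(both, spec)
  expect_equal(tb$values, t1$values + t2$values)

  ## translation: shift all points by (3, -2) within bounds
  inner <- point_annotations(cbind(c(10L, 20L), c(10L, 20L)), H, W)
  shifted <- point_annotations(inner$points + rep(c(3L, -2L), each = 2), H, W)
  ti <- make_count_target(inner, spec)
  ts <- make_count_target(shifted, spec)
  p <- spec$pad
  expect_equal(ts$values[(1 + 3):(H + 2 * p), 1:(W + 2 * p - 2)],
               ti$values[1:(H + 2 * p - 3), (1 + 2):(W + 2 * p)])
})

test_that("rotation maps pixels and points consistently", {
  set.seed(77)
  img <- raster_image(matrix(sample(0:255, 30 * 20, TRUE), 20, 30))
  ann <- random_annotations(5, 20, 30)

  r90 <- rotate_with_annotations(img, ann, 90)
  expect_equal(c(r90$image$height, r90$image$width), c(30L, 20L))
  ## the annotated pixel's value travels with the point
  for (i in seq_len(5)) {
    v0 <- img$pixels[ann$points[i, 1] + 1L, ann$points[i, 2] + 1L, 1]
    v1 <- r90$image$pixels[r90$annotations$points[i, 1] + 1L,
                           r90$annotations$points[i, 2] + 1L, 1]
    expect_equal(v1, v0)
  }

  r180 <- rotate_with_annotations(img, ann, 180)
  back <- rotate_with_annotations(r180$image, r180$annotations, 180)
  expect_true(images_identical(back$image, img))
  expect_equal(back$annotations$points, ann$points)

  expect_error(rotate_with_annotations(img, ann, 45), "angle")
})

test_that("count targets are equivariant under rotation", {
  set.seed(78)
  spec <- count_map_spec(9)
  img <- raster_image(matrix(0L, 24, 16))
  ann <- random_annotations(6, 24, 16)
  r <- rotate_with_annotations(img, ann, 90)
  t_rot <- make_count_target(r$annotations, spec)
  t_orig <- make_count_target(ann, spec)
  ## rotate the original target map by 90 ccw: M'[i,j] = M[j, W-1-i]
  rot_mat <- function(m) t(m)[rev(seq_len(ncol(m))), ]
  expect_equal(t_rot$values, rot_mat(t_orig$values))
})

test_that("count maps export as float TIFF for inspection", {
  td <- withr_like_tempdir()
  ann <- point_annotations(cbind(4L, 5L), 10, 12)
  cm <- make_count_target(ann, count_map_spec(5))
  f <- file.path(td, "map.tif")
  write_count_map(cm, f)
  back <- tiff::readTIFF(f)
  expect_equal(dim(back), dim(cm$values))
  ## normalised to [0, 1]; the support pattern is preserved
  expect_equal(back > 0, cm$values > 0)
})

test_that("infer_count returns exact unrounded reals", {
  spec <- count_map_spec(65)
  ones <- count_map(matrix(1, 65, 65), spec, kind = "prediction")
  expect_identical(infer_count(ones), 1)
  half <- count_map(matrix(0.5, 65, 65), spec, kind = "prediction")
  expect_identical(infer_count(half), 0.5)
})
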