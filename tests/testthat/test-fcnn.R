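test_that("model_spec sizes the large kernels to reach the count kernel", {
  ref <- model_spec(kernel_size = 65)
  expect_equal(ref$large_kernels, c(27L, 27L))
  expect_equal(receptive_field(ref), 65L)  # 3x3 stem + 5 blocks + 27 + 27
  k33 <- model_spec(kernel_size = 33)
  expect_equal(k33$large_kernels, c(11L, 11L))
  expect_equal(receptive_field(k33), 33L)
  expect_error(model_spec(kernel_size = 5),
               "receptive field|exceed")
  expect_error(model_spec(kernel_size = 64), "odd")
})

test_that("the architecture report lists the five inception blocks", {
  m <- build_model(model_spec(kernel_size = 65), count_map_spec(65))
  txt <- capture.output(print(m))
  expect_length(grep("inception block", txt), 5L)
  expect_match(txt[1], "receptive field 65")
  layers <- m$layers
  expect_equal(sum(vapply(layers, function(l) l$type == "incep",
                          logical(1))), 5L)
})

test_that("prediction preserves the padded spatial extent", {
  m <- tiny_model()
  img <- flat_frame(20, 26, 120L)
  cm <- predict_count_map(m, img)
  expect_s3_class(cm, "count_map")
  expect_equal(dim(cm$values), c(20L + 8L, 26L + 8L))
  expect_true(all(cm$values >= 0))  # negatives clipped
  ## channel mismatch is a shape error
  expect_error(predict_count_map(m, flat_frame(8, 8, 1L, channels = 3L)),
               "channel")
  ## kernel mismatch is refused
  expect_error(predict_count_map(m, img, count_map_spec(33)), "kernel")
})

test_that("analytic gradients match numerical differentiation", {
  m <- tiny_model(seed = 5)
  H <- 10L; W <- 9L
  set.seed(1)
  x <- matrix(runif(H * W), ncol = 1)
  tgt <- runif(H * W)
  for (case in list(list(loss = "l2", cw = 0), list(loss = "l1", cw = 0),
                    list(loss = "l2", cw = 0.1))) {
    g <- cellcountr:::.cpp_fcnn_grad(m$layers, m$params, x, tgt, H, W,
                                     case$loss, case$cw, 81)
    set.seed(2)
    for (j in seq_along(m$params)) {
      idx <- sample(length(m$params[[j]]), 1)
      e <- 1e-6
      p1 <- m$params; p2 <- m$params
      p1[[j]][idx] <- p1[[j]][idx] + e
      p2[[j]][idx] <- p2[[j]][idx] - e
      num <- (cellcountr:::.cpp_fcnn_loss(m$layers, p1, x, tgt, H, W,
                                          case$loss, NULL, case$cw, 81) -
              cellcountr:::.cpp_fcnn_loss(m$layers, p2, x, tgt, H, W,
                                          case$loss, NULL, case$cw, 81)) /
             (2 * e)
      ana <- g$grads[[j]][idx]
      expect_lt(abs(ana - num) / max(1e-6, abs(ana) + abs(num)), 1e-3)
    }
  }
})

test_that("the receptive field bounds the output support of a perturbation", {
  m <- tiny_model(seed = 9)   # nominal RF = 9
  H <- 25L; W <- 25L
  x0 <- matrix(0.5, H * W, 1)
  ## frozen batch-norm statistics = inference mode (strictly local)
  y0 <- cellcountr:::.cpp_fcnn_predict(m$layers, m$params, x0, H, W,
                                       m$bn_state)
  x1 <- x0
  centre <- 12L * H + 12L  # 0-based col-major pixel (row 12, col 12)
  x1[centre + 1L] <- 1
  y1 <- cellcountr:::.cpp_fcnn_predict(m$layers, m$params, x1, H, W,
                                       m$bn_state)
  changed <- which(matrix(abs(y1 - y0) > 1e-9, H, W), arr.ind = TRUE)
  ## all changed outputs lie within (RF-1)/2 = 4 of the perturbed pixel
  expect_true(nrow(changed) > 0)
  expect_true(all(abs(changed[, 1] - 13) <= 4))
  expect_true(all(abs(changed[, 2] - 13) <= 4))
})

test_that("training is reproducible and selects the best-validation epoch", {
  set.seed(90)
  scenes <- lapply(1:3, function(i)
    generate_scene(synthetic_config(height = 32, width = 32, n_cells = 4,
                                    red_fraction = 0, seed = 100 + i)))
  items <- lapply(scenes, function(sc)
    list(image = to_grayscale(sc$image), annotations = sc$annotations))
  ms <- model_spec(kernel_size = 9, n_inception_blocks = 1, stem_kernel = 3,
                   stem_channels = 3, incep_channels1 = 2,
                   incep_channels3 = 2, large_channels = 2)
  m0 <- build_model(ms, count_map_spec(9), seed = 4)
  cfg <- train_config(epochs = 3, seed = 4, augment = FALSE)
  r1 <- train_model(m0, items[1:2], cfg, val_set = items[3])
  r2 <- train_model(m0, items[1:2], cfg, val_set = items[3])
  expect_identical(r1$history, r2$history)
  expect_identical(r1$params, r2$params)
  expect_length(r1$history$val_loss, 3L)
  expect_equal(r1$best_epoch, which.min(r1$history$val_loss))

  ## epochs = 0 is a no-op returning the initial weights
  r0 <- train_model(m0, items[1:2], train_config(epochs = 0, seed = 4),
                    val_set = items[3])
  expect_identical(r0$params, m0$params)
  expect_length(r0$history$train_loss, 0L)
  expect_error(train_model(m0, list(), cfg), "empty")
})

test_that("augmentation quadruples the training set", {
  sc <- generate_scene(synthetic_config(height = 24, width = 24, n_cells = 3,
                                        red_fraction = 0, seed = 55))
  items <- list(list(image = to_grayscale(sc$image),
                     annotations = sc$annotations))
  aug <- cellcountr:::.augment_items(items)
  expect_length(aug, 4L)
  ## each rotation preserves the annotation count
  expect_true(all(vapply(aug, function(it) n_cells(it$annotations),
                         integer(1)) == 3L))
})

test_that("checkpoints embed the specs and refuse foreign files", {
  td <- withr_like_tempdir()
  m <- tiny_model()
  f <- file.path(td, "model.ckpt")
  save_model(m, f)
  back <- load_model(f)
  expect_identical(back$params, m$params)
  expect_equal(model_count_spec(back)$kernel_size, 9L)
  g <- file.path(td, "junk.rds")
  saveRDS(list(1), g)
  expect_error(load_model(g), "checkpoint")
})

test_that("training configs load from YAML and JSON files", {
  td <- withr_like_tempdir()
  fy <- file.path(td, "cfg.yaml")
  writeLines(c("learning_rate: 0.002", "epochs: 7", "seed: 3",
               "augment: false"), fy)
  cfg <- train_config_from_file(fy)
  expect_equal(cfg$learning_rate, 0.002)
  expect_equal(cfg$epochs, 7L)
  expect_false(cfg$augment)
  fj <- file.path(td, "cfg.json")
  writeLines('{"epochs": 12, "seed": 9}', fj)
  expect_equal(train_config_from_file(fj)$epochs, 12L)
  fb <- file.path(td, "bad.yaml")
  writeLines("epochz: 3", fb)
  expect_error(train_config_from_file(fb), "unknown")
})

test_that("mismatched model and count kernels are rejected at build time", {
  expect_error(build_model(model_spec(kernel_size = 9,
                                      n_inception_blocks = 1,
                                      stem_kernel = 3),
                           count_map_spec(33)), "match")
})
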