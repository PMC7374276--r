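make_request <- function(path, threshold = NULL, id = 1) {
  params <- list(image = encode_image_b64(path))
  if (!is.null(threshold)) params$red_threshold <- threshold
  jsonlite::toJSON(list(jsonrpc = "2.0", method = "count", params = params,
                        id = id), auto_unbox = TRUE)
}

test_that("service counts equal direct library counts on fixtures", {
  td <- withr_like_tempdir()
  m <- tiny_model()
  scenes <- lapply(1:2, function(i)
    generate_scene(tiny_scene_config(seed = 40 + i, red_fraction = 0.25)))
  paths <- export_scenes(scenes, td)
  for (i in seq_along(paths)) {
    resp <- jsonlite::fromJSON(rpc_handle(make_request(paths[i], 100), m))
    expect_equal(resp$jsonrpc, "2.0")
    img <- read_image(paths[i])
    expect_equal(resp$result$cell_count, count_frame(m, img))
    expect_equal(resp$result$red_cell_count, count_red(m, img, 100))
    expect_equal(resp$result$kernel_size, 9)
    expect_equal(resp$result$cell_count_rounded,
                 round(resp$result$cell_count))
  }
})

test_that("responses are byte-identical across repeated calls", {
  td <- withr_like_tempdir()
  m <- tiny_model()
  p <- export_scenes(list(generate_scene(tiny_scene_config(seed = 50))), td)
  req <- make_request(p[1], 30)
  expect_identical(rpc_handle(req, m), rpc_handle(req, m))
})

test_that("grayscale images count without a red channel", {
  td <- withr_like_tempdir()
  m <- tiny_model()
  f <- file.path(td, "gray.png")
  write_image(to_grayscale(generate_scene(tiny_scene_config(seed = 51))$image),
              f)
  resp <- jsonlite::fromJSON(rpc_handle(make_request(f), m))
  expect_null(resp$result$red_cell_count)
  expect_equal(resp$result$cell_count, count_frame(m, read_image(f)))
})

test_that("protocol errors carry JSON-RPC error codes", {
  m <- tiny_model()
  ## invalid JSON
  r <- jsonlite::fromJSON(rpc_handle("{not json", m))
  expect_equal(r$error$code, -32700)
  ## wrong method
  r <- jsonlite::fromJSON(rpc_handle(
    '{"jsonrpc":"2.0","method":"segment","params":{},"id":2}', m))
  expect_equal(r$error$code, -32601)
  ## missing image
  r <- jsonlite::fromJSON(rpc_handle(
    '{"jsonrpc":"2.0","method":"count","params":{},"id":3}', m))
  expect_equal(r$error$code, -32602)
  ## truncated Base64 -> not a decodable image, no crash
  r <- jsonlite::fromJSON(rpc_handle(paste0(
    '{"jsonrpc":"2.0","method":"count","params":{"image":"AAAA"},"id":4}'),
    m))
  expect_equal(r$error$code, -32602)
  ## out-of-range threshold
  td <- withr_like_tempdir()
  p <- export_scenes(list(generate_scene(tiny_scene_config(seed = 52))), td)
  r <- jsonlite::fromJSON(rpc_handle(make_request(p[1], 300), m))
  expect_equal(r$error$code, -32602)
  ## fractional threshold
  r <- jsonlite::fromJSON(rpc_handle(make_request(p[1], 99.5), m))
  expect_equal(r$error$code, -32602)
  ## no model loaded
  r <- jsonlite::fromJSON(rpc_handle(make_request(p[1], 10), NULL))
  expect_equal(r$error$code, -32603)
})

test_that("batch counting over a directory matches its file census", {
  td <- withr_like_tempdir()
  m <- tiny_model()
  scenes <- lapply(1:3, function(i)
    generate_scene(tiny_scene_config(seed = 60 + i, red_fraction = 0.25)))
  export_scenes(scenes, td)
  df <- count_directory(m, td, red_threshold = 30)
  expect_equal(nrow(df), 3L)
  expect_equal(df$threshold, rep(30L, 3))
  ## counts equal direct calls
  img1 <- read_image(df$path[1])
  expect_equal(df$cell_count[1], count_frame(m, img1))
  expect_equal(df$red_count[1], count_red(m, img1, 30))
  ## empty directory -> empty frame with the right columns
  empty <- withr_like_tempdir()
  df0 <- count_directory(m, empty)
  expect_equal(nrow(df0), 0L)
  expect_equal(names(df0), c("path", "cell_count", "red_count", "threshold"))
})
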