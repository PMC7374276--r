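#' Handle one JSON-RPC 2.0 counting request
#'
#' Implements the service contract: method `"count"` with named params
#' `image` (Base64-encoded bytes of an 8-bit TIFF or PNG file) and optional
#' `red_threshold` (integer 0-255, default 100). The result carries the
#' real-valued `cell_count` and `red_cell_count` (null for grayscale
#' images, which have no red channel), convenience rounded integers, the
#' `model_id` and the `kernel_size`. Counting is delegated to
#' [count_frame()] and [count_red()], so responses equal direct library
#' calls on the decoded image and are bit-reproducible for a fixed
#' checkpoint.
#'
#' Errors follow JSON-RPC 2.0: parse error (-32700), invalid request
#' (-32600), method not found (-32601), invalid params (-32602, e.g.
#' malformed Base64, undecodable image, threshold out of range), internal
#' error (-32603, e.g. no model loaded).
#'
#' @param json Request as a JSON string.
#' @param model A trained `cellcount_model` (the loaded checkpoint).
#' @param default_threshold Red threshold applied when the request omits
#'   one; default 100.
#' @return Response JSON string.
#' @export
rpc_handle <- function(json, model, default_threshold = 100L) {
  req <- tryCatch(jsonlite::fromJSON(json, simplifyVector = TRUE),
                  error = function(e) NULL)
  if (is.null(req))
    return(.rpc_error(NULL, -32700L, "parse error: invalid JSON"))
  id <- req$id
  if (is.null(req$jsonrpc) || !identical(as.character(req$jsonrpc), "2.0") ||
      is.null(req$method))
    return(.rpc_error(id, -32600L, "invalid JSON-RPC 2.0 request"))
  if (!identical(req$method, "count"))
    return(.rpc_error(id, -32601L,
                      paste0("method not found: ", req$method)))
  params <- req$params
  if (is.null(params) || is.null(params$image))
    return(.rpc_error(id, -32602L, "missing required param `image`"))
  thr <- params$red_threshold
  if (is.null(thr)) thr <- default_threshold
  if (!is.numeric(thr) || length(thr) != 1L || is.na(thr) ||
      thr != round(thr) || thr < 0 || thr > 255)
    return(.rpc_error(id, -32602L,
                      "red_threshold must be an integer in [0, 255]"))
  bytes <- tryCatch(jsonlite::base64_dec(params$image),
                    error = function(e) NULL)
  if (is.null(bytes))
    return(.rpc_error(id, -32602L, "image is not valid Base64"))
  img <- tryCatch(read_image(bytes), error = function(e) e)
  if (inherits(img, "error"))
    return(.rpc_error(id, -32602L,
                      paste0("image could not be decoded: ",
                             conditionMessage(img))))
  if (!inherits(model, "cellcount_model"))
    return(.rpc_error(id, -32603L, "no counting model loaded"))
  total <- count_frame(model, img)
  red <- if (img$channels == 3L)
    count_red(model, img, as.integer(thr)) else NA_real_
  result <- list(
    cell_count = total,
    red_cell_count = if (is.na(red)) NULL else red,
    cell_count_rounded = round(total),
    red_cell_count_rounded = if (is.na(red)) NULL else round(red),
    red_threshold = as.integer(thr),
    model_id = paste0("cellcountr-k", model$count_spec$kernel_size,
                      "-seed", model$seed),
    kernel_size = model$count_spec$kernel_size)
  jsonlite::toJSON(list(jsonrpc = "2.0", result = result, id = id),
                   auto_unbox = TRUE, null = "null", digits = NA)
}

.rpc_error <- function(id, code, message) {
  jsonlite::toJSON(
    list(jsonrpc = "2.0",
         error = list(code = code, message = message),
         id = if (is.null(id)) NA else id),
    auto_unbox = TRUE, null = "null")
}

#' Encode an image file for a counting request
#'
#' @param path Image file path.
#' @return Base64 string of the file bytes.
#' @export
encode_image_b64 <- function(path) {
  jsonlite::base64_enc(readBin(path, "raw", file.info(path)$size))
}

#' Serve counting requests over HTTP (blocking)
#'
#' A minimal single-threaded HTTP/1.1 loop on base R sockets exposing the
#' JSON-RPC endpoint `POST /api`. Each request body is passed to
#' [rpc_handle()]. Intended for local use and scripting, not production.
#'
#' @param model A trained `cellcount_model`.
#' @param port TCP port; default 8399.
#' @param default_threshold Default red threshold.
#' @param max_requests Stop after this many requests (Inf = run forever);
#'   useful for scripted shutdown.
#' @return Number of requests served, invisibly.
#' @export
serve_rpc <- function(model, port = 8399L, default_threshold = 100L,
                      max_requests = Inf) {
  served <- 0
  while (served < max_requests) {
    con <- suppressWarnings(socketConnection(
      host = "127.0.0.1", port = port, server = TRUE, blocking = TRUE,
      open = "r+b", timeout = 3600))
    resp_body <- tryCatch({
      head <- character()
      repeat {
        line <- readLines(con, n = 1L)
        if (length(line) == 0L || line == "") break
        head <- c(head, line)
      }
      clen <- grep("^content-length:", head, ignore.case = TRUE, value = TRUE)
      nbytes <- if (length(clen) > 0)
        as.integer(trimws(sub("^[^:]*:", "", clen[1]))) else 0L
      body <- if (nbytes > 0) rawToChar(readBin(con, "raw", nbytes)) else "{}"
      rpc_handle(body, model, default_threshold)
    }, error = function(e)
      .rpc_error(NULL, -32603L, conditionMessage(e)))
    payload <- charToRaw(as.character(resp_body))
    writeLines(c("HTTP/1.1 200 OK",
                 "Content-Type: application/json",
                 paste0("Content-Length: ", length(payload)),
                 "Connection: close", ""), con, sep = "\r\n")
    writeBin(payload, con)
    close(con)
    served <- served + 1
  }
  invisible(served)
}
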