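#' Architecture specification for the counting network
#'
#' A Count-Ception-style fully convolutional network: a stem convolution,
#' `n_inception_blocks` inception blocks (parallel 1x1 and 3x3 convolutions,
#' channel-concatenated), a first chokepoint (1x1 convolution halving the
#' channel count), two large same-padded convolutions sized so the nominal
#' receptive field reaches the count kernel `k`, and a final chokepoint (1x1
#' convolution to 1 channel, linear). Batch normalisation follows every
#' convolution or inception block except the output; all activations are
#' rectified linear. Every convolution is stride-1 with zero same-padding,
#' so the output spatial extent equals the input extent — which the
#' sum-over-map / `k^2` counting rule requires ("chokepoints" therefore
#' reduce channels, never spatial size).
#'
#' The two large kernels are derived from `k`: with a stem of size `s` and
#' `B` blocks, the remaining receptive field `k - (s - 1) - 2 B` is split
#' into two odd kernels (27 and 27 for the default `k = 65`, `s = 3`,
#' `B = 5`). A configuration whose receptive field cannot reach `k` is
#' rejected: an output unit that sees less than the `k x k` target kernel
#' cannot predict its count.
#'
#' @param kernel_size Count kernel `k` (odd), as in [count_map_spec()].
#' @param n_inception_blocks Number of inception blocks; default 5.
#' @param stem_kernel Stem convolution size (odd); default 3.
#' @param stem_channels Stem output channels; default 64.
#' @param incep_channels1,incep_channels3 Widths of the 1x1 and 3x3
#'   inception branches; defaults 16 and 16.
#' @param large_channels Channels of the two large convolutions; default 16.
#' @param large_kernels Optional explicit pair of odd kernel sizes for the
#'   two large convolutions (derived from `kernel_size` when `NULL`).
#' @param in_channels Input channels; the counting model is trained on
#'   grayscale tiles, so the default is 1.
#' @param loss `"l1"` (mean absolute pixel error, default) or `"l2"`.
#' @param count_loss_weight Weight of an auxiliary squared count-error
#'   term, `(sum(pred - target) / k^2)^2` per tile, added to the pixel
#'   loss (0 disables). A per-pixel loss is nearly blind to a small
#'   uniform bias whose integral over a tile is whole cells; the count
#'   term penalises that bias directly and makes best-epoch selection
#'   track counting accuracy; large values destabilise training because
#'   the term's gradient is spatially coherent. Default 0.005.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(kernel_size = 65L, n_inception_blocks = 5L,
                       stem_kernel = 3L, stem_channels = 64L,
                       incep_channels1 = 16L, incep_channels3 = 16L,
                       large_channels = 16L, large_kernels = NULL,
                       in_channels = 1L, loss = c("l1", "l2"),
                       count_loss_weight = 0.005) {
  loss <- match.arg(loss)
  stopifnot(count_loss_weight >= 0)
  k <- as.integer(kernel_size)
  if (k < 1L || k %% 2L == 0L) stop("kernel_size must be odd and positive")
  if (stem_kernel %% 2L == 0L) stop("stem_kernel must be odd")
  if (n_inception_blocks < 1L) stop("need at least one inception block")
  if (is.null(large_kernels)) {
    remaining <- k - (stem_kernel - 1L) - 2L * n_inception_blocks
    if (remaining < 2L)
      stop("receptive field cannot reach kernel_size ", k,
           " with stem ", stem_kernel, " and ", n_inception_blocks,
           " inception blocks: the target kernel would exceed what an ",
           "output unit can see")
    a <- remaining %/% 2L
    large_kernels <- if (a %% 2L == 1L) c(a, remaining - a + 2L)
                     else c(a + 1L, a + 1L)
  }
  large_kernels <- as.integer(large_kernels)
  if (any(large_kernels %% 2L == 0L)) stop("large kernels must be odd")
  spec <- structure(
    list(kernel_size = k, n_inception_blocks = as.integer(n_inception_blocks),
         stem_kernel = as.integer(stem_kernel),
         stem_channels = as.integer(stem_channels),
         incep_channels1 = as.integer(incep_channels1),
         incep_channels3 = as.integer(incep_channels3),
         choke1_channels = as.integer((incep_channels1 + incep_channels3) %/% 2L),
         large_channels = as.integer(large_channels),
         large_kernels = large_kernels,
         in_channels = as.integer(in_channels), loss = loss,
         count_loss_weight = count_loss_weight),
    class = "model_spec")
  rf <- receptive_field(spec)
  if (rf < k)
    stop("nominal receptive field ", rf, " is below kernel_size ", k,
         ": the target kernel would exceed what an output unit can see")
  spec
}

#' Nominal receptive field of a model specification
#'
#' All convolutions are stride 1, so the receptive field is
#' `1 + sum(kernel_i - 1)` over the convolution chain; each inception block
#' contributes its widest branch (3).
#'
#' @param spec A [model_spec()] or a layer list built from one.
#' @return Integer receptive field in pixels.
#' @export
receptive_field <- function(spec) {
  ks <- if (inherits(spec, "model_spec")) {
    c(spec$stem_kernel, rep(3L, spec$n_inception_blocks), 1L,
      spec$large_kernels, 1L)
  } else {
    vapply(spec, function(ly)
      if (ly$type == "incep") 3L else as.integer(ly$k), integer(1))
  }
  1L + sum(ks - 1L)
}

## flat layer descriptors consumed by the C++ kernels
.build_layers <- function(spec) {
  layers <- list()
  cin <- spec$in_channels
  layers[[1]] <- list(type = "conv", k = spec$stem_kernel, cin = cin,
                      cout = spec$stem_channels, bn = TRUE, relu = TRUE)
  cin <- spec$stem_channels
  for (b in seq_len(spec$n_inception_blocks)) {
    layers[[length(layers) + 1L]] <- list(type = "incep", cin = cin,
                                          out1 = spec$incep_channels1,
                                          out3 = spec$incep_channels3)
    cin <- spec$incep_channels1 + spec$incep_channels3
  }
  layers[[length(layers) + 1L]] <- list(type = "conv", k = 1L, cin = cin,
                                        cout = spec$choke1_channels,
                                        bn = TRUE, relu = TRUE)
  cin <- spec$choke1_channels
  for (lk in spec$large_kernels) {
    layers[[length(layers) + 1L]] <- list(type = "conv", k = as.integer(lk),
                                          cin = cin,
                                          cout = spec$large_channels,
                                          bn = TRUE, relu = TRUE)
    cin <- spec$large_channels
  }
  layers[[length(layers) + 1L]] <- list(type = "conv", k = 1L, cin = cin,
                                        cout = 1L, bn = FALSE, relu = FALSE)
  layers
}

## Glorot-uniform parameter initialisation; draws from the current R RNG
.init_params <- function(layers) {
  glorot <- function(krn, cin, cout) {
    fan_in <- krn * krn * cin; fan_out <- krn * krn * cout
    lim <- sqrt(6 / (fan_in + fan_out))
    matrix(stats::runif(krn * krn * cin * cout, -lim, lim),
           krn * krn * cin, cout)
  }
  params <- list()
  for (ly in layers) {
    if (ly$type == "conv") {
      params <- c(params, list(glorot(ly$k, ly$cin, ly$cout), rep(0, ly$cout)))
      if (ly$bn) params <- c(params, list(rep(1, ly$cout), rep(0, ly$cout)))
    } else {
      nc <- ly$out1 + ly$out3
      params <- c(params, list(glorot(1L, ly$cin, ly$out1), rep(0, ly$out1),
                               glorot(3L, ly$cin, ly$out3), rep(0, ly$out3),
                               rep(1, nc), rep(0, nc)))
    }
  }
  params
}

## Batch-norm running statistics (frozen at inference so prediction is
## deterministic and strictly local): one (mean, var) pair per BN layer.
.init_bn_state <- function(layers) {
  st <- list()
  for (ly in layers) {
    nc <- if (ly$type == "incep") ly$out1 + ly$out3
          else if (ly$bn) ly$cout else NA_integer_
    if (!is.na(nc))
      st[[length(st) + 1L]] <- list(mean = rep(0, nc), var = rep(1, nc))
  }
  st
}

#' Training protocol configuration
#'
#' Defaults follow the published protocol for the full-size problem: Adam
#' with learning rate 0.001, batch size 1, 400 epochs, an 8:2
#' training/validation split and rotation augmentation; the model of the
#' epoch with the lowest validation loss is kept.
#'
#' @param learning_rate Adam step size; default 0.001.
#' @param batch_size Images per gradient step; default 1 (the only value
#'   currently implemented, matching the protocol).
#' @param epochs Training epochs; default 400.
#' @param seed Seed for initialisation and shuffling.
#' @param augment Add the three 90-degree rotations of every training tile.
#' @param validation_fraction Fraction held out for validation when no
#'   explicit validation set is given; default 0.2.
#' @param clip_norm Global gradient-norm clip applied before each Adam
#'   step (`Inf` disables). Single-image gradients occasionally spike on
#'   dense clusters; clipping keeps the loss trajectory smooth without
#'   changing the steady-state solution. Default 5.
#' @param decay_after,decay_factor Step decay of the learning rate: after
#'   `decay_after` (fraction of the epoch budget, default 0.7) the rate is
#'   multiplied by `decay_factor` (default 0.1), so batch-1 noise settles
#'   and best-epoch selection happens in the converged regime.
#' @param select_count_weight Weight of the squared mean validation
#'   count bias in the recorded validation loss (the model-selection
#'   metric): `pixel_loss + w * (bias_plain^2 + bias_masked^2)`, where
#'   each bias is the mean signed count error per tile (plain and
#'   red-masked tiles separately, on the clipped inference path). Batch-1
#'   training oscillates around the optimum and two epochs with
#'   near-identical pixel loss can differ by whole cells per tile;
#'   selecting on bias lands on the zero-crossings. The training gradient
#'   keeps the milder `model_spec` count weight because spatially
#'   coherent count gradients destabilise optimisation; selection takes
#'   no gradient steps and can afford full sensitivity. Default 5.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 1L,
                         epochs = 400L, seed = 1L, augment = TRUE,
                         validation_fraction = 0.2, clip_norm = 5,
                         decay_after = 0.7, decay_factor = 0.1,
                         select_count_weight = 5) {
  stopifnot(learning_rate > 0, epochs >= 0, batch_size >= 1, clip_norm > 0,
            decay_after >= 0, decay_after <= 1,
            decay_factor > 0, decay_factor <= 1, select_count_weight >= 0)
  if (batch_size != 1L)
    stop("only batch_size = 1 is implemented (the published protocol)")
  structure(list(learning_rate = learning_rate, batch_size = 1L,
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 augment = isTRUE(augment),
                 validation_fraction = validation_fraction,
                 clip_norm = clip_norm, decay_after = decay_after,
                 decay_factor = decay_factor,
                 select_count_weight = select_count_weight),
            class = "train_config")
}

#' Read a training configuration from a YAML or JSON file
#'
#' The file holds fields of [train_config()] (e.g. `learning_rate`,
#' `epochs`, `seed`, `augment`); unknown fields are an error so typos do
#' not silently fall back to defaults.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A [train_config()].
#' @export
train_config_from_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  fields <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the yaml package")
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    stop("unsupported config format: .", ext, " (use .yaml/.yml/.json)")
  }
  known <- names(formals(train_config))
  bad <- setdiff(names(fields), known)
  if (length(bad) > 0)
    stop("unknown train_config fields: ", paste(bad, collapse = ", "))
  do.call(train_config, fields)
}

#' Build an untrained counting model
#'
#' Initialises the network of `spec` with Glorot-uniform weights drawn from
#' `seed`. The result predicts count maps via [predict_count_map()] and is
#' trained with [train_model()].
#'
#' @param spec A [model_spec()].
#' @param count_spec The [count_map_spec()] the model is bound to; its
#'   `kernel_size` must equal `spec$kernel_size` so inference cannot run
#'   with a mismatched kernel.
#' @param seed Integer seed for the weight draw.
#' @return An object of class `cellcount_model`.
#' @export
build_model <- function(spec, count_spec = count_map_spec(spec$kernel_size),
                        seed = 1L) {
  stopifnot(inherits(spec, "model_spec"), inherits(count_spec, "count_map_spec"))
  if (spec$kernel_size != count_spec$kernel_size)
    stop("model kernel_size ", spec$kernel_size,
         " does not match count-map kernel_size ", count_spec$kernel_size)
  layers <- .build_layers(spec)
  params <- .with_seed(seed, .init_params(layers))
  structure(list(spec = spec, count_spec = count_spec, layers = layers,
                 params = params, bn_state = .init_bn_state(layers),
                 seed = as.integer(seed),
                 history = list(train_loss = numeric(0),
                                val_loss = numeric(0)),
                 best_epoch = NA_integer_),
            class = "cellcount_model")
}

#' @export
print.cellcount_model <- function(x, ...) {
  s <- x$spec
  cat(sprintf("<cellcount_model: k = %d, receptive field %d>\n",
              s$kernel_size, receptive_field(s)))
  cat(sprintf("  stem %dx%d/%d\n", s$stem_kernel, s$stem_kernel,
              s$stem_channels))
  for (b in seq_len(s$n_inception_blocks))
    cat(sprintf("  inception block %d: 1x1/%d + 3x3/%d\n", b,
                s$incep_channels1, s$incep_channels3))
  cat(sprintf("  chokepoint 1x1/%d\n", s$choke1_channels))
  for (lk in s$large_kernels)
    cat(sprintf("  conv %dx%d/%d\n", lk, lk, s$large_channels))
  cat("  chokepoint 1x1/1 (linear output)\n")
  if (length(x$history$val_loss) > 0)
    cat(sprintf("  trained %d epochs, best epoch %d (val loss %.4f)\n",
                length(x$history$val_loss), x$best_epoch,
                x$history$val_loss[x$best_epoch]))
  invisible(x)
}

#' Count-map spec bound to a model
#' @param model A `cellcount_model`.
#' @return Its [count_map_spec()].
#' @export
model_count_spec <- function(model) {
  stopifnot(inherits(model, "cellcount_model"))
  model$count_spec
}

## (padded pixels scaled to [0,1], target vector) for one training item
.prepare_item <- function(item, count_spec) {
  img <- item$image
  if (img$channels == 3L) img <- to_grayscale(img)
  padded <- pad_image(img, count_spec$pad)
  x <- matrix(as.numeric(padded$pixels[, , 1]) / 255, ncol = 1L)
  target <- make_count_target(item$annotations, count_spec)
  list(x = x, target = as.numeric(target$values),
       H = padded$height, W = padded$width,
       w = if (is.null(item$weight)) 1 else item$weight)
}

.augment_items <- function(items) {
  out <- items
  for (it in items) {
    for (ang in c(90, 180, 270)) {
      r <- rotate_with_annotations(it$image, it$annotations, ang)
      out[[length(out) + 1L]] <- list(image = r$image,
                                      annotations = r$annotations,
                                      weight = it$weight)
    }
  }
  out
}

#' Train the counting model
#'
#' Trains with Adam (batch size 1) on padded tiles against their redundant
#' count-map targets, recording mean training loss and validation loss per
#' epoch; the weights of the epoch with the lowest validation loss (first
#' occurrence on ties) are kept. The loss is the mean absolute (or squared,
#' per the model spec) pixel difference between predicted and target maps.
#' All randomness — weight re-initialisation is not performed here, but
#' shuffling is — derives from `cfg$seed`, so fixed-seed runs reproduce
#' identical loss curves.
#'
#' @param model A `cellcount_model` from [build_model()].
#' @param train_set Nonempty list of training items, each a list with
#'   `image` (a [raster_image()] tile) and `annotations`
#'   ([point_annotations()] on that tile). Tiles are padded internally.
#' @param cfg A [train_config()].
#' @param val_set Optional validation items in the same format; when `NULL`,
#'   the last `validation_fraction` of `train_set` is held out.
#' @return The model with trained parameters, `history` (per-epoch
#'   `train_loss` and `val_loss`) and `best_epoch` filled in.
#' @export
train_model <- function(model, train_set, cfg = train_config(),
                        val_set = NULL) {
  stopifnot(inherits(model, "cellcount_model"), inherits(cfg, "train_config"))
  if (length(train_set) == 0L) stop("training set is empty")
  if (is.null(val_set)) {
    n_val <- max(1L, round(cfg$validation_fraction * length(train_set)))
    if (n_val >= length(train_set))
      stop("validation split leaves no training data")
    idx <- seq_len(length(train_set) - n_val)
    val_set <- train_set[-idx]
    train_set <- train_set[idx]
  }
  if (cfg$augment) train_set <- .augment_items(train_set)
  cs <- model$count_spec
  tr <- lapply(train_set, .prepare_item, count_spec = cs)
  va <- lapply(val_set, .prepare_item, count_spec = cs)
  loss_type <- model$spec$loss
  cw <- model$spec$count_loss_weight
  if (is.null(cw)) cw <- 0

  ## model-selection metric: weighted mean pixel loss plus the squared
  ## mean count bias of the plain and masked validation tile groups,
  ## evaluated on the clipped inference path with frozen BN statistics
  val_metric <- function(params, bn_state) {
    pix <- 0; ce_plain <- numeric(0); ce_mask <- numeric(0)
    for (it in va) {
      y <- .cpp_fcnn_predict(model$layers, params, it$x, it$H, it$W,
                             bn_state)
      d <- y - it$target
      pix <- pix + it$w * (if (loss_type == "l2") mean(d^2) else
                             mean(abs(d)))
      ce <- (sum(pmax(y, 0)) - sum(it$target)) / cs$kernel_area
      if (it$w == 1) ce_plain <- c(ce_plain, ce)
      else ce_mask <- c(ce_mask, ce)
    }
    bias2 <- (if (length(ce_plain)) mean(ce_plain) else 0)^2 +
             (if (length(ce_mask)) mean(ce_mask) else 0)^2
    pix / length(va) + cfg$select_count_weight * bias2
  }

  if (cfg$epochs == 0L) {
    model$history <- list(train_loss = numeric(0), val_loss = numeric(0))
    model$best_epoch <- NA_integer_
    return(model)
  }

  params <- model$params
  bn_state <- model$bn_state
  m <- lapply(params, function(p) p * 0)
  v <- m
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; momentum <- 0.99; t <- 0L
  train_hist <- val_hist <- numeric(cfg$epochs)
  best_val <- Inf; best_params <- params; best_bn <- bn_state
  best_epoch <- NA_integer_

  .with_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      lr_ep <- cfg$learning_rate *
        (if (ep > cfg$decay_after * cfg$epochs) cfg$decay_factor else 1)
      ord <- sample.int(length(tr))
      ep_loss <- 0
      for (i in ord) {
        it <- tr[[i]]
        res <- .cpp_fcnn_grad(model$layers, params, it$x, it$target,
                              it$H, it$W, loss_type, cw, cs$kernel_area)
        ep_loss <- ep_loss + it$w * res$loss
        t <- t + 1L
        lr_t <- lr_ep * sqrt(1 - b2^t) / (1 - b1^t)
        gnorm <- it$w * sqrt(sum(vapply(res$grads, function(g) sum(g^2),
                                        numeric(1))))
        scale <- it$w * (if (is.finite(cfg$clip_norm) &&
                             gnorm > cfg$clip_norm)
          cfg$clip_norm / gnorm else 1)
        for (j in seq_along(params)) {
          g <- res$grads[[j]] * scale
          if (!identical(dim(g), dim(params[[j]]))) dim(g) <- dim(params[[j]])
          m[[j]] <- b1 * m[[j]] + (1 - b1) * g
          v[[j]] <- b2 * v[[j]] + (1 - b2) * g^2
          params[[j]] <- params[[j]] - lr_t * m[[j]] / (sqrt(v[[j]]) + eps)
        }
        for (j in seq_along(bn_state)) {  # running-stat update
          bb <- res$bn_batch[[j]]
          bn_state[[j]]$mean <- momentum * bn_state[[j]]$mean +
            (1 - momentum) * as.numeric(bb$mean)
          bn_state[[j]]$var <- momentum * bn_state[[j]]$var +
            (1 - momentum) * as.numeric(bb$var)
        }
      }
      train_hist[ep] <- ep_loss / length(tr)
      val_hist[ep] <- val_metric(params, bn_state)
      if (val_hist[ep] < best_val) {
        best_val <- val_hist[ep]
        best_params <- params
        best_bn <- bn_state
        best_epoch <- ep
      }
    }
  })

  model$params <- best_params
  model$bn_state <- best_bn
  model$history <- list(train_loss = train_hist, val_loss = val_hist)
  model$best_epoch <- best_epoch
  model
}

#' Predict a redundant count map for one tile or frame
#'
#' Pads the (grayscale) image by the spec's pad, runs the network and clips
#' negative raw outputs to zero. `model` may also be a plain function
#' `(img, spec) -> count_map`, which supports exact-target mock predictors
#' in pipeline tests.
#'
#' @param model A trained `cellcount_model`, or a predictor function.
#' @param img A [raster_image()]; 1 channel (a 3-channel image is a shape
#'   error: conversion to grayscale is the caller's responsibility, see
#'   [count_frame()]).
#' @param spec A [count_map_spec()]; defaults to the model's.
#' @return A [count_map()] of kind `"prediction"`, shape
#'   `(H + 2p) x (W + 2p)`.
#' @export
predict_count_map <- function(model, img, spec = NULL) {
  if (is.function(model)) {
    if (is.null(spec)) stop("a count_map_spec is required with a mock predictor")
    return(model(img, spec))
  }
  stopifnot(inherits(model, "cellcount_model"), inherits(img, "raster_image"))
  if (is.null(spec)) spec <- model$count_spec
  if (spec$kernel_size != model$count_spec$kernel_size)
    stop("requested kernel_size ", spec$kernel_size,
         " does not match the model checkpoint (",
         model$count_spec$kernel_size, ")")
  if (img$channels != model$spec$in_channels)
    stop("model expects ", model$spec$in_channels, "-channel input, got ",
         img$channels)
  padded <- pad_image(img, spec$pad)
  x <- matrix(as.numeric(padded$pixels[, , 1]) / 255, ncol = 1L)
  out <- .cpp_fcnn_predict(model$layers, model$params, x,
                           padded$height, padded$width, model$bn_state)
  vals <- matrix(pmax(out, 0), padded$height, padded$width)
  count_map(vals, spec, kind = "prediction")
}

#' Save / load a model checkpoint
#'
#' The checkpoint embeds the architecture spec and the count-map spec, so a
#' loaded model cannot be run with a mismatched kernel.
#'
#' @param model A `cellcount_model`.
#' @param path Checkpoint file path.
#' @return `save_model`: `path` invisibly; `load_model`: the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "cellcount_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "cellcount_model"))
    stop("not a cellcount_model checkpoint: ", path)
  model
}
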