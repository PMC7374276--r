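#' Configuration for synthetic phase-contrast scenes
#'
#' The generator emulates the features of cultured epithelial-like cells
#' imaged in phase contrast that make counting hard: polymorphic non-convex
#' outlines (radially perturbed ellipses), variable sizes, a tendency to
#' form dense clusters (a Thomas cluster process), dark cell bodies with a
#' bright halo rim on a noisy mid-gray background, and an optional subset of
#' cells expressing red fluorescence. Every cell carries a one-pixel
#' annotation at its integer centroid, so scenes are their own ground truth.
#'
#' @param height,width Frame extents in pixels.
#' @param n_cells Number of cells to plant.
#' @param cluster_fraction Fraction of cells placed by the cluster process
#'   (the rest are uniform); in `[0, 1]`.
#' @param cluster_sd Gaussian spread of offspring around cluster centres, px.
#' @param cell_radius_range Min/max mean radius of a cell body, px.
#' @param shape_irregularity Amplitude of the radial outline perturbation
#'   (0 = ellipses; larger = more ragged, non-convex outlines).
#' @param halo_strength Brightness added to the halo rim, 0-255 scale.
#' @param background_level Mean background intensity, 0-255 scale.
#' @param background_noise_sd Gaussian pixel noise SD, 0-255 scale.
#' @param red_fraction Fraction of cells painted into the red channel;
#'   `round(red_fraction * n_cells)` cells are flagged red.
#' @param red_intensity_range Min/max red intensity of fluorescent cells.
#' @param seed Integer seed; scenes are bit-reproducible given the seed.
#' @return An object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(height = 128L, width = 128L, n_cells = 40L,
                             cluster_fraction = 0.5, cluster_sd = 9,
                             cell_radius_range = c(3.5, 6.5),
                             shape_irregularity = 0.25,
                             halo_strength = 70,
                             background_level = 128,
                             background_noise_sd = 6,
                             red_fraction = 0.2,
                             red_intensity_range = c(160, 240),
                             seed = 1L) {
  cfg <- list(height = as.integer(height), width = as.integer(width),
              n_cells = as.integer(n_cells),
              cluster_fraction = cluster_fraction, cluster_sd = cluster_sd,
              cell_radius_range = cell_radius_range,
              shape_irregularity = shape_irregularity,
              halo_strength = halo_strength,
              background_level = background_level,
              background_noise_sd = background_noise_sd,
              red_fraction = red_fraction,
              red_intensity_range = red_intensity_range,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(height >= 8L, width >= 8L, n_cells >= 0L,
              cluster_fraction >= 0, cluster_fraction <= 1,
              red_fraction >= 0, red_fraction <= 1,
              cell_radius_range[1] <= cell_radius_range[2],
              cell_radius_range[1] > 0,
              shape_irregularity >= 0, cluster_sd > 0,
              background_level >= 0, background_level <= 255,
              red_intensity_range[1] <= red_intensity_range[2],
              red_intensity_range[1] >= 0, red_intensity_range[2] <= 255)
  })
  structure(cfg, class = "synthetic_config")
}

## run `expr` under a private RNG stream, restoring the caller's state
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate one synthetic annotated scene
#'
#' Deterministic given `cfg$seed`. Cells are drawn as radially perturbed
#' ellipses (star-convex but non-convex outlines) with a dark interior and a
#' bright phase-contrast halo; `round(red_fraction * n_cells)` of them are
#' additionally painted into the red channel at an intensity drawn from
#' `red_intensity_range`. The annotation of a cell is the integer centroid
#' of its body; centroids are kept at least 2 px apart so marks stay
#' distinct even when bodies overlap.
#'
#' @param cfg A [synthetic_config()].
#' @return An object of class `synthetic_scene`: list with `image` (RGB
#'   [raster_image()]), `annotations` ([point_annotations()], one mark per
#'   cell, same order as generated), `red_flags` (logical per cell),
#'   `config` (the `cfg`).
#' @export
generate_scene <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  .with_seed(cfg$seed, .generate_scene_impl(cfg))
}

.generate_scene_impl <- function(cfg) {
  H <- cfg$height; W <- cfg$width; n <- cfg$n_cells
  margin <- cfg$cell_radius_range[2] + 1
  centers <- .place_centers(n, H, W, margin, cfg)

  gray <- matrix(cfg$background_level, H, W)
  redch <- matrix(0, H, W)
  n_red <- round(cfg$red_fraction * n)
  red_flags <- rep(FALSE, n)
  if (n_red > 0L) red_flags[sample.int(n, n_red)] <- TRUE

  pts <- matrix(0L, nrow = n, ncol = 2L)
  n_harm <- 5L
  for (i in seq_len(n)) {
    r0 <- stats::runif(1, cfg$cell_radius_range[1], cfg$cell_radius_range[2])
    ecc <- stats::runif(1, 0.65, 1)       # ellipse axis ratio
    phi <- stats::runif(1, 0, pi)         # orientation
    amp <- stats::runif(n_harm, 0, cfg$shape_irregularity)
    pha <- stats::runif(n_harm, 0, 2 * pi)
    depth <- stats::runif(1, 0.25, 0.5)   # interior darkening factor
    cell <- .rasterize_cell(centers[i, ], r0, ecc, phi, amp, pha, H, W)
    body <- cell$body; halo <- cell$halo
    gray[body] <- gray[body] * (1 - depth)
    gray[halo] <- gray[halo] + cfg$halo_strength
    if (red_flags[i]) {
      ri <- stats::runif(1, cfg$red_intensity_range[1], cfg$red_intensity_range[2])
      redch[body] <- pmax(redch[body], ri)
      redch[halo] <- pmax(redch[halo], ri)
    }
    pts[i, ] <- cell$centroid
  }
  pts <- .resolve_duplicate_marks(pts, H, W)
  ## noise, clipping, assembly. Phase contrast lives in all three channels,
  ## but the red channel carries only a 25% bleed-through of it plus the
  ## fluorescence overlay, mimicking a composite where the Cy3 channel is
  ## mapped to red: non-fluorescent structures stay well below any sensible
  ## red threshold while fluorescent cells sit at their drawn intensity.
  noise  <- matrix(stats::rnorm(H * W, 0, cfg$background_noise_sd), H, W)
  noise_r <- matrix(stats::rnorm(H * W, 0, cfg$background_noise_sd), H, W)
  gray <- pmin(255, pmax(0, round(gray + noise)))
  bleed <- pmin(255, pmax(0, round(0.25 * gray + noise_r)))
  rch <- ifelse(redch > 0, pmin(255, round(redch)), bleed)
  px <- array(0L, dim = c(H, W, 3L))
  px[, , 1] <- as.integer(rch)
  px[, , 2] <- as.integer(gray)
  px[, , 3] <- as.integer(gray)
  structure(list(image = raster_image(px),
                 annotations = point_annotations(pts, H, W),
                 red_flags = red_flags, config = cfg),
            class = "synthetic_scene")
}

## annotations must be distinct pixels: if two centroids collide, move the
## later one to the nearest free pixel (spiral search, clipped to frame)
.resolve_duplicate_marks <- function(pts, H, W) {
  if (nrow(pts) < 2L) return(pts)
  used <- new.env(hash = TRUE)
  key <- function(p) paste(p[1], p[2])
  for (i in seq_len(nrow(pts))) {
    p <- pts[i, ]
    if (!is.null(used[[key(p)]])) {
      found <- FALSE
      for (rad in 1L:6L) {
        offs <- expand.grid(dr = -rad:rad, dc = -rad:rad)
        offs <- offs[pmax(abs(offs$dr), abs(offs$dc)) == rad, ]
        for (o in seq_len(nrow(offs))) {
          q <- c(p[1] + offs$dr[o], p[2] + offs$dc[o])
          if (q[1] >= 0L && q[1] < H && q[2] >= 0L && q[2] < W &&
              is.null(used[[key(q)]])) {
            p <- as.integer(q); found <- TRUE; break
          }
        }
        if (found) break
      }
      if (!found) stop("could not find a free annotation pixel")
      pts[i, ] <- p
    }
    used[[key(p)]] <- TRUE
  }
  pts
}

## Thomas-process + uniform placement with a minimum 2 px centroid spacing
.place_centers <- function(n, H, W, margin, cfg, max_attempts = 200L) {
  if (n == 0L) return(matrix(numeric(), ncol = 2L))
  n_clustered <- round(cfg$cluster_fraction * n)
  n_parents <- max(1L, round(n_clustered / 8))
  parents <- cbind(stats::runif(n_parents, margin, H - margin),
                   stats::runif(n_parents, margin, W - margin))
  centers <- matrix(0, n, 2L)
  placed <- matrix(numeric(), ncol = 2L)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (a in seq_len(max_attempts)) {
      if (i <= n_clustered) {
        pj <- parents[sample.int(n_parents, 1L), ]
        cand <- pj + stats::rnorm(2, 0, cfg$cluster_sd)
      } else {
        cand <- c(stats::runif(1, margin, H - margin),
                  stats::runif(1, margin, W - margin))
      }
      cand <- pmin(pmax(cand, margin), c(H, W) - margin)
      if (nrow(placed) == 0L ||
          min((placed[, 1] - cand[1])^2 + (placed[, 2] - cand[2])^2) >= 9) {
        ok <- TRUE; break
      }
    }
    if (!ok) stop("could not place cell ", i,
                  " with 2 px centroid separation after ", max_attempts,
                  " attempts; reduce n_cells or enlarge the frame")
    centers[i, ] <- cand
    placed <- rbind(placed, cand)
  }
  centers
}

## star-convex outline: pixel is in the body iff its distance from the
## centre is below R(theta) in the ellipse metric with radial harmonics
.rasterize_cell <- function(center, r0, ecc, phi, amp, pha, H, W) {
  rmax <- r0 * (1 + sum(amp)) / min(ecc, 1) + 2.5
  r_lo <- max(1, floor(center[1] - rmax)); r_hi <- min(H, ceiling(center[1] + rmax))
  c_lo <- max(1, floor(center[2] - rmax)); c_hi <- min(W, ceiling(center[2] + rmax))
  rr <- r_lo:r_hi; cc <- c_lo:c_hi
  dy <- outer(rr - center[1], rep(1, length(cc)))
  dx <- outer(rep(1, length(rr)), cc - center[2])
  ## rotate into the ellipse frame and squeeze the minor axis
  u <- cos(phi) * dx + sin(phi) * dy
  v <- (-sin(phi) * dx + cos(phi) * dy) / ecc
  d <- sqrt(u^2 + v^2)
  th <- atan2(v, u)
  Rb <- r0 * (1 + Reduce(`+`, lapply(seq_along(amp), function(h)
    amp[h] * cos((h + 1) * th + pha[h]))))
  Rb <- pmax(Rb, 1)
  inside <- d <= Rb
  rim <- !inside & d <= Rb + 1.6
  idx <- function(m) {
    w <- which(m, arr.ind = TRUE)
    cbind(rr[w[, 1]], cc[w[, 2]])
  }
  b <- idx(inside)
  centroid <- if (nrow(b) > 0L) {
    cbind(as.integer(round(mean(b[, 1]))) - 1L,
          as.integer(round(mean(b[, 2]))) - 1L)
  } else {
    cbind(as.integer(round(center[1])) - 1L, as.integer(round(center[2])) - 1L)
  }
  centroid[1] <- min(max(centroid[1], 0L), H - 1L)
  centroid[2] <- min(max(centroid[2], 0L), W - 1L)
  list(body = b, halo = idx(rim), centroid = centroid)
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene %d x %d: %d cells (%d red), seed %d>\n",
              x$config$height, x$config$width, n_cells(x$annotations),
              sum(x$red_flags), x$config$seed))
  invisible(x)
}

#' Generate a train/validation/test fixture suite
#'
#' Derives one child seed per scene from the master seed, so two suites
#' built from the same master seed are identical, scene by scene. The
#' default sizes mirror the bookkeeping of a 20-image labelled corpus split
#' 8:2 into training and validation, plus a held-out test series, at reduced
#' scale (16 / 4 / 8).
#'
#' @param base_cfg A [synthetic_config()] used for every scene (its `seed`
#'   field is ignored).
#' @param n_train,n_val,n_test Scene counts, each `>= 0`.
#' @param seed Master seed.
#' @return List with scene lists `train`, `val`, `test`.
#' @export
generate_fixture_suite <- function(base_cfg, n_train = 16L, n_val = 4L,
                                   n_test = 8L, seed = 1L) {
  stopifnot(inherits(base_cfg, "synthetic_config"),
            n_train >= 0L, n_val >= 0L, n_test >= 0L)
  total <- n_train + n_val + n_test
  ## child seeds drawn from a seeded stream, kept within 32-bit range
  child_seeds <- .with_seed(seed, sample.int(2147483646L, total))
  make <- function(idx) lapply(idx, function(i) {
    cfg_i <- base_cfg
    cfg_i$seed <- child_seeds[i]
    generate_scene(cfg_i)
  })
  list(train = make(seq_len(n_train)),
       val   = make(seq_len(n_val) + n_train),
       test  = make(seq_len(n_test) + n_train + n_val))
}

#' Materialize scenes as image + annotation files
#'
#' Writes, for scene `i`, `scene_<i>.tif` (RGB), `scene_<i>_annotations.csv`
#' (`row,col`) and `scene_<i>_red.csv` (`cell,red` flags).
#'
#' @param scenes List of `synthetic_scene`s.
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix, default `"scene"`.
#' @return Character vector of image paths, invisibly.
#' @export
export_scenes <- function(scenes, dir, prefix = "scene") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(length(scenes))
  for (i in seq_along(scenes)) {
    sc <- scenes[[i]]
    stem <- file.path(dir, sprintf("%s_%03d", prefix, i))
    paths[i] <- paste0(stem, ".tif")
    write_image(sc$image, paths[i])
    write_annotations(sc$annotations, paste0(stem, "_annotations.csv"))
    utils::write.csv(
      data.frame(cell = seq_along(sc$red_flags) - 1L,
                 red = as.integer(sc$red_flags)),
      paste0(stem, "_red.csv"), row.names = FALSE, quote = FALSE)
  }
  invisible(paths)
}
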