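# Synthetic vascular-network images and oracle fixtures.
#
# The generator emulates binarized fluorescence images of self-assembled
# microvascular networks: trunks enter from the left/right image edges,
# perform branching correlated random walks, and are dilated to a capillary
# scale width; a few isolated elliptical blobs model disconnected vessel
# fragments. Coverage is controlled to a target percentage.

#' Synthetic network specification
#'
#' Default values describe the study conditions used throughout the test
#' suite: 256 x 256 px at 5 um/px (a 1.28 mm field of view), capillary-scale
#' vessel widths of 4 px (20 um), trunks entering from both inlet sides and
#' a few disconnected fragments.
#'
#' @param seed RNG seed (integer); the same spec always produces the same
#'   image.
#' @param target_coverage target vessel coverage in percent, in (0, 100).
#' @param n_trunks number of inlet-attached trunk walks.
#' @param branch_prob per-step probability that a walk spawns a branch.
#' @param step_length walk step in px.
#' @param wander_angle sd of the per-step heading change (radians).
#' @param vessel_width_px dilation width (px) of rasterized walks.
#' @param n_disconnected number of isolated elliptical blobs.
#' @param width,height image size in px.
#' @param pixel_size um per pixel.
#' @return a `network_spec` list.
#' @export
network_spec <- function(seed = 1, target_coverage = 30, n_trunks = 4,
                         branch_prob = 0.08, step_length = 4,
                         wander_angle = 0.35, vessel_width_px = 4,
                         n_disconnected = 3, width = 256, height = 256,
                         pixel_size = 5) {
  stopifnot(target_coverage > 0, target_coverage < 100,
            n_trunks >= 0, n_disconnected >= 0)
  structure(list(seed = seed, target_coverage = target_coverage,
                 n_trunks = n_trunks, branch_prob = branch_prob,
                 step_length = step_length, wander_angle = wander_angle,
                 vessel_width_px = vessel_width_px,
                 n_disconnected = n_disconnected,
                 width = width, height = height, pixel_size = pixel_size),
            class = "network_spec")
}

# run fn with a private RNG stream; global .Random.seed is untouched
.with_seed <- function(seed, fn) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

# rasterize a set of polyline segments (x0,y0,x1,y1 in px, y-up) onto an
# H x W logical grid
.rasterize_segments <- function(segs, H, W) {
  img <- matrix(FALSE, H, W)
  if (!nrow(segs)) return(img)
  len <- sqrt((segs[, 3L] - segs[, 1L])^2 + (segs[, 4L] - segs[, 2L])^2)
  for (i in seq_len(nrow(segs))) {
    n <- max(2L, ceiling(len[i] / 0.4))
    t <- seq(0, 1, length.out = n)
    x <- segs[i, 1L] + t * (segs[i, 3L] - segs[i, 1L])
    y <- segs[i, 2L] + t * (segs[i, 4L] - segs[i, 2L])
    c0 <- pmin(pmax(ceiling(x), 1L), W)
    r0 <- pmin(pmax(ceiling(H - y + 1e-9), 1L), H)
    img[cbind(r0, c0)] <- TRUE
  }
  img
}

.dilate_disc <- function(img, width_px) {
  if (width_px <= 1) return(img)
  k <- 2L * floor(width_px / 2) + 1L
  EBImage::dilate(img * 1, EBImage::makeBrush(k, shape = "disc")) > 0
}

# one batch of branching correlated random walks; returns segment matrix
.grow_walks <- function(n_trunks, spec) {
  W <- spec$width; H <- spec$height
  segs <- NULL
  queue <- list()
  for (i in seq_len(n_trunks)) {
    from_left <- i %% 2L == 1L
    queue[[length(queue) + 1L]] <- list(
      x = if (from_left) 0 else W,
      y = runif(1, 0.15 * H, 0.85 * H),
      ang = if (from_left) rnorm(1, 0, 0.3) else pi + rnorm(1, 0, 0.3),
      steps = 0L)
  }
  max_steps <- ceiling(2.5 * W / spec$step_length)
  n_branches <- 0L
  while (length(queue)) {
    w <- queue[[length(queue)]]
    queue[[length(queue)]] <- NULL
    repeat {
      if (w$steps >= max_steps) break
      w$ang <- w$ang + rnorm(1, 0, spec$wander_angle)
      nx <- w$x + spec$step_length * cos(w$ang)
      ny <- w$y + spec$step_length * sin(w$ang)
      ny <- min(max(ny, 1), H - 1)
      segs <- rbind(segs, c(w$x, w$y, nx, ny))
      w$x <- nx; w$y <- ny; w$steps <- w$steps + 1L
      if (w$x < -spec$step_length || w$x > W + spec$step_length) break
      if (runif(1) < spec$branch_prob && n_branches < 12L * n_trunks) {
        n_branches <- n_branches + 1L
        queue[[length(queue) + 1L]] <- list(
          x = w$x, y = w$y,
          ang = w$ang + sample(c(-1, 1), 1L) * runif(1, 0.5, 1.1),
          steps = w$steps)
      }
    }
  }
  if (is.null(segs)) matrix(numeric(0), 0L, 4L) else segs
}

.add_blobs <- function(img, n, spec) {
  H <- nrow(img); W <- ncol(img)
  for (i in seq_len(n)) {
    cx <- runif(1, 0.2 * W, 0.8 * W)
    cy <- runif(1, 0.2 * H, 0.8 * H)
    rx <- runif(1, 3, 8); ry <- runif(1, 2, 5)
    th <- runif(1, 0, pi)
    xs <- pmin(pmax(round(cx + c(-12:12)), 1L), W)
    ys <- pmin(pmax(round(cy + c(-12:12)), 1L), H)
    for (c0 in unique(xs)) for (r0 in unique(H - ys + 1L)) {
      dx <- c0 - cx; dy <- (H - r0 + 1) - cy
      u <- dx * cos(th) + dy * sin(th)
      v <- -dx * sin(th) + dy * cos(th)
      if ((u / rx)^2 + (v / ry)^2 <= 1) img[r0, c0] <- TRUE
    }
  }
  img
}

#' Generate a synthetic vascular-network image
#'
#' Deterministic given the spec: trunks start at the left/right image
#' edges, perform branching correlated random walks, are rasterized and
#' dilated to the vessel width; disconnected elliptical blobs are added in
#' the interior. The walk count is scaled over up to 50 attempts until the
#' measured coverage is within +/- 5 percentage points of the target.
#'
#' @param spec a [network_spec()].
#' @return a [binary_image()]; attribute `achieved_coverage` stores the
#'   measured coverage (%).
#' @export
generate_network <- function(spec = network_spec()) {
  stopifnot(inherits(spec, "network_spec"))
  .with_seed(spec$seed, function() {
    H <- spec$height; W <- spec$width
    f <- 1
    best <- NULL; best_err <- Inf
    for (attempt in 1:50) {
      n_tr <- max(if (spec$n_trunks > 0) 1L else 0L,
                  round(spec$n_trunks * f))
      img <- matrix(FALSE, H, W)
      if (n_tr > 0L) {
        segs <- .grow_walks(n_tr, spec)
        img <- .rasterize_segments(segs, H, W)
      }
      img <- .dilate_disc(img, spec$vessel_width_px)
      img <- .add_blobs(img, spec$n_disconnected, spec)
      cov <- 100 * mean(img)
      err <- abs(cov - spec$target_coverage)
      if (err < best_err) { best <- img; best_err <- err }
      if (err <= 5) break
      if (spec$n_trunks == 0L) break
      f <- f * min(2, max(0.5, spec$target_coverage / max(cov, 1)))
    }
    if (best_err > 5 && spec$n_trunks > 0L)
      stop(sprintf("could not reach target coverage %.0f%% (best %.1f%% off)",
                   spec$target_coverage, best_err))
    out <- binary_image(best * 1.0, spec$pixel_size)
    attr(out, "achieved_coverage") <- 100 * mean(best)
    out
  })
}

#' Generate a full-width channel fixture
#'
#' A single horizontal vessel strip touching both inlet sides; the rest is
#' tissue. Used as an analytically tractable transport fixture.
#'
#' @param width_px,height_px image size in px.
#' @param strip_height_px strip thickness in px (centered vertically).
#' @param pixel_size um/pixel.
#' @return a `domain_image` with the strip as connected vessel (code 1).
#' @export
generate_channel <- function(width_px = 100, height_px = 100,
                             strip_height_px = 20, pixel_size = 1) {
  stopifnot(strip_height_px <= height_px)
  codes <- matrix(0, height_px, width_px)
  r0 <- floor((height_px - strip_height_px) / 2) + 1L
  codes[r0:(r0 + strip_height_px - 1L), ] <- 1
  domain_image(codes, pixel_size = pixel_size)
}

#' Generate a two-wall slab fixture
#'
#' Vertical vessel walls along the left and right image edges enclosing a
#' tissue slab: the 1D reaction-diffusion problem across the slab has the
#' closed form of [closed_form_slab()], making this the reference fixture
#' for tissue-phase kinetics.
#'
#' @param width_px,height_px image size in px.
#' @param wall_px wall thickness in px on each side.
#' @param pixel_size um/pixel.
#' @return a `domain_image`; attribute `slab_L_um` gives the tissue slab
#'   width in um and `slab_x0_um` the left interface position.
#' @export
generate_slab <- function(width_px = 120, height_px = 60, wall_px = 10,
                          pixel_size = 1) {
  stopifnot(2 * wall_px < width_px)
  codes <- matrix(0, height_px, width_px)
  codes[, c(seq_len(wall_px), (width_px - wall_px + 1L):width_px)] <- 1
  out <- domain_image(codes, pixel_size = pixel_size)
  attr(out, "slab_L_um") <- (width_px - 2 * wall_px) * pixel_size
  attr(out, "slab_x0_um") <- wall_px * pixel_size
  out
}

#' Synthetic batch presets emulating a multi-condition image population
#'
#' Five coverage bands (10, 25, 40, 60, 75 %) x `n_per_band` seeds,
#' mimicking experimental condition groups spanning poorly to densely
#' vascularized networks.
#'
#' @param n_per_band images per coverage band.
#' @param seed_offset added to each image's seed (so different offsets give
#'   independent replicate batches).
#' @param size image side in px.
#' @return list of [network_spec()] objects with names `band<cov>_s<seed>`.
#' @export
synth_preset_bands <- function(n_per_band = 10, seed_offset = 0, size = 256) {
  bands <- c(10, 25, 40, 60, 75)
  specs <- list()
  for (b in bands) {
    for (s in seq_len(n_per_band)) {
      seed <- seed_offset + b * 1000L + s
      # denser targets need more trunks to be reachable
      specs[[sprintf("band%02d_s%02d", b, s)]] <- network_spec(
        seed = seed, target_coverage = b,
        n_trunks = max(2L, round(b / 8)),
        n_disconnected = 3,
        width = size, height = size)
    }
  }
  specs
}
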