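#' Gaussian-blob image dataset with hidden causes
#'
#' Each image is generated by first drawing a hidden cause `k` from
#' `priors`, then switching every pixel on independently with a probability
#' given by a Gaussian bump centred at `centers[k, ]` (peak `p_max`,
#' isotropic width `blob_sigma`). Pixels that are on in fewer than
#' `min_active_frac` of all images are removed, and the retained pixels
#' are randomly permuted to a 1D index (hiding both the 2D structure and
#' the cause from the downstream network). Each retained pixel is encoded
#' by two input channels (on/off population code).
#'
#' Defaults place the four centers at the quadrant midpoints of a 28 x 28
#' grid with priors (0.1, 0.2, 0.3, 0.4).
#'
#' @param n_images Number of images.
#' @param centers `K x 2` matrix of blob centers (pixel coordinates).
#' @param blob_sigma Gaussian width in pixels.
#' @param priors Cause probabilities (simplex).
#' @param p_max Peak on-probability at a blob center.
#' @param grid Grid side length in pixels.
#' @param min_active_frac Pixels on in less than this fraction of images
#'   are dropped.
#' @return An object of class `labeled_image_dataset`: list with `images`
#'   (`n x n_retained` binary matrix, permuted pixel order), `labels`,
#'   `pixel_mask` (logical over the original grid), `permutation`
#'   (retained-pixel order), `code` (the on/off [binary_code()]),
#'   `patterns` (evidence-matrix view: 1 = on, 2 = off), `grid`,
#'   `centers`, `priors`.
#' @export
gaussian_blob_dataset <- function(n_images,
                                  centers = matrix(c(7, 7, 7, 21, 21, 7,
                                                     21, 21),
                                                   ncol = 2, byrow = TRUE),
                                  blob_sigma = 4,
                                  priors = c(0.1, 0.2, 0.3, 0.4),
                                  p_max = 0.9, grid = 28L,
                                  min_active_frac = 0.04) {
  if (any(priors < 0) || abs(sum(priors) - 1) > 1e-9) {
    stop("degenerate priors: need a probability vector summing to 1")
  }
  stopifnot(nrow(centers) == length(priors))
  K <- length(priors)
  xy <- expand.grid(x = seq_len(grid), y = seq_len(grid))
  # per-cause on-probability per pixel
  pon <- vapply(seq_len(K), function(k) {
    d2 <- (xy$x - centers[k, 1])^2 + (xy$y - centers[k, 2])^2
    p_max * exp(-d2 / (2 * blob_sigma^2))
  }, numeric(grid * grid))
  labels <- sample.int(K, n_images, replace = TRUE, prob = priors)
  imgs <- matrix(stats::runif(n_images * grid * grid) <
                   t(pon[, labels, drop = FALSE]),
                 nrow = n_images)
  active_frac <- colMeans(imgs)
  mask <- active_frac >= min_active_frac
  if (!any(mask)) stop("no pixel survives the activity threshold")
  permutation <- sample(which(mask))
  images <- imgs[, permutation, drop = FALSE]
  storage.mode(images) <- "integer"
  structure(
    list(images = images, labels = labels, pixel_mask = mask,
         permutation = permutation, code = binary_code(ncol(images)),
         patterns = ifelse(images == 1L, 1L, 2L),
         grid = grid, centers = centers, priors = priors),
    class = "labeled_image_dataset"
  )
}

#' @export
print.labeled_image_dataset <- function(x, ...) {
  cat(sprintf("<labeled_image_dataset> %d images, %d retained pixels (of %d), %d causes\n",
              nrow(x$images), ncol(x$images), x$grid^2,
              length(unique(x$labels))))
  invisible(x)
}

#' Noisy oriented-bar image
#'
#' A bar of width `width_px` through the grid center at the given
#' orientation: pixels within perpendicular distance `width_px / 2` of the
#' center line are on. Every pixel is then flipped independently with
#' probability `flip_prob`, and a circular mask of radius `grid / 2`
#' around the center zeroes everything outside (avoiding corner
#' artifacts). Orientations `theta` and `theta + 180` give identical
#' images.
#'
#' @param angle Orientation in degrees, `[0, 180)` (values outside are
#'   wrapped).
#' @param width_px Bar width in pixels.
#' @param grid Grid side length.
#' @param flip_prob Per-pixel flip probability.
#' @return `grid x grid` binary integer matrix.
#' @export
oriented_bar_image <- function(angle, width_px = 7, grid = 28L,
                               flip_prob = 0.02) {
  angle <- angle %% 180
  cx <- grid / 2  # pixel-centred, so an odd width gives that many rows
  xy <- expand.grid(x = seq_len(grid), y = seq_len(grid))
  th <- angle * pi / 180
  # perpendicular distance to the line through the center at angle th
  d <- abs(-sin(th) * (xy$x - cx) + cos(th) * (xy$y - cx))
  img <- as.integer(d <= width_px / 2)
  if (flip_prob > 0) {
    flip <- stats::runif(grid * grid) < flip_prob
    img <- ifelse(flip, 1L - img, img)
  }
  inside <- (xy$x - cx)^2 + (xy$y - cx)^2 <= (grid / 2)^2
  img[!inside] <- 0L
  matrix(img, grid, grid)
}

#' Dataset of oriented bars at uniform random angles
#'
#' @param n_images Number of images.
#' @inheritParams oriented_bar_image
#' @return List with `patterns` (evidence matrix over pixels: 1 = on,
#'   2 = off), `angles` (degrees), `code` (on/off [binary_code()]) and
#'   `grid`.
#' @export
oriented_bar_dataset <- function(n_images, width_px = 7, grid = 28L,
                                 flip_prob = 0.02) {
  angles <- stats::runif(n_images, 0, 180)
  pats <- t(vapply(angles, function(a) {
    as.vector(oriented_bar_image(a, width_px, grid, flip_prob))
  }, integer(grid * grid)))
  list(patterns = ifelse(pats == 1L, 1L, 2L), angles = angles,
       code = binary_code(grid * grid), grid = grid)
}

#' Spike stream with embedded frozen spatio-temporal patterns
#'
#' Five (by default) fixed "frozen" Poisson spike patterns — a single
#' random draw of Poisson spikes at `pattern_rate` Hz over
#' `pattern_len_ms` on all channels, replayed identically at every
#' presentation — are embedded in noise: during a presentation,
#' independent Poisson overlay noise at `overlay_noise_rate` Hz is added;
#' between presentations, pure Poisson noise at `gap_noise_rate` Hz runs
#' for a random duration drawn uniformly from `gap_range_ms`. With the
#' default rates (15 + 5 = 20 Hz) the stream is rate-stationary: channel
#' rates inside and outside patterns match.
#'
#' @param total_duration Stream length in ms.
#' @param n_channels Number of input channels.
#' @param n_patterns Number of distinct frozen patterns.
#' @param pattern_len_ms Pattern duration in ms.
#' @param pattern_rate Rate of the frozen patterns (Hz).
#' @param overlay_noise_rate Noise rate superimposed on patterns (Hz).
#' @param gap_noise_rate Rate of the pure-noise segments (Hz).
#' @param gap_range_ms Range (min, max) of the uniform gap-length law, ms.
#' @param frozen Optional list of pre-drawn frozen patterns (as returned
#'   in `$frozen`), to replay the same patterns in a fresh stream.
#' @return An object of class `pattern_stream`: list with `train` (a
#'   [spike_train()]), `intervals` (data.frame `start`, `end`,
#'   `pattern` with 0 = noise) and `frozen` (list of the frozen patterns'
#'   spike times/channels).
#' @export
pattern_stream <- function(total_duration, n_channels = 500L,
                           n_patterns = 5L, pattern_len_ms = 50,
                           pattern_rate = 15, overlay_noise_rate = 5,
                           gap_noise_rate = 20,
                           gap_range_ms = c(50, 150), frozen = NULL) {
  stopifnot(pattern_rate >= 0, overlay_noise_rate >= 0,
            gap_noise_rate >= 0, total_duration > 0)
  if (is.null(frozen)) {
    frozen <- lapply(seq_len(n_patterns), function(p) {
      tr <- poisson_train(pattern_rate, pattern_len_ms, n_channels)
      list(time = tr$time, channel = tr$channel)
    })
  } else {
    n_patterns <- length(frozen)
  }
  times <- list(); chans <- list()
  starts <- numeric(); ends <- numeric(); ids <- integer()
  t0 <- 0; seg <- 0L
  add_seg <- function(tr, id, dur) {
    seg <<- seg + 1L
    times[[seg]] <<- tr$time + t0
    chans[[seg]] <<- tr$channel
    starts[seg] <<- t0; ends[seg] <<- t0 + dur; ids[seg] <<- id
    t0 <<- t0 + dur
  }
  while (t0 < total_duration) {
    gap <- stats::runif(1, gap_range_ms[1], gap_range_ms[2])
    tr <- poisson_train(gap_noise_rate, gap, n_channels)
    add_seg(list(time = tr$time, channel = tr$channel), 0L, gap)
    if (t0 >= total_duration) break
    id <- sample.int(n_patterns, 1L)
    ov <- poisson_train(overlay_noise_rate, pattern_len_ms, n_channels)
    add_seg(list(time = c(frozen[[id]]$time, ov$time),
                 channel = c(frozen[[id]]$channel, ov$channel)),
            id, pattern_len_ms)
  }
  train <- spike_train(unlist(times), unlist(chans),
                       n_channels = n_channels, duration = t0)
  structure(
    list(train = train,
         intervals = data.frame(start = starts, end = ends,
                                pattern = ids),
         frozen = frozen),
    class = "pattern_stream"
  )
}

#' @export
print.pattern_stream <- function(x, ...) {
  np <- sum(x$intervals$pattern > 0)
  cat(sprintf("<pattern_stream> %.0f ms, %d pattern presentations (%d distinct), %d spikes\n",
              train_duration(x$train), np, length(x$frozen),
              n_spikes(x$train)))
  invisible(x)
}
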