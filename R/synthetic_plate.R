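#' Specification for a synthetic plate time-lapse
#'
#' Describes a scanner-style time-lapse of a petri dish: image geometry,
#' frame timing, background and colony intensity levels (value-channel units
#' in \[0, 1\]), per-pixel Gaussian noise, and one row per colony giving its
#' centre, appearance lag, initial area, exponential area growth rate and
#' saturation area. Colony area grows as
#' \eqn{A(t) = \min(A_0 e^{r (t - lag)}, A_{max})} for \eqn{t > lag} and the
#' colony is rendered as a disk of radius \eqn{\sqrt{A/\pi}}.
#'
#' @param image_width_px,image_height_px frame size in pixels
#' @param frame_interval_h hours between frames (default 2, the scan cadence
#'   of the screening protocol)
#' @param n_frames number of frames (default 129, i.e. 256 h at 2-h steps)
#' @param colonies data.frame with columns `x`, `y` (centre, pixels; `x` is
#'   the column index, `y` the row index), `lag_h`, `init_area_px`,
#'   `rate_per_h`, `max_area_px`, and optionally `edge_ok` (logical; permit
#'   the rendered disk to extend past the frame border)
#' @param background_level,colony_level value-channel levels of agar and
#'   biomass; `colony_level` must exceed `background_level`
#' @param noise_sd per-pixel Gaussian noise standard deviation
#' @param rng_seed integer seed; identical specs give bit-identical output
#' @return object of class `plate_spec`
#' @export
plate_spec <- function(image_width_px, image_height_px,
                       frame_interval_h = 2, n_frames = 129,
                       colonies = empty_colony_table(),
                       background_level = 0.2, colony_level = 0.7,
                       noise_sd = 0.05, rng_seed = 1L) {
  .assert(n_frames >= 2, "n_frames must be >= 2")
  .assert(frame_interval_h > 0, "frame_interval_h must be positive")
  .assert(colony_level > background_level,
          "colony_level must exceed background_level")
  .assert(background_level >= 0 && colony_level <= 1,
          "intensity levels must lie in [0, 1]")
  .assert(noise_sd >= 0, "noise_sd must be non-negative")
  colonies <- as.data.frame(colonies)
  if (is.null(colonies$edge_ok)) colonies$edge_ok <- rep(FALSE, nrow(colonies))
  if (nrow(colonies) > 0) {
    .assert(all(c("x", "y", "lag_h", "init_area_px", "rate_per_h",
                  "max_area_px") %in% names(colonies)),
            "colony table is missing required columns")
    .assert(all(colonies$x >= 1 & colonies$x <= image_width_px &
                colonies$y >= 1 & colonies$y <= image_height_px),
            "all colony centers must lie inside the image")
    .assert(all(colonies$rate_per_h >= 0), "growth rates must be >= 0")
    .assert(all(colonies$lag_h >= 0), "colony lag times must be >= 0")
    if (any(colonies$lag_h <= 0)) {
      warning("colonies with lag_h = 0 appear in the first frame, which ",
              "will then not be colony-free background")
    }
    .assert(all(colonies$init_area_px > 0 & colonies$max_area_px > 0),
            "areas must be positive")
    rmax <- sqrt(colonies$max_area_px / pi)
    inside <- colonies$x - rmax >= 1 & colonies$x + rmax <= image_width_px &
      colonies$y - rmax >= 1 & colonies$y + rmax <= image_height_px
    bad <- !inside & !colonies$edge_ok
    .assert(!any(bad), sum(bad), " colony disk(s) would exceed the frame; ",
            "set edge_ok = TRUE for intended edge colonies")
  }
  structure(list(
    image_width_px = as.integer(image_width_px),
    image_height_px = as.integer(image_height_px),
    frame_interval_h = frame_interval_h,
    n_frames = as.integer(n_frames),
    colonies = colonies,
    background_level = background_level,
    colony_level = colony_level,
    noise_sd = noise_sd,
    rng_seed = as.integer(rng_seed)
  ), class = "plate_spec")
}

#' Empty colony table with the columns `plate_spec()` expects
#' @return zero-row data.frame
#' @export
empty_colony_table <- function() {
  data.frame(x = numeric(0), y = numeric(0), lag_h = numeric(0),
             init_area_px = numeric(0), rate_per_h = numeric(0),
             max_area_px = numeric(0), edge_ok = logical(0))
}

#' Time-lapse image series
#'
#' Ordered stack of same-sized frames with strictly increasing acquisition
#' times. RGB frames are height x width x 3 arrays, grayscale frames are
#' matrices; values in \[0, 1\].
#'
#' @param frames list of frames
#' @param times_h numeric acquisition times in hours
#' @param channels `"rgb"` or `"gray"`
#' @return object of class `image_series`
#' @export
image_series <- function(frames, times_h, channels = c("rgb", "gray")) {
  channels <- match.arg(channels)
  .assert(length(frames) == length(times_h),
          "frames and times_h must have equal length")
  .assert(length(times_h) == 0 || all(diff(times_h) > 0),
          "frame times must be strictly increasing")
  dims <- unique(lapply(frames, function(f) dim(f)[1:2]))
  .assert(length(dims) <= 1, "all frames must share the same dimensions")
  structure(list(frames = frames, times_h = times_h, channels = channels),
            class = "image_series")
}

#' @export
print.image_series <- function(x, ...) {
  d <- if (length(x$frames)) dim(x$frames[[1]]) else c(0, 0)
  cat(sprintf("<image_series> %d frames, %dx%d px, %s, t = %s..%s h\n",
              length(x$frames), d[1], d[2], x$channels,
              format(min(x$times_h)), format(max(x$times_h))))
  invisible(x)
}

# true (analytic) colony area at time t under capped exponential growth;
# the colony exists from its lag onward with A(lag) = a0
.true_area <- function(t, lag, a0, rate, amax) {
  ifelse(t >= lag, pmin(a0 * exp(rate * (t - lag)), amax), 0)
}

# logical disk mask: pixel centre within radius of (y=row, x=col)
.disk_mask <- function(nrow, ncol, cx, cy, radius) {
  if (radius <= 0) return(matrix(FALSE, nrow, ncol))
  r0 <- max(1L, floor(cy - radius)); r1 <- min(nrow, ceiling(cy + radius))
  c0 <- max(1L, floor(cx - radius)); c1 <- min(ncol, ceiling(cx + radius))
  m <- matrix(FALSE, nrow, ncol)
  if (r0 > r1 || c0 > c1) return(m)
  rr <- r0:r1; cc <- c0:c1
  sub <- outer((rr - cy)^2, (cc - cx)^2, `+`) <= radius^2
  m[rr, cc] <- sub
  m
}

#' Render a synthetic plate time-lapse with ground truth
#'
#' Draws each colony as a disk whose area follows capped exponential growth,
#' on a uniform background, adds per-pixel Gaussian noise, and replicates the
#' result into three equal RGB channels (so the HSV value channel recovers
#' the rendered signal exactly). The first frame precedes every colony's
#' appearance, making it a valid background frame. Ground truth records the
#' analytic and rasterised (noise-free pixel-count) area of every colony in
#' every frame, and the first frame at which each pair of colony disks
#' overlaps on the pixel grid.
#'
#' @param spec a [plate_spec()]
#' @return list with elements `series` (an [image_series()] of RGB frames),
#'   and `truth`: a list with `colonies` (the input table plus `colony_id`),
#'   `times_h`, `true_areas` and `raster_areas` (colony x frame matrices),
#'   and `merges` (data.frame `colony_a`, `colony_b`, `first_overlap_frame`,
#'   1-based, only pairs that ever overlap)
#' @export
simulate_plate <- function(spec) {
  .assert(inherits(spec, "plate_spec"), "spec must be a plate_spec")
  h <- spec$image_height_px; w <- spec$image_width_px
  times <- (seq_len(spec$n_frames) - 1) * spec$frame_interval_h
  cl <- spec$colonies
  n <- nrow(cl)
  true_areas <- matrix(0, nrow = n, ncol = spec$n_frames)
  raster_areas <- matrix(0L, nrow = n, ncol = spec$n_frames)
  merges <- list()
  first_overlap <- if (n >= 2) {
    m <- matrix(NA_integer_, n, n)
    m
  } else NULL

  withr::with_seed(spec$rng_seed, {
    frames <- vector("list", spec$n_frames)
    for (f in seq_len(spec$n_frames)) {
      t <- times[f]
      plane <- matrix(spec$background_level, h, w)
      masks_f <- vector("list", n)
      for (i in seq_len(n)) {
        a <- .true_area(t, cl$lag_h[i], cl$init_area_px[i],
                        cl$rate_per_h[i], cl$max_area_px[i])
        true_areas[i, f] <- a
        if (a > 0) {
          mk <- .disk_mask(h, w, cl$x[i], cl$y[i], sqrt(a / pi))
          raster_areas[i, f] <- sum(mk)
          plane[mk] <- spec$colony_level
          masks_f[[i]] <- mk
        }
      }
      if (n >= 2) {
        radius_f <- sqrt(true_areas[, f] / pi)
        for (i in seq_len(n - 1)) for (j in (i + 1):n) {
          # centre-distance prefilter before the exact pixel-grid test
          touching <- sqrt((cl$x[i] - cl$x[j])^2 + (cl$y[i] - cl$y[j])^2) <
            radius_f[i] + radius_f[j] + 2
          if (is.na(first_overlap[i, j]) && touching &&
              !is.null(masks_f[[i]]) && !is.null(masks_f[[j]]) &&
              any(masks_f[[i]] & masks_f[[j]])) {
            first_overlap[i, j] <- f
          }
        }
      }
      if (spec$noise_sd > 0) {
        plane <- plane + matrix(stats::rnorm(h * w, sd = spec$noise_sd), h, w)
      }
      plane <- .clip(plane)
      frames[[f]] <- array(plane, dim = c(h, w, 3))
    }
  })

  merges <- if (n >= 2) {
    idx <- which(!is.na(first_overlap), arr.ind = TRUE)
    data.frame(colony_a = idx[, 1], colony_b = idx[, 2],
               first_overlap_frame = first_overlap[idx])
  } else {
    data.frame(colony_a = integer(0), colony_b = integer(0),
               first_overlap_frame = integer(0))
  }
  cl$colony_id <- seq_len(n)
  list(
    series = image_series(frames, times, "rgb"),
    truth = list(colonies = cl, times_h = times, true_areas = true_areas,
                 raster_areas = raster_areas, merges = merges, spec = spec)
  )
}

#' Lay out a random plate specification on a jittered grid
#'
#' Convenience generator for benchmarking: places `n_colonies` on a grid with
#' spacing chosen so fully grown disks never merge or touch the border,
#' jitters centres, and draws growth rates uniformly from `rate_range`
#' (a colony is a no-growth colony, rate 0, with probability
#' `p_no_growth`). Defaults mirror the screening protocol: 2-h frames for
#' 256 h.
#'
#' @param n_colonies number of colonies
#' @param rate_range range of exponential area growth rates, per hour
#' @param p_no_growth probability a colony has growth rate zero
#' @param init_area_px,max_area_px initial and saturation colony areas
#' @param lag_range_h range of appearance lags, hours
#' @param jitter_px centre jitter amplitude
#' @param rng_seed seed (also used for the rendered noise)
#' @param ... further arguments passed to [plate_spec()]
#' @return a [plate_spec()]
#' @export
random_plate_spec <- function(n_colonies, rate_range = c(0.1, 0.6),
                              p_no_growth = 0, init_area_px = 100,
                              max_area_px = 20000, lag_range_h = c(2, 10),
                              jitter_px = 4, rng_seed = 1L, ...) {
  rmax <- sqrt(max_area_px / pi)
  spacing <- ceiling(2 * rmax + 12 + 2 * jitter_px)
  margin <- ceiling(rmax + 10 + jitter_px)
  ncols <- ceiling(sqrt(n_colonies))
  nrows <- ceiling(n_colonies / ncols)
  width <- 2 * margin + (ncols - 1) * spacing
  height <- 2 * margin + (nrows - 1) * spacing
  withr::with_seed(rng_seed, {
    gx <- margin + ((seq_len(n_colonies) - 1) %% ncols) * spacing
    gy <- margin + ((seq_len(n_colonies) - 1) %/% ncols) * spacing
    colonies <- data.frame(
      x = gx + stats::runif(n_colonies, -jitter_px, jitter_px),
      y = gy + stats::runif(n_colonies, -jitter_px, jitter_px),
      lag_h = stats::runif(n_colonies, lag_range_h[1], lag_range_h[2]),
      init_area_px = init_area_px,
      rate_per_h = ifelse(stats::runif(n_colonies) < p_no_growth, 0,
                          stats::runif(n_colonies, rate_range[1],
                                       rate_range[2])),
      max_area_px = max_area_px,
      edge_ok = FALSE
    )
  })
  plate_spec(image_width_px = width, image_height_px = height,
             colonies = colonies, rng_seed = rng_seed, ...)
}

#' Write an image series as numbered TIFF frames plus a timestamp manifest
#'
#' Frames are written as 16-bit TIFFs named `frame_0000.tif`,
#' `frame_0001.tif`, ... and a `manifest.csv` with columns `frame_index`
#' (0-based) and `time_h`.
#'
#' @param series an [image_series()]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_image_series <- function(series, dir) {
  .assert(inherits(series, "image_series"), "series must be an image_series")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(series$frames)) {
    tiff::writeTIFF(series$frames[[i]],
                    file.path(dir, sprintf("frame_%04d.tif", i - 1)),
                    bits.per.sample = 16)
  }
  utils::write.csv(
    data.frame(frame_index = seq_along(series$frames) - 1L,
               time_h = series$times_h),
    file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read an image series from a frame directory with a manifest
#'
#' @param dir directory containing `frame_NNNN.tif` files and `manifest.csv`
#' @return an [image_series()]
#' @export
read_image_series <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  .assert(file.exists(mf), "manifest.csv not found in ", dir)
  manifest <- utils::read.csv(mf)
  .assert(all(c("frame_index", "time_h") %in% names(manifest)),
          "manifest must have columns frame_index, time_h")
  manifest <- manifest[order(manifest$time_h), ]
  frames <- lapply(manifest$frame_index, function(i) {
    p <- file.path(dir, sprintf("frame_%04d.tif", i))
    .assert(file.exists(p), "missing frame file ", p)
    img <- tiff::readTIFF(p)
    if (length(dim(img)) == 2) img <- array(img, dim = c(dim(img), 3))
    img[, , 1:3, drop = FALSE]
  })
  image_series(frames, manifest$time_h, "rgb")
}
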