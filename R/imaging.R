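#' Preprocessing parameters for the plate-imaging pipeline
#'
#' Defaults follow the screening protocol: images are smoothed twice with a
#' truncated Gaussian kernel (sd 1 px, 7 px support) and a single global
#' threshold is applied to every frame. `threshold_v = "auto"` selects Otsu's
#' threshold computed on the final background-subtracted smoothed frame,
#' which has the best-separated bimodal histogram of the series.
#'
#' @param gaussian_sd_px Gaussian kernel standard deviation in pixels
#' @param gaussian_width_px odd kernel support width in pixels
#' @param smoothing_passes number of smoothing passes (>= 1)
#' @param threshold_v scalar value-channel threshold in \[0, 1\], or `"auto"`
#' @param fallback_threshold threshold used, with a warning, when the
#'   automatic threshold is degenerate (no bimodal signal in the final frame)
#' @return object of class `preprocess_params`
#' @export
preprocess_params <- function(gaussian_sd_px = 1, gaussian_width_px = 7,
                              smoothing_passes = 2, threshold_v = "auto",
                              fallback_threshold = 0.25) {
  .assert(gaussian_width_px %% 2 == 1, "gaussian_width_px must be odd")
  .assert(smoothing_passes >= 1, "smoothing_passes must be >= 1")
  .assert(gaussian_sd_px > 0, "gaussian_sd_px must be positive")
  if (!identical(threshold_v, "auto")) {
    .assert(is.numeric(threshold_v) && threshold_v >= 0 && threshold_v <= 1,
            "threshold_v must be in [0, 1] or \"auto\"")
  }
  structure(list(gaussian_sd_px = gaussian_sd_px,
                 gaussian_width_px = gaussian_width_px,
                 smoothing_passes = smoothing_passes,
                 threshold_v = threshold_v,
                 fallback_threshold = fallback_threshold),
            class = "preprocess_params")
}

#' Truncated, renormalised Gaussian convolution kernel
#'
#' @param sd_px standard deviation in pixels
#' @param width_px odd support width in pixels
#' @return width x width matrix summing to one
#' @export
gaussian_kernel <- function(sd_px = 1, width_px = 7) {
  .assert(width_px %% 2 == 1, "kernel width must be odd")
  half <- (width_px - 1) / 2
  d <- (-half):half
  k <- outer(exp(-d^2 / (2 * sd_px^2)), exp(-d^2 / (2 * sd_px^2)))
  k / sum(k)
}

#' Extract the HSV value channel from an RGB image series
#'
#' Per pixel, V = max(R, G, B), rescaled to \[0, 1\]; the value channel gives
#' the highest colony/background contrast on scanner images. Optionally
#' inverts the result (`v := 1 - v`) for images where colonies are darker
#' than the background.
#'
#' @param series an [image_series()] with RGB frames
#' @param invert invert intensities after conversion
#' @return an [image_series()] with grayscale frames
#' @export
to_value_channel <- function(series, invert = FALSE) {
  .assert(inherits(series, "image_series"), "series must be an image_series")
  .assert(series$channels == "rgb",
          "to_value_channel requires RGB input frames")
  frames <- lapply(series$frames, function(f) {
    .assert(length(dim(f)) == 3 && dim(f)[3] >= 3,
            "RGB frames must be height x width x 3 arrays")
    v <- pmax(f[, , 1], f[, , 2], f[, , 3])
    if (max(v) > 1) {                 # integer-coded input: 8- or 16-bit
      v <- v / if (max(v) <= 255) 255 else 65535
    }
    if (invert) v <- 1 - v
    v
  })
  image_series(frames, series$times_h, "gray")
}

#' Subtract the first (colony-free) frame as background
#'
#' The first image of a time-lapse, acquired before any colony appears, is
#' the background estimate; every frame has it subtracted and is clipped to
#' \[0, 1\]. Frame one becomes identically zero.
#'
#' @param series grayscale [image_series()] with at least two frames
#' @return grayscale [image_series()]
#' @export
subtract_background <- function(series) {
  .assert(inherits(series, "image_series") && series$channels == "gray",
          "subtract_background expects a grayscale image_series")
  .assert(length(series$frames) >= 2, "need at least two frames")
  bg <- series$frames[[1]]
  frames <- lapply(series$frames, function(f) .clip(f - bg))
  image_series(frames, series$times_h, "gray")
}

# one convolution pass with the (separable) truncated Gaussian and
# replicate boundary handling. The 2-D kernel of gaussian_kernel() factors
# exactly into the outer product of its normalised 1-D profile, so two
# clamped shift-and-add 1-D passes reproduce the 2-D convolution while
# staying O(width) per pixel.
.convolve_frame <- function(frame, sd_px = 1, width_px = 7) {
  half <- (width_px - 1) / 2
  g <- exp(-((-half):half)^2 / (2 * sd_px^2))
  g <- g / sum(g)
  h <- nrow(frame); w <- ncol(frame)
  out <- matrix(0, h, w)
  for (d in (-half):half) {          # along rows
    idx <- pmin(pmax(seq_len(h) + d, 1L), h)
    out <- out + g[d + half + 1] * frame[idx, , drop = FALSE]
  }
  res <- matrix(0, h, w)
  for (d in (-half):half) {          # along columns
    idx <- pmin(pmax(seq_len(w) + d, 1L), w)
    res <- res + g[d + half + 1] * out[, idx, drop = FALSE]
  }
  res
}

#' Smooth every frame with a truncated Gaussian kernel
#'
#' Each frame is convolved `smoothing_passes` times (default twice) with the
#' normalised truncated Gaussian of [gaussian_kernel()].
#'
#' @param series grayscale [image_series()]
#' @param params a [preprocess_params()]
#' @return grayscale [image_series()]
#' @export
smooth_frames <- function(series, params = preprocess_params()) {
  .assert(inherits(series, "image_series") && series$channels == "gray",
          "smooth_frames expects a grayscale image_series")
  frames <- lapply(series$frames, function(f) {
    for (p in seq_len(params$smoothing_passes)) {
      f <- .convolve_frame(f, params$gaussian_sd_px,
                           params$gaussian_width_px)
    }
    f
  })
  image_series(frames, series$times_h, "gray")
}

#' Resolve the global threshold for a smoothed series
#'
#' `"auto"` computes Otsu's threshold on the final frame. The automatic
#' choice is accepted only when it separates two classes with a mean
#' contrast of at least `min_auto_contrast` value-channel units — on a
#' colony-free (unimodal, noise-only) frame Otsu splits the noise and the
#' inter-class contrast collapses; in that case a warning is raised and
#' `fallback_threshold` is used.
#'
#' @param series smoothed grayscale [image_series()]
#' @param params a [preprocess_params()]
#' @param min_auto_contrast minimum inter-class mean contrast for the
#'   automatic threshold to be considered non-degenerate
#' @return scalar threshold in \[0, 1\]
#' @export
resolve_threshold <- function(series, params = preprocess_params(),
                              min_auto_contrast = 0.1) {
  if (!identical(params$threshold_v, "auto")) return(params$threshold_v)
  last <- series$frames[[length(series$frames)]]
  thr <- EBImage::otsu(EBImage::as.Image(.clip(last)), range = c(0, 1))
  above <- last > thr
  contrast <- if (any(above) && any(!above)) {
    mean(last[above]) - mean(last[!above])
  } else 0
  if (!is.finite(thr) || thr <= 0 || contrast < min_auto_contrast) {
    warning("automatic threshold is degenerate (no bimodal signal); ",
            "falling back to ", params$fallback_threshold)
    thr <- params$fallback_threshold
  }
  thr
}

#' Threshold a smoothed series into per-frame biomass masks
#'
#' One scalar threshold is applied to every frame for consistency across the
#' time-lapse; a pixel is biomass iff its value exceeds the threshold.
#'
#' @param series smoothed grayscale [image_series()]
#' @param params a [preprocess_params()]
#' @return list with `masks` (list of logical matrices), `times_h`, and
#'   `threshold` (the scalar used)
#' @export
threshold_series <- function(series, params = preprocess_params()) {
  thr <- resolve_threshold(series, params)
  masks <- lapply(series$frames, function(f) f > thr)
  list(masks = masks, times_h = series$times_h, threshold = thr)
}

#' Detect colony seed points on a temporal z-projection
#'
#' The per-pixel sum of the binary biomass masks over time is smoothed once
#' with the preprocessing kernel; one seed is placed at each prominent
#' regional peak. Peaks are identified by watershed-based object detection
#' on the projection, which merges shallow shoulders (the stepped annuli a
#' saturating colony leaves in the projection) into their dominant peak:
#' only maxima rising at least `min_peak_prominence` frames above the
#' ridge to a higher peak count as colonies. Each peak's seed is the
#' centroid of its top plateau; seeds closer than `min_seed_separation_px`
#' are thinned greedily, strongest first, and must fall on the final
#' frame's foreground. An empty foreground yields an empty seed list.
#'
#' @param masks list of logical matrices (from [threshold_series()])
#' @param min_seed_separation_px minimum seed separation in pixels
#' @param params a [preprocess_params()] (kernel used to smooth the
#'   projection)
#' @param min_peak_prominence minimum peak prominence, in units of frames
#'   of coverage, for a regional maximum to count as a colony
#' @return data.frame with columns `seed_id`, `row_px`, `col_px`
#' @export
detect_colony_seeds <- function(masks, min_seed_separation_px = 10,
                                params = preprocess_params(),
                                min_peak_prominence = 2) {
  .assert(length(masks) >= 1, "need at least one mask frame")
  z <- Reduce(`+`, lapply(masks, function(m) m * 1))
  z <- .convolve_frame(z, params$gaussian_sd_px, params$gaussian_width_px)
  final_fg <- masks[[length(masks)]]
  if (!any(final_fg) || max(z) <= 0) {
    return(data.frame(seed_id = integer(0), row_px = integer(0),
                      col_px = integer(0)))
  }
  sep <- max(1L, as.integer(min_seed_separation_px))
  peaks <- EBImage::imageData(
    EBImage::watershed(EBImage::as.Image(z), tolerance = min_peak_prominence,
                       ext = sep))
  cand_list <- lapply(seq_len(max(peaks)), function(lb) {
    sel <- which(peaks == lb)
    top <- sel[z[sel] > max(z[sel]) - 1e-9]
    rc <- arrayInd(top, dim(z))
    data.frame(row_px = round(mean(rc[, 1])), col_px = round(mean(rc[, 2])),
               value = max(z[sel]))
  })
  cand <- do.call(rbind, cand_list)
  cand <- cand[order(-cand$value), ]
  # greedy enforcement of the minimum separation, strongest peaks first
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    dists <- sqrt((cand$row_px[keep] - cand$row_px[i])^2 +
                  (cand$col_px[keep] - cand$col_px[i])^2)
    if (all(dists >= sep)) keep[i] <- TRUE
  }
  cand <- cand[keep, , drop = FALSE]
  on_fg <- final_fg[cbind(cand$row_px, cand$col_px)]
  cand <- cand[on_fg, , drop = FALSE]
  # stable ordering: top-to-bottom, left-to-right
  cand <- cand[order(cand$row_px, cand$col_px), , drop = FALSE]
  data.frame(seed_id = seq_len(nrow(cand)),
             row_px = as.integer(cand$row_px),
             col_px = as.integer(cand$col_px))
}

#' Split merged colonies in one frame from seed markers
#'
#' Computes the Euclidean distance transform of the binary foreground and
#' partitions the foreground among the seed markers by geodesic propagation
#' on the (negated) distance map, splitting touching colonies along the
#' ridge between seeds — for overlapping disks, the perpendicular bisector.
#' Every foreground pixel receives exactly one seed's label; background is 0.
#'
#' @param mask single logical matrix
#' @param seeds seed data.frame from [detect_colony_seeds()]
#' @param warn_dropped warn about seeds not on the foreground (they receive
#'   no region in this frame)
#' @return integer label matrix (0 = background; labels are `seed_id`s)
#' @export
split_merged_colonies <- function(mask, seeds, warn_dropped = TRUE) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  if (nrow(seeds) == 0 || !any(mask)) return(lab)
  on_fg <- mask[cbind(seeds$row_px, seeds$col_px)]
  if (warn_dropped && any(!on_fg)) {
    warning(sum(!on_fg), " seed(s) off the foreground were dropped")
  }
  seeds <- seeds[on_fg, , drop = FALSE]
  if (nrow(seeds) == 0) return(lab)
  # a connected component with a single seed is that seed's region outright;
  # only multi-seed components need the distance-transform split, and only
  # within their bounding box. Identical to a whole-frame seeded propagation
  # (components are independent under geodesic propagation).
  comp <- EBImage::imageData(EBImage::bwlabel(EBImage::as.Image(mask * 1)))
  cid <- comp[cbind(seeds$row_px, seeds$col_px)]
  ncomp <- max(comp)
  seeds_in <- tabulate(cid, nbins = ncomp)
  lut <- integer(ncomp + 1)
  single <- which(seeds_in == 1)
  lut[single + 1] <- seeds$seed_id[match(single, cid)]
  lab <- matrix(lut[comp + 1L], nrow(mask), ncol(mask))
  for (cc in which(seeds_in >= 2)) {
    idx <- which(comp == cc, arr.ind = TRUE)
    r0 <- min(idx[, 1]); r1 <- max(idx[, 1])
    c0 <- min(idx[, 2]); c1 <- max(idx[, 2])
    sub <- comp[r0:r1, c0:c1, drop = FALSE] == cc
    in_cc <- cid == cc
    seed_img <- matrix(0L, r1 - r0 + 1, c1 - c0 + 1)
    seed_img[cbind(seeds$row_px[in_cc] - r0 + 1,
                   seeds$col_px[in_cc] - c0 + 1)] <- seeds$seed_id[in_cc]
    dm <- EBImage::distmap(EBImage::as.Image(sub * 1))
    out <- EBImage::propagate(-dm, seeds = EBImage::as.Image(seed_img),
                              mask = sub, lambda = 100)
    sub_lab <- matrix(as.integer(EBImage::imageData(out)), nrow(sub))
    block <- lab[r0:r1, c0:c1, drop = FALSE]
    block[sub] <- sub_lab[sub]
    lab[r0:r1, c0:c1] <- block
  }
  lab
}

#' Track per-colony areas across all frames
#'
#' Runs [split_merged_colonies()] on every frame with the global seed set
#' and counts the pixels assigned to each seed; frames before a colony
#' appears (its seed off the foreground) give area 0.
#'
#' @param masks list of logical matrices
#' @param times_h frame times in hours
#' @param seeds seed data.frame from [detect_colony_seeds()]
#' @return data.frame with columns `seed_id`, `frame`, `time_h`, `area_px`
#' @export
track_areas <- function(masks, times_h, seeds) {
  .assert(length(masks) == length(times_h),
          "masks and times_h must have equal length")
  if (nrow(seeds) == 0) {
    return(data.frame(seed_id = integer(0), frame = integer(0),
                      time_h = numeric(0), area_px = integer(0)))
  }
  out <- vector("list", length(masks))
  for (f in seq_along(masks)) {
    lab <- split_merged_colonies(masks[[f]], seeds, warn_dropped = FALSE)
    counts <- tabulate(lab[lab > 0], nbins = max(seeds$seed_id))
    out[[f]] <- data.frame(seed_id = seeds$seed_id, frame = f,
                           time_h = times_h[f],
                           area_px = counts[seeds$seed_id])
  }
  do.call(rbind, out)
}

#' Flag colonies to exclude from growth-rate analysis
#'
#' Reproduces the exclusion rules of the screening protocol on the final
#' frame: colonies touching the plate edge, colonies merged with an edge
#' colony, and colonies inside a merged region containing an ambiguous
#' number of seeds.
#'
#' @param masks list of logical matrices
#' @param seeds seed data.frame
#' @param edge_margin_px a colony is `edge` if any pixel of its final-frame
#'   region lies within this many pixels of the image border
#' @param max_seeds_per_component a final-frame connected component holding
#'   more than this many seeds marks all its colonies `ambiguous_merge`
#' @return data.frame with columns `seed_id`, `edge`, `merged_with_edge`,
#'   `ambiguous_merge`, `excluded`, `flags` (comma-joined flag names)
#' @export
apply_exclusions <- function(masks, seeds, edge_margin_px = 5,
                             max_seeds_per_component = 5) {
  n <- nrow(seeds)
  res <- data.frame(seed_id = seeds$seed_id,
                    edge = logical(n), merged_with_edge = logical(n),
                    ambiguous_merge = logical(n))
  if (n == 0) {
    res$excluded <- logical(0); res$flags <- character(0)
    return(res)
  }
  final <- masks[[length(masks)]]
  lab <- split_merged_colonies(final, seeds, warn_dropped = FALSE)
  comp <- EBImage::imageData(EBImage::bwlabel(EBImage::as.Image(final * 1)))
  h <- nrow(final); w <- ncol(final)
  near_edge <- matrix(FALSE, h, w)
  m <- max(0L, as.integer(edge_margin_px))
  if (m > 0) {
    near_edge[c(seq_len(min(m, h)), seq.int(max(1, h - m + 1), h)), ] <- TRUE
    near_edge[, c(seq_len(min(m, w)), seq.int(max(1, w - m + 1), w))] <- TRUE
  }
  comp_of <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    id <- seeds$seed_id[i]
    region <- lab == id
    if (any(region)) {
      res$edge[i] <- any(region & near_edge)
      comp_of[i] <- comp[which(region)[1]]
    }
  }
  edge_comps <- unique(comp_of[res$edge & !is.na(comp_of)])
  seeds_per_comp <- table(comp_of[!is.na(comp_of)])
  for (i in seq_len(n)) {
    if (is.na(comp_of[i])) next
    if (!res$edge[i] && comp_of[i] %in% edge_comps) {
      res$merged_with_edge[i] <- TRUE
    }
    if (seeds_per_comp[[as.character(comp_of[i])]] >
        max_seeds_per_component) {
      res$ambiguous_merge[i] <- TRUE
    }
  }
  res$excluded <- res$edge | res$merged_with_edge | res$ambiguous_merge
  res$flags <- apply(res[, c("edge", "merged_with_edge", "ambiguous_merge")],
                     1, function(r) {
    paste(c("edge", "merged_with_edge", "ambiguous_merge")[as.logical(r)],
          collapse = ";")
  })
  res
}

#' Run the full plate-imaging pipeline on a time-lapse
#'
#' Value-channel extraction, first-frame background subtraction, double
#' Gaussian smoothing, global thresholding, seed detection on the temporal
#' z-projection, per-frame seeded splitting of merged colonies, area
#' tracking, and exclusion flagging.
#'
#' @param series an RGB [image_series()] (e.g. from [read_image_series()] or
#'   [simulate_plate()])
#' @param params a [preprocess_params()]
#' @param invert invert intensities (colonies darker than background)
#' @param min_seed_separation_px,edge_margin_px,max_seeds_per_component see
#'   [detect_colony_seeds()] and [apply_exclusions()]
#' @return list with `seeds`, `tracks` (long data.frame), `exclusions`,
#'   `threshold`, `times_h`
#' @export
analyze_plate <- function(series, params = preprocess_params(),
                          invert = FALSE, min_seed_separation_px = 10,
                          edge_margin_px = 5, max_seeds_per_component = 5) {
  v <- to_value_channel(series, invert = invert)
  v <- subtract_background(v)
  v <- smooth_frames(v, params)
  th <- threshold_series(v, params)
  rm(v)
  seeds <- detect_colony_seeds(th$masks, min_seed_separation_px, params)
  tracks <- track_areas(th$masks, th$times_h, seeds)
  excl <- apply_exclusions(th$masks, seeds, edge_margin_px,
                           max_seeds_per_component)
  list(seeds = seeds, tracks = tracks, exclusions = excl,
       threshold = th$threshold, times_h = th$times_h)
}
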