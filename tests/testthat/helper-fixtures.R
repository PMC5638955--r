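# shared fixture builders; everything is generated in code at test time

# small noiseless plate with one centred colony
one_colony_spec <- function(rate = 0.3, lag = 2, n_frames = 20,
                            noise_sd = 0, max_area = 2000, size = 140,
                            seed = 1) {
  plate_spec(size, size, n_frames = n_frames,
             colonies = data.frame(x = size / 2, y = size / 2, lag_h = lag,
                                   init_area_px = 100, rate_per_h = rate,
                                   max_area_px = max_area),
             noise_sd = noise_sd, rng_seed = seed)
}

# grayscale series wrapper for matrices
gray_series <- function(frames, times_h = seq_along(frames) - 1) {
  image_series(frames, times_h, "gray")
}

# rgb frame from a grayscale matrix
rgb_frame <- function(m) array(m, dim = c(dim(m), 3))

# independent per-base CR scan used as the test-side oracle: marks every
# window base and walks it with an explicit loop (no rle, no intervals)
crs_scan_oracle <- function(ws, we, variants) {
  out <- NULL
  run_start <- NA
  for (p in ws:we) {
    if (p %in% variants) {
      if (!is.na(run_start)) {
        out <- rbind(out, c(run_start, p - 1))
        run_start <- NA
      }
    } else if (is.na(run_start)) {
      run_start <- p
    }
  }
  if (!is.na(run_start)) out <- rbind(out, c(run_start, we))
  if (is.null(out)) {
    return(data.frame(start = integer(0), end = integer(0),
                      length_bp = integer(0)))
  }
  data.frame(start = as.integer(out[, 1]), end = as.integer(out[, 2]),
             length_bp = as.integer(out[, 2] - out[, 1] + 1))
}
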