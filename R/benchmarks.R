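#' Growth-rate recovery benchmark on synthetic plates
#'
#' Simulates well-spaced colonies under the screening conditions (2-h
#' frames, 256 h, rendered noise) in batches of `colonies_per_plate`, runs
#' the full imaging pipeline and the moving-window estimator, and matches
#' every detected colony to the nearest ground-truth centre. Growing
#' colonies draw their true rate uniformly from `rate_range`; `n_no_growth`
#' additional colonies have rate zero (constant area after appearance),
#' emulating a lethal-overexpression target that stops a colony from
#' growing.
#'
#' @param n_colonies number of growing colonies
#' @param n_no_growth number of zero-rate colonies
#' @param colonies_per_plate colonies per simulated plate
#' @param rate_range true rate range, per hour
#' @param rng_seed integer seed (per-plate seeds are derived from it)
#' @param ... passed to [random_plate_spec()]
#' @return data.frame with one row per true colony: `plate`, `true_rate`,
#'   `est_rate` (NA if undetected), `rel_err`, `n_seeds_detected`
#' @export
growth_rate_recovery <- function(n_colonies = 100, n_no_growth = 8,
                                 colonies_per_plate = 4,
                                 rate_range = c(0.1, 0.6), rng_seed = 1,
                                 ...) {
  n_grow_plates <- ceiling(n_colonies / colonies_per_plate)
  n_flat_plates <- ceiling(n_no_growth / colonies_per_plate)
  plan <- data.frame(
    plate = seq_len(n_grow_plates + n_flat_plates),
    flat = rep(c(FALSE, TRUE), c(n_grow_plates, n_flat_plates)))
  out <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    spec <- random_plate_spec(
      colonies_per_plate, rate_range = rate_range,
      p_no_growth = if (plan$flat[i]) 1 else 0,
      rng_seed = (rng_seed * 331L + i) %% .Machine$integer.max, ...)
    sim <- simulate_plate(spec)
    res <- analyze_plate(sim$series)
    rates <- growth_rates(res$tracks, res$exclusions)
    truth <- sim$truth$colonies
    est <- rep(NA_real_, nrow(truth))
    if (nrow(rates) > 0) {
      sd_pos <- res$seeds[match(rates$seed_id, res$seeds$seed_id), ]
      for (k in seq_len(nrow(rates))) {
        d2 <- (truth$x - sd_pos$col_px[k])^2 + (truth$y - sd_pos$row_px[k])^2
        j <- which.min(d2)
        if (d2[j] <= truth$max_area_px[j] / pi) {   # within the disk
          est[j] <- rates$rate_per_h[k]
        }
      }
    }
    out[[i]] <- data.frame(plate = plan$plate[i],
                           true_rate = truth$rate_per_h,
                           est_rate = est,
                           n_seeds_detected = nrow(res$seeds))
    rm(sim, res)
  }
  df <- do.call(rbind, out)
  keep_grow <- which(df$true_rate > 0)[seq_len(min(n_colonies,
                                                   sum(df$true_rate > 0)))]
  keep_flat <- which(df$true_rate == 0)[seq_len(min(n_no_growth,
                                                    sum(df$true_rate == 0)))]
  df <- df[sort(c(keep_grow, keep_flat)), ]
  df$rel_err <- ifelse(df$true_rate > 0,
                       abs(df$est_rate - df$true_rate) / df$true_rate,
                       NA_real_)
  rownames(df) <- NULL
  df
}

#' OD slope recovery benchmark on simulated logistic wells
#'
#' Wells follow logistic curves whose carrying capacity is far from reached
#' inside the 210-330 min fit window (a dilute inoculum growing at typical
#' yeast rates stays below 3% of capacity by 330 min, so the fit interval
#' sits squarely in the semilog-linear phase); read noise is at the level
#' of a research-grade reader in continuous-shake kinetic mode. The semilog
#' estimator is compared to the true rate.
#'
#' @param n_wells number of wells
#' @param rate_range true rates, per minute (defaults span doubling times
#'   of roughly 75-115 min)
#' @param rng_seed integer seed
#' @return data.frame with `well_id`, `true_rate`, `est_rate`, `rel_err`
#' @export
od_rate_recovery <- function(n_wells = 12, rate_range = c(0.006, 0.009),
                             rng_seed = 1) {
  wells <- withr::with_seed(rng_seed, {
    data.frame(well_id = sprintf("W%02d", seq_len(n_wells)),
               initial_od = 0.003, carrying_capacity = 2,
               rate_per_min = stats::runif(n_wells, rate_range[1],
                                           rate_range[2]),
               background_od = 0.08, noise_sd = 1e-4)
  })
  sim <- simulate_od(od_spec(wells, rng_seed = rng_seed + 7L))
  est <- vapply(wells$well_id, function(id) {
    w <- sim$od[sim$od$well == id, ]
    od_growth_rate(w$time_min, w$od, background = "value",
                   background_value = 0.08)$rate_per_min
  }, 1)
  data.frame(well_id = wells$well_id, true_rate = wells$rate_per_min,
             est_rate = unname(est),
             rel_err = abs(unname(est) - wells$rate_per_min) /
               wells$rate_per_min)
}

#' Mean count of long SNP-free runs versus the closed form
#'
#' Under per-base Bernoulli SNPs with probability `p`, the expected number
#' of maximal SNP-free runs of length at least `L` in a window of `W`
#' bases is \eqn{(1-p)^L (1 + (W-L)p)}. Simulates `n_windows` windows and
#' returns the observed mean with its standard error alongside the closed
#' form.
#'
#' @param n_windows number of simulated windows
#' @param window_bp window length `W`
#' @param min_len_bp run length threshold `L`
#' @param snp_prob per-base SNP probability `p`
#' @param rng_seed integer seed
#' @return list with `mean_count`, `se`, `expected`, `n_windows`
#' @export
cr_run_count_experiment <- function(n_windows = 10000, window_bp = 1000,
                                    min_len_bp = 31, snp_prob = 0.02,
                                    rng_seed = 1) {
  counts <- withr::with_seed(rng_seed, {
    vapply(seq_len(n_windows), function(i) {
      v <- which(stats::runif(window_bp) < snp_prob)
      sum(find_conserved_regions(1, window_bp, v)$length_bp >= min_len_bp)
    }, 1)
  })
  list(mean_count = mean(counts),
       se = stats::sd(counts) / sqrt(n_windows),
       expected = (1 - snp_prob)^min_len_bp *
         (1 + (window_bp - min_len_bp) * snp_prob),
       n_windows = n_windows)
}
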