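#' Specification for synthetic plate-reader OD curves
#'
#' Each well follows a logistic growth curve
#' \eqn{OD(t) = K / (1 + ((K - O_0)/O_0) e^{-r t}) + b + \epsilon} with
#' carrying capacity \eqn{K}, initial density \eqn{O_0}, rate \eqn{r} per
#' minute, constant background offset \eqn{b} and Gaussian read noise.
#' Defaults mirror the plate-reader protocol: readings every 10 minutes for
#' 16 hours.
#'
#' @param wells data.frame with columns `well_id`, `initial_od`,
#'   `carrying_capacity`, `rate_per_min`, `background_od`, `noise_sd`
#' @param read_interval_min minutes between readings (default 10)
#' @param duration_min total duration in minutes (default 960, i.e. 16 h)
#' @param rng_seed integer seed
#' @return object of class `od_spec`
#' @export
od_spec <- function(wells, read_interval_min = 10, duration_min = 960,
                    rng_seed = 1L) {
  wells <- as.data.frame(wells)
  .assert(all(c("well_id", "initial_od", "carrying_capacity", "rate_per_min",
                "background_od", "noise_sd") %in% names(wells)),
          "well table is missing required columns")
  .assert(all(wells$initial_od > 0 &
              wells$initial_od < wells$carrying_capacity),
          "need 0 < initial_od < carrying_capacity")
  .assert(all(wells$rate_per_min >= 0), "rates must be >= 0")
  .assert(read_interval_min > 0 && duration_min >= read_interval_min,
          "invalid read schedule")
  structure(list(wells = wells, read_interval_min = read_interval_min,
                 duration_min = duration_min, rng_seed = as.integer(rng_seed)),
            class = "od_spec")
}

#' Simulate plate-reader OD curves with known ground truth
#'
#' @param spec an [od_spec()]
#' @return list with `od` (long data.frame `well`, `time_min`, `od`) and
#'   `truth` (the well table, whose `rate_per_min` column is the true rate)
#' @export
simulate_od <- function(spec) {
  .assert(inherits(spec, "od_spec"), "spec must be an od_spec")
  times <- seq(0, spec$duration_min, by = spec$read_interval_min)
  w <- spec$wells
  out <- withr::with_seed(spec$rng_seed, {
    rows <- lapply(seq_len(nrow(w)), function(i) {
      k <- w$carrying_capacity[i]; o0 <- w$initial_od[i]
      od <- k / (1 + ((k - o0) / o0) * exp(-w$rate_per_min[i] * times)) +
        w$background_od[i]
      if (w$noise_sd[i] > 0) {
        od <- od + stats::rnorm(length(times), sd = w$noise_sd[i])
      }
      data.frame(well = w$well_id[i], time_min = times, od = od)
    })
    do.call(rbind, rows)
  })
  list(od = out, truth = w)
}
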