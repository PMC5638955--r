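#' Moving-window maximum log-linear slope of a colony area track
#'
#' The estimator of the colony screening protocol: the area series is
#' natural-log-transformed and an ordinary least-squares line is fitted in a
#' moving window of `window_h` hours anchored at every observed frame time
#' whose window fits inside the observed range; frames with zero area are
#' dropped within each window, and windows retaining fewer than `min_points`
#' frames are skipped. The maximum slope over all windows is the colony's
#' growth rate (e-folds per hour); ties go to the earliest window.
#'
#' @param time_h frame times in hours
#' @param area_px colony areas in pixels (zeros allowed; dropped per window)
#' @param window_h window length in hours (default 12)
#' @param min_points minimum positive-area frames per window (default 3)
#' @return one-row data.frame with `rate_per_h`, `window_start_h`,
#'   `window_end_h`, `n_points_in_window`, `r_squared`, `status`
#'   (`"ok"` or `"no_estimate"`); a track with no valid window returns
#'   `rate_per_h = NA` and `status = "no_estimate"`, which is distinct from
#'   an estimated slope of zero
#' @export
max_window_slope <- function(time_h, area_px, window_h = 12, min_points = 3) {
  .assert(length(time_h) == length(area_px),
          "time_h and area_px must have equal length")
  .assert(window_h > 0, "window_h must be positive")
  .assert(min_points >= 2, "min_points must be >= 2")
  o <- order(time_h)
  time_h <- time_h[o]; area_px <- area_px[o]
  no_est <- data.frame(rate_per_h = NA_real_, window_start_h = NA_real_,
                       window_end_h = NA_real_,
                       n_points_in_window = NA_integer_,
                       r_squared = NA_real_, status = "no_estimate")
  if (length(time_h) == 0) return(no_est)
  starts <- time_h[time_h + window_h <= max(time_h) + 1e-9]
  best <- NULL
  for (t0 in starts) {
    sel <- time_h >= t0 - 1e-9 & time_h <= t0 + window_h + 1e-9 & area_px > 0
    if (sum(sel) < min_points) next
    fit <- .ols_slope(time_h[sel], log(area_px[sel]))
    if (!is.finite(fit[["slope"]])) next
    if (is.null(best) || fit[["slope"]] > best$rate_per_h + 1e-12) {
      best <- data.frame(rate_per_h = fit[["slope"]], window_start_h = t0,
                         window_end_h = t0 + window_h,
                         n_points_in_window = sum(sel),
                         r_squared = fit[["r_squared"]], status = "ok")
    }
  }
  if (is.null(best)) no_est else best
}

#' Growth rates for all non-excluded colony tracks
#'
#' @param tracks long data.frame from [track_areas()] (columns `seed_id`,
#'   `time_h`, `area_px`)
#' @param exclusions optional exclusion table from [apply_exclusions()];
#'   excluded colonies are omitted
#' @param window_h,min_points see [max_window_slope()]
#' @return data.frame, one row per analysed colony, columns `seed_id` plus
#'   the [max_window_slope()] fields
#' @export
growth_rates <- function(tracks, exclusions = NULL, window_h = 12,
                         min_points = 3) {
  ids <- unique(tracks$seed_id)
  if (!is.null(exclusions)) {
    ids <- setdiff(ids, exclusions$seed_id[exclusions$excluded])
  }
  out <- lapply(ids, function(id) {
    tr <- tracks[tracks$seed_id == id, ]
    cbind(seed_id = id,
          max_window_slope(tr$time_h, tr$area_px, window_h, min_points))
  })
  if (length(out) == 0) {
    return(data.frame(seed_id = integer(0), rate_per_h = numeric(0),
                      window_start_h = numeric(0), window_end_h = numeric(0),
                      n_points_in_window = integer(0),
                      r_squared = numeric(0), status = character(0)))
  }
  do.call(rbind, out)
}

#' Semilog growth rate from a plate-reader OD curve
#'
#' Background-subtracted OD is fitted on a semilog scale over the linear
#' portion of the curve, by default between 210 and 330 minutes. The
#' background is the well's first reading (default) or an explicit value
#' such as a blank-well mean. Non-positive background-subtracted readings
#' inside the window are dropped; fewer than three remaining points is an
#' error.
#'
#' @param time_min reading times in minutes
#' @param od optical density readings
#' @param fit_start_min,fit_end_min fit interval in minutes
#' @param background `"first"` (subtract the well's first reading) or
#'   `"value"` (subtract `background_value`)
#' @param background_value background OD when `background = "value"`
#' @return one-row data.frame with `rate_per_min`, `n_points`, `r_squared`,
#'   `background_od`
#' @export
od_growth_rate <- function(time_min, od, fit_start_min = 210,
                           fit_end_min = 330,
                           background = c("first", "value"),
                           background_value = NULL) {
  background <- match.arg(background)
  .assert(length(time_min) == length(od), "time and OD lengths differ")
  .assert(fit_start_min < fit_end_min, "fit interval is empty")
  o <- order(time_min); time_min <- time_min[o]; od <- od[o]
  .assert(min(time_min) <= fit_start_min && max(time_min) >= fit_end_min,
          "readings do not cover the fit interval")
  bg <- switch(background,
               first = od[1],
               value = {
                 .assert(is.numeric(background_value),
                         "background_value required for background = \"value\"")
                 background_value
               })
  sel <- time_min >= fit_start_min & time_min <= fit_end_min
  y <- od[sel] - bg
  t <- time_min[sel]
  pos <- y > 0
  .assert(sum(pos) >= 3,
          "fewer than 3 positive background-subtracted readings in the fit ",
          "interval; no growth signal to fit")
  fit <- .ols_slope(t[pos], log(y[pos]))
  data.frame(rate_per_min = fit[["slope"]], n_points = sum(pos),
             r_squared = fit[["r_squared"]], background_od = bg)
}

#' Compare growth rates across conditions by one-way ANOVA and Tukey HSD
#'
#' @param rates_by_condition named list of numeric growth-rate vectors, one
#'   element per condition (at least two conditions with two rates each)
#' @return list with `f_statistic`, `anova_p`, `tukey` (data.frame `pair`,
#'   `diff`, `lwr`, `upr`, `p_adj`), and `n_per_condition`
#' @export
compare_groups <- function(rates_by_condition) {
  .assert(is.list(rates_by_condition) &&
          length(rates_by_condition) >= 2 &&
          !is.null(names(rates_by_condition)),
          "need a named list of at least two conditions")
  .assert(all(vapply(rates_by_condition, length, 1L) >= 2),
          "every condition needs at least two rates")
  df <- data.frame(
    rate = unlist(rates_by_condition, use.names = FALSE),
    condition = factor(rep(names(rates_by_condition),
                           vapply(rates_by_condition, length, 1L)))
  )
  within_var <- vapply(rates_by_condition, stats::var, 1)
  .assert(any(within_var > 0),
          "zero within-group variance in every condition; F is undefined")
  fit <- stats::aov(rate ~ condition, data = df)
  tab <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$condition
  pairs <- rownames(tk)
  list(
    f_statistic = tab[["F value"]][1],
    anova_p = tab[["Pr(>F)"]][1],
    tukey = data.frame(pair = pairs, diff = tk[, "diff"],
                       lwr = tk[, "lwr"], upr = tk[, "upr"],
                       p_adj = tk[, "p adj"], row.names = NULL),
    n_per_condition = vapply(rates_by_condition, length, 1L)
  )
}
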