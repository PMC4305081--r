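# Sleep architecture in 12-hr light/dark windows and binned profiles.

#' Binned sleep profile
#'
#' Sleep minutes per Zeitgeber-aligned bin (default 30 min), per day — the
#' standard sleep-profile plot input. Bins start at ZT0 and `bin_minutes`
#' must divide 1440, so a complete day yields `1440 / bin_minutes` bins whose
#' values sum to that day's total sleep.
#'
#' @param record `"sleep_record"` from [score_sleep()].
#' @param timeline Timeline data frame of the matching `channel_series`
#'   (columns `zt_minute`, `day_index`).
#' @param bin_minutes Bin width in minutes; must divide 1440 (default 30).
#' @return Data frame with `day_index`, `bin` (0-based, bin `b` covers ZT
#'   minutes `[b * bin_minutes, (b + 1) * bin_minutes)`), `zt_min` (bin start
#'   in ZT minutes) and `sleep_min`.
#' @export
sleep_profile_binned <- function(record, timeline, bin_minutes = 30L) {
  stopifnot(inherits(record, "sleep_record"))
  if (1440L %% bin_minutes != 0L)
    stop("bin_minutes must divide 1440 (bins are aligned to ZT0)")
  stopifnot(nrow(timeline) == length(record$sleep))
  bin <- timeline$zt_minute %/% bin_minutes
  sleep <- as.integer(record$sleep)       # NA for missing
  agg <- tapply(sleep, list(day_index = timeline$day_index, bin = bin),
                function(v) sum(v, na.rm = TRUE))
  out <- expand.grid(day_index = as.integer(rownames(agg)),
                     bin = as.integer(colnames(agg)))
  out$sleep_min <- as.vector(agg)
  out <- out[!is.na(out$sleep_min), , drop = FALSE]
  out$zt_min <- out$bin * bin_minutes
  out <- out[order(out$day_index, out$bin),
             c("day_index", "bin", "zt_min", "sleep_min")]
  rownames(out) <- NULL
  out
}

#' Sleep architecture of one 12-hr light or dark window
#'
#' Computes the standard per-window metrics: total sleep, number of sleep
#' episodes, mean and maximum episode duration, and activity while awake
#' (beam crossings per waking minute).
#'
#' Attribution of episodes that span the window boundary: sleep *minutes*
#' are credited to the window they fall in, so totals over a day are
#' conserved; episode *counts and durations* are attributed to the window
#' containing the episode's first minute, using the full episode duration.
#'
#' @param series A `channel_series`.
#' @param record The matching `sleep_record`.
#' @param day Day index of the window.
#' @param light `"L"` or `"D"`.
#' @return One-row data frame: `fly_id`, `genotype`, `role`, `day_index`,
#'   `light`, `phase`, `total_sleep_min`, `n_episodes`, `mean_episode_min`
#'   (`NA` when no episodes), `max_episode_min`, `activity_while_awake`
#'   (`NA` when no waking minutes), `n_minutes`, `partial` (TRUE when the
#'   window has fewer than 720 non-missing minutes).
#' @export
period_architecture <- function(series, record, day, light = c("L", "D")) {
  light <- match.arg(light)
  stopifnot(inherits(series, "channel_series"),
            inherits(record, "sleep_record"))
  tl <- series$timeline
  in_win <- tl$day_index == day & tl$light == light
  if (!any(in_win))
    stop(sprintf("window day %s/%s not covered by the timeline", day, light))
  idx <- which(in_win)
  sleep <- record$sleep[idx]
  miss <- record$missing[idx]
  n_scored <- sum(!miss)
  total_sleep <- sum(sleep, na.rm = TRUE)
  # episodes starting inside the window, full durations
  ep <- record$episodes
  ep_in <- ep[ep$start %in% idx, , drop = FALSE]
  n_ep <- nrow(ep_in)
  waking <- !miss & !ifelse(is.na(sleep), TRUE, sleep)
  n_wake <- sum(waking)
  aww <- if (n_wake > 0)
    sum(series$counts[idx][waking], na.rm = TRUE) / n_wake else NA_real_
  data.frame(fly_id = series$fly_id,
             genotype = series$genotype,
             role = series$role,
             day_index = day,
             light = light,
             phase = tl$phase[idx[1]],
             total_sleep_min = total_sleep,
             n_episodes = n_ep,
             mean_episode_min = if (n_ep > 0) mean(ep_in$duration)
                                else NA_real_,
             max_episode_min = if (n_ep > 0) max(ep_in$duration)
                               else NA_real_,
             activity_while_awake = aww,
             n_minutes = n_scored,
             partial = n_scored < 720L,
             stringsAsFactors = FALSE)
}

#' Activity while awake in a window
#'
#' Total beam crossings divided by the number of waking (non-sleep,
#' non-missing) minutes in the window; `NA` when the fly never wakes.
#'
#' @inheritParams period_architecture
#' @return A single number (counts per waking minute) or `NA`.
#' @export
activity_while_awake <- function(series, record, day, light = c("L", "D")) {
  period_architecture(series, record, day, light)$activity_while_awake
}

#' All 12-hr window metrics for one fly
#'
#' Runs [period_architecture()] over every (day, light) window present in
#' the timeline.
#'
#' @param series A `channel_series`.
#' @param record Optional pre-computed `sleep_record` (scored from the
#'   series' counts if omitted).
#' @param ... Passed to [score_sleep()] when `record` is `NULL`.
#' @return Data frame, one row per window.
#' @export
fly_period_metrics <- function(series, record = NULL, ...) {
  if (is.null(record))
    record <- score_sleep(series$counts, series$missing, ...)
  tl <- series$timeline
  wins <- unique(tl[c("day_index", "light")])
  out <- do.call(rbind, lapply(seq_len(nrow(wins)), function(i)
    period_architecture(series, record, wins$day_index[i], wins$light[i])))
  rownames(out) <- NULL
  out
}

#' Average per-window metrics across days
#'
#' Arithmetic mean of each metric over the selected days, separately for the
#' light and dark windows, excluding missing values pairwise. Partial
#' windows (fewer than 720 scored minutes) are dropped by default.
#'
#' @param metrics Data frame of per-window metrics (rows for one fly, e.g.
#'   from [fly_period_metrics()]).
#' @param days Integer vector of day indices to average over (default: all
#'   days present).
#' @param include_partial Keep partial windows (default `FALSE`).
#' @return Data frame with one row per light state carrying the averaged
#'   metrics and `n_days` actually averaged.
#' @export
average_across_days <- function(metrics, days = NULL,
                                include_partial = FALSE) {
  stopifnot(is.data.frame(metrics))
  if (!is.null(days)) metrics <- metrics[metrics$day_index %in% days, ,
                                         drop = FALSE]
  if (!include_partial) metrics <- metrics[!metrics$partial, , drop = FALSE]
  if (nrow(metrics) == 0L) stop("no complete windows selected")
  cols <- c("total_sleep_min", "n_episodes", "mean_episode_min",
            "max_episode_min", "activity_while_awake")
  out <- do.call(rbind, lapply(split(metrics, metrics$light), function(d) {
    means <- vapply(cols, function(cl) mean(d[[cl]], na.rm = TRUE),
                    numeric(1))
    means[is.nan(means)] <- NA_real_
    cbind(data.frame(fly_id = d$fly_id[1], light = d$light[1],
                     n_days = nrow(d), stringsAsFactors = FALSE),
          as.data.frame(as.list(means)))
  }))
  rownames(out) <- NULL
  out
}
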