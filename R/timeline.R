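# Experimental timeline: Zeitgeber time, light/dark state, phase schedule.

#' Describe a DAM experiment
#'
#' Captures everything needed to annotate raw monitor data: the lights-on
#' clock time, the ordered phase schedule (e.g. baseline -> temperature
#' shift -> recovery) and the mapping from monitor channels to flies.
#'
#' @param lights_on Lights-on clock time as `"HH:MM"` (default `"08:00"`).
#'   Zeitgeber time zero (ZT0) is defined as this instant; ZT0-ZT12 is the
#'   light phase.
#' @param phase_schedule Data frame with columns `phase` (character, unique
#'   labels per contiguous block), `n_days` (positive integers) and `temp_c`
#'   (numeric, degrees Celsius).
#' @param channel_map Data frame with columns `monitor` (character),
#'   `channel` (integer 1-32), `fly_id`, `genotype` and `role` (one of
#'   `"experimental"`, `"gal4_control"`, `"uas_control"`).
#' @return A list of class `"dam_design"`.
#' @export
experiment_design <- function(lights_on = "08:00",
                              phase_schedule,
                              channel_map) {
  stopifnot(is.data.frame(phase_schedule),
            all(c("phase", "n_days", "temp_c") %in% names(phase_schedule)),
            is.data.frame(channel_map),
            all(c("monitor", "channel", "fly_id", "genotype", "role") %in%
                  names(channel_map)))
  if (anyDuplicated(phase_schedule$phase))
    stop("phase labels must be unique")
  if (any(phase_schedule$n_days < 1))
    stop("each phase needs at least one day")
  if (!all(channel_map$role %in%
             c("experimental", "gal4_control", "uas_control")))
    stop("role must be experimental, gal4_control or uas_control")
  if (!all(channel_map$channel %in% 1:32))
    stop("channel must be in 1..32")
  if (anyDuplicated(channel_map[c("monitor", "channel")]))
    stop("duplicate monitor/channel assignment")
  lo <- strsplit(lights_on, ":", fixed = TRUE)[[1]]
  if (length(lo) != 2L) stop("lights_on must be \"HH:MM\"")
  lights_on_min <- as.integer(lo[1]) * 60L + as.integer(lo[2])
  structure(list(lights_on = lights_on,
                 lights_on_min = lights_on_min,
                 phase_schedule = phase_schedule,
                 channel_map = channel_map),
            class = "dam_design")
}

# per-day phase labels in schedule order
schedule_days <- function(design) {
  rep(design$phase_schedule$phase, design$phase_schedule$n_days)
}

#' Annotate parsed DAM data with the experimental timeline
#'
#' Converts the raw count matrix of one monitor into per-fly
#' `channel_series` objects carrying, for every minute: Zeitgeber time
#' (`zt_minute`, 0-1439, 0 at lights-on), light state (`"L"` for
#' `zt_minute < 720`, else `"D"`), experiment phase and day index. Day 0
#' starts at the lights-on at or before the first record. Channels not in
#' the design's channel map are omitted.
#'
#' @param dam A `"dam_data"` object from [parse_dam_file()].
#' @param design A [experiment_design()].
#' @param monitor Monitor name used to select rows of the channel map
#'   (default the first monitor named there).
#' @return Named list of `channel_series` objects (names are fly ids).
#' @export
annotate_timeline <- function(dam, design, monitor = NULL) {
  stopifnot(inherits(dam, "dam_data"), inherits(design, "dam_design"))
  cm <- design$channel_map
  if (is.null(monitor)) monitor <- cm$monitor[1]
  cm <- cm[cm$monitor == monitor, , drop = FALSE]
  if (nrow(cm) == 0L) stop(sprintf("no channels mapped for monitor '%s'",
                                   monitor))
  n <- nrow(dam$counts)
  if (n == 0L) stop("no data rows to annotate")
  tmin <- as.numeric(dam$timestamps) %/% 60    # minutes since epoch
  rel <- (tmin - design$lights_on_min) %/% 1440
  zt_minute <- as.integer((tmin - design$lights_on_min) %% 1440)
  day_index <- as.integer(rel - rel[1])
  phases <- schedule_days(design)
  n_sched <- length(phases)
  complete <- vapply(seq_len(n_sched) - 1L,
                     function(d) sum(day_index == d) == 1440L, logical(1))
  if (!all(complete))
    stop(sprintf("coverage error: schedule days not fully recorded: %s",
                 paste(which(!complete) - 1L, collapse = ", ")))
  if (any(day_index >= n_sched))
    stop(sprintf("file extends beyond the phase schedule (day %d)",
                 max(day_index)))
  timeline <- data.frame(zt_minute = zt_minute,
                         light = ifelse(zt_minute < 720L, "L", "D"),
                         phase = phases[day_index + 1L],
                         day_index = day_index,
                         stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(cm)), function(i) {
    structure(list(fly_id = as.character(cm$fly_id[i]),
                   genotype = as.character(cm$genotype[i]),
                   role = as.character(cm$role[i]),
                   counts = dam$counts[, cm$channel[i]],
                   missing = dam$missing,
                   timeline = timeline,
                   start = dam$timestamps[1]),
              class = "channel_series")
  })
  names(out) <- vapply(out, `[[`, "", "fly_id")
  out
}

#' @export
print.channel_series <- function(x, ...) {
  cat(sprintf("channel_series: fly %s (%s, %s)\n", x$fly_id, x$genotype,
              x$role))
  cat(sprintf("  %d minutes over days %s; total counts %d; %d missing\n",
              length(x$counts),
              paste(range(x$timeline$day_index), collapse = "-"),
              sum(x$counts, na.rm = TRUE), sum(x$missing)))
  invisible(x)
}

#' @export
as.data.frame.channel_series <- function(x, ...) {
  data.frame(fly_id = x$fly_id,
             timestamp = x$start + 60 * (seq_along(x$counts) - 1),
             zt_minute = x$timeline$zt_minute,
             light = x$timeline$light,
             phase = x$timeline$phase,
             day_index = x$timeline$day_index,
             counts = x$counts,
             stringsAsFactors = FALSE)
}

#' Exclude flies that died during the recording
#'
#' A fly is excluded when it produced zero beam crossings over the final
#' `window_hours` of its recording — the usual actigraphy death criterion.
#'
#' @param series List of `channel_series` objects.
#' @param window_hours Length of the trailing window (default 24).
#' @return List with `retained` (surviving `channel_series`) and `excluded`
#'   (data frame of `fly_id` and `reason`).
#' @export
filter_dead_flies <- function(series, window_hours = 24) {
  stopifnot(window_hours > 0)
  w <- as.integer(round(window_hours * 60))
  dead <- vapply(series, function(s) {
    if (w > length(s$counts))
      stop("window_hours exceeds the recording duration")
    tailc <- tail(s$counts, w)
    sum(tailc, na.rm = TRUE) == 0
  }, logical(1))
  excluded <- data.frame(
    fly_id = vapply(series[dead], `[[`, "", "fly_id"),
    reason = rep(sprintf("no activity in final %g h", window_hours),
                 sum(dead)),
    stringsAsFactors = FALSE)
  list(retained = series[!dead], excluded = excluded)
}
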