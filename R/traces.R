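# ROI fluorescence trace analysis: percent delta-F/F, normalized FRET
# ratios, polarity-aware maximum responses, and gated group statistics.

#' Construct an ROI fluorescence trace
#'
#' @param values Numeric vector of per-frame intensities (single-channel
#'   sensors), or `NULL` for FRET traces.
#' @param cfp,yfp Donor (CFP) and acceptor (YFP) channel intensities for
#'   two-channel FRET sensors; same length.
#' @param roi_id ROI identifier.
#' @param sensor One of `"GCaMP"`, `"SpH"`, `"Arclight"`, `"EPAC"`,
#'   `"SuperClomeleon"`, `"other"`.
#' @param sample_rate Frames per second (default 2).
#' @param stimulus_onset_s Stimulus onset in seconds (default 30, i.e. after
#'   30 s of baseline recording).
#' @param stimulus_duration_s Stimulus duration in seconds.
#' @return Object of class `"fluor_trace"`.
#' @export
fluor_trace <- function(values = NULL, cfp = NULL, yfp = NULL,
                        roi_id = "roi1",
                        sensor = c("GCaMP", "SpH", "Arclight", "EPAC",
                                   "SuperClomeleon", "other"),
                        sample_rate = 2, stimulus_onset_s = 30,
                        stimulus_duration_s = 30) {
  sensor <- match.arg(sensor)
  two_channel <- !is.null(cfp)
  if (two_channel) {
    stopifnot(!is.null(yfp), length(cfp) == length(yfp))
    if (any(!is.finite(cfp)) || any(!is.finite(yfp)))
      stop("channel intensities must be finite")
  } else {
    stopifnot(!is.null(values))
    if (any(!is.finite(values))) stop("intensities must be finite")
  }
  structure(list(roi_id = roi_id, sensor = sensor,
                 sample_rate = sample_rate,
                 channels = if (two_channel) 2L else 1L,
                 values = values, cfp = cfp, yfp = yfp,
                 stimulus_onset_s = stimulus_onset_s,
                 stimulus_duration_s = stimulus_duration_s),
            class = "fluor_trace")
}

#' @export
print.fluor_trace <- function(x, ...) {
  n <- if (x$channels == 2L) length(x$cfp) else length(x$values)
  cat(sprintf("fluor_trace %s: %s sensor, %d channel(s), %d frames @ %g Hz\n",
              x$roi_id, x$sensor, x$channels, n, x$sample_rate))
  invisible(x)
}

#' Percent fluorescence change (delta-F/F)
#'
#' `series[n] = (F[n] - F0) / F0 * 100`, with `F0` the fluorescence of the
#' first frame (default) or the mean over the pre-stimulus baseline. Under
#' the default, `series[1]` is exactly 0 and the series is invariant to
#' scaling the whole trace by any positive gain.
#'
#' @param trace A single-channel `fluor_trace`, or a numeric vector.
#' @param f0_mode `"first"` (default) or `"prestim_mean"`.
#' @param prestim_frames Number of leading frames defining the baseline for
#'   `"prestim_mean"`; defaults to the frames before stimulus onset when
#'   `trace` is a `fluor_trace`.
#' @return Numeric vector of percent changes.
#' @export
compute_dff <- function(trace, f0_mode = c("first", "prestim_mean"),
                        prestim_frames = NULL) {
  f0_mode <- match.arg(f0_mode)
  if (inherits(trace, "fluor_trace")) {
    if (trace$channels != 1L)
      stop("compute_dff needs a single-channel trace; use fret_ratio_trace")
    if (is.null(prestim_frames))
      prestim_frames <- floor(trace$stimulus_onset_s * trace$sample_rate)
    f <- trace$values
  } else {
    f <- as.numeric(trace)
  }
  if (length(f) == 0L) stop("empty trace")
  f0 <- switch(f0_mode,
               first = f[1],
               prestim_mean = {
                 if (is.null(prestim_frames) || prestim_frames < 1L)
                   stop("prestim_frames must be >= 1 for prestim_mean")
                 mean(f[seq_len(min(prestim_frames, length(f)))])
               })
  if (!is.finite(f0) || f0 <= 0) stop("F0 must be positive")
  (f - f0) / f0 * 100
}

#' Response polarity of a sensor
#'
#' Arclight reports depolarization as *decreased* fluorescence, so its
#' maximum response is the minimum percent change; all other supported
#' sensors respond upward.
#'
#' @param sensor Sensor name as in [fluor_trace()].
#' @return `"positive_up"` or `"negative_up"`.
#' @export
sensor_polarity <- function(sensor) {
  if (identical(sensor, "Arclight")) "negative_up" else "positive_up"
}

#' Maximum response of a percent-change series
#'
#' The signed extremum of the series over the whole recording (default) or
#' a restricted frame window: the maximum for `positive_up` sensors, the
#' minimum for `negative_up` (Arclight-type) sensors.
#'
#' @param series Numeric percent-change series.
#' @param polarity `"positive_up"` (default) or `"negative_up"`.
#' @param search_window Optional integer range of frame indices to search.
#' @return The signed maximum percent change.
#' @export
extract_max_response <- function(series,
                                 polarity = c("positive_up", "negative_up"),
                                 search_window = NULL) {
  polarity <- match.arg(polarity)
  if (length(series) == 0L) stop("empty series")
  if (!is.null(search_window)) series <- series[search_window]
  if (polarity == "positive_up") max(series) else min(series)
}

#' Normalized FRET ratio series
#'
#' For two-channel FRET sensors (Epac1-camps for cAMP, SuperClomeleon for
#' chloride) the per-frame donor/acceptor ratio is normalized to the first
#' frame. Because signal binding *decreases* FRET (CFP up, YFP down), the
#' default orientation `"cfp_over_yfp"` makes signal increases read as
#' positive percentages: `series[n] = 100 * (r[n]/r[1] - 1)` with
#' `r = CFP/YFP`. Set `orientation = "yfp_over_cfp"` for the raw FRET-ratio
#' convention (signal increases then read negative). The series is
#' invariant to a constant gain applied to either whole channel, and
#' `series[1] = 0` exactly.
#'
#' @param trace A two-channel `fluor_trace`, or the CFP vector.
#' @param yfp YFP vector when `trace` is given as a plain vector.
#' @param orientation `"cfp_over_yfp"` (default, signal-up-positive) or
#'   `"yfp_over_cfp"`.
#' @return Numeric vector of normalized ratio changes in percent.
#' @export
fret_ratio_trace <- function(trace, yfp = NULL,
                             orientation = c("cfp_over_yfp",
                                             "yfp_over_cfp")) {
  orientation <- match.arg(orientation)
  if (inherits(trace, "fluor_trace")) {
    if (trace$channels != 2L) stop("fret_ratio_trace needs a FRET trace")
    cfp <- trace$cfp; yfp <- trace$yfp
  } else {
    cfp <- as.numeric(trace)
    stopifnot(!is.null(yfp), length(cfp) == length(yfp))
  }
  if (length(cfp) == 0L) stop("empty trace")
  if (any(cfp <= 0) || any(yfp <= 0))
    stop("both channels must be strictly positive at every frame")
  r <- switch(orientation,
              cfp_over_yfp = cfp / yfp,
              yfp_over_cfp = yfp / cfp)
  100 * (r / r[1] - 1)
}

#' Group summary of maximum responses with gated pairwise tests
#'
#' Per-group mean and SEM of the extracted maximum responses, a
#' Kruskal-Wallis test across all groups, and — only when the
#' Kruskal-Wallis p value is below `alpha` — pairwise Mann-Whitney tests of
#' the experimental group against each control, reported together with the
#' conservative (greatest) pairwise p value.
#'
#' @param responses Named list of numeric vectors of per-ROI maximum
#'   responses, one element per condition.
#' @param experimental Name of the experimental condition (default the
#'   first element).
#' @param alpha Gate level for running pairwise tests (default 0.05).
#' @return Object of class `"response_summary"`: list with `groups` (data
#'   frame of `condition`, `n`, `mean`, `sem`), `kw` (`rank_test`),
#'   `pairwise` (data frame of `control`, `U`, `p`, or `NULL` when gated
#'   out) and `conservative_p` (`NA` when gated out).
#' @export
group_response_summary <- function(responses, experimental = NULL,
                                   alpha = 0.05) {
  stopifnot(is.list(responses), length(responses) >= 2L,
            !is.null(names(responses)))
  if (any(lengths(responses) == 0L)) stop("every group must be non-empty")
  if (is.null(experimental)) experimental <- names(responses)[1]
  stopifnot(experimental %in% names(responses))
  groups <- do.call(rbind, lapply(names(responses), function(nm) {
    ms <- mean_sem(responses[[nm]])
    data.frame(condition = nm, n = length(responses[[nm]]),
               mean = ms[["mean"]], sem = ms[["sem"]],
               stringsAsFactors = FALSE)
  }))
  kw <- kruskal_wallis(responses)
  pairwise <- NULL; cons <- NA_real_
  if (kw$p.value < alpha) {
    ctrl <- setdiff(names(responses), experimental)
    pairwise <- do.call(rbind, lapply(ctrl, function(nm) {
      tst <- mann_whitney_u(responses[[experimental]], responses[[nm]])
      data.frame(control = nm, U = tst$statistic, p = tst$p.value,
                 stringsAsFactors = FALSE)
    }))
    cons <- conservative_p(pairwise$p)
  }
  structure(list(groups = groups, kw = kw, pairwise = pairwise,
                 conservative_p = cons, alpha = alpha,
                 experimental = experimental),
            class = "response_summary")
}

#' @export
print.response_summary <- function(x, ...) {
  cat("response_summary\n")
  for (i in seq_len(nrow(x$groups)))
    cat(sprintf("  %s: %.2f +/- %.2f %% (n = %d)\n",
                x$groups$condition[i], x$groups$mean[i], x$groups$sem[i],
                x$groups$n[i]))
  cat(sprintf("  Kruskal-Wallis H = %.3f, p = %.4g\n", x$kw$statistic,
              x$kw$p.value))
  if (is.null(x$pairwise)) {
    cat(sprintf("  (p >= %g: pairwise tests not run)\n", x$alpha))
  } else {
    for (i in seq_len(nrow(x$pairwise)))
      cat(sprintf("  %s vs %s: U = %g, p = %.4g\n", x$experimental,
                  x$pairwise$control[i], x$pairwise$U[i], x$pairwise$p[i]))
    cat(sprintf("  conservative p = %.4g\n", x$conservative_p))
  }
  invisible(x)
}
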