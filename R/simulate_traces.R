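# Synthetic ROI fluorescence traces with known ground truth: baseline,
# exponential photobleaching, and an evoked response shaped as a normalized
# double-exponential kernel starting at stimulus onset.

#' Parameters for a synthetic fluorescence trace
#'
#' Each channel follows
#' `F_c(t) = B_c * exp(-t / tau_c) * (1 + s_c * (A / 100) * k(t)) + eps_t`,
#' where `k(t)` is a double-exponential kernel (rise and decay time
#' constants) starting at stimulus onset and normalized to a maximum of 1
#' on the sampled frame grid, `s_c` is the channel polarity sign, `A` the
#' programmed response amplitude in percent of baseline, and `eps_t`
#' Gaussian noise. For FRET pairs the donor (CFP) and acceptor (YFP) carry
#' opposite polarity signs, emulating a FRET decrease on signal binding.
#'
#' @param frames Number of frames (default 240, i.e. 120 s at 2 Hz).
#' @param sample_rate Frames per second (default 2).
#' @param baseline Baseline intensity per channel (default 100; length 2
#'   for FRET).
#' @param bleach_tau_s Photobleach time constant per channel in seconds;
#'   `Inf` (default) disables bleaching.
#' @param amplitude_pct Programmed response amplitude `A` (percent of
#'   baseline, default 20).
#' @param polarity `+1` (fluorescence increases, default) or `-1`
#'   (Arclight-like decrease); ignored for FRET pairs, which use `c(+1,
#'   -1)` for (CFP, YFP).
#' @param rise_s,decay_s Kernel rise and decay time constants in seconds
#'   (defaults 2 and 8).
#' @param onset_s Stimulus onset in seconds (default 30).
#' @param duration_s Stimulus duration in seconds (metadata only,
#'   default 30).
#' @param noise_sd Gaussian noise SD in intensity units (default 0).
#' @param fret Generate a CFP/YFP pair (default `FALSE`).
#' @return List of class `"trace_sim_params"`.
#' @export
trace_sim_params <- function(frames = 240L, sample_rate = 2,
                             baseline = 100, bleach_tau_s = Inf,
                             amplitude_pct = 20, polarity = 1,
                             rise_s = 2, decay_s = 8, onset_s = 30,
                             duration_s = 30, noise_sd = 0,
                             fret = FALSE) {
  stopifnot(frames >= 2L, all(baseline > 0), rise_s > 0, decay_s > rise_s,
            onset_s >= 0, frames / sample_rate > onset_s)
  if (fret) {
    if (length(baseline) == 1L) baseline <- rep(baseline, 2L)
    if (length(bleach_tau_s) == 1L) bleach_tau_s <- rep(bleach_tau_s, 2L)
    polarity <- c(1, -1)
  }
  structure(list(frames = as.integer(frames), sample_rate = sample_rate,
                 baseline = baseline, bleach_tau_s = bleach_tau_s,
                 amplitude_pct = amplitude_pct, polarity = polarity,
                 rise_s = rise_s, decay_s = decay_s, onset_s = onset_s,
                 duration_s = duration_s, noise_sd = noise_sd,
                 fret = fret),
            class = "trace_sim_params")
}

# double-exponential kernel on the sampled frame grid, max exactly 1
response_kernel <- function(t_s, onset_s, rise_s, decay_s) {
  s <- t_s - onset_s
  k <- ifelse(s >= 0, exp(-s / decay_s) - exp(-s / rise_s), 0)
  pk <- max(k)
  if (pk > 0) k / pk else k
}

#' Simulate a fluorescence trace
#'
#' @param params A [trace_sim_params()].
#' @param roi_id ROI identifier for the emitted trace.
#' @param sensor Sensor label for the emitted trace (default `"GCaMP"`,
#'   or `"EPAC"` for FRET pairs).
#' @param seed Integer seed.
#' @return List of class `"trace_sim"`: `trace` (a [fluor_trace()]),
#'   `kernel` (the sampled kernel), `peak_frame` (index of the kernel
#'   maximum), `truth` (list with the programmed amplitude and, for FRET,
#'   the exact expected normalized-ratio peak in percent), `params`,
#'   `seed`.
#' @export
simulate_fluorescence_trace <- function(params, roi_id = "roi1",
                                        sensor = NULL, seed = 1L) {
  stopifnot(inherits(params, "trace_sim_params"))
  set.seed(seed)
  t_s <- (seq_len(params$frames) - 1L) / params$sample_rate
  k <- response_kernel(t_s, params$onset_s, params$rise_s, params$decay_s)
  peak_frame <- which.max(k)
  a <- params$amplitude_pct / 100
  make_channel <- function(b, tau, s_c) {
    bleach <- if (is.finite(tau)) exp(-t_s / tau) else rep(1, params$frames)
    v <- b * bleach * (1 + s_c * a * k)
    if (params$noise_sd > 0)
      v <- v + rnorm(params$frames, 0, params$noise_sd)
    v
  }
  if (params$fret) {
    cfp <- make_channel(params$baseline[1], params$bleach_tau_s[1], 1)
    yfp <- make_channel(params$baseline[2], params$bleach_tau_s[2], -1)
    if (is.null(sensor)) sensor <- "EPAC"
    trace <- fluor_trace(cfp = cfp, yfp = yfp, roi_id = roi_id,
                         sensor = sensor,
                         sample_rate = params$sample_rate,
                         stimulus_onset_s = params$onset_s,
                         stimulus_duration_s = params$duration_s)
    # noiseless, bleach-matched expectation of the normalized CFP/YFP peak
    ratio_peak_pct <- 100 * ((1 + a) / (1 - a) - 1)
  } else {
    if (is.null(sensor)) sensor <- "GCaMP"
    v <- make_channel(params$baseline[1], params$bleach_tau_s[1],
                      params$polarity[1])
    trace <- fluor_trace(values = v, roi_id = roi_id, sensor = sensor,
                         sample_rate = params$sample_rate,
                         stimulus_onset_s = params$onset_s,
                         stimulus_duration_s = params$duration_s)
    ratio_peak_pct <- NA_real_
  }
  structure(list(trace = trace, kernel = k, peak_frame = peak_frame,
                 truth = list(amplitude_pct = params$amplitude_pct,
                              polarity = params$polarity,
                              ratio_peak_pct = ratio_peak_pct),
                 params = params, seed = seed),
            class = "trace_sim")
}

#' Write one or more simulated traces as a tidy CSV
#'
#' Columns: `frame`, `time_s`, `roi_id`, `channel` (`"F"` for
#' single-channel, `"CFP"`/`"YFP"` for FRET), `intensity`.
#'
#' @param sims A `"trace_sim"` or list of them.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_trace_csv <- function(sims, path) {
  if (inherits(sims, "trace_sim")) sims <- list(sims)
  rows <- lapply(sims, function(s) {
    tr <- s$trace
    t_s <- (seq_len(s$params$frames) - 1L) / tr$sample_rate
    if (tr$channels == 2L) {
      rbind(data.frame(frame = seq_along(t_s), time_s = t_s,
                       roi_id = tr$roi_id, channel = "CFP",
                       intensity = tr$cfp, stringsAsFactors = FALSE),
            data.frame(frame = seq_along(t_s), time_s = t_s,
                       roi_id = tr$roi_id, channel = "YFP",
                       intensity = tr$yfp, stringsAsFactors = FALSE))
    } else {
      data.frame(frame = seq_along(t_s), time_s = t_s, roi_id = tr$roi_id,
                 channel = "F", intensity = tr$values,
                 stringsAsFactors = FALSE)
    }
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
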