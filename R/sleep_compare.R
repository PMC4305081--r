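# Temperature-shift sleep-change analysis: per-fly baseline subtraction and
# genotype comparison against both genetic controls.

#' Per-window metrics for a cohort
#'
#' Convenience wrapper: [fly_period_metrics()] for every fly, stacked.
#'
#' @param series List of `channel_series`.
#' @param ... Passed to [score_sleep()].
#' @return Data frame, one row per fly x window.
#' @export
cohort_period_metrics <- function(series, ...) {
  out <- do.call(rbind, lapply(series, fly_period_metrics, ...))
  rownames(out) <- NULL
  out
}

#' Per-fly baseline-subtracted sleep change
#'
#' For each fly, subtracts the metric of its baseline window from the same
#' fly's metric in the target window of the same light type (e.g. baseline
#' night at the rearing temperature vs the first night at 31 degrees C).
#' Flies missing either window (or with a partial window) are omitted and
#' listed in the `"omitted"` attribute.
#'
#' @param metrics Cohort per-window metrics ([cohort_period_metrics()]).
#' @param baseline_day,target_day Day indices of the two windows.
#' @param light `"L"` or `"D"`.
#' @param metric Metric column to difference (default `"total_sleep_min"`).
#' @return Data frame `fly_id`, `genotype`, `role`, `delta`, plus attributes
#'   `omitted` (character vector of fly ids) and `window`.
#' @export
per_fly_baseline_delta <- function(metrics, baseline_day, target_day,
                                   light = c("L", "D"),
                                   metric = "total_sleep_min") {
  light <- match.arg(light)
  stopifnot(metric %in% names(metrics))
  pick <- function(day) {
    d <- metrics[metrics$day_index == day & metrics$light == light &
                   !metrics$partial, , drop = FALSE]
    d[!is.na(d[[metric]]), , drop = FALSE]
  }
  base <- pick(baseline_day)
  targ <- pick(target_day)
  if (nrow(base) == 0L || nrow(targ) == 0L)
    stop(sprintf("no complete %s windows on day %d and/or day %d",
                 light, baseline_day, target_day))
  common <- intersect(base$fly_id, targ$fly_id)
  all_ids <- union(base$fly_id, targ$fly_id)
  omitted <- setdiff(all_ids, common)
  b <- base[match(common, base$fly_id), ]
  t_ <- targ[match(common, targ$fly_id), ]
  out <- data.frame(fly_id = common,
                    genotype = b$genotype,
                    role = b$role,
                    delta = t_[[metric]] - b[[metric]],
                    stringsAsFactors = FALSE)
  attr(out, "omitted") <- omitted
  attr(out, "window") <- list(baseline_day = baseline_day,
                              target_day = target_day, light = light,
                              metric = metric)
  out
}

#' Deltas for an explicit list of (baseline day, target day) pairs
#'
#' Implements repeated-shift designs where successive day pairs are each
#' analysed with their own baseline (e.g. day 1 baseline for day 2, day 3
#' baseline for day 4).
#'
#' @param metrics Cohort per-window metrics.
#' @param pairing List of length-2 integer vectors `c(baseline_day,
#'   target_day)`. Days may not be reused across pairs.
#' @param light `"L"` or `"D"`.
#' @param metric Metric column (default `"total_sleep_min"`).
#' @return Named list of delta data frames (names
#'   `"<baseline>-><target>"`).
#' @export
paired_day_deltas <- function(metrics, pairing, light = c("L", "D"),
                              metric = "total_sleep_min") {
  light <- match.arg(light)
  stopifnot(is.list(pairing), length(pairing) > 0L)
  # a day reused across two different pairs is a configuration error;
  # self-pairing (baseline == target) within one pair is allowed
  if (anyDuplicated(unlist(lapply(pairing, unique))) > 0)
    stop("overlapping day pairs: each day may appear in only one pair")
  out <- lapply(pairing, function(p) {
    stopifnot(length(p) == 2L)
    have <- unique(metrics$day_index)
    miss <- setdiff(p, have)
    if (length(miss) > 0L)
      stop(sprintf("pair (%d, %d): day %s absent from the metrics table",
                   p[1], p[2], paste(miss, collapse = ", ")))
    per_fly_baseline_delta(metrics, p[1], p[2], light, metric)
  })
  names(out) <- vapply(pairing, function(p) sprintf("%d->%d", p[1], p[2]),
                       "")
  out
}

#' Sleep gained or lost vs one control genotype
#'
#' Point estimate is `mean(experimental deltas) - mean(control deltas)`
#' (minutes gained when positive, lost when negative). The standard error is
#' the quadrature combination of the two group SEMs. The p value is a
#' two-sided Mann-Whitney test on the per-fly delta lists.
#'
#' @param exp_deltas Numeric vector of per-fly values (deltas, or raw
#'   day-averaged metrics for constitutive designs) for the experimental
#'   genotype.
#' @param ctrl_deltas Same for one control genotype.
#' @param ctrl_label Label of the control (e.g. `"gal4"` or `"uas"`).
#' @return One-row data frame: `control`, `estimate`, `sem`, `n_exp`,
#'   `n_ctrl`, `U`, `p`. With fewer than 2 flies in a group the estimate is
#'   still reported but `sem` and `p` are `NA`.
#' @export
genotype_sleep_change <- function(exp_deltas, ctrl_deltas,
                                  ctrl_label = "control") {
  exp_deltas <- as.numeric(exp_deltas)
  ctrl_deltas <- as.numeric(ctrl_deltas)
  if (length(exp_deltas) == 0L || length(ctrl_deltas) == 0L)
    stop("both groups must be non-empty")
  ms_e <- mean_sem(exp_deltas); ms_c <- mean_sem(ctrl_deltas)
  est <- ms_e[["mean"]] - ms_c[["mean"]]
  sem <- if (is.na(ms_e[["sem"]]) || is.na(ms_c[["sem"]])) NA_real_
         else sqrt(ms_e[["sem"]]^2 + ms_c[["sem"]]^2)
  if (length(exp_deltas) >= 2L && length(ctrl_deltas) >= 2L) {
    tst <- mann_whitney_u(exp_deltas, ctrl_deltas)
    u <- tst$statistic; p <- tst$p.value
  } else {
    u <- NA_real_; p <- NA_real_
  }
  data.frame(control = ctrl_label, estimate = est, sem = sem,
             n_exp = length(exp_deltas), n_ctrl = length(ctrl_deltas),
             U = u, p = p, stringsAsFactors = FALSE)
}

#' Compare the experimental genotype to both genetic controls
#'
#' Runs [genotype_sleep_change()] of the experimental group against the
#' GAL4-control and UAS-control groups and reports, alongside the two
#' pairwise p values, the conservative (numerically greatest) one — the
#' convention for dual-control genetic designs. Works identically on
#' baseline-subtracted deltas (temperature-shift designs) and on raw
#' day-averaged metrics (constitutive designs such as RNAi knockdowns).
#'
#' @param values Data frame with columns `role` (one of `"experimental"`,
#'   `"gal4_control"`, `"uas_control"`) and the value column.
#' @param value_col Name of the value column (default `"delta"`).
#' @param window Optional label describing the window analysed.
#' @return Object of class `"sleep_change"`: list with `window`, `vs_gal4`
#'   and `vs_uas` (rows from [genotype_sleep_change()]) and
#'   `conservative_p`.
#' @export
compare_to_controls <- function(values, value_col = "delta",
                                window = NULL) {
  stopifnot(is.data.frame(values), "role" %in% names(values),
            value_col %in% names(values))
  get <- function(role) values[[value_col]][values$role == role]
  for (role in c("experimental", "gal4_control", "uas_control"))
    if (length(get(role)) == 0L)
      stop(sprintf("missing group: %s", role))
  vs_gal4 <- genotype_sleep_change(get("experimental"), get("gal4_control"),
                                   "gal4")
  vs_uas <- genotype_sleep_change(get("experimental"), get("uas_control"),
                                  "uas")
  ps <- c(vs_gal4$p, vs_uas$p)
  cons <- if (anyNA(ps)) NA_real_ else conservative_p(ps)
  structure(list(window = window, vs_gal4 = vs_gal4, vs_uas = vs_uas,
                 conservative_p = cons),
            class = "sleep_change")
}

#' @export
print.sleep_change <- function(x, ...) {
  if (!is.null(x$window))
    cat(sprintf("sleep change, window %s\n",
                paste(unlist(x$window), collapse = " ")))
  for (nm in c("vs_gal4", "vs_uas")) {
    r <- x[[nm]]
    cat(sprintf("  vs %s: %+.1f min (sem %.1f), U = %g, p = %.4g\n",
                r$control, r$estimate, r$sem, r$U, r$p))
  }
  cat(sprintf("  conservative p = %.4g\n", x$conservative_p))
  invisible(x)
}

#' Full temperature-shift sleep-change table
#'
#' For each requested target day and light state, computes per-fly
#' baseline-subtracted deltas and compares the experimental genotype to
#' both controls.
#'
#' @param metrics Cohort per-window metrics ([cohort_period_metrics()]).
#' @param baseline_day Baseline day index (the pre-shift day).
#' @param target_days Integer vector of shift/recovery day indices.
#' @param lights Light states to analyse (default both).
#' @param metric Metric column (default `"total_sleep_min"`).
#' @return Data frame with one row per window x control comparison:
#'   `target_day`, `light`, `control`, `estimate`, `sem`, `n_exp`,
#'   `n_ctrl`, `U`, `p`, `conservative_p`.
#' @export
tempshift_sleep_change <- function(metrics, baseline_day, target_days,
                                   lights = c("L", "D"),
                                   metric = "total_sleep_min") {
  rows <- list()
  for (day in target_days) {
    for (lt in lights) {
      deltas <- per_fly_baseline_delta(metrics, baseline_day, day, lt,
                                       metric)
      res <- compare_to_controls(deltas, "delta",
                                 window = list(target_day = day,
                                               light = lt))
      for (nm in c("vs_gal4", "vs_uas")) {
        r <- res[[nm]]
        r <- cbind(data.frame(target_day = day, light = lt,
                              stringsAsFactors = FALSE), r)
        r$conservative_p <- res$conservative_p
        rows[[length(rows) + 1L]] <- r
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
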