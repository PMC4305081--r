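# Config-driven end-to-end pipelines. A run is described by a single config
# (a named list, or a YAML file); all defaults are resolved explicitly and
# the resolved config is serialized into the output directory, so a result
# folder is self-describing. Logs carry the package version, a hash of the
# resolved config and any exclusions — but no wall-clock time, so reruns of
# the same config are byte-identical.

read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    stopifnot(file.exists(config))
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  config
}

config_as_design <- function(design) {
  if (inherits(design, "dam_design")) return(design)
  experiment_design(
    lights_on = design$lights_on %||% "08:00",
    phase_schedule = as.data.frame(do.call(rbind, lapply(
      design$phase_schedule, as.data.frame)), stringsAsFactors = FALSE),
    channel_map = as.data.frame(do.call(rbind, lapply(
      design$channel_map, as.data.frame)), stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

finish_run <- function(out_dir, config, log_lines) {
  config$out_dir <- NULL   # the folder describes itself; keeps reruns of
                           # the same analysis byte-identical anywhere
  cfg_file <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(serialize_config(config), cfg_file)
  hash <- unname(tools::md5sum(cfg_file))
  log_lines <- c(sprintf("damsleep version %s",
                         as.character(utils::packageVersion("damsleep"))),
                 sprintf("config md5 %s", hash),
                 log_lines)
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(hash)
}

# yaml can't serialize S4/objects; keep plain lists, frames as row records
serialize_config <- function(x) {
  if (is.data.frame(x)) return(lapply(seq_len(nrow(x)), function(i)
    lapply(as.list(x[i, , drop = FALSE]), unclass)))
  if (inherits(x, "dam_design"))
    return(list(lights_on = x$lights_on,
                phase_schedule = serialize_config(x$phase_schedule),
                channel_map = serialize_config(x$channel_map)))
  if (is.list(x)) return(lapply(x, serialize_config))
  if (is.function(x)) return("<function>")
  x
}

#' Run the sleep-analysis pipeline
#'
#' Parses the configured DAM monitor files, annotates the timeline, applies
#' the dead-fly filter, scores sleep, and writes per-minute data, per-window
#' architecture metrics and per-genotype 30-min profiles. When
#' `baseline_day`/`target_days` are configured, the temperature-shift
#' sleep-change table (per-fly baseline deltas, comparison against both
#' controls, conservative p) is computed as well; with
#' `mode = "constitutive"` the comparison instead runs on day-averaged raw
#' metrics.
#'
#' @param config A named list or path to a YAML file. Fields: `dam_files`
#'   (named list, monitor name -> path), `design` (an
#'   [experiment_design()] or its plain-list form), `out_dir`, and options
#'   `bin_minutes` (30), `dead_fly_window_hours` (24), `mode`
#'   (`"tempshift"` or `"constitutive"`), `baseline_day`, `target_days`,
#'   `average_days` (constitutive mode), `metric` (`"total_sleep_min"`).
#' @return Invisibly, a list with the computed tables (`metrics`,
#'   `profile`, `sleep_change`, `exclusions`) and `out_dir`.
#' @export
run_sleep_pipeline <- function(config) {
  config <- read_run_config(config)
  stopifnot(!is.null(config$dam_files), !is.null(config$design),
            !is.null(config$out_dir))
  design <- config_as_design(config$design)
  bin_minutes <- config$bin_minutes %||% 30L
  dead_h <- config$dead_fly_window_hours %||% 24
  metric <- config$metric %||% "total_sleep_min"
  mode <- config$mode %||% "tempshift"
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- character(0)

  roles_present <- unique(design$channel_map$role)
  for (role in c("experimental", "gal4_control", "uas_control"))
    if (!role %in% roles_present)
      stop(sprintf("sleep pipeline: design is missing the %s group", role))

  series <- list()
  for (mon in names(config$dam_files)) {
    dam <- parse_dam_file(config$dam_files[[mon]])
    series <- c(series, annotate_timeline(dam, design, monitor = mon))
    log <- c(log, sprintf("monitor %s: %d rows, %d dropped", mon,
                          nrow(dam$counts), dam$n_dropped))
  }
  flt <- filter_dead_flies(series, dead_h)
  series <- flt$retained
  if (nrow(flt$excluded) > 0L)
    log <- c(log, sprintf("excluded (dead): %s",
                          paste(flt$excluded$fly_id, collapse = ", ")))
  if (length(series) == 0L) stop("sleep pipeline: no flies retained")

  records <- lapply(series, function(s) score_sleep(s$counts, s$missing))
  metrics <- do.call(rbind, Map(function(s, r) fly_period_metrics(s, r),
                                series, records))
  rownames(metrics) <- NULL

  # tidy per-minute table
  per_minute <- do.call(rbind, Map(function(s, r) {
    d <- as.data.frame(s)
    d$sleep <- r$sleep
    d
  }, series, records))
  rownames(per_minute) <- NULL

  # per-genotype binned profile, mean +/- SEM across flies of per-fly
  # day-averaged bins
  prof_fly <- do.call(rbind, Map(function(s, r) {
    p <- sleep_profile_binned(r, s$timeline, bin_minutes)
    agg <- tapply(p$sleep_min, p$bin, mean)
    data.frame(fly_id = s$fly_id, genotype = s$genotype,
               bin = as.integer(names(agg)), sleep_min = as.vector(agg),
               stringsAsFactors = FALSE)
  }, series, records))
  profile <- do.call(rbind, lapply(
    split(prof_fly, list(prof_fly$genotype, prof_fly$bin), drop = TRUE),
    function(d) {
      ms <- mean_sem(d$sleep_min)
      data.frame(genotype = d$genotype[1], bin = d$bin[1],
                 zt_min = d$bin[1] * bin_minutes,
                 mean_sleep_min = ms[["mean"]], sem = ms[["sem"]],
                 n = nrow(d), stringsAsFactors = FALSE)
    }))
  profile <- profile[order(profile$genotype, profile$bin), ]
  rownames(profile) <- NULL

  sleep_change <- NULL
  if (identical(mode, "tempshift") && !is.null(config$baseline_day)) {
    sleep_change <- tempshift_sleep_change(
      metrics, config$baseline_day, config$target_days,
      lights = config$lights %||% c("L", "D"), metric = metric)
  } else if (identical(mode, "constitutive")) {
    avg <- do.call(rbind, lapply(split(metrics, metrics$fly_id),
                                 average_across_days,
                                 days = config$average_days))
    role_of <- vapply(series, `[[`, "", "role")
    names(role_of) <- vapply(series, `[[`, "", "fly_id")
    avg$role <- role_of[avg$fly_id]
    rows <- lapply(c("L", "D"), function(lt) {
      d <- avg[avg$light == lt, ]
      res <- compare_to_controls(d, metric, window = list(light = lt))
      out <- rbind(res$vs_gal4, res$vs_uas)
      out$light <- lt
      out$conservative_p <- res$conservative_p
      out
    })
    sleep_change <- do.call(rbind, rows)
    rownames(sleep_change) <- NULL
  }

  write.csv(per_minute, file.path(out_dir, "per_minute.csv"),
            row.names = FALSE)
  write.csv(metrics, file.path(out_dir, "period_metrics.csv"),
            row.names = FALSE)
  write.csv(profile, file.path(out_dir, "sleep_profile.csv"),
            row.names = FALSE)
  write.csv(flt$excluded, file.path(out_dir, "exclusions.csv"),
            row.names = FALSE)
  if (!is.null(sleep_change))
    write.csv(sleep_change, file.path(out_dir, "sleep_change.csv"),
              row.names = FALSE)
  finish_run(out_dir, config, log)
  invisible(list(metrics = metrics, profile = profile,
                 sleep_change = sleep_change, exclusions = flt$excluded,
                 out_dir = out_dir))
}

#' Run the fluorescence-trace pipeline
#'
#' Reads a tidy trace CSV (`frame` or `time_s`, `roi_id`, `channel`,
#' `intensity`) plus per-ROI metadata (`roi_id`, `condition`, `sensor`),
#' computes each ROI's percent-change series (delta-F/F for single-channel
#' sensors, normalized CFP/YFP ratio for FRET pairs), extracts
#' polarity-aware maximum responses and writes per-ROI and per-condition
#' summaries with the Kruskal-Wallis-gated pairwise statistics.
#'
#' @param config Named list or YAML path. Fields: `trace_csv`, `roi_csv`,
#'   `out_dir`, options `experimental` (condition name; default first),
#'   `alpha` (0.05), `f0_mode` (`"first"`), `orientation`
#'   (`"cfp_over_yfp"`).
#' @return Invisibly, list with `responses`, `summary`
#'   (a [group_response_summary()]) and `out_dir`.
#' @export
run_trace_pipeline <- function(config) {
  config <- read_run_config(config)
  stopifnot(!is.null(config$trace_csv), !is.null(config$roi_csv),
            !is.null(config$out_dir))
  traces <- read.csv(config$trace_csv, stringsAsFactors = FALSE)
  rois <- read.csv(config$roi_csv, stringsAsFactors = FALSE)
  stopifnot(all(c("roi_id", "channel", "intensity") %in% names(traces)),
            all(c("roi_id", "condition", "sensor") %in% names(rois)))
  if (nrow(traces) == 0L) stop("trace pipeline: empty input")
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  f0_mode <- config$f0_mode %||% "first"
  orientation <- config$orientation %||% "cfp_over_yfp"

  responses <- do.call(rbind, lapply(seq_len(nrow(rois)), function(i) {
    roi <- rois$roi_id[i]
    d <- traces[traces$roi_id == roi, , drop = FALSE]
    if (nrow(d) == 0L) stop(sprintf("no trace rows for roi %s", roi))
    ord_col <- if ("frame" %in% names(d)) "frame" else "time_s"
    sensor <- rois$sensor[i]
    if (sensor %in% c("EPAC", "SuperClomeleon")) {
      cfp <- d[d$channel == "CFP", , drop = FALSE]
      yfp <- d[d$channel == "YFP", , drop = FALSE]
      series <- fret_ratio_trace(cfp$intensity[order(cfp[[ord_col]])],
                                 yfp$intensity[order(yfp[[ord_col]])],
                                 orientation = orientation)
      pol <- "positive_up"
    } else {
      v <- d$intensity[order(d[[ord_col]])]
      series <- compute_dff(v, f0_mode = f0_mode)
      pol <- sensor_polarity(sensor)
    }
    data.frame(roi_id = roi, condition = rois$condition[i],
               sensor = sensor, polarity = pol,
               max_change_pct = extract_max_response(series, pol),
               stringsAsFactors = FALSE)
  }))

  groups <- split(responses$max_change_pct, responses$condition)
  experimental <- config$experimental %||% responses$condition[1]
  summ <- group_response_summary(groups, experimental = experimental,
                                 alpha = config$alpha %||% 0.05)
  gdf <- summ$groups
  gdf$kw_H <- summ$kw$statistic
  gdf$kw_p <- summ$kw$p.value
  gdf$conservative_p <- summ$conservative_p

  write.csv(responses, file.path(out_dir, "responses.csv"),
            row.names = FALSE)
  write.csv(gdf, file.path(out_dir, "group_summary.csv"),
            row.names = FALSE)
  if (!is.null(summ$pairwise))
    write.csv(summ$pairwise, file.path(out_dir, "pairwise_tests.csv"),
              row.names = FALSE)
  finish_run(out_dir, config,
             c(sprintf("rois: %d", nrow(rois)),
               sprintf("ratio orientation: %s", orientation),
               sprintf("f0 mode: %s", f0_mode)))
  invisible(list(responses = responses, summary = summ, out_dir = out_dir))
}

#' Run the colocalization pipeline
#'
#' Reads two single-channel multi-page TIFF stacks (or one interleaved
#' stack), subtracts the morphological background per slice, Z-projects,
#' computes the PDM intensity-correlation map and writes the map (32-bit
#' float TIFF), a false-color PNG and a summary CSV.
#'
#' @param config Named list or YAML path. Fields: `r_tiff` and `g_tiff`
#'   (or `tiff` with `interleaved: true`, odd pages = channel R),
#'   `out_dir`, options `background_radius` (50; 0 disables subtraction),
#'   `projection` (`"sum"` or `"max"`), `slice_range`, `mask_tiff`,
#'   `render_png` (TRUE).
#' @return Invisibly, list with the `pdm_map`, `summary` data frame and
#'   `out_dir`.
#' @export
run_coloc_pipeline <- function(config) {
  config <- read_run_config(config)
  stopifnot(!is.null(config$out_dir))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (isTRUE(config$interleaved)) {
    stopifnot(!is.null(config$tiff))
    pages <- read_tiff_stack(config$tiff)
    if (length(pages) < 2L) stop("interleaved stack needs >= 2 pages")
    r_stack <- pages[seq(1, length(pages), by = 2)]
    g_stack <- pages[seq(2, length(pages), by = 2)]
  } else {
    stopifnot(!is.null(config$r_tiff), !is.null(config$g_tiff))
    r_stack <- read_tiff_stack(config$r_tiff)
    g_stack <- read_tiff_stack(config$g_tiff)
  }
  radius <- config$background_radius %||% 50
  if (radius > 0) {
    r_stack <- subtract_background(r_stack, radius)
    g_stack <- subtract_background(g_stack, radius)
  }
  projection <- config$projection %||% "sum"
  r_img <- z_project(r_stack, projection, config$slice_range)
  g_img <- z_project(g_stack, projection, config$slice_range)
  mask <- NULL
  if (!is.null(config$mask_tiff))
    mask <- read_tiff_stack(config$mask_tiff)[[1]] > 0
  map <- compute_pdm(r_img, g_img, mask)
  png_path <- if (isTRUE(config$render_png %||% TRUE))
    file.path(out_dir, "pdm.png") else NULL
  summary <- pdm_summary(map, png_path)
  # 32-bit float TIFF; PDM in [-scale, scale] is stored as
  # (pdm / (2 * scale)) + 0.5 with the scale recorded in the summary CSV,
  # since TIFF storage outside [0, 1] is not portable. NA outside the mask
  # is stored as 0.5 (i.e. PDM 0).
  pdm_out <- map$pdm
  pdm_out[is.na(pdm_out)] <- 0
  scale <- max(abs(pdm_out), .Machine$double.eps)
  tiff::writeTIFF(pdm_out / (2 * scale) + 0.5,
                  file.path(out_dir, "pdm.tif"), bits.per.sample = 32L)
  summary$scale <- scale
  write.csv(summary, file.path(out_dir, "pdm_summary.csv"),
            row.names = FALSE)
  finish_run(out_dir, config,
             c(sprintf("projection: %s", projection),
               sprintf("background radius: %g", radius)))
  invisible(list(pdm_map = map, summary = summary, out_dir = out_dir))
}
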