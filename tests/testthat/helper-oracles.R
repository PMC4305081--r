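# Independent oracles and small fixture builders shared across tests.

# Brute-force maximal-run sleep scanner: a plain minute-by-minute loop,
# deliberately unrelated to the run-length-encoding implementation.
scan_sleep_oracle <- function(counts, min_bout = 5L) {
  n <- length(counts)
  sleep <- rep(FALSE, n)
  run <- 0L
  for (t in seq_len(n + 1L)) {
    zero <- t <= n && counts[t] == 0
    if (zero) {
      run <- run + 1L
    } else {
      if (run >= min_bout) sleep[(t - run):(t - 1L)] <- TRUE
      run <- 0L
    }
  }
  sleep
}

# Exact two-sided Mann-Whitney p by explicit enumeration of all labelings.
mwu_enum_oracle <- function(x, y) {
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  splits <- utils::combn(n + m, n)
  us <- apply(splits, 2, function(idx) sum(r[idx]) - n * (n + 1) / 2)
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# One fly's annotated series built directly from a count vector (single
# channel, day starts at lights-on).
make_series <- function(counts, n_days = NULL, fly_id = "f1",
                        genotype = "g", role = "experimental",
                        phases = NULL) {
  n <- length(counts)
  if (is.null(n_days)) n_days <- ceiling(n / 1440)
  zt <- (seq_len(n) - 1L) %% 1440L
  day <- (seq_len(n) - 1L) %/% 1440L
  if (is.null(phases)) phases <- rep("baseline", n_days)
  structure(list(fly_id = fly_id, genotype = genotype, role = role,
                 counts = counts, missing = rep(FALSE, n),
                 timeline = data.frame(
                   zt_minute = zt,
                   light = ifelse(zt < 720L, "L", "D"),
                   phase = phases[day + 1L],
                   day_index = day,
                   stringsAsFactors = FALSE),
                 start = as.POSIXct("2024-01-01 08:00:00", tz = "UTC")),
            class = "channel_series")
}

# A small complete temperature-shift experiment: simulate, parse the emitted
# text, annotate, and return the cohort metrics table plus the sim object.
sim_cohort_metrics <- function(n_flies = 8, seed = 1, ...) {
  p <- sleep_sim_params(n_flies = n_flies, ...)
  sim <- simulate_dam_experiment(p, seed = seed)
  series <- list()
  for (mon in names(sim$dam_text)) {
    dam <- parse_dam_file(sim$dam_text[[mon]])
    series <- c(series, annotate_timeline(dam, sim$design, mon))
  }
  list(sim = sim, series = series,
       metrics = cohort_period_metrics(series))
}
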