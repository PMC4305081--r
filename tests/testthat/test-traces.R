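test_that("delta-F/F follows the percent-change definition", {
  expect_equal(compute_dff(rep(7, 10)), rep(0, 10))
  expect_equal(compute_dff(c(100, 150))[2], 50)
  expect_equal(compute_dff(c(100, 150))[1], 0)

  # gain invariance: scaling the whole trace changes nothing
  set.seed(3)
  f <- 100 + cumsum(rnorm(50))
  for (k in c(0.01, 3, 1e4))
    expect_equal(compute_dff(k * f), compute_dff(f))

  expect_error(compute_dff(c(0, 1, 2)), "positive")
  expect_error(compute_dff(c(-5, 1, 2)), "positive")

  # pre-stimulus mean baseline option
  f2 <- c(10, 14, 24)
  expect_equal(compute_dff(f2, "prestim_mean", prestim_frames = 2),
               (f2 - 12) / 12 * 100)
})

test_that("maximum response respects sensor polarity and window", {
  ser <- c(0, 5, 23.7, 11, -8, 2)
  expect_equal(extract_max_response(ser), 23.7)
  expect_equal(extract_max_response(ser, "negative_up"), -8)
  expect_equal(extract_max_response(ser, search_window = 4:6), 11)
  expect_identical(sensor_polarity("Arclight"), "negative_up")
  expect_identical(sensor_polarity("GCaMP"), "positive_up")
  expect_error(extract_max_response(numeric(0)), "empty")
})

test_that("normalized FRET ratio: zeros, arithmetic, gain invariance", {
  expect_equal(fret_ratio_trace(rep(5, 8), rep(3, 8)), rep(0, 8))

  # CFP doubled at one frame, YFP unchanged -> +100% there
  cfp <- rep(10, 6); cfp[4] <- 20
  yfp <- rep(8, 6)
  r <- fret_ratio_trace(cfp, yfp)
  expect_equal(r[4], 100)
  expect_equal(r[1], 0)

  # per-channel gain invariance
  set.seed(9)
  cfp <- 100 + cumsum(rnorm(40)); yfp <- 80 + cumsum(rnorm(40))
  base <- fret_ratio_trace(cfp, yfp)
  expect_equal(fret_ratio_trace(2.5 * cfp, yfp), base)
  expect_equal(fret_ratio_trace(cfp, 0.3 * yfp), base)

  # orientation flip gives the reciprocal-normalized series
  flip <- fret_ratio_trace(cfp, yfp, orientation = "yfp_over_cfp")
  expect_equal((1 + flip / 100) * (1 + base / 100), rep(1, 40))

  expect_error(fret_ratio_trace(c(1, 0, 2), c(1, 1, 1)), "positive")
})

test_that("group summaries gate pairwise tests on Kruskal-Wallis", {
  # three identical groups: gate shut, no pairwise tests
  same <- list(a = rep(2, 6), b = rep(2, 6), c = rep(2, 6))
  s <- group_response_summary(same, experimental = "a")
  expect_equal(s$kw$p.value, 1)
  expect_null(s$pairwise)
  expect_true(is.na(s$conservative_p))

  # summary arithmetic
  g <- group_response_summary(list(a = c(10, 20, 30), b = c(1, 2, 3)),
                              experimental = "a", alpha = 1.1)
  row <- g$groups[g$groups$condition == "a", ]
  expect_equal(row$mean, 20)
  expect_equal(row$sem, 10 / sqrt(3), tolerance = 1e-12)

  # clear separation opens the gate and yields small conservative p
  set.seed(12)
  resp <- list(exp = rnorm(10, 20, 2), ctrl1 = rnorm(10, 0, 2),
               ctrl2 = rnorm(10, 0, 2))
  s2 <- group_response_summary(resp, experimental = "exp")
  expect_lt(s2$kw$p.value, 0.05)
  expect_equal(nrow(s2$pairwise), 2)
  expect_lt(s2$conservative_p, 0.05)
  expect_equal(s2$conservative_p, max(s2$pairwise$p))

  expect_error(group_response_summary(list(a = 1:3, b = numeric(0))),
               "non-empty")
})

test_that("synthetic traces recover the programmed amplitude", {
  # noiseless: exact at the kernel peak
  s <- simulate_fluorescence_trace(trace_sim_params(amplitude_pct = 50,
                                                    noise_sd = 0))
  d <- compute_dff(s$trace)
  expect_equal(max(d), 50)
  expect_equal(which.max(d), s$peak_frame)

  # Arclight-like polarity: minimum rule recovers -A
  sa <- simulate_fluorescence_trace(
    trace_sim_params(amplitude_pct = 30, polarity = -1, noise_sd = 0),
    sensor = "Arclight")
  da <- compute_dff(sa$trace)
  expect_equal(extract_max_response(da, sensor_polarity("Arclight")), -30)

  # FRET pair, closed form (1 + a) / (1 - a) at the peak
  sf <- simulate_fluorescence_trace(trace_sim_params(amplitude_pct = 20,
                                                     fret = TRUE,
                                                     noise_sd = 0))
  fr <- fret_ratio_trace(sf$trace)
  expect_equal(max(fr), 100 * (1.2 / 0.8 - 1))
  expect_equal(max(fr), sf$truth$ratio_peak_pct)

  # noisy recovery: A = 30, sigma = 1 -> mean absolute error of the
  # extracted maximum stays below 3 sigma; the max-of-noise bias is positive
  errs <- vapply(1:40, function(seed) {
    sn <- simulate_fluorescence_trace(
      trace_sim_params(amplitude_pct = 30, noise_sd = 1), seed = seed)
    max(compute_dff(sn$trace)) - 30
  }, numeric(1))
  expect_lt(mean(abs(errs)), 3)
  expect_gt(mean(errs), 0)   # documented positive bias of the maximum
})

test_that("gain and bleach interact with the series as constructed", {
  # bleach without response: series decays but starts at zero
  sb <- simulate_fluorescence_trace(
    trace_sim_params(amplitude_pct = 0, bleach_tau_s = 60, noise_sd = 0))
  d <- compute_dff(sb$trace)
  expect_equal(d[1], 0)
  expect_lt(d[length(d)], 0)
  # constant trace when everything is off
  s0 <- simulate_fluorescence_trace(
    trace_sim_params(amplitude_pct = 0, noise_sd = 0))
  expect_equal(compute_dff(s0$trace), rep(0, 240))
})
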