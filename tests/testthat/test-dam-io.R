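test_that("DAM parsing round-trips generator output and handles edge cases", {
  # empty input: 32 empty channels
  empty <- parse_dam_file("")
  expect_equal(dim(empty$counts), c(0L, 32L))

  # 3-row fixture with known counts round-trips exactly
  counts <- matrix(0L, 3, 32)
  counts[, 1] <- c(2L, 0L, 5L); counts[, 32] <- c(1L, 1L, 1L)
  lines <- format_dam_lines(counts)
  dam <- parse_dam_file(lines)
  expect_identical(dam$counts, counts)
  expect_equal(as.numeric(diff(dam$timestamps), units = "mins"), c(1, 1))

  # malformed rows are reported with their line number
  bad <- lines
  bad[2] <- sub("\t[0-9]+$", "", bad[2])      # 31 count fields
  expect_error(parse_dam_file(bad), "line 2")
  bad <- lines
  bad[3] <- sub("\t1$", "\tx", bad[3])        # non-integer count
  expect_error(parse_dam_file(bad), "non-integer")

  # non-monotone timestamps
  expect_error(parse_dam_file(lines[c(2, 1, 3)]), "non-monotone")
})

test_that("status codes and gaps follow the dialect policy", {
  counts <- matrix(1L, 5, 32)
  lines <- format_dam_lines(counts)
  lines[3] <- sub("^(([^\t]*\t){3})1", "\\151", lines[3])  # status 51
  # an invalid reading is masked, not removed: the timeline stays contiguous
  dropped <- parse_dam_file(lines)
  expect_equal(nrow(dropped$counts), 5)
  expect_equal(dropped$n_dropped, 1L)
  expect_true(dropped$missing[3])
  expect_true(all(is.na(dropped$counts[3, ])))
  expect_error(
    parse_dam_file(lines, dam_dialect(on_invalid_status = "error")),
    "status")

  # dropping a row leaves a gap: error by default, maskable
  expect_error(parse_dam_file(lines[-3]), "gap")
  masked <- parse_dam_file(lines[-3], dam_dialect(on_gap = "mask"))
  expect_equal(nrow(masked$counts), 5)
  expect_true(masked$missing[3])
  expect_true(all(is.na(masked$counts[3, ])))
})

test_that("timeline annotation assigns ZT, light, phase and day", {
  sched <- data.frame(phase = c("baseline", "shift", "recovery"),
                      n_days = c(1L, 2L, 1L), temp_c = c(22, 31, 22))
  cmap <- data.frame(monitor = "M1", channel = 1:2,
                     fly_id = c("a", "b"), genotype = c("g1", "g2"),
                     role = c("experimental", "gal4_control"),
                     stringsAsFactors = FALSE)
  design <- experiment_design("08:00", sched, cmap)
  counts <- matrix(rpois(4 * 1440 * 32, 1), ncol = 32)
  lines <- format_dam_lines(counts,
                            start = as.POSIXct("2024-01-01 08:00:00",
                                               tz = "UTC"))
  series <- annotate_timeline(parse_dam_file(lines), design)
  expect_named(series, c("a", "b"))
  tl <- series$a$timeline

  # lights-on minute is ZT0 and light; minute 720 is dark
  expect_equal(tl$zt_minute[1], 0)
  expect_equal(tl$light[1], "L")
  expect_equal(tl$light[721], "D")
  expect_equal(tl$zt_minute[721], 720)

  # schedule hand-walk: days 0..3 -> baseline, shift, shift, recovery
  byday <- unique(tl[c("day_index", "phase")])
  expect_equal(byday$phase, c("baseline", "shift", "shift", "recovery"))

  # light labels partition each complete day 720/720
  for (d in 0:3) {
    expect_equal(sum(tl$day_index == d & tl$light == "L"), 720)
    expect_equal(sum(tl$day_index == d & tl$light == "D"), 720)
  }

  # counts survive annotation untouched
  expect_identical(series$a$counts, counts[, 1])
  expect_equal(sum(series$b$counts), sum(counts[, 2]))

  # a file shorter than the schedule is a coverage error
  short <- format_dam_lines(counts[1:(2 * 1440), ])
  expect_error(annotate_timeline(parse_dam_file(short), design),
               "coverage")

  # unmapped channels are omitted
  expect_length(series, 2)
})

test_that("dead-fly filter excludes programmed deaths and nothing else", {
  dead <- make_series(rep(0L, 2 * 1440), fly_id = "dead")
  alive <- make_series(rpois(2 * 1440, 2), fly_id = "alive")
  res <- filter_dead_flies(list(dead, alive))
  expect_equal(res$excluded$fly_id, "dead")
  expect_length(res$retained, 1)
  expect_equal(res$retained[[1]]$fly_id, "alive")

  # generator cohort with two programmed deaths
  p <- sleep_sim_params(n_flies = 4, deaths = 2L)
  sim <- simulate_dam_experiment(p, seed = 5)
  dam <- parse_dam_file(sim$dam_text$M1)
  series <- annotate_timeline(dam, sim$design, "M1")
  res <- filter_dead_flies(series)
  expect_setequal(res$excluded$fly_id, sim$dead_ids)
  expect_error(filter_dead_flies(list(alive), window_hours = 1e6),
               "duration")
})
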