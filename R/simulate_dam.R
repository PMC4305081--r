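# Synthetic DAM experiments: a minute-resolution two-state (wake/sleep)
# Markov chain per fly, with light/dark- and phase-dependent transition
# probabilities; wake minutes emit Poisson beam-crossing counts, sleep
# minutes emit zero. Effects are programmed as changes to the stationary
# sleep fraction, so ground truth is exact.

#' Parameters for a synthetic temperature-shift DAM experiment
#'
#' Defines a three-genotype (experimental, GAL4 control, UAS control)
#' cohort run through a baseline / temperature-shift / recovery schedule.
#' Sleep/wake dynamics are a per-minute two-state Markov chain whose
#' stationary sleep fraction is `p_ws / (p_ws + p_sw)`; the default rates
#' give about 216 min of daytime and 600 min of nighttime sleep per 12-hr
#' window, in the range typical of wild-type flies. A shift effect is
#' programmed for the experimental genotype only, during shift days only,
#' by re-solving `p_ws` (at fixed `p_sw`) so the stationary sleep fraction
#' changes by `effect / 720` — e.g. `shift_effect_dark_min = -90` lowers
#' expected nighttime sleep by 90 min.
#'
#' @param n_flies Flies per genotype (default 16).
#' @param n_days Named integer vector of days per phase (default
#'   `c(baseline = 1, shift = 2, recovery = 1)`).
#' @param p_ws_light,p_sw_light Wake->sleep and sleep->wake per-minute
#'   probabilities during the light phase (defaults 0.03, 0.07).
#' @param p_ws_dark,p_sw_dark Same for the dark phase (defaults 0.15,
#'   0.03).
#' @param lambda_wake Mean Poisson beam crossings per waking minute
#'   (default 3).
#' @param shift_effect_light_min,shift_effect_dark_min Programmed change,
#'   in expected minutes per 720-min window, of the experimental genotype's
#'   sleep during shift days (defaults 0 and -90).
#' @param deaths Integer: number of experimental-genotype flies programmed
#'   to die (all-zero counts from the start of the final day; default 0).
#' @return List of class `"sleep_sim_params"`, including the per
#'   (genotype, phase, light) rate table in `$rates`.
#' @export
sleep_sim_params <- function(n_flies = 16L,
                             n_days = c(baseline = 1L, shift = 2L,
                                        recovery = 1L),
                             p_ws_light = 0.03, p_sw_light = 0.07,
                             p_ws_dark = 0.15, p_sw_dark = 0.03,
                             lambda_wake = 3,
                             shift_effect_light_min = 0,
                             shift_effect_dark_min = -90,
                             deaths = 0L) {
  check_prob <- function(p) all(p >= 0 & p <= 1)
  if (!check_prob(c(p_ws_light, p_sw_light, p_ws_dark, p_sw_dark)))
    stop("transition probabilities must lie in [0, 1]")
  if (lambda_wake <= 0) stop("lambda_wake must be positive")
  genotypes <- data.frame(
    genotype = c("gal4>uas", "gal4/+", "uas/+"),
    role = c("experimental", "gal4_control", "uas_control"),
    stringsAsFactors = FALSE)
  phases <- names(n_days)
  rates <- expand.grid(genotype = genotypes$genotype, phase = phases,
                       light = c("L", "D"), stringsAsFactors = FALSE)
  rates$p_ws <- ifelse(rates$light == "L", p_ws_light, p_ws_dark)
  rates$p_sw <- ifelse(rates$light == "L", p_sw_light, p_sw_dark)
  rates$lambda <- lambda_wake
  # program the shift effect for the experimental genotype
  for (lt in c("L", "D")) {
    eff <- if (lt == "L") shift_effect_light_min else shift_effect_dark_min
    if (eff == 0) next
    i <- which(rates$genotype == "gal4>uas" & rates$phase == "shift" &
                 rates$light == lt)
    f0 <- rates$p_ws[i] / (rates$p_ws[i] + rates$p_sw[i])
    f1 <- f0 + eff / 720
    if (any(f1 <= 0 | f1 >= 1))
      stop("programmed effect pushes the sleep fraction outside (0, 1)")
    rates$p_ws[i] <- rates$p_sw[i] * f1 / (1 - f1)
  }
  rates$sleep_frac <- rates$p_ws / (rates$p_ws + rates$p_sw)
  structure(list(n_flies = as.integer(n_flies), n_days = n_days,
                 genotypes = genotypes, rates = rates,
                 deaths = as.integer(deaths),
                 effects = c(L = shift_effect_light_min,
                             D = shift_effect_dark_min)),
            class = "sleep_sim_params")
}

#' Simulate a DAM temperature-shift experiment
#'
#' Generates minute-resolution wake/sleep state chains for every fly,
#' emits Poisson counts on wake minutes, formats the result as DAM monitor
#' file text (32 channels per monitor, spilling into additional monitors as
#' needed), and returns exact ground truth: the latent state matrix,
#' latent sleep minutes per 12-hr window, the five-minute-rule scoring of
#' the latent sleep runs, and the programmed stationary sleep fractions.
#'
#' @param params A [sleep_sim_params()].
#' @param lights_on Lights-on clock time, `"HH:MM"` (default `"08:00"`).
#'   The recording starts at lights-on of day 0.
#' @param start_date Calendar date of day 0 (default `"2024-01-01"`).
#' @param seed Integer seed; the simulation is fully reproducible.
#' @return List of class `"dam_sim"`:
#'   * `dam_text` — named list of character vectors, one per monitor;
#'   * `design` — the matching [experiment_design()];
#'   * `counts` — minutes x flies integer matrix;
#'   * `latent` — minutes x flies logical matrix (`TRUE` = asleep);
#'   * `truth` — data frame per fly x window: `latent_sleep_min` and
#'     `rule_sleep_min` (>= 5-min maximal runs of the latent states);
#'   * `params`, `seed`.
#' @export
simulate_dam_experiment <- function(params, lights_on = "08:00",
                                    start_date = "2024-01-01",
                                    seed = 1L) {
  stopifnot(inherits(params, "sleep_sim_params"))
  set.seed(seed)
  n_per <- params$n_flies
  geno <- params$genotypes
  n_fly <- n_per * nrow(geno)
  fly_geno <- rep(geno$genotype, each = n_per)
  fly_role <- rep(geno$role, each = n_per)
  fly_id <- sprintf("%s_f%02d", gsub("[^a-zA-Z0-9]", "", fly_geno),
                    rep(seq_len(n_per), times = nrow(geno)))

  phases_by_day <- rep(names(params$n_days), params$n_days)
  n_day <- length(phases_by_day)
  n_min <- n_day * 1440L
  zt <- (seq_len(n_min) - 1L) %% 1440L
  light <- ifelse(zt < 720L, "L", "D")
  day_index <- (seq_len(n_min) - 1L) %/% 1440L
  phase <- phases_by_day[day_index + 1L]

  # per-minute, per-fly transition probabilities via a rate-row lookup
  rates <- params$rates
  rate_key <- paste(rates$genotype, rates$phase, rates$light)
  block_key <- paste(phase, light)                 # per minute
  key_per_geno <- lapply(geno$genotype, function(g)
    match(paste(g, block_key), rate_key))
  if (anyNA(unlist(key_per_geno)))
    stop("rate table does not cover every genotype x phase x light cell")

  latent <- matrix(FALSE, nrow = n_min, ncol = n_fly)
  geno_of_fly <- match(fly_geno, geno$genotype)
  # initial state: stationary draw for the first minute's block
  idx0 <- vapply(geno_of_fly, function(gi) key_per_geno[[gi]][1], 0L)
  state <- runif(n_fly) < rates$sleep_frac[idx0]   # TRUE = asleep
  # per-minute loop, vectorized across flies; probabilities change only at
  # 720-min block boundaries
  cur_block <- -1L
  pws <- psw <- numeric(n_fly)
  for (t in seq_len(n_min)) {
    blk <- (t - 1L) %/% 720L
    if (blk != cur_block) {
      idx <- vapply(geno_of_fly, function(gi) key_per_geno[[gi]][t], 0L)
      pws <- rates$p_ws[idx]; psw <- rates$p_sw[idx]
      cur_block <- blk
    }
    u <- runif(n_fly)
    state <- (state & u >= psw) | (!state & u < pws)
    latent[t, ] <- state
  }

  counts <- matrix(0L, nrow = n_min, ncol = n_fly)
  wake <- !latent
  n_wake <- sum(wake)
  lam <- matrix(rates$lambda[vapply(geno_of_fly, function(gi)
    key_per_geno[[gi]], integer(n_min))], nrow = n_min)
  counts[wake] <- rpois(n_wake, lam[wake])

  # programmed deaths: first `deaths` experimental flies emit all-zero
  # counts from the start of the final day
  dead_ids <- character(0)
  if (params$deaths > 0L) {
    which_dead <- which(fly_role == "experimental")[seq_len(params$deaths)]
    counts[day_index == (n_day - 1L), which_dead] <- 0L
    latent[day_index == (n_day - 1L), which_dead] <- FALSE
    dead_ids <- fly_id[which_dead]
  }

  # ground truth per fly x 12-hr window
  truth <- do.call(rbind, lapply(seq_len(n_fly), function(f) {
    do.call(rbind, lapply(0:(n_day - 1L), function(d) {
      do.call(rbind, lapply(c("L", "D"), function(lt) {
        w <- day_index == d & light == lt
        lat <- latent[w, f]
        data.frame(fly_id = fly_id[f], genotype = fly_geno[f],
                   role = fly_role[f], day_index = d, light = lt,
                   phase = phases_by_day[d + 1L],
                   latent_sleep_min = sum(lat),
                   rule_sleep_min = rule_minutes(lat),
                   stringsAsFactors = FALSE)
      }))
    }))
  }))
  rownames(truth) <- NULL

  # pack into monitors of 32 channels
  n_mon <- ceiling(n_fly / 32L)
  start <- as.POSIXct(paste(start_date,
                            sprintf("%s:00", lights_on)), tz = "UTC")
  dam_text <- list()
  cm <- list()
  for (m in seq_len(n_mon)) {
    cols <- ((m - 1L) * 32L + 1L):min(m * 32L, n_fly)
    mat <- matrix(0L, nrow = n_min, ncol = 32L)
    mat[, seq_along(cols)] <- counts[, cols]
    mon <- sprintf("M%d", m)
    dam_text[[mon]] <- format_dam_lines(mat, start = start)
    cm[[m]] <- data.frame(monitor = mon, channel = seq_along(cols),
                          fly_id = fly_id[cols], genotype = fly_geno[cols],
                          role = fly_role[cols], stringsAsFactors = FALSE)
  }
  design <- experiment_design(
    lights_on = lights_on,
    phase_schedule = data.frame(phase = names(params$n_days),
                                n_days = as.integer(params$n_days),
                                temp_c = ifelse(names(params$n_days) ==
                                                  "shift", 31, 22)),
    channel_map = do.call(rbind, cm))

  structure(list(dam_text = dam_text, design = design, counts = counts,
                 latent = latent, truth = truth, fly_id = fly_id,
                 dead_ids = dead_ids, params = params, seed = seed),
            class = "dam_sim")
}

# minutes belonging to maximal TRUE-runs of length >= 5
rule_minutes <- function(x, min_bout = 5L) {
  if (length(x) == 0L) return(0L)
  r <- rle(x)
  sum(r$lengths[r$values & r$lengths >= min_bout])
}

#' Write a simulated experiment to disk
#'
#' Emits one DAM text file per monitor plus a ground-truth JSON sidecar.
#'
#' @param sim A `"dam_sim"` object.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_dam_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "dam_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c()
  for (mon in names(sim$dam_text)) {
    f <- file.path(dir, sprintf("%s.txt", mon))
    writeLines(sim$dam_text[[mon]], f)
    files[mon] <- f
  }
  truth_file <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(list(truth = sim$truth,
                            effects = as.list(sim$params$effects),
                            dead_ids = sim$dead_ids,
                            seed = sim$seed),
                       truth_file, dataframe = "columns", digits = NA)
  files["truth"] <- truth_file
  invisible(files)
}
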