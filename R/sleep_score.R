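# Sleep scoring: the >= 5 min uninterrupted-inactivity rule.

#' Score sleep from minute activity counts
#'
#' A minute is scored as sleep iff it belongs to a maximal run of
#' consecutive zero-count minutes of length at least `min_bout` (default 5,
#' the field-standard Drosophila definition). Each such maximal run is one
#' sleep episode. Missing minutes (masked gaps) break inactivity runs and
#' are scored neither as sleep nor as wake.
#'
#' Runs touching the edges of the recording count as episodes if long
#' enough; set `censor_edges = TRUE` to drop episodes that touch either end
#' (their minutes are then not scored as sleep either).
#'
#' @param counts Non-negative integer vector of per-minute activity counts.
#'   `NA` entries are treated as missing.
#' @param missing_mask Optional logical vector marking missing minutes.
#' @param min_bout Minimum run length in minutes (default 5).
#' @param censor_edges Drop runs that touch the first or last minute
#'   (default `FALSE`).
#' @return Object of class `"sleep_record"`: list with `sleep` (logical
#'   vector; `NA` where missing), `episodes` (data frame with `start`,
#'   `duration`, 1-based start index) and `missing` (logical vector).
#' @examples
#' r <- score_sleep(c(1, 0, 0, 0, 0, 0, 0, 0, 0, 0, 1))
#' r$episodes  # one episode: start 2, duration 9
#' @export
score_sleep <- function(counts, missing_mask = NULL, min_bout = 5L,
                        censor_edges = FALSE) {
  counts <- as.numeric(counts)
  if (any(counts < 0, na.rm = TRUE)) stop("activity counts must be >= 0")
  n <- length(counts)
  if (is.null(missing_mask)) missing_mask <- is.na(counts)
  else missing_mask <- missing_mask | is.na(counts)
  stopifnot(length(missing_mask) == n)
  inactive <- !missing_mask & counts == 0
  sleep <- rep(FALSE, n)
  eps_start <- integer(0); eps_dur <- integer(0)
  if (n > 0) {
    r <- rle(inactive)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= min_bout
    if (censor_edges && any(keep)) {
      keep <- keep & !(starts == 1L | ends == n)
    }
    eps_start <- starts[keep]
    eps_dur <- r$lengths[keep]
    for (i in seq_along(eps_start))
      sleep[eps_start[i]:(eps_start[i] + eps_dur[i] - 1L)] <- TRUE
  }
  sleep[missing_mask] <- NA
  structure(list(sleep = sleep,
                 episodes = data.frame(start = eps_start,
                                       duration = eps_dur),
                 missing = missing_mask,
                 min_bout = as.integer(min_bout)),
            class = "sleep_record")
}

#' @export
print.sleep_record <- function(x, ...) {
  cat(sprintf("sleep_record: %d min scored, %d sleep min in %d episodes\n",
              length(x$sleep), sum(x$sleep, na.rm = TRUE),
              nrow(x$episodes)))
  if (any(x$missing)) cat(sprintf("  %d missing minutes\n", sum(x$missing)))
  invisible(x)
}
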