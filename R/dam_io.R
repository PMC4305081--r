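# Trikinetics DAM monitor file input.
#
# A DAM monitor file is tab-delimited text, one row per minute, with a block
# of metadata fields (record index, date, time, status code, ...) followed by
# exactly 32 integer beam-crossing counts, one per channel. Monitor versions
# differ in how many metadata fields precede the counts, so the layout is an
# explicit dialect option rather than sniffed.

#' DAM file dialect options
#'
#' @param n_metadata Number of tab-separated metadata fields before the 32
#'   count fields (default 10, the common DAMSystem3 layout: index, date,
#'   time, status, and six extra fields).
#' @param status_valid Integer status code marking a valid reading
#'   (default 1).
#' @param on_invalid_status What to do with rows whose status code is not
#'   `status_valid`: `"drop"` (default), which masks the minute as missing
#'   (removing the row outright would fabricate a timeline gap), or
#'   `"error"`.
#' @param on_gap What to do when consecutive timestamps are not exactly one
#'   minute apart: `"error"` (default) or `"mask"`, which inserts the missing
#'   minutes with `NA` counts and marks them in the missing mask. Silent
#'   zero-filling is never done, since a fabricated zero minute would be
#'   scored as sleep.
#' @return A list of class `"dam_dialect"`.
#' @export
dam_dialect <- function(n_metadata = 10L,
                        status_valid = 1L,
                        on_invalid_status = c("drop", "error"),
                        on_gap = c("error", "mask")) {
  stopifnot(n_metadata >= 4L)
  structure(list(n_metadata = as.integer(n_metadata),
                 status_valid = as.integer(status_valid),
                 on_invalid_status = match.arg(on_invalid_status),
                 on_gap = match.arg(on_gap)),
            class = "dam_dialect")
}

#' Parse a DAM monitor file
#'
#' Reads a Trikinetics DAM System monitor file (tab-delimited, 1-min bins,
#' 32 channels) into a count matrix plus minute-resolution timestamps.
#'
#' @param input Path to a monitor file, or its contents as a character vector
#'   of lines (a single string containing newlines is also accepted).
#' @param dialect A [dam_dialect()].
#' @return A list of class `"dam_data"` with elements:
#'   * `counts` — integer matrix, one row per retained minute, 32 columns;
#'   * `timestamps` — `POSIXct` (UTC) vector of the same length;
#'   * `status` — integer status codes of retained rows;
#'   * `missing` — logical vector, `TRUE` for minutes masked because of an
#'     invalid status code or inserted by gap masking (counts are `NA`);
#'   * `n_dropped` — number of readings masked for invalid status.
#' @export
parse_dam_file <- function(input, dialect = dam_dialect()) {
  stopifnot(inherits(dialect, "dam_dialect"))
  if (length(input) == 1L && !grepl("[\n\t]", input) && file.exists(input)) {
    lines <- readLines(input)
  } else {
    lines <- unlist(strsplit(input, "\n", fixed = TRUE), use.names = FALSE)
  }
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(structure(list(counts = matrix(integer(0), 0, 32),
                          timestamps = as.POSIXct(character(0), tz = "UTC"),
                          status = integer(0),
                          missing = logical(0),
                          n_dropped = 0L),
                     class = "dam_data"))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  want <- dialect$n_metadata + 32L
  nf <- lengths(fields)
  bad <- which(nf != want)
  if (length(bad) > 0L)
    stop(sprintf("parse error at line %d: expected %d tab-separated fields, found %d",
                 bad[1], want, nf[bad[1]]))
  meta <- t(vapply(fields, function(f) f[1:4], character(4)))
  count_chr <- t(vapply(fields, function(f) f[(dialect$n_metadata + 1L):want],
                        character(32)))
  counts <- suppressWarnings(matrix(as.integer(count_chr), ncol = 32))
  if (anyNA(counts)) {
    bad_row <- which(apply(is.na(counts), 1, any))[1]
    stop(sprintf("parse error at line %d: non-integer count field", bad_row))
  }
  if (any(counts < 0))
    stop("parse error: negative activity count")
  status <- suppressWarnings(as.integer(meta[, 4]))
  if (anyNA(status)) stop("parse error: non-integer status code")
  ts <- parse_dam_timestamp(meta[, 2], meta[, 3])

  bad_status <- status != dialect$status_valid
  if (any(bad_status) && dialect$on_invalid_status == "error")
    stop(sprintf("invalid status code %d at line %d",
                 status[which(bad_status)[1]], which(bad_status)[1]))
  n_dropped <- sum(bad_status)
  # dropped readings become masked minutes: removing the row outright would
  # fabricate a timeline gap
  counts[bad_status, ] <- NA_integer_
  missing <- bad_status
  if (length(ts) > 1L) {
    dmin <- as.numeric(diff(ts), units = "mins")
    if (any(dmin <= 0))
      stop(sprintf("timeline error: non-monotone timestamps at line %d",
                   which(dmin <= 0)[1] + 1L))
    if (any(dmin != 1)) {
      if (dialect$on_gap == "error")
        stop(sprintf("timeline error: %g-minute gap after line %d (use on_gap = \"mask\" to tolerate gaps)",
                     dmin[which(dmin != 1)[1]], which(dmin != 1)[1]))
      full <- seq(ts[1], ts[length(ts)], by = "1 min")
      idx <- match(as.numeric(ts), as.numeric(full))
      filled <- matrix(NA_integer_, nrow = length(full), ncol = 32)
      filled[idx, ] <- counts
      st <- rep(NA_integer_, length(full)); st[idx] <- status
      miss_full <- rep(TRUE, length(full))
      miss_full[idx] <- missing
      missing <- miss_full
      counts <- filled; ts <- full; status <- st
    }
  }
  structure(list(counts = counts, timestamps = ts, status = status,
                 missing = missing, n_dropped = n_dropped),
            class = "dam_data")
}

# DAM timestamps are "d mmm yy" + "HH:MM:SS". Month names are matched against
# the English abbreviations directly so parsing does not depend on the locale.
parse_dam_timestamp <- function(date_chr, time_chr) {
  parts <- strsplit(trimws(date_chr), " +")
  ok <- lengths(parts) == 3L
  if (!all(ok)) stop(sprintf("parse error at line %d: bad date field",
                             which(!ok)[1]))
  day <- as.integer(vapply(parts, `[`, "", 1L))
  mon <- match(tolower(vapply(parts, `[`, "", 2L)), tolower(month.abb))
  yr <- as.integer(vapply(parts, `[`, "", 3L))
  if (anyNA(day) || anyNA(mon) || anyNA(yr))
    stop("parse error: unparseable date field")
  yr <- ifelse(yr < 100L, yr + 2000L, yr)
  tparts <- strsplit(time_chr, ":", fixed = TRUE)
  ok <- lengths(tparts) == 3L
  if (!all(ok)) stop("parse error: bad time field")
  hh <- as.integer(vapply(tparts, `[`, "", 1L))
  mm <- as.integer(vapply(tparts, `[`, "", 2L))
  ss <- as.integer(vapply(tparts, `[`, "", 3L))
  if (anyNA(hh) || anyNA(mm) || anyNA(ss))
    stop("parse error: unparseable time field")
  ISOdatetime(yr, mon, day, hh, mm, ss, tz = "UTC")
}

#' Format a count matrix as DAM monitor file lines
#'
#' Inverse of [parse_dam_file()] under the default dialect; used by the
#' synthetic generator so that emitted files round-trip bit-exactly.
#'
#' @param counts Integer matrix with 32 columns (one row per minute).
#' @param start Start timestamp (`POSIXct`, minute resolution).
#' @param status Integer status code written on every row (default 1).
#' @return Character vector of tab-delimited lines.
#' @export
format_dam_lines <- function(counts, start = as.POSIXct("2024-01-01 08:00:00",
                                                        tz = "UTC"),
                             status = 1L) {
  stopifnot(is.matrix(counts), ncol(counts) == 32)
  n <- nrow(counts)
  ts <- start + 60 * (seq_len(n) - 1)
  lt <- as.POSIXlt(ts)
  date_chr <- sprintf("%d %s %02d", lt$mday, month.abb[lt$mon + 1L],
                      lt$year %% 100L)
  time_chr <- sprintf("%02d:%02d:%02d", lt$hour, lt$min, lt$sec)
  meta <- paste(seq_len(n), date_chr, time_chr, status,
                1, 0, 0, 0, 0, 0, sep = "\t")
  paste0(meta, "\t", apply(counts, 1, paste, collapse = "\t"))
}
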