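#' Clock-time helpers
#'
#' Clock times are parsed as minutes since midnight; durations are carried
#' as minutes from bedtime so that arithmetic crossing midnight never
#' touches clock representations downstream.
#'
#' @param x Clock time string `"HH:MM"`.
#' @return Minutes since midnight.
#' @keywords internal
parse_clock <- function(x) {
  if (is.null(x) || is.na(x)) return(NA_real_)
  parts <- strsplit(as.character(x), ":", fixed = TRUE)[[1]]
  if (length(parts) != 2) stop("malformed clock time: ", x)
  h <- as.numeric(parts[1]); m <- as.numeric(parts[2])
  if (is.na(h) || is.na(m) || h < 0 || h > 23 || m < 0 || m >= 60)
    stop("malformed clock time: ", x)
  h * 60 + m
}

#' @rdname parse_clock
#' @param minutes Minutes since midnight (wrapped modulo 24 h).
#' @keywords internal
format_clock <- function(minutes) {
  m <- ((minutes %% 1440) + 1440) %% 1440
  sprintf("%02d:%02d", floor(m / 60), round(m %% 60))
}

#' Minutes elapsed from one clock time to the next occurrence of another
#' @keywords internal
clock_diff_min <- function(from_min, to_min) {
  d <- to_min - from_min
  if (is.na(d)) return(NA_real_)
  if (d < 0) d <- d + 1440
  d
}

#' Parse a subjective sleep-diary record
#'
#' Validates one subject-night of diary data. Required keys: `bt` (bedtime
#' clock, `"HH:MM"`), `sl_subj_min`, `tst_subj_min`. Optional:
#' `waso_subj_min`, `nawk_subj`, `final_wake`, `out_of_bed`,
#' `completed_within_min`, `subject_id`. The subjective sleep-onset clock
#' time is derived as bedtime + subjective sleep latency (crossing midnight
#' as needed).
#'
#' @param record Named list or one-row data frame.
#' @return An object of class `sleep_diary`.
#' @export
parse_diary <- function(record) {
  record <- as.list(record)
  for (key in c("bt", "sl_subj_min", "tst_subj_min")) {
    if (is.null(record[[key]]) || is.na(record[[key]]))
      stop("diary record is missing required field '", key, "'")
  }
  num_fields <- c("sl_subj_min", "tst_subj_min", "waso_subj_min", "nawk_subj")
  for (key in num_fields) {
    v <- record[[key]]
    if (!is.null(v) && !is.na(v) && as.numeric(v) < 0)
      stop("diary field '", key, "' must be non-negative (got ", v, ")")
  }
  nawk <- record$nawk_subj
  if (!is.null(nawk) && !is.na(nawk) && as.numeric(nawk) %% 1 != 0)
    stop("diary field 'nawk_subj' must be an integer count")
  bt_min <- parse_clock(record$bt)
  d <- structure(list(
    subject_id = if (is.null(record$subject_id)) NA_character_ else as.character(record$subject_id),
    bt_clock = as.character(record$bt),
    sl_subj_min = as.numeric(record$sl_subj_min),
    tst_subj_min = as.numeric(record$tst_subj_min),
    waso_subj_min = if (is.null(record$waso_subj_min)) NA_real_ else as.numeric(record$waso_subj_min),
    nawk_subj = if (is.null(nawk) || is.na(nawk)) NA_integer_ else as.integer(nawk),
    final_wake_clock = if (is.null(record$final_wake)) NA_character_ else as.character(record$final_wake),
    out_of_bed_clock = if (is.null(record$out_of_bed)) NA_character_ else as.character(record$out_of_bed),
    completed_within_min = if (is.null(record$completed_within_min)) NA_real_ else as.numeric(record$completed_within_min)
  ), class = "sleep_diary")
  d$so_subj_clock <- format_clock(bt_min + d$sl_subj_min)
  if (!is.na(d$out_of_bed_clock)) {
    tib <- clock_diff_min(bt_min, parse_clock(d$out_of_bed_clock))
    if (!is.na(tib) && d$tst_subj_min >= tib)
      warning("subjective TST (", d$tst_subj_min,
              " min) meets or exceeds time in bed (", tib, " min)")
  }
  d
}

#' @export
print.sleep_diary <- function(x, ...) {
  cat(sprintf("<sleep_diary> %s BT %s, SL %g min (SO %s), TST %g min, WASO %s, nAWK %s\n",
              ifelse(is.na(x$subject_id), "", x$subject_id),
              x$bt_clock, x$sl_subj_min, x$so_subj_clock, x$tst_subj_min,
              ifelse(is.na(x$waso_subj_min), "-", x$waso_subj_min),
              ifelse(is.na(x$nawk_subj), "-", x$nawk_subj)))
  invisible(x)
}

#' Read sleep diaries from JSON or CSV
#'
#' JSON holds an array of one object per subject-night; CSV the same
#' columns (`subject_id, bt, sl_subj_min, tst_subj_min, waso_subj_min,
#' nawk_subj, final_wake, out_of_bed, completed_within_min`).
#'
#' @param path File path (`.json` or `.csv`).
#' @return List of [parse_diary()] objects.
#' @export
read_diaries <- function(path) {
  df <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  lapply(seq_len(nrow(df)), function(i) parse_diary(df[i, , drop = FALSE]))
}

#' @rdname read_diaries
#' @param diaries List of `sleep_diary` objects.
#' @export
write_diaries <- function(diaries, path) {
  df <- do.call(rbind, lapply(diaries, function(d) {
    data.frame(subject_id = d$subject_id, bt = d$bt_clock,
               sl_subj_min = d$sl_subj_min, tst_subj_min = d$tst_subj_min,
               waso_subj_min = d$waso_subj_min, nawk_subj = d$nawk_subj,
               final_wake = d$final_wake_clock,
               out_of_bed = d$out_of_bed_clock,
               completed_within_min = d$completed_within_min,
               stringsAsFactors = FALSE)
  }))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(df, path, auto_unbox = FALSE, digits = NA, na = "null")
  } else {
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}
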