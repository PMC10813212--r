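#' Sleep stage labels
#'
#' The closed set of 30-s epoch stage labels used throughout the package:
#' wake plus the four AASM sleep stages.
#'
#' @format Character vector of length 5: `W`, `N1`, `N2`, `N3`, `REM`.
#' @export
SLEEP_STAGES <- c("W", "N1", "N2", "N3", "REM")

#' Construct a hypnogram
#'
#' A hypnogram is an ordered sequence of fixed-length epoch stage labels
#' anchored at a named time origin (bedtime by default). Epoch `i`
#' (0-based) covers `[i * epoch_len_s, (i + 1) * epoch_len_s)` seconds from
#' the anchor; all latencies are therefore reported at epoch-start
#' resolution (0.5 min for 30-s epochs).
#'
#' @param stages Character vector of stage labels from [SLEEP_STAGES].
#'   `NA` marks an unscored epoch.
#' @param epoch_len_s Seconds per epoch (default 30).
#' @param anchor Name of the time origin, `"BEDTIME"` or `"LIGHTS_OFF"`.
#' @param anchor_clock Optional clock time of the anchor, `"HH:MM"`.
#' @return An object of class `hypnogram`.
#' @export
hypnogram <- function(stages, epoch_len_s = 30, anchor = "BEDTIME",
                      anchor_clock = NULL) {
  stages <- as.character(stages)
  if (length(stages) == 0L) stop("hypnogram must contain at least one epoch")
  if (!is.numeric(epoch_len_s) || epoch_len_s <= 0)
    stop("epoch_len_s must be > 0")
  bad <- !is.na(stages) & !(stages %in% SLEEP_STAGES)
  if (any(bad))
    stop("unknown stage token(s): ", paste(unique(stages[bad]), collapse = ", "),
         " at epoch(s) ", paste(which(bad)[seq_len(min(5, sum(bad)))] - 1L, collapse = ", "))
  anchor <- match.arg(anchor, c("BEDTIME", "LIGHTS_OFF"))
  structure(list(stages = stages, epoch_len_s = epoch_len_s,
                 anchor = anchor, anchor_clock = anchor_clock),
            class = "hypnogram")
}

#' @export
length.hypnogram <- function(x) length(x$stages)

#' @export
print.hypnogram <- function(x, ...) {
  cat(sprintf("<hypnogram> %d epochs x %gs, anchor %s%s\n",
              length(x$stages), x$epoch_len_s, x$anchor,
              if (is.null(x$anchor_clock)) "" else paste0(" @ ", x$anchor_clock)))
  tab <- table(factor(x$stages, levels = SLEEP_STAGES), useNA = "ifany")
  print(tab)
  invisible(x)
}

#' Duration of a hypnogram in minutes
#' @param hyp A [hypnogram()].
#' @return Total recording time in minutes.
#' @export
hyp_duration_min <- function(hyp) length(hyp$stages) * hyp$epoch_len_s / 60

#' Parse a hypnogram from tabular records
#'
#' @param rows Data frame with columns `epoch_index` (contiguous integers
#'   from 0) and `stage`.
#' @param epoch_len_s Seconds per epoch.
#' @param anchor,anchor_clock Time origin, see [hypnogram()].
#' @param unscored Optional token mapped to a missing epoch (never to a
#'   stage).
#' @return A [hypnogram()].
#' @export
parse_hypnogram <- function(rows, epoch_len_s = 30, anchor = "BEDTIME",
                            anchor_clock = NULL, unscored = NULL) {
  if (!all(c("epoch_index", "stage") %in% names(rows)))
    stop("rows must have columns 'epoch_index' and 'stage'")
  idx <- as.integer(rows$epoch_index)
  if (anyDuplicated(idx))
    stop("duplicate epoch_index: ", idx[anyDuplicated(idx)])
  o <- order(idx)
  idx <- idx[o]
  if (!identical(idx, seq_along(idx) - 1L))
    stop("epoch_index must be contiguous from 0 (gap or offset found)")
  stages <- as.character(rows$stage)[o]
  if (!is.null(unscored)) stages[stages == unscored] <- NA_character_
  hypnogram(stages, epoch_len_s = epoch_len_s, anchor = anchor,
            anchor_clock = anchor_clock)
}

#' Read / write hypnogram CSV
#'
#' CSV with header `epoch_index,stage` and optional leading `#` comment
#' lines carrying `epoch_len_s` and the anchor. The writer emits files that
#' round-trip bit-exactly through the reader.
#'
#' @param path File path.
#' @param ... Passed to [parse_hypnogram()].
#' @return `read_hypnogram()` a [hypnogram()]; `write_hypnogram()` `path`,
#'   invisibly.
#' @export
read_hypnogram <- function(path, ...) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  epoch_len_s <- 30
  anchor <- "BEDTIME"
  anchor_clock <- NULL
  for (m in meta) {
    if (grepl("epoch_len_s:", m))
      epoch_len_s <- as.numeric(sub(".*epoch_len_s:\\s*", "", m))
    if (grepl("anchor:", m)) {
      parts <- strsplit(trimws(sub(".*anchor:\\s*", "", m)), "\\s+")[[1]]
      anchor <- parts[1]
      if (length(parts) > 1) anchor_clock <- parts[2]
    }
  }
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        stringsAsFactors = FALSE)
  parse_hypnogram(df, epoch_len_s = epoch_len_s, anchor = anchor,
                  anchor_clock = anchor_clock, ...)
}

#' @rdname read_hypnogram
#' @param hyp A [hypnogram()].
#' @export
write_hypnogram <- function(hyp, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# epoch_len_s: %g", hyp$epoch_len_s), con)
  writeLines(paste0("# anchor: ", hyp$anchor,
                    if (is.null(hyp$anchor_clock)) "" else paste0(" ", hyp$anchor_clock)),
             con)
  writeLines("epoch_index,stage", con)
  writeLines(sprintf("%d,%s", seq_along(hyp$stages) - 1L, hyp$stages), con)
  invisible(path)
}

#' Objective sleep parameters from a hypnogram
#'
#' Computes the polysomnographic summary measures: objective sleep latency
#' (minutes from the anchor to the first non-wake epoch), total sleep time,
#' wake after sleep onset, number of awakenings, and stage percentages of
#' total sleep time.
#'
#' @param hyp A [hypnogram()] anchored at bedtime.
#' @param waso_span WASO convention: `"last-sleep"` counts wake epochs
#'   between the first and last sleep epoch (default); `"end"` extends the
#'   span to the end of the recording.
#' @return A list of class `objective_sleep_params` with elements
#'   `sl_obj_min`, `tst_obj_min`, `waso_obj_min`, `nawk_obj`, `stage_pct`
#'   (fractions of TST over `N1`,`N2`,`N3`,`REM`).
#' @export
objective_sleep_params <- function(hyp, waso_span = c("last-sleep", "end")) {
  waso_span <- match.arg(waso_span)
  s <- hyp$stages
  epoch_min <- hyp$epoch_len_s / 60
  asleep <- !is.na(s) & s != "W"
  out <- list(sl_obj_min = NA_real_, tst_obj_min = 0, waso_obj_min = 0,
              nawk_obj = 0L,
              stage_pct = stats::setNames(rep(NA_real_, 4), SLEEP_STAGES[-1]))
  if (!any(asleep)) {
    warning("hypnogram contains no sleep epochs; SL undefined, TST = 0")
    class(out) <- "objective_sleep_params"
    return(out)
  }
  first_sleep <- which(asleep)[1]
  last_sleep <- max(which(asleep))
  out$sl_obj_min <- (first_sleep - 1L) * epoch_min
  out$tst_obj_min <- sum(asleep) * epoch_min
  span_end <- if (waso_span == "end") length(s) else last_sleep
  span <- seq.int(first_sleep, span_end)
  wake_in_span <- !is.na(s[span]) & s[span] == "W"
  out$waso_obj_min <- sum(wake_in_span) * epoch_min
  r <- rle(wake_in_span)
  out$nawk_obj <- sum(r$values)
  tab <- table(factor(s[asleep], levels = SLEEP_STAGES[-1]))
  out$stage_pct <- as.numeric(tab) / sum(tab)
  names(out$stage_pct) <- SLEEP_STAGES[-1]
  class(out) <- "objective_sleep_params"
  out
}

#' Latency from the anchor to the first epoch of a target stage
#'
#' @param hyp A [hypnogram()] anchored at bedtime.
#' @param target A stage label from [SLEEP_STAGES], or `"sleep"` for the
#'   first non-wake epoch.
#' @return Minutes from the anchor to the start of the first matching
#'   epoch, or `NA` if the stage is never reached.
#' @export
stage_latency <- function(hyp, target) {
  epoch_min <- hyp$epoch_len_s / 60
  hit <- if (identical(target, "sleep")) {
    !is.na(hyp$stages) & hyp$stages != "W"
  } else {
    if (!target %in% SLEEP_STAGES) stop("unknown target stage: ", target)
    !is.na(hyp$stages) & hyp$stages == target
  }
  if (!any(hit)) return(NA_real_)
  (which(hit)[1] - 1L) * epoch_min
}

#' Restrict a hypnogram to a half-open time window
#'
#' An epoch is retained iff its start time lies in `[start_min, end_min)`
#' measured from the anchor. Windows extending beyond the recording are
#' truncated with a warning.
#'
#' @param hyp A [hypnogram()].
#' @param start_min,end_min Window bounds in minutes, `0 <= start < end`.
#' @return A [hypnogram()] covering the windowed epochs. The anchor is kept;
#'   the offset of the first retained epoch is stored as attribute
#'   `offset_min`.
#' @export
restrict_window <- function(hyp, start_min, end_min) {
  if (!(start_min >= 0 && start_min < end_min))
    stop("window must satisfy 0 <= start_min < end_min")
  epoch_min <- hyp$epoch_len_s / 60
  starts <- (seq_along(hyp$stages) - 1L) * epoch_min
  if (end_min > hyp_duration_min(hyp) + 1e-12) {
    warning("window extends beyond recording end; truncated")
  }
  keep <- starts >= start_min & starts < end_min
  if (!any(keep)) stop("window contains no epochs")
  out <- hypnogram(hyp$stages[keep], epoch_len_s = hyp$epoch_len_s,
                   anchor = hyp$anchor, anchor_clock = hyp$anchor_clock)
  attr(out, "offset_min") <- starts[which(keep)[1]]
  out
}
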