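#' Multichannel physiological signal record
#'
#' In-memory container for sampled EEG/EMG signals with channel roles. All
#' channels share one sampling rate and length; `t0_s` places the first
#' sample on the same time axis as the paired hypnogram (seconds from the
#' bedtime anchor), so a record may cover only the window it is scored in
#' (e.g. the sleep-onset period or one REM bout).
#'
#' @param channels Named list of numeric vectors (microvolts), equal length.
#' @param fs_hz Sampling rate in Hz, >= 100 so that alpha and >16 Hz
#'   content is resolvable.
#' @param roles Named list mapping roles (`occipital`, `frontal`, `emg`)
#'   to channel-name vectors.
#' @param t0_s Time of the first sample, seconds from the anchor.
#' @return Object of class `signal_record`.
#' @export
signal_record <- function(channels, fs_hz, roles = list(), t0_s = 0) {
  if (!is.list(channels) || is.null(names(channels)) || any(names(channels) == ""))
    stop("channels must be a named list of numeric vectors")
  lens <- vapply(channels, length, integer(1))
  if (length(unique(lens)) != 1) stop("all channels must have equal length")
  if (!is.numeric(fs_hz) || fs_hz < 100)
    stop("fs_hz must be >= 100 Hz")
  unknown <- setdiff(unlist(roles), names(channels))
  if (length(unknown))
    stop("role refers to unknown channel(s): ", paste(unknown, collapse = ", "))
  structure(list(channels = channels, fs_hz = fs_hz, roles = roles,
                 t0_s = t0_s, n = lens[[1]]),
            class = "signal_record")
}

#' @export
print.signal_record <- function(x, ...) {
  cat(sprintf("<signal_record> %d ch x %d samples @ %g Hz, t0 = %gs (%.1f min span)\n",
              length(x$channels), x$n, x$fs_hz, x$t0_s, x$n / x$fs_hz / 60))
  for (r in names(x$roles))
    cat(sprintf("  %-10s %s\n", r, paste(x$roles[[r]], collapse = ", ")))
  invisible(x)
}

#' Channels registered under a role
#' @param sig A [signal_record()].
#' @param role Role name (`occipital`, `frontal`, `emg`).
#' @return Named list of channel vectors.
#' @keywords internal
role_channels <- function(sig, role) {
  ch <- sig$roles[[role]]
  if (is.null(ch) || !length(ch))
    stop("signal record has no channel with role '", role, "'")
  sig$channels[ch]
}

#' Write / read a signal record as plain CSV
#'
#' Wide CSV, one column per channel, with `#` header lines carrying the
#' sampling rate, `t0_s` and the role map. Intended for small excerpts and
#' test fixtures; whole-night recordings are kept in memory.
#'
#' @param sig A [signal_record()].
#' @param path File path.
#' @export
write_signal_csv <- function(sig, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs_hz: %g", sig$fs_hz), con)
  writeLines(sprintf("# t0_s: %g", sig$t0_s), con)
  for (r in names(sig$roles))
    writeLines(sprintf("# role %s: %s", r, paste(sig$roles[[r]], collapse = " ")), con)
  utils::write.table(as.data.frame(sig$channels, check.names = FALSE), con,
                     sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_signal_csv
#' @export
read_signal_csv <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  fs <- as.numeric(sub(".*fs_hz:\\s*", "", grep("fs_hz:", meta, value = TRUE)[1]))
  t0 <- as.numeric(sub(".*t0_s:\\s*", "", grep("t0_s:", meta, value = TRUE)[1]))
  roles <- list()
  for (m in grep("^# role ", meta, value = TRUE)) {
    body <- sub("^# role ", "", m)
    nm <- sub(":.*", "", body)
    roles[[nm]] <- strsplit(trimws(sub(".*:", "", body)), "\\s+")[[1]]
  }
  df <- utils::read.csv(text = paste(lines[!grepl("^#", lines)], collapse = "\n"),
                        check.names = FALSE)
  signal_record(as.list(df), fs_hz = fs, roles = roles, t0_s = t0)
}

#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth applied forwards and backwards
#' (`signal::filtfilt`), so event timing is not skewed by filter delay.
#'
#' @param x Numeric vector.
#' @param fs_hz Sampling rate.
#' @param lo,hi Band edges in Hz; `hi` is clipped below Nyquist.
#' @param order Filter order per pass.
#' @return Filtered vector, same length.
#' @export
bandpass <- function(x, fs_hz, lo, hi, order = 4) {
  nyq <- fs_hz / 2
  hi <- min(hi, nyq * 0.98)
  if (lo <= 0) {
    bf <- signal::butter(order, hi / nyq, type = "low")
  } else {
    bf <- signal::butter(order, c(lo, hi) / nyq, type = "pass")
  }
  as.numeric(signal::filtfilt(bf, x))
}

#' Instantaneous amplitude envelope
#'
#' Magnitude of the analytic signal, computed by the FFT method (positive
#' frequencies doubled, negative zeroed). Input should already be
#' band-limited.
#'
#' @param x Numeric vector.
#' @return Non-negative envelope, same length.
#' @export
envelope <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

#' Centred moving average
#' @keywords internal
smooth_ma <- function(x, width) {
  if (width <= 1) return(x)
  k <- rep(1 / width, width)
  y <- as.numeric(stats::filter(x, k, sides = 2))
  # fill filter edges with nearest computed value
  idx <- which(!is.na(y))
  if (!length(idx)) return(x)
  y[seq_len(idx[1] - 1)] <- y[idx[1]]
  y[seq.int(idx[length(idx)] + 1, length.out = length(y) - idx[length(idx)])] <- y[idx[length(idx)]]
  y
}

#' Runs of TRUE in a logical vector
#' @return Data frame with columns `start`, `end` (sample indices).
#' @keywords internal
logical_runs <- function(x) {
  x[is.na(x)] <- FALSE
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}
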