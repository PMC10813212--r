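#' Alpha-density parameters
#'
#' Thresholding parameters for the micro-epoch alpha-density operator. A
#' micro-epoch is alpha-positive on a channel when at least `min_frac` of
#' its samples exceed `k` times a robust baseline amplitude of the
#' band-limited envelope.
#'
#' Baseline estimators:
#' \describe{
#'   \item{`twopass` (default)}{Initial threshold at `k` times a low
#'     quantile (`baseline_q`) of per-micro-epoch median envelopes; the
#'     baseline is then re-estimated as the median envelope over the
#'     micro-epochs negative at the first pass. Robust to alpha bursts
#'     covering most of the window, where a plain median tracks the bursts
#'     rather than the noise floor.}
#'   \item{`median`}{Median envelope over the whole window.}
#'   \item{`quantile`}{Quantile `baseline_q` of the envelope.}
#' }
#'
#' @param k Threshold multiplier over the baseline (default 2).
#' @param min_frac Fraction of supra-threshold samples required (default
#'   0.5, i.e. 1.5 s of a 3-s micro-epoch).
#' @param micro_epoch_s Micro-epoch length in seconds (default 3).
#' @param band Alpha band in Hz (default 8-13).
#' @param baseline Baseline estimator, see Details.
#' @param baseline_q Quantile for `twopass`/`quantile` estimators.
#' @param combine Combination across occipital channels: a micro-epoch is
#'   positive if flagged on any channel (`"or"`, mirroring visual scoring
#'   on either lead) or on all (`"and"`).
#' @return List of class `alpha_params`.
#' @export
alpha_params <- function(k = 2, min_frac = 0.5, micro_epoch_s = 3,
                         band = c(8, 13),
                         baseline = c("twopass", "median", "quantile"),
                         baseline_q = 0.05, combine = c("or", "and")) {
  structure(list(k = k, min_frac = min_frac, micro_epoch_s = micro_epoch_s,
                 band = band, baseline = match.arg(baseline),
                 baseline_q = baseline_q, combine = match.arg(combine)),
            class = "alpha_params")
}

alpha_labels_channel <- function(x, fs, p) {
  env <- envelope(bandpass(x, fs, p$band[1], p$band[2]))
  spm <- round(p$micro_epoch_s * fs)           # samples per micro-epoch
  n_micro <- floor(length(env) / spm)
  env <- env[seq_len(n_micro * spm)]
  epoch_of <- rep(seq_len(n_micro), each = spm)
  med_i <- tapply(env, epoch_of, stats::median)
  baseline <- switch(p$baseline,
    median = stats::median(env),
    quantile = stats::quantile(env, p$baseline_q, names = FALSE),
    twopass = {
      b1 <- stats::quantile(med_i, p$baseline_q, names = FALSE)
      frac1 <- tapply(env > p$k * b1, epoch_of, mean)
      neg <- frac1 < p$min_frac
      if (any(neg)) stats::median(env[neg[epoch_of]]) else b1
    })
  frac <- tapply(env > p$k * baseline, epoch_of, mean)
  as.logical(frac >= p$min_frac)
}

#' Micro-epoch alpha density
#'
#' Automated stand-in for visual alpha scoring: occipital channels are
#' band-limited to the alpha band, the instantaneous amplitude envelope is
#' thresholded at `k` times a robust baseline, and each 3-s micro-epoch is
#' labelled alpha-positive when at least half of its samples exceed the
#' threshold on any occipital channel. The alpha density is the proportion
#' of positive micro-epochs; computed over the objective sleep-latency
#' window it is the %alpha index.
#'
#' Because the threshold is relative, the labels are invariant to a common
#' rescaling of all channels.
#'
#' @param sig A [signal_record()] with an `occipital` role.
#' @param window_min Length-2 vector, window in minutes from the anchor;
#'   must lie within the record and contain at least one micro-epoch.
#' @param params An [alpha_params()].
#' @return List of class `alpha_density_result`: `alpha_prop` (proportion
#'   in \[0,1\]), `alpha_pct`, `micro_labels`, `n_micro`, `window`.
#' @export
alpha_density <- function(sig, window_min, params = alpha_params()) {
  occ <- role_channels(sig, "occipital")
  fs <- sig$fs_hz
  i0 <- round((window_min[1] * 60 - sig$t0_s) * fs) + 1L
  i1 <- round((window_min[2] * 60 - sig$t0_s) * fs)
  if (i0 < 1 || i1 > sig$n)
    stop("window [", window_min[1], ", ", window_min[2],
         ") min lies outside the signal record")
  if ((i1 - i0 + 1) < params$micro_epoch_s * fs)
    stop("window shorter than one micro-epoch")
  labels <- lapply(occ, function(ch) alpha_labels_channel(ch[i0:i1], fs, params))
  lab <- Reduce(if (params$combine == "or") `|` else `&`, labels)
  structure(list(alpha_prop = mean(lab), alpha_pct = 100 * mean(lab),
                 micro_labels = lab, n_micro = length(lab),
                 window = window_min),
            class = "alpha_density_result")
}

#' K-complex detector parameters
#'
#' @param amp_neg_uv Candidate gate: trough must fall below
#'   `-amp_neg_uv` (default 40 uV).
#' @param min_pp_uv Keep gate: peak-to-peak amplitude of the negative
#'   deflection and following positive component (default 75 uV; applied as
#'   `>=`, the canonical scoring direction).
#' @param dur_s Admissible event duration in seconds (default 0.5-3).
#' @param band Detection band in Hz (default 0.5-4, the K-complex's
#'   delta-range energy).
#' @return List of class `kc_params`.
#' @export
kc_params <- function(amp_neg_uv = 40, min_pp_uv = 75, dur_s = c(0.5, 3),
                      band = c(0.5, 4)) {
  structure(list(amp_neg_uv = amp_neg_uv, min_pp_uv = min_pp_uv,
                 dur_s = dur_s, band = band),
            class = "kc_params")
}

kc_events_channel <- function(x, fs, p, channel, t0_s) {
  xf <- bandpass(x, fs, p$band[1], p$band[2])
  deep <- xf < -p$amp_neg_uv
  runs <- logical_runs(deep)
  if (!nrow(runs)) return(NULL)
  out <- list()
  last_end <- 0L
  for (r in seq_len(nrow(runs))) {
    seg <- runs$start[r]:runs$end[r]
    tmin <- seg[which.min(xf[seg])]
    if (tmin <= last_end) next
    # event start: last non-negative sample before the trough
    pre <- which(xf[seq_len(tmin)] >= 0)
    i_start <- if (length(pre)) max(pre) else 1L
    # forward: first zero up-crossing, then the positive component until it
    # returns to baseline
    post <- seq.int(tmin, length(xf))
    up <- post[which(xf[post] >= 0)[1]]
    if (is.na(up)) next
    after_up <- seq.int(up, length(xf))
    down <- after_up[which(xf[after_up] < 0)[1]]
    i_end <- if (is.na(down)) length(xf) else down
    dur <- (i_end - i_start) / fs
    pp <- max(xf[up:i_end]) - xf[tmin]
    if (dur >= p$dur_s[1] && dur <= p$dur_s[2] && pp >= p$min_pp_uv) {
      out[[length(out) + 1L]] <- data.frame(
        t_start_s = t0_s + (i_start - 1) / fs,
        t_end_s = t0_s + (i_end - 1) / fs,
        peak_to_peak_uv = pp, channel = channel,
        stringsAsFactors = FALSE)
      last_end <- i_end
    }
  }
  if (length(out)) do.call(rbind, out) else NULL
}

#' Detect K-complexes on frontal derivations
#'
#' A candidate is a sharp negative deflection (trough below `-amp_neg_uv`
#' in the delta-band signal) immediately followed by a positive component;
#' event boundaries are the surrounding baseline crossings. Candidates are
#' kept when the total duration is 0.5-3 s and the peak-to-peak amplitude
#' reaches `min_pp_uv`. Events overlapping across F3/F4 are merged
#' (earliest start wins).
#'
#' @param sig A [signal_record()] with a `frontal` role.
#' @param params A [kc_params()].
#' @return Data frame of events (`t_start_s`, `t_end_s`,
#'   `peak_to_peak_uv`, `channel`), sorted by onset; zero rows if none.
#' @export
detect_kcomplexes <- function(sig, params = kc_params()) {
  fr <- role_channels(sig, "frontal")
  evs <- do.call(rbind, Filter(Negate(is.null), lapply(names(fr), function(nm) {
    kc_events_channel(fr[[nm]], sig$fs_hz, params, nm, sig$t0_s)
  })))
  empty <- data.frame(t_start_s = numeric(0), t_end_s = numeric(0),
                      peak_to_peak_uv = numeric(0), channel = character(0),
                      stringsAsFactors = FALSE)
  if (is.null(evs) || !nrow(evs)) return(empty)
  evs <- evs[order(evs$t_start_s), , drop = FALSE]
  keep <- rep(TRUE, nrow(evs))
  cur_end <- -Inf
  for (i in seq_len(nrow(evs))) {
    if (evs$t_start_s[i] <= cur_end) keep[i] <- FALSE
    else cur_end <- evs$t_end_s[i]
  }
  rownames(evs) <- NULL
  evs[keep, , drop = FALSE]
}

#' Latency to the first K-complex
#'
#' @param events Event data frame from [detect_kcomplexes()].
#' @return Onset of the earliest event in minutes from the anchor; `NA`
#'   when no event was detected.
#' @export
first_kc_latency <- function(events) {
  if (is.null(events) || !nrow(events)) return(NA_real_)
  min(events$t_start_s) / 60
}

#' REM arousal detector parameters
#'
#' @param power_factor EEG shift gate: smoothed shift-band envelope must
#'   exceed this multiple of its REM-window median (default 2).
#' @param emg_factor Chin-EMG gate: smoothed EMG envelope must exceed this
#'   multiple of its REM-window median (default 1.5).
#' @param min_shift_s Minimum duration of the EEG frequency shift (default
#'   3 s).
#' @param min_emg_s Minimum duration of the concurrent EMG elevation
#'   (default 1 s).
#' @param stable_s Required preceding stable sleep free of other arousals
#'   (default 10 s).
#' @param shift_bands List of frequency bands (Hz) whose envelopes are
#'   summed for the shift criterion. The default covers alpha/theta
#'   (4-11 Hz) and fast (>16 Hz) activity while excluding 11-16 Hz, so that
#'   sleep-spindle-range activity cannot satisfy the gate.
#' @param emg_band Chin-EMG band in Hz.
#' @param smooth_s Moving-average width for envelopes, seconds.
#' @return List of class `arousal_params`.
#' @export
arousal_params <- function(power_factor = 2, emg_factor = 1.5,
                           min_shift_s = 3, min_emg_s = 1, stable_s = 10,
                           shift_bands = list(c(4, 11), c(16, 45)),
                           emg_band = c(20, 45), smooth_s = 0.5) {
  structure(list(power_factor = power_factor, emg_factor = emg_factor,
                 min_shift_s = min_shift_s, min_emg_s = min_emg_s,
                 stable_s = stable_s, shift_bands = shift_bands,
                 emg_band = emg_band, smooth_s = smooth_s),
            class = "arousal_params")
}

#' Detect arousals within REM sleep
#'
#' Implements the scoring rule for REM arousals: an abrupt EEG frequency
#' shift toward alpha/theta or >16 Hz activity (sleep-spindle frequencies
#' excluded) lasting at least 3 s, accompanied by a chin-EMG amplitude
#' increase of at least 1 s, and preceded by at least 10 s of stable sleep
#' with no other detected arousal. Only epochs scored REM in the paired
#' hypnogram are searched, so every returned event lies inside a REM epoch.
#'
#' @param sig A [signal_record()] with `occipital` (or `frontal`) and
#'   `emg` roles, covering (part of) the REM sleep in `hyp`.
#' @param hyp The paired [hypnogram()] (same anchor).
#' @param params An [arousal_params()].
#' @return Data frame of events (`t_start_s`, `t_end_s`, `stage_context`,
#'   `emg_confirmed`), sorted by onset; zero rows if none. Returns an empty
#'   frame with a warning when the hypnogram contains no REM epoch.
#' @export
detect_rem_arousals <- function(sig, hyp, params = arousal_params()) {
  empty <- data.frame(t_start_s = numeric(0), t_end_s = numeric(0),
                      stage_context = character(0), emg_confirmed = logical(0),
                      stringsAsFactors = FALSE)
  if (!any(hyp$stages == "REM", na.rm = TRUE)) {
    warning("hypnogram contains no REM epoch; no arousals scored")
    return(empty)
  }
  eeg <- c(if (!is.null(sig$roles$occipital)) role_channels(sig, "occipital"),
           if (!is.null(sig$roles$frontal)) role_channels(sig, "frontal"))
  if (!length(eeg)) stop("signal record has no occipital or frontal channel")
  emg <- role_channels(sig, "emg")[[1]]
  fs <- sig$fs_hz
  w <- max(1L, round(params$smooth_s * fs))

  # per-sample stage context from the hypnogram
  t_s <- sig$t0_s + (seq_len(sig$n) - 1) / fs
  ep <- floor(t_s / hyp$epoch_len_s) + 1L
  ok <- ep >= 1L & ep <= length(hyp$stages)
  stage_s <- rep(NA_character_, sig$n)
  stage_s[ok] <- hyp$stages[ep[ok]]
  rem_mask <- !is.na(stage_s) & stage_s == "REM"
  if (!any(rem_mask)) return(empty)

  env_shift <- Reduce(`+`, lapply(eeg[1], function(ch) {
    Reduce(`+`, lapply(params$shift_bands, function(b)
      envelope(bandpass(ch, fs, b[1], b[2]))))
  }))
  env_shift <- smooth_ma(env_shift, w)
  base_shift <- stats::median(env_shift[rem_mask])
  shift_on <- env_shift > params$power_factor * base_shift & rem_mask

  env_emg <- smooth_ma(envelope(bandpass(emg, fs, params$emg_band[1], params$emg_band[2])), w)
  base_emg <- stats::median(env_emg[rem_mask])
  emg_on <- env_emg > params$emg_factor * base_emg

  runs <- logical_runs(shift_on)
  if (!nrow(runs)) return(empty)
  runs <- runs[(runs$end - runs$start + 1) / fs >= params$min_shift_s, , drop = FALSE]
  out <- list()
  accepted_ends <- numeric(0)
  for (i in seq_len(nrow(runs))) {
    a <- runs$start[i]; b <- runs$end[i]
    # EMG elevation of at least min_emg_s overlapping the shift run
    emg_runs <- logical_runs(emg_on[a:b])
    if (!nrow(emg_runs) ||
        max(emg_runs$end - emg_runs$start + 1) / fs < params$min_emg_s) next
    # preceding stable sleep: stable_s seconds of sleep epochs, no prior event
    pre0 <- a - round(params$stable_s * fs)
    if (pre0 < 1) next
    pre_stage <- stage_s[pre0:(a - 1L)]
    if (any(is.na(pre_stage)) || any(pre_stage == "W")) next
    t_pre0 <- t_s[pre0]
    if (length(accepted_ends) && any(accepted_ends > t_pre0)) next
    out[[length(out) + 1L]] <- data.frame(
      t_start_s = t_s[a], t_end_s = t_s[b], stage_context = "REM",
      emg_confirmed = TRUE, stringsAsFactors = FALSE)
    accepted_ends <- c(accepted_ends, t_s[b])
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res[order(res$t_start_s), , drop = FALSE]
}

#' REM arousal density (A-REMd)
#'
#' The proportion of REM epochs containing at least one arousal onset,
#' reported on the \[0,1\] scale (the only scale on which the regression
#' layer's coefficients are dimensionally coherent).
#'
#' @param events Event data frame(s) from [detect_rem_arousals()]; a list
#'   of frames (one per scored REM bout) is concatenated.
#' @param hyp The paired [hypnogram()].
#' @return Proportion in \[0,1\]; `NA` with a warning when the hypnogram
#'   has no REM epoch.
#' @export
rem_arousal_density <- function(events, hyp) {
  if (is.data.frame(events)) events <- list(events)
  ev <- do.call(rbind, events)
  rem_idx <- which(!is.na(hyp$stages) & hyp$stages == "REM")
  if (!length(rem_idx)) {
    warning("hypnogram contains no REM epoch; A-REMd undefined")
    return(NA_real_)
  }
  if (is.null(ev) || !nrow(ev)) return(0)
  onset_epoch <- floor(ev$t_start_s / hyp$epoch_len_s) + 1L
  length(intersect(unique(onset_epoch), rem_idx)) / length(rem_idx)
}
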