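#' Sample a hypnogram from a first-order Markov chain
#'
#' @param chain 5x5 row-stochastic matrix over [SLEEP_STAGES] (rows sum to
#'   1; dimnames optional, stage order assumed).
#' @param n_epochs Number of epochs to draw, >= 2.
#' @param start Starting stage label.
#' @param seed Optional integer seed (`set.seed` locally for the draw).
#' @param epoch_len_s Seconds per epoch.
#' @return A [hypnogram()].
#' @export
generate_hypnogram <- function(chain, n_epochs, start = "W", seed = NULL,
                               epoch_len_s = 30) {
  chain <- validate_chain(chain)
  if (n_epochs < 2) stop("n_epochs must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  hypnogram(sample_chain(chain, n_epochs, start), epoch_len_s = epoch_len_s)
}

validate_chain <- function(chain) {
  chain <- as.matrix(chain)
  if (!all(dim(chain) == c(5, 5)))
    stop("chain must be a 5x5 matrix over ", paste(SLEEP_STAGES, collapse = ","))
  if (any(chain < 0) || any(abs(rowSums(chain) - 1) > 1e-8))
    stop("chain rows must be non-negative and sum to 1 (non-stochastic row)")
  dimnames(chain) <- list(SLEEP_STAGES, SLEEP_STAGES)
  chain
}

sample_chain <- function(chain, n_epochs, start) {
  cur <- match(start, SLEEP_STAGES)
  if (is.na(cur)) stop("unknown start stage: ", start)
  out <- integer(n_epochs)
  out[1] <- cur
  for (i in 2:n_epochs) {
    cur <- sample.int(5L, 1L, prob = chain[cur, ])
    out[i] <- cur
  }
  SLEEP_STAGES[out]
}

#' Sleep-onset and whole-night generator chains
#'
#' `onset_chain()` builds the transition matrix governing the sleep-onset
#' window, parameterized by the N1->W return probability that
#' distinguishes low- from high-misperception sleepers (N1->N2 shrinks as
#' N1->W grows so the row stays stochastic). `night_chain()` is the fixed
#' whole-night chain used after the onset window.
#'
#' @param n1_to_w Probability of returning to wake from N1.
#' @return 5x5 row-stochastic matrix.
#' @export
onset_chain <- function(n1_to_w = 0.05) {
  if (n1_to_w < 0 || n1_to_w > 0.75) stop("n1_to_w must be in [0, 0.75]")
  n1_to_n2 <- 0.25 * (1 - n1_to_w)
  m <- rbind(
    W   = c(0.88, 0.12, 0, 0, 0),
    N1  = c(n1_to_w, 1 - n1_to_w - n1_to_n2, n1_to_n2, 0, 0),
    N2  = c(0.04, 0.06, 0.88, 0.02, 0),
    N3  = c(0, 0, 0.10, 0.90, 0),
    REM = c(0, 0, 0.10, 0, 0.90))
  colnames(m) <- SLEEP_STAGES
  m
}

#' @rdname onset_chain
#' @export
night_chain <- function() {
  m <- rbind(
    W   = c(0.60, 0.40, 0, 0, 0),
    N1  = c(0.05, 0.40, 0.50, 0, 0.05),
    N2  = c(0.02, 0.03, 0.86, 0.06, 0.03),
    N3  = c(0, 0, 0.12, 0.88, 0),
    REM = c(0.02, 0.02, 0.06, 0, 0.90))
  colnames(m) <- SLEEP_STAGES
  m
}

pink_noise <- function(n, sd_uv) {
  white <- stats::rnorm(n)
  X <- stats::fft(white)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)           # mirrored frequency index
  X <- X / sqrt(f)
  x <- Re(stats::fft(X, inverse = TRUE) / n)
  x * sd_uv / stats::sd(x)
}

kc_template <- function(fs, dur_s = 1.0, neg_uv = -70, pos_uv = 45) {
  n_neg <- round(0.4 * dur_s * fs)
  n_pos <- round(0.6 * dur_s * fs)
  c(neg_uv * sin(pi * seq_len(n_neg) / (n_neg + 1)),
    pos_uv * sin(pi * seq_len(n_pos) / (n_pos + 1)))
}

add_burst <- function(x, fs, start_s, end_s, freq_hz, amp_uv, t0_s = 0) {
  i0 <- max(1L, round((start_s - t0_s) * fs) + 1L)
  i1 <- min(length(x), round((end_s - t0_s) * fs))
  if (i1 <= i0) return(x)
  idx <- i0:i1
  tt <- (idx - 1) / fs
  ramp <- pmin(1, pmin(idx - i0, i1 - idx) / (0.05 * fs))
  x[idx] <- x[idx] + amp_uv * ramp * sin(2 * pi * freq_hz * tt)
  x
}

#' Synthesize a multichannel EEG/EMG record with known events
#'
#' Occipital channels are 1/f (pink) noise with 10 Hz alpha bursts added
#' over the scheduled intervals, at an amplitude a fixed multiple
#' (`alpha_snr`) of the channel's own alpha-band envelope median, so the
#' envelope SNR of each burst is known. Frontal channels carry biphasic
#' K-complex templates at the scheduled times; the chin-EMG channel is
#' low-amplitude noise with amplitude bursts over the scheduled arousal
#' intervals; arousals also add a 10 Hz shift burst to the occipital
#' leads.
#'
#' @param duration_s Record length in seconds.
#' @param fs_hz Sampling rate (>= 100).
#' @param alpha_schedule Data frame `start,end` (seconds) of alpha bursts,
#'   or `NULL`.
#' @param kc_times Numeric vector of K-complex onset times (seconds), or
#'   `NULL`.
#' @param arousal_schedule Data frame `start,end,emg_start,emg_end`
#'   (seconds) of REM-arousal shift and EMG bursts, or `NULL`.
#' @param seed Optional integer seed.
#' @param t0_s Time of the first sample on the anchor axis.
#' @param alpha_snr Envelope SNR of alpha bursts (default 4).
#' @param occ_noise_uv,frontal_noise_uv,emg_noise_uv Background noise SD.
#' @param shift_amp_uv Amplitude of the arousal EEG shift burst.
#' @param emg_burst_uv SD of the extra EMG noise during arousal bursts.
#' @param kc_amp_uv Length-2: negative trough and positive peak of the
#'   K-complex template (microvolts).
#' @param kc_dur_s K-complex template duration.
#' @param channels Which channel groups to render: any of `"occipital"`,
#'   `"frontal"`, `"emg"`.
#' @return A [signal_record()]; the realized schedules are attached as
#'   attribute `ground_truth`.
#' @export
generate_eeg <- function(duration_s, fs_hz = 128, alpha_schedule = NULL,
                         kc_times = NULL, arousal_schedule = NULL,
                         seed = NULL, t0_s = 0, alpha_snr = 4,
                         occ_noise_uv = 10, frontal_noise_uv = 8,
                         emg_noise_uv = 2, shift_amp_uv = 45,
                         emg_burst_uv = 8, kc_amp_uv = c(-70, 45),
                         kc_dur_s = 1.0,
                         channels = c("occipital", "frontal", "emg")) {
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration_s * fs_hz)
  chans <- list()
  roles <- list()
  if ("occipital" %in% channels) {
    for (nm in c("O1", "O2")) {
      x <- pink_noise(n, occ_noise_uv)
      amp <- alpha_snr * stats::median(envelope(bandpass(x, fs_hz, 8, 13)))
      if (!is.null(alpha_schedule) && nrow(alpha_schedule)) {
        for (i in seq_len(nrow(alpha_schedule)))
          x <- add_burst(x, fs_hz, alpha_schedule$start[i] - t0_s,
                         alpha_schedule$end[i] - t0_s, 10, amp)
      }
      if (!is.null(arousal_schedule) && nrow(arousal_schedule)) {
        for (i in seq_len(nrow(arousal_schedule)))
          x <- add_burst(x, fs_hz, arousal_schedule$start[i] - t0_s,
                         arousal_schedule$end[i] - t0_s, 10, shift_amp_uv)
      }
      chans[[nm]] <- x
    }
    roles$occipital <- c("O1", "O2")
  }
  if ("frontal" %in% channels) {
    tmpl <- kc_template(fs_hz, kc_dur_s, kc_amp_uv[1], kc_amp_uv[2])
    for (nm in c("F3", "F4")) {
      x <- pink_noise(n, frontal_noise_uv)
      for (tk in kc_times) {
        i0 <- round((tk - t0_s) * fs_hz) + 1L
        idx <- i0:(i0 + length(tmpl) - 1L)
        inb <- idx >= 1 & idx <= n
        if (!all(inb))
          warning("K-complex template at ", tk, " s clipped by record bounds")
        x[idx[inb]] <- x[idx[inb]] + tmpl[inb]
      }
      chans[[nm]] <- x
    }
    roles$frontal <- c("F3", "F4")
  }
  if ("emg" %in% channels) {
    x <- stats::rnorm(n, sd = emg_noise_uv)
    if (!is.null(arousal_schedule) && nrow(arousal_schedule)) {
      for (i in seq_len(nrow(arousal_schedule))) {
        i0 <- max(1L, round((arousal_schedule$emg_start[i] - t0_s) * fs_hz) + 1L)
        i1 <- min(n, round((arousal_schedule$emg_end[i] - t0_s) * fs_hz))
        if (i1 > i0) x[i0:i1] <- x[i0:i1] + stats::rnorm(i1 - i0 + 1, sd = emg_burst_uv)
      }
    }
    chans[["EMG"]] <- x
    roles$emg <- "EMG"
  }
  sig <- signal_record(chans, fs_hz = fs_hz, roles = roles, t0_s = t0_s)
  attr(sig, "ground_truth") <- list(alpha_schedule = alpha_schedule,
                                    kc_times = kc_times,
                                    arousal_schedule = arousal_schedule)
  sig
}

#' Misperception model parameters
#'
#' Links the subjective diary to objective sleep and the EEG indices:
#' multiplicative on sleep latency (matching the ratio form and heavy
#' right skew of SLm), linear on the TSTm percentage scale:
#' \deqn{SL_{subj} = SL_{obj} \exp(slm\_slope \cdot \alpha + \epsilon_1)}
#' \deqn{TST_{subj} = TST_{obj} (b_0 + b_1 AREMd + b_2 \alpha + \epsilon_2)/100}
#'
#' @param slm_slope Effect of alpha density (proportion) on log SL ratio.
#' @param tstm_intercept,tstm_beta_aremd,tstm_beta_alpha TSTm-scale
#'   regression parameters.
#' @param noise_sd SD of the TSTm noise (percentage points).
#' @param sl_noise_sd SD of the log-SL-ratio noise.
#' @return List of class `misperception_model`.
#' @export
misperception_model <- function(slm_slope = 6, tstm_intercept = 132.67,
                                tstm_beta_aremd = -56.04,
                                tstm_beta_alpha = -178.48,
                                noise_sd = 10, sl_noise_sd = 0.2) {
  structure(list(slm_slope = slm_slope, tstm_intercept = tstm_intercept,
                 tstm_beta_aremd = tstm_beta_aremd,
                 tstm_beta_alpha = tstm_beta_alpha,
                 noise_sd = noise_sd, sl_noise_sd = sl_noise_sd),
            class = "misperception_model")
}

#' Generate a subjective diary from objective sleep plus the
#' misperception model
#'
#' @param obj An [objective_sleep_params()] with `sl_obj_min > 0` and
#'   `tst_obj_min > 0`.
#' @param alpha_prop True alpha density (proportion).
#' @param aremd True REM arousal density (proportion).
#' @param model A [misperception_model()].
#' @param seed Optional integer seed.
#' @param bt Bedtime clock string.
#' @param subject_id Optional id.
#' @return A [parse_diary()] object.
#' @export
generate_diary <- function(obj, alpha_prop, aremd,
                           model = misperception_model(), seed = NULL,
                           bt = "23:30", subject_id = NA) {
  if (is.na(obj$sl_obj_min) || obj$sl_obj_min <= 0)
    stop("objective sleep latency must be > 0")
  if (obj$tst_obj_min <= 0) stop("objective TST must be > 0")
  if (!is.null(seed)) set.seed(seed)
  e1 <- if (model$sl_noise_sd > 0) stats::rnorm(1, 0, model$sl_noise_sd) else 0
  e2 <- if (model$noise_sd > 0) stats::rnorm(1, 0, model$noise_sd) else 0
  sl_subj <- obj$sl_obj_min * exp(model$slm_slope * alpha_prop + e1)
  tstm <- model$tstm_intercept + model$tstm_beta_aremd * aremd +
    model$tstm_beta_alpha * alpha_prop + e2
  tst_subj <- max(0, obj$tst_obj_min * tstm / 100)
  waso_subj <- max(0, obj$waso_obj_min * stats::runif(1, 0.4, 0.9))
  nawk_subj <- max(0L, obj$nawk_obj + sample(-2:1, 1))
  parse_diary(list(subject_id = subject_id, bt = bt,
                   sl_subj_min = sl_subj, tst_subj_min = tst_subj,
                   waso_subj_min = waso_subj, nawk_subj = nawk_subj,
                   completed_within_min = 10))
}

#' Cohort configuration for the synthetic study
#'
#' Defines the emulated study design: `n_subjects` single-night
#' recordings, half drawn from low-discrepancy settings and half from
#' high-discrepancy settings (the 8/8 split of the emulated design at the
#' default n = 16). Low/high subjects differ in their sleep-onset N1->W
#' return probability and alpha-density range; the diary follows the
#' misperception model. Group membership in the 10-min discrepancy split
#' is guaranteed by construction: low-group subjective latencies are
#' capped at `SL_obj + low_cap_min` and high-group ones floored at
#' `SL_obj + high_floor_min` (caps rarely bind under the defaults).
#'
#' @param n_subjects Number of subjects (>= 2; split half/half).
#' @param seed Integer seed; a fixed seed yields a byte-identical cohort.
#' @param fs_hz Sampling rate of synthesized signals.
#' @param n_epochs Night length in 30-s epochs (default 960 = 8 h).
#' @param onset_epochs Epochs governed by the sleep-onset chain (default
#'   80 = 40 min); signals are synthesized for this window and for REM
#'   bouts only.
#' @param onset_n1w_low,onset_n1w_high Per-subject uniform ranges of the
#'   N1->W onset probability.
#' @param alpha_range_low,alpha_range_high Uniform ranges of true alpha
#'   density (proportions; defaults bracket the 0.026/0.165 subgroup
#'   means).
#' @param aremd_range Uniform range of true REM arousal density.
#' @param kc_offset_range_min First K-complex latency offset after sleep
#'   onset, minutes.
#' @param misperception A [misperception_model()].
#' @param low_cap_min,high_floor_min Discrepancy guards, minutes.
#' @param cutoff_min Discrepancy cutoff used downstream.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 16, seed = 1, fs_hz = 128,
                          n_epochs = 960, onset_epochs = 80,
                          onset_n1w_low = c(0.005, 0.10),
                          onset_n1w_high = c(0.30, 0.70),
                          alpha_range_low = c(0, 0.08),
                          alpha_range_high = c(0.05, 0.35),
                          aremd_range = c(0.1, 0.7),
                          kc_offset_range_min = c(2, 12),
                          misperception = misperception_model(),
                          low_cap_min = 8, high_floor_min = 12,
                          cutoff_min = 10) {
  stopifnot(n_subjects >= 2, fs_hz >= 100, n_epochs > onset_epochs)
  rng_ok <- function(r) length(r) == 2 && r[1] <= r[2] && r[1] >= 0 && r[2] <= 1
  stopifnot(rng_ok(alpha_range_low), rng_ok(alpha_range_high),
            rng_ok(aremd_range))
  structure(list(n_subjects = n_subjects, seed = seed, fs_hz = fs_hz,
                 n_epochs = n_epochs, onset_epochs = onset_epochs,
                 onset_n1w_low = onset_n1w_low, onset_n1w_high = onset_n1w_high,
                 alpha_range_low = alpha_range_low,
                 alpha_range_high = alpha_range_high,
                 aremd_range = aremd_range,
                 kc_offset_range_min = kc_offset_range_min,
                 misperception = misperception,
                 low_cap_min = low_cap_min, high_floor_min = high_floor_min,
                 cutoff_min = cutoff_min),
            class = "cohort_config")
}

#' Simulate one subject-night
#'
#' Draws from the current RNG stream (the caller seeds it); used by
#' [generate_cohort()] and the streaming pipeline.
#'
#' @param cfg A [cohort_config()].
#' @param i Subject index (1-based).
#' @param group `"LOW"` or `"HIGH"`.
#' @param keep_signals Render EEG/EMG signals (set `FALSE` for
#'   hypnogram/diary-only cohorts).
#' @return List: `subject_id`, `group`, `hyp`, `diary`, `signals`
#'   (`onset` record and `rem` record list, or `NULL`), `ground_truth`.
#' @export
simulate_subject <- function(cfg, i, group, keep_signals = TRUE) {
  epoch_min <- 0.5
  onset_min <- cfg$onset_epochs * epoch_min
  n1w_range <- if (group == "LOW") cfg$onset_n1w_low else cfg$onset_n1w_high
  n1w <- stats::runif(1, n1w_range[1], n1w_range[2])
  chain <- onset_chain(n1w)
  # reject onset draws whose sleep latency would crowd out the subjective
  # window (keeps SL_obj + high floor inside the onset segment)
  repeat {
    onset_stages <- sample_chain(chain, cfg$onset_epochs, "W")
    sl_idx <- which(onset_stages != "W")[1]
    if (!is.na(sl_idx) && sl_idx > 1 && (sl_idx - 1) * epoch_min <= 25) break
  }
  night_stages <- sample_chain(night_chain(), cfg$n_epochs - cfg$onset_epochs + 1L,
                               onset_stages[cfg$onset_epochs])[-1]
  hyp <- hypnogram(c(onset_stages, night_stages), anchor_clock = "23:30")
  obj <- objective_sleep_params(hyp)

  # alpha-burst schedule over the objective sleep-latency window
  n_micro <- floor(obj$sl_obj_min * 60 / 3)
  alpha_target <- stats::runif(1, if (group == "LOW") cfg$alpha_range_low[1] else cfg$alpha_range_high[1],
                               if (group == "LOW") cfg$alpha_range_low[2] else cfg$alpha_range_high[2])
  k_alpha <- round(alpha_target * n_micro)
  alpha_epochs <- if (k_alpha > 0) sort(sample.int(n_micro, k_alpha)) else integer(0)
  alpha_schedule <- if (length(alpha_epochs)) {
    data.frame(start = (alpha_epochs - 1) * 3 + 0.3,
               end = (alpha_epochs - 1) * 3 + 2.5)
  } else NULL
  alpha_true <- if (n_micro > 0) k_alpha / n_micro else NA_real_

  # K-complexes after sleep onset, inside the onset record
  kc_first <- obj$sl_obj_min + stats::runif(1, cfg$kc_offset_range_min[1],
                                            cfg$kc_offset_range_min[2])
  kc_times <- cumsum(c(kc_first, stats::runif(3, 1, 3))) * 60
  kc_times <- kc_times[kc_times < onset_min * 60 - 5]

  # REM arousal schedule: one injected arousal per chosen REM epoch
  rem_idx <- which(hyp$stages == "REM")
  n_rem <- length(rem_idx)
  aremd_target <- stats::runif(1, cfg$aremd_range[1], cfg$aremd_range[2])
  k_ar <- if (n_rem > 0) round(aremd_target * n_rem) else 0L
  ar_epochs <- if (k_ar > 0) sort(rem_idx[sample.int(n_rem, k_ar)]) else integer(0)
  ar_onsets <- (ar_epochs - 1) * 30 + 12
  arousal_schedule <- if (length(ar_onsets)) {
    data.frame(start = ar_onsets, end = ar_onsets + 4,
               emg_start = ar_onsets + 1, emg_end = ar_onsets + 3)
  } else NULL
  aremd_true <- if (n_rem > 0) k_ar / n_rem else NA_real_

  signals <- NULL
  if (keep_signals) {
    onset_sig <- generate_eeg(onset_min * 60, cfg$fs_hz,
                              alpha_schedule = alpha_schedule,
                              kc_times = kc_times, t0_s = 0,
                              channels = c("occipital", "frontal"))
    rem_sigs <- list()
    if (n_rem > 0) {
      runs <- logical_runs(hyp$stages == "REM")
      for (r in seq_len(nrow(runs))) {
        b0 <- (runs$start[r] - 1) * 30
        b1 <- runs$end[r] * 30
        sched <- if (!is.null(arousal_schedule)) {
          arousal_schedule[arousal_schedule$start >= b0 & arousal_schedule$start < b1, , drop = FALSE]
        } else NULL
        rem_sigs[[r]] <- generate_eeg(b1 - b0, cfg$fs_hz,
                                      arousal_schedule = sched, t0_s = b0,
                                      channels = c("occipital", "emg"))
      }
    }
    signals <- list(onset = onset_sig, rem = rem_sigs)
  }

  diary <- generate_diary(obj, alpha_true, aremd_true,
                          model = cfg$misperception,
                          subject_id = sprintf("S%02d", i))
  # discrepancy guards: group membership in the cutoff split is by construction
  cap_high <- onset_min - 2
  if (group == "LOW") {
    diary$sl_subj_min <- min(diary$sl_subj_min, obj$sl_obj_min + cfg$low_cap_min)
  } else {
    diary$sl_subj_min <- min(cap_high,
                             max(diary$sl_subj_min, obj$sl_obj_min + cfg$high_floor_min))
  }
  diary$so_subj_clock <- format_clock(parse_clock(diary$bt_clock) + diary$sl_subj_min)

  list(subject_id = sprintf("S%02d", i), group = group, hyp = hyp,
       diary = diary, signals = signals,
       ground_truth = list(group = group, n1_to_w = n1w, chain = chain,
                           alpha_prop = alpha_true, aremd = aremd_true,
                           kc_first_min = if (length(kc_times)) kc_times[1] / 60 else NA_real_,
                           kc_times_s = kc_times,
                           n_rem_epochs = n_rem,
                           sl_obj_min = obj$sl_obj_min))
}

#' Generate a synthetic cohort
#'
#' @param cfg A [cohort_config()].
#' @param keep_signals Render signals for each subject (default `TRUE`).
#' @return List of class `ssm_cohort` of [simulate_subject()] outputs;
#'   deterministic given `cfg` (identical config, identical cohort).
#' @export
generate_cohort <- function(cfg, keep_signals = TRUE) {
  set.seed(cfg$seed)
  n_low <- floor(cfg$n_subjects / 2)
  groups <- c(rep("LOW", n_low), rep("HIGH", cfg$n_subjects - n_low))
  out <- lapply(seq_len(cfg$n_subjects), function(i)
    simulate_subject(cfg, i, groups[i], keep_signals = keep_signals))
  structure(out, class = "ssm_cohort", config = cfg)
}

#' Write cohort inputs as plain-text files
#'
#' Writes per-subject hypnogram CSVs, a diary JSON, and a ground-truth
#' JSON sidecar (all synthetic). Signals are not persisted; they are
#' regenerable from the configuration seed.
#'
#' @param cohort An [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort)
    write_hypnogram(s$hyp, file.path(dir, paste0("hypnogram_", s$subject_id, ".csv")))
  write_diaries(lapply(cohort, `[[`, "diary"), file.path(dir, "diaries.json"))
  gt <- lapply(cohort, function(s) {
    g <- s$ground_truth
    g$chain <- NULL                     # matrices go in the config, not per subject
    c(list(subject_id = s$subject_id), g)
  })
  jsonlite::write_json(gt, file.path(dir, "ground_truth_synthetic.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}
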