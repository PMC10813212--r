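test_that("alpha density counts positive micro-epochs as scheduled", {
  # bursts covering micro-epochs 1 and 4 of 4 -> labels 1,0,0,1
  sig <- generate_eeg(12, 128, alpha_schedule = alpha_schedule_for(c(1, 4)),
                      seed = 11, alpha_snr = 4, channels = "occipital")
  ad <- alpha_density(sig, c(0, 0.2))
  expect_equal(ad$n_micro, 4)
  expect_equal(ad$micro_labels, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(ad$alpha_prop, 0.5)
  # schedule-aligned construction on micro-epochs {1, 3}
  sig2 <- generate_eeg(12, 128, alpha_schedule = alpha_schedule_for(c(1, 3)),
                       seed = 12, channels = "occipital")
  expect_equal(alpha_density(sig2, c(0, 0.2))$micro_labels,
               c(TRUE, FALSE, TRUE, FALSE))
})

test_that("a pure alpha-band sinusoid saturates the index for sub-unit k", {
  fs <- 128
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  x <- 30 * sin(2 * pi * 10 * t)
  sig <- signal_record(list(O1 = x, O2 = x), fs,
                       roles = list(occipital = c("O1", "O2")))
  expect_equal(alpha_density(sig, c(0, 0.5), alpha_params(k = 0.8))$alpha_prop, 1)
})

test_that("alpha labels are invariant to a common amplitude rescaling", {
  sig <- generate_eeg(60, 128, alpha_schedule = alpha_schedule_for(c(2, 5, 9, 14)),
                      seed = 21, channels = "occipital")
  lab1 <- alpha_density(sig, c(0, 1))$micro_labels
  sig$channels <- lapply(sig$channels, function(x) 3.7 * x)
  expect_equal(alpha_density(sig, c(0, 1))$micro_labels, lab1)
})

test_that("alpha density is monotone in burst coverage at fixed noise", {
  fs <- 128
  win_min <- 3
  n_micro <- win_min * 60 / 3
  set.seed(303)
  order_ep <- sample.int(n_micro)
  props <- vapply(seq(0, 0.9, by = 0.1), function(cov) {
    k <- round(cov * n_micro)
    sched <- alpha_schedule_for(sort(order_ep[seq_len(k)]))
    sig <- generate_eeg(win_min * 60, fs, alpha_schedule = sched, seed = 99,
                        channels = "occipital")
    alpha_density(sig, c(0, win_min))$alpha_prop
  }, numeric(1))
  expect_true(all(diff(props) >= 0))
})

test_that("alpha density rejects malformed windows and roles", {
  sig <- generate_eeg(12, 128, seed = 1, channels = "occipital")
  expect_error(alpha_density(sig, c(0, 0.02)), "micro-epoch")
  expect_error(alpha_density(sig, c(0, 5)), "outside")
  sig2 <- generate_eeg(12, 128, seed = 1, channels = "frontal")
  expect_error(alpha_density(sig2, c(0, 0.2)), "occipital")
})

test_that("K-complex gates on amplitude and duration are each falsifiable", {
  fs <- 128
  base <- rep(0, 60 * fs)
  tmpl <- ssmpipe:::kc_template(fs, 1.0, -65, 45)      # 110 uV pp, 1 s
  put <- function(x, tmpl, at_s) {
    idx <- round(at_s * fs) + seq_along(tmpl)
    x[idx] <- x[idx] + tmpl
    x
  }
  mk <- function(x) signal_record(list(F3 = x, F4 = rep(0, length(x))), fs,
                                  roles = list(frontal = c("F3", "F4")))
  ev <- detect_kcomplexes(mk(put(base, tmpl, 20)))
  expect_equal(nrow(ev), 1)
  expect_gte(ev$peak_to_peak_uv, 75)
  expect_lt(abs(ev$t_start_s - 20), 0.3)
  # scaled below the 75 uV peak-to-peak gate
  expect_equal(nrow(detect_kcomplexes(mk(put(base, 0.36 * tmpl, 20)))), 0)
  # stretched beyond the 3 s duration gate
  long <- ssmpipe:::kc_template(fs, 4.0, -65, 45)
  expect_equal(nrow(detect_kcomplexes(mk(put(rep(0, 60 * fs), long, 20)))), 0)
  # overlapping detections across F3/F4 merge into one event
  x <- put(base, tmpl, 20)
  sig2 <- signal_record(list(F3 = x, F4 = put(rep(0, 60 * fs), tmpl, 20.1)), fs,
                        roles = list(frontal = c("F3", "F4")))
  expect_equal(nrow(detect_kcomplexes(sig2)), 1)
})

test_that("first K-complex latency equals the brute-force minimum", {
  expect_equal(first_kc_latency(data.frame(t_start_s = c(300, 900))), 5)
  expect_true(is.na(first_kc_latency(data.frame(t_start_s = numeric(0)))))
  set.seed(44)
  for (i in 1:200) {
    t <- runif(sample(1:8, 1), 0, 3000)
    ev <- data.frame(t_start_s = t[sample.int(length(t))])
    expect_equal(first_kc_latency(ev), min(t) / 60)
  }
})

test_that("REM arousal gates (shift, EMG, stability) are each falsifiable", {
  fs <- 128
  hyp <- hypnogram(rep(c("N2", "REM"), c(4, 16)))
  t0 <- 120                            # REM bout starts at epoch 5
  mk <- function(sched) {
    generate_eeg(16 * 30, fs, arousal_schedule = sched, t0_s = t0, seed = 17,
                 channels = c("occipital", "emg"))
  }
  full <- data.frame(start = 140, end = 144, emg_start = 141, emg_end = 143)
  expect_equal(nrow(detect_rem_arousals(mk(full), hyp)), 1)
  # shift lasting only 2 s fails the 3-s gate
  short <- data.frame(start = 140, end = 142, emg_start = 140.2, emg_end = 141.8)
  expect_equal(nrow(detect_rem_arousals(mk(short), hyp)), 0)
  # missing EMG burst fails the EMG-confirmation gate
  noemg <- data.frame(start = 140, end = 144, emg_start = NA, emg_end = NA)
  sig <- generate_eeg(16 * 30, fs,
                      arousal_schedule = transform(noemg, emg_start = 0, emg_end = 0),
                      t0_s = t0, seed = 17, channels = c("occipital", "emg"))
  expect_equal(nrow(detect_rem_arousals(sig, hyp)), 0)
  # a second shift 6 s after the first fails the 10-s stability gate
  two <- data.frame(start = c(140, 150), end = c(144, 154),
                    emg_start = c(141, 151), emg_end = c(143, 153))
  ev <- detect_rem_arousals(mk(two), hyp)
  expect_equal(nrow(ev), 1)
  expect_lt(abs(ev$t_start_s[1] - 140), 1)
  # spaced 20 s apart both survive
  two_ok <- data.frame(start = c(140, 164), end = c(144, 168),
                       emg_start = c(141, 165), emg_end = c(143, 167))
  expect_equal(nrow(detect_rem_arousals(mk(two_ok), hyp)), 2)
})

test_that("arousals are only scored inside REM epochs of the paired hypnogram", {
  fs <- 128
  hyp <- hypnogram(rep(c("N2", "REM", "N2"), c(4, 8, 8)))
  sched <- data.frame(start = c(140, 400), end = c(144, 404),
                      emg_start = c(141, 401), emg_end = c(143, 403))
  sig <- generate_eeg(16 * 30, fs, arousal_schedule = sched, t0_s = 120,
                      seed = 23, channels = c("occipital", "emg"))
  ev <- detect_rem_arousals(sig, hyp)
  ep <- floor(ev$t_start_s / 30) + 1
  expect_true(all(hyp$stages[ep] == "REM"))
  expect_warning(detect_rem_arousals(sig, hypnogram(rep("N2", 20))), "no REM")
})

test_that("REM arousal density equals the brute-force epoch-membership count", {
  hyp <- hypnogram(rep(c("N2", "REM"), c(2, 10)))
  ev <- data.frame(t_start_s = c(70, 95, 130, 190))  # epochs 3, 4, 5, 7
  expect_equal(rem_arousal_density(ev, hyp), 4 / 10)
  expect_equal(rem_arousal_density(ev[0, , drop = FALSE], hyp), 0)
  expect_warning(d <- rem_arousal_density(ev, hypnogram(rep("N2", 4))), "no REM")
  expect_true(is.na(d))
  set.seed(55)
  for (i in 1:500) {
    stages <- random_stages(sample(5:60, 1), p_w = 0.2)
    h <- hypnogram(stages)
    rem <- which(stages == "REM")
    if (!length(rem)) next
    ev <- data.frame(t_start_s = runif(sample(0:10, 1), 0, length(stages) * 30))
    got <- rem_arousal_density(ev, h)
    hit <- vapply(rem, function(e) any(ev$t_start_s >= (e - 1) * 30 &
                                         ev$t_start_s < e * 30), logical(1))
    expect_equal(got, mean(hit))
  }
})

test_that("signal records validate roles and round-trip through CSV", {
  expect_error(signal_record(list(a = 1:10, b = 1:5), 128), "equal length")
  expect_error(signal_record(list(a = 1:10), 50), "100")
  expect_error(signal_record(list(a = 1:10), 128, roles = list(emg = "zz")),
               "unknown channel")
  sig <- generate_eeg(3, 128, seed = 2, channels = c("occipital", "emg"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_signal_csv(sig, f)
  back <- read_signal_csv(f)
  expect_equal(back$roles, sig$roles)
  expect_equal(back$fs_hz, sig$fs_hz)
  expect_equal(back$channels$O1, sig$channels$O1, tolerance = 1e-6)
})
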