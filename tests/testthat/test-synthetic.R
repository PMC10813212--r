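test_that("Markov hypnogram generation honors the chain structure", {
  # impossible event never occurs
  P <- onset_chain(0)
  h <- generate_hypnogram(P, 2000, start = "N1", seed = 3)
  tc <- transition_counts(h$stages)
  expect_equal(tc$counts["N1", "W"], 0L)
  # absorbing chain yields a constant sequence
  I5 <- diag(5); dimnames(I5) <- list(SLEEP_STAGES, SLEEP_STAGES)
  expect_equal(unique(generate_hypnogram(I5, 50, start = "N2", seed = 4)$stages), "N2")
  # non-stochastic rows are rejected
  bad <- I5; bad[2, 2] <- 0.5
  expect_error(generate_hypnogram(bad, 10), "non-stochastic")
  expect_error(generate_hypnogram(I5, 1), "n_epochs")
  # MLE recovery from a long sample
  P2 <- mixed_chain()
  h2 <- generate_hypnogram(P2, 10000, start = "W", seed = 5)
  est <- transition_matrix(transition_counts(h2$stages))$probs
  expect_lte(max(abs(est - P2)), 0.05)
})

test_that("empty schedules give a pure-noise record with a near-zero alpha floor", {
  sig <- generate_eeg(180, 128, seed = 71, channels = "occipital")
  expect_lte(alpha_density(sig, c(0, 3))$alpha_prop, 0.02)
  gt <- attr(sig, "ground_truth")
  expect_null(gt$alpha_schedule)
})

test_that("scheduled K-complexes are recovered exactly", {
  times <- c(20, 80, 150, 260, 400)
  sig <- generate_eeg(500, 128, kc_times = times, seed = 73, channels = "frontal")
  ev <- detect_kcomplexes(sig)
  expect_equal(nrow(ev), 5)
  expect_equal(ev$t_start_s, times, tolerance = 0.5)
})

test_that("diary model reduces to identity at zero noise and null effects", {
  h <- hypnogram(c("W", "W", rep("N2", 100)))
  obj <- objective_sleep_params(h)
  m <- misperception_model(slm_slope = 0, tstm_intercept = 100,
                           tstm_beta_aremd = 0, tstm_beta_alpha = 0,
                           noise_sd = 0, sl_noise_sd = 0)
  d <- generate_diary(obj, 0.2, 0.4, m, seed = 9)
  expect_equal(d$sl_subj_min, obj$sl_obj_min)
  expect_equal(d$tst_subj_min, obj$tst_obj_min)
})

test_that("zero-noise SLm is an exact deterministic function of alpha density", {
  h <- hypnogram(c("W", "W", "W", "W", rep("N2", 60)))
  obj <- objective_sleep_params(h)
  m <- misperception_model(noise_sd = 0, sl_noise_sd = 0)
  alphas <- seq(0, 0.35, length.out = 12)
  slm <- vapply(alphas, function(a) {
    d <- generate_diary(obj, a, 0.3, m, seed = 1)
    sl_misperception(d$sl_subj_min, obj$sl_obj_min)
  }, numeric(1))
  expect_equal(slm, 100 * exp(m$slm_slope * alphas), tolerance = 1e-9)
  expect_equal(spearman(alphas, slm)$rho, 1)
})

test_that("a fixed cohort config reproduces the cohort exactly", {
  cfg <- cohort_config(n_subjects = 2, seed = 77, n_epochs = 200)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1, c2)
})

test_that("the default split assigns half the cohort to each discrepancy group", {
  cfg <- cohort_config(n_subjects = 6, seed = 78, n_epochs = 300)
  coh <- generate_cohort(cfg, keep_signals = FALSE)
  groups <- vapply(coh, `[[`, character(1), "group")
  expect_equal(sum(groups == "LOW"), 3)
  disc <- vapply(coh, function(s)
    s$diary$sl_subj_min - s$ground_truth$sl_obj_min, numeric(1))
  expect_true(all(disc[groups == "HIGH"] > 10))
  expect_true(all(disc[groups == "LOW"] <= 10))
})

test_that("cohort files are written as readable plain text", {
  cfg <- cohort_config(n_subjects = 2, seed = 79, n_epochs = 200)
  coh <- generate_cohort(cfg, keep_signals = FALSE)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "hypnogram_S01.csv")))
  h <- read_hypnogram(file.path(dir, "hypnogram_S01.csv"))
  expect_identical(h$stages, coh[[1]]$hyp$stages)
  ds <- read_diaries(file.path(dir, "diaries.json"))
  expect_equal(ds[[2]]$sl_subj_min, coh[[2]]$diary$sl_subj_min)
  gt <- jsonlite::fromJSON(file.path(dir, "ground_truth_synthetic.json"))
  expect_equal(gt$subject_id, c("S01", "S02"))
})

test_that("detector estimates track ground truth across a cohort", {
  cfg <- cohort_config(n_subjects = 12, seed = 80)
  rcfg <- run_config(synthetic = cfg)
  set.seed(cfg$seed)
  groups <- rep(c("LOW", "HIGH"), each = 6)
  est_alpha <- true_alpha <- est_aremd <- true_aremd <- numeric(12)
  est_n1w <- true_n1w <- numeric(12)
  for (i in 1:12) {
    sub <- simulate_subject(cfg, i, groups[i])
    sc <- score_subject(sub, rcfg)
    est_alpha[i] <- sc$row$alpha_prop
    est_aremd[i] <- sc$row$aremd
    est_n1w[i] <- sc$row$p_n1_to_w
    true_alpha[i] <- sub$ground_truth$alpha_prop
    true_aremd[i] <- sub$ground_truth$aremd
    true_n1w[i] <- sub$ground_truth$n1_to_w
  }
  expect_gte(spearman(est_alpha, true_alpha)$rho, 0.9)
  expect_gte(spearman(est_aremd, true_aremd)$rho, 0.9)
  # short subjective windows can leave N1 unvisited: missing, never zero
  ok <- !is.na(est_n1w)
  expect_gte(sum(ok), 6)
})

test_that("transition estimates over the onset window track the generator chain", {
  # estimated over the full 40-min segment the onset chain governs; the
  # subjective window is a (sometimes very short) sub-sample of it
  cfg <- cohort_config(n_subjects = 50, seed = 81)
  coh <- generate_cohort(cfg, keep_signals = FALSE)
  est <- vapply(coh, function(s) {
    win <- restrict_window(s$hyp, 0, 40)
    transition_matrix(transition_counts(win$stages))$probs["N1", "W"]
  }, numeric(1))
  truth <- vapply(coh, function(s) s$ground_truth$n1_to_w, numeric(1))
  ok <- !is.na(est)
  expect_gte(sum(ok), 45)
  expect_gte(spearman(est[ok], truth[ok])$rho, 0.9)
})
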