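#' Pipeline run configuration
#'
#' Exactly one of `synthetic` (a [cohort_config()]) or the real-input
#' paths (`hypnogram_dir` + `diary_file`) must be given. Signal records
#' for real data are supplied per subject as CSV (see
#' [read_signal_csv()]); synthetic runs render them from the cohort seed.
#'
#' @param synthetic A [cohort_config()], or `NULL`.
#' @param hypnogram_dir Directory of `hypnogram_<id>.csv` files.
#' @param diary_file Diary JSON/CSV covering the same subject ids.
#' @param signal_dir Optional directory of `signals_<id>.csv` excerpts.
#' @param alpha A [alpha_params()].
#' @param kc A [kc_params()].
#' @param arousal An [arousal_params()].
#' @param cutoff_min Discrepancy cutoff (minutes, default 10).
#' @param group_order Order in which groups enter two-sample tests; the
#'   first group is the comparison group, giving the rank-biserial its
#'   sign.
#' @param stepwise_criterion Passed to [backward_stepwise()].
#' @param out_dir Output directory for report files, or `NULL` to skip
#'   writing.
#' @return List of class `run_config`.
#' @export
run_config <- function(synthetic = NULL, hypnogram_dir = NULL,
                       diary_file = NULL, signal_dir = NULL,
                       alpha = alpha_params(), kc = kc_params(),
                       arousal = arousal_params(), cutoff_min = 10,
                       group_order = c("LOW", "HIGH"),
                       stepwise_criterion = "adjr2", out_dir = NULL) {
  real <- !is.null(hypnogram_dir) || !is.null(diary_file)
  if (is.null(synthetic) == !real)
    stop("give exactly one of 'synthetic' or real-input paths")
  if (real) {
    for (p in c(hypnogram_dir, diary_file, signal_dir))
      if (!file.exists(p)) stop("input path does not exist: ", p)
  }
  structure(list(synthetic = synthetic, hypnogram_dir = hypnogram_dir,
                 diary_file = diary_file, signal_dir = signal_dir,
                 alpha = alpha, kc = kc, arousal = arousal,
                 cutoff_min = cutoff_min, group_order = group_order,
                 stepwise_criterion = stepwise_criterion,
                 out_dir = out_dir),
            class = "run_config")
}

#' Score one subject-night
#'
#' Computes the full per-subject row: objective sleep parameters,
#' latencies (N1, N3, first K-complex), alpha density over the objective
#' sleep-latency window, REM arousal density, misperception indices, and
#' the subjective-sleep-latency transition matrix.
#'
#' @param sub A subject as produced by [simulate_subject()] (fields
#'   `subject_id`, `hyp`, `diary`, `signals`).
#' @param cfg A [run_config()] (detector parameters, cutoff).
#' @return List: `row` (one-row data frame) and `matrix` (the subject's
#'   [transition_matrix()] or `NULL`).
#' @export
score_subject <- function(sub, cfg) {
  hyp <- sub$hyp
  diary <- sub$diary
  obj <- objective_sleep_params(hyp)
  lat_n1 <- stage_latency(hyp, "N1")
  lat_n3 <- stage_latency(hyp, "N3")

  alpha_prop <- NA_real_
  kc_lat <- NA_real_
  aremd <- NA_real_
  if (!is.null(sub$signals)) {
    if (!is.null(sub$signals$onset) && !is.na(obj$sl_obj_min) && obj$sl_obj_min >= 0.1) {
      ad <- alpha_density(sub$signals$onset, c(0, obj$sl_obj_min), cfg$alpha)
      alpha_prop <- ad$alpha_prop
      kc_lat <- first_kc_latency(detect_kcomplexes(sub$signals$onset, cfg$kc))
    }
    if (length(sub$signals$rem)) {
      evs <- lapply(sub$signals$rem, function(sg)
        suppressWarnings(detect_rem_arousals(sg, hyp, cfg$arousal)))
      aremd <- rem_arousal_density(evs, hyp)
    } else if (any(hyp$stages == "REM", na.rm = TRUE)) {
      aremd <- rem_arousal_density(list(), hyp)
    }
  }

  mi <- suppressWarnings(
    misperception_indices(diary$sl_subj_min, obj$sl_obj_min,
                          diary$tst_subj_min, obj$tst_obj_min,
                          cutoff_min = cfg$cutoff_min))
  tm <- suppressWarnings(subjective_sl_matrix(hyp, diary))

  row <- data.frame(
    subject_id = sub$subject_id,
    sl_obj_min = obj$sl_obj_min, tst_obj_min = obj$tst_obj_min,
    waso_obj_min = obj$waso_obj_min, nawk_obj = obj$nawk_obj,
    pct_n1 = obj$stage_pct[["N1"]], pct_n2 = obj$stage_pct[["N2"]],
    pct_n3 = obj$stage_pct[["N3"]], pct_rem = obj$stage_pct[["REM"]],
    lat_n1_min = lat_n1, lat_n3_min = lat_n3, lat_first_kc_min = kc_lat,
    alpha_prop = alpha_prop, alpha_pct = 100 * alpha_prop, aremd = aremd,
    sl_subj_min = diary$sl_subj_min, tst_subj_min = diary$tst_subj_min,
    waso_subj_min = diary$waso_subj_min, nawk_subj = diary$nawk_subj,
    slm_pct = mi$slm_pct, tstm_pct = mi$tstm_pct,
    sl_discrepancy_min = mi$sl_discrepancy_min,
    discrepancy_group = mi$discrepancy_group,
    p_n1_to_w = if (is.null(tm)) NA_real_ else tm$probs["N1", "W"],
    stringsAsFactors = FALSE)
  list(row = row, matrix = tm)
}

safe_test <- function(expr) tryCatch(expr, error = function(e) NULL)

strip_lm <- function(fit) {
  if (is.null(fit)) return(NULL)
  fit$lm <- NULL
  unclass(fit)
}

#' Run the full misperception analysis pipeline
#'
#' Ingestion (or synthesis) -> per-subject indices -> discrepancy split ->
#' group comparisons (Mann-Whitney with rank-biserial), Spearman
#' correlations, normality gate, backward-stepwise regression of TSTm on
#' A-REMd, alpha density and N3 latency, and the N1->W transition
#' comparison. Per-subject scoring failures are isolated: the subject is
#' flagged in `failures` and the run continues.
#'
#' When `cfg$out_dir` is set, writes `subjects.csv`, `stats.json`,
#' `transitions.csv` and `manifest.json` (config hash + seed; identical
#' manifests imply byte-identical reports).
#'
#' @param cfg A [run_config()].
#' @return List of class `study_report`: `subjects` (one row per subject,
#'   explicit `NA` for excluded indices), `tests`, `correlations`,
#'   `regression`, `normality`, `matrices`, `failures`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  rows <- list(); mats <- list(); failures <- character(0)
  if (!is.null(cfg$synthetic)) {
    ccfg <- cfg$synthetic
    set.seed(ccfg$seed)
    n_low <- floor(ccfg$n_subjects / 2)
    groups <- c(rep("LOW", n_low), rep("HIGH", ccfg$n_subjects - n_low))
    for (i in seq_len(ccfg$n_subjects)) {
      sub <- simulate_subject(ccfg, i, groups[i], keep_signals = TRUE)
      sc <- tryCatch(score_subject(sub, cfg), error = function(e) e)
      if (inherits(sc, "error")) {
        failures <- c(failures, sprintf("%s: %s", sub$subject_id, conditionMessage(sc)))
        next
      }
      rows[[sub$subject_id]] <- sc$row
      mats[sub$subject_id] <- list(sc$matrix)
    }
  } else {
    files <- sort(list.files(cfg$hypnogram_dir, "^hypnogram_.*\\.csv$",
                             full.names = TRUE))
    diaries <- read_diaries(cfg$diary_file)
    names(diaries) <- vapply(diaries, `[[`, character(1), "subject_id")
    for (f in files) {
      id <- sub("^hypnogram_(.*)\\.csv$", "\\1", basename(f))
      sub_in <- list(subject_id = id, hyp = read_hypnogram(f),
                     diary = diaries[[id]], signals = NULL)
      if (!is.null(cfg$signal_dir)) {
        sf <- file.path(cfg$signal_dir, paste0("signals_", id, ".csv"))
        if (file.exists(sf))
          sub_in$signals <- list(onset = read_signal_csv(sf), rem = list())
      }
      if (is.null(sub_in$diary)) {
        failures <- c(failures, paste0(id, ": no diary record"))
        next
      }
      sc <- tryCatch(score_subject(sub_in, cfg), error = function(e) e)
      if (inherits(sc, "error")) {
        failures <- c(failures, sprintf("%s: %s", id, conditionMessage(sc)))
        next
      }
      rows[[id]] <- sc$row
      mats[id] <- list(sc$matrix)
    }
  }
  if (!length(rows)) stop("pipeline stage 'scoring' produced no subjects")
  subjects <- do.call(rbind, rows)
  rownames(subjects) <- NULL

  g1 <- cfg$group_order[1]; g2 <- cfg$group_order[2]
  in_g <- function(g) subjects$discrepancy_group %in% g
  grab <- function(var, g) subjects[[var]][in_g(g) & !is.na(subjects[[var]])]

  tests <- list(
    alpha_by_group = safe_test(mann_whitney(grab("alpha_prop", g1), grab("alpha_prop", g2))),
    n1_to_w_by_group = safe_test(mann_whitney(grab("p_n1_to_w", g1), grab("p_n1_to_w", g2))),
    sl_subj_vs_obj = safe_test(mann_whitney(subjects$sl_obj_min, subjects$sl_subj_min)),
    tst_subj_vs_obj = safe_test(mann_whitney(subjects$tst_obj_min, subjects$tst_subj_min)),
    waso_subj_vs_obj = safe_test(mann_whitney(
      subjects$waso_obj_min, subjects$waso_subj_min[!is.na(subjects$waso_subj_min)]))
  )

  cor_pairs <- list(
    alpha_vs_slm = c("alpha_prop", "slm_pct"),
    alpha_vs_tstm = c("alpha_prop", "tstm_pct"),
    aremd_vs_tstm = c("aremd", "tstm_pct"),
    lat_n1_vs_slm = c("lat_n1_min", "slm_pct"),
    lat_n3_vs_slm = c("lat_n3_min", "slm_pct"),
    lat_kc_vs_slm = c("lat_first_kc_min", "slm_pct"))
  correlations <- lapply(cor_pairs, function(pr) {
    ok <- !is.na(subjects[[pr[1]]]) & !is.na(subjects[[pr[2]]])
    if (sum(ok) < 3) return(NULL)
    safe_test(spearman(subjects[[pr[1]]][ok], subjects[[pr[2]]][ok]))
  })

  normality <- suppressWarnings(shapiro_wilk_gate(list(
    slm_pct = subjects$slm_pct, tstm_pct = subjects$tstm_pct,
    alpha_prop = subjects$alpha_prop, aremd = subjects$aremd)))

  reg_ok <- stats::complete.cases(subjects[, c("aremd", "alpha_prop", "lat_n3_min", "tstm_pct")])
  regression <- if (sum(reg_ok) >= 6) {
    safe_test(backward_stepwise(
      data.frame(aremd = subjects$aremd[reg_ok],
                 alpha_prop = subjects$alpha_prop[reg_ok],
                 lat_n3_min = subjects$lat_n3_min[reg_ok]),
      subjects$tstm_pct[reg_ok], criterion = cfg$stepwise_criterion))
  } else NULL

  report <- structure(list(subjects = subjects, tests = tests,
                           correlations = correlations,
                           regression = regression, normality = normality,
                           matrices = mats, failures = failures,
                           group_order = cfg$group_order),
                      class = "study_report")
  if (!is.null(cfg$out_dir)) write_report(report, cfg)
  report
}

#' @export
print.study_report <- function(x, ...) {
  n <- nrow(x$subjects)
  tab <- table(x$subjects$discrepancy_group)
  cat(sprintf("<study_report> %d subjects (LOW %d / HIGH %d)%s\n", n,
              tab[["LOW"]], tab[["HIGH"]],
              if (length(x$failures)) paste0(", ", length(x$failures), " failed") else ""))
  if (!is.null(x$correlations$alpha_vs_slm)) {
    cat("  Spearman alpha~SLm: ")
    print(x$correlations$alpha_vs_slm)
  }
  if (!is.null(x$tests$alpha_by_group)) {
    cat("  alpha by group:     ")
    print(x$tests$alpha_by_group)
  }
  if (!is.null(x$regression)) {
    cat("  stepwise TSTm model: ")
    print(x$regression)
  }
  invisible(x)
}

#' Write report files for a pipeline run
#'
#' @param report A `study_report`.
#' @param cfg The [run_config()] used (for the manifest hash).
#' @return Output directory, invisibly.
#' @export
write_report <- function(report, cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$subjects, file.path(cfg$out_dir, "subjects.csv"),
                   row.names = FALSE)
  long <- transitions_long(report$matrices)
  if (!is.null(long))
    utils::write.csv(long, file.path(cfg$out_dir, "transitions.csv"),
                     row.names = FALSE)
  stats_obj <- list(
    tests = lapply(report$tests, function(t) if (is.null(t)) NULL else unclass(t)),
    correlations = lapply(report$correlations, function(t) if (is.null(t)) NULL else unclass(t)),
    regression = strip_lm(report$regression),
    normality = as.list(report$normality),
    failures = report$failures)
  jsonlite::write_json(stats_obj, file.path(cfg$out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  manifest <- list(config_hash = config_hash(cfg),
                   seed = if (!is.null(cfg$synthetic)) cfg$synthetic$seed else NA,
                   n_subjects = nrow(report$subjects),
                   package_version = as.character(utils::packageVersion("ssmpipe")))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(cfg$out_dir)
}

#' Deterministic hash of a run configuration
#' @keywords internal
config_hash <- function(cfg) {
  x <- cfg
  x$out_dir <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::serializeJSON(x), tmp)
  unname(tools::md5sum(tmp))
}

#' Round-for-report helper (2 decimals, matching the summary-table style)
#' @param df Data frame.
#' @return Data frame with numeric columns rounded to 2 decimals.
#' @export
report_round <- function(df) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = 2)
  df
}
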