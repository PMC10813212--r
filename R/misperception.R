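#' Sleep-latency misperception index (SLm)
#'
#' `SLm = (SL_subj / SL_obj) x 100`. Values above 100% indicate
#' overestimation of sleep latency. Undefined when `SL_obj = 0` (sleep at
#' the very first epoch); such subjects are excluded from SLm analyses.
#'
#' @param sl_subj_min Subjective sleep latency, minutes.
#' @param sl_obj_min Objective sleep latency, minutes; must be > 0.
#' @return Percent.
#' @export
sl_misperception <- function(sl_subj_min, sl_obj_min) {
  if (any(is.na(sl_obj_min)) || any(sl_obj_min <= 0))
    stop("SLm undefined: objective sleep latency must be > 0")
  if (any(sl_subj_min < 0)) stop("subjective sleep latency must be >= 0")
  (sl_subj_min / sl_obj_min) * 100
}

#' Total-sleep-time misperception index (TSTm)
#'
#' `TSTm = (TST_subj / TST_obj) x 100`. Values below 100% indicate
#' underestimation of total sleep time.
#'
#' @param tst_subj_min Subjective TST, minutes.
#' @param tst_obj_min Objective TST, minutes; must be > 0.
#' @return Percent.
#' @export
tst_misperception <- function(tst_subj_min, tst_obj_min) {
  if (any(is.na(tst_obj_min)) || any(tst_obj_min <= 0))
    stop("TSTm undefined: objective TST must be > 0")
  if (any(tst_subj_min < 0)) stop("subjective TST must be >= 0")
  (tst_subj_min / tst_obj_min) * 100
}

#' Split subjects by raw sleep-latency discrepancy
#'
#' The raw discrepancy is `SL_subj - SL_obj` (minutes). Subjects whose
#' discrepancy exceeds the cutoff (10 min by default, below which a
#' discrepancy may be attributed to chance) form the HIGH group; the rest
#' the LOW group. A discrepancy exactly at the cutoff is assigned LOW
#' (configurable).
#'
#' @param subjects Data frame with columns `subject_id`, `sl_subj_min`,
#'   `sl_obj_min`.
#' @param cutoff_min Cutoff in minutes, > 0.
#' @param tie Group receiving discrepancies exactly at the cutoff.
#' @return The input data frame with added columns `sl_discrepancy_min`
#'   and `discrepancy_group` (factor `LOW`/`HIGH`).
#' @export
split_by_discrepancy <- function(subjects, cutoff_min = 10,
                                 tie = c("LOW", "HIGH")) {
  tie <- match.arg(tie)
  if (!is.numeric(cutoff_min) || cutoff_min <= 0)
    stop("cutoff_min must be > 0")
  stopifnot(all(c("subject_id", "sl_subj_min", "sl_obj_min") %in% names(subjects)))
  disc <- subjects$sl_subj_min - subjects$sl_obj_min
  high <- if (tie == "LOW") disc > cutoff_min else disc >= cutoff_min
  subjects$sl_discrepancy_min <- disc
  subjects$discrepancy_group <- factor(ifelse(high, "HIGH", "LOW"),
                                       levels = c("LOW", "HIGH"))
  subjects
}

#' Misperception indices for one subject
#'
#' Bundles SLm, TSTm and the raw sleep-latency discrepancy. SLm is `NA`
#' (with a warning) when the objective sleep latency is zero.
#'
#' @param sl_subj_min,sl_obj_min Subjective/objective sleep latency (min).
#' @param tst_subj_min,tst_obj_min Subjective/objective TST (min).
#' @param cutoff_min Discrepancy cutoff for the group label.
#' @return List of class `misperception_indices` with `slm_pct`,
#'   `tstm_pct`, `sl_discrepancy_min`, `discrepancy_group`.
#' @export
misperception_indices <- function(sl_subj_min, sl_obj_min,
                                  tst_subj_min, tst_obj_min,
                                  cutoff_min = 10) {
  slm <- if (!is.na(sl_obj_min) && sl_obj_min > 0) {
    sl_misperception(sl_subj_min, sl_obj_min)
  } else {
    warning("objective sleep latency is 0 or missing; SLm undefined for this subject")
    NA_real_
  }
  tstm <- tst_misperception(tst_subj_min, tst_obj_min)
  disc <- sl_subj_min - sl_obj_min
  structure(list(slm_pct = slm, tstm_pct = tstm, sl_discrepancy_min = disc,
                 discrepancy_group = if (is.na(disc)) NA_character_
                                     else if (disc > cutoff_min) "HIGH" else "LOW"),
            class = "misperception_indices")
}
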