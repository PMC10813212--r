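#' Stage-transition counts
#'
#' Counts consecutive epoch pairs over the fixed state space
#' `{W, N1, N2, N3, REM}`; self-transitions are included. `counts[a, b]`
#' is the number of `a -> b` pairs.
#'
#' @param seq Character vector of stage labels, length >= 2.
#' @return Object of class `transition_counts`: 5x5 integer matrix
#'   `counts` plus `n_transitions`.
#' @export
transition_counts <- function(seq) {
  seq <- as.character(seq)
  if (length(seq) < 2) stop("need at least 2 epochs to count transitions")
  bad <- !is.na(seq) & !(seq %in% SLEEP_STAGES)
  if (any(bad)) stop("unknown stage token(s): ", paste(unique(seq[bad]), collapse = ", "))
  from <- factor(seq[-length(seq)], levels = SLEEP_STAGES)
  to <- factor(seq[-1], levels = SLEEP_STAGES)
  keep <- !is.na(from) & !is.na(to)
  counts <- table(from[keep], to[keep])
  counts <- matrix(as.integer(counts), 5, 5,
                   dimnames = list(SLEEP_STAGES, SLEEP_STAGES))
  structure(list(counts = counts, n_transitions = sum(counts)),
            class = "transition_counts")
}

#' Maximum-likelihood transition-probability matrix
#'
#' Row-normalizes transition counts. A from-stage that is never visited
#' yields a missing (all-`NA`) row — never a zero-filled one, so that
#' "never left stage a" and "never reached stage a" stay distinguishable.
#'
#' @param counts A [transition_counts()] object.
#' @return Object of class `transition_matrix`: 5x5 `probs` (rows summing
#'   to 1 or all-`NA`), `row_visits` (per-from-stage counts), and
#'   `missing_rows` (logical per row).
#' @export
transition_matrix <- function(counts) {
  stopifnot(inherits(counts, "transition_counts"))
  rs <- rowSums(counts$counts)
  probs <- counts$counts / ifelse(rs > 0, rs, 1)
  probs[rs == 0, ] <- NA_real_
  structure(list(probs = probs, row_visits = rs, missing_rows = rs == 0),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("<transition_matrix> row visits:",
      paste(sprintf("%s=%d", names(x$row_visits), x$row_visits), collapse = " "), "\n")
  print(round(x$probs, 3))
  invisible(x)
}

#' Transition matrix within the subjective sleep-latency window
#'
#' Restricts the hypnogram to `[0, SL_subj)` minutes from bedtime and
#' estimates the stage-transition matrix there — the window in which the
#' subject believed themselves still awake.
#'
#' @param hyp A [hypnogram()] anchored at bedtime.
#' @param diary A [parse_diary()] record for the same night.
#' @return A [transition_matrix()], or `NULL` with a warning when the
#'   window holds fewer than two epochs.
#' @export
subjective_sl_matrix <- function(hyp, diary) {
  sl <- diary$sl_subj_min
  epoch_min <- hyp$epoch_len_s / 60
  if (is.na(sl) || sl < 2 * epoch_min) {
    warning("subjective sleep-latency window shorter than two epochs; no matrix")
    return(NULL)
  }
  win <- restrict_window(hyp, 0, min(sl, hyp_duration_min(hyp)))
  if (length(win) < 2) {
    warning("subjective sleep-latency window shorter than two epochs; no matrix")
    return(NULL)
  }
  transition_matrix(transition_counts(win$stages))
}

#' Compare one transition probability between two groups
#'
#' Extracts `P(from -> to)` per subject (subjects whose `from` row is
#' missing are excluded and counted) and compares the groups with the
#' Mann-Whitney U test including the rank-biserial effect size. Group A is
#' ranked first, so a negative rank-biserial means group A tends to have
#' the smaller probabilities.
#'
#' @param groupA,groupB Lists of [transition_matrix()] objects (`NULL`
#'   entries allowed and excluded).
#' @param from,to Stage labels.
#' @return List of class `transition_comparison`: per-group values, means,
#'   SDs, exclusion counts, and the [mann_whitney()] result.
#' @export
compare_transition <- function(groupA, groupB, from, to) {
  stopifnot(from %in% SLEEP_STAGES, to %in% SLEEP_STAGES)
  pull <- function(g) vapply(g, function(m) {
    if (is.null(m)) return(NA_real_)
    m$probs[from, to]
  }, numeric(1))
  a <- pull(groupA); b <- pull(groupB)
  excl <- c(A = sum(is.na(a)), B = sum(is.na(b)))
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b))
    stop("all '", from, "' rows missing in group ",
         if (!length(a)) "A" else "B")
  test <- mann_whitney(a, b)
  structure(list(from = from, to = to, values_A = a, values_B = b,
                 mean_A = mean(a), sd_A = stats::sd(a),
                 mean_B = mean(b), sd_B = stats::sd(b),
                 excluded = excl, test = test),
            class = "transition_comparison")
}

#' Long-format export of per-subject transition matrices
#'
#' @param mats Named list of [transition_matrix()] objects (names are
#'   subject ids; `NULL` entries skipped).
#' @return Data frame `subject_id, from, to, prob, row_visits, missing`.
#' @export
transitions_long <- function(mats) {
  rows <- lapply(names(mats), function(id) {
    m <- mats[[id]]
    if (is.null(m)) return(NULL)
    expand <- expand.grid(from = SLEEP_STAGES, to = SLEEP_STAGES,
                          stringsAsFactors = FALSE)
    data.frame(subject_id = id, expand,
               prob = m$probs[cbind(expand$from, expand$to)],
               row_visits = m$row_visits[expand$from],
               missing = m$missing_rows[expand$from],
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, Filter(Negate(is.null), rows))
}
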