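# ---------------------------------------------------------------------------
# Behavioral scoring: log-linear d-prime, the RT-penalized continuous trial
# score, and the fMRS-matched windowed performance curve with AUC.
# ---------------------------------------------------------------------------

#' Log-linear adjusted signal-detection summary
#'
#' hit_rate = (hits + 0.5) / (n_congruent + 1), fa_rate = (fas + 0.5) /
#' (n_incongruent + 1); d' = qnorm(hit_rate) - qnorm(fa_rate). The
#' adjustment keeps rates inside (0, 1) so d' is always finite, including
#' perfect scores.
#'
#' @param hits,n_congruent Hit count and number of congruent trials.
#' @param fas,n_incongruent False-alarm count and number of incongruent
#'   trials.
#' @return List `hits`, `misses`, `fas`, `crs`, `hit_rate`, `fa_rate`,
#'   `dprime`.
#' @export
dprime_loglinear <- function(hits, n_congruent, fas, n_incongruent) {
  if (n_congruent <= 0 || n_incongruent <= 0) stop("zero trial totals")
  if (hits < 0 || fas < 0 || hits > n_congruent || fas > n_incongruent) {
    stop("counts must be non-negative and no larger than their totals")
  }
  hr <- (hits + 0.5) / (n_congruent + 1)
  fr <- (fas + 0.5) / (n_incongruent + 1)
  list(hits = hits, misses = n_congruent - hits, fas = fas,
       crs = n_incongruent - fas, hit_rate = hr, fa_rate = fr,
       dprime = stats::qnorm(hr) - stats::qnorm(fr))
}

#' RT-penalized continuous trial score
#'
#' RT is normalized between 400 and 800 ms: RTn = clamp((rt - 400)/400,
#' 0, 1). Hits score 1 - RTn (fast correct responses approach 1);
#' congruent misses score 0; correct rejections score 1; false alarms are
#' RT-penalized at 0.25 x (1 - RTn), so the fastest false alarm scores
#' 0.25 and slower ones less.
#'
#' @param type `"congruent"` or `"incongruent"` (vectorized).
#' @param responded Logical.
#' @param rt_ms RT in ms (NA for non-responses).
#' @param hit_floor Lower bound for hit scores (default 0: an 800 ms-or-
#'   slower correct response ties a miss).
#' @return Numeric scores in [0, 1].
#' @export
score_trial <- function(type, responded, rt_ms = NA_real_, hit_floor = 0) {
  n <- max(length(type), length(responded), length(rt_ms))
  type <- rep_len(as.character(type), n)
  responded <- rep_len(as.logical(responded), n)
  rt_ms <- rep_len(as.numeric(rt_ms), n)
  if (any(responded & (is.na(rt_ms)))) stop("responded trials need an RT")
  if (any(responded & rt_ms < 0)) stop("negative RT")
  rtn <- pmin(pmax((rt_ms - 400) / 400, 0), 1)
  score <- numeric(n)
  hit <- type == "congruent" & responded
  miss <- type == "congruent" & !responded
  fa <- type == "incongruent" & responded
  cr <- type == "incongruent" & !responded
  score[hit] <- pmax(1 - rtn[hit], hit_floor)
  score[miss] <- 0
  score[cr] <- 1
  score[fa] <- 0.25 * (1 - rtn[fa])
  score
}

#' Score a whole trial table
#'
#' @param trials Data.frame `trial block type responded rt_ms`.
#' @param design The [session_design()] used to compute trial onset times
#'   (trial t starts at (t - 1) x (stimulus + ISI) seconds, blocks
#'   concatenated).
#' @param hit_floor Passed to [score_trial()].
#' @return The table with `score` and `time_s` columns added.
#' @export
score_trials <- function(trials, design, hit_floor = 0) {
  trials$score <- score_trial(trials$type, trials$responded, trials$rt_ms,
                              hit_floor = hit_floor)
  step <- design$stim_duration_s + design$isi_s
  trials$time_s <- (trials$trial - 1) * step
  trials
}

#' fMRS-matched windowed performance curve and AUC
#'
#' The fMRS window grid is mapped proportionally onto the behavioral
#' timeline; each window's score is the mean over trials starting inside
#' it (empty windows carry the previous window's value forward with a
#' warning). The AUC is the trapezoidal integral of (curve - curve[1]).
#'
#' @param scored Output of [score_trials()].
#' @param grid The session's [window_indices()] grid.
#' @param design The [session_design()].
#' @return List `curve` (data.frame `window`, `mean_score`), `auc`.
#' @export
windowed_performance_auc <- function(scored, grid, design) {
  stopifnot(inherits(grid, "window_grid"))
  total_s <- design$n_blocks * design$trials_per_block *
    (design$stim_duration_s + design$isi_s)
  w <- grid$windows
  # proportional time mapping from pair indices to the behavioral timeline
  t_start <- (w$start - 1) / grid$n_pairs * total_s
  t_end <- w$end / grid$n_pairs * total_s
  means <- rep(NA_real_, nrow(w))
  for (i in seq_len(nrow(w))) {
    sel <- scored$time_s >= t_start[i] & scored$time_s < t_end[i]
    if (!any(sel)) {
      if (i == 1) stop("first window contains no trials")
      warning("window ", i, " contains no trials; carrying previous value")
      means[i] <- means[i - 1]
    } else {
      means[i] <- mean(scored$score[sel])
    }
  }
  curve <- data.frame(window = seq_len(nrow(w)), mean_score = means)
  list(curve = curve,
       auc = pracma::trapz(seq_along(means), means - means[1]))
}
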