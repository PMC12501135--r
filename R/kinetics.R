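# ---------------------------------------------------------------------------
# Sliding-window concentration curves ("dynamic frames"): window enumeration,
# outlier interpolation, baseline normalization, AUC, static concentrations.
# ---------------------------------------------------------------------------

#' Enumerate sliding windows over ON/OFF pairs
#'
#' Windows of `window_pairs` pairs shifted by `step_pairs` (60/3 by default:
#' 4 min frames shifted 12 s at TR = 2 s). With `target_frames` given,
#' leading pairs are trimmed so that exactly `target_frames` windows fit
#' flush with the session end: trim = n_pairs - (window + (target-1) * step).
#' 112 task pairs yield 18 frames; trimming 3 of 96 rest pairs yields 12.
#'
#' @param n_pairs Number of ON/OFF pairs in the session.
#' @param window_pairs,step_pairs Window length and shift in pairs.
#' @param target_frames Optional required number of windows.
#' @return A `window_grid` list: `windows` data.frame (`start`, `end`,
#'   inclusive 1-based pair indices), `n_pairs`, `window_pairs`,
#'   `step_pairs`, `trim_leading_pairs`, `n_windows`.
#' @export
window_indices <- function(n_pairs, window_pairs = 60, step_pairs = 3,
                           target_frames = NULL) {
  n_pairs <- as.integer(n_pairs)
  if (n_pairs < window_pairs) {
    stop("n_pairs (", n_pairs, ") smaller than window length ", window_pairs)
  }
  if (is.null(target_frames)) {
    trim <- 0L
  } else {
    span <- window_pairs + (target_frames - 1L) * step_pairs
    trim <- n_pairs - as.integer(span)
    if (trim < 0) {
      max_frames <- (n_pairs - window_pairs) %/% step_pairs + 1L
      stop("target_frames = ", target_frames, " unachievable; at most ",
           max_frames, " windows fit in ", n_pairs, " pairs")
    }
  }
  starts <- seq.int(trim + 1L, n_pairs - window_pairs + 1L, by = step_pairs)
  if (!is.null(target_frames)) starts <- starts[seq_len(target_frames)]
  grid <- structure(list(
    windows = data.frame(start = starts, end = starts + window_pairs - 1L),
    n_pairs = n_pairs, window_pairs = as.integer(window_pairs),
    step_pairs = as.integer(step_pairs), trim_leading_pairs = trim,
    n_windows = length(starts)), class = "window_grid")
  grid
}

#' Median interpolation of outlier frames
#'
#' Frames deviating from the curve median by more than `z` robust SDs
#' (1.4826 x MAD) are replaced by the median of their two neighbors (single
#' neighbor at the endpoints). Idempotent on the cleaned curve.
#'
#' @param x Numeric curve.
#' @param z Threshold in robust SDs (default 2).
#' @return List with `values` and logical `mask` of replaced frames.
#' @export
interpolate_outliers <- function(x, z = 2.0) {
  med <- stats::median(x)
  rsd <- 1.4826 * stats::mad(x, constant = 1)
  if (!is.finite(rsd) || rsd == 0) {
    return(list(values = x, mask = rep(FALSE, length(x))))
  }
  mask <- abs(x - med) > z * rsd
  out <- x
  n <- length(x)
  for (i in which(mask)) {
    nb <- c(if (i > 1) x[i - 1], if (i < n) x[i + 1])
    out[i] <- stats::median(nb)
  }
  list(values = out, mask = mask)
}

#' Sliding-window EIB concentration curve
#'
#' Builds per-window GABA+, Glx and EIB estimates. In spectral mode the ON
#' and OFF spectra of each window are averaged, differenced, peak-fitted and
#' water/tissue-quantified; in concentration mode the per-pair values are
#' averaged directly. EIB is computed per frame from that frame's Glx and
#' GABA+ (never from the normalized curves), outliers are median-interpolated
#' per curve, and each curve is then divided by its first frame.
#'
#' @param session An `edited_session`, or a data.frame of per-pair
#'   concentrations with columns `glx` and `gaba`.
#' @param grid A [window_indices()] grid consistent with the session length.
#' @param outlier_z Outlier threshold in robust SDs.
#' @param mm_correct Passed to [quantify_concentration()] (spectral mode).
#' @return A `concentration_curve` list: `frames` data.frame (`frame`,
#'   `gaba`, `glx`, `eib`, `gaba_norm`, `glx_norm`, `eib_norm`, `outlier`),
#'   `condition`, `auc` (AUC of the normalized EIB curve), `grid`.
#' @export
eib_curve <- function(session, grid, outlier_z = 2.0, mm_correct = FALSE) {
  stopifnot(inherits(grid, "window_grid"))
  w <- grid$windows
  if (max(w$end) > .session_n_pairs(session)) {
    stop("window grid extends beyond the session length")
  }
  if (inherits(session, "edited_session")) {
    condition <- session$design$condition
    water_area <- water_reference_area(session$water)
    vals <- lapply(seq_len(nrow(w)), function(i) {
      idx <- w$start[i]:w$end[i]
      d <- difference_spectrum(average_spectra(session$on[idx], "ON"),
                               average_spectra(session$off[idx], "OFF"))
      fit <- fit_diff_spectrum(d)
      conc <- quantify_concentration(fit, water_area, session$tissue,
                                     mm_correct = mm_correct)
      c(gaba = conc$gaba_plus, glx = conc$glx, eib = conc$eib)
    })
    m <- do.call(rbind, vals)
  } else {
    df <- as.data.frame(session)
    condition <- attr(session, "condition") %||% "unknown"
    m <- t(vapply(seq_len(nrow(w)), function(i) {
      idx <- w$start[i]:w$end[i]
      g <- mean(df$gaba[idx]); x <- mean(df$glx[idx])
      c(gaba = g, glx = x, eib = x / g)
    }, c(gaba = 0, glx = 0, eib = 0)))
  }
  gaba <- interpolate_outliers(m[, "gaba"], outlier_z)
  glx <- interpolate_outliers(m[, "glx"], outlier_z)
  eib <- interpolate_outliers(m[, "eib"], outlier_z)
  norm1 <- function(v) {
    if (v[1] <= 0) stop("normalization error: first-frame value <= 0")
    v / v[1]
  }
  frames <- data.frame(frame = seq_len(nrow(m)),
                       gaba = gaba$values, glx = glx$values,
                       eib = eib$values,
                       gaba_norm = norm1(gaba$values),
                       glx_norm = norm1(glx$values),
                       eib_norm = norm1(eib$values),
                       outlier = eib$mask)
  curve <- structure(list(frames = frames, condition = condition,
                          grid = grid), class = "concentration_curve")
  curve$auc <- curve_auc(curve)
  curve
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.session_n_pairs <- function(session) {
  if (inherits(session, "edited_session")) length(session$on) else {
    nrow(as.data.frame(session))
  }
}

#' Area under a baseline-normalized curve
#'
#' Trapezoidal integral of (normalized - 1) with unit frame spacing; a flat
#' curve scores 0 and a net increase above baseline is positive.
#'
#' @param curve A `concentration_curve`, or a numeric normalized curve.
#' @param what Which normalized curve to integrate (default `"eib_norm"`).
#' @return Numeric AUC.
#' @export
curve_auc <- function(curve, what = "eib_norm") {
  y <- if (inherits(curve, "concentration_curve")) {
    curve$frames[[what]]
  } else as.numeric(curve)
  if (length(y) < 2) stop("need at least 2 frames")
  pracma::trapz(seq_along(y), y - 1)
}

#' Static per-session concentration
#'
#' Averages all ON and all OFF spectra of a session, fits the single
#' difference spectrum and quantifies it; the resting-state value serves as
#' the subject-specific baseline.
#'
#' @param session An `edited_session`.
#' @param mm_correct Passed to [quantify_concentration()].
#' @return A `concentration` with attribute `baseline` set to TRUE for the
#'   rest condition.
#' @export
static_concentration <- function(session, mm_correct = FALSE) {
  stopifnot(inherits(session, "edited_session"))
  d <- difference_spectrum(average_spectra(session$on, "ON"),
                           average_spectra(session$off, "OFF"))
  fit <- fit_diff_spectrum(d)
  conc <- quantify_concentration(fit, water_reference_area(session$water),
                                 session$tissue, mm_correct = mm_correct)
  attr(conc, "baseline") <- session$design$condition == "rest"
  conc
}
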