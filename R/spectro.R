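# ---------------------------------------------------------------------------
# Edited-spectrum processing: difference spectra, frequency alignment, peak
# fitting, water-referenced tissue-corrected quantification, QC exclusion.
# ---------------------------------------------------------------------------

#' Construct a spectrum
#'
#' @param ppm Strictly monotone ppm axis.
#' @param intensity Intensities, same length as `ppm`.
#' @param kind One of `"ON"`, `"OFF"`, `"DIFF"`, `"WATER"`.
#' @return A `spectrum` list with the stored axis direction recorded.
#' @export
spectrum <- function(ppm, intensity, kind = c("ON", "OFF", "DIFF", "WATER")) {
  kind <- match.arg(kind)
  if (length(ppm) != length(intensity)) {
    stop("ppm and intensity must have equal lengths")
  }
  d <- diff(ppm)
  if (!(all(d > 0) || all(d < 0))) stop("ppm axis must be strictly monotone")
  structure(list(ppm = as.numeric(ppm), intensity = as.numeric(intensity),
                 kind = kind,
                 direction = if (d[1] > 0) "increasing" else "decreasing"),
            class = "spectrum")
}

#' ON - OFF difference spectrum
#'
#' @param on,off `spectrum` objects on identical ppm axes.
#' @return A `spectrum` of kind `"DIFF"`.
#' @export
difference_spectrum <- function(on, off) {
  stopifnot(inherits(on, "spectrum"), inherits(off, "spectrum"))
  if (length(on$ppm) != length(off$ppm) ||
      max(abs(on$ppm - off$ppm)) > 0) {
    stop("alignment error: ON and OFF ppm axes differ")
  }
  spectrum(on$ppm, on$intensity - off$intensity, "DIFF")
}

.noise_sd <- function(spec, noise_region = c(9, 10)) {
  idx <- spec$ppm >= noise_region[1] & spec$ppm <= noise_region[2]
  if (!any(idx)) return(NA_real_)
  stats::sd(spec$intensity[idx])
}

#' Align spectra by integer-grid cross-correlation
#'
#' Shifts each spectrum along the ppm axis (within +/- `max_shift_ppm`,
#' integer grid steps) to maximize its cross-correlation with the first
#' spectrum; ties are broken toward zero shift. Spectra whose maximum
#' amplitude is below 3x the noise SD (no detectable reference peak) get a
#' warning and zero shift.
#'
#' @param spectra List of `spectrum` objects on a common axis.
#' @param reference_ppm Center of the correlation window (default 3.0 ppm,
#'   window +/- 0.5 ppm).
#' @param max_shift_ppm Maximum allowed shift (default 0.1 ppm).
#' @return List with `spectra` (aligned) and `shifts_ppm`.
#' @export
align_spectra <- function(spectra, reference_ppm = 3.0, max_shift_ppm = 0.1) {
  stopifnot(length(spectra) >= 1)
  ref <- spectra[[1]]
  dppm <- abs(stats::median(diff(ref$ppm)))
  max_steps <- floor(max_shift_ppm / dppm)
  win <- which(abs(ref$ppm - reference_ppm) <= 0.5)
  ref_int <- ref$intensity[win]
  shifts <- numeric(length(spectra))
  out <- spectra
  for (i in seq_along(spectra)) {
    s <- spectra[[i]]
    nsd <- .noise_sd(s)
    if (is.finite(nsd) && nsd > 0 && max(abs(s$intensity[win])) < 3 * nsd) {
      warning("no detectable reference peak in spectrum ", i,
              "; zero shift applied")
      shifts[i] <- 0
      next
    }
    cand <- -max_steps:max_steps
    score <- vapply(cand, function(k) {
      idx <- win + k
      ok <- idx >= 1 & idx <= length(s$intensity)
      sum(ref_int[ok] * s$intensity[idx[ok]])
    }, 0)
    best <- max(score)
    # ties toward zero shift
    ties <- cand[score >= best - 1e-12 * max(1, abs(best))]
    k <- ties[which.min(abs(ties))]
    shifts[i] <- -k * sign(ref$ppm[2] - ref$ppm[1]) * dppm
    if (k != 0) {
      n <- length(s$intensity)
      shifted <- rep(0, n)
      src <- seq_len(n) + k
      ok <- src >= 1 & src <= n
      shifted[ok] <- s$intensity[src[ok]]
      out[[i]] <- spectrum(s$ppm, shifted, s$kind)
    }
  }
  list(spectra = out, shifts_ppm = shifts)
}

#' Average a list of spectra pointwise
#' @param spectra List of `spectrum` objects on identical axes.
#' @param kind Kind label of the result.
#' @return A `spectrum`.
#' @export
average_spectra <- function(spectra, kind = spectra[[1]]$kind) {
  int <- rowMeans(vapply(spectra, function(s) s$intensity,
                         numeric(length(spectra[[1]]$intensity))))
  spectrum(spectra[[1]]$ppm, int, kind)
}

.fit_window <- function(spec, lo, hi) {
  idx <- spec$ppm >= lo & spec$ppm <= hi
  list(x = spec$ppm[idx], y = spec$intensity[idx])
}

#' Fit GABA+ and Glx peaks in a difference spectrum
#'
#' Nonlinear least squares of a single Gaussian plus linear baseline over
#' 2.8-3.2 ppm (GABA+) and a two-Gaussian doublet (fixed 0.08 ppm split,
#' shared width) plus linear baseline over 3.55-3.95 ppm (Glx). Areas are
#' the analytic Gaussian integrals of the fitted parameters. Fit error is
#' 100 x SD(residual)/amplitude; SNR is amplitude / (2 x SD of the 9-10 ppm
#' noise region). Non-convergence yields a flagged result with infinite fit
#' error, never an exception.
#'
#' @param diff A `spectrum` of kind `"DIFF"` covering 2.6-4.2 ppm and a
#'   noise region.
#' @param noise_region ppm range used for the SNR denominator.
#' @param glx_split_ppm Fixed doublet split.
#' @return A `fit_result` list: `gaba_area`, `glx_area`,
#'   `gaba_fit_error_pct`, `glx_fit_error_pct`, `gaba_snr`, `glx_snr`,
#'   `converged`.
#' @export
fit_diff_spectrum <- function(diff, noise_region = c(9, 10),
                              glx_split_ppm = 0.08) {
  stopifnot(inherits(diff, "spectrum"))
  nsd <- .noise_sd(diff, noise_region)
  flagged <- list(gaba_area = 0, glx_area = 0,
                  gaba_fit_error_pct = Inf, glx_fit_error_pct = Inf,
                  gaba_snr = 0, glx_snr = 0, converged = FALSE)
  class(flagged) <- "fit_result"

  gw <- .fit_window(diff, 2.8, 3.2)
  g_fit <- tryCatch({
    a0 <- max(gw$y) - stats::median(gw$y)
    fit <- minpack.lm::nlsLM(
      y ~ a * exp(-(x - c0)^2 / (2 * s0^2)) + m * x + b,
      data = gw,
      start = list(a = max(a0, 1e-6), c0 = 3.0, s0 = 0.045,
                   m = 0, b = stats::median(gw$y)),
      lower = c(a = -Inf, c0 = 2.85, s0 = 0.01, m = -Inf, b = -Inf),
      upper = c(a = Inf, c0 = 3.15, s0 = 0.2, m = Inf, b = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- stats::coef(fit)
    list(amp = unname(cf["a"]), sd = unname(cf["s0"]),
         res_sd = stats::sd(stats::residuals(fit)))
  }, error = function(e) NULL)

  xw <- .fit_window(diff, 3.55, 3.95)
  half <- glx_split_ppm / 2
  x_fit <- tryCatch({
    a0 <- (max(xw$y) - stats::median(xw$y))
    fit <- minpack.lm::nlsLM(
      y ~ a1 * exp(-(x - (c0 - half))^2 / (2 * s0^2)) +
        a2 * exp(-(x - (c0 + half))^2 / (2 * s0^2)) + m * x + b,
      data = xw,
      start = list(a1 = max(a0, 1e-6), a2 = max(a0, 1e-6), c0 = 3.75,
                   s0 = 0.04, m = 0, b = stats::median(xw$y)),
      lower = c(a1 = -Inf, a2 = -Inf, c0 = 3.65, s0 = 0.01,
                m = -Inf, b = -Inf),
      upper = c(a1 = Inf, a2 = Inf, c0 = 3.85, s0 = 0.15,
                m = Inf, b = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- stats::coef(fit)
    list(a1 = unname(cf["a1"]), a2 = unname(cf["a2"]),
         sd = unname(cf["s0"]), res_sd = stats::sd(stats::residuals(fit)))
  }, error = function(e) NULL)

  if (is.null(g_fit) && is.null(x_fit)) return(flagged)

  sqrt2pi <- sqrt(2 * pi)
  gaba_area <- if (is.null(g_fit)) 0 else g_fit$amp * g_fit$sd * sqrt2pi
  glx_amp <- if (is.null(x_fit)) 0 else max(x_fit$a1, x_fit$a2)
  glx_area <- if (is.null(x_fit)) 0 else {
    (x_fit$a1 + x_fit$a2) * x_fit$sd * sqrt2pi
  }
  res <- list(
    gaba_area = max(gaba_area, 0),
    glx_area = max(glx_area, 0),
    gaba_fit_error_pct = if (is.null(g_fit)) Inf else {
      100 * g_fit$res_sd / abs(g_fit$amp)
    },
    glx_fit_error_pct = if (is.null(x_fit)) Inf else {
      100 * x_fit$res_sd / abs(glx_amp)
    },
    gaba_snr = if (is.null(g_fit) || !is.finite(nsd) || nsd == 0) 0 else {
      abs(g_fit$amp) / (2 * nsd)
    },
    glx_snr = if (is.null(x_fit) || !is.finite(nsd) || nsd == 0) 0 else {
      abs(glx_amp) / (2 * nsd)
    },
    converged = !is.null(g_fit) && !is.null(x_fit))
  class(res) <- "fit_result"
  res
}

#' Integrated area of a water reference spectrum
#' @param water A `spectrum` of kind `"WATER"`.
#' @return Numeric area by trapezoidal integration over the ppm axis.
#' @export
water_reference_area <- function(water) {
  stopifnot(inherits(water, "spectrum"))
  abs(pracma::trapz(water$ppm, water$intensity))
}

#' Tissue fractions of the MRS voxel
#' @param f_gm,f_wm,f_csf Gray matter, white matter and CSF fractions;
#'   must sum to 1 within 1e-6.
#' @return A `tissue_fractions` list.
#' @export
tissue_fractions <- function(f_gm, f_wm, f_csf) {
  if (any(c(f_gm, f_wm, f_csf) < 0) || abs(f_gm + f_wm + f_csf - 1) > 1e-6) {
    stop("tissue fractions must be non-negative and sum to 1")
  }
  structure(list(f_gm = f_gm, f_wm = f_wm, f_csf = f_csf),
            class = "tissue_fractions")
}

#' Water-referenced, tissue-corrected concentrations
#'
#' conc = (area / water_area) * W_pure * (f_gm w_gm + f_wm w_wm + f_csf
#' w_csf) / (1 - f_csf), with pure-water concentration W_pure = 55556 mM and
#' relative water visibilities 0.78 (GM), 0.65 (WM), 0.97 (CSF). EIB is the
#' Glx / GABA+ ratio; the optional macromolecule correction multiplies GABA+
#' by 0.55 (45% of the edited GABA+ peak area attributed to co-edited MM).
#'
#' @param fit A `fit_result`.
#' @param water_area Positive water reference area.
#' @param fractions A [tissue_fractions()].
#' @param mm_correct Also report MM-corrected GABA.
#' @return A `concentration` list: `gaba_plus`, `glx`, `eib`, optionally
#'   `mm_corrected_gaba`.
#' @export
quantify_concentration <- function(fit, water_area, fractions,
                                   mm_correct = FALSE) {
  stopifnot(inherits(fractions, "tissue_fractions"))
  if (!is.numeric(water_area) || water_area <= 0) {
    stop("water_area must be positive")
  }
  w_pure <- 55556
  vis <- fractions$f_gm * 0.78 + fractions$f_wm * 0.65 +
    fractions$f_csf * 0.97
  scale <- w_pure * vis / (1 - fractions$f_csf)
  gaba <- fit$gaba_area / water_area * scale
  glx <- fit$glx_area / water_area * scale
  if (gaba <= 0) stop("EIB undefined: non-positive GABA+ area")
  out <- list(gaba_plus = gaba, glx = glx, eib = glx / gaba)
  if (mm_correct) out$mm_corrected_gaba <- 0.55 * gaba
  structure(out, class = "concentration")
}

#' Quality-control exclusion by group z-scores
#'
#' Each (subject, session, metric) quality value is standardized per metric
#' against the pooled group distribution; a cell is flagged when |z| >= 1 and
#' a subject is excluded when it accrues two or more flagged cells (two
#' different metrics, or the same metric in two sessions).
#'
#' @param metrics Data.frame with columns `subject`, `session`, `metric`,
#'   `value`.
#' @param z_threshold Flagging threshold on |z| (default 1).
#' @param n_flags_exclude Flag count triggering exclusion (default 2).
#' @return Data.frame `subject`, `n_flagged`, `exclude`.
#' @export
qc_exclusion <- function(metrics, z_threshold = 1, n_flags_exclude = 2) {
  need <- c("subject", "session", "metric", "value")
  if (!all(need %in% names(metrics))) {
    stop("metrics needs columns subject, session, metric, value")
  }
  if (length(unique(metrics$subject)) < 3) {
    stop("z-scores undefined with fewer than 3 subjects")
  }
  z <- stats::ave(metrics$value, metrics$metric,
                  FUN = function(v) (v - mean(v)) / stats::sd(v))
  flagged <- abs(z) >= z_threshold
  n_flagged <- tapply(flagged, metrics$subject, sum)
  subjects <- names(n_flagged)
  data.frame(subject = subjects,
             n_flagged = as.integer(n_flagged),
             exclude = as.integer(n_flagged) >= n_flags_exclude,
             row.names = NULL)
}
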