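make_gauss_spec <- function(amp, center, sd, kind = "DIFF",
                            ppm = seq(10.5, 0.5, length.out = 1024),
                            baseline = 0) {
  spectrum(ppm, amp * exp(-(ppm - center)^2 / (2 * sd^2)) + baseline, kind)
}

test_that("difference spectrum is pointwise ON - OFF", {
  on <- make_gauss_spec(1, 3.0, 0.05, "ON")
  off <- spectrum(on$ppm, rep(0, length(on$ppm)), "OFF")
  d <- difference_spectrum(on, off)
  expect_equal(d$intensity, on$intensity)
  expect_identical(d$kind, "DIFF")
  d0 <- difference_spectrum(on, spectrum(on$ppm, on$intensity, "OFF"))
  expect_true(all(d0$intensity == 0))
  off_bad <- spectrum(on$ppm + 0.01, on$intensity, "OFF")
  expect_error(difference_spectrum(on, off_bad), "axes differ")
})

test_that("alignment recovers a constructed grid shift and is idempotent", {
  ppm <- seq(10.5, 0.5, length.out = 1001)   # 0.01 ppm grid
  ref <- make_gauss_spec(10, 3.0, 0.05, "ON", ppm = ppm)
  shifted <- make_gauss_spec(10, 3.02, 0.05, "ON", ppm = ppm)
  res <- align_spectra(list(ref, shifted))
  expect_equal(res$shifts_ppm[1], 0)
  expect_equal(abs(res$shifts_ppm[2]), 0.02, tolerance = 1e-9)
  # shifted spectrum now matches the reference at the peak
  expect_equal(which.max(res$spectra[[2]]$intensity),
               which.max(ref$intensity))
  res2 <- align_spectra(res$spectra)
  expect_equal(res2$shifts_ppm, c(0, 0))
})

test_that("featureless spectra get a warning and zero shift", {
  ppm <- seq(10.5, 0.5, length.out = 1001)
  ref <- make_gauss_spec(10, 3.0, 0.05, "ON", ppm = ppm)
  set.seed(1)
  noise <- spectrum(ppm, rnorm(length(ppm), 0, 1), "ON")
  expect_warning(res <- align_spectra(list(ref, noise)), "reference peak")
  expect_equal(res$shifts_ppm[2], 0)
})

test_that("fitted areas match the analytic Gaussian integral", {
  ppm <- seq(10.5, 0.5, length.out = 1024)
  gaba <- 2 * exp(-(ppm - 3.0)^2 / (2 * 0.05^2))
  glx <- 1.5 * exp(-(ppm - 3.71)^2 / (2 * 0.04^2)) +
    1.5 * exp(-(ppm - 3.79)^2 / (2 * 0.04^2))
  d <- spectrum(ppm, gaba + glx, "DIFF")
  f <- fit_diff_spectrum(d)
  expect_true(f$converged)
  expect_equal(f$gaba_area, 2 * 0.05 * sqrt(2 * pi), tolerance = 1e-3)
  expect_equal(f$glx_area, 2 * 1.5 * 0.04 * sqrt(2 * pi), tolerance = 1e-3)
  # scaling intensities scales areas, leaves the relative fit error alone
  d2 <- spectrum(d$ppm, 3 * d$intensity, "DIFF")
  f2 <- fit_diff_spectrum(d2)
  expect_equal(f2$gaba_area / f$gaba_area, 3, tolerance = 1e-6)
})

test_that("pure-noise spectra are flagged, not fitted silently", {
  set.seed(8)
  ppm <- seq(10.5, 0.5, length.out = 1024)
  d <- spectrum(ppm, rnorm(length(ppm), 0, 1), "DIFF")
  f <- fit_diff_spectrum(d)
  # amplitude is on the noise scale, so SNR sits near amp / (2 sd) ~ O(1)
  expect_lt(f$gaba_snr, 3)
  expect_gt(f$gaba_fit_error_pct, 10)
})

test_that("quantification is a pure ratio scaled by tissue constants", {
  fr <- tissue_fractions(0.6, 0.4, 0)
  fit <- structure(list(gaba_area = 2, glx_area = 2), class = "fit_result")
  c1 <- quantify_concentration(fit, water_area = 100, fr)
  expect_equal(c1$eib, 1)
  c2 <- quantify_concentration(fit, water_area = 1000, fr)
  expect_equal(c2$eib, 1)                      # water scaling cancels in EIB
  expect_equal(c1$gaba_plus / c2$gaba_plus, 10) # degree -1 in water area
  fit2 <- structure(list(gaba_area = 4, glx_area = 4), class = "fit_result")
  c3 <- quantify_concentration(fit2, water_area = 100, fr)
  expect_equal(c3$gaba_plus / c1$gaba_plus, 2)  # degree 1 in areas
  expect_equal(c3$eib, 1)
})

test_that("macromolecule correction multiplies GABA+ by 0.55", {
  fr <- tissue_fractions(0.6, 0.4, 0)
  fit <- structure(list(gaba_area = 2, glx_area = 2), class = "fit_result")
  cc <- quantify_concentration(fit, 100, fr, mm_correct = TRUE)
  expect_equal(cc$mm_corrected_gaba, 0.55 * cc$gaba_plus)
  bad <- structure(list(gaba_area = 0, glx_area = 1), class = "fit_result")
  expect_error(quantify_concentration(bad, 100, fr), "EIB undefined")
})

test_that("tissue fractions must be a unit simplex", {
  expect_error(tissue_fractions(0.5, 0.4, 0.2), "sum to 1")
  expect_silent(tissue_fractions(0.6, 0.35, 0.05))
})

test_that("QC exclusion flags by |z| >= 1 cells and is order-invariant", {
  # 8 subjects, 2 sessions, 2 metrics; balanced +/-0.1 background pattern
  # keeps every clean cell at |z| < 1 while a deviant value dominates
  base <- expand.grid(subject = paste0("s", 1:8),
                      session = c("a", "b"),
                      metric = c("gaba_snr", "gaba_fit"),
                      stringsAsFactors = FALSE)
  base$value <- 10 + rep(c(0.1, -0.1), length.out = nrow(base))
  hit <- function(df, sub, ses, met, v) {
    df$value[df$subject == sub & df$session == ses & df$metric == met] <- v
    df
  }
  # two metrics flagged within one session -> excluded
  m1 <- hit(hit(base, "s1", "a", "gaba_snr", 30), "s1", "a", "gaba_fit", 30)
  r1 <- qc_exclusion(m1)
  expect_true(r1$exclude[r1$subject == "s1"])
  # exactly one flagged cell -> retained
  m2 <- hit(base, "s2", "a", "gaba_snr", 30)
  r2 <- qc_exclusion(m2)
  expect_false(r2$exclude[r2$subject == "s2"])
  # same metric flagged in two sessions -> excluded
  m3 <- hit(hit(base, "s3", "a", "gaba_snr", 30), "s3", "b", "gaba_snr", 30)
  r3 <- qc_exclusion(m3)
  expect_true(r3$exclude[r3$subject == "s3"])
  # invariance to row ordering
  shuf <- m3[sample(nrow(m3)), ]
  r3b <- qc_exclusion(shuf)
  expect_equal(r3b[order(r3b$subject), ], r3[order(r3$subject), ],
               ignore_attr = TRUE)
  expect_error(qc_exclusion(m3[m3$subject %in% c("s1", "s2"), ]),
               "fewer than 3")
})
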