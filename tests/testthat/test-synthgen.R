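test_that("metabolite series reproduces flat truth exactly and is seeded", {
  des <- session_design("0back")
  prof <- kinetic_profile("0back", glx_shape = function(t) 1,
                          gaba_shape = function(t) 1,
                          noise_sd = 0, outlier_rate = 0, seed = 11)
  s <- simulate_metabolite_series(prof, des)
  expect_equal(nrow(s), 112)
  expect_equal(s$glx, rep(prof$baseline_glx, 112))
  expect_equal(s$gaba, rep(prof$baseline_gaba, 112))
  # pair k's midpoint is (k - 0.5) * 4 s
  expect_equal(s$time_s, (seq_len(112) - 0.5) * 4)

  prof2 <- kinetic_profile("0back", noise_sd = 0.05, outlier_rate = 0.05,
                           seed = 42)
  expect_identical(simulate_metabolite_series(prof2, des),
                   simulate_metabolite_series(prof2, des))
})

test_that("a step in the glx shape lands on the stated pairs", {
  des <- session_design("rest")
  step_shape <- function(t) if (t > 30 * 4) 1.1 else 1.0
  prof <- kinetic_profile("rest", glx_shape = step_shape,
                          gaba_shape = function(t) 1,
                          noise_sd = 0, outlier_rate = 0, seed = 1)
  s <- simulate_metabolite_series(prof, des)
  expect_equal(s$glx[1:30], rep(prof$baseline_glx, 30))
  expect_equal(s$glx[31:96], rep(1.1 * prof$baseline_glx, 66))
})

test_that("non-positive shapes raise an invalid-profile error", {
  des <- session_design("rest")
  prof <- kinetic_profile("rest", glx_shape = function(t) -1,
                          noise_sd = 0, outlier_rate = 0)
  expect_error(simulate_metabolite_series(prof, des), "invalid profile")
})

test_that("edited DIFF spectra carry the configured Gaussian areas", {
  ses <- make_tiny_session(n_pairs = 2, glx = 1, gaba = 1)
  d <- difference_spectrum(ses$on[[1]], ses$off[[1]])
  # numeric integral of the GABA+ region equals area-per-unit (a w sqrt(2pi))
  idx <- d$ppm >= 2.7 & d$ppm <= 3.3
  gaba_area <- abs(pracma::trapz(d$ppm[idx], d$intensity[idx]))
  expect_equal(gaba_area, 1.0, tolerance = 1e-6)
  # OFF contains no 3.0 ppm peak, so DIFF = ON there
  at3 <- which.min(abs(d$ppm - 3.0))
  expect_equal(d$intensity[at3], ses$on[[1]]$intensity[at3])
  expect_lt(abs(ses$off[[1]]$intensity[at3]), 1e-6)
})

test_that("doubling concentrations doubles fitted areas", {
  s1 <- make_tiny_session(glx = 5, gaba = 1)
  s2 <- make_tiny_session(glx = 10, gaba = 2)
  f1 <- fit_diff_spectrum(difference_spectrum(s1$on[[1]], s1$off[[1]]))
  f2 <- fit_diff_spectrum(difference_spectrum(s2$on[[1]], s2$off[[1]]))
  expect_equal(f2$gaba_area / f1$gaba_area, 2, tolerance = 1e-4)
  expect_equal(f2$glx_area / f1$glx_area, 2, tolerance = 1e-4)
})

test_that("non-monotone ppm axes are rejected", {
  expect_error(spectrum(c(1, 2, 2), c(0, 0, 0), "ON"), "monotone")
  des <- session_design("rest", n_on_off_pairs = 2)
  series <- data.frame(glx = c(1, 1), gaba = c(1, 1))
  expect_error(simulate_edited_session(series, peak_params(), des,
                                       ppm = c(1, 3, 2)), "monotone")
})

test_that("BOLD generator recovers its own states when noiseless", {
  dims <- c(5, 5, 5)
  set.seed(3)
  patterns <- c(list(array(0, dims)),
                lapply(1:2, function(m) array(rnorm(prod(dims)), dims)))
  P <- cap_transition_matrix(2, p00 = 0.4, self = 0.4, exit0 = 0.3)
  model <- markov_state_model(P, patterns, emission_noise_sd = 0, seed = 9)
  bold <- simulate_bold_session(model, 50, seed_boost = 0)
  # frame-wise nearest-pattern assignment recovers the path exactly
  mat <- matrix(bold$volume, nrow = prod(dims))
  pm <- cbind(as.vector(patterns[[1]]), as.vector(patterns[[2]]),
              as.vector(patterns[[3]]))
  rec <- apply(mat, 2, function(fr) {
    which.min(colSums((pm - fr)^2)) - 1L
  })
  expect_identical(as.integer(rec), bold$states)
})

test_that("identity transition matrix freezes the state path", {
  dims <- c(3, 3, 3)
  patterns <- list(array(0, dims), array(1, dims))
  model <- markov_state_model(diag(2), patterns, emission_noise_sd = 0,
                              seed = 5)
  bold <- simulate_bold_session(model, 20, init_state = 1L, seed_boost = 0)
  expect_identical(bold$states, rep(1L, 20))
})

test_that("empirical self-transitions match the chain probability", {
  dims <- c(3, 3, 3)
  p <- 0.8
  patterns <- list(array(0, dims), array(1, dims))
  P <- matrix(c(p, 1 - p, 1 - p, p), 2, byrow = TRUE)
  model <- markov_state_model(P, patterns, emission_noise_sd = 0, seed = 21)
  n <- 10000
  bold <- simulate_bold_session(model, n, seed_boost = 0)
  frac <- mean(bold$states[-1] == bold$states[-n])
  se <- sqrt(p * (1 - p) / (n - 1))
  expect_lt(abs(frac - p), 3 * se)
})

test_that("non-stochastic transition matrices are rejected", {
  dims <- c(2, 2, 2)
  patterns <- list(array(0, dims), array(1, dims))
  expect_error(markov_state_model(matrix(c(0.9, 0.2, 0.5, 0.5), 2,
                                         byrow = TRUE), patterns),
               "row-stochastic")
})

test_that("behavioral sessions respect the block design", {
  des <- session_design("2back")
  tab <- simulate_behavior_session(des, seed = 7)
  expect_equal(nrow(tab), 176)
  expect_equal(sum(tab$type == "congruent"), 36)
  expect_true(all(tapply(tab$type == "congruent", tab$block, sum) == 9))
  expect_true(all(is.na(tab$rt_ms[!tab$responded])))
  expect_true(all(!is.na(tab$rt_ms[tab$responded])))
  expect_identical(tab, simulate_behavior_session(des, seed = 7))
})

test_that("degenerate response rates behave deterministically", {
  des <- session_design("1back")
  tab <- simulate_behavior_session(des, list(hit_rate = 1, fa_rate = 0,
                                             rt_location_ms = 500,
                                             rt_scale_ms = 50), seed = 2)
  expect_true(all(tab$responded[tab$type == "congruent"]))
  expect_true(all(!tab$responded[tab$type == "incongruent"]))
  expect_error(simulate_behavior_session(des, list(hit_rate = 1.2,
                                                   fa_rate = 0,
                                                   rt_location_ms = 500,
                                                   rt_scale_ms = 50)),
               "\\[0, 1\\]")
})
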