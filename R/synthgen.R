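# ---------------------------------------------------------------------------
# Synthetic-data generators: edited-MRS sessions, Markov-driven BOLD volumes,
# and n-back behavioral trial tables, all pure functions of (parameters, seed).
# ---------------------------------------------------------------------------

#' Session design constants
#'
#' Describes one acquisition session: the n-back block structure and the
#' number of editing ON/OFF pairs acquired. Protocol-faithful designs use
#' 4 blocks x 44 trials with 9 congruent trials per block, 96 ON/OFF pairs
#' at rest and 112 during task, TR = 2 s (one ON/OFF pair = 4 s).
#'
#' @param condition One of `"rest"`, `"0back"`, `"1back"`, `"2back"`.
#' @param n_blocks,trials_per_block,congruent_per_block Block structure.
#' @param stim_duration_s,isi_s Stimulus duration and inter-stimulus interval
#'   in seconds (one trial every `stim_duration_s + isi_s` seconds).
#' @param n_on_off_pairs Number of ON/OFF average pairs; defaults to 96 for
#'   rest and 112 for task conditions.
#' @param tr_s Repetition time in seconds.
#' @return A `session_design` list.
#' @export
session_design <- function(condition = c("rest", "0back", "1back", "2back"),
                           n_blocks = 4L, trials_per_block = 44L,
                           congruent_per_block = 9L,
                           stim_duration_s = 2.0, isi_s = 0.5,
                           n_on_off_pairs = NULL, tr_s = 2.0) {
  condition <- match.arg(condition)
  if (is.null(n_on_off_pairs)) {
    n_on_off_pairs <- if (condition == "rest") 96L else 112L
  }
  if (congruent_per_block > trials_per_block) {
    stop("congruent_per_block must not exceed trials_per_block")
  }
  structure(list(condition = condition, n_blocks = as.integer(n_blocks),
                 trials_per_block = as.integer(trials_per_block),
                 congruent_per_block = as.integer(congruent_per_block),
                 stim_duration_s = stim_duration_s, isi_s = isi_s,
                 n_on_off_pairs = as.integer(n_on_off_pairs), tr_s = tr_s),
            class = "session_design")
}

#' Kinetic profile of underlying metabolite concentrations
#'
#' Defines the ground-truth time courses of Glx and GABA+ for a synthetic
#' session as unitless multipliers of a baseline concentration (baseline
#' multiplier 1.0). The default task shapes emulate a fast excitatory (Glx)
#' rise and a slower biphasic GABAergic pattern (initial increase followed by
#' a decline), scaled by cognitive load.
#'
#' @param condition Session condition label.
#' @param glx_shape,gaba_shape Functions of time (seconds) returning positive
#'   relative concentration multipliers. Defaults depend on `condition`.
#' @param noise_sd Gaussian noise SD as a fraction of baseline (per pair).
#' @param outlier_rate Probability that a pair is replaced by an extreme value.
#' @param baseline_glx,baseline_gaba Baseline concentrations (institutional
#'   units; their ratio sets the baseline EIB of 5).
#' @param seed Integer seed making the generator deterministic.
#' @return A `kinetic_profile` list.
#' @export
kinetic_profile <- function(condition = c("rest", "0back", "1back", "2back"),
                            glx_shape = NULL, gaba_shape = NULL,
                            noise_sd = 0.03, outlier_rate = 0.01,
                            baseline_glx = 10, baseline_gaba = 2,
                            seed = 1L) {
  condition <- match.arg(condition)
  # load-scaled defaults: Glx saturating rise within minutes; GABA+ biphasic
  load <- switch(condition, rest = 0, `0back` = 0.25, `1back` = 0.5,
                 `2back` = 1)
  if (is.null(glx_shape)) {
    glx_shape <- function(t) 1 + 0.10 * load * (1 - exp(-t / 60))
  }
  if (is.null(gaba_shape)) {
    gaba_shape <- function(t) {
      1 + 0.06 * load * (t / 150) * exp(1 - t / 150)
    }
  }
  stopifnot(is.function(glx_shape), is.function(gaba_shape),
            noise_sd >= 0, outlier_rate >= 0, outlier_rate < 0.5,
            baseline_glx > 0, baseline_gaba > 0)
  structure(list(condition = condition, glx_shape = glx_shape,
                 gaba_shape = gaba_shape, noise_sd = noise_sd,
                 outlier_rate = outlier_rate, baseline_glx = baseline_glx,
                 baseline_gaba = baseline_gaba, seed = as.integer(seed)),
            class = "kinetic_profile")
}

#' Pair midpoint times
#'
#' One ON/OFF pair spans 2 TR = 4 s; pair k's midpoint is (k - 0.5) * 4 s.
#' @param n_pairs Number of pairs.
#' @param tr_s Repetition time (s).
#' @return Numeric vector of midpoint times in seconds.
#' @export
pair_midpoints <- function(n_pairs, tr_s = 2.0) {
  (seq_len(n_pairs) - 0.5) * 2 * tr_s
}

#' Simulate per-pair metabolite concentrations
#'
#' Evaluates the profile's shapes at each pair midpoint, scales by the
#' baselines, then adds i.i.d. Gaussian noise and replaces a random subset of
#' pairs by extreme outliers (|z| > 4 on the noise scale).
#'
#' @param profile A [kinetic_profile()].
#' @param design A [session_design()].
#' @return A data.frame with columns `pair`, `time_s`, `glx_true`,
#'   `gaba_true`, `glx`, `gaba`, `outlier`.
#' @export
simulate_metabolite_series <- function(profile, design) {
  stopifnot(inherits(profile, "kinetic_profile"),
            inherits(design, "session_design"))
  n <- design$n_on_off_pairs
  t <- pair_midpoints(n, design$tr_s)
  glx_true <- profile$baseline_glx * vapply(t, profile$glx_shape, 0)
  gaba_true <- profile$baseline_gaba * vapply(t, profile$gaba_shape, 0)
  if (any(!is.finite(glx_true)) || any(glx_true <= 0) ||
      any(!is.finite(gaba_true)) || any(gaba_true <= 0)) {
    stop("invalid profile: shapes must evaluate to positive finite values")
  }
  withr_seed <- profile$seed
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(withr_seed)
  sd_glx <- profile$noise_sd * profile$baseline_glx
  sd_gaba <- profile$noise_sd * profile$baseline_gaba
  glx <- glx_true + stats::rnorm(n, 0, sd_glx)
  gaba <- gaba_true + stats::rnorm(n, 0, sd_gaba)
  out <- stats::runif(n) < profile$outlier_rate
  if (any(out)) {
    # extreme value: > 4 noise SDs from truth (floor on the scale so that the
    # noiseless case still produces a visible artifact)
    sgn <- sample(c(-1, 1), sum(out), replace = TRUE)
    mag <- 4.5 + stats::rexp(sum(out), rate = 2)
    scale_glx <- max(sd_glx, 0.05 * profile$baseline_glx)
    scale_gaba <- max(sd_gaba, 0.05 * profile$baseline_gaba)
    glx[out] <- glx_true[out] + sgn * mag * scale_glx
    gaba[out] <- gaba_true[out] - sgn * mag * scale_gaba
  }
  data.frame(pair = seq_len(n), time_s = t, glx_true = glx_true,
             gaba_true = gaba_true, glx = glx, gaba = gaba, outlier = out)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Spectral peak parameters for the edited-spectrum generator
#'
#' GABA+ is a single Gaussian at 3.0 ppm present only in the ON spectra;
#' Glx is a symmetric Gaussian doublet split 0.08 ppm about 3.75 ppm whose
#' edited (ON - OFF) area is proportional to concentration. Areas are in
#' arbitrary units per unit concentration.
#'
#' @param gaba_center_ppm,gaba_width_ppm GABA+ Gaussian center and SD (ppm).
#' @param glx_center_ppm,glx_split_ppm,glx_width_ppm Glx doublet center,
#'   split and per-line SD (ppm).
#' @param gaba_area_per_unit,glx_area_per_unit Edited peak area per unit
#'   concentration (a.u.).
#' @param glx_off_fraction Fraction of the Glx amplitude present in the OFF
#'   spectrum (cancels in the difference).
#' @param water_area Area of the water reference Gaussian at 4.68 ppm.
#' @param noise_sd Additive Gaussian spectral noise SD (a.u.).
#' @return A `peak_params` list.
#' @export
peak_params <- function(gaba_center_ppm = 3.0, gaba_width_ppm = 0.045,
                        glx_center_ppm = 3.75, glx_split_ppm = 0.08,
                        glx_width_ppm = 0.04,
                        gaba_area_per_unit = 1.0, glx_area_per_unit = 1.0,
                        glx_off_fraction = 0.5, water_area = 5000,
                        noise_sd = 0) {
  structure(as.list(environment()), class = "peak_params")
}

.gaussian <- function(x, center, sd, area) {
  amp <- area / (sd * sqrt(2 * pi))
  amp * exp(-(x - center)^2 / (2 * sd^2))
}

#' Simulate an edited MEGA-PRESS session
#'
#' Builds `n_on_off_pairs` ON and OFF spectra on a shared ppm axis such that
#' each pair's ON - OFF difference contains a GABA+ peak at 3.0 ppm and a Glx
#' doublet near 3.75 ppm with areas proportional to that pair's
#' concentrations, plus one water-reference spectrum.
#'
#' @param series Data.frame from [simulate_metabolite_series()] (columns
#'   `glx`, `gaba`; noisy values are used as the emitted concentrations).
#' @param params A [peak_params()].
#' @param design A [session_design()].
#' @param ppm ppm axis (strictly monotone); default 1024 points from 10.5
#'   down to 0.5 ppm, covering the fit windows and the 9-10 ppm noise region.
#' @param seed Seed for the spectral noise.
#' @return An `edited_session` list: `on`, `off` (lists of spectra), `water`,
#'   `ppm`, `design`, `tissue` ([tissue_fractions()], defaults 60/35/5).
#' @export
simulate_edited_session <- function(series, params = peak_params(),
                                    design, ppm = NULL, seed = 1L) {
  if (is.null(ppm)) ppm <- seq(10.5, 0.5, length.out = 1024)
  d <- diff(ppm)
  if (!(all(d > 0) || all(d < 0))) stop("ppm axis must be strictly monotone")
  n <- nrow(series)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  half_split <- params$glx_split_ppm / 2
  make_glx <- function(area) {
    .gaussian(ppm, params$glx_center_ppm - half_split, params$glx_width_ppm,
              area / 2) +
      .gaussian(ppm, params$glx_center_ppm + half_split, params$glx_width_ppm,
                area / 2)
  }
  on <- vector("list", n); off <- vector("list", n)
  for (k in seq_len(n)) {
    glx_edit <- params$glx_area_per_unit * series$glx[k]
    gaba_edit <- params$gaba_area_per_unit * series$gaba[k]
    off_int <- make_glx(params$glx_off_fraction * glx_edit)
    on_int <- off_int + make_glx(glx_edit) +
      .gaussian(ppm, params$gaba_center_ppm, params$gaba_width_ppm, gaba_edit)
    if (params$noise_sd > 0) {
      on_int <- on_int + stats::rnorm(length(ppm), 0, params$noise_sd)
      off_int <- off_int + stats::rnorm(length(ppm), 0, params$noise_sd)
    }
    on[[k]] <- spectrum(ppm, on_int, "ON")
    off[[k]] <- spectrum(ppm, off_int, "OFF")
  }
  water <- spectrum(ppm, .gaussian(ppm, 4.68, 0.06, params$water_area),
                    "WATER")
  structure(list(on = on, off = off, water = water, ppm = ppm,
                 design = design, params = params,
                 tissue = tissue_fractions(0.60, 0.35, 0.05)),
            class = "edited_session")
}

#' Markov model driving synthetic BOLD states
#'
#' State 0 is the non-active state and emits zeros; states 1..K emit the
#' given spatial patterns. Rows of the transition matrix must sum to 1.
#'
#' @param transition_matrix (K+1)x(K+1) row-stochastic matrix; row/col 1 is
#'   state 0.
#' @param emission_patterns List of K+1 arrays sharing one grid shape
#'   (element 1, state 0, is ignored and emitted as zeros).
#' @param emission_noise_sd Gaussian emission noise SD.
#' @param seed Integer seed.
#' @return A `markov_state_model` list.
#' @export
markov_state_model <- function(transition_matrix, emission_patterns,
                               emission_noise_sd = 0.5, seed = 1L) {
  P <- as.matrix(transition_matrix)
  if (nrow(P) != ncol(P)) stop("transition matrix must be square")
  if (any(abs(rowSums(P) - 1) > 1e-12) || any(P < 0)) {
    stop("transition matrix must be row-stochastic")
  }
  if (length(emission_patterns) != nrow(P)) {
    stop("need one emission pattern per state (state 0 included)")
  }
  dims <- lapply(emission_patterns, dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1) {
    stop("emission patterns must share one grid shape")
  }
  structure(list(n_states = nrow(P), transition_matrix = P,
                 emission_patterns = emission_patterns,
                 emission_noise_sd = emission_noise_sd,
                 seed = as.integer(seed)),
            class = "markov_state_model")
}

#' Standard CAP transition matrix
#'
#' Row-stochastic (K+1)x(K+1) chain in the empirical CAP regime: a dominant
#' non-active state 0 with self-transition `p00`, active states with
#' self-transition `self` that exit back to state 0 (`exit0`) and route the
#' remaining mass between each other. The active states stay a minority of
#' the timeline, as for seed-selected coactivation patterns. With
#' `inter = "ring"` (the default) inter-state transitions follow a cycle
#' (state m prefers m + 1), giving the sparse, structured transition graphs
#' seen in empirical CAP sequences, where betweenness centrality is
#' informative; `inter = "uniform"` spreads the mass evenly instead.
#'
#' @param K Number of active states.
#' @param p00 Self-transition of the non-active state.
#' @param self Self-transition of each active state.
#' @param exit0 Probability of an active state returning to state 0.
#' @param inter Topology of transitions between active states.
#' @return (K+1)x(K+1) row-stochastic matrix (row/col 1 = state 0).
#' @export
cap_transition_matrix <- function(K, p00 = 0.9, self = 0.55, exit0 = 0.2,
                                  inter = c("ring", "uniform")) {
  inter <- match.arg(inter)
  stopifnot(K >= 1, p00 >= 0, p00 <= 1, self + exit0 <= 1)
  P <- matrix(0, K + 1, K + 1)
  P[1, 1] <- p00
  P[1, -1] <- (1 - p00) / K
  rest <- 1 - self - exit0
  for (m in seq_len(K)) {
    P[m + 1, m + 1] <- self
    P[m + 1, 1] <- exit0
    if (K > 1) {
      if (inter == "ring") {
        P[m + 1, (m %% K) + 2] <- rest
      } else {
        P[m + 1, setdiff(2:(K + 1), m + 1)] <- rest / (K - 1)
      }
    } else {
      P[m + 1, 1] <- P[m + 1, 1] + rest
    }
  }
  P
}

#' Simulate a BOLD-like 4D session from a Markov state model
#'
#' Samples a state path, emits the state's spatial pattern plus Gaussian
#' noise per frame, and elevates the mean signal inside the seed sphere by
#' `seed_boost` whenever the state is seed-coupled. Returns the true path for
#' recovery tests.
#'
#' @param model A [markov_state_model()].
#' @param n_frames Number of frames (>= 2).
#' @param seed_center Seed sphere center in mm.
#' @param seed_radius_mm Sphere radius (default 10 mm).
#' @param voxel_size_mm Isotropic voxel size (default 3 mm).
#' @param seed_coupled Integer states (1..K) whose frames get the seed boost;
#'   defaults to all active states.
#' @param seed_boost Added seed-region amplitude for seed-coupled frames.
#' @param init_state Initial state (default 0, the non-active state).
#' @return List with `volume` (4D array x,y,z,t), `states` (length
#'   `n_frames`, values 0..K), `seed` (list center/radius/voxel size).
#' @export
simulate_bold_session <- function(model, n_frames, seed_center = NULL,
                                  seed_radius_mm = 10, voxel_size_mm = 3,
                                  seed_coupled = NULL, seed_boost = 2,
                                  init_state = 0L) {
  stopifnot(inherits(model, "markov_state_model"), n_frames >= 2)
  dims <- dim(model$emission_patterns[[2]])
  if (is.null(dims)) dims <- c(length(model$emission_patterns[[2]]), 1L, 1L)
  if (is.null(seed_center)) seed_center <- (dims / 2) * voxel_size_mm
  if (is.null(seed_coupled)) seed_coupled <- seq_len(model$n_states - 1L)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(model$seed)
  K1 <- model$n_states
  states <- integer(n_frames)
  s <- as.integer(init_state) + 1L  # 1-based row index
  for (t in seq_len(n_frames)) {
    s <- sample.int(K1, 1L, prob = model$transition_matrix[s, ])
    states[t] <- s - 1L
  }
  mask <- sphere_mask(dims, seed_center, seed_radius_mm, voxel_size_mm)
  if (!any(mask)) stop("seed sphere does not intersect the grid")
  nvox <- prod(dims)
  vol <- array(0, dim = c(dims, n_frames))
  zero <- array(0, dim = dims)
  for (t in seq_len(n_frames)) {
    st <- states[t]
    base <- if (st == 0L) zero else model$emission_patterns[[st + 1L]]
    frame <- base
    if (st %in% seed_coupled) frame <- frame + seed_boost * mask
    if (model$emission_noise_sd > 0) {
      frame <- frame + array(stats::rnorm(nvox, 0, model$emission_noise_sd),
                             dim = dims)
    }
    vol[, , , t] <- frame
  }
  list(volume = vol, states = states,
       seed = list(center = seed_center, radius_mm = seed_radius_mm,
                   voxel_size_mm = voxel_size_mm))
}

#' Simulate an n-back behavioral session
#'
#' Places exactly `congruent_per_block` congruent trials in each block,
#' draws responses from per-condition hit and false-alarm rates, and samples
#' RTs (ms) for responded trials from a truncated normal distribution.
#'
#' @param design A [session_design()].
#' @param perf_params List with `hit_rate`, `fa_rate`, `rt_location_ms`,
#'   `rt_scale_ms`.
#' @param seed Integer seed.
#' @return Data.frame `trial block type responded rt_ms` (one row per trial,
#'   `rt_ms` NA for non-responses).
#' @export
simulate_behavior_session <- function(design,
                                      perf_params = list(hit_rate = 0.9,
                                                         fa_rate = 0.05,
                                                         rt_location_ms = 550,
                                                         rt_scale_ms = 90),
                                      seed = 1L) {
  stopifnot(inherits(design, "session_design"))
  hr <- perf_params$hit_rate; fa <- perf_params$fa_rate
  if (hr < 0 || hr > 1 || fa < 0 || fa > 1) {
    stop("hit_rate and fa_rate must lie in [0, 1]")
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  nb <- design$n_blocks; tpb <- design$trials_per_block
  cpb <- design$congruent_per_block
  rows <- vector("list", nb)
  for (b in seq_len(nb)) {
    type <- rep("incongruent", tpb)
    type[sample.int(tpb, cpb)] <- "congruent"
    responded <- ifelse(type == "congruent",
                        stats::runif(tpb) < hr, stats::runif(tpb) < fa)
    rt <- rep(NA_real_, tpb)
    nresp <- sum(responded)
    if (nresp > 0) {
      r <- stats::rnorm(nresp, perf_params$rt_location_ms,
                        perf_params$rt_scale_ms)
      rt[responded] <- pmax(r, 150)
    }
    rows[[b]] <- data.frame(trial = (b - 1L) * tpb + seq_len(tpb),
                            block = b, type = type, responded = responded,
                            rt_ms = rt)
  }
  do.call(rbind, rows)
}
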