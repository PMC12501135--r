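# ---------------------------------------------------------------------------
# End-to-end orchestration over synthetic cohorts:
# simulate -> spectro/kinetics -> visgraph + caps -> behavior -> plsc -> stats.
# ---------------------------------------------------------------------------

.default_config <- function() {
  list(
    n_subjects = 12L,
    conditions = c("rest", "0back", "1back", "2back"),
    seed = 1L,
    # fMRS windowing (60-pair windows shifted 3 pairs = 12 s; rest trimmed
    # to 12 frames, task sessions carry 18)
    window_pairs = 60L, step_pairs = 3L, target_frames_rest = 12L,
    outlier_z = 2.0,
    mrs_mode = "spectral",          # "spectral" or "concentration"
    spectral_noise_sd = 0.3,
    kinetic_noise_sd = 0.03, outlier_rate = 0.01,
    # CAP stage
    grid_dims = c(10L, 10L, 10L), voxel_size_mm = 3,
    n_cap_states = 4L, cap_self_transition = 0.55,
    emission_noise_sd = 0.6, seed_boost = 2,
    z_threshold = 1.0, two_sided = FALSE,
    k_range = 2:6, n_subsamples = 50L, subsample_frac = 0.8,
    consensus_max_frames = 400L,
    fpn_cap = 1L,
    # behavior
    hit_rates = c(`0back` = 0.95, `1back` = 0.88, `2back` = 0.78),
    fa_rates = c(`0back` = 0.02, `1back` = 0.06, `2back` = 0.12),
    rt_locations = c(`0back` = 480, `1back` = 560, `2back` = 640),
    rt_scale_ms = 90,
    # PLSC
    n_perm = 1000L, n_boot = 2000L,
    # toggles for pinned-but-open design choices
    include_boundary_nodes = TRUE, hit_floor = 0,
    write_spectra = FALSE)
}

#' Pipeline configuration with study-protocol defaults
#'
#' Builds and validates the configuration list for [run_pipeline()]. All
#' defaults match the study design (96/112 ON-OFF pairs, 60/3 windowing,
#' 12 rest frames, z > 1 frame selection, 10 mm seed) so a faithful run
#' needs no edits; unknown keys are rejected.
#'
#' @param ... Named overrides of the default fields.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- .default_config()
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  cfg[names(over)] <- over
  stopifnot(cfg$n_subjects >= 1, cfg$window_pairs >= 1, cfg$step_pairs >= 1,
            cfg$mrs_mode %in% c("spectral", "concentration"),
            cfg$z_threshold > -Inf, all(cfg$k_range >= 1))
  structure(cfg, class = "pipeline_config")
}

.stage_seed <- function(cfg, stage, i = 0L) {
  # small deterministic per-stage seeds derived from the master seed
  (cfg$seed * 10007L + stage * 101L + i) %% 2147480000L
}

#' Run the full synthetic-cohort pipeline
#'
#' Executes every stage in dependency order on a synthetic cohort, writes
#' each stage's tables under `out_dir`, and hashes all outputs into
#' `manifest.json`. Reruns with an identical configuration reproduce
#' identical hashes. A stage failure still writes a partial manifest naming
#' the failed stage, then signals the error.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Run directory (created).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = unclass(config), stages = list(), files = list())
  flush_manifest <- function() {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  run_stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(res))
      flush_manifest()
      stop("stage '", name, "' failed: ", conditionMessage(res))
    }
    manifest$stages[[name]] <<- list(status = "ok")
    res
  }
  write_tsv <- function(df, file) {
    path <- file.path(out_dir, file)
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
    manifest$files[[file]] <<- unname(tools::md5sum(path))
    path
  }
  cfg <- config
  conditions <- cfg$conditions
  subjects <- sprintf("sub%02d", seq_len(cfg$n_subjects))

  # ---- stage 1: simulate -------------------------------------------------
  sim <- run_stage("simulate", function() {
    out <- list()
    for (si in seq_along(subjects)) {
      for (ci in seq_along(conditions)) {
        cond <- conditions[ci]
        design <- session_design(cond)
        prof <- kinetic_profile(cond, noise_sd = cfg$kinetic_noise_sd,
                                outlier_rate = cfg$outlier_rate,
                                seed = .stage_seed(cfg, 1L, si * 10L + ci))
        series <- simulate_metabolite_series(prof, design)
        beh <- NULL
        if (cond != "rest") {
          pp <- list(hit_rate = cfg$hit_rates[[cond]],
                     fa_rate = cfg$fa_rates[[cond]],
                     rt_location_ms = cfg$rt_locations[[cond]],
                     rt_scale_ms = cfg$rt_scale_ms)
          beh <- simulate_behavior_session(design, pp,
                                           seed = .stage_seed(cfg, 2L,
                                                              si * 10L + ci))
        }
        out[[paste(subjects[si], cond, sep = ".")]] <-
          list(subject = subjects[si], condition = cond, design = design,
               series = series, behavior = beh)
      }
    }
    out
  })

  # ---- stage 2: kinetics (spectro chain in spectral mode) ----------------
  kin <- run_stage("kinetics", function() {
    rows <- list(); curves <- list()
    for (key in names(sim)) {
      s <- sim[[key]]
      grid <- window_indices(s$design$n_on_off_pairs, cfg$window_pairs,
                             cfg$step_pairs,
                             target_frames = if (s$condition == "rest")
                               cfg$target_frames_rest else NULL)
      if (cfg$mrs_mode == "spectral") {
        session <- simulate_edited_session(
          s$series, peak_params(noise_sd = cfg$spectral_noise_sd), s$design,
          seed = .stage_seed(cfg, 3L, match(key, names(sim))))
        curve <- eib_curve(session, grid, outlier_z = cfg$outlier_z)
        curve$condition <- s$condition
      } else {
        conc <- s$series[, c("glx", "gaba")]
        attr(conc, "condition") <- s$condition
        curve <- eib_curve(conc, grid, outlier_z = cfg$outlier_z)
      }
      curves[[key]] <- curve
      fr <- curve$frames
      rows[[key]] <- data.frame(subject = s$subject, session = s$condition,
                                frame = fr$frame, gaba = fr$gaba,
                                glx = fr$glx, eib = fr$eib,
                                eib_norm = fr$eib_norm,
                                outlier = fr$outlier, auc = curve$auc)
    }
    write_tsv(do.call(rbind, rows), "kinetics.tsv")
    curves
  })

  # ---- stage 3: visibility-graph features --------------------------------
  vis <- run_stage("visgraph", function() {
    rows <- lapply(names(kin), function(key) {
      s <- sim[[key]]
      f <- visibility_features(kin[[key]],
                               include_boundary = cfg$include_boundary_nodes)
      data.frame(subject = s$subject, session = s$condition,
                 feature = c("mean_out_degree", "kld"),
                 value = c(f$mean_out_degree, f$kld))
    })
    df <- do.call(rbind, rows)
    write_tsv(df, "visgraph.tsv")
    df
  })

  # ---- stage 4: CAP analysis ---------------------------------------------
  caps <- run_stage("caps", function() {
    K <- cfg$n_cap_states
    dims <- cfg$grid_dims
    patterns <- c(list(array(0, dims)), lapply(seq_len(K), function(m) {
      set.seed(.stage_seed(cfg, 4L, m))
      array(stats::rnorm(prod(dims)), dims)
    }))
    P <- cap_transition_matrix(K, self = cfg$cap_self_transition)
    seg <- list(); frames_all <- list(); sel_all <- list()
    for (key in names(sim)) {
      s <- sim[[key]]
      n_frames <- 2L * s$design$n_on_off_pairs
      model <- markov_state_model(P, patterns,
                                  emission_noise_sd = cfg$emission_noise_sd,
                                  seed = .stage_seed(cfg, 5L,
                                                     match(key, names(sim))))
      bold <- simulate_bold_session(model, n_frames,
                                    voxel_size_mm = cfg$voxel_size_mm,
                                    seed_boost = cfg$seed_boost)
      z <- seed_timecourse(bold$volume, bold$seed$center,
                           bold$seed$radius_mm, cfg$voxel_size_mm)
      sel <- select_frames(z, cfg$z_threshold, cfg$two_sided)
      mat <- t(matrix(bold$volume, nrow = prod(dims),
                      ncol = n_frames)[, sel, drop = FALSE])
      seg[[key]] <- list(n_frames = n_frames, sel = sel)
      frames_all[[key]] <- mat
    }
    frames <- do.call(rbind, frames_all)
    set.seed(.stage_seed(cfg, 6L))
    sub <- if (nrow(frames) > cfg$consensus_max_frames) {
      sort(sample.int(nrow(frames), cfg$consensus_max_frames))
    } else seq_len(nrow(frames))
    cons <- choose_k_consensus(frames[sub, , drop = FALSE], cfg$k_range,
                               n_subsamples = cfg$n_subsamples,
                               subsample_frac = cfg$subsample_frac,
                               seed = .stage_seed(cfg, 7L))
    fit <- fit_caps(frames, cons$k, seed = .stage_seed(cfg, 8L))
    # split concatenated labels back into subject-session segments
    offsets <- cumsum(c(0, vapply(frames_all, nrow, 0L)))
    metrics <- list(); persist <- list()
    for (i in seq_along(seg)) {
      key <- names(seg)[i]
      s <- sim[[key]]
      lab_sel <- fit$labels[(offsets[i] + 1):offsets[i + 1]]
      labels <- integer(seg[[key]]$n_frames)
      labels[seg[[key]]$sel] <- lab_sel
      tm <- temporal_metrics(labels, n_states = cons$k + 1L)
      tm$subject <- s$subject; tm$session <- s$condition
      metrics[[key]] <- tm
      grid <- window_indices(s$design$n_on_off_pairs, cfg$window_pairs,
                             cfg$step_pairs,
                             target_frames = if (s$condition == "rest")
                               cfg$target_frames_rest else NULL)
      fw <- map_windows_to_frames(grid, seg[[key]]$n_frames)
      pc <- persistence_curve(labels, cfg$fpn_cap, fw)
      pc$subject <- s$subject; pc$session <- s$condition
      persist[[key]] <- pc
    }
    metrics <- do.call(rbind, metrics)
    persist <- do.call(rbind, persist)
    write_tsv(metrics, "cap_metrics.tsv")
    write_tsv(persist, "cap_persistence.tsv")
    list(k = cons$k, consensus = cons$consensus_stats, fit = fit,
         metrics = metrics, persistence = persist)
  })

  # ---- stage 5: behavior --------------------------------------------------
  beh <- run_stage("behavior", function() {
    rows <- list()
    for (key in names(sim)) {
      s <- sim[[key]]
      if (is.null(s$behavior)) next
      scored <- score_trials(s$behavior, s$design, hit_floor = cfg$hit_floor)
      grid <- window_indices(s$design$n_on_off_pairs, cfg$window_pairs,
                             cfg$step_pairs)
      wp <- windowed_performance_auc(scored, grid, s$design)
      nc <- sum(scored$type == "congruent")
      ni <- sum(scored$type == "incongruent")
      sdt <- dprime_loglinear(sum(scored$type == "congruent" &
                                    scored$responded), nc,
                              sum(scored$type == "incongruent" &
                                    scored$responded), ni)
      rows[[key]] <- data.frame(subject = s$subject, session = s$condition,
                                dprime = sdt$dprime,
                                hit_rate = sdt$hit_rate,
                                fa_rate = sdt$fa_rate,
                                mean_rt = mean(scored$rt_ms, na.rm = TRUE),
                                behavior_auc = wp$auc)
    }
    df <- do.call(rbind, rows)
    write_tsv(df, "behavior.tsv")
    df
  })

  # ---- stage 6: PLSC coupling ---------------------------------------------
  plsc <- run_stage("plsc", function() {
    cm <- caps$metrics[caps$metrics$state == cfg$fpn_cap, ]
    cap_long <- do.call(rbind, lapply(
      c("occurrences_pct", "resilience", "in_degree", "out_degree",
        "betweenness"),
      function(m) data.frame(subject = cm$subject, session = cm$session,
                             metric = m, value = cm[[m]])))
    blocks <- assemble_blocks(cap_long, vis, sessions = conditions)
    res <- plsc_significance(blocks$X, blocks$Y, n_perm = cfg$n_perm,
                             n_boot = cfg$n_boot,
                             seed = .stage_seed(cfg, 9L))
    summary <- list(explained_cov_pct = res$explained_cov_pct,
                    perm_p = res$perm_p,
                    score_correlation = res$score_correlation)
    jsonlite::write_json(summary, file.path(out_dir, "plsc.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest$files[["plsc.json"]] <<-
      unname(tools::md5sum(file.path(out_dir, "plsc.json")))
    res
  })

  # ---- stage 7: session statistics ----------------------------------------
  stats_res <- run_stage("stats", function() {
    kin_tab <- utils::read.delim(file.path(out_dir, "kinetics.tsv"))
    aucs <- unique(kin_tab[, c("subject", "session", "auc")])
    groups <- split(aucs$auc, factor(aucs$session, levels = conditions))
    kw_auc <- kruskal_wallis_mrd(groups)
    vis_od <- vis[vis$feature == "mean_out_degree", ]
    kw_od <- kruskal_wallis_mrd(split(vis_od$value,
                                      factor(vis_od$session,
                                             levels = conditions)))
    pc <- caps$persistence
    kw_pers <- kruskal_wallis_mrd(split(pc$persistence,
                                        factor(pc$session,
                                               levels = conditions)))
    out <- list(
      eib_auc = list(statistic = kw_auc$statistic, df = kw_auc$df,
                     n = kw_auc$n, p = kw_auc$p),
      eib_out_degree = list(statistic = kw_od$statistic, df = kw_od$df,
                            n = kw_od$n, p = kw_od$p),
      fpn_persistence = list(statistic = kw_pers$statistic, df = kw_pers$df,
                             n = kw_pers$n, p = kw_pers$p))
    jsonlite::write_json(out, file.path(out_dir, "stats.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest$files[["stats.json"]] <<-
      unname(tools::md5sum(file.path(out_dir, "stats.json")))
    list(auc = kw_auc, out_degree = kw_od, persistence = kw_pers)
  })

  flush_manifest()
  invisible(list(sim = sim, curves = kin, visgraph = vis, caps = caps,
                 behavior = beh, plsc = plsc, stats = stats_res,
                 manifest = manifest, out_dir = out_dir))
}
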