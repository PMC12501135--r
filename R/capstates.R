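# ---------------------------------------------------------------------------
# Seed-based coactivation-pattern (CAP) analysis: seed time course and frame
# selection, consensus choice of k, k-means CAP fitting, template matching,
# transition-graph temporal metrics, fMRS-matched persistence curves.
# ---------------------------------------------------------------------------

#' Spherical seed mask on a voxel grid
#'
#' Voxel centers sit at (index - 0.5) * voxel size along each axis; a voxel
#' belongs to the mask when its center lies within `radius_mm` of `center`.
#'
#' @param dims Grid dimensions (3 integers).
#' @param center Sphere center in mm.
#' @param radius_mm Sphere radius in mm.
#' @param voxel_size_mm Isotropic voxel size in mm.
#' @return Logical 3D array.
#' @export
sphere_mask <- function(dims, center, radius_mm, voxel_size_mm = 3) {
  cx <- (seq_len(dims[1]) - 0.5) * voxel_size_mm
  cy <- (seq_len(dims[2]) - 0.5) * voxel_size_mm
  cz <- (seq_len(dims[3]) - 0.5) * voxel_size_mm
  dx2 <- (cx - center[1])^2
  dy2 <- (cy - center[2])^2
  dz2 <- (cz - center[3])^2
  d2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
  array(d2 <= radius_mm^2, dim = dims)
}

#' Z-scored seed time course
#'
#' Means the signal over a spherical seed region per frame and z-scores the
#' resulting series over the session.
#'
#' @param volume4d 4D array (x, y, z, t).
#' @param center Seed center in mm.
#' @param radius_mm Seed radius in mm (default 10).
#' @param voxel_size_mm Isotropic voxel size (default 3).
#' @return Numeric z-scored series of length `dim(volume4d)[4]`.
#' @export
seed_timecourse <- function(volume4d, center, radius_mm = 10,
                            voxel_size_mm = 3) {
  dims <- dim(volume4d)
  stopifnot(length(dims) == 4)
  mask <- sphere_mask(dims[1:3], center, radius_mm, voxel_size_mm)
  if (!any(mask)) stop("empty seed mask: sphere does not cover any voxel")
  mat <- matrix(volume4d, nrow = prod(dims[1:3]), ncol = dims[4])
  tc <- colMeans(mat[as.vector(mask), , drop = FALSE])
  s <- stats::sd(tc)
  if (!is.finite(s) || s == 0) {
    stop("seed time course has zero variance; cannot z-score")
  }
  (tc - mean(tc)) / s
}

#' Select supra-threshold frames
#'
#' Frames where the seed z-score strictly exceeds `threshold` (positive
#' tail; activation CAPs). `two_sided = TRUE` selects on |z| instead.
#'
#' @param seed_z Z-scored seed series.
#' @param threshold Z threshold (default 1).
#' @param two_sided Select on absolute z.
#' @return Integer frame indices.
#' @export
select_frames <- function(seed_z, threshold = 1.0, two_sided = FALSE) {
  z <- if (two_sided) abs(seed_z) else seed_z
  idx <- which(z > threshold)
  if (length(idx) == 0) {
    stop("no frames exceed z = ", threshold, "; lower the threshold")
  }
  idx
}

.row_normalize <- function(m) {
  m <- sweep(m, 1, rowMeans(m))
  nrm <- sqrt(rowSums(m^2))
  nrm[nrm == 0] <- 1
  m / nrm
}

.kmeans_safe <- function(x, k, nstart = 20, max_restarts = 5) {
  for (i in seq_len(max_restarts)) {
    km <- tryCatch(stats::kmeans(x, centers = k, nstart = nstart,
                                 iter.max = 100),
                   error = function(e) NULL)
    if (!is.null(km) && length(unique(km$cluster)) == k) return(km)
  }
  stop("k-means failed to produce ", k, " non-empty clusters after ",
       max_restarts, " restarts")
}

#' Consensus-clustering choice of k
#'
#' For each candidate k, k-means is run on repeated random subsamples of
#' the selected frames; co-assignment frequencies among co-sampled frame
#' pairs form a consensus matrix, and stability is scored as 1 - PAC (the
#' proportion of ambiguous consensus entries in (0.1, 0.9)). The most stable
#' k wins, ties going to the smaller k.
#'
#' @param frames Matrix of selected frames (rows) x voxels.
#' @param k_range Candidate k values.
#' @param n_subsamples Subsampling repeats per k (default 100).
#' @param subsample_frac Fraction of frames per subsample (default 0.8).
#' @param seed Integer seed.
#' @param pac_bounds Ambiguity interval for PAC.
#' @return List `k`, `consensus_stats` (data.frame `k`, `stability`).
#' @export
choose_k_consensus <- function(frames, k_range = 2:6, n_subsamples = 100,
                               subsample_frac = 0.8, seed = 1L,
                               pac_bounds = c(0.1, 0.9)) {
  frames <- as.matrix(frames)
  n <- nrow(frames)
  if (n < max(k_range) * 5) {
    stop("need at least 5 frames per candidate cluster")
  }
  if (stats::sd(frames) == 0 ||
      all(apply(frames, 1, function(r) all(r == frames[1, ])))) {
    warning("degenerate input: identical frames; returning k = 1")
    return(list(k = 1L,
                consensus_stats = data.frame(k = 1L, stability = 1)))
  }
  normed <- .row_normalize(frames)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  m <- floor(subsample_frac * n)
  stability <- numeric(length(k_range))
  for (ki in seq_along(k_range)) {
    k <- k_range[ki]
    co <- matrix(0, n, n)     # co-assignment counts
    tog <- matrix(0, n, n)    # co-sampling counts
    for (r in seq_len(n_subsamples)) {
      idx <- sample.int(n, m)
      km <- .kmeans_safe(normed[idx, , drop = FALSE], k, nstart = 3)
      lab <- km$cluster
      same <- outer(lab, lab, `==`)
      co[idx, idx] <- co[idx, idx] + same
      tog[idx, idx] <- tog[idx, idx] + 1
    }
    ut <- upper.tri(co)
    ok <- tog[ut] > 0
    cons <- co[ut][ok] / tog[ut][ok]
    pac <- mean(cons > pac_bounds[1] & cons < pac_bounds[2])
    stability[ki] <- 1 - pac
  }
  best <- which(stability == max(stability))
  k <- min(k_range[best])   # ties toward smaller k
  list(k = as.integer(k),
       consensus_stats = data.frame(k = k_range, stability = stability))
}

#' Fit CAPs by k-means and map labels to the timeline
#'
#' Frames are row-normalized (zero mean, unit norm: correlation-equivalent
#' Euclidean k-means) and clustered with `nstart = 20`. CAP maps are the
#' arithmetic means of the raw assigned frames; z-maps divide by the voxel
#' standard error. Unselected frames carry label 0 (CAP0).
#'
#' @param frames Matrix of selected frames x voxels.
#' @param k Number of CAPs.
#' @param seed Integer seed.
#' @param selected_idx Frame indices of `frames` rows in the full timeline.
#' @param n_frames Total frames in the timeline.
#' @return A `cap_set` list: `k`, `maps` (k x voxels), `z_maps`, `labels`
#'   (full timeline, 0 = non-active), `selected_idx`, `sizes`.
#' @export
fit_caps <- function(frames, k, seed = 1L, selected_idx = NULL,
                     n_frames = NULL) {
  frames <- as.matrix(frames)
  stopifnot(k >= 1)
  if (is.null(selected_idx)) selected_idx <- seq_len(nrow(frames))
  if (is.null(n_frames)) n_frames <- max(selected_idx)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (k == 1L) {
    lab <- rep(1L, nrow(frames))
  } else {
    km <- .kmeans_safe(.row_normalize(frames), k, nstart = 20)
    lab <- km$cluster
  }
  maps <- t(vapply(seq_len(k), function(m) {
    colMeans(frames[lab == m, , drop = FALSE])
  }, numeric(ncol(frames))))
  z_maps <- t(vapply(seq_len(k), function(m) {
    sub <- frames[lab == m, , drop = FALSE]
    mu <- colMeans(sub)
    if (nrow(sub) < 2) return(mu * 0)
    se <- apply(sub, 2, stats::sd) / sqrt(nrow(sub))
    ifelse(se > 0, mu / se, 0)
  }, numeric(ncol(frames))))
  labels <- integer(n_frames)
  labels[selected_idx] <- lab
  structure(list(k = as.integer(k), maps = maps, z_maps = z_maps,
                 labels = labels, selected_idx = selected_idx,
                 sizes = tabulate(lab, k)), class = "cap_set")
}

#' Match CAPs against named spatial templates
#'
#' Pearson correlation over voxels between each CAP z-map and each template;
#' a match is accepted only when the best r strictly exceeds `r_threshold`.
#'
#' @param caps A `cap_set`.
#' @param templates Named list (or matrix rows) of template maps on the CAP
#'   voxel grid.
#' @param r_threshold Acceptance threshold (strict; default 0.3).
#' @return Data.frame `cap`, `template`, `r`, `accepted`.
#' @export
match_templates <- function(caps, templates, r_threshold = 0.3) {
  stopifnot(inherits(caps, "cap_set"))
  tm <- if (is.matrix(templates)) templates else {
    do.call(rbind, lapply(templates, as.numeric))
  }
  if (ncol(tm) != ncol(caps$z_maps)) {
    stop("template grid does not match the CAP grid; resample inputs first")
  }
  nm <- rownames(tm) %||% paste0("template", seq_len(nrow(tm)))
  res <- lapply(seq_len(caps$k), function(m) {
    r <- vapply(seq_len(nrow(tm)), function(j) {
      stats::cor(caps$z_maps[m, ], tm[j, ])
    }, 0)
    best <- which.max(r)
    data.frame(cap = m, template = nm[best], r = r[best],
               accepted = r[best] > r_threshold)
  })
  do.call(rbind, res)
}

#' CAP temporal metrics from a state sequence
#'
#' With T frames and T-1 transitions, for each state m (CAP0 included):
#' occurrences = 100 x frame share; resilience = self-transition count /
#' (T-1); in-degree = entries from other states / (T-1); out-degree = exits
#' to other states / (T-1); betweenness = betweenness centrality of m in the
#' directed transition graph with distances 1/count, normalized by the
#' (K)(K-1) ordered node pairs excluding m.
#'
#' @param labels Integer state sequence (values 0..K).
#' @param n_states Number of states K+1 (default `max(labels) + 1`).
#' @return Data.frame `state`, `occurrences_pct`, `resilience`, `in_degree`,
#'   `out_degree`, `betweenness`.
#' @export
temporal_metrics <- function(labels, n_states = NULL) {
  labels <- as.integer(labels)
  T_ <- length(labels)
  if (T_ < 2) stop("need at least 2 frames")
  if (is.null(n_states)) n_states <- max(labels) + 1L
  states <- 0:(n_states - 1L)
  from <- labels[-T_]; to <- labels[-1]
  nt <- T_ - 1L
  counts <- table(factor(from, levels = states), factor(to, levels = states))
  counts <- unclass(counts)
  occ <- 100 * tabulate(labels + 1L, nbins = n_states) / T_
  resil <- diag(counts) / nt
  indeg <- (colSums(counts) - diag(counts)) / nt
  outdeg <- (rowSums(counts) - diag(counts)) / nt
  # betweenness on the weighted directed transition graph
  btw <- rep(0, n_states)
  offdiag <- counts; diag(offdiag) <- 0
  if (n_states >= 3 && any(offdiag > 0)) {
    idx <- which(offdiag > 0, arr.ind = TRUE)
    g <- igraph::graph_from_data_frame(
      data.frame(from = states[idx[, 1]], to = states[idx[, 2]],
                 weight = 1 / offdiag[idx]),
      directed = TRUE,
      vertices = data.frame(name = states))
    b <- igraph::betweenness(g, directed = TRUE)
    btw <- as.numeric(b)[match(states, as.integer(igraph::V(g)$name))] /
      ((n_states - 1) * (n_states - 2))
  }
  data.frame(state = states, occurrences_pct = occ,
             resilience = as.numeric(resil), in_degree = as.numeric(indeg),
             out_degree = as.numeric(outdeg), betweenness = btw,
             row.names = NULL)
}

#' Map an fMRS window grid proportionally onto an fMRI timeline
#'
#' Produces one frame-index window per fMRS window, covering the same
#' fraction of the session timeline (window length and step scaled
#' proportionally, rounded to frames).
#'
#' @param grid A [window_indices()] grid.
#' @param n_frames Number of fMRI frames in the session.
#' @return Data.frame `window`, `start`, `end` (inclusive frame indices).
#' @export
map_windows_to_frames <- function(grid, n_frames) {
  stopifnot(inherits(grid, "window_grid"))
  w <- grid$windows
  start <- pmax(1L, floor((w$start - 1) / grid$n_pairs * n_frames) + 1L)
  end <- pmin(n_frames, ceiling(w$end / grid$n_pairs * n_frames))
  if (any(end > n_frames) || any(start < 1)) {
    stop("mapped windows fall outside the timeline")
  }
  data.frame(window = seq_len(nrow(w)), start = start, end = end)
}

#' Per-window persistence probability of a CAP
#'
#' For each mapped window, the probability that a transition starting in
#' `cap_id` stays in it: #(cap -> cap) / #(cap -> any) among transitions
#' whose origin frame lies inside the window; 0 when the CAP never starts a
#' transition there.
#'
#' @param labels Full-timeline state sequence.
#' @param cap_id CAP of interest.
#' @param frame_windows Data.frame from [map_windows_to_frames()].
#' @return Data.frame `window`, `persistence`.
#' @export
persistence_curve <- function(labels, cap_id, frame_windows) {
  n <- length(labels)
  if (max(frame_windows$end) > n) {
    stop("mapped windows fall outside the timeline")
  }
  pers <- vapply(seq_len(nrow(frame_windows)), function(i) {
    s <- frame_windows$start[i]; e <- min(frame_windows$end[i], n - 1L)
    if (e < s) return(0)
    t0 <- s:e
    origin <- labels[t0] == cap_id
    if (!any(origin)) return(0)
    sum(origin & labels[t0 + 1L] == cap_id) / sum(origin)
  }, 0)
  data.frame(window = frame_windows$window, persistence = pers)
}
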