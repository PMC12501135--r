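test_that("a 10 mm sphere on a 3 mm grid covers 171 voxels", {
  dims <- c(15, 15, 15)
  center <- c(8 - 0.5, 8 - 0.5, 8 - 0.5) * 3  # a voxel center
  mask <- sphere_mask(dims, center, 10, 3)
  # oracle: integer offsets with 9 (i^2 + j^2 + k^2) <= 100
  off <- expand.grid(i = -4:4, j = -4:4, k = -4:4)
  expect_equal(sum(mask), sum(9 * (off$i^2 + off$j^2 + off$k^2) <= 100))
  expect_equal(sum(mask), 171)
})

test_that("seed time courses are z-scored and reject degenerate input", {
  set.seed(31)
  vol <- array(rnorm(6 * 6 * 6 * 40), c(6, 6, 6, 40))
  z <- seed_timecourse(vol, c(9, 9, 9), 10, 3)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_error(seed_timecourse(array(1, c(6, 6, 6, 10)), c(9, 9, 9)),
               "zero variance")
  expect_error(seed_timecourse(vol, c(1e6, 1e6, 1e6), 10, 3), "empty seed")
})

test_that("frame selection takes the strict positive tail", {
  z <- c(-1, 0.5, 1.5, 2.0, -0.5)
  expect_equal(select_frames(z, 1.0), c(3, 4))
  expect_equal(select_frames(z, -Inf), 1:5)
  expect_error(select_frames(z, 10), "lower the threshold")
  # monotone: raising the threshold never adds frames
  set.seed(37)
  zz <- rnorm(200)
  for (th in c(0, 0.5, 1)) {
    expect_true(all(select_frames(zz, th + 0.5) %in% select_frames(zz, th)))
  }
  expect_equal(select_frames(c(-2, 0.1, 2), 1.5, two_sided = TRUE),
               c(1, 3))
})

test_that("consensus clustering recovers a planted k and is seeded", {
  set.seed(41)
  centers <- matrix(rnorm(4 * 40, sd = 3), 4)
  frames <- centers[rep(1:4, each = 30), ] + matrix(rnorm(120 * 40, 0, 0.5),
                                                    120)
  res <- choose_k_consensus(frames, 2:6, n_subsamples = 30, seed = 3)
  expect_equal(res$k, 4L)
  res2 <- choose_k_consensus(frames, 2:6, n_subsamples = 30, seed = 3)
  expect_identical(res$consensus_stats, res2$consensus_stats)
  # two well-separated families -> near-perfect consensus at k = 2
  fr2 <- centers[rep(1:2, each = 30), ] + matrix(rnorm(60 * 40, 0, 0.2), 60)
  res3 <- choose_k_consensus(fr2, 2:3, n_subsamples = 30, seed = 5)
  stab2 <- res3$consensus_stats$stability[res3$consensus_stats$k == 2]
  expect_gt(stab2, 0.99)
  expect_warning(r0 <- choose_k_consensus(matrix(1, 40, 10), 2:3,
                                          n_subsamples = 10),
                 "identical frames")
  expect_equal(r0$k, 1L)
})

test_that("k-means CAPs recover planted partitions and average exactly", {
  set.seed(43)
  pats <- matrix(rnorm(2 * 50, sd = 2), 2)
  lab_true <- rep(1:2, times = c(20, 25))
  frames <- pats[lab_true, ] + matrix(rnorm(45 * 50, 0, 0.1), 45)
  fit <- fit_caps(frames, 2, seed = 7)
  lab <- fit$labels
  agree <- max(mean(lab == lab_true), mean(lab == 3 - lab_true))
  expect_equal(agree, 1)
  for (m in 1:2) {
    expect_equal(fit$maps[m, ], colMeans(frames[lab == m, , drop = FALSE]))
  }
  # single-cluster CAP of identical frames is the frame itself
  same <- matrix(5, 10, 8)
  f1 <- fit_caps(same, 1, seed = 1)
  expect_equal(f1$maps[1, ], rep(5, 8))
  # labels land back on the full timeline with 0 elsewhere
  fit2 <- fit_caps(frames, 2, seed = 7, selected_idx = seq(2, 90, by = 2),
                   n_frames = 90)
  expect_true(all(fit2$labels[seq(1, 89, by = 2)] == 0))
})

test_that("template matching is strict at r = 0.3", {
  caps <- structure(list(k = 2L,
                         z_maps = rbind(c(3, -3, 0, 0, 0),
                                        c(1, 2, 3, 4, 5))),
                    class = "cap_set")
  # template correlating exactly 0.3 with CAP 1 (orthogonal remainder)
  templates <- rbind(exact03 = c(3, -3, 9, -10, 1))
  m <- match_templates(caps, templates)
  expect_equal(m$r[1], 0.3, tolerance = 1e-12)
  expect_false(m$accepted[1])             # strict inequality
  self <- rbind(self = c(1, 2, 3, 4, 5))
  m2 <- match_templates(caps, self)
  expect_equal(m2$r[2], 1)
  expect_true(m2$accepted[2])
  expect_error(match_templates(caps, rbind(a = 1:4)), "grid")
})

test_that("random templates on large grids are rejected", {
  set.seed(47)
  v <- 5000
  caps <- structure(list(k = 1L, z_maps = matrix(rnorm(v), 1)),
                    class = "cap_set")
  m <- match_templates(caps, rbind(null = rnorm(v)))
  expect_lt(abs(m$r[1]), 5 / sqrt(v))   # null correlation ~ N(0, 1/sqrt(V))
  expect_false(m$accepted[1])
})

test_that("temporal metrics count transitions as defined", {
  tm <- temporal_metrics(c(0, 1, 1, 1, 0, 1))
  c1 <- tm[tm$state == 1, ]
  expect_equal(c1$occurrences_pct, 100 * 4 / 6, tolerance = 1e-12)
  expect_equal(c1$resilience, 2 / 5)
  expect_equal(c1$in_degree, 2 / 5)
  expect_equal(c1$out_degree, 1 / 5)

  const <- temporal_metrics(rep(1L, 30), n_states = 2L)
  c2 <- const[const$state == 1, ]
  expect_equal(c2$occurrences_pct, 100)
  expect_equal(c2$resilience, 1)
  expect_equal(c2$in_degree + c2$out_degree + c2$betweenness, 0)
})

test_that("transition shares conserve across states for random sequences", {
  set.seed(53)
  for (i in 1:50) {
    K <- sample(2:6, 1)
    seq_ <- random_state_seq(sample(10:200, 1), K)
    tm <- temporal_metrics(seq_, n_states = K + 1L)
    expect_equal(sum(tm$resilience + tm$in_degree), 1, tolerance = 1e-12)
    expect_equal(sum(tm$resilience + tm$out_degree), 1, tolerance = 1e-12)
    expect_equal(sum(tm$occurrences_pct), 100, tolerance = 1e-12)
    expect_true(all(tm$betweenness >= 0))
  }
})

test_that("persistence is the conditional self-transition rate per window", {
  fw <- data.frame(window = 1, start = 1, end = 4)
  expect_equal(persistence_curve(c(1, 1, 0, 1), 1, fw)$persistence, 0.5)
  expect_equal(persistence_curve(c(1, 1, 1, 1), 1, fw)$persistence, 1)
  expect_equal(persistence_curve(c(0, 0, 2, 0), 1, fw)$persistence, 0)
  expect_error(persistence_curve(c(1, 1), 1,
                                 data.frame(window = 1, start = 1, end = 9)),
               "outside the timeline")
})

test_that("fMRS windows map proportionally onto the fMRI timeline", {
  g <- window_indices(112)
  fw <- map_windows_to_frames(g, 224)
  expect_equal(nrow(fw), 18)
  expect_equal(fw$start[1], 1)
  expect_equal(fw$end[18], 222)  # last fMRS window ends at pair 111
  # each window covers the same timeline fraction (60/112) in frames
  expect_true(all(fw$end - fw$start + 1 == 120))
})
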