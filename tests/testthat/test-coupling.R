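make_feature_tables <- function(n_subjects = 12, seed = 61) {
  set.seed(seed)
  sessions <- c("rest", "0back", "1back", "2back")
  subjects <- sprintf("s%02d", seq_len(n_subjects))
  cm <- expand.grid(subject = subjects, session = sessions,
                    metric = c("occurrences_pct", "resilience", "in_degree",
                               "out_degree", "betweenness"),
                    stringsAsFactors = FALSE)
  cm$value <- rnorm(nrow(cm))
  ef <- expand.grid(subject = subjects, session = sessions,
                    feature = c("mean_out_degree", "kld"),
                    stringsAsFactors = FALSE)
  ef$value <- rnorm(nrow(ef))
  list(cap = cm, eib = ef)
}

test_that("feature blocks assemble to 5x4 and 2x4 z-scored columns", {
  tabs <- make_feature_tables(12)
  b <- assemble_blocks(tabs$cap, tabs$eib)
  expect_equal(dim(b$X), c(12, 20))
  expect_equal(dim(b$Y), c(12, 8))
  expect_equal(unname(colMeans(b$X)), rep(0, 20), tolerance = 1e-10)
  expect_equal(unname(apply(b$Y, 2, sd)), rep(1, 8), tolerance = 1e-10)
  # deterministic metric-major, session-minor column order
  expect_equal(colnames(b$X)[1:4],
               paste("occurrences_pct", c("rest", "0back", "1back", "2back"),
                     sep = "."))
  expect_equal(colnames(b$Y)[1:2], c("mean_out_degree.rest",
                                     "mean_out_degree.0back"))
})

test_that("missing cells and constant columns are explicit errors", {
  tabs <- make_feature_tables(6)
  cap_miss <- tabs$cap[-1, ]
  expect_error(assemble_blocks(cap_miss, tabs$eib), "missing CAP-metric")
  tabs$eib$value[tabs$eib$feature == "kld" &
                   tabs$eib$session == "rest"] <- 2
  expect_error(assemble_blocks(tabs$cap, tabs$eib), "kld.rest")
})

test_that("a shared single column yields one perfect component", {
  set.seed(67)
  x <- scale(rnorm(15))
  colnames(x) <- "v"
  r <- plsc_fit(x, x)
  expect_equal(r$explained_cov_pct, 100)
  expect_equal(r$score_correlation[1], 1)
  expect_equal(r$singular_values[1], 1, tolerance = 1e-12)  # z-scored cov
})

test_that("orthogonal blocks give a zero decomposition with warning", {
  X <- cbind(a = c(1, -1, 1, -1)); Y <- cbind(b = c(1, 1, -1, -1))
  expect_warning(r <- plsc_fit(scale(X), scale(Y)), "rank-0")
  expect_equal(r$singular_values, 0)
})

test_that("singular values match a brute-force eigendecomposition", {
  X <- matrix(c(1, 2, 0, 1, 3, 1, 2, 0), 4)
  Y <- matrix(c(2, 0, 1, 1, 0, 1, 3, 2), 4)
  R <- crossprod(Y, X) / 3
  oracle <- sqrt(sort(eigen(crossprod(R))$values, decreasing = TRUE))
  r <- plsc_fit(X, Y)
  expect_equal(r$singular_values, oracle, tolerance = 1e-12)
  expect_equal(sum(r$explained_cov_pct), 100, tolerance = 1e-6)
  expect_true(all(diff(r$singular_values) <= 1e-12))
})

test_that("loadings permute with the columns", {
  set.seed(71)
  X <- scale(matrix(rnorm(20 * 4), 20)); colnames(X) <- paste0("x", 1:4)
  Y <- scale(matrix(rnorm(20 * 3), 20)); colnames(Y) <- paste0("y", 1:3)
  r1 <- plsc_fit(X, Y)
  perm <- c(3, 1, 4, 2)
  r2 <- plsc_fit(X[, perm], Y)
  expect_equal(abs(r2$x_loadings[order(perm), 1]),
               abs(r1$x_loadings[, 1]), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(r2$singular_values, r1$singular_values, tolerance = 1e-12)
})

test_that("sign convention puts the largest X loading positive", {
  set.seed(73)
  X <- scale(matrix(rnorm(20 * 5), 20))
  Y <- scale(matrix(rnorm(20 * 2), 20))
  r <- plsc_fit(X, Y)
  for (i in seq_along(r$singular_values)) {
    expect_gt(r$x_loadings[which.max(abs(r$x_loadings[, i])), i], 0)
  }
})

test_that("permutation p-values detect maximal signal and are seeded", {
  set.seed(79)
  x <- scale(rnorm(20)); colnames(x) <- "v"
  r <- plsc_significance(x, x, n_perm = 200, n_boot = 50, seed = 5)
  expect_equal(r$perm_p[1], 1 / 201, tolerance = 2 / 201)
  r2 <- plsc_significance(x, x, n_perm = 200, n_boot = 50, seed = 5)
  expect_identical(r$perm_p, r2$perm_p)
  expect_identical(r$x_ci, r2$x_ci)
  expect_true(all(r$perm_p > 0 & r$perm_p <= 1))
  expect_warning(plsc_significance(x, x, n_perm = 50, n_boot = 0),
                 "unstable")
})

test_that("bootstrap intervals flag a strong planted loading", {
  set.seed(83)
  n <- 40
  latent <- rnorm(n)
  X <- scale(cbind(latent + rnorm(n, 0, 0.3), rnorm(n), rnorm(n)))
  Y <- scale(cbind(latent + rnorm(n, 0, 0.3), rnorm(n)))
  colnames(X) <- paste0("x", 1:3); colnames(Y) <- paste0("y", 1:2)
  r <- plsc_significance(X, Y, n_perm = 100, n_boot = 300, seed = 9)
  expect_true(r$x_reliable[1, 1])
  expect_true(r$y_reliable[1, 1])
  expect_lt(r$perm_p[1], 0.05)
})

test_that("bootstrap CI width shrinks with sample size", {
  width_at <- function(n, seed) {
    set.seed(seed)
    latent <- rnorm(n)
    X <- scale(cbind(latent + rnorm(n, 0, 0.5), rnorm(n)))
    Y <- scale(cbind(latent + rnorm(n, 0, 0.5)))
    colnames(X) <- c("a", "b"); colnames(Y) <- "c"
    r <- plsc_significance(X, Y, n_perm = 100, n_boot = 400, seed = seed)
    r$x_ci["a", "hi", 1] - r$x_ci["a", "lo", 1]
  }
  w_small <- mean(vapply(1:5, function(s) width_at(20, s), 0))
  w_large <- mean(vapply(1:5, function(s) width_at(160, s), 0))
  expect_lt(w_large, w_small)
})
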