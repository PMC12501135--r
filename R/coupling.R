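# ---------------------------------------------------------------------------
# Partial Least Squares Correlation (PLSC) between CAP temporal features and
# EIB visibility-graph features, with permutation significance and bootstrap
# loading stability.
# ---------------------------------------------------------------------------

.zscore_cols <- function(m) {
  mu <- colMeans(m)
  sd_ <- apply(m, 2, stats::sd)
  bad <- which(!is.finite(sd_) | sd_ == 0)
  if (length(bad)) {
    stop("constant column(s) cannot be z-scored: ",
         paste(colnames(m)[bad], collapse = ", "))
  }
  sweep(sweep(m, 2, mu), 2, sd_, `/`)
}

#' Assemble z-scored PLSC feature blocks
#'
#' X gathers the 5 CAP temporal metrics x sessions (metric-major,
#' session-minor column order); Y gathers the EIB visibility features (mean
#' out-degree and KLD by default) x sessions. Rows are subjects; columns are
#' z-scored. Missing subject-session cells raise an explicit error.
#'
#' @param cap_metrics Data.frame `subject`, `session`, `metric`, `value`.
#' @param eib_features Data.frame `subject`, `session`, `feature`, `value`.
#' @param sessions Session order (default rest, 0back, 1back, 2back).
#' @param cap_metric_names,eib_feature_names Column families and order.
#' @return List `X`, `Y` (matrices with subject rownames), `subjects`.
#' @export
assemble_blocks <- function(cap_metrics, eib_features,
                            sessions = c("rest", "0back", "1back", "2back"),
                            cap_metric_names = c("occurrences_pct",
                                                 "resilience", "in_degree",
                                                 "out_degree", "betweenness"),
                            eib_feature_names = c("mean_out_degree", "kld")) {
  subjects <- sort(unique(cap_metrics$subject))
  if (!setequal(subjects, unique(eib_features$subject))) {
    stop("subject sets differ between CAP metrics and EIB features")
  }
  build <- function(df, value_col_family, families, what) {
    cols <- expand.grid(session = sessions, family = families,
                        stringsAsFactors = FALSE)
    cols <- cols[order(match(cols$family, families),
                       match(cols$session, sessions)), ]
    m <- matrix(NA_real_, length(subjects), nrow(cols),
                dimnames = list(subjects,
                                paste(cols$family, cols$session, sep = ".")))
    for (i in seq_len(nrow(cols))) {
      sel <- df[[value_col_family]] == cols$family[i] &
        df$session == cols$session[i]
      sub <- df[sel, ]
      m[match(sub$subject, subjects), i] <- sub$value
    }
    if (anyNA(m)) {
      miss <- which(is.na(m), arr.ind = TRUE)
      stop("missing ", what, " cells: ",
           paste(paste(rownames(m)[miss[, 1]], colnames(m)[miss[, 2]],
                       sep = "/"), collapse = ", "))
    }
    m
  }
  X <- build(cap_metrics, "metric", cap_metric_names, "CAP-metric")
  Y <- build(eib_features, "feature", eib_feature_names, "EIB-feature")
  list(X = .zscore_cols(X), Y = .zscore_cols(Y), subjects = subjects)
}

#' PLSC decomposition of the cross-block covariance
#'
#' Computes R = t(Y) X / (n - 1) and its SVD R = U S t(V); latent scores
#' are X V and Y U. Signs are fixed so that each component's largest-|value|
#' X loading is positive. Explained covariance is the squared singular value
#' share.
#'
#' @param X,Y Z-scored blocks with matching rows.
#' @return A `plsc_result` list: `singular_values`, `explained_cov_pct`,
#'   `x_loadings` (V), `y_loadings` (U), `x_scores`, `y_scores`,
#'   `score_correlation`.
#' @export
plsc_fit <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  if (n < 3 || nrow(Y) != n) stop("need >= 3 matching rows")
  R <- crossprod(Y, X) / (n - 1)
  if (all(abs(R) < 1e-15)) {
    warning("rank-0 cross-covariance; returning zero result")
    r <- min(dim(R))
    return(structure(list(
      singular_values = rep(0, r), explained_cov_pct = rep(0, r),
      x_loadings = matrix(0, ncol(X), r), y_loadings = matrix(0, ncol(Y), r),
      x_scores = matrix(0, n, r), y_scores = matrix(0, n, r),
      score_correlation = rep(NA_real_, r)), class = "plsc_result"))
  }
  sv <- svd(R)
  U <- sv$u; V <- sv$v; s <- sv$d
  for (i in seq_along(s)) {
    j <- which.max(abs(V[, i]))
    if (V[j, i] < 0) {
      V[, i] <- -V[, i]; U[, i] <- -U[, i]
    }
  }
  xs <- X %*% V; ys <- Y %*% U
  rho <- vapply(seq_along(s), function(i) {
    if (stats::sd(xs[, i]) == 0 || stats::sd(ys[, i]) == 0) NA_real_
    else stats::cor(xs[, i], ys[, i])
  }, 0)
  rownames(V) <- colnames(X); rownames(U) <- colnames(Y)
  structure(list(singular_values = s,
                 explained_cov_pct = 100 * s^2 / sum(s^2),
                 x_loadings = V, y_loadings = U,
                 x_scores = xs, y_scores = ys,
                 score_correlation = rho), class = "plsc_result")
}

#' Permutation significance and bootstrap stability for PLSC
#'
#' Permutation: Y rows are shuffled and the decomposition refit; component
#' i's null statistic is the i-th singular value, and
#' p = (1 + #(null >= observed)) / (1 + n_perm). Bootstrap: subjects are
#' resampled with replacement, loadings are sign-aligned to the original by
#' inner product, and percentile 95% CIs flag loadings whose interval
#' excludes zero.
#'
#' @param X,Y Z-scored blocks.
#' @param n_perm Number of permutations (default 1000; < 100 warns).
#' @param n_boot Number of bootstrap resamples (default 10000).
#' @param seed Integer seed.
#' @param conf Bootstrap CI level.
#' @return The [plsc_fit()] result extended with `perm_p`, `x_ci`, `y_ci`
#'   (arrays loading x (lo, hi) x component), `x_reliable`, `y_reliable`.
#' @export
plsc_significance <- function(X, Y, n_perm = 1000, n_boot = 10000,
                              seed = 1L, conf = 0.95) {
  if (n_perm < 100) warning("n_perm < 100 gives unstable p-values")
  fit <- plsc_fit(X, Y)
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); r <- length(fit$singular_values)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  exceed <- integer(r)
  for (p in seq_len(n_perm)) {
    sp <- svd(crossprod(Y[sample.int(n), , drop = FALSE], X) / (n - 1),
              nu = 0, nv = 0)$d
    exceed <- exceed + (sp >= fit$singular_values - 1e-15)
  }
  fit$perm_p <- (1 + exceed) / (1 + n_perm)
  alpha <- (1 - conf) / 2
  if (n_boot > 0) {
    xb <- array(NA_real_, c(ncol(X), r, n_boot))
    yb <- array(NA_real_, c(ncol(Y), r, n_boot))
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, replace = TRUE)
      sv <- svd(crossprod(Y[idx, , drop = FALSE],
                          X[idx, , drop = FALSE]) / (n - 1))
      U <- sv$u; V <- sv$v
      for (i in seq_len(r)) {
        if (sum(V[, i] * fit$x_loadings[, i]) < 0) {
          V[, i] <- -V[, i]; U[, i] <- -U[, i]
        }
      }
      xb[, , b] <- V[, seq_len(r)]
      yb[, , b] <- U[, seq_len(r)]
    }
    qfun <- function(a) apply(a, c(1, 2), stats::quantile,
                              probs = c(alpha, 1 - alpha))
    xq <- qfun(xb); yq <- qfun(yb)   # 2 x loading x comp
    fit$x_ci <- aperm(xq, c(2, 1, 3))
    fit$y_ci <- aperm(yq, c(2, 1, 3))
    dimnames(fit$x_ci) <- list(rownames(fit$x_loadings), c("lo", "hi"), NULL)
    dimnames(fit$y_ci) <- list(rownames(fit$y_loadings), c("lo", "hi"), NULL)
    fit$x_reliable <- fit$x_ci[, "lo", ] > 0 | fit$x_ci[, "hi", ] < 0
    fit$y_reliable <- fit$y_ci[, "lo", ] > 0 | fit$y_ci[, "hi", ] < 0
  }
  fit
}
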