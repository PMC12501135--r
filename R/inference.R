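# ---------------------------------------------------------------------------
# Nonparametric session-level statistics: Kruskal-Wallis with Dunn-style
# post hoc mean-rank differences and multiplicity corrections.
# ---------------------------------------------------------------------------

#' Kruskal-Wallis test with post hoc mean-rank differences
#'
#' The omnibus H (tie-corrected) and its chi-square p-value come from
#' [stats::kruskal.test()]; post hoc comparisons report all pairwise
#' differences of pooled-rank group means with Dunn z-statistics
#' (tie-corrected) and adjusted p-values. Reported in the field's
#' chi-square(df, N) convention.
#'
#' @param groups Named list of numeric samples (>= 2 groups).
#' @param adjust `"fdr_bh"` or `"bonferroni"` for the post hoc p-values.
#' @return A `kw_result` list: `statistic` (H), `df`, `n`, `p`, `posthoc`
#'   data.frame (`pair`, `mean_rank_diff`, `z`, `p_raw`, `p_adjusted`).
#' @export
kruskal_wallis_mrd <- function(groups, adjust = c("fdr_bh", "bonferroni")) {
  adjust <- match.arg(adjust)
  stopifnot(is.list(groups), length(groups) >= 2,
            all(lengths(groups) >= 1))
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  N <- length(x)
  if (length(unique(x)) == 1) {
    kw_stat <- 0; p <- 1
  } else {
    kw <- stats::kruskal.test(x, g)
    kw_stat <- unname(kw$statistic); p <- kw$p.value
  }
  rk <- rank(x)
  mean_ranks <- tapply(rk, g, mean)
  ns <- lengths(groups)
  # tie correction term for the Dunn z denominator
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(names(groups), 2)
  ph <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    diff <- mean_ranks[[a]] - mean_ranks[[b]]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / ns[[a]] + 1 / ns[[b]]))
    z <- if (se > 0) diff / se else 0
    data.frame(pair = paste(a, b, sep = " vs "),
               mean_rank_diff = diff, z = z,
               p_raw = 2 * stats::pnorm(-abs(z)))
  })
  ph <- do.call(rbind, ph)
  ph$p_adjusted <- adjust_pvalues(ph$p_raw, adjust)
  structure(list(statistic = kw_stat, df = length(groups) - 1L, n = N,
                 p = p, posthoc = ph), class = "kw_result")
}

#' @export
print.kw_result <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis chi-square(%d,%d) = %.2f, p = %.4g\n",
              x$df, x$n, x$statistic, x$p))
  print(x$posthoc, row.names = FALSE)
  invisible(x)
}

#' Multiplicity correction
#'
#' Benjamini-Hochberg step-up (with monotonicity enforcement) or Bonferroni
#' min(m p, 1), via [stats::p.adjust()].
#'
#' @param p P-values in [0, 1].
#' @param method `"fdr_bh"` or `"bonferroni"`.
#' @param m Number of comparisons (defaults to `length(p)`).
#' @return Adjusted p-values.
#' @export
adjust_pvalues <- function(p, method = c("fdr_bh", "bonferroni"),
                           m = length(p)) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = switch(method, fdr_bh = "BH",
                                     bonferroni = "bonferroni"), n = m)
}
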