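# ---------------------------------------------------------------------------
# Natural visibility graph (NVG) temporal features of a concentration curve:
# mean out-degree of the time-directed graph and the Kullback-Leibler
# divergence between out- and in-degree distributions.
# ---------------------------------------------------------------------------

#' Directed natural visibility graph of a uniformly sampled series
#'
#' Points a < b are connected when every intermediate point lies strictly
#' below the chord between them (the natural visibility criterion with
#' strict inequality: collinear points are not mutually visible). Edges are
#' directed forward in time (a -> b). Uniform unit spacing is assumed; the
#' spacing constant cancels in the criterion.
#'
#' @param series Finite numeric series of length >= 2.
#' @return A `visibility_graph` list: `n`, `edges` (2-column matrix of
#'   index pairs a < b), `out_degree`, `in_degree`.
#' @export
nvg_adjacency <- function(series) {
  y <- as.numeric(series)
  n <- length(y)
  if (n < 2) stop("series must have length >= 2")
  if (any(!is.finite(y))) {
    stop("non-finite values at frames: ",
         paste(which(!is.finite(y)), collapse = ", "))
  }
  from <- integer(0); to <- integer(0)
  for (a in seq_len(n - 1)) {
    max_slope <- -Inf
    for (b in (a + 1):n) {
      slope <- (y[b] - y[a]) / (b - a)
      if (slope > max_slope) {
        from <- c(from, a); to <- c(to, b)
        max_slope <- slope
      }
    }
  }
  edges <- cbind(from = from, to = to)
  out_degree <- tabulate(from, nbins = n)
  in_degree <- tabulate(to, nbins = n)
  structure(list(n = n, edges = edges, out_degree = out_degree,
                 in_degree = in_degree), class = "visibility_graph")
}

#' Mean out-degree of a visibility graph
#'
#' Used as a surrogate for the temporal gradient of the curve; equals
#' |edges| / n (and therefore also the mean in-degree).
#'
#' @param graph A `visibility_graph`.
#' @return Numeric mean out-degree.
#' @export
degree_features <- function(graph) {
  stopifnot(inherits(graph, "visibility_graph"))
  mean(graph$out_degree)
}

#' KLD between out- and in-degree distributions
#'
#' Empirical degree distributions are restricted to their common support,
#' renormalized, and compared with the Kullback-Leibler divergence
#' sum P_out log(P_out / P_in) in natural log. Zero iff the renormalized
#' distributions coincide (e.g. palindromic series); a proxy for temporal
#' irreversibility / non-stationarity of the curve.
#'
#' @param graph A `visibility_graph`.
#' @param include_boundary Include the first node (in-degree 0) and last
#'   node (out-degree 0) in the distributions (default TRUE).
#' @return Non-negative numeric KLD (`Inf` with a warning if the common
#'   support is empty).
#' @export
degree_kld <- function(graph, include_boundary = TRUE) {
  stopifnot(inherits(graph, "visibility_graph"))
  outd <- graph$out_degree
  ind <- graph$in_degree
  if (!include_boundary) {
    keep_out <- seq_len(graph$n) < graph$n   # last node has out-degree 0
    keep_in <- seq_len(graph$n) > 1          # first node has in-degree 0
    outd <- outd[keep_out]; ind <- ind[keep_in]
  }
  ks <- 0:max(outd, ind)
  p_out <- tabulate(outd + 1L, nbins = length(ks)) / length(outd)
  p_in <- tabulate(ind + 1L, nbins = length(ks)) / length(ind)
  common <- p_out > 0 & p_in > 0
  if (!any(common)) {
    warning("empty common support between degree distributions")
    return(Inf)
  }
  po <- p_out[common] / sum(p_out[common])
  pi_ <- p_in[common] / sum(p_in[common])
  sum(po * log(po / pi_))
}

#' Visibility-graph features of a curve
#'
#' @param series Numeric curve (or a `concentration_curve`, whose normalized
#'   EIB frames are used).
#' @param include_boundary Passed to [degree_kld()].
#' @return List `mean_out_degree`, `kld`, `n_frames`.
#' @export
visibility_features <- function(series, include_boundary = TRUE) {
  if (inherits(series, "concentration_curve")) {
    series <- series$frames$eib_norm
  }
  g <- nvg_adjacency(series)
  list(mean_out_degree = degree_features(g),
       kld = degree_kld(g, include_boundary = include_boundary),
       n_frames = g$n)
}
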