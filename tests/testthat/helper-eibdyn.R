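# Shared fixtures and independent oracles, built in code at test time.

# O(n^3) brute-force natural-visibility check, independent of the
# running-max implementation in nvg_adjacency().
nvg_edges_bruteforce <- function(y) {
  n <- length(y)
  from <- integer(0); to <- integer(0)
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      visible <- TRUE
      if (b > a + 1) {
        for (cc in (a + 1):(b - 1)) {
          chord <- y[b] + (y[a] - y[b]) * (b - cc) / (b - a)
          if (y[cc] >= chord) { visible <- FALSE; break }
        }
      }
      if (visible) { from <- c(from, a); to <- c(to, b) }
    }
  }
  cbind(from = from, to = to)
}

# Tiny noiseless edited session with constant concentrations.
make_tiny_session <- function(n_pairs = 4, glx = 10, gaba = 2,
                              noise_sd = 0, seed = 1) {
  design <- session_design("0back", n_on_off_pairs = n_pairs)
  series <- data.frame(glx = rep(glx, n_pairs), gaba = rep(gaba, n_pairs))
  simulate_edited_session(series, peak_params(noise_sd = noise_sd), design,
                          seed = seed)
}

# Random state sequence over states 0..K.
random_state_seq <- function(n, K) sample(0:K, n, replace = TRUE)

# Stationary distribution of a row-stochastic matrix.
stationary_dist <- function(P) {
  ev <- eigen(t(P))
  v <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
  v / sum(v)
}
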