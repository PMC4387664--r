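# Independent oracles used to cross-check the recursive simulator.

# Thinning (rejection) simulator of an inhomogeneous Poisson process on
# [0, tau]: candidates from a homogeneous process at the majorant rate are
# accepted with probability rate(t) / rate_max.  Independent of the
# conditional-cumulative-hazard inversion used by the package.
thinning_counts <- function(rate_fn, rate_max, tau, n) {
  vapply(seq_len(n), function(i) {
    t <- 0
    k <- 0L
    repeat {
      t <- t + stats::rexp(1, rate_max)
      if (t > tau) break
      if (stats::runif(1) < rate_fn(t) / rate_max) k <- k + 1L
    }
    k
  }, integer(1))
}

# events per subject from a counting-process table
events_per_subject <- function(tab, n) {
  tabulate(tab$id[tab$status == 1], nbins = n)
}

# pool integer count vectors into bins with expected counts >= 5 under the
# reference probabilities; returns observed matrix (one row per sample)
# and reference probs, for chi-square tests
pool_bins <- function(counts_list, probs, n_ref) {
  kmax <- length(probs) - 1L
  upper <- kmax
  while (upper > 1 && n_ref * probs[upper + 1L] < 5) upper <- upper - 1L
  pool <- function(x) {
    h <- tabulate(pmin(x, upper) + 1L, nbins = upper + 1L)
    h
  }
  p <- c(probs[seq_len(upper)], sum(probs[(upper + 1L):(kmax + 1L)]))
  list(obs = t(vapply(counts_list, pool, numeric(upper + 1L))), probs = p)
}

# mean of trial-design defaults used across design tests
base_design <- function(...) trial_design(...)
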