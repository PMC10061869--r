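# Small simulated datasets shared across test files; built once per session.
tiny_sim_cache <- new.env(parent = emptyenv())

# 3 groups x 8 donors x 1 dose, 150 genes, a few injected effects: big enough
# to run every stage, small enough for fast tests.
tiny_sim <- function() {
  if (is.null(tiny_sim_cache$sim)) {
    cfg <- sim_config(n_genes = 150, samples_per_group = 8, doses = "0",
                      frac_hyper = 0.1, frac_hypo = 0.1, frac_bimodal = 0.06,
                      frac_de = 0.04, effect_hyper = 10, effect_hypo = 10,
                      seed = 404)
    tiny_sim_cache$sim <- simulate_counts(cfg)
  }
  tiny_sim_cache$sim
}

# brute-force tau-b oracle: O(n^2) pair counting with tie correction
tau_b_oracle <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- sign(x[j] - x[i]); dy <- sign(y[j] - y[i])
      if (dx == 0 && dy == 0) next
      if (dx == 0) tx <- tx + 1
      else if (dy == 0) ty <- ty + 1
      else if (dx == dy) conc <- conc + 1
      else disc <- disc + 1
    }
  }
  (conc - disc) / sqrt((conc + disc + tx) * (conc + disc + ty))
}

# exact bootstrap-MAD oracle for length-3 input: enumerate all 27 resamples
boot_mad_enum_oracle <- function(x, constant = 1.4826) {
  stopifnot(length(x) == 3)
  grid <- expand.grid(1:3, 1:3, 1:3)
  mads <- apply(grid, 1, function(idx) stats::mad(x[idx], constant = constant))
  stats::median(mads)
}

# direct one-sided hypergeometric upper tail by summation
hyper_tail_oracle <- function(k, K, N, n) {
  j <- k:min(n, K)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# direct BH definition: min over ranks >= i of p_(j) * m / j
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  adj[order(o)]
}
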