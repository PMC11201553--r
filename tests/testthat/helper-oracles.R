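# Independent oracles and small generators shared across the suite.

# Central finite-difference forces from energies alone; deliberately
# separate from any gradient code in the package.
fd_forces_oracle <- function(energy_fn, coords, h = 1e-5) {
  f <- matrix(0, nrow(coords), 3)
  for (i in seq_len(nrow(coords))) {
    for (d in 1:3) {
      cp <- coords; cp[i, d] <- cp[i, d] + h
      cm <- coords; cm[i, d] <- cm[i, d] - h
      f[i, d] <- -(energy_fn(cp) - energy_fn(cm)) / (2 * h)
    }
  }
  f
}

# Product-moment correlation straight from the covariance formula.
brute_pearson <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Rank-then-Pearson with average ranks, built from first principles.
brute_spearman <- function(x, y) {
  avg_rank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) r[i] <- mean(which(sort(v) == v[i]))
    r
  }
  brute_pearson(avg_rank(x), avg_rank(y))
}

# Atoms on a jittered lattice: random but never closer than ~1 sigma,
# keeping LJ forces in a numerically benign range for FD checks.
random_lattice_coords <- function(n, spacing = 1.4, jitter = 0.1) {
  side <- ceiling(n^(1 / 3))
  g <- unname(as.matrix(expand.grid(seq_len(side), seq_len(side),
                                    seq_len(side))))
  g[seq_len(n), , drop = FALSE] * spacing +
    matrix(stats::runif(3 * n, -jitter, jitter), n, 3)
}
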