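# Independent oracles used across the suite. These deliberately share no code
# with the package implementation paths they check.

# Two-sided Fisher p by exhaustive hypergeometric enumeration over all tables
# with the observed margins (minimum-likelihood rule).
fisher_enumeration_oracle <- function(tab) {
  a <- tab[1, 1]
  m1 <- sum(tab[1, ]); m2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  xs <- max(0, c1 - m2):min(m1, c1)
  probs <- stats::dhyper(xs, m1, m2, c1)
  p0 <- stats::dhyper(a, m1, m2, c1)
  sum(probs[probs <= p0 * (1 + 1e-7)])
}

# Cox partial log-likelihood for a single binary covariate, tie-free data,
# written directly from the definition (no Newton-Raphson, no Efron terms).
cox_partial_loglik_oracle <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- which(time >= time[i])
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# Grid maximization of the oracle partial likelihood.
cox_grid_oracle <- function(time, event, x, grid = seq(-4, 4, by = 1e-4)) {
  ll <- vapply(grid, cox_partial_loglik_oracle, numeric(1),
               time = time, event = event, x = x)
  grid[which.max(ll)]
}

# Elemental-formula oracle for permethylated residue increments:
# dehydro residue formula plus n methylene groups, from scratch.
residue_increment_oracle <- function(kind) {
  masses <- c(C = 12, H = 1.0078250319, N = 14.0030740052, O = 15.9949146221)
  f <- function(C = 0, H = 0, N = 0, O = 0) {
    sum(c(C, H, N, O) * masses)
  }
  switch(kind,
    Hex = f(C = 6, H = 10, O = 5) + 3 * f(C = 1, H = 2),
    dHex = f(C = 6, H = 10, O = 4) + 2 * f(C = 1, H = 2),
    HexNAc = f(C = 8, H = 13, N = 1, O = 5) + 3 * f(C = 1, H = 2),
    NeuAc = f(C = 11, H = 17, N = 1, O = 8) + 5 * f(C = 1, H = 2)
  )
}

# One-row spectrum wrapper for match_spectrum tests.
make_spectrum <- function(peaks, precursor_mz, charge = 2L) {
  list(precursor_mz = precursor_mz, charge = charge, peaks = peaks)
}
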