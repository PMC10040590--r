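# Shared fixtures: all data are generated in code at test time.

# a tiny deterministic genotype panel
tiny_geno <- function(n = 8, m = 12, seed = 424) {
  simulate_genotypes(sim_config(n_lines = n, m_markers = m, seed = seed))
}

# short chain for unit tests (module behavior, not posterior precision)
mc_test <- function(n_iter = 600, burn_in = 200, thin = 2)
  mcmc_settings(n_iter, burn_in, thin)

# phenotype from a planted single QTL explaining `prop` of the variance
planted_qtl_phenotype <- function(geno, qtl, prop = 0.5, seed = 1) {
  set.seed(seed)
  x <- geno$values[, qtl]
  g <- (x - mean(x)) / sd(x) * sqrt(prop)
  y <- g + rnorm(nrow(geno$values), 0, sqrt(1 - prop))
  setNames(y, geno$line_ids)
}

# closed-form GLS oracle for the fixed-variance kernel model:
# mu by GLS under V = vu*K + ve*I, then u = vu*K V^-1 (y - mu)
conjugate_oracle <- function(y, K, vu, ve) {
  n <- length(y)
  V <- vu * K + ve * diag(n)
  Vi <- solve(V)
  one <- rep(1, n)
  mu <- as.numeric((t(one) %*% Vi %*% y) / (t(one) %*% Vi %*% one))
  as.numeric(vu * K %*% Vi %*% (y - mu))
}

# brute-force pairwise r^2 between all marker columns (LD-pruning oracle)
brute_force_r2 <- function(X) {
  m <- ncol(X)
  out <- matrix(0, m, m)
  for (a in seq_len(m - 1)) for (b in (a + 1):m) {
    r <- suppressWarnings(cor(X[, a], X[, b]))
    out[a, b] <- out[b, a] <- if (is.na(r)) 0 else r^2
  }
  out
}
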