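# Shared fixtures and independent oracles.

sch9 <- b_scheme()

# Closed-form AUC of two Gaussian classes (higher mean = positive class).
auc_two_gaussians <- function(mu_pos, sd_pos, mu_neg, sd_neg) {
  stats::pnorm((mu_pos - mu_neg) / sqrt(sd_pos^2 + sd_neg^2))
}

# Brute-force exact two-sided Mann-Whitney p by enumerating every assignment
# of the pooled ranks to group a.
mw_exact_bruteforce <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  sets <- utils::combn(length(pooled), n1)
  us <- apply(sets, 2, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Dense grid-search IVIM oracle: lowest residual sum of squares over a
# regular grid of the bounded parameter box.
ivim_grid_rss <- function(b, y, n = 50) {
  dt <- seq(1e-5, 3e-3, length.out = n)
  dp <- seq(1e-3, 0.5, length.out = n)
  f <- seq(0, 1, length.out = n)
  grid <- expand.grid(dt = dt, dp = dp, f = f)
  slow <- exp(-outer(grid$dt, b))
  fast <- exp(-outer(grid$dt + grid$dp, b))
  pred <- (1 - grid$f) * slow + grid$f * fast
  min(rowSums(sweep(pred, 2, y)^2))
}

# Random blob-ish 3-D mask for overlap identities.
random_mask <- function(d = c(8, 8, 4), p = 0.4) {
  array(stats::runif(prod(d)) < p, d)
}
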