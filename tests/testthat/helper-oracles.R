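# Independent oracles used across the suite. These deliberately recompute
# quantities with explicit matrix algebra / brute force, never by calling
# the implementation under test.

# 2SLS coefficients via the explicit projection matrix P = Z (Z'Z)^-1 Z'.
oracle_tsls <- function(Z, X, y) {
  P <- Z %*% solve(crossprod(Z)) %*% t(Z)
  Xh <- P %*% X
  solve(crossprod(Xh, Xh), crossprod(Xh, y))
}

# HC1 sandwich for 2SLS: bread from the projected design, residuals from
# the actual regressors, explicit diagonal weighting matrix.
oracle_tsls_hc1 <- function(Z, X, y) {
  n <- nrow(X); k <- ncol(X)
  P <- Z %*% solve(crossprod(Z)) %*% t(Z)
  Xh <- P %*% X
  b <- solve(crossprod(Xh), crossprod(Xh, y))
  u <- drop(y - X %*% b)
  bread <- solve(crossprod(Xh))
  meat <- t(Xh) %*% diag(u^2) %*% Xh
  V <- bread %*% meat %*% bread * n / (n - k)
  list(b = drop(b), se = sqrt(diag(V)))
}

# Elementwise multiply-sum-divide risk score.
oracle_grs <- function(geno, weights) {
  sapply(rownames(geno), function(i) {
    s <- 0; m <- 0
    for (j in seq_len(nrow(weights))) {
      d <- geno[i, weights$snp_id[j]]
      if (!is.na(d)) { s <- s + d * weights$weight[j]; m <- m + 1 }
    }
    s / m
  })
}

# Exact Hardy-Weinberg chi-square test from genotype counts.
oracle_hwe_p <- function(d) {
  n <- length(d)
  counts <- c(sum(d == 0), sum(d == 1), sum(d == 2))
  f <- mean(d) / 2
  expd <- n * c((1 - f)^2, 2 * f * (1 - f), f^2)
  stat <- sum((counts - expd)^2 / expd)
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

# Brute-force weighted median: order, midpoint cumulative weights,
# piecewise-linear inverse evaluated at one half.
oracle_weighted_median <- function(r, w) {
  o <- order(r)
  r <- r[o]; w <- w[o] / sum(w)
  cw <- cumsum(w) - w / 2
  stats::approx(cw, r, xout = 0.5, rule = 2)$y
}

# The documented bandwidth rule, recomputed independently:
# bf * 0.9 * min(weighted SD, 1.4826 * weighted MAD) * J^(-1/5).
oracle_bandwidth <- function(r, w, bf = 1) {
  w <- w / sum(w)
  mu <- sum(w * r)
  wsd <- sqrt(sum(w * (r - mu)^2))
  med <- oracle_weighted_median(r, w)
  wmad <- 1.4826 * oracle_weighted_median(abs(r - med), w)
  spread <- min(wsd, if (wmad > 0) wmad else wsd)
  bf * 0.9 * spread * length(r)^(-1 / 5)
}

# Grid-search KDE mode with a normal kernel and supplied bandwidth.
oracle_kde_mode <- function(r, w, h, n_grid = 512) {
  w <- w / sum(w)
  grid <- seq(min(r) - 3 * h, max(r) + 3 * h, length.out = n_grid)
  dens <- sapply(grid, function(x) sum(w * stats::dnorm(x, mean = r, sd = h)))
  grid[which.max(dens)]
}

# Shorthand: simulated data frame ready for the 2SLS fitters.
prep <- function(cfg) prepare_cohort(simulate_cohort(cfg))

# Small non-preset configuration used by many unit tests.
tiny_config <- function(n = 3000, seed = 1, ...) {
  sim_config(n_individuals = n, n_snps_bmi = 8, n_snps_whr = 8,
             n_snps_shared = 0, h2_bmi = 0.1, h2_whr = 0.1,
             delta_bmi_to_whr = 0.3, conf_bmi = 0.3, conf_whr = 0.2,
             kappa_confounder = 0.4,
             outcomes = list(trig = list(theta_bmi = 0.1, theta_whr = 0.4)),
             seed = seed, ...)
}
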