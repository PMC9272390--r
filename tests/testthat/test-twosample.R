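mk_stats <- function(bx, by, sx = 0.03, sy = 0.05) {
  J <- length(bx)
  data.frame(snp = paste0("rs", seq_len(J)), effect_allele = "A",
             other_allele = "G", beta_x = bx, se_x = rep_len(sx, J),
             beta_y = by, se_y = rep_len(sy, J), eaf = 0.3,
             stringsAsFactors = FALSE)
}

gwas_df <- function(snp, ea, oa, beta, se = 0.02, eaf = NA) {
  data.frame(snp = snp, effect_allele = ea, other_allele = oa,
             beta = beta, se = se, eaf = eaf, stringsAsFactors = FALSE)
}

test_that("harmonisation aligns alleles, flips, and drops ambiguity", {
  ex <- gwas_df(c("rs1", "rs2", "rs3"), c("A", "C", "T"), c("G", "T", "C"),
                c(0.1, 0.2, 0.3), eaf = c(0.2, 0.3, 0.25))
  # rs1 identical orientation; rs2 swapped alleles; rs3 mismatched pair
  out <- gwas_df(c("rs1", "rs2", "rs3"), c("A", "T", "A"), c("G", "C", "C"),
                 c(0.5, 0.6, 0.7), eaf = c(0.2, 0.7, 0.5))
  expect_message(h <- harmonise_sumstats(ex, out), "dropped 1")
  expect_equal(h$snp, c("rs1", "rs2"))
  expect_equal(h$beta_y, c(0.5, -0.6))
  expect_equal(h$beta_x, c(0.1, 0.2))
})

test_that("palindromic SNPs are resolved by allele frequency or dropped", {
  cases <- list(
    # eaf_x, eaf_y, expected flip (NA = dropped)
    c(0.10, 0.11, FALSE), # same orientation
    c(0.10, 0.89, TRUE),  # opposite orientation
    c(0.90, 0.12, TRUE),
    c(0.50, 0.10, NA)     # exposure side ambiguous
  )
  for (cs in cases) {
    ex <- gwas_df("rs9", "A", "T", 0.2, eaf = cs[1])
    out <- gwas_df("rs9", "A", "T", 0.4, eaf = cs[2])
    if (is.na(cs[3])) {
      expect_error(suppressMessages(harmonise_sumstats(ex, out)), "survived")
    } else {
      h <- harmonise_sumstats(ex, out)
      expect_equal(h$beta_y, if (cs[3]) -0.4 else 0.4)
    }
  }
})

test_that("IVW: Wald ratio, weighted-mean identity, WLS oracle", {
  one <- mk_stats(0.05, 0.02)
  expect_equal(mr_ivw(one)$beta, 0.02 / 0.05)
  # all ratios equal: the estimate is that common ratio for any weights
  bx <- c(0.02, 0.05, 0.09, 0.04)
  same <- mk_stats(bx, 0.3 * bx, sy = c(0.01, 0.05, 0.02, 0.08))
  expect_equal(mr_ivw(same)$beta, 0.3, tolerance = 1e-12)

  set.seed(31)
  st <- mk_stats(runif(5, 0.02, 0.1), rnorm(5, 0.04, 0.02),
                 sy = runif(5, 0.02, 0.08))
  fit <- lm(beta_y ~ 0 + beta_x, data = st, weights = 1 / st$se_y^2)
  expect_equal(mr_ivw(st)$beta, unname(coef(fit)), tolerance = 1e-10)
  # zero-effect SNPs are excluded with a warning, not fatal
  st2 <- rbind(st, mk_stats(0, 0.01))
  expect_warning(r2 <- mr_ivw(st2), "beta_x = 0")
  expect_equal(r2$n_snps, 5L)
})

test_that("Egger: exact linear data, intercept-constrained reduction", {
  bx <- c(0.02, 0.04, 0.055, 0.07, 0.1)
  st <- mk_stats(bx, 0.05 + 0.3 * bx)
  r <- mr_egger(st)
  expect_equal(r$beta, 0.3, tolerance = 1e-10)
  expect_equal(r$egger_intercept, 0.05, tolerance = 1e-10)

  set.seed(32)
  st2 <- mk_stats(runif(8, 0.02, 0.1), rnorm(8, 0.03, 0.02),
                  sy = runif(8, 0.02, 0.06))
  # with the intercept forced to zero the Egger regression is exactly IVW
  constrained <- lm(beta_y ~ 0 + beta_x, data = st2, weights = 1 / st2$se_y^2)
  expect_equal(mr_ivw(st2)$beta, unname(coef(constrained)), tolerance = 1e-10)
  expect_error(mr_egger(mk_stats(rep(0.05, 5), rnorm(5, 0.02, 0.01))),
               "instrument strength")
})

test_that("weighted median: equal-weight median, dominant SNP, oracle match", {
  st <- mk_stats(c(0.1, 0.1, 0.1), c(0.1, 0.2, 0.9)) # ratios 1, 2, 9
  expect_equal(mr_weighted_median(st, n_boot = 100, seed = 1)$beta, 2)

  # one SNP with most of the weight, rest symmetric: pinned at its ratio
  st2 <- mk_stats(c(0.1, 0.1, 0.1), c(0.05, 0.30, 0.50),
                  sy = c(0.08, 0.02, 0.08)) # weights prop 1/16, 1, 1/16
  expect_equal(mr_weighted_median(st2, n_boot = 100, seed = 1)$beta, 3)

  set.seed(33)
  st3 <- mk_stats(runif(9, 0.02, 0.1), rnorm(9, 0.04, 0.03),
                  sy = runif(9, 0.02, 0.08))
  r <- st3$beta_y / st3$beta_x
  w <- st3$beta_x^2 / st3$se_y^2
  expect_equal(mr_weighted_median(st3, n_boot = 100, seed = 1)$beta,
               oracle_weighted_median(r, w), tolerance = 1e-12)
})

test_that("weighted median resists contamination better than IVW", {
  reps <- 300
  set.seed(34)
  bias <- replicate(reps, {
    J <- 20
    bx <- runif(J, 0.03, 0.1)
    sy <- rep(0.02, J)
    by <- 0.3 * bx + rnorm(J, 0, sy)
    bad <- seq_len(J) <= 6 # 30% pleiotropic, +1 offset on the ratio scale
    by[bad] <- by[bad] + 1 * bx[bad]
    st <- mk_stats(bx, by, sy = sy)
    c(ivw = mr_ivw(st)$beta - 0.3,
      med = adipomr:::weighted_median_point(by / bx, bx^2 / sy^2) - 0.3)
  })
  expect_lt(abs(mean(bias["med", ]) ), abs(mean(bias["ivw", ])))
})

test_that("weighted mode: point mass, dominant cluster, flat-kernel limit", {
  st <- mk_stats(c(0.05, 0.1, 0.2), c(0.05, 0.1, 0.2) * 0.7)
  expect_equal(mr_weighted_mode(st, n_boot = 100, seed = 1)$beta, 0.7)

  bx <- rep(0.1, 10)
  by <- c(rep(0.03, 7), rep(0.2, 3)) # ratios: 7 at 0.3, 3 at 2.0
  st2 <- mk_stats(bx, by)
  r2 <- mr_weighted_mode(st2, n_boot = 100, seed = 1)
  expect_lt(abs(r2$beta - 0.3), 0.05)
  expect_gt(abs(r2$beta - mean(by / bx)), 0.3) # not the mean (~0.81)
  # matches the independent grid-search KDE oracle at the same bandwidth
  r <- by / bx
  w <- bx^2 / st2$se_y^2
  h <- oracle_bandwidth(r, w, 1)
  expect_equal(r2$beta, oracle_kde_mode(r, w, h), tolerance = 1e-9)
  # very large bandwidth: estimate approaches the weighted mean, up to the
  # resolution of the evaluation grid (which widens with the bandwidth)
  rbig <- mr_weighted_mode(st2, bandwidth_factor = 200, n_boot = 100, seed = 1)
  wm <- sum(w * r) / sum(w)
  hbig <- oracle_bandwidth(r, w, 200)
  step <- (diff(range(r)) + 6 * hbig) / 511
  expect_lt(abs(rbig$beta - wm), 2 * step)
  expect_gt(abs(rbig$beta - 0.3), abs(rbig$beta - wm)) # left the cluster mode
})

test_that("estimators are invariant to SNP order and joint sign flips", {
  set.seed(35)
  st <- mk_stats(runif(12, 0.02, 0.1), rnorm(12, 0.04, 0.03),
                 sy = runif(12, 0.02, 0.08))
  flip <- c(2, 5, 9)
  st_f <- st
  st_f$beta_x[flip] <- -st_f$beta_x[flip]
  st_f$beta_y[flip] <- -st_f$beta_y[flip]
  st_p <- st[sample(12), ]
  for (fun in list(mr_ivw,
                   mr_egger,
                   function(s) mr_weighted_median(s, n_boot = 100, seed = 2),
                   function(s) mr_weighted_mode(s, n_boot = 100, seed = 2))) {
    b0 <- fun(st)$beta
    expect_equal(fun(st_f)$beta, b0, tolerance = 1e-9)
    expect_equal(fun(st_p)$beta, b0, tolerance = 1e-9)
  }
})

test_that("estimator preconditions are enforced", {
  st2 <- mk_stats(c(0.1, 0.2), c(0.1, 0.1))
  expect_error(mr_egger(st2), "at least 3")
  expect_error(mr_weighted_median(st2), "at least 3")
  expect_warning(
    mr_weighted_median(mk_stats(c(0.1, 0.1, 0.2), c(0.1, 0.1, 0.1)),
                       n_boot = 50, seed = 1), "n_boot")
})
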