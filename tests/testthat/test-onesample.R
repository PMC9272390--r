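# Shared fixture: modest cohort with known columns.
fix_d <- prep(tiny_config(n = 1200, seed = 21))

test_that("degenerate and closed-form cases of univariable 2SLS", {
  d <- fix_d
  # outcome identical to the exposure: slope 1, (near-)zero residual SE
  d$same <- d$bmi
  r <- fit_2sls(d, mr_spec("bmi", "grs_bmi", "same", covariates = character()))
  expect_equal(r$beta, 1, tolerance = 1e-10)
  expect_lt(r$se, 1e-10)
  # just-identified, no covariates: exactly the Wald ratio
  r2 <- fit_2sls(d, mr_spec("bmi", "grs_bmi", "trig", covariates = character()))
  wald <- cov(d$grs_bmi, d$trig) / cov(d$grs_bmi, d$bmi)
  expect_equal(r2$beta, wald, tolerance = 1e-10)
  expect_true(r2$ci_low <= r2$beta && r2$beta <= r2$ci_high)
})

test_that("2SLS coefficients and robust SEs match the matrix oracle", {
  set.seed(22)
  n <- 200
  z <- rnorm(n); c1 <- rnorm(n)
  x <- 0.6 * z + 0.4 * c1 + rnorm(n)
  y <- 0.5 * x + 0.3 * c1 + rnorm(n) * (1 + 0.5 * abs(c1)) # heteroskedastic
  d <- data.frame(z = z, c1 = c1, x = x, y = y)
  r <- fit_2sls(d, mr_spec("x", "z", "y", covariates = "c1"))
  Z <- cbind(1, z, c1); X <- cbind(1, x, c1)
  o <- oracle_tsls_hc1(Z, X, y)
  expect_equal(r$beta, unname(o$b[2]), tolerance = 1e-10)
  expect_equal(r$se, unname(o$se[2]), tolerance = 1e-10)
})

test_that("2SLS is scale equivariant", {
  d <- fix_d
  sp <- mr_spec("bmi", "grs_bmi", "trig", covariates = c("age", "sex"))
  base <- fit_2sls(d, sp)
  d2 <- d; d2$trig <- 3 * d$trig
  r2 <- fit_2sls(d2, sp)
  expect_equal(r2$beta, 3 * base$beta, tolerance = 1e-10)
  expect_equal(r2$se, 3 * base$se, tolerance = 1e-10)
  d3 <- d; d3$bmi <- d$bmi / 2
  r3 <- fit_2sls(d3, sp)
  expect_equal(r3$beta, 2 * base$beta, tolerance = 1e-10)
})

test_that("covariates orthogonal to the system leave the estimate nearly unchanged", {
  d <- fix_d
  set.seed(23)
  d$noise_cov <- rnorm(nrow(d))
  b0 <- fit_2sls(d, mr_spec("bmi", "grs_bmi", "trig", covariates = character()))$beta
  b1 <- fit_2sls(d, mr_spec("bmi", "grs_bmi", "trig", covariates = "noise_cov"))$beta
  expect_lt(abs(b1 - b0), 0.02)
})

test_that("multivariable 2SLS returns per-exposure rows and rejects degeneracy", {
  d <- fix_d
  sp <- mr_spec(c("bmi", "whr"), c("grs_bmi", "grs_whr"), "trig",
                covariates = c("age", "sex"))
  r <- fit_mv_2sls(d, sp)
  expect_equal(nrow(r), 2L)
  expect_setequal(r$exposure, c("bmi", "whr"))
  expect_true(all(is.finite(r$f_stat_conditional)))
  # identical exposures instrumented by the same score twice: singular
  d2 <- d; d2$whr <- d$bmi; d2$grs_whr <- d$grs_bmi
  expect_error(fit_mv_2sls(d2, sp), "singular|condition number")
})

test_that("casewise deletion reports per-model n", {
  d <- fix_d
  d$trig[1:25] <- NA
  r <- fit_2sls(d, mr_spec("bmi", "grs_bmi", "trig", covariates = c("age", "sex")))
  expect_equal(r$n, nrow(d) - 25L)
})

test_that("logistic second stage: null outcome, degenerate outcome", {
  d <- fix_d
  set.seed(24)
  d$flag <- rbinom(nrow(d), 1, 0.2) # independent of everything
  r <- fit_2sls_logistic(d, mr_spec("bmi", "grs_bmi", "flag",
                                    covariates = c("age", "sex")))
  expect_true(r$or_ci_low < 1 && 1 < r$or_ci_high)
  d$zero <- 0
  expect_error(fit_2sls_logistic(d, mr_spec("bmi", "grs_bmi", "zero",
                                            covariates = c("age", "sex"))),
               "single class")
  d$cont <- rnorm(nrow(d))
  expect_error(fit_2sls_logistic(d, mr_spec("bmi", "grs_bmi", "cont",
                                            covariates = character())), "0/1")
})

test_that("logistic second stage recovers a generative statin slope", {
  # large single cohort; whr/ldl paths switched off isolates the BMI slope
  cfg <- ukb_like_config(50000, seed = 25, statin_slope_whr = 0,
                         statin_slope_ldl = 0, age_statin_gradient = 0,
                         statin_intercept = -1.5)
  d <- prep(cfg)
  r <- fit_2sls_logistic(d, mr_spec("bmi", "grs_bmi", "statin"))
  expect_lt(abs(r$beta - 0.4), 3 * r$se + 0.05)
  expect_gt(r$or, 1)
})

test_that("interaction test: parameterisation identities on a binary modifier", {
  d <- fix_d
  sp <- mr_spec("bmi", "grs_bmi", "trig", covariates = c("age"))
  r0 <- interaction_test(d, sp, modifier = "sex")
  d$sexflip <- 1 - d$sex
  r1 <- interaction_test(d, sp, modifier = "sexflip")
  # recoding the modifier flips the product term and shifts the main effect
  expect_equal(r1$beta, -r0$beta, tolerance = 1e-10)
  expect_equal(r1$main_beta, r0$main_beta + r0$beta, tolerance = 1e-10)
  d$const <- 1
  expect_error(interaction_test(d, sp, modifier = "const"), "constant")
})

test_that("interaction test recovers a sex difference in effects", {
  cfg <- ukb_like_config(40000, seed = 26, sex_effect_overrides = list(
    trig = list(male = list(theta_bmi = 0, theta_whr = 0.45),
                female = list(theta_bmi = 0, theta_whr = 0.75))))
  d <- prep(cfg)
  sp <- mr_spec("whr", "grs_whr", "trig",
                covariates = c("age", paste0("pc", 1:10)))
  r <- interaction_test(d, sp, modifier = "sex")
  expect_lt(abs(r$beta - 0.3), 3 * r$se)
  expect_lt(r$interaction_p, 0.01)
})

test_that("conditional F: univariable reduction, collinear limit, identification", {
  d <- fix_d
  f_uv <- conditional_f(d, mr_spec("bmi", "grs_bmi", "trig",
                                   covariates = c("age", "sex")))
  r_uv <- fit_2sls(d, mr_spec("bmi", "grs_bmi", "trig",
                              covariates = c("age", "sex")))
  expect_equal(unname(f_uv), r_uv$f_stat, tolerance = 1e-10)

  # duplicated exposure: the partialled residual vanishes and the
  # conditional F collapses to noise level, far below the unconditional F
  d2 <- d; d2$whr <- d$bmi + rnorm(nrow(d)) * 1e-8
  sp2 <- mr_spec(c("bmi", "whr"), c("grs_bmi", "grs_whr"), "trig",
                 covariates = c("age", "sex"))
  f2 <- conditional_f(d2, sp2)
  expect_lt(max(f2), 30)
  expect_lt(max(f2) / r_uv$f_stat, 0.5)
})
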