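#' Specify a one-sample MR model
#'
#' Declares which columns of a cohort table play which role in a
#' two-stage least squares fit: one or two exposures, the same number of
#' genetic-score instruments, an outcome, covariates, the second-stage
#' family, and an optional observed effect modifier for product-term
#' interaction tests.
#'
#' @param exposures Character vector of 1 or 2 exposure columns.
#' @param instruments Character vector of instrument (risk-score) columns,
#'   same length as `exposures`. In multivariable fits every exposure is
#'   instrumented by all scores jointly.
#' @param outcome Outcome column.
#' @param covariates Covariate columns (default: age, sex and ten genetic
#'   principal components).
#' @param second_stage `"linear"` or `"logistic"`.
#' @param interaction_with Optional observed modifier column.
#' @return Object of class `mr_spec`.
#' @export
mr_spec <- function(exposures, instruments, outcome,
                    covariates = c("age", "sex", paste0("pc", 1:10)),
                    second_stage = c("linear", "logistic"),
                    interaction_with = NULL) {
  second_stage <- match.arg(second_stage)
  stopifnot(length(exposures) %in% 1:2,
            length(instruments) == length(exposures),
            length(outcome) == 1L)
  if (any(exposures %in% covariates))
    stop("exposures must be disjoint from covariates")
  structure(list(exposures = exposures, instruments = instruments,
                 outcome = outcome, covariates = covariates,
                 second_stage = second_stage,
                 interaction_with = interaction_with),
            class = "mr_spec")
}

# Assemble complete-case design pieces for an IV fit. Rows with any
# missing model variable are dropped per model (n varies across models).
iv_frame <- function(data, spec, extra = character()) {
  vars <- unique(c(spec$exposures, spec$instruments, spec$outcome,
                   spec$covariates, extra))
  miss <- setdiff(vars, names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  mf <- data[stats::complete.cases(data[vars]), vars, drop = FALSE]
  n <- nrow(mf)
  k_needed <- 1L + length(spec$exposures) + length(spec$covariates) +
    2L * length(extra)
  if (n < k_needed + 1L) stop("too few complete cases (n = ", n, ")")
  C <- if (length(spec$covariates)) data.matrix(mf[spec$covariates]) else NULL
  list(mf = mf, n = n, C = C,
       X = data.matrix(mf[spec$exposures]),
       Z = data.matrix(mf[spec$instruments]),
       y = mf[[spec$outcome]])
}

# Classical joint first-stage F of the instrument block for one exposure:
# compares exposure ~ instruments + covariates against exposure ~ covariates.
first_stage_f <- function(x, Zins, C, n) {
  q0 <- qr(cbind(rep(1, n), C))
  q1 <- qr(cbind(1, Zins, C))
  rss0 <- sum(qr.resid(q0, x)^2)
  rss1 <- sum(qr.resid(q1, x)^2)
  kz <- ncol(Zins)
  ((rss0 - rss1) / kz) / (rss1 / (n - ncol(cbind(1, Zins, C))))
}

# 2SLS point estimates with the IV heteroskedasticity-robust (HC1)
# sandwich: bread from the substituted design, residuals from the actual
# exposures. Returns coefficients, robust SEs and the design pieces.
tsls_core <- function(fr, spec) {
  Zfull <- cbind(`(Intercept)` = 1, fr$Z, fr$C)
  qz <- qr(Zfull)
  if (qz$rank < ncol(Zfull))
    stop("singular design: instruments collinear with covariates")
  Xhat <- qr.fitted(qz, fr$X)
  D <- cbind(1, fr$X, fr$C)
  Dh <- cbind(1, Xhat, fr$C)
  colnames(D) <- colnames(Dh) <-
    c("(Intercept)", spec$exposures, spec$covariates)
  XtX <- crossprod(Dh)
  if (kappa(XtX, exact = FALSE) > 1e10)
    stop("singular design: condition number above 1e10 (near-collinear instruments/exposures)")
  bread <- solve(XtX)
  b <- drop(bread %*% crossprod(Dh, fr$y))
  names(b) <- colnames(Dh)
  u <- drop(fr$y - D %*% b)
  k <- ncol(Dh)
  meat <- crossprod(Dh * u)
  V <- bread %*% meat %*% bread * fr$n / (fr$n - k)
  list(b = b, se = sqrt(diag(V)), V = V, Dh = Dh, u = u, qz = qz, Xhat = Xhat)
}

#' Univariable two-stage least squares
#'
#' First stage regresses the exposure on its genetic score and the
#' covariates; second stage regresses the outcome on the predicted
#' exposure and the actual covariates. Standard errors are
#' heteroskedasticity-robust (HC1) sandwich estimates in the IV influence
#' form; the 95\% CI is beta +/- 1.96 SE and p-values use the normal
#' reference. Also reports the classical first-stage F statistic.
#'
#' @param data Cohort data.frame.
#' @param spec [mr_spec()] with one exposure and one instrument and a
#'   linear second stage.
#' @param stratum Label recorded in the result row.
#' @return One-row data.frame (model_kind, exposure, outcome, stratum, n,
#'   beta, se, ci_low, ci_high, p, f_stat, f_stat_conditional,
#'   interaction_p).
#' @export
fit_2sls <- function(data, spec, stratum = "all") {
  stopifnot(inherits(spec, "mr_spec"), length(spec$exposures) == 1L,
            spec$second_stage == "linear")
  fr <- iv_frame(data, spec)
  fit <- tsls_core(fr, spec)
  f1 <- first_stage_f(fr$X[, 1L], fr$Z, fr$C, fr$n)
  mr_result_row("uv-2sls", spec$exposures, spec$outcome, stratum, fr$n,
                beta = fit$b[spec$exposures], se = fit$se[spec$exposures],
                f_stat = f1)
}

#' Multivariable two-stage least squares
#'
#' Mutual-adjustment model: each exposure is regressed on both genetic
#' scores plus covariates in the first stage, and the outcome on both
#' predicted exposures plus covariates in the second, so each coefficient
#' is the direct effect of that exposure holding the other fixed. Robust
#' (HC1) IV sandwich SEs. Reports, per exposure, the classical joint
#' first-stage F and the Sanderson-Windmeijer conditional F.
#'
#' @inheritParams fit_2sls
#' @param spec [mr_spec()] with two exposures and two instruments.
#' @return Two-row data.frame, one row per exposure (model_kind
#'   `"mv-2sls"`).
#' @export
fit_mv_2sls <- function(data, spec, stratum = "all") {
  stopifnot(inherits(spec, "mr_spec"), length(spec$exposures) == 2L,
            spec$second_stage == "linear")
  fr <- iv_frame(data, spec)
  fit <- tsls_core(fr, spec)
  fs <- vapply(1:2, function(j) first_stage_f(fr$X[, j], fr$Z, fr$C, fr$n),
               numeric(1))
  cf <- conditional_f(data, spec)
  out <- do.call(rbind, lapply(1:2, function(j) {
    ex <- spec$exposures[j]
    mr_result_row("mv-2sls", ex, spec$outcome, stratum, fr$n,
                  beta = fit$b[ex], se = fit$se[ex],
                  f_stat = fs[j], f_stat_conditional = cf[ex])
  }))
  out
}

#' Two-stage least squares with a logistic second stage
#'
#' Predictor substitution for a binary outcome: stage 1 as in
#' [fit_2sls()], stage 2 a maximum-likelihood logistic regression of the
#' outcome on the predicted exposure(s) plus covariates. `beta` is the
#' log odds ratio with its naive ML standard error (substitution SEs
#' ignore first-stage noise; set `n_boot` for a nonparametric bootstrap
#' of both stages instead). Columns `or`, `or_ci_low`, `or_ci_high` carry
#' the odds-ratio scale.
#'
#' @inheritParams fit_2sls
#' @param n_boot If > 0, number of bootstrap resamples used for the SE.
#' @return One row per exposure (model_kind `"uv-2sls-logistic"` or
#'   `"mv-2sls-logistic"`).
#' @export
fit_2sls_logistic <- function(data, spec, stratum = "all", n_boot = 0L) {
  stopifnot(inherits(spec, "mr_spec"))
  fr <- iv_frame(data, spec)
  yy <- fr$y
  if (!all(yy %in% c(0, 1))) stop("logistic second stage needs a 0/1 outcome")
  if (length(unique(yy)) < 2L)
    stop("binary outcome has a single class in the analysis sample")
  est <- function(fr) {
    Zfull <- cbind(1, fr$Z, fr$C)
    qz <- qr(Zfull)
    Xhat <- qr.fitted(qz, fr$X)
    Dh <- cbind(Xhat, fr$C)
    colnames(Dh) <- c(spec$exposures, spec$covariates)
    g <- stats::glm.fit(cbind(1, Dh), fr$y, family = stats::binomial())
    if (!g$converged) stop("logistic second stage did not converge (possible separation)")
    names(g$coefficients) <- c("(Intercept)", colnames(Dh))
    g
  }
  g <- est(fr)
  b <- g$coefficients[spec$exposures]
  # naive ML covariance from the IRLS weights
  W <- g$weights
  Dfull <- cbind(1, qr.fitted(qr(cbind(1, fr$Z, fr$C)), fr$X), fr$C)
  V <- solve(crossprod(Dfull * sqrt(W)))
  se <- sqrt(diag(V))[1L + seq_along(spec$exposures)]
  if (n_boot > 0L) {
    bs <- replicate(n_boot, {
      i <- sample.int(fr$n, fr$n, replace = TRUE)
      frb <- list(n = fr$n,
                  C = if (is.null(fr$C)) NULL else fr$C[i, , drop = FALSE],
                  X = fr$X[i, , drop = FALSE], Z = fr$Z[i, , drop = FALSE],
                  y = fr$y[i])
      tryCatch(est(frb)$coefficients[spec$exposures],
               error = function(e) rep(NA_real_, length(spec$exposures)))
    })
    se <- apply(matrix(bs, nrow = length(spec$exposures)), 1L,
                stats::sd, na.rm = TRUE)
  }
  kind <- if (length(spec$exposures) == 1L) "uv-2sls-logistic" else "mv-2sls-logistic"
  out <- do.call(rbind, lapply(seq_along(spec$exposures), function(j) {
    mr_result_row(kind, spec$exposures[j], spec$outcome, stratum, fr$n,
                  beta = b[j], se = se[j])
  }))
  out$or <- exp(out$beta)
  out$or_ci_low <- exp(out$ci_low)
  out$or_ci_high <- exp(out$ci_high)
  out
}

#' Product-term interaction test in a 2SLS model
#'
#' Tests effect modification by an observed variable (sex, statin use,
#' age): the second stage is augmented with the modifier's main effect
#' and the product of the genetically predicted exposure with the
#' modifier. Predictor substitution with heteroskedasticity-robust (HC1)
#' SEs on the second-stage design. With a binary 0/1 modifier, the main
#' exposure coefficient is the slope in the modifier-0 stratum.
#'
#' @inheritParams fit_2sls
#' @param modifier Observed modifier column; overrides
#'   `spec$interaction_with`.
#' @return One row per exposure (model_kind `"interaction"`): `beta` is
#'   the product-term coefficient and `interaction_p` its robust Wald
#'   p-value.
#' @export
interaction_test <- function(data, spec, modifier = spec$interaction_with,
                             stratum = "all") {
  stopifnot(inherits(spec, "mr_spec"), !is.null(modifier))
  fr <- iv_frame(data, spec, extra = modifier)
  mod <- fr$mf[[modifier]]
  if (length(unique(mod)) < 2L)
    stop("modifier '", modifier, "' is constant in the analysis sample")
  Zfull <- cbind(1, fr$Z, fr$C)
  qz <- qr(Zfull)
  Xhat <- qr.fitted(qz, fr$X)
  prod_terms <- Xhat * mod
  Dh <- cbind(1, Xhat, fr$C, mod, prod_terms)
  pnames <- paste0(spec$exposures, ":", modifier)
  colnames(Dh) <- c("(Intercept)", spec$exposures, spec$covariates,
                    modifier, pnames)
  XtX <- crossprod(Dh)
  if (kappa(XtX, exact = FALSE) > 1e10) stop("singular interaction design")
  bread <- solve(XtX)
  b <- drop(bread %*% crossprod(Dh, fr$y))
  names(b) <- colnames(Dh)
  u <- drop(fr$y - Dh %*% b)
  k <- ncol(Dh)
  V <- bread %*% crossprod(Dh * u) %*% bread * fr$n / (fr$n - k)
  se <- sqrt(diag(V))
  names(se) <- colnames(Dh)
  out <- do.call(rbind, lapply(seq_along(spec$exposures), function(j) {
    pj <- pnames[j]
    pv <- 2 * stats::pnorm(-abs(b[pj] / se[pj]))
    r <- mr_result_row("interaction", spec$exposures[j], spec$outcome,
                       stratum, fr$n, beta = b[pj], se = se[pj],
                       interaction_p = pv)
    r$main_beta <- b[spec$exposures[j]]
    r$main_se <- se[spec$exposures[j]]
    r
  }))
  out
}

#' Instrument-strength F statistics
#'
#' For a univariable spec, the classical first-stage F of the instrument.
#' For a multivariable spec, the Sanderson-Windmeijer conditional F of
#' each exposure given the other: exposures and scores are residualised
#' on the covariates; the conditioning exposure is partialled out of the
#' target exposure by IV using both scores; and the joint F of the scores
#' on that IV residual is scaled by k_Z / (k_Z - k_other) (here 2/1). A
#' conditional F above 10 is the conventional adequacy threshold.
#'
#' @inheritParams fit_2sls
#' @return Named numeric vector of F statistics, one per exposure.
#' @export
conditional_f <- function(data, spec) {
  stopifnot(inherits(spec, "mr_spec"))
  fr <- iv_frame(data, spec)
  if (length(spec$exposures) == 1L) {
    f <- first_stage_f(fr$X[, 1L], fr$Z, fr$C, fr$n)
    return(stats::setNames(f, spec$exposures))
  }
  if (ncol(fr$Z) < ncol(fr$X))
    stop("fewer instruments than exposures: model not identified")
  qc <- qr(cbind(rep(1, fr$n), fr$C))
  rX <- qr.resid(qc, fr$X)
  rZ <- qr.resid(qc, fr$Z)
  n <- fr$n
  out <- vapply(1:2, function(j) {
    x1 <- rX[, j]
    x2 <- rX[, -j, drop = FALSE]
    # IV regression x1 = delta x2 with both scores as instruments
    x2hat <- qr.fitted(qr(rZ), x2)
    delta <- drop(solve(crossprod(x2hat, x2), crossprod(x2hat, x1)))
    r <- x1 - drop(x2 %*% delta)
    q1 <- qr(cbind(1, rZ))
    rss1 <- sum(qr.resid(q1, r)^2)
    rss0 <- sum((r - mean(r))^2)
    kz <- ncol(rZ)
    fj <- ((rss0 - rss1) / kz) / (rss1 / (n - kz - 1L))
    fj * kz / (kz - ncol(x2))
  }, numeric(1))
  stats::setNames(out, spec$exposures)
}
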