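#' @keywords internal
"_PACKAGE"

expit <- function(x) 1 / (1 + exp(-x))

#' Z-score standardisation
#'
#' Centres and scales a numeric vector to mean 0, SD 1 (sample SD, n-1
#' denominator), computed over non-missing entries; missing values stay
#' missing. This is the standardisation applied to exposures, risk scores
#' and outcomes before model fitting, always among sexes combined.
#'
#' @param x Numeric vector with at least two distinct finite values.
#' @param name Column name used in error messages.
#' @return Numeric vector of the same length, mean 0 and SD 1 on the
#'   non-missing subset.
#' @examples
#' standardise(c(1, 2, 3))
#' @export
standardise <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x)) stop("standardise: '", name, "' is not numeric")
  ok <- is.finite(x)
  if (sum(ok) < 2L) stop("standardise: '", name, "' has fewer than 2 finite values")
  s <- stats::sd(x[ok])
  if (!is.finite(s) || s == 0)
    stop("standardise: column '", name, "' is constant")
  out <- x
  out[ok] <- (x[ok] - mean(x[ok])) / s
  out
}

# OLS of y on cbind(1, C) residuals; returns residual-maker applied to a
# matrix or vector. qc is qr(cbind(1, C)).
resid_on <- function(qc, m) {
  if (is.null(dim(m))) drop(qr.resid(qc, m)) else qr.resid(qc, m)
}

# Per-SNP OLS of a trait on each dosage column plus shared covariates,
# vectorised via Frisch-Waugh: residualise trait and dosages on the
# covariate block once, then slope/SE per column in closed form.
# Returns data.frame(beta, se) with one row per column of D.
per_snp_ols <- function(y, D, C = NULL) {
  n <- length(y)
  Cmat <- cbind(rep(1, n), C)
  qc <- qr(Cmat)
  yr <- drop(qr.resid(qc, y))
  Dr <- qr.resid(qc, D)
  ss_d <- colSums(Dr^2)
  beta <- colSums(Dr * yr) / ss_d
  rss <- sum(yr^2) - beta^2 * ss_d
  df <- n - ncol(Cmat) - 1L
  se <- sqrt(pmax(rss, 0) / df / ss_d)
  data.frame(beta = beta, se = se, row.names = colnames(D))
}

# One-row result record shared by every estimator in the package.
mr_result_row <- function(model_kind, exposure, outcome, stratum = "all",
                          n, beta, se, p = NULL,
                          f_stat = NA_real_, f_stat_conditional = NA_real_,
                          interaction_p = NA_real_) {
  if (is.null(p)) p <- 2 * stats::pnorm(-abs(beta / se))
  data.frame(
    model_kind = model_kind, exposure = exposure, outcome = outcome,
    stratum = stratum, n = as.integer(n),
    beta = beta, se = se,
    ci_low = beta - 1.96 * se, ci_high = beta + 1.96 * se,
    p = p, f_stat = f_stat, f_stat_conditional = f_stat_conditional,
    interaction_p = interaction_p,
    stringsAsFactors = FALSE, row.names = NULL
  )
}
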