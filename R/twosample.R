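#' Harmonise exposure and outcome summary statistics
#'
#' Merges two per-SNP association tables on SNP ID and aligns the outcome
#' associations to the exposure's effect alleles: if the outcome file
#' reports the swapped allele pair, its beta is negated and the alleles
#' swapped; strand-ambiguous palindromic SNPs (A/T, C/G) are dropped
#' unless the effect-allele frequency on both sides resolves orientation
#' (both frequencies outside [0.42, 0.58]); any other allele mismatch is
#' dropped with a message giving the count.
#'
#' @param exposure_stats,outcome_stats data.frames with columns `snp`,
#'   `effect_allele`, `other_allele`, `beta`, `se` and optionally `eaf`.
#' @return Harmonised data.frame with columns snp, effect_allele,
#'   other_allele, beta_x, se_x, beta_y, se_y, eaf (exposure-side).
#' @export
harmonise_sumstats <- function(exposure_stats, outcome_stats) {
  req <- c("snp", "effect_allele", "other_allele", "beta", "se")
  for (d in list(exposure_stats, outcome_stats))
    if (!all(req %in% names(d)))
      stop("summary statistics need columns: ", paste(req, collapse = ", "))
  m <- merge(exposure_stats, outcome_stats, by = "snp",
             suffixes = c("_x", "_y"))
  if (nrow(m) == 0L) stop("no shared SNPs between exposure and outcome statistics")
  up <- function(a) toupper(a)
  ea_x <- up(m$effect_allele_x); oa_x <- up(m$other_allele_x)
  ea_y <- up(m$effect_allele_y); oa_y <- up(m$other_allele_y)
  pal <- (ea_x == chartr("ACGT", "TGCA", oa_x)) & nchar(ea_x) == 1L
  same <- ea_x == ea_y & oa_x == oa_y
  swapped <- ea_x == oa_y & oa_x == ea_y
  flip <- rep(FALSE, nrow(m))
  keep <- rep(TRUE, nrow(m))
  flip[swapped & !pal] <- TRUE
  keep[!same & !swapped] <- FALSE
  # palindromic: same/swapped are indistinguishable by alleles; use EAF
  if (any(pal)) {
    has_eaf <- !is.null(m$eaf_x) && !is.null(m$eaf_y)
    for (i in which(pal)) {
      ok <- has_eaf && !is.na(m$eaf_x[i]) && !is.na(m$eaf_y[i]) &&
        abs(m$eaf_x[i] - 0.5) > 0.08 && abs(m$eaf_y[i] - 0.5) > 0.08
      if (!ok) { keep[i] <- FALSE; next }
      # frequencies on opposite sides of 0.5 imply opposite orientation
      flip[i] <- (m$eaf_x[i] < 0.5) != (m$eaf_y[i] < 0.5)
    }
  }
  n_drop <- sum(!keep)
  if (n_drop > 0L)
    message("harmonise_sumstats: dropped ", n_drop,
            " SNP(s) with unresolvable alleles")
  out <- data.frame(snp = m$snp, effect_allele = ea_x, other_allele = oa_x,
                    beta_x = m$beta_x, se_x = m$se_x,
                    beta_y = ifelse(flip, -m$beta_y, m$beta_y),
                    se_y = m$se_y,
                    eaf = if (is.null(m$eaf_x)) NA_real_ else m$eaf_x,
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  if (nrow(out) == 0L) stop("no SNPs survived harmonisation")
  rownames(out) <- NULL
  out
}

check_sumstats <- function(stats, min_snps = 1L, method = "estimator") {
  req <- c("beta_x", "se_x", "beta_y", "se_y")
  if (!all(req %in% names(stats)))
    stop(method, ": need columns ", paste(req, collapse = ", "))
  zero <- stats$beta_x == 0
  if (any(zero)) {
    warning(method, ": excluding ", sum(zero), " SNP(s) with beta_x = 0")
    stats <- stats[!zero, , drop = FALSE]
  }
  if (nrow(stats) < min_snps)
    stop(method, " needs at least ", min_snps, " usable SNPs")
  if (any(stats$se_x <= 0) || any(stats$se_y <= 0))
    stop(method, ": standard errors must be positive")
  stats
}

ts_result <- function(method, beta, se, n_snps, p = NULL, ...) {
  if (is.null(p)) p <- 2 * stats::pnorm(-abs(beta / se))
  out <- data.frame(method = method, beta = beta, se = se,
                    ci_low = beta - 1.96 * se, ci_high = beta + 1.96 * se,
                    p = p, n_snps = as.integer(n_snps),
                    stringsAsFactors = FALSE, row.names = NULL)
  extra <- list(...)
  for (nm in names(extra)) out[[nm]] <- extra[[nm]]
  out
}

#' Inverse-variance weighted estimator
#'
#' Weighted mean of per-SNP Wald ratios r_j = beta_y / beta_x with
#' first-order weights w_j = beta_x^2 / se_y^2 — equivalently a
#' zero-intercept regression of outcome betas on exposure betas weighted
#' by 1/se_y^2; in one-sample data this is equivalent to 2SLS. Assumes
#' every SNP is a valid instrument. The SE uses multiplicative
#' random-effects scaling, inflated by sqrt(Q / (J - 1)) when Cochran's Q
#' exceeds its degrees of freedom, never deflated.
#'
#' @param stats Harmonised summary statistics (see
#'   [harmonise_sumstats()] or [make_summary_stats()]).
#' @return One-row data.frame (method, beta, se, ci_low, ci_high, p,
#'   n_snps).
#' @export
mr_ivw <- function(stats) {
  stats <- check_sumstats(stats, 1L, "mr_ivw")
  r <- stats$beta_y / stats$beta_x
  w <- stats$beta_x^2 / stats$se_y^2
  beta <- sum(w * r) / sum(w)
  se_fe <- sqrt(1 / sum(w))
  J <- length(r)
  scale <- if (J > 1L) max(1, sqrt(sum(w * (r - beta)^2) / (J - 1L))) else 1
  ts_result("ivw", beta, se_fe * scale, J)
}

#' MR-Egger regression
#'
#' Weighted regression of outcome betas on exposure betas with a free
#' intercept (weights 1/se_y^2), after orienting SNPs so all exposure
#' betas are non-negative. The slope is the causal estimate under the
#' InSIDE assumption; the intercept estimates average directional
#' pleiotropy. Multiplicative random-effects SE scaling with J - 2
#' degrees of freedom; p-values use the t reference with J - 2 df.
#'
#' @inheritParams mr_ivw
#' @return One-row data.frame with additional columns `egger_intercept`,
#'   `intercept_se`, `intercept_p`.
#' @export
mr_egger <- function(stats) {
  stats <- check_sumstats(stats, 3L, "mr_egger")
  sgn <- sign(stats$beta_x)
  bx <- stats$beta_x * sgn
  by <- stats$beta_y * sgn
  if (stats::sd(bx) < 1e-12 * mean(abs(bx)))
    stop("mr_egger: no variation in instrument strength; fit is unstable")
  w <- 1 / stats$se_y^2
  X <- cbind(1, bx)
  XtWX <- crossprod(X * sqrt(w))
  b <- drop(solve(XtWX, crossprod(X, w * by)))
  res <- by - drop(X %*% b)
  J <- length(bx)
  sig2 <- sum(w * res^2) / (J - 2L)
  V <- solve(XtWX) * max(1, sig2)
  se <- sqrt(diag(V))
  p_slope <- 2 * stats::pt(-abs(b[2] / se[2]), df = J - 2L)
  p_int <- 2 * stats::pt(-abs(b[1] / se[1]), df = J - 2L)
  ts_result("egger", b[2], se[2], J, p = p_slope,
            egger_intercept = b[1], intercept_se = se[1], intercept_p = p_int)
}

weighted_median_point <- function(r, w) {
  o <- order(r)
  r <- r[o]; w <- w[o] / sum(w)
  cw <- cumsum(w) - 0.5 * w # midpoint cumulative weight
  if (cw[1] >= 0.5) return(r[1])
  if (cw[length(cw)] <= 0.5) return(r[length(r)])
  below <- max(which(cw < 0.5))
  r[below] + (r[below + 1L] - r[below]) *
    (0.5 - cw[below]) / (cw[below + 1L] - cw[below])
}

boot_draws <- function(stats, n_boot, seed, point_fun) {
  set.seed(seed)
  vapply(seq_len(n_boot), function(i) {
    bx <- stats::rnorm(nrow(stats), stats$beta_x, stats$se_x)
    by <- stats::rnorm(nrow(stats), stats$beta_y, stats$se_y)
    bad <- bx == 0
    point_fun(by[!bad] / bx[!bad], bx[!bad]^2 / stats$se_y[!bad]^2)
  }, numeric(1))
}

#' Weighted median estimator
#'
#' The median of the per-SNP Wald ratios under inverse-variance weights
#' (delta-method ratio variance se_y^2 / beta_x^2): ratios are ordered
#' and the estimate is the linear interpolation of the ratio at
#' cumulative weight 0.5, using midpoint cumulative sums. Consistent when
#' at least half the weight comes from valid instruments; robust to
#' outlying SNPs. SE by parametric bootstrap of the summary statistics.
#'
#' @inheritParams mr_ivw
#' @param n_boot Bootstrap replicates (default 1000; fewer than 100
#'   raises a warning).
#' @param seed Seed for the bootstrap.
#' @return One-row data.frame with additional column `n_boot`.
#' @export
mr_weighted_median <- function(stats, n_boot = 1000L, seed = 1L) {
  stats <- check_sumstats(stats, 3L, "mr_weighted_median")
  if (n_boot < 100L) warning("n_boot < 100 gives unstable bootstrap SEs")
  r <- stats$beta_y / stats$beta_x
  w <- stats$beta_x^2 / stats$se_y^2
  if (all(w == 0)) stop("mr_weighted_median: all weights are zero")
  beta <- weighted_median_point(r, w)
  se <- stats::sd(boot_draws(stats, n_boot, seed,
                             function(r, w) weighted_median_point(r, w)))
  ts_result("weighted_median", beta, se, nrow(stats), n_boot = as.integer(n_boot))
}

weighted_mode_point <- function(r, w, bandwidth_factor = 1) {
  w <- w / sum(w)
  mu <- sum(w * r)
  wsd <- sqrt(sum(w * (r - mu)^2))
  med <- weighted_median_point(r, w)
  wmad <- 1.4826 * weighted_median_point(abs(r - med), w)
  spread <- min(wsd, if (wmad > 0) wmad else wsd)
  if (!is.finite(spread) || spread <= 0) return(sum(w * r)) # point mass
  h <- bandwidth_factor * 0.9 * spread * length(r)^(-1 / 5)
  grid <- seq(min(r) - 3 * h, max(r) + 3 * h, length.out = 512L)
  dens <- vapply(grid, function(x) sum(w * stats::dnorm((x - r) / h)) / h,
                 numeric(1))
  cand <- grid[dens == max(dens)]
  cand[which.min(abs(cand))] # ties toward the smallest absolute estimate
}

#' Weighted mode estimator
#'
#' Assumes the most common SNP effect is the true effect: a weighted
#' normal-kernel density is formed over the per-SNP Wald ratios
#' (bandwidth = `bandwidth_factor` times a weighted Silverman rule on the
#' ratios) and the estimate is the density's argmax on a 512-point grid
#' spanning the ratios; ties break toward the smallest absolute value.
#' Degenerate zero spread falls back to the weighted mean of the
#' (identical) ratios. SE by parametric bootstrap. The NOME bandwidth
#' penalty is not applied.
#'
#' @inheritParams mr_weighted_median
#' @param bandwidth_factor Positive multiplier on the Silverman
#'   bandwidth.
#' @return One-row data.frame with additional columns `bandwidth_factor`,
#'   `n_boot`.
#' @export
mr_weighted_mode <- function(stats, bandwidth_factor = 1, n_boot = 1000L,
                             seed = 1L) {
  stopifnot(bandwidth_factor > 0)
  stats <- check_sumstats(stats, 3L, "mr_weighted_mode")
  if (n_boot < 100L) warning("n_boot < 100 gives unstable bootstrap SEs")
  r <- stats$beta_y / stats$beta_x
  w <- stats$beta_x^2 / stats$se_y^2
  beta <- weighted_mode_point(r, w, bandwidth_factor)
  se <- stats::sd(boot_draws(stats, n_boot, seed,
                             function(r, w) weighted_mode_point(r, w, bandwidth_factor)))
  ts_result("weighted_mode", beta, se, nrow(stats),
            bandwidth_factor = bandwidth_factor, n_boot = as.integer(n_boot))
}

#' Run all four summary-level estimators
#'
#' Convenience wrapper returning IVW, MR-Egger, weighted-median and
#' weighted-mode results — four models carrying different assumptions
#' about horizontal pleiotropy — as one table.
#'
#' @inheritParams mr_weighted_median
#' @param methods Subset of `c("ivw", "egger", "weighted_median",
#'   "weighted_mode")`.
#' @return data.frame with one row per method.
#' @export
mr_twosample <- function(stats,
                         methods = c("ivw", "egger", "weighted_median",
                                     "weighted_mode"),
                         n_boot = 1000L, seed = 1L) {
  methods <- match.arg(methods, several.ok = TRUE)
  rows <- list()
  if ("ivw" %in% methods) rows$ivw <- mr_ivw(stats)
  if ("egger" %in% methods) rows$egger <- mr_egger(stats)
  if ("weighted_median" %in% methods)
    rows$wm <- mr_weighted_median(stats, n_boot, seed)
  if ("weighted_mode" %in% methods)
    rows$wmo <- mr_weighted_mode(stats, 1, n_boot, seed)
  out <- do.call(rbind, lapply(rows, function(d) {
    for (col in c("egger_intercept", "intercept_se", "intercept_p",
                  "bandwidth_factor", "n_boot"))
      if (is.null(d[[col]])) d[[col]] <- NA_real_
    d
  }))
  rownames(out) <- NULL
  out
}
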