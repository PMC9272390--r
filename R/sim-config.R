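#' Simulation configuration for a synthetic adiposity cohort
#'
#' Defines the generative model used throughout the package's tests and
#' examples: polygenic biallelic instruments for two correlated adiposity
#' exposures (BMI and WHR, both unit-variance in expectation), a causal
#' BMI -> WHR path, metabolite outcomes driven directly by one or both
#' exposures plus a shared standard-normal confounder, and statin use
#' generated logistically from the exposures, latent LDL cholesterol and
#' age, with a constant SD-scale treatment effect lowering measured LDL-C.
#'
#' The genetic architecture gives each exposure-specific SNP an equal
#' share of that exposure's heritability: a SNP with effect-allele
#' frequency f carries per-allele weight sqrt(h2 / (m * 2 f (1 - f)))
#' where m is the number of contributing SNPs. Shared SNPs affect BMI
#' directly and WHR only through the BMI-to-WHR path; they enter the WHR
#' weight table with their marginal WHR effect delta * b (as an
#' unadjusted WHR GWAS would select them), inducing a positive
#' correlation between the two scores without violating any instrument's
#' exclusion restriction.
#'
#' @param n_individuals Cohort size.
#' @param n_snps_bmi,n_snps_whr,n_snps_shared Counts of BMI-specific,
#'   WHR-specific and shared instrument SNPs.
#' @param maf_range Length-2 vector of minor-allele frequencies in (0, 0.5];
#'   per-SNP frequencies are drawn uniformly from this range.
#' @param h2_bmi,h2_whr Genetic variance fractions of each exposure, in [0, 1).
#' @param delta_bmi_to_whr Path coefficient of BMI on WHR (unitless).
#' @param conf_bmi,conf_whr Confounder loadings on the exposures.
#' @param kappa_confounder Confounder loading on every outcome.
#' @param outcomes Named list; each element is a list with `theta_bmi` and
#'   `theta_whr`, the direct SD-scale effects of the exposures on that
#'   outcome.
#' @param statin_outcome Name of the outcome whose latent value enters the
#'   statin model and is lowered by treatment (typically "ldl"); NULL
#'   disables the medication mechanism.
#' @param statin_intercept,statin_slope_bmi,statin_slope_whr,statin_slope_ldl
#'   Logit-scale coefficients of the statin-use model.
#' @param tau_statin LDL-lowering treatment effect, in SD units of the
#'   latent outcome (measured value = latent - tau * statin).
#' @param age_range Length-2 vector of ages in years; age is uniform on
#'   this range and independent of genotype and adiposity.
#' @param age_statin_gradient Logit-scale statin coefficient per year of
#'   age (age is centred at the midpoint of `age_range`).
#' @param sex_effect_overrides Optional per-sex effects: a named list
#'   (by outcome) of lists `male`/`female`, each with `theta_bmi` and
#'   `theta_whr`, replacing the sexes-combined values for that outcome.
#' @param seed Integer seed; a fixed seed makes the cohort byte-identical.
#' @return An object of class `sim_config`.
#' @seealso [ukb_like_config()] for the default preset,
#'   [simulate_cohort()] to draw a cohort.
#' @export
sim_config <- function(n_individuals,
                       n_snps_bmi, n_snps_whr, n_snps_shared = 0L,
                       maf_range = c(0.05, 0.45),
                       h2_bmi = 0.05, h2_whr = 0.04,
                       delta_bmi_to_whr = 0,
                       conf_bmi = 0, conf_whr = 0,
                       kappa_confounder = 0,
                       outcomes = list(trait = list(theta_bmi = 0, theta_whr = 0)),
                       statin_outcome = NULL,
                       statin_intercept = -2,
                       statin_slope_bmi = 0, statin_slope_whr = 0,
                       statin_slope_ldl = 0,
                       tau_statin = 0,
                       age_range = c(38, 73),
                       age_statin_gradient = 0,
                       sex_effect_overrides = NULL,
                       seed = 1L) {
  stopifnot(n_individuals >= 1, n_snps_bmi >= 1, n_snps_whr >= 1,
            n_snps_shared >= 0, length(maf_range) == 2,
            length(age_range) == 2, age_range[1] < age_range[2])
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stop("maf_range must lie within (0, 0.5]")
  for (h in c(h2_bmi = h2_bmi, h2_whr = h2_whr))
    if (h < 0 || h >= 1) stop("variance fractions must be in [0, 1)")
  if (is.null(names(outcomes)) || any(!nzchar(names(outcomes))))
    stop("outcomes must be a named list")
  if (!is.null(statin_outcome) && !statin_outcome %in% names(outcomes))
    stop("statin_outcome '", statin_outcome, "' is not among the outcomes")
  if (!is.null(sex_effect_overrides) &&
      !all(names(sex_effect_overrides) %in% names(outcomes)))
    stop("sex_effect_overrides names must be outcome names")
  cfg <- structure(list(
    n_individuals = as.integer(n_individuals),
    n_snps_bmi = as.integer(n_snps_bmi),
    n_snps_whr = as.integer(n_snps_whr),
    n_snps_shared = as.integer(n_snps_shared),
    maf_range = maf_range, h2_bmi = h2_bmi, h2_whr = h2_whr,
    delta_bmi_to_whr = delta_bmi_to_whr,
    conf_bmi = conf_bmi, conf_whr = conf_whr,
    kappa_confounder = kappa_confounder,
    outcomes = outcomes, statin_outcome = statin_outcome,
    statin_intercept = statin_intercept,
    statin_slope_bmi = statin_slope_bmi,
    statin_slope_whr = statin_slope_whr,
    statin_slope_ldl = statin_slope_ldl,
    tau_statin = tau_statin,
    age_range = age_range,
    age_statin_gradient = age_statin_gradient,
    sex_effect_overrides = sex_effect_overrides,
    seed = as.integer(seed)
  ), class = "sim_config")
  cohort_moments(cfg) # fail fast on impossible residual variances
  cfg
}

# Closed-form second moments of the generative model; the source of truth
# for residual-variance bookkeeping and for covariance-algebra oracles in
# the tests. Errors name the parameter that makes a residual variance
# non-positive.
#
# Shared SNPs affect BMI directly and WHR only through the BMI -> WHR
# path; an unadjusted WHR GWAS would select them with marginal per-allele
# effect delta * b_j, which is the weight they carry in the WHR score.
# This keeps every instrument's effect on downstream traits mediated by
# its exposure (no direct pleiotropic path), while still inducing the
# observed positive correlation between the two scores.
cohort_moments <- function(cfg) {
  m_b <- cfg$n_snps_bmi + cfg$n_snps_shared
  m_w <- cfg$n_snps_whr + cfg$n_snps_shared
  d <- cfg$delta_bmi_to_whr
  s <- cfg$n_snps_shared / m_b # shared fraction of BMI heritability
  var_e_bmi <- 1 - cfg$h2_bmi - cfg$conf_bmi^2
  if (var_e_bmi <= 0)
    stop("sim_config: h2_bmi + conf_bmi^2 leaves non-positive BMI residual variance")
  var_e_whr <- 1 - cfg$h2_whr - d^2 - cfg$conf_whr^2 -
    2 * d * cfg$conf_bmi * cfg$conf_whr
  if (var_e_whr <= 0)
    stop("sim_config: delta_bmi_to_whr (with h2_whr, conf_whr) leaves non-positive WHR residual variance")
  # correlation of the two average-dose scores, from the shared block
  denom <- cfg$h2_whr + d^2 * cfg$h2_bmi * s
  grs_cor <- if (denom > 0) d * sqrt(cfg$h2_bmi) * s / sqrt(denom) else 0
  cov_bmi_whr <- d + cfg$conf_bmi * cfg$conf_whr
  cov_bmi_u <- cfg$conf_bmi
  cov_whr_u <- d * cfg$conf_bmi + cfg$conf_whr
  k <- cfg$kappa_confounder

  outcome_var <- function(tb, tw) {
    v <- tb^2 + tw^2 + k^2 + 2 * tb * tw * cov_bmi_whr +
      2 * k * (tb * cov_bmi_u + tw * cov_whr_u)
    1 - v
  }
  var_e_y <- list()
  for (nm in names(cfg$outcomes)) {
    ov <- cfg$sex_effect_overrides[[nm]]
    if (is.null(ov)) {
      th <- cfg$outcomes[[nm]]
      v <- outcome_var(th$theta_bmi, th$theta_whr)
      if (v <= 0)
        stop("sim_config: theta values for outcome '", nm,
             "' leave non-positive residual variance")
      var_e_y[[nm]] <- v
    } else {
      vs <- vapply(c("male", "female"), function(sx) {
        outcome_var(ov[[sx]]$theta_bmi, ov[[sx]]$theta_whr)
      }, numeric(1))
      if (any(vs <= 0))
        stop("sim_config: sex_effect_overrides for outcome '", nm,
             "' leave non-positive residual variance")
      var_e_y[[nm]] <- vs
    }
  }
  list(m_bmi = m_b, m_whr = m_w,
       expected_grs_cor = grs_cor,
       cov_bmi_whr = cov_bmi_whr, cov_bmi_u = cov_bmi_u,
       cov_whr_u = cov_whr_u,
       var_e_bmi = var_e_bmi, var_e_whr = var_e_whr, var_e_y = var_e_y)
}

#' Biobank-like default preset
#'
#' A scaled-down cohort preset emulating the qualitative structure of a
#' large adult biobank: a modest positive correlation (0.25) between the
#' BMI and WHR genetic scores via shared SNPs; WHR carrying the whole
#' direct effect on a triglyceride-like outcome (0.6 SD) while BMI affects
#' it only through WHR (path 0.4, so a total BMI effect of 0.24 SD); a
#' smaller WHR-specific direct effect on LDL cholesterol; statin use
#' rising steeply with age (roughly 5\%, 17\% and 29\% across age
#' tertiles) and with adiposity and latent LDL-C; and a 1.5 SD
#' statin-induced lowering of measured LDL-C.
#'
#' @param n_individuals Cohort size (default 20000).
#' @param seed Integer seed.
#' @param ... Overrides passed on to [sim_config()].
#' @return A `sim_config` object.
#' @export
ukb_like_config <- function(n_individuals = 20000L, seed = 1L, ...) {
  args <- list(
    n_individuals = n_individuals,
    n_snps_bmi = 16L, n_snps_whr = 24L, n_snps_shared = 24L,
    maf_range = c(0.05, 0.45),
    h2_bmi = 0.05, h2_whr = 0.04,
    delta_bmi_to_whr = 0.4,
    conf_bmi = 0.25, conf_whr = 0.20,
    kappa_confounder = 0.3,
    outcomes = list(
      trig = list(theta_bmi = 0,    theta_whr = 0.6),
      ldl  = list(theta_bmi = 0,    theta_whr = 0.15),
      hdl  = list(theta_bmi = -0.1, theta_whr = -0.3)
    ),
    statin_outcome = "ldl",
    statin_intercept = -2.15,
    statin_slope_bmi = 0.4, statin_slope_whr = 0.5, statin_slope_ldl = 0.7,
    tau_statin = 1.5,
    age_range = c(38, 73),
    age_statin_gradient = 0.095,
    seed = seed
  )
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}
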