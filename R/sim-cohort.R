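# Genotype draws for given per-SNP effect-allele frequencies, using the
# current RNG stream. Hardy-Weinberg: dosage ~ Binomial(2, f).
r_genotypes <- function(n, f, snp_ids, individual_ids) {
  p <- length(f)
  G <- matrix(stats::rbinom(n * p, 2L, rep(f, each = n)), nrow = n, ncol = p)
  dimnames(G) <- list(individual_ids, snp_ids)
  G
}

#' Simulate a biallelic genotype matrix
#'
#' Draws unlinked SNPs in Hardy-Weinberg equilibrium: each SNP's
#' effect-allele frequency is uniform on `maf_range` and each dosage is
#' Binomial(2, f). Columns carry stable SNP identifiers.
#'
#' @param n Number of individuals.
#' @param n_snps Number of SNPs.
#' @param maf_range Length-2 frequency range within (0, 0.5].
#' @param seed Integer seed.
#' @return Integer matrix of dosages in \{0, 1, 2\} with individual IDs as
#'   row names, SNP IDs as column names, and the drawn frequencies in
#'   attribute `"maf"`.
#' @export
simulate_genotypes <- function(n, n_snps, maf_range = c(0.05, 0.45), seed = 1L) {
  stopifnot(n >= 1, n_snps >= 1)
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stop("maf_range must lie within (0, 0.5]")
  set.seed(seed)
  f <- stats::runif(n_snps, maf_range[1], maf_range[2])
  G <- r_genotypes(n, f, sprintf("rs%05d", seq_len(n_snps)),
                   sprintf("id%06d", seq_len(n)))
  attr(G, "maf") <- f
  G
}

#' Simulate a full synthetic cohort
#'
#' Draws genotypes, exposures, confounder, outcomes, medication and
#' covariates under the causal structure declared in a [sim_config()]:
#' BMI is its genetic score plus confounder plus noise (unit variance in
#' expectation, genetic fraction `h2_bmi`); WHR adds a causal BMI
#' component; each outcome is a linear combination of the exposures and
#' the confounder; statin use is Bernoulli on a logistic scale in BMI,
#' WHR, latent LDL-C and age; measured LDL-C is the latent value minus
#' `tau_statin` for statin users. Age, genetic principal-component
#' stand-ins, and education/smoking proxies (correlated with the
#' confounder) are also emitted.
#'
#' @param cfg A `sim_config` object.
#' @return Object of class `synthetic_cohort`: a list with elements
#'   `genotypes` (dosage matrix), `phenotypes` (data.frame with id, sex
#'   \{0 = male, 1 = female\}, age, bmi, whr, statin, covariate proxies,
#'   pc1..pc10, one column per outcome and a `<statin_outcome>_latent`
#'   column), `weights_bmi` / `weights_whr` (SNP weight tables),
#'   `snp_info`, `truth` (every generative coefficient, the estimands),
#'   and `config`.
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  mom <- cohort_moments(cfg)
  n <- cfg$n_individuals
  set.seed(cfg$seed)

  p <- cfg$n_snps_bmi + cfg$n_snps_shared + cfg$n_snps_whr
  idx_bmi <- seq_len(cfg$n_snps_bmi)
  idx_shared <- cfg$n_snps_bmi + seq_len(cfg$n_snps_shared)
  idx_whr <- cfg$n_snps_bmi + cfg$n_snps_shared + seq_len(cfg$n_snps_whr)
  snp_ids <- sprintf("rs%05d", seq_len(p))
  ids <- sprintf("id%06d", seq_len(n))

  f <- stats::runif(p, cfg$maf_range[1], cfg$maf_range[2])
  alleles <- t(vapply(seq_len(p),
                      function(i) sample(c("A", "C", "G", "T"), 2L),
                      character(2)))
  G <- r_genotypes(n, f, snp_ids, ids)

  # per-allele weights giving each SNP an equal heritability share;
  # shared SNPs are BMI SNPs whose WHR weight is the marginal effect
  # delta * b (mediated entirely by BMI)
  w_of <- function(h2, m, j) sqrt(h2 / (m * 2 * f[j] * (1 - f[j])))
  j_b <- c(idx_bmi, idx_shared)
  j_w <- c(idx_shared, idx_whr)
  wb <- w_of(cfg$h2_bmi, mom$m_bmi, j_b)
  w_wd <- w_of(cfg$h2_whr, cfg$n_snps_whr, idx_whr)
  ww <- c(cfg$delta_bmi_to_whr * wb[match(idx_shared, j_b)], w_wd)
  Gc <- sweep(G, 2L, 2 * f) # centred dosages
  g_bmi <- drop(Gc[, j_b, drop = FALSE] %*% wb)
  g_whr_direct <- drop(Gc[, idx_whr, drop = FALSE] %*% w_wd)

  U <- stats::rnorm(n)
  bmi <- g_bmi + cfg$conf_bmi * U + stats::rnorm(n, sd = sqrt(mom$var_e_bmi))
  whr <- g_whr_direct + cfg$delta_bmi_to_whr * bmi + cfg$conf_whr * U +
    stats::rnorm(n, sd = sqrt(mom$var_e_whr))

  sex <- stats::rbinom(n, 1L, 0.5) # 0 = male, 1 = female
  age <- stats::runif(n, cfg$age_range[1], cfg$age_range[2])

  theta_used <- list()
  Y <- matrix(NA_real_, n, length(cfg$outcomes),
              dimnames = list(NULL, names(cfg$outcomes)))
  for (nm in names(cfg$outcomes)) {
    ov <- cfg$sex_effect_overrides[[nm]]
    if (is.null(ov)) {
      th <- cfg$outcomes[[nm]]
      tb <- rep(th$theta_bmi, n); tw <- rep(th$theta_whr, n)
      sd_e <- rep(sqrt(mom$var_e_y[[nm]]), n)
      theta_used[[nm]] <- list(theta_bmi = th$theta_bmi, theta_whr = th$theta_whr)
    } else {
      tb <- ifelse(sex == 0L, ov$male$theta_bmi, ov$female$theta_bmi)
      tw <- ifelse(sex == 0L, ov$male$theta_whr, ov$female$theta_whr)
      v <- mom$var_e_y[[nm]]
      sd_e <- sqrt(ifelse(sex == 0L, v["male"], v["female"]))
      theta_used[[nm]] <- list(male = ov$male, female = ov$female)
    }
    Y[, nm] <- tb * bmi + tw * whr + cfg$kappa_confounder * U +
      stats::rnorm(n) * sd_e
  }

  pheno <- data.frame(id = ids, sex = sex, age = age, bmi = bmi, whr = whr,
                      stringsAsFactors = FALSE)

  so <- cfg$statin_outcome
  if (!is.null(so)) {
    lin <- cfg$statin_intercept +
      cfg$statin_slope_bmi * bmi + cfg$statin_slope_whr * whr +
      cfg$statin_slope_ldl * Y[, so] +
      cfg$age_statin_gradient * (age - mean(cfg$age_range))
    statin <- stats::rbinom(n, 1L, expit(lin))
  } else {
    statin <- integer(n)
  }
  pheno$statin <- statin

  # observational-covariate proxies, correlated with the confounder
  edu_lat <- 0.5 * U + stats::rnorm(n)
  pheno$education <- findInterval(edu_lat, stats::quantile(edu_lat, c(0.25, 0.5, 0.75))) + 1L
  smk_lat <- 0.4 * U + stats::rnorm(n)
  pheno$smoking <- findInterval(smk_lat, stats::quantile(smk_lat, c(0.5, 0.8)))
  PC <- matrix(stats::rnorm(n * 10L), n, 10L,
               dimnames = list(NULL, paste0("pc", 1:10)))
  pheno <- cbind(pheno, PC)

  for (nm in colnames(Y)) pheno[[nm]] <- Y[, nm]
  if (!is.null(so)) {
    pheno[[paste0(so, "_latent")]] <- Y[, so]
    pheno[[so]] <- Y[, so] - cfg$tau_statin * statin
  }

  snp_info <- data.frame(
    snp_id = snp_ids, effect_allele = alleles[, 1], other_allele = alleles[, 2],
    maf = f, in_bmi_score = seq_len(p) %in% j_b,
    in_whr_score = seq_len(p) %in% j_w, stringsAsFactors = FALSE)
  weights_bmi <- data.frame(snp_id = snp_ids[j_b],
                            effect_allele = alleles[j_b, 1],
                            other_allele = alleles[j_b, 2],
                            weight = wb, eaf = f[j_b], stringsAsFactors = FALSE)
  weights_whr <- data.frame(snp_id = snp_ids[j_w],
                            effect_allele = alleles[j_w, 1],
                            other_allele = alleles[j_w, 2],
                            weight = ww, eaf = f[j_w], stringsAsFactors = FALSE)

  truth <- c(mom, list(
    theta = theta_used,
    delta_bmi_to_whr = cfg$delta_bmi_to_whr,
    conf_bmi = cfg$conf_bmi, conf_whr = cfg$conf_whr,
    kappa_confounder = cfg$kappa_confounder,
    h2_bmi = cfg$h2_bmi, h2_whr = cfg$h2_whr,
    statin = list(intercept = cfg$statin_intercept,
                  slope_bmi = cfg$statin_slope_bmi,
                  slope_whr = cfg$statin_slope_whr,
                  slope_ldl = cfg$statin_slope_ldl,
                  age_gradient = cfg$age_statin_gradient,
                  tau = cfg$tau_statin,
                  outcome = so)
  ))

  structure(list(genotypes = G, phenotypes = pheno,
                 weights_bmi = weights_bmi, weights_whr = weights_whr,
                 snp_info = snp_info, truth = truth, config = cfg),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort:", nrow(x$phenotypes), "individuals,",
      ncol(x$genotypes), "SNPs,",
      length(x$config$outcomes), "outcomes\n")
  invisible(x)
}

#' Per-SNP association summary statistics from a cohort
#'
#' Regresses an exposure and an outcome on each SNP's dosage (plus shared
#' covariates) by ordinary least squares, producing the per-SNP beta/SE
#' pairs used by the summary-level (two-sample style) estimators. SNPs
#' with constant dosage are dropped with a warning.
#'
#' @param cohort A `synthetic_cohort`, or a list with elements `genotypes`
#'   (dosage matrix, individuals x SNPs) and `phenotypes` (data.frame).
#' @param exposure,outcome Phenotype column names.
#' @param covariates Optional phenotype columns adjusted for in both
#'   regressions.
#' @return data.frame with columns snp, effect_allele, other_allele,
#'   beta_x, se_x, beta_y, se_y, eaf.
#' @export
make_summary_stats <- function(cohort, exposure, outcome,
                               covariates = character()) {
  G <- cohort$genotypes
  ph <- cohort$phenotypes
  for (v in c(exposure, outcome, covariates))
    if (!v %in% names(ph)) stop("make_summary_stats: no column '", v, "'")
  keep <- apply(G, 2L, function(d) stats::var(d) > 0)
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " constant-dosage SNP(s): ",
            paste(colnames(G)[!keep], collapse = ", "))
    G <- G[, keep, drop = FALSE]
  }
  if (ncol(G) == 0L) stop("make_summary_stats: no non-constant SNPs left")
  C <- if (length(covariates)) data.matrix(ph[covariates]) else NULL
  fx <- per_snp_ols(ph[[exposure]], G, C)
  fy <- per_snp_ols(ph[[outcome]], G, C)
  info <- cohort$snp_info
  if (is.null(info)) {
    info <- data.frame(snp_id = colnames(G), effect_allele = "A",
                       other_allele = "G", stringsAsFactors = FALSE)
  }
  m <- match(colnames(G), info$snp_id)
  data.frame(snp = colnames(G),
             effect_allele = info$effect_allele[m],
             other_allele = info$other_allele[m],
             beta_x = fx$beta, se_x = fx$se,
             beta_y = fy$beta, se_y = fy$se,
             eaf = colMeans(G) / 2,
             stringsAsFactors = FALSE, row.names = NULL)
}
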