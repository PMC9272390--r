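#' Prepare a cohort table for analysis
#'
#' Builds the BMI and WHR genetic risk scores from the cohort's genotypes
#' and weight tables, joins them to the phenotypes, and z-standardises
#' scores, exposures and outcomes among sexes combined (stratified models
#' reuse these combined-sample units, so within-stratum SDs are not 1).
#'
#' @param cohort A `synthetic_cohort`, or a list with `genotypes`,
#'   `phenotypes`, `weights_bmi`, `weights_whr`.
#' @param standardise_cols Extra phenotype columns to z-score besides the
#'   exposures, scores and outcomes.
#' @return data.frame with added `grs_bmi` and `grs_whr` columns.
#' @export
prepare_cohort <- function(cohort, standardise_cols = character()) {
  ph <- cohort$phenotypes
  sb <- build_grs(cohort$genotypes, cohort$weights_bmi)
  sw <- build_grs(cohort$genotypes, cohort$weights_whr)
  ph$grs_bmi <- sb$score[match(ph$id, sb$id)]
  ph$grs_whr <- sw$score[match(ph$id, sw$id)]
  outs <- names(cohort$config$outcomes)
  so <- cohort$config$statin_outcome
  zcols <- unique(c("grs_bmi", "grs_whr", "bmi", "whr", outs,
                    if (!is.null(so)) paste0(so, "_latent"),
                    standardise_cols))
  for (cl in intersect(zcols, names(ph))) ph[[cl]] <- standardise(ph[[cl]], cl)
  ph
}

#' Define an analysis grid
#'
#' Declares the model x exposure x outcome x stratum grid run by
#' [run_grid()]: total (univariable) and direct (multivariable,
#' mutually-adjusted) effect models for each exposure and outcome, over
#' one or more stratifications.
#'
#' @param exposures Character vector of exposure columns (typically
#'   `c("bmi", "whr")`).
#' @param instruments Matching genetic-score columns.
#' @param outcomes Outcome columns.
#' @param models Subset of `c("uv-2sls", "mv-2sls")`.
#' @param strata Stratification kinds, each one of `"all"`, `"by_sex"`,
#'   `"exclude_statin"`, `"age_tertile"`, `"sex_by_age_tertile"`.
#' @param covariates Covariates for the MR models.
#' @param obs_covariates Covariates for conventional observational models
#'   (education and smoking enter only here).
#' @param min_n Minimum analyzable stratum size; smaller cells are
#'   logged as skips.
#' @return Object of class `analysis_grid`.
#' @export
analysis_grid <- function(exposures = c("bmi", "whr"),
                          instruments = c("grs_bmi", "grs_whr"),
                          outcomes,
                          models = c("uv-2sls", "mv-2sls"),
                          strata = "all",
                          covariates = c("age", "sex", paste0("pc", 1:10)),
                          obs_covariates = c("age", "sex", "education", "smoking"),
                          min_n = 50L) {
  models <- match.arg(models, c("uv-2sls", "mv-2sls"), several.ok = TRUE)
  ok <- c("all", "by_sex", "exclude_statin", "age_tertile", "sex_by_age_tertile")
  if (!all(strata %in% ok))
    stop("strata must be among: ", paste(ok, collapse = ", "))
  structure(list(exposures = exposures, instruments = instruments,
                 outcomes = outcomes, models = models, strata = strata,
                 covariates = covariates, obs_covariates = obs_covariates,
                 min_n = as.integer(min_n)),
            class = "analysis_grid")
}

# Tertile labels from empirical age quantiles; boundary ages go to the
# lower tertile.
age_tertile_labels <- function(age, n_tertiles = 3L) {
  if (length(unique(age)) < n_tertiles) stop("too few distinct ages to form tertiles")
  qs <- stats::quantile(age, probs = seq_len(n_tertiles - 1L) / n_tertiles)
  cut(age, breaks = c(-Inf, qs, Inf), right = TRUE,
      labels = paste0("age_t", seq_len(n_tertiles)))
}

# Named list of logical row masks for one stratification kind.
make_strata <- function(data, kind, n_tertiles = 3L) {
  switch(kind,
    all = list(all = rep(TRUE, nrow(data))),
    by_sex = list(men = data$sex == 0, women = data$sex == 1),
    exclude_statin = list(no_statin = data$statin == 0),
    age_tertile = {
      lab <- age_tertile_labels(data$age, n_tertiles)
      stats::setNames(lapply(levels(lab), function(l) lab == l), levels(lab))
    },
    sex_by_age_tertile = {
      lab <- age_tertile_labels(data$age, n_tertiles)
      out <- list()
      for (sx in 0:1) {
        snm <- if (sx == 0) "men" else "women"
        for (l in levels(lab))
          out[[paste(snm, l, sep = "_")]] <- data$sex == sx & lab == l
      }
      out
    },
    stop("unknown stratum kind: ", kind))
}

#' Run the full MR analysis grid
#'
#' Loops model x exposure x outcome x stratum, fitting univariable
#' (total-effect) and multivariable (direct-effect) 2SLS models, and
#' returns one long-format results table. A failing cell is logged and
#' skipped, never aborting the grid; the skip log is in attribute
#' `"skips"`. Standardisation happens once, among sexes combined, in
#' [prepare_cohort()], before any stratification.
#'
#' @param data Prepared cohort data.frame (see [prepare_cohort()]).
#' @param grid An [analysis_grid()].
#' @return data.frame of result rows; attribute `"skips"` is a data.frame
#'   of skipped cells with messages.
#' @export
run_grid <- function(data, grid) {
  stopifnot(inherits(grid, "analysis_grid"))
  rows <- list()
  skips <- list()
  note_skip <- function(stratum, model, exposure, outcome, msg) {
    skips[[length(skips) + 1L]] <<- data.frame(
      stratum = stratum, model = model, exposure = exposure,
      outcome = outcome, message = conditionMessage(msg),
      stringsAsFactors = FALSE)
  }
  for (kind in grid$strata) {
    masks <- make_strata(data, kind)
    for (snm in names(masks)) {
      sub <- data[masks[[snm]], , drop = FALSE]
      covs <- grid$covariates
      if (kind %in% c("by_sex", "sex_by_age_tertile"))
        covs <- setdiff(covs, "sex")
      label <- if (kind == "all") "all" else snm
      for (oc in grid$outcomes) {
        if (nrow(sub) < grid$min_n) {
          for (md in grid$models)
            for (ex in grid$exposures) note_skip(label, md, ex, oc,
              simpleError(paste0("stratum n = ", nrow(sub), " below min_n")))
          next
        }
        for (md in grid$models) {
          if (md == "uv-2sls") {
            for (j in seq_along(grid$exposures)) {
              sp <- mr_spec(grid$exposures[j], grid$instruments[j], oc,
                            covariates = covs)
              r <- tryCatch(fit_2sls(sub, sp, stratum = label),
                            error = function(e) e)
              if (inherits(r, "error"))
                note_skip(label, md, grid$exposures[j], oc, r)
              else rows[[length(rows) + 1L]] <- r
            }
          } else {
            sp <- mr_spec(grid$exposures, grid$instruments, oc,
                          covariates = covs)
            r <- tryCatch(fit_mv_2sls(sub, sp, stratum = label),
                          error = function(e) e)
            if (inherits(r, "error"))
              for (ex in grid$exposures) note_skip(label, md, ex, oc, r)
            else rows[[length(rows) + 1L]] <- r
          }
        }
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    mr_result_row("x", "x", "x", "x", 1L, 0, 1)[0, ]
  rownames(out) <- NULL
  attr(out, "skips") <- if (length(skips)) do.call(rbind, skips) else
    data.frame(stratum = character(0), model = character(0),
               exposure = character(0), outcome = character(0),
               message = character(0), stringsAsFactors = FALSE)
  out
}

#' Conventional (observational) regression comparators
#'
#' Ordinary least-squares regressions of each outcome on each measured
#' exposure with heteroskedasticity-robust (HC1) standard errors,
#' without instruments: first adjusted for the observational covariate
#' set (age, sex, education, smoking by default), then additionally for
#' the other adiposity measure. Output schema matches the MR rows, with
#' model_kind `"obs-uv"` / `"obs-mv"`.
#'
#' @inheritParams run_grid
#' @return data.frame of result rows.
#' @export
conventional_models <- function(data, grid) {
  stopifnot(inherits(grid, "analysis_grid"))
  covs <- intersect(grid$obs_covariates, names(data))
  rows <- list()
  for (oc in grid$outcomes) {
    for (j in seq_along(grid$exposures)) {
      ex <- grid$exposures[j]
      other <- setdiff(grid$exposures, ex)
      for (md in c("obs-uv", "obs-mv")) {
        rhs <- c(ex, if (md == "obs-mv") other, covs)
        vars <- c(oc, rhs)
        sub <- data[stats::complete.cases(data[vars]), vars, drop = FALSE]
        fml <- stats::reformulate(rhs, response = oc)
        fit <- stats::lm(fml, data = sub)
        ct <- lmtest::coeftest(fit, vcov. = sandwich::vcovHC(fit, type = "HC1"))
        rows[[length(rows) + 1L]] <- mr_result_row(
          md, ex, oc, "all", nrow(sub),
          beta = ct[ex, "Estimate"], se = ct[ex, "Std. Error"],
          p = ct[ex, "Pr(>|t|)"])
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Statin-exclusion sensitivity analysis
#'
#' Reruns the MR grid on the statin-free subset — a stratification
#' expected to induce collider bias whenever statin use is caused by both
#' adiposity and the (latent) outcome — and reports, per multivariable
#' estimate, the deviation from the generative truth and from the
#' all-sample estimate on the latent (pre-treatment) outcome when one is
#' available.
#'
#' @inheritParams run_grid
#' @param truth Optional truth record from a [simulate_cohort()] cohort;
#'   enables the bias columns.
#' @param latent_suffix Suffix of latent-outcome columns (default
#'   `"_latent"`).
#' @return List with `results` (grid on the statin-free subset) and
#'   `bias_report` (data.frame comparing estimates with truth and with
#'   all-sample latent-outcome estimates).
#' @export
statin_exclusion_analysis <- function(data, grid, truth = NULL,
                                      latent_suffix = "_latent") {
  if (!"statin" %in% names(data)) stop("no 'statin' column")
  prev <- mean(data$statin)
  if (prev == 0)
    warning("statin prevalence is 0; exclusion analysis equals the main analysis")
  sub <- data[data$statin == 0, , drop = FALSE]
  res <- run_grid(sub, grid)
  rep_rows <- list()
  mv <- res[res$model_kind == "mv-2sls", , drop = FALSE]
  for (i in seq_len(nrow(mv))) {
    ex <- mv$exposure[i]; oc <- mv$outcome[i]
    base_oc <- sub(paste0(latent_suffix, "$"), "", oc)
    tr <- NA_real_
    if (!is.null(truth) && !is.null(truth$theta[[base_oc]])) {
      th <- truth$theta[[base_oc]]
      if (!is.null(th$theta_bmi))
        tr <- if (ex == "bmi") th$theta_bmi else th$theta_whr
    }
    lat_col <- paste0(base_oc, latent_suffix)
    lat_beta <- NA_real_; lat_se <- NA_real_
    if (lat_col %in% names(data)) {
      sp <- mr_spec(grid$exposures, grid$instruments, lat_col,
                    covariates = grid$covariates)
      lf <- tryCatch(fit_mv_2sls(data, sp), error = function(e) NULL)
      if (!is.null(lf)) {
        lat_beta <- lf$beta[lf$exposure == ex]
        lat_se <- lf$se[lf$exposure == ex]
      }
    }
    rep_rows[[length(rep_rows) + 1L]] <- data.frame(
      exposure = ex, outcome = oc, stratum = mv$stratum[i],
      beta_excluded = mv$beta[i], se_excluded = mv$se[i],
      truth = tr, bias_vs_truth = mv$beta[i] - tr,
      beta_latent_all = lat_beta, se_latent_all = lat_se,
      bias_vs_latent = mv$beta[i] - lat_beta,
      statin_prevalence = prev, stringsAsFactors = FALSE)
  }
  bias <- if (length(rep_rows)) do.call(rbind, rep_rows) else NULL
  list(results = res, bias_report = bias)
}

#' Age-tertile stratified analysis
#'
#' Stratifies the cohort into age tertiles (empirical 1/3 and 2/3
#' quantiles, boundary ages to the lower tertile) and reruns the MR grid
#' within each. Age is not caused by adiposity, so this stratification is
#' less prone to collider bias than excluding statin users, while still
#' proxying medication exposure: the per-tertile statin prevalence is
#' reported alongside.
#'
#' @inheritParams run_grid
#' @param n_tertiles Number of age groups (default 3).
#' @return List with `results` (long results table, stratum = tertile)
#'   and `tertiles` (per-tertile age range, n, statin prevalence).
#' @export
age_stratified_analysis <- function(data, grid, n_tertiles = 3L) {
  if (!"age" %in% names(data)) stop("no 'age' column")
  lab <- age_tertile_labels(data$age, n_tertiles)
  g2 <- grid
  g2$strata <- "age_tertile"
  res <- run_grid(data, g2)
  tert <- do.call(rbind, lapply(levels(lab), function(l) {
    m <- lab == l
    data.frame(tertile = l, age_min = min(data$age[m]),
               age_max = max(data$age[m]), n = sum(m),
               statin_prevalence = if ("statin" %in% names(data))
                 mean(data$statin[m]) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(results = res, tertiles = tert)
}
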