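#' Subject-specific slopes from a random-intercept/random-slope model
#'
#' Fits `value ~ time + (time | subject)` by REML and returns per-subject
#' slopes (fixed slope + the subject's best linear unbiased predictor).
#' A singular random-effects covariance triggers a fall back to
#' independent random effects `(time || subject)`, logged in the result;
#' if the mixed model fails entirely, a two-stage fallback (per-subject
#' OLS slopes shrunk toward their mean by an empirical-Bayes factor) is
#' used.
#'
#' @param long data.frame with columns `subject`, `time` (months) and
#'   `value`.
#' @return data.frame with `subject`, `intercept` and `slope`
#'   (units/month); attributes `method` (`"reml"`, `"reml_diag"` or
#'   `"two_stage"`) and `diagnostics` (residual SD, random-effect SDs).
#' @export
fit_random_slopes <- function(long) {
  stopifnot(all(c("subject", "time", "value") %in% names(long)))
  long <- long[stats::complete.cases(long[c("subject", "time", "value")]), ]
  if (length(unique(long$subject)) < 20) {
    stop("need at least 20 subjects")
  }
  method <- "reml"
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::lmer(value ~ time + (time | subject), data = long,
                 REML = TRUE,
                 control = lme4::lmerControl(calc.derivs = FALSE)))),
    error = function(e) NULL)
  if (!is.null(fit) && lme4::isSingular(fit, tol = 1e-5)) {
    fit2 <- tryCatch(
      suppressMessages(suppressWarnings(
        lme4::lmer(value ~ time + (time || subject), data = long,
                   REML = TRUE,
                   control = lme4::lmerControl(calc.derivs = FALSE)))),
      error = function(e) NULL)
    if (!is.null(fit2)) {
      fit <- fit2
      method <- "reml_diag"
    }
  }
  if (!is.null(fit)) {
    re <- lme4::ranef(fit)$subject
    fe <- lme4::fixef(fit)
    out <- data.frame(subject = rownames(re),
                      intercept = fe[["(Intercept)"]] + re[["(Intercept)"]],
                      slope = fe[["time"]] + re[["time"]],
                      stringsAsFactors = FALSE)
    vc <- as.data.frame(lme4::VarCorr(fit))
    attr(out, "method") <- method
    attr(out, "diagnostics") <- list(
      sigma = stats::sigma(fit),
      varcorr = vc,
      singular = lme4::isSingular(fit, tol = 1e-5))
    return(out)
  }
  # two-stage fallback: per-subject OLS with empirical-Bayes shrinkage
  sp <- split(long, long$subject)
  ols <- t(vapply(sp, function(d) {
    if (length(unique(d$time)) < 2) return(c(NA_real_, NA_real_))
    cf <- stats::coef(stats::lm(value ~ time, data = d))
    c(cf[1], cf[2])
  }, numeric(2)))
  sl <- ols[, 2]
  v_tot <- stats::var(sl, na.rm = TRUE)
  resid_var <- mean(vapply(sp, function(d) {
    if (nrow(d) < 3) return(NA_real_)
    stats::sigma(stats::lm(value ~ time, data = d))^2
  }, numeric(1)), na.rm = TRUE)
  mean_t2 <- mean(vapply(sp, function(d)
    sum((d$time - mean(d$time))^2), numeric(1)))
  v_noise <- resid_var / mean_t2
  shrink <- max(0, (v_tot - v_noise)) / v_tot
  out <- data.frame(subject = rownames(ols), intercept = ols[, 1],
                    slope = mean(sl, na.rm = TRUE) +
                      shrink * (sl - mean(sl, na.rm = TRUE)),
                    stringsAsFactors = FALSE)
  attr(out, "method") <- "two_stage"
  attr(out, "diagnostics") <- list(sigma = sqrt(resid_var),
                                   shrinkage = shrink)
  out
}

#' Long-format records for one biomarker across visits
#'
#' @param dataset a `trial_dataset`.
#' @param var variable measured per visit.
#' @return data.frame with `subject`, `time` (months) and `value`.
#' @export
biomarker_long <- function(dataset, var) {
  sch <- dataset$schema
  vl <- visit_labels(sch)
  do.call(rbind, lapply(seq_along(vl), function(j) {
    data.frame(subject = dataset$data$subject_id,
               time = unname(sch$visits[j]),
               value = visit_col(dataset, var, vl[j]),
               stringsAsFactors = FALSE)
  }))
}

#' Regress an outcome slope on two protein slopes with adjustment
#'
#' Ordinary least squares of the subject-specific outcome slope on the
#' two protein slopes, adjusted for age, sex, study arm and eGFR (or any
#' covariates supplied). The omnibus p-value is the joint F-test of the
#' two protein-slope coefficients (full vs. covariate-only model). A
#' prediction surface over the observed slope ranges is evaluated with
#' covariates held at their sample means. Model-adequacy diagnostics
#' (residual summary, Shapiro normality statistic, max Cook's distance)
#' and a robust refit are attached.
#'
#' @param outcome_slope numeric subject slopes of the variable of
#'   interest.
#' @param slope_a,slope_b subject slopes of the two proteins.
#' @param covariates data.frame of adjustment covariates (same subjects).
#' @param grid_n grid resolution per axis for the prediction surface.
#' @return object of class `slope_regression`: `coefficients` (data.frame
#'   with estimate, se, p per term), `omnibus` (F statistic, df, p),
#'   `robust` (robust coefficients + divergence flag), `grid`,
#'   `diagnostics`, `n`.
#' @export
regress_slopes <- function(outcome_slope, slope_a, slope_b,
                           covariates = NULL, grid_n = 20) {
  d <- data.frame(y = outcome_slope, slope_a = slope_a, slope_b = slope_b)
  if (!is.null(covariates)) d <- cbind(d, covariates)
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (nrow(d) <= ncol(d) + 1) stop("not enough observations for the model")
  cov_terms <- setdiff(names(d), c("y", "slope_a", "slope_b"))
  rhs_cov <- if (length(cov_terms)) paste(cov_terms, collapse = " + ")
  full_f <- stats::as.formula(paste(
    "y ~ slope_a + slope_b", if (!is.null(rhs_cov)) paste("+", rhs_cov)))
  red_f <- stats::as.formula(paste(
    "y ~", if (!is.null(rhs_cov)) rhs_cov else "1"))
  fit <- stats::lm(full_f, data = d)
  red <- stats::lm(red_f, data = d)
  an <- stats::anova(red, fit)
  cs <- stats::coef(summary(fit))
  coefs <- data.frame(term = rownames(cs), estimate = cs[, "Estimate"],
                      se = cs[, "Std. Error"], p = cs[, "Pr(>|t|)"],
                      row.names = NULL, stringsAsFactors = FALSE)
  omnibus <- list(statistic = an$F[2], df1 = an$Df[2], df2 = an$Res.Df[2],
                  p = an$`Pr(>F)`[2])
  rob <- robust_refit(fit, d)
  grid <- expand.grid(
    slope_a = seq(min(d$slope_a), max(d$slope_a), length.out = grid_n),
    slope_b = seq(min(d$slope_b), max(d$slope_b), length.out = grid_n))
  for (v in cov_terms) grid[[v]] <- mean(d[[v]])
  grid$predicted <- stats::predict(fit, newdata = grid)
  res <- stats::residuals(fit)
  sw <- if (length(res) >= 3 && length(res) <= 5000)
    stats::shapiro.test(res) else NULL
  diagnostics <- list(
    residual_summary = summary(res),
    shapiro_w = if (is.null(sw)) NA_real_ else unname(sw$statistic),
    shapiro_p = if (is.null(sw)) NA_real_ else sw$p.value,
    max_cooks = max(stats::cooks.distance(fit), na.rm = TRUE))
  structure(list(coefficients = coefs, omnibus = omnibus, robust = rob,
                 grid = grid, diagnostics = diagnostics, n = nrow(d),
                 fit = fit),
            class = "slope_regression")
}

#' Robust (M-estimation) refit of a linear model
#'
#' Re-estimates a fitted OLS model with a bounded-loss M-estimator
#' (Tukey bisquare). Always computed; a `diverged` flag marks
#' coefficients that moved by more than one OLS standard error. On
#' non-convergence the OLS coefficients are reported with
#' `converged = FALSE`.
#'
#' @param fit an `lm` fit.
#' @param data the model data.
#' @return list with `coefficients` (robust), `ols` (original), `diverged`
#'   (per-coefficient logical), `converged`.
#' @export
robust_refit <- function(fit, data = stats::model.frame(fit)) {
  ols_cf <- stats::coef(fit)
  ols_se <- stats::coef(summary(fit))[, "Std. Error"]
  rob <- tryCatch(
    suppressWarnings(MASS::rlm(stats::formula(fit), data = data,
                               psi = MASS::psi.bisquare, maxit = 100)),
    error = function(e) NULL)
  if (is.null(rob) || !rob$converged) {
    return(list(coefficients = ols_cf, ols = ols_cf,
                diverged = rep(FALSE, length(ols_cf)), converged = FALSE))
  }
  rcf <- stats::coef(rob)
  list(coefficients = rcf, ols = ols_cf,
       diverged = abs(rcf - ols_cf) > ols_se, converged = TRUE)
}
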