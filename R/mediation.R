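#' Screen proteins as mediator candidates
#'
#' Two selection criteria, each at level `alpha`:
#' \describe{
#'   \item{effect}{treatment changed the protein: the arm coefficient in a
#'     model of the protein's log2 change adjusted for the baseline protein
#'     level and the eGFR fold-change. When both follow-up visits are
#'     supplied the changes are stacked and fitted as a mixed model with a
#'     random subject intercept; with one visit an ordinary regression is
#'     used.}
#'   \item{interaction}{treatment modified the protein's association slope
#'     with the outcome: the arm x protein-fold-change interaction in a
#'     model of the outcome fold-change adjusted for the eGFR fold-change
#'     and the baseline outcome and protein values.}
#' }
#'
#' @param dataset a `trial_dataset`.
#' @param proteins proteins to screen (subset of the panel).
#' @param visit follow-up visit for the interaction criterion (and the
#'   only change visit when `all_visits = FALSE`).
#' @param alpha significance level (default 0.05).
#' @param all_visits use both follow-up visits for the effect criterion.
#' @return data.frame with per-protein estimates and p-values for both
#'   criteria, the `selected` flag and `reason`
#'   (`"effect"`, `"interaction"`, `"both"`, or `""`). Zero-variance
#'   proteins are skipped with reason `"skipped"`.
#' @export
screen_candidates <- function(dataset, proteins, visit, alpha = 0.05,
                              all_visits = TRUE) {
  sch <- dataset$schema
  stopifnot(all(proteins %in% sch$proteins))
  vl <- visit_labels(sch)
  base <- vl[1]
  fups <- if (all_visits) vl[-1] else visit
  egfr_fc <- visit_col(dataset, "egfr", visit) /
    visit_col(dataset, "egfr", base)
  out_fc <- visit_col(dataset, sch$outcome, visit) /
    visit_col(dataset, sch$outcome, base)
  out_bl <- visit_col(dataset, sch$outcome, base)
  arm <- dataset$data$arm
  id <- dataset$data$subject_id

  rows <- lapply(proteins, function(p) {
    bl <- visit_col(dataset, p, base)
    row <- data.frame(protein = p, effect_est = NA_real_,
                      effect_p = NA_real_, inter_est = NA_real_,
                      inter_p = NA_real_, selected = FALSE, reason = "",
                      stringsAsFactors = FALSE)
    # criterion 1: treatment effect on the protein change
    chg <- lapply(fups, function(v) visit_col(dataset, p, v) - bl)
    if (all(vapply(chg, function(x) stats::var(x, na.rm = TRUE), 1) == 0)) {
      row$reason <- "skipped"
      return(row)
    }
    eff <- tryCatch({
      if (length(fups) > 1) {
        ld <- data.frame(
          y = unlist(chg), arm = rep(arm, length(fups)),
          bl = rep(bl, length(fups)),
          egfr_fc = rep(egfr_fc, length(fups)),
          id = rep(id, length(fups)))
        fit <- suppressMessages(suppressWarnings(
          lme4::lmer(y ~ arm + bl + egfr_fc + (1 | id), data = ld,
                     REML = TRUE)))
        cc <- stats::coef(summary(fit))["arm", ]
        # Wald z on the fixed effect (df large in this design)
        c(cc["Estimate"], 2 * stats::pnorm(-abs(cc["t value"])))
      } else {
        fit <- stats::lm(chg[[1]] ~ arm + bl + egfr_fc)
        cc <- stats::coef(summary(fit))["arm", ]
        c(cc["Estimate"], cc["Pr(>|t|)"])
      }
    }, error = function(e) c(NA_real_, NA_real_))
    row$effect_est <- eff[1]; row$effect_p <- eff[2]
    # criterion 2: arm x protein interaction on the outcome fold-change
    pfc <- npx_fold_change(bl, visit_col(dataset, p, visit))
    inter <- tryCatch({
      fit <- stats::lm(out_fc ~ arm * pfc + egfr_fc + out_bl + bl)
      cc <- stats::coef(summary(fit))
      if (!"arm:pfc" %in% rownames(cc)) stop("singular design")
      c(cc["arm:pfc", "Estimate"], cc["arm:pfc", "Pr(>|t|)"])
    }, error = function(e) c(NA_real_, NA_real_))
    row$inter_est <- inter[1]; row$inter_p <- inter[2]
    hit_e <- !is.na(row$effect_p) && row$effect_p < alpha
    hit_i <- !is.na(row$inter_p) && row$inter_p < alpha
    row$selected <- hit_e || hit_i
    row$reason <- if (hit_e && hit_i) "both" else if (hit_e) "effect" else
      if (hit_i) "interaction" else ""
    row
  })
  do.call(rbind, rows)
}

#' Build the mediation signature score
#'
#' All candidate fold-changes enter one ordinary least-squares regression
#' of the outcome on the candidates; the score is the fitted linear
#' predictor, used downstream as a single composite mediator.
#'
#' @param fc matrix/data.frame of candidate mediator fold-changes
#'   (columns = candidates), complete cases.
#' @param outcome outcome fold-change aligned with `fc` rows.
#' @return object of class `signature_score`: `score` (fitted values),
#'   `weights` (named, including `(Intercept)`), `r2`, and `dropped`
#'   (columns removed for exact collinearity).
#' @export
build_signature_score <- function(fc, outcome) {
  fc <- as.matrix(fc)
  stopifnot(ncol(fc) >= 1, !anyNA(fc), !anyNA(outcome))
  if (ncol(fc) >= nrow(fc)) {
    stop("more candidates than subjects; refusing to build the score")
  }
  X <- cbind("(Intercept)" = 1, fc)
  cf <- ols_coef(X, outcome)
  dropped <- names(cf)[is.na(cf)]
  if (length(dropped)) {
    fc <- fc[, setdiff(colnames(fc), dropped), drop = FALSE]
    X <- cbind("(Intercept)" = 1, fc)
    cf <- ols_coef(X, outcome)
  }
  score <- drop(X %*% cf)
  structure(list(score = score, weights = cf,
                 r2 = r_squared(outcome, score), dropped = dropped),
            class = "signature_score")
}

# Point estimates of the linear-SEM decomposition from prebuilt matrices.
# Xm: design for score ~ arm + covariates; Xy: design for
# outcome ~ arm + score + covariates. Column names must contain "arm"
# and (for Xy) "score".
mediate_point <- function(Xm, score, Xy, outcome) {
  alpha1 <- ols_coef(Xm, score)[["arm"]]
  cf <- ols_coef(Xy, outcome)
  beta1 <- cf[["arm"]]; beta2 <- cf[["score"]]
  acme <- alpha1 * beta2
  c(acme = acme, ade = beta1, te = acme + beta1)
}

#' Causal mediation analysis of a composite mediator score
#'
#' Linear product-of-coefficients estimator with a nonparametric subject
#' bootstrap. Two models are fitted: the mediator model
#' `score ~ arm + covariates` and the outcome model
#' `outcome ~ arm + score + covariates`. Point estimates are
#' ACME = alpha1 * beta2, ADE = beta1, TE = ACME + ADE and mediated
#' proportion = ACME/TE; for this no-interaction linear estimator
#' ACME + ADE = TE holds exactly. Inference is by percentile bootstrap
#' over subjects.
#'
#' @param outcome outcome fold-change per subject.
#' @param score composite mediator score per subject.
#' @param arm 0/1 treatment indicator.
#' @param covariates data.frame of pretreatment covariates (baseline
#'   outcome and baseline mediator values, per the design).
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed RNG seed.
#' @param conf confidence level (default 0.95).
#' @param te_tol |TE| below which the proportion is flagged unstable.
#' @return object of class `mediation_result`: `estimates` (data.frame of
#'   acme/ade/te/proportion with CIs), `n_boot`, `seed`, and
#'   `proportion_unstable` (TRUE when |TE| < `te_tol` or ACME and TE have
#'   opposite signs).
#' @export
mediate <- function(outcome, score, arm, covariates = NULL, n_boot = 1000,
                    seed = 1L, conf = 0.95, te_tol = 1e-8) {
  stopifnot(all(arm %in% c(0, 1)), length(unique(arm)) == 2)
  n <- length(outcome)
  C <- if (is.null(covariates)) NULL else as.matrix(covariates)
  Xm <- cbind("(Intercept)" = 1, arm = arm, C)
  Xy <- cbind("(Intercept)" = 1, arm = arm, score = score, C)
  pt <- mediate_point(Xm, score, Xy, outcome)
  prop <- unname(pt["acme"] / pt["te"])
  unstable <- abs(pt["te"]) < te_tol ||
    sign(pt["acme"]) * sign(pt["te"]) < 0

  boot <- matrix(NA_real_, n_boot, 4,
                 dimnames = list(NULL, c("acme", "ade", "te", "proportion")))
  with_seed(seed, {
    for (bi in seq_len(n_boot)) {
      idx <- sample.int(n, replace = TRUE)
      bpt <- mediate_point(Xm[idx, , drop = FALSE], score[idx],
                           Xy[idx, , drop = FALSE], outcome[idx])
      boot[bi, 1:3] <- bpt
      boot[bi, 4] <- bpt["acme"] / bpt["te"]
    }
  })
  al <- (1 - conf) / 2
  ci <- apply(boot, 2, stats::quantile, probs = c(al, 1 - al), na.rm = TRUE)
  est <- data.frame(
    effect = c("acme", "ade", "te", "proportion"),
    estimate = c(pt, proportion = prop),
    ci_lower = ci[1, ], ci_upper = ci[2, ],
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(estimates = est, n_boot = n_boot, seed = seed,
                 conf = conf, proportion_unstable = unname(unstable),
                 boot = boot),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("mediation (linear, %d bootstrap resamples):\n", x$n_boot))
  print(x$estimates, digits = 4)
  if (x$proportion_unstable) cat("note: mediated proportion unstable\n")
  invisible(x)
}

#' Counterfactual-prediction ACME (independent estimation route)
#'
#' Computes the average causal mediation effect by explicit
#' potential-outcome prediction from the two fitted linear models:
#' ACME = mean over subjects of
#' `Y(1, M(1)) - Y(1, M(0))`, where `M(a)` is the mediator-model
#' prediction with arm set to `a` and `Y(a, m)` the outcome-model
#' prediction. For linear no-interaction models this equals the
#' product-of-coefficients estimate to machine precision; it is kept as a
#' separate code path (formula-based [stats::lm()] fits and `predict`)
#' for exactly that check.
#'
#' @inheritParams mediate
#' @return numeric ACME.
#' @export
acme_counterfactual <- function(outcome, score, arm, covariates = NULL) {
  d <- data.frame(outcome = outcome, score = score, arm = arm)
  if (!is.null(covariates)) d <- cbind(d, covariates)
  cov_terms <- setdiff(names(d), c("outcome", "score", "arm"))
  fm <- stats::as.formula(paste(
    "score ~ arm", if (length(cov_terms))
      paste("+", paste(cov_terms, collapse = " + ")) else ""))
  fy <- stats::as.formula(paste(
    "outcome ~ arm + score", if (length(cov_terms))
      paste("+", paste(cov_terms, collapse = " + ")) else ""))
  mfit <- stats::lm(fm, data = d)
  yfit <- stats::lm(fy, data = d)
  d1 <- d; d1$arm <- 1
  d0 <- d; d0$arm <- 0
  m1 <- stats::predict(mfit, newdata = d1)
  m0 <- stats::predict(mfit, newdata = d0)
  y11 <- d1; y11$score <- m1
  y10 <- d1; y10$score <- m0
  mean(stats::predict(yfit, newdata = y11) -
         stats::predict(yfit, newdata = y10))
}

#' Leave-one-out mediated-proportion loss
#'
#' For each candidate mediator the signature score is refit without it,
#' the mediation analysis rerun, and the loss defined as the full-model
#' mediated proportion minus the reduced-model proportion. Within each
#' bootstrap replicate the same subject resample is used for the full and
#' every reduced model, so each loss is a paired difference; score weights
#' are refit on each resample.
#'
#' @param outcome outcome fold-change per subject.
#' @param fc matrix of candidate mediator fold-changes (>= 2 columns).
#' @param arm 0/1 treatment indicator.
#' @param covariates data.frame of pretreatment covariates.
#' @param n_boot bootstrap resamples for the loss CIs (default 1000).
#' @param seed RNG seed.
#' @param conf confidence level.
#' @return object of class `loo_result`: `full` (the full-model
#'   [mediate()]-style point estimates), `losses` (data.frame per
#'   mediator: point loss, CI, rank; rank 1 = largest loss).
#' @export
loo_proportion_loss <- function(outcome, fc, arm, covariates = NULL,
                                n_boot = 1000, seed = 1L, conf = 0.95) {
  fc <- as.matrix(fc)
  k <- ncol(fc)
  if (k < 2) stop("need at least 2 candidate mediators")
  C <- if (is.null(covariates)) NULL else as.matrix(covariates)
  n <- length(outcome)

  prop_for <- function(cols, idx) {
    Xs <- cbind(1, fc[idx, cols, drop = FALSE])
    w <- ols_coef(Xs, outcome[idx])
    w[is.na(w)] <- 0
    score <- drop(Xs %*% w)
    Xm <- cbind(1, arm = arm[idx], C[idx, , drop = FALSE])
    colnames(Xm)[2] <- "arm"
    Xy <- cbind(1, arm = arm[idx], score = score, C[idx, , drop = FALSE])
    colnames(Xy)[2:3] <- c("arm", "score")
    pt <- mediate_point(Xm, score, Xy, outcome[idx])
    unname(pt["acme"] / pt["te"])
  }

  all_idx <- seq_len(n)
  full_prop <- prop_for(seq_len(k), all_idx)
  point_loss <- vapply(seq_len(k), function(j)
    full_prop - prop_for(setdiff(seq_len(k), j), all_idx), numeric(1))

  boot_loss <- matrix(NA_real_, n_boot, k)
  with_seed(seed, {
    for (bi in seq_len(n_boot)) {
      idx <- sample.int(n, replace = TRUE)
      fp <- prop_for(seq_len(k), idx)
      boot_loss[bi, ] <- vapply(seq_len(k), function(j)
        fp - prop_for(setdiff(seq_len(k), j), idx), numeric(1))
    }
  })
  al <- (1 - conf) / 2
  ci <- apply(boot_loss, 2, stats::quantile, probs = c(al, 1 - al),
              na.rm = TRUE)
  losses <- data.frame(
    mediator = colnames(fc) %||% paste0("m", seq_len(k)),
    loss = point_loss, ci_lower = ci[1, ], ci_upper = ci[2, ],
    stringsAsFactors = FALSE, row.names = NULL)
  losses$rank <- rank(-losses$loss, ties.method = "first")
  losses <- losses[order(losses$rank), , drop = FALSE]
  structure(list(full_proportion = full_prop, losses = losses,
                 n_boot = n_boot, seed = seed),
            class = "loo_result")
}
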