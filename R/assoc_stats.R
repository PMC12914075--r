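#' Spearman p-for-trend across quartile groups
#'
#' Rank correlation of a continuous variable with the ordered group index
#' (1..k), two-sided p from the t approximation (ties make the exact
#' distribution unavailable).
#'
#' @param values numeric variable.
#' @param group ordered group index per subject (1..k).
#' @return list with `rho`, `p`, `n`, `flag` (`"constant"` when the
#'   variable or grouping is constant, else `""`).
#' @export
spearman_trend <- function(values, group) {
  ok <- !is.na(values) & !is.na(group)
  values <- values[ok]; group <- group[ok]
  if (length(unique(group)) < 3) stop("need at least 3 groups represented")
  if (length(unique(values)) == 1) {
    return(list(rho = NA_real_, p = NA_real_, n = length(values),
                flag = "constant"))
  }
  ct <- suppressWarnings(
    stats::cor.test(values, group, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(values),
       flag = "")
}

#' Cochran-Armitage trend test for a binary variable across ordered groups
#'
#' Score test for a linear trend in proportions of a 2 x k table. The
#' statistic is `Z = (T - E[T]) / sqrt(Var[T])` with `T = sum(s_k * x_k)`,
#' `x_k` the successes in column k, expectation and variance under the
#' null of a common proportion (hypergeometric sampling). Two-sided p
#' from the normal reference; `Z^2` equals the usual chi-squared trend
#' statistic. Scores default to equally spaced 1..k.
#'
#' @param counts 2 x k matrix of non-negative integer counts; row 1 =
#'   successes, row 2 = failures.
#' @param scores column scores (default `1:k`).
#' @return list with `z`, `p`, `scores`, `dropped` (empty columns removed
#'   with a warning).
#' @export
cochran_armitage <- function(counts, scores = NULL) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == 2, ncol(counts) >= 2, all(counts >= 0))
  empty <- colSums(counts) == 0
  dropped <- which(empty)
  if (any(empty)) {
    warning("dropping ", sum(empty), " empty column(s)")
    counts <- counts[, !empty, drop = FALSE]
    if (!is.null(scores)) scores <- scores[!empty]
  }
  k <- ncol(counts)
  if (is.null(scores)) scores <- seq_len(k)
  n_col <- colSums(counts)
  N <- sum(n_col)
  R <- sum(counts[1, ])
  T_obs <- sum(scores * counts[1, ])
  p_bar <- R / N
  E_T <- p_bar * sum(scores * n_col)
  s_bar <- sum(scores * n_col) / N
  V_T <- p_bar * (1 - p_bar) * sum(n_col * (scores - s_bar)^2)
  z <- if (V_T > 0) (T_obs - E_T) / sqrt(V_T) else 0
  list(z = z, p = 2 * stats::pnorm(-abs(z)), scores = scores,
       dropped = dropped)
}

#' Treatment x protein interaction on the outcome fold-change
#'
#' OLS of the outcome fold-change on the randomization arm, the protein
#' fold-change, their interaction, the eGFR fold-change, and the baseline
#' outcome and protein values. Returns the interaction coefficient, which
#' tests whether treatment modifies the protein's association slope with
#' the outcome.
#'
#' @param dataset a `trial_dataset`.
#' @param protein protein name.
#' @param visit follow-up visit label.
#' @return list with `estimate`, `se`, `p`, `n`, `fit`.
#' @export
interaction_model <- function(dataset, protein, visit) {
  sch <- dataset$schema
  base <- visit_labels(sch)[1]
  arm <- dataset$data$arm
  if (length(unique(arm)) < 2) stop("single-arm data: no interaction model")
  pfc <- npx_fold_change(visit_col(dataset, protein, base),
                         visit_col(dataset, protein, visit))
  d <- data.frame(
    out_fc = visit_col(dataset, sch$outcome, visit) /
      visit_col(dataset, sch$outcome, base),
    arm = arm, pfc = pfc,
    egfr_fc = visit_col(dataset, "egfr", visit) /
      visit_col(dataset, "egfr", base),
    out_bl = visit_col(dataset, sch$outcome, base),
    p_bl = visit_col(dataset, protein, base))
  d <- d[stats::complete.cases(d), ]
  fit <- stats::lm(out_fc ~ arm * pfc + egfr_fc + out_bl + p_bl, data = d)
  cs <- stats::coef(summary(fit))
  if (!"arm:pfc" %in% rownames(cs)) {
    stop("singular design: interaction term not estimable")
  }
  list(estimate = cs["arm:pfc", "Estimate"],
       se = cs["arm:pfc", "Std. Error"],
       p = cs["arm:pfc", "Pr(>|t|)"], n = nrow(d), fit = fit)
}

#' Treatment effect stratified by the median of a baseline variable
#'
#' Splits subjects at the median baseline value (below-or-equal vs.
#' above), estimates the covariate-adjusted treatment effect on the
#' outcome fold-change within each stratum, and reports the
#' treatment x stratum interaction p from the pooled model.
#'
#' @param dataset a `trial_dataset`.
#' @param baseline_var variable whose baseline value defines the split.
#' @param visit follow-up visit label.
#' @param conf confidence level for the stratum effect CIs.
#' @return list with `strata` (data.frame: stratum, n, effect, ci, p),
#'   `interaction_p`, `median` (the split value).
#' @export
stratified_effect <- function(dataset, baseline_var, visit, conf = 0.95) {
  sch <- dataset$schema
  base <- visit_labels(sch)[1]
  bl <- visit_col(dataset, baseline_var, base)
  d <- data.frame(
    out_fc = visit_col(dataset, sch$outcome, visit) /
      visit_col(dataset, sch$outcome, base),
    arm = dataset$data$arm, bl = bl,
    egfr_fc = visit_col(dataset, "egfr", visit) /
      visit_col(dataset, "egfr", base),
    out_bl = visit_col(dataset, sch$outcome, base))
  d <- d[stats::complete.cases(d), ]
  med <- stats::median(d$bl)
  d$above <- as.integer(d$bl > med)
  if (!all(table(d$above) > 0)) stop("one stratum is empty")
  z <- stats::qnorm(1 - (1 - conf) / 2)
  strata <- do.call(rbind, lapply(c(0, 1), function(s) {
    ds <- d[d$above == s, ]
    if (length(unique(ds$arm)) < 2) {
      return(data.frame(stratum = ifelse(s, "above", "below"),
                        n = nrow(ds), effect = NA_real_,
                        ci_lower = NA_real_, ci_upper = NA_real_,
                        p = NA_real_, stringsAsFactors = FALSE))
    }
    fit <- stats::lm(out_fc ~ arm + egfr_fc + out_bl, data = ds)
    cs <- stats::coef(summary(fit))["arm", ]
    data.frame(stratum = ifelse(s, "above", "below"), n = nrow(ds),
               effect = cs[["Estimate"]],
               ci_lower = cs[["Estimate"]] - z * cs[["Std. Error"]],
               ci_upper = cs[["Estimate"]] + z * cs[["Std. Error"]],
               p = cs[["Pr(>|t|)"]], stringsAsFactors = FALSE)
  }))
  pooled <- stats::lm(out_fc ~ arm * above + egfr_fc + out_bl, data = d)
  cs <- stats::coef(summary(pooled))
  list(strata = strata,
       interaction_p = cs["arm:above", "Pr(>|t|)"],
       median = med)
}

#' Adjusted two-predictor regression plane
#'
#' OLS of the outcome fold-change on two protein fold-changes, adjusted
#' for the baseline values of the outcome and both proteins, with a
#' prediction grid over the observed fold-change ranges (baselines held
#' at their sample means).
#'
#' @param outcome_fc outcome fold-change per subject.
#' @param fc_a,fc_b the two protein fold-changes.
#' @param baselines data.frame with the three baseline columns.
#' @param grid_n grid resolution per axis.
#' @return list with `coefficients` (data.frame), `r2`, `grid`, `fit`.
#' @export
regression_plane <- function(outcome_fc, fc_a, fc_b, baselines = NULL,
                             grid_n = 20) {
  d <- data.frame(y = outcome_fc, fc_a = fc_a, fc_b = fc_b)
  if (!is.null(baselines)) d <- cbind(d, baselines)
  d <- d[stats::complete.cases(d), ]
  fit <- stats::lm(y ~ ., data = d)
  cs <- stats::coef(summary(fit))
  grid <- expand.grid(
    fc_a = seq(min(d$fc_a), max(d$fc_a), length.out = grid_n),
    fc_b = seq(min(d$fc_b), max(d$fc_b), length.out = grid_n))
  for (v in setdiff(names(d), c("y", "fc_a", "fc_b"))) {
    grid[[v]] <- mean(d[[v]])
  }
  grid$predicted <- stats::predict(fit, newdata = grid)
  list(coefficients = data.frame(term = rownames(cs),
                                 estimate = cs[, "Estimate"],
                                 se = cs[, "Std. Error"],
                                 p = cs[, "Pr(>|t|)"], row.names = NULL,
                                 stringsAsFactors = FALSE),
       r2 = summary(fit)$r.squared, grid = grid, fit = fit)
}

#' Quartile summary table with p-for-trend
#'
#' Table-1-style report: continuous variables as median (IQR), binary
#' variables as n (%), per quartile of the outcome fold-change, with
#' Spearman (continuous) or Cochran-Armitage (binary) p-for-trend.
#' Trend p-values are reported unadjusted; a Benjamini-Hochberg column
#' is emitted alongside.
#'
#' @param values named list of numeric vectors (one per variable, aligned
#'   with `group`); binary variables are detected as 0/1.
#' @param group quartile index per subject from [assign_quartiles()].
#' @return data.frame: variable, one summary column per quartile, `type`,
#'   `p_trend`, `p_trend_bh`.
#' @export
quartile_table <- function(values, group) {
  ks <- sort(unique(group[!is.na(group)]))
  rows <- lapply(names(values), function(v) {
    x <- values[[v]]
    binary <- all(stats::na.omit(x) %in% c(0, 1))
    cells <- vapply(ks, function(g) {
      xi <- x[!is.na(group) & group == g]
      if (binary) {
        sprintf("%d (%.1f)", sum(xi, na.rm = TRUE),
                100 * mean(xi, na.rm = TRUE))
      } else {
        q <- stats::quantile(xi, c(0.25, 0.5, 0.75), na.rm = TRUE)
        sprintf("%.1f (%.1f-%.1f)", q[2], q[1], q[3])
      }
    }, character(1))
    p <- if (binary) {
      tab <- rbind(
        vapply(ks, function(g) sum(x[group == g], na.rm = TRUE), 1),
        vapply(ks, function(g) sum(1 - x[group == g], na.rm = TRUE), 1))
      cochran_armitage(tab)$p
    } else {
      spearman_trend(x, group)$p
    }
    out <- data.frame(variable = v, t(cells),
                      type = ifelse(binary, "binary", "continuous"),
                      p_trend = p, stringsAsFactors = FALSE)
    names(out)[2:(1 + length(ks))] <- paste0("Q", ks)
    out
  })
  tab <- do.call(rbind, rows)
  tab$p_trend_bh <- stats::p.adjust(tab$p_trend, method = "BH")
  tab
}
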