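test_that("screening has power for a treated mediator and skips constants", {
  hits <- vapply(1:20, function(s) {
    sim <- simulate_trial(small_cfg(400 + s, n = 500, n_proteins = 3,
                                    a = c(0.5, 0, 0), b = c(0.4, 0, 0)))
    scr <- screen_candidates(sim$dataset, "P001", "month1")
    scr$selected[1] && scr$reason[1] %in% c("effect", "both")
  }, logical(1))
  expect_gte(sum(hits), 19)

  # zero-variance protein is skipped
  sim <- small_sim()
  ds <- sim$dataset
  for (v in c("baseline", "month1", "month9")) {
    ds$data[[paste0("P009__", v)]] <- 3.14
  }
  scr <- screen_candidates(ds, "P009", "month1")
  expect_equal(scr$reason, "skipped")
  expect_false(scr$selected)
})

test_that("screening criteria hold their type-I level on null proteins", {
  # 200 noise proteins, no treatment effect anywhere
  sim <- simulate_trial(sim_config(
    n_subjects = 300, n_proteins = 200, a = 0, b = 0, c_direct = 0,
    seed = 71))
  scr <- screen_candidates(sim$dataset, sim$dataset$schema$proteins,
                           "month1", all_visits = FALSE)
  rate_effect <- mean(scr$effect_p < 0.05, na.rm = TRUE)
  rate_inter <- mean(scr$inter_p < 0.05, na.rm = TRUE)
  # binomial(200, 0.05) 99.9% envelope
  expect_gt(rate_effect, 0.005); expect_lt(rate_effect, 0.115)
  expect_gt(rate_inter, 0.005); expect_lt(rate_inter, 0.115)
})

test_that("the signature score is the OLS linear predictor", {
  set.seed(21)
  n <- 200
  fc <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- 0.5 * fc[, 1] - 0.3 * fc[, 2] + rnorm(n, 0, 0.4)
  sig <- build_signature_score(fc, y)
  # reproduces lm predictions exactly
  ref <- lm(y ~ fc)
  expect_equal(unname(sig$score), unname(fitted(ref)), tolerance = 1e-10)
  expect_equal(sig$r2, summary(ref)$r.squared, tolerance = 1e-10)

  # single candidate: affine transform of that fold-change
  sig1 <- build_signature_score(fc[, 1, drop = FALSE], y)
  expect_equal(cor(sig1$score, fc[, 1]), 1, tolerance = 1e-10)

  # orthogonal candidates: weights equal univariate slopes
  x1 <- rep(c(-1, 1), n / 2); x2 <- rep(c(-1, 1), each = n / 2)
  yo <- x1 + 2 * x2 + rnorm(n, 0, 0.1)
  sigo <- build_signature_score(cbind(u = x1, v = x2), yo)
  expect_equal(unname(sigo$weights["u"]),
               unname(coef(lm(yo ~ x1))[2]), tolerance = 1e-10)

  # exact collinearity: offending column dropped and reported
  fcc <- cbind(fc, dup = fc[, 1])
  sigc <- build_signature_score(fcc, y)
  expect_equal(sigc$dropped, "dup")
  # p >= n refused
  expect_error(build_signature_score(matrix(rnorm(20), 4, 5), rnorm(4)),
               "more candidates")
})

test_that("ACME + ADE = TE exactly and TE matches the total-effect regression", {
  sim <- small_sim()
  mi <- mediation_inputs(sim)
  sig <- build_signature_score(mi$fc, mi$outcome)
  mr <- mediate(mi$outcome, sig$score, mi$arm, mi$covariates,
                n_boot = 50, seed = 3)
  est <- mr$estimates
  expect_lt(abs(est$estimate[1] + est$estimate[2] - est$estimate[3]),
            1e-10)
  # TE equals the arm coefficient of the no-mediator regression
  te_fit <- lm(mi$outcome ~ mi$arm + as.matrix(mi$covariates))
  expect_equal(est$estimate[3], unname(coef(te_fit)[2]), tolerance = 1e-10)
  # CIs contain the point estimates
  expect_true(all(est$ci_lower <= est$estimate + 1e-12 &
                    est$estimate <= est$ci_upper + 1e-12))
})

test_that("bootstrap draws are seed-stable", {
  sim <- small_sim()
  mi <- mediation_inputs(sim)
  sig <- build_signature_score(mi$fc, mi$outcome)
  m1 <- mediate(mi$outcome, sig$score, mi$arm, mi$covariates,
                n_boot = 100, seed = 12)
  m2 <- mediate(mi$outcome, sig$score, mi$arm, mi$covariates,
                n_boot = 100, seed = 12)
  expect_identical(m1$estimates, m2$estimates)
  expect_identical(m1$boot, m2$boot)
})

test_that("product-of-coefficients equals counterfactual prediction", {
  set.seed(31)
  for (i in 1:50) {
    n <- 60
    arm <- rep(0:1, n / 2)
    cov1 <- rnorm(n)
    score <- rnorm(n, 0.4 * arm + 0.2 * cov1, 0.5)
    outcome <- rnorm(n, 0.3 * arm + 0.7 * score - 0.1 * cov1, 0.5)
    covs <- data.frame(cov1 = cov1)
    mr <- mediate(outcome, score, arm, covs, n_boot = 2, seed = 1)
    cf <- acme_counterfactual(outcome, score, arm, covs)
    expect_equal(mr$estimates$estimate[1], cf, tolerance = 1e-12)
  }
})

test_that("a null mediator path gives ACME near zero with covering CI", {
  covered <- vapply(1:30, function(s) {
    set.seed(1000 + s)
    n <- 300
    arm <- sample(rep(0:1, n / 2))
    med <- rnorm(n, 0.5 * arm, 1)     # treatment moves the mediator
    outc <- rnorm(n, 0.4 * arm, 1)    # but the outcome ignores it
    mr <- mediate(outc, med, arm, n_boot = 300, seed = s)
    est <- mr$estimates[mr$estimates$effect == "acme", ]
    est$ci_lower <= 0 && 0 <= est$ci_upper
  }, logical(1))
  expect_gte(mean(covered), 0.85)
})

test_that("an unstable proportion (opposite signs) is flagged", {
  set.seed(33)
  n <- 200
  arm <- rep(0:1, n / 2)
  med <- rnorm(n, 1.0 * arm, 0.3)
  outc <- rnorm(n, -0.5 * arm + 0.4 * med, 0.3)  # ACME and ADE oppose
  mr <- mediate(outc, med, arm, n_boot = 20, seed = 2)
  est <- mr$estimates
  acme <- est$estimate[est$effect == "acme"]
  te <- est$estimate[est$effect == "te"]
  expect_true(sign(acme) != sign(te))
  expect_true(mr$proportion_unstable)
})

test_that("leave-one-out losses isolate null and dominant mediators", {
  # mediator 1 dominates (a*b = 0.2), mediator 3 is null
  sim <- simulate_trial(small_cfg(55, n = 600, n_proteins = 5,
                                  a = c(0.5, 0.25, 0),
                                  b = c(0.4, 0.2, 0),
                                  c_direct = 0.1))
  mi <- mediation_inputs(sim)
  loo <- loo_proportion_loss(mi$outcome, mi$fc, mi$arm, mi$covariates,
                             n_boot = 200, seed = 4)
  losses <- loo$losses
  expect_equal(losses$mediator[losses$rank == 1], "P001")
  null_row <- losses[losses$mediator == "P003", ]
  expect_lt(abs(null_row$loss), 0.05)
  expect_true(null_row$ci_lower <= 0 && 0 <= null_row$ci_upper)
  expect_error(loo_proportion_loss(mi$outcome, mi$fc[, 1, drop = FALSE],
                                   mi$arm), "at least 2")
})

test_that("duplicated mediators compensate each other in LOO losses", {
  sim <- simulate_trial(small_cfg(66, n = 500, n_proteins = 4,
                                  a = c(0.5, 0.3), b = c(0.4, 0.25),
                                  c_direct = 0.1))
  mi <- mediation_inputs(sim)
  fc <- cbind(mi$fc[, 1:2], P001twin = mi$fc[, 1])
  loo <- loo_proportion_loss(mi$outcome, fc, mi$arm, mi$covariates,
                             n_boot = 100, seed = 5)
  l <- loo$losses
  # removing either twin is compensated by the other
  expect_lt(abs(l$loss[l$mediator == "P001"]), 0.05)
  expect_lt(abs(l$loss[l$mediator == "P001twin"]), 0.05)
  expect_gt(l$loss[l$mediator == "P002"],
            abs(l$loss[l$mediator == "P001"]))
})
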