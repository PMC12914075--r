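test_that("Spearman trend sees monotone signals and flags constants", {
  g <- rep(1:4, each = 25)
  st <- spearman_trend(as.numeric(g), g)
  expect_equal(st$rho, 1, tolerance = 1e-10)
  # antisymmetry under reversed group order
  set.seed(1)
  x <- rnorm(100) + 0.3 * g
  s1 <- spearman_trend(x, g)
  s2 <- spearman_trend(x, 5 - g)
  expect_equal(s1$rho, -s2$rho, tolerance = 1e-10)
  expect_equal(spearman_trend(rep(1, 100), g)$flag, "constant")
  expect_error(spearman_trend(x[1:50], rep(1:2, 25)), "3 groups")
})

test_that("Spearman trend p-values are uniform under the null", {
  g <- rep(1:4, each = 30)
  ps <- vapply(1:500, function(s) {
    set.seed(s)
    spearman_trend(rnorm(120), g)$p
  }, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("Cochran-Armitage matches the base-R score-test oracle", {
  tab <- rbind(c(10, 20, 30, 40), c(40, 30, 20, 10))
  ca <- cochran_armitage(tab)
  oracle <- prop.trend.test(tab[1, ], colSums(tab))
  expect_equal(ca$z^2, unname(oracle$statistic), tolerance = 1e-10)
  expect_equal(ca$p, oracle$p.value, tolerance = 1e-10)
  # more random small tables against the oracle
  set.seed(2)
  for (i in 1:50) {
    k <- sample(2:5, 1)
    t2 <- matrix(rpois(2 * k, 8) + 1, 2, k)
    ca2 <- cochran_armitage(t2)
    or2 <- prop.trend.test(t2[1, ], colSums(t2))
    expect_equal(ca2$z^2, unname(or2$statistic), tolerance = 1e-8)
  }
})

test_that("Cochran-Armitage p agrees with a permutation oracle on a small table", {
  tab <- rbind(c(3, 6, 9), c(9, 6, 3))
  ca <- cochran_armitage(tab)
  # Monte Carlo permutation of the 36 subjects across columns
  set.seed(5)
  cols <- rep(1:3, colSums(tab))
  succ <- 12
  T_obs <- sum(1:3 * tab[1, ])
  stats <- replicate(20000, {
    hit <- sample(cols, succ)
    sum(hit)
  })
  p_perm <- mean(abs(stats - mean(stats)) >= abs(T_obs - mean(stats)) - 1e-9)
  expect_lt(abs(ca$p - p_perm), 0.02)
})

test_that("Cochran-Armitage edge behaviour: equal proportions, reversal, scaling", {
  tab_eq <- rbind(c(10, 20, 30), c(10, 20, 30))
  expect_equal(cochran_armitage(tab_eq)$z, 0)
  tab <- rbind(c(5, 10, 20), c(20, 10, 5))
  z1 <- cochran_armitage(tab)$z
  z2 <- cochran_armitage(tab, scores = 3:1)$z
  expect_equal(z1, -z2, tolerance = 1e-12)
  # multiplying counts by m grows |Z| and shrinks p (directional)
  z4 <- cochran_armitage(4 * tab)$z
  expect_gt(abs(z4), abs(z1))
  expect_lt(cochran_armitage(4 * tab)$p, cochran_armitage(tab)$p)
  # empty column dropped with warning
  expect_warning(ca <- cochran_armitage(rbind(c(5, 0, 10), c(5, 0, 10))),
                 "empty")
  expect_equal(ca$dropped, 2)
})

test_that("Cochran-Armitage null p-values are uniform", {
  ps <- vapply(1:500, function(s) {
    set.seed(s)
    x <- rbinom(4, 60, 0.4)
    cochran_armitage(rbind(x, 60 - x))$p
  }, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("interaction model recovers a planted arm x protein interaction", {
  set.seed(2024)
  # outcome fold-change built with an explicit interaction on P001
  mk <- function(seed, gamma) {
    sim <- simulate_trial(small_cfg(seed, n = 500, n_proteins = 3,
                                    a = c(0, 0, 0), b = c(0, 0, 0),
                                    c_direct = 0))
    d <- sim$dataset$data
    pfc <- npx_fold_change(d$P001__baseline, d$P001__month1)
    y <- 1 + 0.05 * d$arm + gamma * d$arm * (pfc - 1) +
      rnorm(nrow(d), 0, 0.05)
    d$picp__month1 <- d$picp__baseline * y
    sim$dataset$data <- d
    sim$dataset
  }
  ds <- mk(201, 0.4)
  im <- interaction_model(ds, "P001", "month1")
  expect_lt(abs(im$estimate - 0.4), 3 * im$se)
  expect_lt(im$p, 0.05)

  # null interaction: rejection rate near alpha over repeated trials
  rejections <- vapply(1:60, function(s)
    interaction_model(mk(300 + s, 0), "P001", "month1")$p < 0.05,
    logical(1))
  expect_lte(sum(rejections), 9)  # binom(60, .05) upper tail

  # single-arm data refused
  ds1 <- ds; ds1$data$arm <- 1
  expect_error(interaction_model(ds1, "P001", "month1"), "single-arm")
})

test_that("stratified effects localize a planted above-median interaction", {
  set.seed(42)
  mk <- function(seed, effect_above) {
    sim <- simulate_trial(small_cfg(seed, n = 600, n_proteins = 3,
                                    a = c(0, 0, 0), b = c(0, 0, 0),
                                    c_direct = 0))
    d <- sim$dataset$data
    above <- d$P001__baseline > median(d$P001__baseline)
    y <- 1 + effect_above * d$arm * above + rnorm(nrow(d), 0, 0.08)
    d$picp__month1 <- d$picp__baseline * y
    sim$dataset$data <- d
    sim$dataset
  }
  hits <- vapply(1:20, function(s) {
    se <- stratified_effect(mk(500 + s, 0.15), "P001", "month1")
    below <- se$strata[se$strata$stratum == "below", ]
    above <- se$strata[se$strata$stratum == "above", ]
    covers0 <- below$ci_lower <= 0 && 0 <= below$ci_upper
    excludes0 <- above$ci_lower > 0 || above$ci_upper < 0
    covers0 && excludes0
  }, logical(1))
  expect_gte(sum(hits), 18)

  # interaction p uniform under a homogeneous effect
  ps <- vapply(1:150, function(s)
    stratified_effect(mk(700 + s, 0), "P001", "month1")$interaction_p,
    numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)

  # even median split of 368 subjects
  sim <- simulate_trial(small_cfg(3, n = 368))
  se <- stratified_effect(sim$dataset, "P001", "month1")
  expect_equal(sort(se$strata$n), c(184, 184))
})

test_that("regression plane is exact for an exactly linear outcome", {
  set.seed(31)
  n <- 150
  fa <- runif(n, 0.5, 2); fb <- runif(n, 0.5, 2)
  y <- 0.5 * fa - 0.5 * fb
  rp <- regression_plane(y, fa, fb)
  est <- rp$coefficients
  expect_equal(est$estimate[est$term == "fc_a"], 0.5, tolerance = 1e-10)
  expect_equal(est$estimate[est$term == "fc_b"], -0.5, tolerance = 1e-10)
  expect_equal(rp$r2, 1, tolerance = 1e-10)
  # grid corners equal the linear form
  corner <- rp$grid[1, ]
  expect_equal(corner$predicted,
               0.5 * corner$fc_a - 0.5 * corner$fc_b, tolerance = 1e-8)
})

test_that("regression plane recovers coefficients under the generator", {
  # two mediators only, no covariate paths: the fitted plane is the
  # generating model and recovery is unbiased
  zero <- c(age = 0, sex = 0, egfr = 0)
  sim <- simulate_trial(small_cfg(91, n = 500, a = c(0.5, -0.4),
                                  b = c(0.4, -0.3), c_direct = 0,
                                  cov_mediator = zero, cov_outcome = zero))
  d <- sim$dataset$data
  meds <- sim$truth$mediators
  fa <- npx_fold_change(d[[paste0(meds[1], "__baseline")]],
                        d[[paste0(meds[1], "__month1")]])
  fb <- npx_fold_change(d[[paste0(meds[2], "__baseline")]],
                        d[[paste0(meds[2], "__month1")]])
  y <- log(d$picp__month1 / d$picp__baseline)
  # on the log scale the generator's slope in log2(fc) units is b*log2(e)
  rp <- regression_plane(y, log2(fa), log2(fb),
                         data.frame(picp_bl = log(d$picp__baseline),
                                    a_bl = d[[paste0(meds[1], "__baseline")]],
                                    b_bl = d[[paste0(meds[2], "__baseline")]]))
  est <- rp$coefficients
  ca <- est[est$term == "fc_a", ]
  cb <- est[est$term == "fc_b", ]
  expect_lt(abs(ca$estimate - sim$truth$b[1]), 3 * ca$se)
  expect_lt(abs(cb$estimate - sim$truth$b[2]), 3 * cb$se)
})

test_that("quartile table formats summaries with BH-adjusted trends", {
  set.seed(41)
  n <- 200
  fc <- runif(n)
  q <- assign_quartiles(fc)
  vars <- list(age = rnorm(n, 70, 5) + 2 * q$group,
               male = rbinom(n, 1, 0.6))
  tab <- quartile_table(vars, q$group)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$type, c("continuous", "binary"))
  expect_true(all(tab$p_trend >= 0 & tab$p_trend <= 1))
  expect_true(all(tab$p_trend_bh >= tab$p_trend - 1e-12))
  expect_match(tab$Q1[1], "^[0-9.]+ \\([0-9.]+-[0-9.]+\\)$")
  expect_match(tab$Q1[2], "^[0-9]+ \\([0-9.]+\\)$")
  expect_lt(tab$p_trend[1], 0.01)
})
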