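test_that("train/test split is stratified, disjoint and reproducible", {
  set.seed(3)
  arm <- rbinom(488, 1, 0.5)
  y <- rnorm(488)
  sp <- split_train_test(arm, y, seed = 5)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), seq_len(488))
  expect_true(abs(length(sp$train) - 390) <= 4)
  sp2 <- split_train_test(arm, y, seed = 5)
  expect_identical(sp, sp2)
  expect_false(identical(sp, split_train_test(arm, y, seed = 6)))
  expect_error(split_train_test(rep(0:1, 4)), "at least 10")
})

test_that("arm proportions are balanced across partitions over many seeds", {
  set.seed(4)
  arm <- rbinom(200, 1, 0.5)
  y <- rnorm(200)
  for (s in 1:100) {
    sp <- split_train_test(arm, y, seed = s)
    gap <- abs(mean(arm[sp$train]) - mean(arm[sp$test]))
    expect_lt(gap, 0.05)
  }
})

test_that("the linear learner recovers a noiseless linear target", {
  set.seed(10)
  n <- 120; p <- 15
  x <- matrix(runif(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  y <- 2 * x[, 1] - x[, 2] + 0.5 * x[, 3]
  sp <- split_train_test(rep(0:1, n / 2), y, seed = 1)
  fit <- fit_learner(x[sp$train, ], y[sp$train],
                     learner_spec("enet",
                                  expand.grid(alpha = 0.5,
                                              lambda = c(1e-4, 1e-3))),
                     seed = 2, x_test = x[sp$test, ], y_test = y[sp$test])
  expect_gt(fit$report$r2[fit$report$partition == "test"], 0.99)
})

test_that("a pure-noise target gives test R2 near zero", {
  r2s <- vapply(1:20, function(s) {
    set.seed(s)
    n <- 150; p <- 10
    x <- matrix(runif(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
    y <- rnorm(n)
    fit <- fit_learner(x[1:100, ], y[1:100],
                       learner_spec("enet",
                                    expand.grid(alpha = 0.5, lambda = 0.05)),
                       seed = s, x_test = x[101:150, ], y_test = y[101:150])
    fit$report$r2[2]
  }, numeric(1))
  expect_lt(abs(mean(r2s)), 0.1)
})

test_that("a constant target is fit with zero RMSE", {
  set.seed(11)
  x <- matrix(runif(600), 60, 10, dimnames = list(NULL, paste0("f", 1:10)))
  y <- rep(2.5, 60)
  fit <- fit_learner(x, y, learner_spec("enet",
                                        expand.grid(alpha = 0.5,
                                                    lambda = 0.01)),
                     seed = 1)
  expect_lt(fit$report$rmse[1], 1e-8)
})

test_that("failing grid points are scored Inf and skipped, never fatal", {
  set.seed(12)
  x <- matrix(runif(400), 40, 10, dimnames = list(NULL, paste0("f", 1:10)))
  y <- rnorm(40)
  # negative size makes nnet error on that grid point only
  spec <- learner_spec("nnet", data.frame(size = c(-1, 2), decay = 0.1,
                                          maxit = 30))
  fit <- fit_learner(x, y, spec, seed = 1)
  expect_equal(fit$params$size, 2)
  expect_true(any(is.infinite(fit$cv$cv_rmse)))
  expect_match(paste(fit$log, collapse = " "), "failed")
})

test_that("permutation importance is near zero for independent features", {
  set.seed(13)
  n <- 150
  x <- cbind(sig = runif(n), nul = runif(n),
             matrix(runif(n * 8), n, 8,
                    dimnames = list(NULL, paste0("f", 1:8))))
  y <- 3 * x[, "sig"] + rnorm(n, 0, 0.5)
  fit <- fit_learner(x, y, learner_spec("enet",
                                        expand.grid(alpha = 0.5,
                                                    lambda = 0.05)),
                     seed = 1)
  imp <- permutation_importance(fit, x, y, n_perm = 300, seed = 2)
  nul_row <- imp[imp$feature == "nul", ]
  z <- nul_row$importance / max(nul_row$sd, 1e-12)
  expect_lt(abs(z), 3)
  expect_gt(imp$importance[imp$feature == "sig"],
            10 * abs(nul_row$importance))
  expect_error(permutation_importance(fit, x, y, n_perm = 0), "n_perm")
})

test_that("the planted feature ranks first for every learner family", {
  specs <- list(
    enet = learner_spec("enet", expand.grid(alpha = 0.5, lambda = 0.01)),
    rf = learner_spec("rf", expand.grid(num.trees = 60, mtry_frac = 0.33,
                                        min.node.size = 5, max.depth = 6)),
    gbt = learner_spec("gbt", expand.grid(nrounds = 60, eta = 0.2,
                                          max_depth = 2)),
    nnet = learner_spec("nnet", expand.grid(size = 3, decay = 0.05,
                                            maxit = 150)))
  hits <- sapply(1:10, function(s) {
    set.seed(s)
    n <- 200
    x <- matrix(runif(n * 10), n, 10,
                dimnames = list(NULL, paste0("f", 1:10)))
    y <- 2 * x[, 4] + rnorm(n, 0, 0.3)
    vapply(specs, function(sp) {
      fit <- fit_learner(x, y, sp, seed = s)
      imp <- permutation_importance(fit, x, y, n_perm = 100, seed = s + 1)
      imp$feature[which.max(imp$importance)] == "f4"
    }, logical(1))
  })
  # every family finds the generative feature in (almost) every seed
  expect_true(all(rowMeans(hits) >= 0.9))
})

test_that("duplicating a feature splits, never increases, its importance", {
  set.seed(14)
  n <- 300
  x <- matrix(runif(n * 6), n, 6, dimnames = list(NULL, paste0("f", 1:6)))
  y <- 2 * x[, 1] + rnorm(n, 0, 0.2)
  spec <- learner_spec("enet", expand.grid(alpha = 0, lambda = 0.01))
  fit1 <- fit_learner(x, y, spec, seed = 1)
  imp1 <- permutation_importance(fit1, x, y, n_perm = 200, seed = 2)
  x2 <- cbind(x, f1dup = x[, 1])
  fit2 <- fit_learner(x2, y, spec, seed = 1)
  imp2 <- permutation_importance(fit2, x2, y, n_perm = 200, seed = 2)
  single <- imp1$importance[imp1$feature == "f1"]
  expect_lt(imp2$importance[imp2$feature == "f1"], single)
  expect_lt(imp2$importance[imp2$feature == "f1dup"], single)
})

test_that("top-decile counts follow the ceiling rule with stable ties", {
  imp <- data.frame(feature = sprintf("f%03d", 1:40),
                    importance = seq(40, 1), sd = 1, n_perm = 10)
  expect_length(top_decile(imp), 4)
  imp553 <- data.frame(feature = sprintf("f%03d", 1:553),
                       importance = rev(seq_len(553)), sd = 1, n_perm = 10)
  expect_length(top_decile(imp553), 56)
  # all-equal importances: first by name, flagged
  impeq <- data.frame(feature = sprintf("f%02d", 1:20),
                      importance = 1, sd = 0, n_perm = 10)
  td <- top_decile(impeq)
  expect_equal(as.vector(td), c("f01", "f02"))
  expect_true(attr(td, "tie_degenerate"))
  expect_error(top_decile(imp[1:5, ]), "at least 10")
})

test_that("consensus keeps features supported by >= 2 learners", {
  sets <- list(m1 = c("A", "B"), m2 = c("A", "C"), m3 = "D", m4 = "E")
  cs <- consensus_features(sets)
  expect_equal(cs$feature, "A")
  expect_equal(cs$support, 2)
  same <- list(m1 = c("A", "B"), m2 = c("A", "B"),
               m3 = c("A", "B"), m4 = c("A", "B"))
  cs2 <- consensus_features(same)
  expect_setequal(cs2$feature, c("A", "B"))
  expect_equal(cs2$support, c(4, 4))
  disj <- list(m1 = "A", m2 = "B", m3 = "C", m4 = "D")
  expect_equal(nrow(consensus_features(disj)), 0)
  expect_error(consensus_features(list(m1 = "A")), "at least 2")
})

test_that("cross-timepoint intersection behaves as set intersection", {
  c1 <- data.frame(feature = c("A", "B", "C"), support = c(4, 3, 2))
  c2 <- data.frame(feature = c("B", "C", "D"), support = c(2, 4, 2))
  both <- cross_timepoint_intersection(c1, c2)
  expect_setequal(both$feature, c("B", "C"))
  expect_equal(both$support_v1[both$feature == "B"], 3)
  expect_equal(both$support_v2[both$feature == "B"], 2)
  expect_equal(nrow(cross_timepoint_intersection(
    c1, data.frame(feature = "Z", support = 2))), 0)
  self <- cross_timepoint_intersection(c1, c1)
  expect_equal(self$feature, c1$feature)
})

test_that("selection is reproducible under a fixed seed", {
  sim <- small_sim()
  fm <- build_feature_matrix(sim$dataset, "month1")
  arm <- sim$dataset$data$arm[match(fm$subject_id,
                                    sim$dataset$data$subject_id)]
  specs <- list(
    enet = learner_spec("enet", expand.grid(alpha = 0.5, lambda = 0.01)),
    rf = learner_spec("rf", expand.grid(num.trees = 30, mtry_frac = 0.33,
                                        min.node.size = 5, max.depth = 5)))
  s1 <- select_features(fm, arm, specs = specs, n_perm = 30, seed = 9)
  s2 <- select_features(fm, arm, specs = specs, n_perm = 30, seed = 9)
  expect_identical(s1$importance, s2$importance)
  expect_identical(s1$consensus, s2$consensus)
})
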