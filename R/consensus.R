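#' Stratified train/test split
#'
#' Splits subjects into training and test partitions, stratified by
#' treatment arm and by quartile of the target value so the partitions are
#' balanced on both. Strata too small to split (< 2 members) are merged
#' into their arm-level stratum.
#'
#' @param arm 0/1 treatment indicator per subject.
#' @param strat_values optional numeric target (e.g. outcome fold-change)
#'   whose quartiles refine the strata.
#' @param fraction training fraction (default 0.8).
#' @param seed RNG seed.
#' @return list with integer index vectors `train` and `test` (disjoint,
#'   exhaustive).
#' @export
split_train_test <- function(arm, strat_values = NULL, fraction = 0.8,
                             seed = 1L) {
  n <- length(arm)
  if (n < 10) stop("need at least 10 subjects to split")
  strata <- as.character(arm)
  if (!is.null(strat_values)) {
    q <- assign_quartiles(strat_values)$group
    strata <- paste(arm, q, sep = ":")
    small <- names(which(table(strata) < 2))
    if (length(small)) strata[strata %in% small] <- as.character(arm)[strata %in% small]
  }
  with_seed(seed, {
    test <- integer(0)
    for (s in unique(strata)) {
      idx <- which(strata == s)
      n_test <- round((1 - fraction) * length(idx))
      if (n_test > 0) test <- c(test, sample(idx, n_test))
    }
    test <- sort(test)
    list(train = setdiff(seq_len(n), test), test = test)
  })
}

#' Specify a regression learner
#'
#' Four families are available: `"enet"` (elastic-net penalized linear
#' regression), `"rf"` (random forest), `"gbt"` (gradient-boosted trees)
#' and `"nnet"` (a small feed-forward network with one hidden layer).
#' Hyperparameters are optimized by k-fold cross-validated grid search on
#' mean RMSE.
#'
#' @param family learner family.
#' @param grid data.frame of hyperparameter combinations; `NULL` uses a
#'   small default grid per family.
#' @param folds number of CV folds (default 3).
#' @return object of class `learner_spec`.
#' @export
learner_spec <- function(family = c("enet", "rf", "gbt", "nnet"),
                         grid = NULL, folds = 3) {
  family <- match.arg(family)
  if (is.null(grid)) {
    grid <- switch(family,
      enet = expand.grid(alpha = c(0.1, 0.5, 0.9),
                         lambda = c(0.001, 0.01, 0.1)),
      rf   = expand.grid(num.trees = 200, mtry_frac = c(0.1, 0.33),
                         min.node.size = 5, max.depth = 0),
      gbt  = expand.grid(nrounds = c(100, 300), eta = c(0.05, 0.1),
                         max_depth = c(2, 3)),
      nnet = expand.grid(size = c(4, 8), decay = c(0.01, 0.1), maxit = 300)
    )
  }
  stopifnot(nrow(grid) >= 1, folds >= 2)
  structure(list(family = family, grid = grid, folds = folds),
            class = "learner_spec")
}

fit_one <- function(family, x, y, params) {
  if (stats::var(y) == 0) {
    # degenerate target: intercept-only prediction, zero training RMSE
    return(structure(list(value = y[1]), class = "constant_fit"))
  }
  switch(family,
    enet = glmnet::glmnet(x, y, alpha = params$alpha,
                          lambda = params$lambda),
    rf = {
      mtry <- max(1, floor((params$mtry_frac %||% 0.33) * ncol(x)))
      ranger::ranger(x = x, y = y, num.trees = params$num.trees,
                     mtry = mtry, min.node.size = params$min.node.size,
                     max.depth = params$max.depth, num.threads = 1,
                     seed = sample.int(.Machine$integer.max, 1))
    },
    gbt = xgboost::xgb.train(
      params = list(max_depth = params$max_depth, eta = params$eta,
                    objective = "reg:squarederror", nthread = 1),
      data = xgboost::xgb.DMatrix(x, label = y, nthread = 1),
      nrounds = params$nrounds, verbose = 0),
    nnet = nnet::nnet(x = x, y = y, size = params$size,
                      decay = params$decay, maxit = params$maxit,
                      linout = TRUE, trace = FALSE, MaxNWts = 100000)
  )
}

predict_one <- function(family, model, x) {
  if (inherits(model, "constant_fit")) return(rep(model$value, nrow(x)))
  switch(family,
    enet = drop(glmnet::predict.glmnet(model, newx = x,
                                       s = model$lambda[1])),
    rf = stats::predict(model, data = x, num.threads = 1)$predictions,
    gbt = stats::predict(model, xgboost::xgb.DMatrix(x, nthread = 1)),
    nnet = drop(stats::predict(model, x))
  )
}

#' Fit a learner with cross-validated grid search
#'
#' For each grid point the mean RMSE over `spec$folds` CV folds of the
#' training data is computed; the best point is refit on the full training
#' partition. A grid point whose fit fails is scored +Inf and logged,
#' never fatal.
#'
#' @param x numeric feature matrix (no missing cells), training rows.
#' @param y numeric target (outcome fold-change).
#' @param spec a [learner_spec()].
#' @param seed RNG seed (fold assignment and learner initialization).
#' @param x_test,y_test optional held-out partition for the fit report.
#' @return object of class `picp_learner` with elements `fit`, `family`,
#'   `params` (chosen grid row), `cv` (grid with mean CV RMSE), `report`
#'   (train/test RMSE and R2) and `log`.
#' @export
fit_learner <- function(x, y, spec, seed = 1L, x_test = NULL, y_test = NULL) {
  stopifnot(inherits(spec, "learner_spec"), !anyNA(x), !anyNA(y))
  with_seed(seed, {
    n <- nrow(x)
    folds <- sample(rep(seq_len(spec$folds), length.out = n))
    log <- character()
    cv_rmse <- rep(NA_real_, nrow(spec$grid))
    if (nrow(spec$grid) == 1) {
      # nothing to select: skip the CV loop
      cv_rmse[1] <- 0
    } else for (g in seq_len(nrow(spec$grid))) {
      params <- as.list(spec$grid[g, , drop = FALSE])
      fold_rmse <- rep(Inf, spec$folds)
      for (f in seq_len(spec$folds)) {
        hold <- folds == f
        res <- tryCatch({
          m <- fit_one(spec$family, x[!hold, , drop = FALSE], y[!hold], params)
          rmse(y[hold], predict_one(spec$family, m, x[hold, , drop = FALSE]))
        }, error = function(e) {
          log <<- log_line(log, "cv", sprintf(
            "grid point %d fold %d failed: %s", g, f, conditionMessage(e)))
          Inf
        })
        fold_rmse[f] <- res
      }
      cv_rmse[g] <- mean(fold_rmse)
    }
    best <- which.min(cv_rmse)
    params <- as.list(spec$grid[best, , drop = FALSE])
    fit <- fit_one(spec$family, x, y, params)
    pred_tr <- predict_one(spec$family, fit, x)
    report <- data.frame(
      partition = "train", rmse = rmse(y, pred_tr),
      r2 = r_squared(y, pred_tr), stringsAsFactors = FALSE)
    if (!is.null(x_test)) {
      pred_te <- predict_one(spec$family, fit, x_test)
      report <- rbind(report, data.frame(
        partition = "test", rmse = rmse(y_test, pred_te),
        r2 = r_squared(y_test, pred_te), stringsAsFactors = FALSE))
    }
    structure(list(family = spec$family, fit = fit, params = params,
                   cv = cbind(spec$grid, cv_rmse = cv_rmse),
                   report = report, feature_names = colnames(x), log = log),
              class = "picp_learner")
  })
}

#' @export
predict.picp_learner <- function(object, newdata, ...) {
  predict_one(object$family, object$fit, newdata)
}

# Weights of a fitted elastic-net model as (intercept, beta).
enet_weights <- function(fit) {
  cf <- as.matrix(glmnet::coef.glmnet(fit, s = fit$lambda[1]))
  list(a0 = cf[1, 1], beta = cf[-1, 1])
}

# Weight matrices of a single-hidden-layer nnet (logistic hidden units,
# linear output): W1 is (p+1) x h with the bias in row 1, W2 is h+1.
nnet_weights <- function(fit) {
  nn <- fit$n
  p <- nn[1]; h <- nn[2]
  w <- fit$wts
  W1 <- matrix(w[seq_len((p + 1) * h)], nrow = p + 1)
  W2 <- w[(p + 1) * h + seq_len(h + 1)]
  list(W1 = W1, W2 = W2)
}

#' Permutation variable importance
#'
#' Importance of a feature is the mean increase in prediction RMSE when
#' that feature's column is shuffled (target and all other columns held
#' fixed), averaged over `n_perm` independent shuffles. Negative values
#' are possible for uninformative features.
#'
#' The definition is evaluated exactly for every family; the
#' implementation differs only in how predictions for the shuffled copies
#' are obtained. For the linear and network learners the forward pass is
#' recomputed algebraically from the fitted weights (only the shuffled
#' column's contribution changes), verified against the model's own
#' `predict` on the unshuffled data; tree ensembles reuse a single
#' prediction buffer whose target column is swapped and restored per
#' feature.
#'
#' @param model a `picp_learner`.
#' @param x evaluation feature matrix (rows of the chosen partition).
#' @param y evaluation target.
#' @param n_perm number of permutations (>= 1).
#' @param seed RNG seed.
#' @param features subset of features to score (default all).
#' @param chunk_elements upper bound on elements in the prediction
#'   buffer, trading memory for call overhead.
#' @return data.frame with `feature`, `importance` (mean RMSE increase),
#'   `sd` (SD over permutations) and `n_perm`; attribute `base_loss`.
#' @export
permutation_importance <- function(model, x, y, n_perm = 1000, seed = 1L,
                                   features = colnames(x),
                                   chunk_elements = 8e6) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  n <- nrow(x)
  base_pred <- predict(model, x)
  base_loss <- rmse(y, base_pred)

  # closed-path forward recomputation where the family permits it;
  # each path is verified against the model's own predictions on the
  # unshuffled data and abandoned on any mismatch
  fast <- NULL
  if (inherits(model$fit, "constant_fit")) {
    err <- rep(model$fit$value, n) - y
    fast <- function(f, perm) rep(sqrt(mean(err^2)), ncol(perm))
  } else if (model$family == "enet") {
    w <- enet_weights(model$fit)
    check <- drop(x %*% w$beta) + w$a0
    if (isTRUE(all.equal(unname(check), unname(base_pred),
                         tolerance = 1e-8))) {
      err <- unname(base_pred) - y
      fast <- function(f, perm) {
        delta <- matrix(x[, f][perm], n, ncol(perm)) - x[, f]
        sqrt(colMeans((err + w$beta[f] * delta)^2))
      }
    }
  } else if (model$family == "nnet") {
    w <- nnet_weights(model$fit)
    Z <- cbind(1, x) %*% w$W1             # n x h pre-activations
    check <- drop(stats::plogis(Z) %*% w$W2[-1]) + w$W2[1]
    if (isTRUE(all.equal(unname(check), unname(base_pred),
                         tolerance = 1e-8))) {
      fast <- function(f, perm) {
        m <- ncol(perm)
        delta <- matrix(x[, f][perm], n, m) - x[, f]
        pred <- matrix(w$W2[1], n, m)
        for (j in seq_len(ncol(Z))) {
          pred <- pred + w$W2[j + 1] *
            stats::plogis(Z[, j] + delta * w$W1[f + 1, j])
        }
        sqrt(colMeans((pred - y)^2))
      }
    }
  } else if (model$family %in% c("rf", "gbt")) {
    fast <- forest_fast_path(model, x, y, base_pred, base_loss)
  }

  m_chunk <- max(1L, min(n_perm,
                         floor(chunk_elements / (n * ncol(x)))))
  f_idx <- match(features, colnames(x))
  with_seed(seed, {
    if (is.null(fast)) {
      # buffer of replicated rows; per feature swap one column in place
      buf <- x[rep(seq_len(n), m_chunk), , drop = FALSE]
    }
    res <- lapply(seq_along(features), function(fi) {
      f <- f_idx[fi]
      col_f <- x[, f]
      losses <- numeric(n_perm)
      done <- 0L
      while (done < n_perm) {
        m <- min(m_chunk, n_perm - done)
        perm <- vapply(seq_len(m), function(i) sample.int(n),
                       integer(n))
        if (!is.null(fast)) {
          losses[done + seq_len(m)] <- fast(f, perm)
        } else if (m == m_chunk) {
          buf[, f] <- col_f[as.vector(perm)]
          pred <- predict(model, buf)
          sq <- (pred - rep(y, m))^2
          losses[done + seq_len(m)] <-
            sqrt(colMeans(matrix(sq, nrow = n, ncol = m)))
          buf[, f] <- rep(col_f, m)
        } else {
          rows <- seq_len(n * m)
          tail_buf <- buf[rows, , drop = FALSE]
          tail_buf[, f] <- col_f[as.vector(perm)]
          pred <- predict(model, tail_buf)
          sq <- (pred - rep(y, m))^2
          losses[done + seq_len(m)] <-
            sqrt(colMeans(matrix(sq, nrow = n, ncol = m)))
        }
        done <- done + m
      }
      data.frame(feature = features[fi],
                 importance = mean(losses) - base_loss,
                 sd = stats::sd(losses), n_perm = n_perm,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, res)
    attr(out, "base_loss") <- base_loss
    out
  })
}

#' Top-decile feature set of an importance table
#'
#' Returns the `ceiling(fraction * p)` features with the largest
#' importance; ties are broken by importance then feature name.
#'
#' @param importance data.frame from [permutation_importance()].
#' @param fraction fraction of features to keep (default 0.10).
#' @return character vector of features; attribute `tie_degenerate` is
#'   TRUE when all importances are equal.
#' @export
top_decile <- function(importance, fraction = 0.10) {
  p <- nrow(importance)
  if (p < 10) stop("need at least 10 features")
  k <- ceiling(fraction * p)
  ord <- order(-importance$importance, importance$feature)
  out <- importance$feature[ord][seq_len(k)]
  attr(out, "tie_degenerate") <-
    length(unique(importance$importance)) == 1
  out
}

#' Consensus features across learners
#'
#' Features appearing in at least `min_models` of the per-learner sets are
#' considered consistently predictive.
#'
#' @param sets named list of character vectors (one per learner).
#' @param min_models minimum number of supporting learners (default 2).
#' @return data.frame with `feature`, `support` (number of learners) and
#'   `models` (comma-separated learner names), sorted by decreasing
#'   support.
#' @export
consensus_features <- function(sets, min_models = 2) {
  if (length(sets) < 2) stop("need at least 2 learner sets")
  all_feats <- sort(unique(unlist(sets)))
  hits <- vapply(all_feats, function(f)
    sum(vapply(sets, function(s) f %in% s, logical(1))), integer(1))
  models <- vapply(all_feats, function(f)
    paste(names(sets)[vapply(sets, function(s) f %in% s, logical(1))],
          collapse = ","), character(1))
  keep <- hits >= min_models
  out <- data.frame(feature = all_feats[keep], support = hits[keep],
                    models = models[keep], stringsAsFactors = FALSE,
                    row.names = NULL)
  out[order(-out$support, out$feature), , drop = FALSE]
}

#' Features in the consensus sets of both timepoints
#'
#' @param consensus_v1,consensus_v2 data.frames from
#'   [consensus_features()] computed at the two follow-up visits.
#' @return data.frame with `feature` and per-visit support columns.
#' @export
cross_timepoint_intersection <- function(consensus_v1, consensus_v2) {
  common <- intersect(consensus_v1$feature, consensus_v2$feature)
  data.frame(
    feature = common,
    support_v1 = consensus_v1$support[match(common, consensus_v1$feature)],
    support_v2 = consensus_v2$support[match(common, consensus_v2$feature)],
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Run the consensus selection stage at one visit
#'
#' Convenience wrapper: stratified split, four learners with CV grid
#' search, permutation importance, top-decile sets and the >= 2-model
#' consensus.
#'
#' @param fm a `feature_matrix` from [build_feature_matrix()].
#' @param arm treatment arm aligned with `fm$subject_id`.
#' @param specs named list of [learner_spec()]s (default all four
#'   families with default grids).
#' @param n_perm permutations for importance (default 1000).
#' @param fraction top fraction per learner (default 0.10).
#' @param min_models consensus threshold (default 2).
#' @param importance_on partition on which importance is evaluated.
#' @param seed RNG seed.
#' @return list with `split`, `learners`, `importance` (per learner),
#'   `top` (per-learner top-decile sets) and `consensus`.
#' @export
select_features <- function(fm, arm,
                            specs = list(enet = learner_spec("enet"),
                                         rf = learner_spec("rf"),
                                         gbt = learner_spec("gbt"),
                                         nnet = learner_spec("nnet")),
                            n_perm = 1000, fraction = 0.10, min_models = 2,
                            importance_on = c("train", "test"),
                            seed = 1L) {
  importance_on <- match.arg(importance_on)
  split <- split_train_test(arm, fm$y, seed = seed)
  xtr <- fm$x[split$train, , drop = FALSE]; ytr <- fm$y[split$train]
  xte <- fm$x[split$test, , drop = FALSE]; yte <- fm$y[split$test]
  xev <- if (importance_on == "train") xtr else xte
  yev <- if (importance_on == "train") ytr else yte
  learners <- list(); importance <- list(); top <- list()
  for (nm in names(specs)) {
    learners[[nm]] <- fit_learner(xtr, ytr, specs[[nm]],
                                  seed = seed + match(nm, names(specs)),
                                  x_test = xte, y_test = yte)
    importance[[nm]] <- permutation_importance(
      learners[[nm]], xev, yev, n_perm = n_perm,
      seed = seed + 100 + match(nm, names(specs)))
    top[[nm]] <- top_decile(importance[[nm]], fraction)
  }
  list(split = split, learners = learners, importance = importance,
       top = top, consensus = consensus_features(top, min_models))
}
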