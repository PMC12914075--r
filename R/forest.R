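# Exact sparse re-evaluation of tree ensembles under single-feature
# shuffling. Shuffling a feature can only change the predictions of trees
# that split on it, so permutation importance needs per-tree base
# predictions plus re-traversal of the (few) trees using the shuffled
# feature. Parsed forests are verified against the model's own predict
# on the unshuffled data before use; on any mismatch the caller falls
# back to full batched prediction.

# Common tree representation: parallel vectors over nodes, 1-based;
# var = 0 marks a leaf. `le`: TRUE when the split rule is x <= val
# (ranger), FALSE for x < val (xgboost).
new_tree <- function() {
  e <- new.env(parent = emptyenv())
  e$var <- integer(0); e$val <- numeric(0)
  e$left <- integer(0); e$right <- integer(0); e$pred <- numeric(0)
  e
}

tree_as_list <- function(e) {
  list(var = e$var, val = e$val, left = e$left, right = e$right,
       pred = e$pred)
}

parse_ranger_forest <- function(fit, feature_names) {
  trees <- lapply(seq_len(fit$num.trees), function(t) {
    ti <- ranger::treeInfo(fit, t)
    leaf <- ti$terminal
    list(var = ifelse(leaf, 0L, ti$splitvarID + 1L),
         val = ifelse(leaf, 0, ti$splitval),
         left = ifelse(leaf, 0L, ti$leftChild + 1L),
         right = ifelse(leaf, 0L, ti$rightChild + 1L),
         pred = ifelse(leaf, ti$prediction, 0))
  })
  list(trees = trees, combine = "mean", le = TRUE, offset = 0)
}

parse_xgb_forest <- function(fit, feature_names) {
  dump <- xgboost::xgb.dump(fit, dump_format = "json")
  js <- jsonlite::fromJSON(dump, simplifyVector = FALSE)
  trees <- lapply(js, function(root) {
    e <- new_tree()
    add <- function(nd) {
      i <- length(e$var) + 1L
      # reserve slot i before recursing
      e$var[i] <- 0L; e$val[i] <- 0; e$left[i] <- 0L; e$right[i] <- 0L
      e$pred[i] <- 0
      if (!is.null(nd$leaf)) {
        e$pred[i] <- nd$leaf
      } else {
        fi <- match(nd$split, feature_names)
        if (is.na(fi)) stop("unknown split feature: ", nd$split)
        e$var[i] <- fi
        e$val[i] <- nd$split_condition
        ids <- vapply(nd$children, function(ch) ch$nodeid, numeric(1))
        yes_child <- nd$children[[match(nd$yes, ids)]]
        no_child <- nd$children[[match(nd$no, ids)]]
        e$left[i] <- add(yes_child)
        e$right[i] <- add(no_child)
      }
      i
    }
    add(root)
    tr <- tree_as_list(e)
    # dumped split conditions are decimal renderings of float32 values;
    # re-round so tie comparisons match the model's single precision
    tr$val <- round_f32(tr$val)
    tr
  })
  list(trees = trees, combine = "sum", le = FALSE, offset = 0)
}

# Predict one tree on virtual rows: row r carries the features of
# x[base_row[r], ] except feature f, replaced by fval[r].
tree_predict_sub <- function(tr, x, base_row, f = 0L, fval = NULL,
                             le = TRUE) {
  pred <- numeric(length(base_row))
  rec <- function(nd, rows) {
    if (!length(rows)) return(invisible())
    v <- tr$var[nd]
    if (v == 0L) {
      pred[rows] <<- tr$pred[nd]
      return(invisible())
    }
    xv <- if (v == f) fval[rows] else x[base_row[rows], v]
    gl <- if (le) xv <= tr$val[nd] else xv < tr$val[nd]
    rec(tr$left[nd], rows[gl])
    rec(tr$right[nd], rows[!gl])
    invisible()
  }
  rec(1L, seq_along(base_row))
  pred
}

# Round doubles to the nearest float32 value (still stored as double).
# xgboost compares features in single precision; traversing its trees
# with full-precision values mis-routes rows that straddle a float32
# threshold, so inputs are rounded the same way before comparison.
round_f32 <- function(v) {
  dm <- dim(v)
  out <- readBin(writeBin(as.vector(v), raw(), size = 4L), "numeric",
                 n = length(v), size = 4L)
  dim(out) <- dm
  dimnames(out) <- dimnames(v)
  out
}

# Build the fast importance closure for a tree-ensemble learner, or NULL
# if the parsed forest does not reproduce the model's own predictions.
forest_fast_path <- function(model, x, y, base_pred, base_loss) {
  forest <- tryCatch(
    switch(model$family,
           rf = parse_ranger_forest(model$fit, colnames(x)),
           gbt = parse_xgb_forest(model$fit, colnames(x))),
    error = function(e) NULL)
  if (is.null(forest)) return(NULL)
  if (model$family == "gbt") x <- round_f32(x)
  n <- nrow(x)
  rows0 <- seq_len(n)
  B <- vapply(forest$trees, function(tr)
    tree_predict_sub(tr, x, rows0, le = forest$le), numeric(n))
  total <- rowSums(B)
  if (forest$combine == "mean") {
    check <- total / length(forest$trees)
  } else {
    # recover the constant margin offset (xgboost base_score)
    off <- unname(base_pred) - total
    if (diff(range(off)) > 1e-4) return(NULL)
    forest$offset <- mean(off)
    check <- total + forest$offset
  }
  if (!isTRUE(all.equal(unname(check), unname(base_pred),
                        tolerance = 1e-5))) {
    return(NULL)
  }
  uses <- lapply(seq_len(ncol(x)), function(f)
    which(vapply(forest$trees, function(tr) any(tr$var == f), logical(1))))
  function(f, perm) {
    m <- ncol(perm)
    tf <- uses[[f]]
    if (!length(tf)) return(rep(base_loss, m))
    base_row <- rep.int(rows0, m)
    fval <- x[, f][as.vector(perm)]
    acc <- rep.int(total - rowSums(B[, tf, drop = FALSE]), m)
    for (t in tf) {
      acc <- acc + tree_predict_sub(forest$trees[[t]], x, base_row,
                                    f = f, fval = fval, le = forest$le)
    }
    pred <- if (forest$combine == "mean") acc / length(forest$trees) else
      acc + forest$offset
    sq <- (pred - rep.int(y, m))^2
    sqrt(colMeans(matrix(sq, nrow = length(y), ncol = m)))
  }
}
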