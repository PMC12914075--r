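# Internal helpers shared across modules.

# Run `expr` under a private RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so package functions never clobber user randomness.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  expr
}

rmse <- function(obs, pred) sqrt(mean((obs - pred)^2))

r_squared <- function(obs, pred) {
  ss_res <- sum((obs - pred)^2)
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot == 0) return(NA_real_)
  1 - ss_res / ss_tot
}

# Fast OLS on a prebuilt model matrix; returns named coefficients.
# Rank-deficient fits keep NA for aliased columns (as lm does).
ols_coef <- function(X, y) {
  fit <- .lm.fit(X, y)
  cf <- rep(NA_real_, ncol(X))
  cf[fit$pivot[seq_len(fit$rank)]] <- fit$coefficients[seq_len(fit$rank)]
  names(cf) <- colnames(X)
  cf
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Simple structured message log used by loaders and pipeline stages.
log_line <- function(log, stage, msg) {
  c(log, sprintf("[%s] %s", stage, msg))
}
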