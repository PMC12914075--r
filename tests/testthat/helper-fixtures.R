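# Shared fixtures built in code; cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Small planted-mediator configuration used across modules.
small_cfg <- function(seed, n = 300, n_proteins = 12,
                      a = c(0.5, -0.4, 0.3), b = c(0.4, -0.3, 0.3),
                      c_direct = 0.1, ...) {
  sim_config(n_subjects = n, n_proteins = n_proteins, a = a, b = b,
             c_direct = c_direct, seed = seed, ...)
}

small_sim <- function(seed = 11, ...) {
  cached(paste0("sim", seed), simulate_trial(small_cfg(seed, ...)))
}

# A hand-written 3-subject wide table on disk.
tiny_table_path <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "tiny.tsv")
  header <- c("subject_id", "arm", "age", "sex", "smoker", "diabetes",
              "cad", "qrs",
              "picp__baseline", "picp__month1", "picp__month9",
              "egfr__baseline", "egfr__month1", "egfr__month9",
              "P001__baseline", "P001__month1", "P001__month9")
  rows <- list(
    c("A", "0", "70", "1", "0", "0", "1", "92", "90", "85", "82",
      "75", "74", "73", "5", "5.5", "6"),
    c("B", "1", "66", "0", "0", "1", "0", "101", "80", "70", "68",
      "80", "81", "79", "4.25", "4", "3.75"),
    c("C", "1", "75", "1", "1", "0", "1", "88", "100", "101", "99",
      "60", "62", "61", "6", "6", "6"))
  writeLines(c(paste(header, collapse = "\t"),
               vapply(rows, paste, "", collapse = "\t")), path)
  path
}

tiny_schema <- function() {
  trial_schema(proteins = "P001",
               clinical_dynamic = "egfr", echo = character())
}

# Mediation inputs extracted from a simulated trial on the log outcome
# scale (where the generator's structural model is exactly linear).
mediation_inputs <- function(sim, visit = "month1") {
  d <- sim$dataset$data
  meds <- sim$truth$mediators
  out_fc <- log(d[[paste0("picp__", visit)]] / d$picp__baseline)
  fc <- as.matrix(d[paste0(meds, "__", visit)]) -
    as.matrix(d[paste0(meds, "__baseline")])
  colnames(fc) <- meds
  covs <- data.frame(out_bl = log(d$picp__baseline))
  for (p in meds) covs[[paste0(p, "_bl")]] <- d[[paste0(p, "__baseline")]]
  list(outcome = out_fc, fc = fc, arm = d$arm, covariates = covs)
}
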