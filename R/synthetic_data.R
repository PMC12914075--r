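#' Configuration for the synthetic trial generator
#'
#' The generator emulates a two-arm randomized trial in which treatment
#' affects a positive outcome biomarker (serum PICP-like, ug/L) partly
#' through a configurable set of mediator proteins on a log2 NPX panel,
#' with three visits and subject-specific random slopes that couple
#' designated protein trajectories to echocardiographic trajectories.
#'
#' The structural model is linear on the analysis scale: the log outcome
#' fold-change at a follow-up visit is
#' `c * arm + sum_j b_j * (mediator log2 change) + covariate terms + noise`,
#' and each mediator's log2 change is `a_j * arm + covariate terms + noise`.
#' Under this no-interaction linear model the true causal decomposition is
#' closed form: ACME = `sum(a*b)`, ADE = `c`, TE = ACME + ADE, mediated
#' proportion = ACME/TE.
#'
#' Defaults mirror the trial setting the pipeline was designed around:
#' 488 subjects, 276 proteins over three visits (0, 1, 9 months), eight
#' mediator proteins whose products `a_j*b_j` give a true mediated
#' proportion of about 0.70, and persistent treatment effects at the late
#' visit.
#'
#' @param n_subjects number of subjects (1:1 randomization).
#' @param n_proteins panel size; mediators are the first `length(a)`
#'   proteins.
#' @param a treatment-to-mediator coefficients (log2 NPX units).
#' @param b mediator-to-outcome coefficients (log outcome per log2 NPX).
#' @param c_direct direct treatment effect on the log outcome fold-change.
#' @param visit2_decay multiplier on `a` (and `c_direct`) at the second
#'   follow-up; 1 = persistent effects.
#' @param cov_mediator,cov_outcome named coefficients (age, sex, egfr) for
#'   the covariate terms of the mediator and outcome equations; covariates
#'   are entered centered and scaled.
#' @param sd_npx_baseline between-subject SD of baseline NPX.
#' @param sd_npx_change SD of visit-level mediator/protein change noise.
#' @param sd_outcome SD of the log outcome fold-change noise.
#' @param sd_slope SD of subject random slopes (NPX/month) for the
#'   slope-designated proteins.
#' @param slope_proteins indices of proteins given subject random slopes.
#' @param kappa list: per echo variable, coefficients linking its subject
#'   slope to the designated protein slopes.
#' @param sd_echo_slope,sd_echo_resid slope and residual SDs of echo
#'   trajectories.
#' @param visits named numeric vector of visit times (months).
#' @param outcome_median median baseline outcome concentration (ug/L).
#' @param seed mandatory RNG seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 488,
                       n_proteins = 276,
                       a = c(-0.35, -0.30, 0.30, 0.25, -0.25, 0.20, 0.30, -0.20),
                       b = c(0.10, 0.08, -0.08, -0.07, 0.06, -0.05, -0.06, 0.05),
                       c_direct = -0.066,
                       visit2_decay = 1,
                       cov_mediator = c(age = 0.005, sex = 0.08, egfr = -0.04),
                       cov_outcome = c(age = 0.002, sex = 0.02, egfr = -0.02),
                       sd_npx_baseline = 1,
                       sd_npx_change = 0.35,
                       sd_outcome = 0.12,
                       sd_slope = 0.04,
                       slope_proteins = c(1, 2),
                       kappa = list(lavi = c(60, -40), ea_ratio = c(2, -1.5)),
                       sd_echo_slope = list(lavi = 0.15, ea_ratio = 0.005),
                       sd_echo_resid = list(lavi = 2.5, ea_ratio = 0.08),
                       visits = c(baseline = 0, month1 = 1, month9 = 9),
                       outcome_median = 80,
                       seed = 1L) {
  stopifnot(length(a) == length(b), n_proteins >= length(a),
            sd_npx_baseline >= 0, sd_npx_change >= 0, sd_outcome >= 0,
            sd_slope >= 0, length(visits) == 3, !is.null(seed))
  if (any(diff(visits) <= 0)) stop("visit times must be strictly increasing")
  structure(
    list(n_subjects = n_subjects, n_proteins = n_proteins, a = a, b = b,
         c_direct = c_direct, visit2_decay = visit2_decay,
         cov_mediator = cov_mediator, cov_outcome = cov_outcome,
         sd_npx_baseline = sd_npx_baseline, sd_npx_change = sd_npx_change,
         sd_outcome = sd_outcome, sd_slope = sd_slope,
         slope_proteins = slope_proteins, kappa = kappa,
         sd_echo_slope = sd_echo_slope, sd_echo_resid = sd_echo_resid,
         visits = visits, outcome_median = outcome_median, seed = seed),
    class = "sim_config"
  )
}

#' Closed-form causal ground truth of a generator configuration
#'
#' Independent of any realized sample: ACME = `sum(a*b)`, ADE = `c`,
#' TE = ACME + ADE, mediated proportion = ACME/TE (reported as `NA` with
#' `proportion_defined = FALSE` when TE = 0). Quantities are on the log
#' outcome fold-change scale, where the structural model is exactly linear.
#'
#' @param config a [sim_config()].
#' @return list with `acme`, `ade`, `te`, `proportion`,
#'   `proportion_defined`, and the coefficient vectors.
#' @export
true_mediation <- function(config) {
  acme <- sum(config$a * config$b)
  ade <- config$c_direct
  te <- acme + ade
  defined <- te != 0
  list(acme = acme, ade = ade, te = te,
       proportion = if (defined) acme / te else NA_real_,
       proportion_defined = defined,
       a = config$a, b = config$b)
}

#' Simulate a trial dataset with known ground truth
#'
#' Generates arm assignment (exact 1:1), clinical covariates, baseline NPX
#' for every protein, mediator changes driven by treatment, a log-linear
#' outcome equation, and three-visit protein/echo trajectories built from
#' subject random intercepts and slopes. All randomness derives from
#' `config$seed`, so repeated calls are reproducible.
#'
#' @param config a [sim_config()].
#' @return list with `dataset` (a `trial_dataset`) and `truth`
#'   (ground-truth coefficients, closed-form effects, and the realized
#'   subject slopes of the designated proteins and echo variables; also
#'   the per-visit log outcome fold-changes on the exact analysis scale).
#' @export
simulate_trial <- function(config) {
  tm <- true_mediation(config)
  if (!tm$proportion_defined && tm$acme != 0) {
    stop("degenerate config: total effect is 0 while ACME is nonzero; ",
         "the mediated proportion is undefined")
  }
  with_seed(config$seed, {
    n <- config$n_subjects
    p <- config$n_proteins
    k <- length(config$a)
    vlab <- names(config$visits)
    tms <- unname(config$visits)
    prot <- sprintf("P%03d", seq_len(p))

    subject_id <- sprintf("S%04d", seq_len(n))
    arm <- sample(rep(c(0L, 1L), length.out = n))

    # clinical covariates; age/sex/egfr also drive mediators and outcome
    age <- round(stats::rnorm(n, 72, 6))
    sex <- stats::rbinom(n, 1, 0.75)
    smoker <- stats::rbinom(n, 1, 0.08)
    diabetes <- stats::rbinom(n, 1, 0.40)
    cad <- stats::rbinom(n, 1, 0.72)
    qrs <- round(stats::rnorm(n, 95, 12))
    egfr0 <- stats::rnorm(n, 74, 14)
    zage <- (age - 72) / 6
    zegfr <- (egfr0 - 74) / 14
    covm <- config$cov_mediator
    covo <- config$cov_outcome
    med_cov <- covm["age"] * zage + covm["sex"] * sex + covm["egfr"] * zegfr
    out_cov <- covo["age"] * zage + covo["sex"] * sex + covo["egfr"] * zegfr

    cols <- list(subject_id = subject_id, arm = arm, age = age,
                 sex = sex, smoker = smoker, diabetes = diabetes,
                 cad = cad, qrs = qrs)

    dyn_base <- list(bmi = stats::rnorm(n, 28.3, 3.5),
                     sbp = stats::rnorm(n, 140, 15),
                     dbp = stats::rnorm(n, 78, 8),
                     sodium = stats::rnorm(n, 139.5, 2.5),
                     potassium = stats::rnorm(n, 4.3, 0.35),
                     egfr = egfr0,
                     breathless = pmax(0, round(stats::rnorm(n, 5, 2))))
    for (v in names(dyn_base)) {
      cols[[paste0(v, "__", vlab[1])]] <- dyn_base[[v]]
      for (j in 2:3) {
        drift <- stats::rnorm(n, 0, 0.03 * abs(mean(dyn_base[[v]])) + 1e-9)
        cols[[paste0(v, "__", vlab[j])]] <- dyn_base[[v]] + drift
      }
    }

    # NPX panel: baseline + treatment-driven mediator changes + random
    # slopes on the designated proteins
    mu <- stats::runif(p, 2, 9)
    npx0 <- sweep(matrix(stats::rnorm(n * p, 0, config$sd_npx_baseline),
                         n, p), 2, mu, "+")
    slopes <- matrix(0, n, p)
    slopes[, config$slope_proteins] <-
      stats::rnorm(n * length(config$slope_proteins), 0, config$sd_slope)
    a_full <- numeric(p)
    a_full[seq_len(k)] <- config$a
    decay <- c(1, config$visit2_decay)

    delta <- vector("list", 2)  # realized log2 change per follow-up
    cov_mat <- outer(med_cov, as.numeric(a_full != 0))
    for (j in 1:2) {
      t_j <- tms[j + 1]
      delta[[j]] <- outer(arm, a_full * decay[j]) + cov_mat + slopes * t_j +
        matrix(stats::rnorm(n * p, 0, config$sd_npx_change), n, p)
    }
    for (ip in seq_len(p)) {
      cols[[paste0(prot[ip], "__", vlab[1])]] <- npx0[, ip]
      cols[[paste0(prot[ip], "__", vlab[2])]] <- npx0[, ip] + delta[[1]][, ip]
      cols[[paste0(prot[ip], "__", vlab[3])]] <- npx0[, ip] + delta[[2]][, ip]
    }

    # outcome: log fold-change linear in arm and mediator changes
    out0 <- config$outcome_median * exp(stats::rnorm(n, 0, 0.25))
    logfc <- vector("list", 2)
    for (j in 1:2) {
      med_part <- delta[[j]][, seq_len(k), drop = FALSE] %*% config$b
      logfc[[j]] <- config$c_direct * decay[j] * arm + drop(med_part) +
        out_cov + stats::rnorm(n, 0, config$sd_outcome)
    }
    cols[[paste0("picp__", vlab[1])]] <- out0
    cols[[paste0("picp__", vlab[2])]] <- out0 * exp(logfc[[1]])
    cols[[paste0("picp__", vlab[3])]] <- out0 * exp(logfc[[2]])

    # echo trajectories: slopes coupled to designated protein slopes
    echo_slopes <- list()
    echo_names <- names(config$kappa)
    echo_base <- list(lavi = stats::rnorm(n, 31, 5),
                      ea_ratio = stats::rnorm(n, 0.85, 0.15))
    for (e in echo_names) {
      kap <- config$kappa[[e]]
      s <- drop(slopes[, config$slope_proteins, drop = FALSE] %*% kap) +
        stats::rnorm(n, 0, config$sd_echo_slope[[e]])
      echo_slopes[[e]] <- s
      base_e <- echo_base[[e]] %||% stats::rnorm(n, 1, 0.2)
      for (j in 1:3) {
        cols[[paste0(e, "__", vlab[j])]] <- base_e + s * tms[j] +
          stats::rnorm(n, 0, config$sd_echo_resid[[e]])
      }
    }

    d <- as.data.frame(cols, stringsAsFactors = FALSE,
                       check.names = FALSE)
    schema <- trial_schema(visits = config$visits, outcome = "picp",
                           proteins = prot, echo = echo_names)
    ds <- new_trial_dataset(d, schema)
    validate_trial_dataset(ds)
    truth <- c(tm, list(
      mediators = prot[seq_len(k)],
      slope_proteins = prot[config$slope_proteins],
      protein_slopes = slopes[, config$slope_proteins, drop = FALSE],
      echo_slopes = echo_slopes,
      log_outcome_fc = data.frame(subject_id = subject_id,
                                  v1 = logfc[[1]], v2 = logfc[[2]])
    ))
    list(dataset = ds, truth = truth)
  })
}
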