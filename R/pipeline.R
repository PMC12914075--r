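#' Configuration for an end-to-end pipeline run
#'
#' Bundles the generator configuration (or an input file), the analysis
#' thresholds, and one explicit seed per stochastic stage. The
#' field-standard constants are named keys, not literals: top decile
#' fraction 0.10, consensus at >= 2 of 4 learners, alpha 0.05, 1000
#' permutations, 1000 bootstrap resamples, 80/20 split, 3-fold CV.
#'
#' @param sim a [sim_config()] (used unless `input_path` is given).
#' @param input_path optional wide trial table to load instead of
#'   simulating; requires `schema`.
#' @param schema schema for `input_path`.
#' @param decile_fraction,min_models,alpha,n_perm,n_boot,split_fraction
#'   analysis constants.
#' @param specs learner specifications for the selection stage.
#' @param importance_on partition for permutation importance.
#' @param gmt_path optional GMT annotation file for the enrichment stage.
#' @param seeds named list of per-stage seeds.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            input_path = NULL, schema = NULL,
                            decile_fraction = 0.10, min_models = 2,
                            alpha = 0.05, n_perm = 1000, n_boot = 1000,
                            split_fraction = 0.8,
                            specs = NULL,
                            importance_on = "train",
                            gmt_path = NULL,
                            seeds = list(split = 101, learners = 202,
                                         mediation = 303)) {
  structure(list(sim = sim, input_path = input_path, schema = schema,
                 decile_fraction = decile_fraction,
                 min_models = min_models, alpha = alpha, n_perm = n_perm,
                 n_boot = n_boot, split_fraction = split_fraction,
                 specs = specs, importance_on = importance_on,
                 gmt_path = gmt_path, seeds = seeds),
            class = "pipeline_config")
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Stages, in order: data (simulate or load), feature matrices at both
#' follow-up visits, learner selection at both visits, consensus and
#' cross-timepoint intersection, candidate screening, signature score +
#' mediation + leave-one-out losses, trajectory slope regressions,
#' quartile trend table, and (when an annotation file is configured)
#' over-representation analysis. Each stage writes its artifacts under
#' `out_dir`, appends a structured line to `log.jsonl`, and leaves an RDS
#' checkpoint; with `resume = TRUE` stages whose checkpoint exists are
#' reloaded instead of recomputed. A `manifest.tsv` with the MD5 checksum
#' of every artifact is written at the end.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param resume reuse existing stage checkpoints.
#' @return (invisibly) the output directory; side effect: artifacts.
#' @export
run_pipeline <- function(config, out_dir, resume = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "log.jsonl")
  if (!resume && file.exists(log_path)) unlink(log_path)
  stage_log <- function(stage, status, ...) {
    rec <- c(list(stage = stage, status = status), list(...))
    cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
        file = log_path, append = TRUE, sep = "")
  }
  checkpoint <- function(stage, compute) {
    ck <- file.path(out_dir, paste0("stage_", stage, ".rds"))
    if (resume && file.exists(ck)) {
      stage_log(stage, "reused")
      return(readRDS(ck))
    }
    res <- tryCatch(compute(), error = function(e) {
      stage_log(stage, "failed", error = conditionMessage(e))
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e))
    })
    saveRDS(res, ck)
    stage_log(stage, "done")
    res
  }
  saveRDS(config, file.path(out_dir, "config.rds"))

  dat <- checkpoint("data", function() {
    if (!is.null(config$input_path)) {
      list(dataset = load_trial_table(config$input_path, config$schema),
           truth = NULL)
    } else {
      simulate_trial(config$sim)
    }
  })
  ds <- dat$dataset
  vl <- visit_labels(ds$schema)
  v1 <- vl[2]; v2 <- vl[3]

  sel <- checkpoint("selection", function() {
    specs <- config$specs %||% list(
      enet = learner_spec("enet"), rf = learner_spec("rf"),
      gbt = learner_spec("gbt"), nnet = learner_spec("nnet"))
    out <- list()
    for (v in c(v1, v2)) {
      fm <- build_feature_matrix(ds, v)
      arm <- ds$data$arm[match(fm$subject_id, ds$data$subject_id)]
      out[[v]] <- select_features(
        fm, arm, specs = specs, n_perm = config$n_perm,
        fraction = config$decile_fraction,
        min_models = config$min_models,
        importance_on = config$importance_on,
        seed = config$seeds$learners)
      for (nm in names(out[[v]]$importance)) {
        write_tsv(out[[v]]$importance[[nm]],
                  file.path(out_dir, sprintf("importance_%s_%s.tsv", v, nm)))
      }
      write_tsv(out[[v]]$consensus,
                file.path(out_dir, sprintf("consensus_%s.tsv", v)))
    }
    out$intersection <- cross_timepoint_intersection(
      out[[v1]]$consensus, out[[v2]]$consensus)
    write_tsv(out$intersection, file.path(out_dir, "consensus_common.tsv"))
    out
  })

  med <- checkpoint("mediation", function() {
    common <- sel$intersection$feature
    prots <- unique(sub("__(bl|fc)$", "", common))
    prots <- intersect(prots, ds$schema$proteins)
    if (length(prots) < 2) prots <- ds$schema$proteins[1:2]
    scr <- screen_candidates(ds, prots, v1, alpha = config$alpha)
    cands <- scr$protein[scr$selected]
    if (length(cands) < 2) cands <- prots
    write_tsv(scr, file.path(out_dir, "screen.tsv"))
    res <- list(screen = scr, candidates = cands)
    for (v in c(v1, v2)) {
      fcs <- fold_changes(ds, v, vars = cands)
      base <- visit_labels(ds$schema)[1]
      out_fc <- visit_col(ds, ds$schema$outcome, v) /
        visit_col(ds, ds$schema$outcome, base)
      covs <- data.frame(out_bl = visit_col(ds, ds$schema$outcome, base))
      for (p in cands) covs[[paste0(p, "_bl")]] <- visit_col(ds, p, base)
      fcm <- as.matrix(fcs[cands])
      ok <- stats::complete.cases(fcm) & !is.na(out_fc) &
        stats::complete.cases(covs)
      sig <- build_signature_score(fcm[ok, , drop = FALSE], out_fc[ok])
      mr <- mediate(out_fc[ok], sig$score, ds$data$arm[ok],
                    covs[ok, , drop = FALSE], n_boot = config$n_boot,
                    seed = config$seeds$mediation)
      loo <- loo_proportion_loss(out_fc[ok], fcm[ok, , drop = FALSE],
                                 ds$data$arm[ok], covs[ok, , drop = FALSE],
                                 n_boot = config$n_boot,
                                 seed = config$seeds$mediation)
      write_tsv(mr$estimates,
                file.path(out_dir, sprintf("mediation_%s.tsv", v)))
      write_tsv(loo$losses, file.path(out_dir, sprintf("loo_%s.tsv", v)))
      res[[v]] <- list(signature = sig, mediation = mr, loo = loo)
    }
    res
  })

  traj <- checkpoint("trajectories", function() {
    prots <- utils::head(med$candidates, 2)
    sl <- lapply(prots, function(p) fit_random_slopes(biomarker_long(ds, p)))
    names(sl) <- prots
    out <- list(slopes = sl)
    for (e in ds$schema$echo) {
      se <- fit_random_slopes(biomarker_long(ds, e))
      idx <- match(se$subject, sl[[1]]$subject)
      covs <- data.frame(
        age = ds$data$age[match(se$subject, ds$data$subject_id)],
        sex = ds$data$sex[match(se$subject, ds$data$subject_id)],
        arm = ds$data$arm[match(se$subject, ds$data$subject_id)],
        egfr = visit_col(ds, "egfr", vl[1])[
          match(se$subject, ds$data$subject_id)])
      reg <- regress_slopes(se$slope, sl[[1]]$slope[idx],
                            sl[[2]]$slope[idx], covs)
      write_tsv(reg$coefficients,
                file.path(out_dir, sprintf("slope_regression_%s.tsv", e)))
      out[[e]] <- reg
    }
    out
  })

  trend <- checkpoint("trends", function() {
    fc <- fold_changes(ds, v1)[[ds$schema$outcome]]
    q <- assign_quartiles(fc)
    vars <- list(age = ds$data$age, sex = ds$data$sex,
                 picp_bl = visit_col(ds, ds$schema$outcome, vl[1]),
                 arm = ds$data$arm)
    tab <- quartile_table(vars, q$group)
    write_tsv(tab, file.path(out_dir, sprintf("trend_table_%s.tsv", v1)))
    list(quartiles = q, table = tab)
  })

  if (!is.null(config$gmt_path)) {
    checkpoint("enrichment", function() {
      ann <- read_gmt(config$gmt_path)
      query <- med$candidates
      res <- ora(query, ds$schema$proteins, ann)
      write_tsv(res, file.path(out_dir, "enrichment_panel.tsv"))
      res
    })
  }

  arts <- setdiff(list.files(out_dir),
                  c("manifest.tsv"))
  manifest <- data.frame(
    file = arts,
    md5 = unname(tools::md5sum(file.path(out_dir, arts))),
    stringsAsFactors = FALSE)
  write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  invisible(out_dir)
}
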