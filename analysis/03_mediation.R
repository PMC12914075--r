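#!/usr/bin/env Rscript
# Stage 3: candidate screening, signature score, causal mediation and
# leave-one-out mediated-proportion losses at both visits.
#
# Candidates are the proteins behind the cross-timepoint consensus
# features (stage 2), screened for a treatment effect on their change
# and/or an arm x protein interaction on the outcome. The mediation runs
# on the log outcome fold-change (the scale on which the generator's
# structural model is linear) with 1000 bootstrap resamples.

suppressPackageStartupMessages(library(picpmed))

dat_dir <- "results/data"
sel_dir <- "results/selection"
out_dir <- "results/mediation"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

truth <- jsonlite::fromJSON(file.path(dat_dir, "ground_truth.json"))
schema <- trial_schema(proteins = sprintf("P%03d", 1:276),
                       echo = c("lavi", "ea_ratio"))
ds <- load_trial_table(file.path(dat_dir, "trial_wide.tsv"), schema)
common <- read.delim(file.path(sel_dir, "consensus_common.tsv"))

prots <- intersect(unique(sub("__(bl|fc)$", "", common$feature)),
                   ds$schema$proteins)
cat("Screening", length(prots), "consensus proteins...\n")
scr <- screen_candidates(ds, prots, "month1", alpha = 0.05)
write.table(scr, file.path(out_dir, "screen.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cands <- scr$protein[scr$selected]
cat("Selected", length(cands), "candidate mediators:",
    paste(cands, collapse = ", "), "\n")
if (length(cands) < 2) cands <- prots

d <- ds$data
for (v in c("month1", "month9")) {
  y <- log(d[[paste0("picp__", v)]] / d$picp__baseline)
  fc <- as.matrix(d[paste0(cands, "__", v)]) -
    as.matrix(d[paste0(cands, "__baseline")])
  colnames(fc) <- cands
  covs <- data.frame(out_bl = log(d$picp__baseline))
  for (p in cands) covs[[paste0(p, "_bl")]] <- d[[paste0(p, "__baseline")]]
  ok <- complete.cases(fc) & !is.na(y) & complete.cases(covs)

  sig <- build_signature_score(fc[ok, , drop = FALSE], y[ok])
  mr <- mediate(y[ok], sig$score, d$arm[ok], covs[ok, , drop = FALSE],
                n_boot = 1000, seed = 616)
  loo <- loo_proportion_loss(y[ok], fc[ok, , drop = FALSE], d$arm[ok],
                             covs[ok, , drop = FALSE], n_boot = 1000,
                             seed = 616)
  write.table(mr$estimates, file.path(out_dir, sprintf("mediation_%s.tsv", v)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(loo$losses, file.path(out_dir, sprintf("loo_%s.tsv", v)),
              sep = "\t", quote = FALSE, row.names = FALSE)

  est <- mr$estimates
  pr <- est[est$effect == "proportion", ]
  cat(sprintf(
    "%s: mediated proportion %.3f [%.3f, %.3f] (true %.3f); top LOO: %s\n",
    v, pr$estimate, pr$ci_lower, pr$ci_upper, truth$proportion,
    paste(head(loo$losses$mediator, 3), collapse = " > ")))
}
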