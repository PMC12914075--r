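#!/usr/bin/env Rscript
# Stage 5: quartile trend table, median-stratified treatment effect,
# adjusted regression plane, and over-representation of the candidate
# mediators against the bundled synthetic pathway annotation.

suppressPackageStartupMessages(library(picpmed))

dat_dir <- "results/data"
med_dir <- "results/mediation"
out_dir <- "results/trends"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

truth <- jsonlite::fromJSON(file.path(dat_dir, "ground_truth.json"))
schema <- trial_schema(proteins = sprintf("P%03d", 1:276),
                       echo = c("lavi", "ea_ratio"))
ds <- load_trial_table(file.path(dat_dir, "trial_wide.tsv"), schema)
d <- ds$data

## Table-1-style quartile summary at 1 month
fc <- fold_changes(ds, "month1")$picp
q <- assign_quartiles(fc)
vars <- list(age = d$age, male = d$sex, smoker = d$smoker,
             diabetes = d$diabetes, qrs = d$qrs,
             spironolactone = d$arm, picp_baseline = d$picp__baseline,
             egfr_baseline = d$egfr__baseline)
tab <- quartile_table(vars, q$group)
write.table(tab, file.path(out_dir, "quartile_table_month1.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("Quartile sizes:", paste(q$sizes, collapse = "/"), "\n")
cat("Variables with unadjusted p-trend < 0.05:",
    paste(tab$variable[tab$p_trend < 0.05], collapse = ", "), "\n")

## treatment x baseline stratification on the first mediator protein
p1 <- truth$mediators[1]
se <- stratified_effect(ds, p1, "month1")
write.table(se$strata, file.path(out_dir, "stratified_effect.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf(
  "Baseline %s median %.2f NPX: arm effect below %.3f / above %.3f, interaction p = %.3g\n",
  p1, se$median, se$strata$effect[1], se$strata$effect[2],
  se$interaction_p))

## adjusted regression plane on the two slope-designated mediators
m <- truth$slope_proteins
fa <- npx_fold_change(d[[paste0(m[1], "__baseline")]],
                      d[[paste0(m[1], "__month1")]])
fb <- npx_fold_change(d[[paste0(m[2], "__baseline")]],
                      d[[paste0(m[2], "__month1")]])
rp <- regression_plane(fc, fa, fb,
                       data.frame(picp_bl = d$picp__baseline,
                                  a_bl = d[[paste0(m[1], "__baseline")]],
                                  b_bl = d[[paste0(m[2], "__baseline")]]))
write.table(rp$coefficients, file.path(out_dir, "plane_coefficients.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(rp$grid, file.path(out_dir, "plane_surface.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("Regression plane R2 = %.3f\n", rp$r2))

## enrichment of screened candidates, panel background and both filters
scr <- read.delim(file.path(med_dir, "screen.tsv"))
query <- scr$protein[scr$selected]
gmt <- system.file("extdata", "synthetic_pathways.gmt", package = "picpmed")
ann <- read_gmt(gmt)
res <- ora(query, ds$schema$proteins, ann)
write.table(res, file.path(out_dir, "enrichment_panel.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
for (mode in c("adjusted", "fold")) {
  kept <- filter_terms(res, mode)
  cat(sprintf("ORA (%s filter): %d of %d terms kept\n",
              mode, nrow(kept), nrow(res)))
}
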