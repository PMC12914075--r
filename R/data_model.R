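#' Describe the layout of a wide trial table
#'
#' A schema names the visits (with their times in months), the outcome
#' biomarker, the NPX protein columns, and the clinical and
#' echocardiographic variables of a per-subject wide table. Time-varying
#' variables are stored as `<variable>__<visit>` columns; variables measured
#' once (demographics, history) appear under their plain name.
#'
#' @param visits named numeric vector of visit times in months, in
#'   chronological order; the first entry is the baseline visit.
#' @param outcome name of the outcome biomarker (a concentration, e.g.
#'   serum PICP in ug/L), measured at every visit.
#' @param proteins character vector of protein identifiers measured on the
#'   log2 NPX scale at every visit.
#' @param clinical_static variables measured once at baseline.
#' @param clinical_dynamic variables measured at baseline and follow-up.
#' @param echo optional echocardiographic variables measured per visit.
#' @return an object of class `trial_schema`.
#' @export
trial_schema <- function(visits = c(baseline = 0, month1 = 1, month9 = 9),
                         outcome = "picp",
                         proteins = character(),
                         clinical_static = c("age", "sex", "smoker",
                                             "diabetes", "cad", "qrs"),
                         clinical_dynamic = c("bmi", "sbp", "dbp", "sodium",
                                              "potassium", "egfr",
                                              "breathless"),
                         echo = character()) {
  stopifnot(is.numeric(visits), length(visits) >= 2, !is.null(names(visits)))
  if (any(diff(visits) <= 0)) {
    stop("visit times must be strictly increasing")
  }
  structure(
    list(visits = visits, outcome = outcome, proteins = proteins,
         clinical_static = clinical_static,
         clinical_dynamic = clinical_dynamic, echo = echo),
    class = "trial_schema"
  )
}

visit_labels <- function(schema) names(schema$visits)

timevar_cols <- function(var, schema) paste0(var, "__", visit_labels(schema))

new_trial_dataset <- function(data, schema, log = character()) {
  structure(list(data = data, schema = schema, log = log),
            class = "trial_dataset")
}

#' @export
print.trial_dataset <- function(x, ...) {
  cat(sprintf("trial_dataset: %d subjects, %d proteins, visits %s\n",
              nrow(x$data), length(x$schema$proteins),
              paste(sprintf("%s (%g mo)", visit_labels(x$schema),
                            x$schema$visits), collapse = ", ")))
  invisible(x)
}

#' Number of subjects in a trial dataset
#' @param dataset a `trial_dataset`.
#' @return integer subject count.
#' @export
n_subjects <- function(dataset) nrow(dataset$data)

validate_trial_dataset <- function(dataset) {
  d <- dataset$data
  sch <- dataset$schema
  for (col in c("subject_id", "arm")) {
    if (!col %in% names(d)) stop("missing mandatory column: ", col)
  }
  bad_arm <- which(!(d$arm %in% c(0, 1)))
  if (length(bad_arm)) {
    stop("arm must be 0 or 1; violated for subject ",
         paste(d$subject_id[bad_arm], collapse = ", "))
  }
  base_col <- paste0(sch$outcome, "__", visit_labels(sch)[1])
  if (!base_col %in% names(d)) {
    stop("missing mandatory column: ", base_col)
  }
  if (anyDuplicated(d$subject_id)) stop("duplicated subject_id")
  npx_cols <- intersect(unlist(lapply(sch$proteins, timevar_cols, sch)),
                        names(d))
  if (length(npx_cols)) {
    vals <- unlist(d[npx_cols], use.names = FALSE)
    if (any(is.infinite(vals))) stop("non-finite NPX values present")
  }
  invisible(dataset)
}

#' Load a wide trial table
#'
#' Reads a delimited text file with one row per subject and columns
#' `subject_id`, `arm`, plain names for once-measured clinical variables and
#' `<variable>__<visit>` for everything measured per visit. Unparseable
#' numeric cells become missing and are reported in the load log; missing
#' mandatory columns (`subject_id`, `arm`, the baseline outcome) are a hard
#' failure.
#'
#' @param path file path.
#' @param schema a [trial_schema()].
#' @param sep field separator (default tab).
#' @return a `trial_dataset`; the character vector attribute `$log` records
#'   coercion and validation notes.
#' @export
load_trial_table <- function(path, schema, sep = "\t") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           na.strings = "")
  if (!"subject_id" %in% names(raw)) stop("missing mandatory column: subject_id")
  log <- character()
  num_cols <- setdiff(names(raw), "subject_id")
  for (col in num_cols) {
    v <- raw[[col]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(num))
    if (length(bad)) {
      log <- log_line(log, "load", sprintf(
        "column %s: %d unparseable cell(s) set to missing (subjects %s)",
        col, length(bad),
        paste(raw$subject_id[utils::head(bad, 5)], collapse = ",")))
    }
    raw[[col]] <- num
  }
  ds <- new_trial_dataset(raw, schema, log)
  validate_trial_dataset(ds)
  ds
}

#' Write a trial dataset back to a wide delimited table
#'
#' Values are written as decimal text with full precision (17 significant
#' digits), so a write/load round trip preserves every non-missing value.
#'
#' @param dataset a `trial_dataset`.
#' @param path output path.
#' @param sep field separator.
#' @export
write_trial_table <- function(dataset, path, sep = "\t") {
  d <- dataset$data
  out <- d
  for (col in setdiff(names(out), "subject_id")) {
    x <- out[[col]]
    out[[col]] <- ifelse(is.na(x), NA, formatC(x, digits = 17, format = "g"))
  }
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' NPX fold-change
#'
#' Olink NPX values are log2-scale relative abundances, so the fold-change
#' between two visits is `2^(final - baseline)`. Missing inputs give a
#' missing result (never 0).
#'
#' @param npx_baseline,npx_final NPX values (log2 scale).
#' @return positive fold-change ratio.
#' @export
npx_fold_change <- function(npx_baseline, npx_final) {
  2^(npx_final - npx_baseline)
}

# Column of per-visit values for one variable.
visit_col <- function(dataset, var, visit) {
  col <- paste0(var, "__", visit)
  if (!col %in% names(dataset$data)) stop("no column ", col)
  dataset$data[[col]]
}

#' Per-subject fold-changes for a set of variables
#'
#' For NPX proteins the fold-change is `2^(final - baseline)`; for
#' concentration-scale variables (the outcome, dynamic clinical values) it
#' is the plain ratio final/baseline.
#'
#' @param dataset a `trial_dataset`.
#' @param visit label of the follow-up visit.
#' @param vars variables to compute; default the outcome.
#' @return data.frame with `subject_id` and one fold-change column per
#'   variable; the `provenance` attribute tags each as `"npx"` or `"ratio"`.
#' @export
fold_changes <- function(dataset, visit,
                         vars = dataset$schema$outcome) {
  sch <- dataset$schema
  base <- visit_labels(sch)[1]
  out <- data.frame(subject_id = dataset$data$subject_id,
                    stringsAsFactors = FALSE)
  prov <- character(length(vars)); names(prov) <- vars
  for (v in vars) {
    b <- visit_col(dataset, v, base)
    f <- visit_col(dataset, v, visit)
    if (v %in% sch$proteins) {
      out[[v]] <- npx_fold_change(b, f)
      prov[v] <- "npx"
    } else {
      out[[v]] <- f / b
      prov[v] <- "ratio"
    }
  }
  attr(out, "provenance") <- prov
  out
}

#' Assign subjects to quartile groups of a fold-change
#'
#' Subjects are ranked by value (ascending, ties kept in stable input
#' order) and cut into four contiguous rank blocks with sizes as equal as
#' possible; when `n` is not divisible by 4 the remainder subjects are
#' allocated to the lowest groups first, so e.g. 481 subjects give groups
#' of 121/120/120/120.
#'
#' @param values numeric fold-changes; missing values are left unassigned.
#' @param n_groups number of groups (default 4).
#' @return list with `group` (integer per input element, NA where the value
#'   was missing), `sizes`, `cuts` (boundary values between groups), and
#'   `degenerate` (TRUE when all values are identical).
#' @export
assign_quartiles <- function(values, n_groups = 4) {
  ok <- which(!is.na(values))
  n <- length(ok)
  if (n < n_groups) stop("need at least ", n_groups, " non-missing values")
  group <- rep(NA_integer_, length(values))
  degenerate <- length(unique(values[ok])) == 1
  sizes <- rep(n %/% n_groups, n_groups)
  rem <- n %% n_groups
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1
  ord <- ok[order(values[ok])]            # radix order: stable for ties
  grp_seq <- rep(seq_len(n_groups), times = sizes)
  group[ord] <- grp_seq
  cuts <- vapply(seq_len(n_groups - 1), function(g) {
    hi <- values[ord][cumsum(sizes)[g]]
    lo <- values[ord][cumsum(sizes)[g] + 1]
    (hi + lo) / 2
  }, numeric(1))
  list(group = group, sizes = sizes, cuts = cuts, degenerate = degenerate)
}

#' Build the learner feature matrix for one follow-up visit
#'
#' Columns are the baseline NPX value and the NPX fold-change of every
#' protein, the baseline outcome, and the baseline (and, for time-varying
#' ones, fold-change) values of the clinical roster. Baseline and
#' fold-change of the same protein are distinct, separately selectable
#' features (suffixes `__bl` and `__fc`). Every column is min-max rescaled
#' to \[0,1\] with the scaling fitted on the reference (training) rows only
#' and applied to all rows; values outside \[0,1\] on non-reference rows
#' are preserved (no clipping). Zero-variance columns on the reference
#' rows are scaled to constant 0 and logged.
#'
#' Rows with any missing feature or missing target are dropped
#' (complete-case) and recorded in the log.
#'
#' @param dataset a `trial_dataset`.
#' @param visit follow-up visit label defining the fold-changes.
#' @param train_ids subject ids forming the reference partition for
#'   scaling; defaults to all subjects.
#' @return list of class `feature_matrix` with `x` (scaled matrix), `y`
#'   (outcome fold-change), `subject_id`, `info` (per-feature source and
#'   type), `scale` (per-feature min and range), and `log`.
#' @export
build_feature_matrix <- function(dataset, visit, train_ids = NULL) {
  sch <- dataset$schema
  base <- visit_labels(sch)[1]
  d <- dataset$data
  feats <- list()
  info <- list()
  add <- function(name, values, source, type) {
    feats[[name]] <<- values
    info[[name]] <<- data.frame(feature = name, source = source,
                                type = type, stringsAsFactors = FALSE)
  }
  for (p in sch$proteins) {
    b <- visit_col(dataset, p, base)
    f <- visit_col(dataset, p, visit)
    add(paste0(p, "__bl"), b, p, "baseline")
    add(paste0(p, "__fc"), npx_fold_change(b, f), p, "fold_change")
  }
  add(paste0(sch$outcome, "__bl"), visit_col(dataset, sch$outcome, base),
      sch$outcome, "baseline")
  for (v in sch$clinical_static) {
    if (v %in% names(d)) add(paste0(v, "__bl"), d[[v]], v, "baseline")
  }
  for (v in sch$clinical_dynamic) {
    bcol <- paste0(v, "__", base)
    fcol <- paste0(v, "__", visit)
    if (bcol %in% names(d)) add(paste0(v, "__bl"), d[[bcol]], v, "baseline")
    if (bcol %in% names(d) && fcol %in% names(d)) {
      add(paste0(v, "__fc"), d[[fcol]] / d[[bcol]], v, "fold_change")
    }
  }
  x <- do.call(cbind, feats)
  x[!is.finite(x)] <- NA  # e.g. ratio fold-change over a zero baseline
  rownames(x) <- d$subject_id
  y <- visit_col(dataset, sch$outcome, visit) /
    visit_col(dataset, sch$outcome, base)

  log <- character()
  complete <- stats::complete.cases(x) & !is.na(y)
  if (any(!complete)) {
    log <- log_line(log, "features", sprintf(
      "%d subject(s) dropped as incomplete cases", sum(!complete)))
  }
  x <- x[complete, , drop = FALSE]
  y <- y[complete]
  ids <- d$subject_id[complete]

  ref <- if (is.null(train_ids)) rep(TRUE, nrow(x)) else ids %in% train_ids
  if (!any(ref)) stop("no reference (training) rows available for scaling")
  mins <- apply(x[ref, , drop = FALSE], 2, min)
  maxs <- apply(x[ref, , drop = FALSE], 2, max)
  rng <- maxs - mins
  flat <- rng == 0
  if (any(flat)) {
    log <- log_line(log, "features", sprintf(
      "%d zero-variance column(s) scaled to constant 0: %s", sum(flat),
      paste(utils::head(colnames(x)[flat], 5), collapse = ",")))
    rng[flat] <- 1
  }
  xs <- sweep(sweep(x, 2, mins), 2, rng, "/")
  xs[, flat] <- 0
  structure(
    list(x = xs, y = y, subject_id = ids,
         info = do.call(rbind, info),
         scale = data.frame(feature = colnames(x), min = mins, range = rng),
         log = log),
    class = "feature_matrix"
  )
}
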