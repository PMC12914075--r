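#' Read a GMT gene-set annotation file
#'
#' Standard GMT: one term per line, tab-separated
#' `term_id<TAB>description<TAB>member1<TAB>member2...`. Member symbols
#' are de-duplicated within a term.
#'
#' @param path GMT file path.
#' @return data.frame of class `annotation_map` with `term`, `name`, and
#'   list-column `members`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad)) stop("malformed GMT line(s): ", which(bad)[1])
  out <- data.frame(
    term = vapply(parts, `[`, "", 1),
    name = vapply(parts, `[`, "", 2),
    stringsAsFactors = FALSE)
  out$members <- lapply(parts, function(p) unique(p[-(1:2)]))
  class(out) <- c("annotation_map", "data.frame")
  out
}

harmonize_symbols <- function(x) toupper(trimws(x))

#' Hypergeometric over-representation analysis
#'
#' For each term with at least one universe member: the upper-tail
#' hypergeometric probability of observing at least `k` query hits given
#' `n` query genes, `K` term genes, and a universe of `N`
#' (equivalently a one-sided Fisher exact test on the 2 x 2 table).
#' Benjamini-Hochberg adjustment is applied once across the tested terms.
#' Fold-enrichment is `(k/n) / (K/N)`.
#'
#' Symbols are harmonized by case-folding exact match; query symbols
#' absent from the universe are dropped and reported in the `unmatched`
#' attribute, never silently.
#'
#' @param query character vector of query gene symbols.
#' @param universe background gene symbols (genome file or panel list).
#' @param annotation an `annotation_map` from [read_gmt()].
#' @return data.frame: `term`, `name`, `k`, `n`, `K`, `N`, `p`, `q`,
#'   `fold_enrichment`, sorted by `q` then decreasing fold-enrichment.
#'   Attribute `unmatched` holds query symbols outside the universe.
#' @export
ora <- function(query, universe, annotation) {
  universe <- unique(harmonize_symbols(universe))
  query0 <- unique(harmonize_symbols(query))
  query <- intersect(query0, universe)
  unmatched <- setdiff(query0, query)
  if (length(unmatched)) {
    warning(length(unmatched), " query symbol(s) not in universe: ",
            paste(utils::head(unmatched, 5), collapse = ","))
  }
  if (!length(query)) {
    warning("empty query after intersection with universe")
    out <- data.frame(term = character(), name = character(),
                      k = integer(), n = integer(), K = integer(),
                      N = integer(), p = numeric(), q = numeric(),
                      fold_enrichment = numeric())
    attr(out, "unmatched") <- unmatched
    return(out)
  }
  N <- length(universe)
  n <- length(query)
  rows <- lapply(seq_len(nrow(annotation)), function(i) {
    members <- intersect(harmonize_symbols(annotation$members[[i]]),
                         universe)
    K <- length(members)
    if (K == 0) return(NULL)
    k <- length(intersect(members, query))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = annotation$term[i], name = annotation$name[i],
               k = k, n = n, K = K, N = N, p = p,
               fold_enrichment = (k / n) / (K / N),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(term = character(), name = character(),
                      k = integer(), n = integer(), K = integer(),
                      N = integer(), p = numeric(),
                      fold_enrichment = numeric())
  }
  out$q <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$q, -out$fold_enrichment, out$term), ,
             drop = FALSE]
  rownames(out) <- NULL
  out <- out[, c("term", "name", "k", "n", "K", "N", "p", "q",
                 "fold_enrichment")]
  attr(out, "unmatched") <- unmatched
  out
}

#' Filter enrichment results
#'
#' Two conventions: `"adjusted"` keeps terms with both unadjusted p and
#' BH q below 0.05; `"fold"` keeps terms with fold-enrichment > 5 and
#' unadjusted p < 0.05 (used with the panel-list background, where the
#' small universe makes adjusted significance unattainable).
#'
#' @param rows data.frame from [ora()].
#' @param mode `"adjusted"` or `"fold"`.
#' @param p_cut,q_cut,fold_cut thresholds.
#' @return the filtered rows.
#' @export
filter_terms <- function(rows, mode = c("adjusted", "fold"),
                         p_cut = 0.05, q_cut = 0.05, fold_cut = 5) {
  mode <- match.arg(mode)
  keep <- switch(mode,
    adjusted = rows$p < p_cut & rows$q < q_cut,
    fold = rows$fold_enrichment > fold_cut & rows$p < p_cut)
  rows[keep, , drop = FALSE]
}
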