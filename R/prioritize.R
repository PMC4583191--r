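#' Configuration for guilt-by-association prioritization
#'
#' Candidate genes are prioritized when their expression correlates strongly
#' with several confirmed disease genes, on the premise that genes involved
#' in the same disease mechanism belong to the same or related co-expression
#' networks. "Strongly" is defined empirically: a quantile of the absolute
#' correlations among a random gene set (the null), so the threshold adapts
#' to how clean the data is.
#'
#' @param known confirmed disease gene identifiers (character or
#'   [gene_set()]).
#' @param candidates candidate gene identifiers.
#' @param null_size number of random genes for the null distribution
#'   (default 1000, capped at the number of genes).
#' @param null_quantile quantile of null `|r|` used as the significance
#'   threshold, in `(0, 1)` (default 0.99).
#' @param min_links minimum number of known genes a candidate must exceed
#'   the threshold with (default 2).
#' @param seed seed for the random null draw.
#' @return an object of class `"prioritization_config"`.
#' @export
prioritization_config <- function(known, candidates, null_size = 1000,
                                  null_quantile = 0.99, min_links = 2,
                                  seed = 1L) {
  if (null_quantile <= 0 || null_quantile >= 1)
    stop("null_quantile must be in (0, 1)")
  if (min_links < 1) stop("min_links must be >= 1")
  structure(list(known = as.character(known),
                 candidates = as.character(candidates),
                 null_size = null_size, null_quantile = null_quantile,
                 min_links = min_links, seed = as.integer(seed)),
            class = "prioritization_config")
}

#' Empirical correlation-significance threshold from a random-gene null
#'
#' Samples `null_size` random genes, computes the distribution of their
#' absolute off-diagonal correlations, and returns its `null_quantile`
#' quantile. When the data is dominated by shared systematic noise the null
#' itself is saturated; if the null median of `|r|` exceeds 0.5 the
#' threshold is declared unreliable, and degenerate data (no variation)
#' yields an undefined status. Callers must branch on `status` rather than
#' rely on exceptions — an unusable threshold is an informative outcome, not
#' a bug.
#'
#' @param Y samples-by-genes expression matrix.
#' @param config a [prioritization_config()].
#' @return a list of class `"correlation_threshold"` with `threshold`
#'   (`NA` unless `status == "ok"`), `status` (`"ok"`, `"unreliable"`,
#'   `"undefined"`), `null_median`, and `null_size`.
#' @export
correlation_threshold <- function(Y, config) {
  stopifnot(inherits(config, "prioritization_config"))
  Y <- as_expression_matrix(Y)
  size <- min(config$null_size, ncol(Y))
  genes <- sample_random_genes(Y, size = size, seed = config$seed)
  sds <- apply(Y[, genes, drop = FALSE], 2L, stats::sd)
  genes <- genes[sds > 0]
  if (length(genes) < 3)
    return(structure(list(threshold = NA_real_, status = "undefined",
                          null_median = NA_real_, null_size = size),
                     class = "correlation_threshold"))
  v <- abs(offdiag(stats::cor(Y[, genes, drop = FALSE])))
  if (diff(range(v)) < 1e-12)     # e.g. all genes identical: every |r| = 1
    return(structure(list(threshold = NA_real_, status = "undefined",
                          null_median = stats::median(v), null_size = size),
                     class = "correlation_threshold"))
  med <- stats::median(v)
  if (med > 0.5)
    return(structure(list(threshold = NA_real_, status = "unreliable",
                          null_median = med, null_size = size),
                     class = "correlation_threshold"))
  structure(list(threshold = stats::quantile(v, config$null_quantile,
                                             names = FALSE),
                 status = "ok", null_median = med, null_size = size),
            class = "correlation_threshold")
}

#' @export
print.correlation_threshold <- function(x, ...) {
  cat("Correlation-significance threshold (random-gene null)\n")
  cat(sprintf("  status: %s, null |r| median: %.3f, threshold: %s\n",
              x$status, x$null_median,
              if (is.na(x$threshold)) "-" else sprintf("%.3f", x$threshold)))
  invisible(x)
}

#' Prioritize candidate genes by co-expression with known disease genes
#'
#' A candidate is prioritized when its absolute correlation with at least
#' `min_links` known disease genes exceeds the empirical null threshold of
#' [correlation_threshold()]. If no reliable threshold exists (data
#' dominated by systematic noise), the result is marked not computable and
#' no candidate is flagged.
#'
#' @param Y samples-by-genes expression matrix (typically the cleaned data).
#' @param config a [prioritization_config()].
#' @return an object of class `"prioritization_result"`: data frame `table`
#'   (per candidate: `links`, `max_abs_r`, `prioritized`), `threshold`
#'   (the `"correlation_threshold"` object), `computable`, `n_prioritized`,
#'   `config`, and the numbers of known/candidate genes dropped for being
#'   absent.
#' @export
prioritize_candidates <- function(Y, config) {
  stopifnot(inherits(config, "prioritization_config"))
  Y <- as_expression_matrix(Y)
  known <- intersect(config$known, colnames(Y))
  cands <- intersect(config$candidates, colnames(Y))
  dropped <- c(known = length(config$known) - length(known),
               candidates = length(config$candidates) - length(cands))
  if (any(dropped > 0))
    message("dropped ", dropped[["known"]], " known and ",
            dropped[["candidates"]], " candidate gene(s) absent from the data")
  if (length(known) == 0 || length(cands) == 0)
    stop("no known or no candidate genes present in the data")
  overlap <- intersect(known, cands)
  if (length(overlap) > 0)
    stop("known and candidate sets overlap: ",
         paste(utils::head(overlap, 5), collapse = ", "))
  thr <- correlation_threshold(Y, config)
  tab <- data.frame(candidate = sort(cands), links = NA_integer_,
                    max_abs_r = NA_real_, prioritized = FALSE,
                    row.names = NULL)
  if (thr$status == "ok") {
    R <- abs(stats::cor(Y[, tab$candidate, drop = FALSE],
                        Y[, known, drop = FALSE]))
    R[is.na(R)] <- 0                       # zero-variance genes link nothing
    tab$links <- as.integer(rowSums(R > thr$threshold))
    tab$max_abs_r <- apply(R, 1L, max)
    tab$prioritized <- tab$links >= config$min_links
  }
  structure(list(table = tab, threshold = thr,
                 computable = thr$status == "ok",
                 n_prioritized = sum(tab$prioritized),
                 known_used = known, dropped = dropped, config = config),
            class = "prioritization_result")
}

#' @export
print.prioritization_result <- function(x, ...) {
  cat("Guilt-by-association prioritization\n")
  if (!x$computable) {
    cat("  not computable: ", x$threshold$status,
        " correlation-significance threshold (null |r| median ",
        sprintf("%.3f", x$threshold$null_median), ")\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf("  threshold |r| > %.3f, min_links = %d\n",
              x$threshold$threshold, x$config$min_links))
  cat(sprintf("  %d of %d candidates prioritized\n",
              x$n_prioritized, nrow(x$table)))
  invisible(x)
}

#' Cross-study consistency of prioritization results
#'
#' For candidates evaluated in every study, counts how many are prioritized
#' in all studies and in at least `j` studies for each `j`. Results whose
#' threshold was not computable are dropped with a message (their study
#' cannot vote).
#'
#' @param results a list of `"prioritization_result"` objects.
#' @return a list with `shared_candidates`, `prioritized_in_all` (ids and
#'   count), and `by_min_studies` (data frame: `j`, `count`).
#' @export
consistency_report <- function(results) {
  stopifnot(length(results) >= 1,
            all(vapply(results, inherits, logical(1), "prioritization_result")))
  usable <- Filter(function(r) r$computable, results)
  if (length(usable) < length(results))
    message("dropping ", length(results) - length(usable),
            " result(s) without a computable threshold")
  if (length(usable) == 0) stop("no computable prioritization results")
  shared <- Reduce(intersect, lapply(usable, function(r) r$table$candidate))
  if (length(shared) == 0) stop("no candidates shared across all results")
  hits <- vapply(shared, function(g) {
    sum(vapply(usable, function(r)
      r$table$prioritized[match(g, r$table$candidate)], logical(1)))
  }, integer(1))
  j <- seq_len(length(usable))
  list(shared_candidates = shared,
       prioritized_in_all = list(ids = shared[hits == length(usable)],
                                 count = sum(hits == length(usable))),
       by_min_studies = data.frame(j = j,
                                   count = vapply(j, function(v) sum(hits >= v),
                                                  integer(1))))
}
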