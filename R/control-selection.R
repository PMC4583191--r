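#' Load a gene set from a plain-text list
#'
#' Reads one identifier per line (`#` comments and blank lines allowed),
#' deduplicates, and intersects with the genes of `Y`, preserving file
#' order. Unmatched identifiers are reported via [message()].
#'
#' @param path path to the gene list file.
#' @param Y expression matrix whose genes the list is matched against.
#' @param role role of the set, see [gene_set()].
#' @return a [gene_set()].
#' @export
load_gene_set <- function(path, Y, role = "negative") {
  if (!file.exists(path)) stop("gene list not found: ", path)
  ids <- read_gene_list(path)
  gene_set(ids, role = role, Y = as_expression_matrix(Y))
}

#' Discover candidate negative-control genes by low variance
#'
#' An empirical instantiation of the housekeeping-gene heuristic: genes
#' whose observed expression is fairly constant across a wide range of
#' biological states are candidates for negative controls. After removing
#' per-sample median offsets (so global sample shifts do not masquerade as
#' gene variance), genes are ranked by variance across samples and the
#' lowest-variance fraction is returned. Curated control lists grounded in
#' prior biology are preferable when available; treat discovered controls
#' with caution, since a low-variance gene may still carry signal.
#'
#' @param Y samples-by-genes expression matrix with at least 50 genes.
#' @param fraction fraction of genes to return, in `(0, 0.5]`.
#' @param exclude gene identifiers that must not be selected (e.g. genes of
#'   interest).
#' @return a negative-control [gene_set()]; the attribute `"variances"`
#'   holds the full named variance distribution for inspection.
#' @export
discover_negative_controls <- function(Y, fraction = 0.1, exclude = NULL) {
  Y <- as_expression_matrix(Y)
  if (ncol(Y) < 50)
    stop("control discovery needs at least 50 genes")
  if (fraction <= 0 || fraction > 0.5)
    stop("fraction must be in (0, 0.5]")
  Ys <- sweep(Y, 1L, apply(Y, 1L, stats::median), "-")
  v <- apply(Ys, 2L, stats::var)
  keep <- setdiff(colnames(Y), exclude)
  n_sel <- max(1L, round(fraction * ncol(Y)))
  sel <- names(sort(v[keep]))[seq_len(min(n_sel, length(keep)))]
  out <- gene_set(sel, role = "negative")
  attr(out, "variances") <- v
  out
}

#' Sample a random gene set
#'
#' Uniform sample of genes without replacement, reproducible from the seed;
#' random gene sets serve as the empirical null for correlation thresholds
#' and as the background set in density and ECDF diagnostics.
#'
#' @param Y expression matrix.
#' @param size number of genes to draw (default 1000, at most `n`).
#' @param seed integer seed; the caller's RNG stream is left untouched.
#' @return a [gene_set()] with role `"random"`.
#' @export
sample_random_genes <- function(Y, size = 1000, seed = 1L) {
  Y <- as_expression_matrix(Y)
  if (size > ncol(Y))
    stop("size exceeds the number of genes (", ncol(Y), ")")
  if (size < 1) stop("size must be >= 1")
  ids <- with_seed(seed, sample(colnames(Y), size))
  gene_set(ids, role = "random")
}

read_gene_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}
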