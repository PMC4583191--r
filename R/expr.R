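#' @keywords internal
"_PACKAGE"

# Internal orientation is samples x genes (rows = samples), matching the
# multivariate linear model Y = X beta + W alpha + eps with Y in R^{m x n}.
# File I/O uses the genes-in-rows expression-table convention and transposes
# on ingestion (see read_expression).

#' Validate an expression matrix
#'
#' Checks that `Y` is a numeric samples-by-genes matrix with unique sample and
#' gene identifiers and no missing values.
#'
#' @param Y numeric matrix, samples in rows, genes in columns, log-2 scale.
#' @param impute_missing if `TRUE`, missing values are replaced by the gene
#'   mean (with a warning); if `FALSE` (default) missing values are an error.
#' @return the validated (possibly imputed) matrix, invisibly unchanged
#'   otherwise.
#' @export
as_expression_matrix <- function(Y, impute_missing = FALSE) {
  if (!is.matrix(Y) || !is.numeric(Y))
    stop("expression data must be a numeric matrix (samples x genes)")
  if (is.null(colnames(Y)))
    colnames(Y) <- paste0("gene_", seq_len(ncol(Y)))
  if (is.null(rownames(Y)))
    rownames(Y) <- paste0("sample_", seq_len(nrow(Y)))
  if (anyDuplicated(colnames(Y)))
    stop("duplicate gene identifiers: ",
         paste(unique(colnames(Y)[duplicated(colnames(Y))]), collapse = ", "))
  if (anyDuplicated(rownames(Y)))
    stop("duplicate sample identifiers: ",
         paste(unique(rownames(Y)[duplicated(rownames(Y))]), collapse = ", "))
  if (anyNA(Y)) {
    if (!impute_missing)
      stop("expression matrix contains missing values; ",
           "set impute_missing = TRUE to impute by gene mean")
    warning("imputing ", sum(is.na(Y)), " missing values by gene mean")
    for (j in which(colSums(is.na(Y)) > 0)) {
      mu <- mean(Y[, j], na.rm = TRUE)
      if (is.nan(mu)) stop("gene ", colnames(Y)[j], " is entirely missing")
      Y[is.na(Y[, j]), j] <- mu
    }
  }
  Y
}

#' Center each gene across samples
#'
#' Subtracts the per-gene mean: `Y* = (I - J/m) Y`, where `J` is the all-ones
#' matrix. Centering is advisable before estimating unwanted variation for
#' correlation analysis, since an estimated intercept can introduce spurious
#' correlations; Pearson correlations are unaffected. The operation is
#' idempotent, and the result carries a `"centered"` attribute.
#'
#' @param Y numeric samples-by-genes matrix with at least two samples.
#' @return the gene-centered matrix with `attr(., "centered") = TRUE`.
#' @examples
#' Y <- matrix(c(1, 3, 5, 5), 2, 2, dimnames = list(NULL, c("g1", "g2")))
#' center_genes(Y)
#' @export
center_genes <- function(Y) {
  Y <- as_expression_matrix(Y)
  if (nrow(Y) < 2)
    stop("centering requires at least 2 samples")
  Ys <- sweep(Y, 2L, colMeans(Y), "-")
  attr(Ys, "centered") <- TRUE
  Ys
}

is_centered <- function(Y, tol = 1e-10) {
  isTRUE(attr(Y, "centered")) || max(abs(colMeans(Y))) < tol
}

#' Construct a gene set
#'
#' A gene set is a character vector of gene identifiers with a `role`
#' attribute; roles distinguish negative controls (assumed unrelated to the
#' biology of interest), positive controls (known co-regulated genes), and
#' random background sets.
#'
#' @param ids character vector of gene identifiers.
#' @param role one of `"negative"`, `"positive"`, `"random"`.
#' @param Y optional expression matrix to validate membership against.
#' @return a character vector of class `"gene_set"`.
#' @export
gene_set <- function(ids, role = c("negative", "positive", "random"), Y = NULL) {
  role <- match.arg(role)
  ids <- as.character(ids)
  if (length(ids) == 0) stop("gene set must be non-empty")
  if (anyDuplicated(ids)) {
    warning("dropping ", sum(duplicated(ids)), " duplicate gene identifiers")
    ids <- ids[!duplicated(ids)]
  }
  if (!is.null(Y)) {
    missing <- setdiff(ids, colnames(Y))
    if (length(missing) == length(ids))
      stop("none of the gene identifiers are present in the expression matrix")
    if (length(missing) > 0) {
      message(length(missing), " gene(s) not present in the expression matrix: ",
              paste(utils::head(missing, 10), collapse = ", "),
              if (length(missing) > 10) ", ...")
      ids <- ids[ids %in% colnames(Y)]
    }
  }
  structure(ids, class = "gene_set", role = role)
}

#' @export
print.gene_set <- function(x, ...) {
  cat("Gene set (role: ", attr(x, "role"), "), ", length(x), " genes\n", sep = "")
  cat(paste(utils::head(unclass(x), 8), collapse = ", "),
      if (length(x) > 8) ", ...", "\n", sep = "")
  invisible(x)
}

# resolve a controls argument (gene_set or character) against Y's genes
resolve_genes <- function(Y, genes) {
  ids <- as.character(genes)
  bad <- setdiff(ids, colnames(Y))
  if (length(bad) > 0)
    stop("gene identifiers not present in the matrix: ",
         paste(utils::head(bad, 10), collapse = ", "))
  ids
}

# run expr with a private RNG stream, leaving the caller's stream untouched
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
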