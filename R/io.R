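#' Read an expression table
#'
#' Reads a delimited text table with gene identifiers in the first column
#' and sample identifiers in the header row (the de-facto expression-table
#' convention) and transposes it to the internal samples-by-genes
#' orientation. The delimiter is sniffed from the header (tab or comma).
#' Values are assumed to be on a log-2 scale; a maximum above 50 triggers a
#' "looks unlogged" warning.
#'
#' @param path path to a TSV/CSV file.
#' @param impute_missing see [as_expression_matrix()].
#' @return a samples-by-genes numeric matrix.
#' @export
read_expression <- function(path, impute_missing = FALSE) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = NA)
  if (ncol(tab) < 2) stop("expression table needs gene ids plus >= 1 sample")
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids))
    stop("duplicate gene identifiers in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(is.na(suppressWarnings(matrix(as.numeric(vals), nrow(vals)))) &
                   !is.na(vals), arr.ind = TRUE)
    stop("non-numeric value at gene ", ids[bad[1, 1]], ", sample ",
         colnames(vals)[bad[1, 2]])
  }
  rownames(vals) <- ids
  Y <- t(vals)
  if (max(Y, na.rm = TRUE) > 50)
    warning("values exceed 50; the data looks unlogged (log-2 scale expected)")
  as_expression_matrix(Y, impute_missing = impute_missing)
}

#' Write an expression table
#'
#' Writes the transposed (genes-in-rows) table as TSV with full double
#' precision, so that a write/read round trip reproduces the matrix to
#' within 1e-12.
#'
#' @param Y samples-by-genes matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(Y, path) {
  Y <- as_expression_matrix(Y)
  tab <- t(Y)
  df <- data.frame(gene_id = rownames(tab),
                   apply(tab, 2L, function(col) formatC(col, digits = 17,
                                                        format = "g")),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline run configuration
#'
#' JSON (or YAML, when the yaml package is available) with the same schema
#' as [run_config()]'s arguments.
#'
#' @param path path to a .json/.yaml/.yml file.
#' @return a `"run_config"` object.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML configs need the yaml package; use JSON instead")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, cfg)
}

#' Assemble a pipeline run configuration
#'
#' @param expression path to the expression table.
#' @param method one of `"raw"`, `"bc"`, `"qn"`, `"bc+qn"`, `"ruv"`,
#'   `"bc+ruv"` (names mirror the usual data versions compared in
#'   co-expression benchmarking).
#' @param out_dir output directory (created if needed).
#' @param neg_controls path to a negative-control gene list (required for
#'   the RUV methods).
#' @param k,nu RUV parameters, see [ruv_random()].
#' @param truth optional path to a true-correlation TSV matrix (simulation
#'   benchmarks); enables the metric report.
#' @param known,candidates optional gene-list paths enabling prioritization.
#' @param annotation optional sample-annotation TSV (first column
#'   `sample_id`) for the PCA diagnostic.
#' @param positive_controls optional gene-list path for the correlation
#'   density diagnostic.
#' @param random_genes size of the random background gene set.
#' @param seed integer seed for all randomized steps.
#' @return a `"run_config"` object.
#' @export
run_config <- function(expression, method = "ruv", out_dir = "ruvclean_run",
                       neg_controls = NULL, k = NULL, nu = NULL,
                       truth = NULL, known = NULL, candidates = NULL,
                       annotation = NULL, positive_controls = NULL,
                       random_genes = 1000, seed = 1L) {
  methods <- c("raw", "bc", "qn", "bc+qn", "ruv", "bc+ruv")
  if (!method %in% methods)
    stop("method must be one of: ", paste(methods, collapse = ", "))
  for (p in c(expression, neg_controls, truth, known, candidates, annotation,
              positive_controls))
    if (!is.null(p) && !file.exists(p)) stop("file not found: ", p)
  if (method %in% c("ruv", "bc+ruv")) {
    if (is.null(neg_controls)) stop("RUV methods need neg_controls")
    if (is.null(k)) stop("RUV methods need k")
  }
  structure(list(expression = expression, method = method, out_dir = out_dir,
                 neg_controls = neg_controls, k = k, nu = nu, truth = truth,
                 known = known, candidates = candidates,
                 annotation = annotation,
                 positive_controls = positive_controls,
                 random_genes = random_genes, seed = as.integer(seed)),
            class = "run_config")
}

method_label <- function(method) {
  switch(method, raw = "raw", bc = "BC-surrogate", qn = "QN",
         "bc+qn" = "BC+QN", ruv = "RUV-random", "bc+ruv" = "BC+RUV-random")
}

#' Run the cleaning/evaluation pipeline
#'
#' Executes the configured cleaning method on the input expression table and
#' writes, under `out_dir`: the cleaned (gene-centered) matrix, the fit
#' report (for RUV methods: k, nu, singular values, variance removed) as
#' JSON, the random-gene correlation density and RLE summary tables, a PCA
#' score table, the metric report when a truth matrix is supplied, the
#' prioritization table when known/candidate lists are supplied, and a
#' machine-readable `manifest.json` (configuration, seed, package version)
#' from which the run can be reproduced.
#'
#' @param config a [run_config()] or path to one.
#' @return the output directory, invisibly; the manifest is also returned as
#'   the `"manifest"` attribute.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(stage, ...) {
    msg <- sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage,
                   paste(..., collapse = " "))
    message(msg)
    cat(msg, "\n", file = file.path(config$out_dir, "run.log"), append = TRUE)
  }

  log_stage("read", config$expression)
  Y <- read_expression(config$expression)

  fit <- NULL
  cleaned <- switch(
    config$method,
    raw = center_genes(Y),
    bc = center_genes(background_correct(Y)),
    qn = center_genes(quantile_normalize(Y)),
    "bc+qn" = center_genes(quantile_normalize(background_correct(Y))),
    ruv = , "bc+ruv" = {
      Yin <- if (config$method == "bc+ruv") background_correct(Y) else Y
      controls <- load_gene_set(config$neg_controls, Yin, role = "negative")
      fit <- ruv_random(Yin, controls, k = config$k, nu = config$nu)
      residuals(fit)
    })
  log_stage("clean", "method =", method_label(config$method))
  write_expression(cleaned, file.path(config$out_dir, "cleaned.tsv"))
  if (!is.null(fit)) {
    jsonlite::write_json(
      list(k = fit$k, nu = fit$nu, n_controls = length(fit$control_ids),
           singular_values = fit$singular_values,
           var_removed = fit$var_removed),
      file.path(config$out_dir, "ruv_fit.json"),
      auto_unbox = TRUE, digits = NA)
  }

  n_rand <- min(config$random_genes, ncol(cleaned))
  rand <- sample_random_genes(cleaned, size = n_rand, seed = config$seed)
  rand_corr <- pearson_matrix(cleaned, rand,
                              source_label = method_label(config$method))
  dens <- correlation_density(rand_corr)
  utils::write.table(dens$table,
                     file.path(config$out_dir, "random_density.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(rle_summary(cleaned),
                     file.path(config$out_dir, "rle_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ann <- if (!is.null(config$annotation))
    utils::read.delim(config$annotation, stringsAsFactors = FALSE) else NULL
  pca <- pca_projection(cleaned, annotation = ann,
                        d = min(2, dim(cleaned) - 1))
  pca_tab <- data.frame(sample_id = rownames(pca$scores), pca$scores)
  if (!is.null(pca$annotation))
    pca_tab <- cbind(pca_tab,
                     pca$annotation[setdiff(names(pca$annotation), "sample_id")])
  utils::write.table(pca_tab, file.path(config$out_dir, "pca_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_stage("diagnostics", sprintf("random genes = %d", n_rand))

  if (!is.null(config$positive_controls)) {
    pos <- load_gene_set(config$positive_controls, cleaned, role = "positive")
    pos_corr <- pearson_matrix(cleaned, pos,
                               source_label = method_label(config$method))
    utils::write.table(correlation_density(pos_corr)$table,
                       file.path(config$out_dir, "positive_density.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  report <- NULL
  if (!is.null(config$truth)) {
    truth_mat <- as.matrix(utils::read.delim(config$truth, row.names = 1,
                                             check.names = FALSE))
    truth_cs <- correlation_set(truth_mat, source_label = "truth")
    est <- pearson_matrix(cleaned, rownames(truth_mat),
                          source_label = method_label(config$method))
    report <- metric_report(est, truth_cs)
    jsonlite::write_json(unclass(report),
                         file.path(config$out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    log_stage("evaluate", sprintf("FN2 = %.4g", report$fn2))
  }

  prio <- NULL
  if (!is.null(config$known) && !is.null(config$candidates)) {
    pc <- prioritization_config(
      known = read_gene_list(config$known),
      candidates = read_gene_list(config$candidates),
      null_size = config$random_genes, seed = config$seed)
    prio <- prioritize_candidates(cleaned, pc)
    utils::write.table(prio$table,
                       file.path(config$out_dir, "prioritization.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(computable = prio$computable,
           status = prio$threshold$status,
           threshold = prio$threshold$threshold,
           n_prioritized = prio$n_prioritized),
      file.path(config$out_dir, "prioritization.json"),
      auto_unbox = TRUE, digits = NA)
    log_stage("prioritize",
              if (prio$computable) sprintf("%d prioritized", prio$n_prioritized)
              else "threshold not computable")
  }

  manifest <- list(
    package = "ruvclean",
    version = as.character(utils::packageVersion("ruvclean")),
    seed = config$seed,
    config = unclass(config),
    outputs = list.files(config$out_dir))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  log_stage("done", config$out_dir)
  invisible(structure(config$out_dir, manifest = manifest))
}
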