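#' Aligned expression/response data for one study
#'
#' The unit the multi-source regression consumes: a samples x genes expression
#' matrix aligned with a per-sample response vector (one drug's AUC, or GRD),
#' plus optional per-sample covariates.
#'
#' @param expression samples x genes numeric matrix with row (sample) and
#'   column (gene) names.
#' @param response named per-sample numeric vector; names must match the
#'   expression rows (order is realigned).
#' @param covariates optional data frame of per-sample covariates.
#' @param dataset_id study identifier.
#' @return object of class `source_dataset`.
#' @export
source_dataset <- function(expression, response, covariates = NULL,
                           dataset_id = "source") {
  stopifnot(is.matrix(expression), is.numeric(expression))
  if (is.null(rownames(expression)) || is.null(colnames(expression)))
    stop_input("expression needs sample row names and gene column names")
  if (any(!is.finite(expression))) stop_input("expression must be finite")
  if (is.null(names(response))) {
    if (length(response) != nrow(expression))
      stop_input("response length does not match samples")
    names(response) <- rownames(expression)
  }
  if (!all(rownames(expression) %in% names(response)))
    stop_input("response missing for some samples")
  response <- response[rownames(expression)]
  if (any(!is.finite(response))) stop_input("responses must be finite after alignment")
  structure(list(expression = expression, response = response,
                 covariates = covariates, dataset_id = dataset_id),
            class = "source_dataset")
}

#' @export
print.source_dataset <- function(x, ...) {
  cat(sprintf("source_dataset '%s': %d samples x %d genes\n",
              x$dataset_id, nrow(x$expression), ncol(x$expression)))
  invisible(x)
}

#' Filter low-expression / low-variance genes
#'
#' Keeps genes whose mean expression and variance both exceed the
#' dataset-specific quantile thresholds, the usual pre-regression pruning of
#' uninformative transcripts.
#'
#' @param expr genes x samples expression matrix (log scale).
#' @param min_expression_quantile,min_variance_quantile quantiles in `[0, 1)`
#'   of the per-gene mean and variance distributions; genes must exceed both.
#' @return the filtered genes x samples matrix, with a `retention` attribute
#'   (data frame of per-gene mean, variance, and kept flag).
#' @export
filter_genes <- function(expr, min_expression_quantile = 0.25,
                         min_variance_quantile = 0.25) {
  stopifnot(is.matrix(expr))
  for (q in c(min_expression_quantile, min_variance_quantile))
    if (q < 0 || q >= 1) stop_input("quantiles must be in [0, 1)")
  mu <- rowMeans(expr)
  v <- apply(expr, 1L, var)
  keep <- rep(TRUE, nrow(expr))
  if (min_expression_quantile > 0)
    keep <- keep & mu > quantile(mu, min_expression_quantile)
  if (min_variance_quantile > 0)
    keep <- keep & v > quantile(v, min_variance_quantile)
  if (!any(keep)) stop_input("all genes filtered out")
  out <- expr[keep, , drop = FALSE]
  attr(out, "retention") <- data.frame(gene_id = rownames(expr), mean = mu,
                                       variance = v, kept = keep,
                                       row.names = NULL)
  out
}

zscore <- function(x) {
  s <- sd(x)
  if (s == 0 || !is.finite(s)) return(x - mean(x))
  (x - mean(x)) / s
}

#' Harmonize several studies onto a common gene space
#'
#' Intersects gene ids across studies, orders them identically, and z-scores
#' every gene and every response within each study. Joint regression across
#' studies is then performed on this standardized common space; the operation
#' is idempotent on already-harmonized input.
#'
#' @param exprs list of genes x samples expression matrices (one per study).
#' @param responses list of named per-sample response vectors; samples absent
#'   from a response (or non-finite there) are dropped from that study.
#' @param dataset_ids study identifiers.
#' @return list of [source_dataset()] objects on the common gene space
#'   (expression transposed to samples x genes), with attribute `n_genes`.
#' @export
harmonize_sources <- function(exprs, responses,
                              dataset_ids = sprintf("source%d", seq_along(exprs))) {
  if (length(exprs) < 1L) stop_input("need at least one study")
  if (length(responses) != length(exprs)) stop_input("exprs/responses length mismatch")
  common <- Reduce(intersect, lapply(exprs, rownames))
  if (length(common) == 0L) stop_input("no genes shared by all studies")
  common <- sort(common)
  out <- vector("list", length(exprs))
  for (d in seq_along(exprs)) {
    x <- t(exprs[[d]][common, , drop = FALSE])  # samples x genes
    y <- responses[[d]]
    if (is.null(names(y))) {
      if (length(y) != nrow(x)) stop_input("study %d: unnamed response of wrong length", d)
      names(y) <- rownames(x)
    }
    y <- y[names(y) %in% rownames(x)]
    y <- y[is.finite(y)]
    if (length(y) < 3L) stop_input("study %d: fewer than 3 samples with response", d)
    x <- x[names(y), , drop = FALSE]
    x <- apply(x, 2L, zscore)
    rownames(x) <- names(y)
    y <- zscore(y)
    out[[d]] <- source_dataset(x, y, dataset_id = dataset_ids[d])
  }
  attr(out, "n_genes") <- length(common)
  out
}
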