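#' General response across drugs (GRD)
#'
#' A sample's mean raw AUC over a drug panel — the per-patient pan-drug
#' sensitivity statistic. Computed over the observed entries of the chosen
#' drug subset; samples with fewer than `min_drugs` observed drugs get `NA`.
#'
#' @param auc drugs x samples AUC matrix (`NA` allowed).
#' @param drug_subset optional drug ids to restrict to.
#' @param exclude_drug optional drug id removed before averaging (leave-drug-
#'   out discipline when GRD is used to model that drug's own response).
#' @param min_drugs minimum observed drugs per sample.
#' @return named per-sample GRD vector.
#' @export
compute_grd <- function(auc, drug_subset = NULL, exclude_drug = NULL,
                        min_drugs = 10L) {
  stopifnot(is.matrix(auc))
  rows <- rownames(auc)
  if (is.null(rows)) rows <- as.character(seq_len(nrow(auc)))
  use <- if (is.null(drug_subset)) rows else {
    if (!all(drug_subset %in% rows))
      stop_input("drug_subset contains unknown drugs")
    drug_subset
  }
  use <- setdiff(use, exclude_drug)
  if (length(use) == 0L) stop_input("no drugs left after subsetting/exclusion")
  sub <- auc[match(use, rows), , drop = FALSE]
  n_obs <- colSums(is.finite(sub))
  grd <- colMeans(sub, na.rm = TRUE)
  grd[n_obs < min_drugs] <- NA_real_
  grd[n_obs == 0L] <- NA_real_
  grd
}

#' Mean response across patients (MRP)
#'
#' A drug's mean raw AUC over samples; drugs with fewer than `min_samples`
#' observed samples get `NA`.
#'
#' @param auc drugs x samples AUC matrix.
#' @param min_samples minimum observed samples per drug.
#' @return named per-drug MRP vector.
#' @export
compute_mrp <- function(auc, min_samples = 1L) {
  stopifnot(is.matrix(auc))
  n_obs <- rowSums(is.finite(auc))
  mrp <- rowMeans(auc, na.rm = TRUE)
  mrp[n_obs < min_samples | n_obs == 0L] <- NA_real_
  mrp
}

#' Standardize AUCs per drug
#'
#' Centers and scales each drug row to mean zero and unit standard deviation
#' across its observed samples; missing cells are preserved. Zero-variance
#' rows are set to zero with a warning.
#'
#' @param auc drugs x samples AUC matrix.
#' @return matrix of per-drug z-scores.
#' @export
standardize_auc <- function(auc) {
  stopifnot(is.matrix(auc))
  out <- auc
  for (i in seq_len(nrow(auc))) {
    x <- auc[i, ]
    ok <- is.finite(x)
    if (sum(ok) < 2L) stop_input("drug row %d has < 2 observed samples", i)
    s <- sd(x[ok])
    if (s == 0) {
      warning(sprintf("zero-variance drug row %s set to 0",
                      rownames(auc)[i] %||% i), call. = FALSE)
      out[i, ok] <- 0
    } else {
      out[i, ok] <- (x[ok] - mean(x[ok])) / s
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Drug-drug correlation matrix
#'
#' Pairwise-complete Pearson (or Spearman) correlations between drug rows;
#' cells backed by fewer than `min_pairs` complete sample pairs are `NA`.
#'
#' @param auc drugs x samples AUC matrix.
#' @param method `"pearson"` or `"spearman"`.
#' @param min_pairs minimum complete pairs per cell.
#' @return symmetric drugs x drugs correlation matrix with unit diagonal.
#' @export
drug_drug_correlation <- function(auc, method = c("pearson", "spearman"),
                                  min_pairs = 5L) {
  method <- match.arg(method)
  stopifnot(is.matrix(auc))
  r <- suppressWarnings(cor(t(auc), use = "pairwise.complete.obs", method = method))
  obs <- is.finite(auc)
  npairs <- obs %*% t(obs)
  r[npairs < min_pairs] <- NA_real_
  diag(r) <- 1
  r
}

upper_tri_vals <- function(m) m[upper.tri(m)]

#' Correlation of correlations between two studies
#'
#' The cross-study Pearson correlation of the two within-study drug-drug
#' correlation matrices, computed over the upper triangle restricted to the
#' drugs shared by both studies — a global measure of inter-study consistency.
#'
#' @param auc_a,auc_b drugs x samples AUC matrices from the two studies.
#' @param ... passed to [drug_drug_correlation()].
#' @return list with `r`, `p`, `n` (number of drug pairs used).
#' @export
correlation_of_correlations <- function(auc_a, auc_b, ...) {
  shared <- sort(intersect(rownames(auc_a), rownames(auc_b)))
  if (length(shared) < 3L) stop_input("need >= 3 shared drugs, got %d", length(shared))
  ra <- drug_drug_correlation(auc_a[shared, , drop = FALSE], ...)
  rb <- drug_drug_correlation(auc_b[shared, , drop = FALSE], ...)
  cor_with_p(upper_tri_vals(ra), upper_tri_vals(rb))
}

#' Per-drug cross-study concordance
#'
#' Represents each shared drug in each study by the vector of its correlations
#' to all other shared drugs, and correlates the two representations — a
#' per-drug measure of cross-study consistency.
#'
#' @param auc_a,auc_b drugs x samples AUC matrices.
#' @param ... passed to [drug_drug_correlation()].
#' @return named per-drug Pearson correlation vector over the shared drugs.
#' @export
cross_dataset_drug_concordance <- function(auc_a, auc_b, ...) {
  shared <- sort(intersect(rownames(auc_a), rownames(auc_b)))
  if (length(shared) < 3L) stop_input("need >= 3 shared drugs, got %d", length(shared))
  ra <- drug_drug_correlation(auc_a[shared, , drop = FALSE], ...)
  rb <- drug_drug_correlation(auc_b[shared, , drop = FALSE], ...)
  vapply(shared, function(dr) {
    va <- ra[dr, setdiff(shared, dr)]
    vb <- rb[dr, setdiff(shared, dr)]
    ok <- is.finite(va) & is.finite(vb)
    if (sum(ok) < 2L) return(NA_real_)
    suppressWarnings(cor(va[ok], vb[ok]))
  }, numeric(1))
}

#' Bootstrap stability of GRD under drug subsampling
#'
#' Repeatedly draws random drug subsets and correlates the subset GRD with
#' the full-panel GRD, quantifying how stable the general-response statistic
#' is to the drug panel composition.
#'
#' @param auc drugs x samples AUC matrix.
#' @param subset_size drugs per random subset.
#' @param n_boot number of random subsets.
#' @param seed integer seed.
#' @param min_drugs passed to [compute_grd()] for the subset GRD (default
#'   adapts to the subset size).
#' @return list with the per-draw correlations `r`, their `mean`, and the
#'   percentile `ci` (2.5/97.5%).
#' @export
grd_subset_stability <- function(auc, subset_size, n_boot = 100L, seed = 1L,
                                 min_drugs = max(1L, subset_size %/% 2L)) {
  stopifnot(is.matrix(auc))
  subset_size <- check_count(subset_size, "subset_size")
  if (subset_size > nrow(auc)) stop_input("subset_size exceeds number of drugs")
  full <- compute_grd(auc, min_drugs = min(10L, nrow(auc)))
  drugs <- rownames(auc) %||% as.character(seq_len(nrow(auc)))
  rs <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
    sub <- sample(drugs, subset_size)
    g <- compute_grd(auc, drug_subset = sub, min_drugs = min_drugs)
    ok <- is.finite(g) & is.finite(full)
    suppressWarnings(cor(g[ok], full[ok]))
  }, numeric(1)))
  list(r = rs, mean = mean(rs, na.rm = TRUE),
       ci = unname(quantile(rs, c(0.025, 0.975), na.rm = TRUE)))
}
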