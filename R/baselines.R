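#' Ridge regression with inner cross-validated penalty selection
#'
#' Closed-form ridge solve `(X'X + penalty I)^(-1) X'y` (via the singular
#' value decomposition) on centered `y`, with the penalty chosen by k-fold
#' inner cross-validation over a log-spaced grid. `X` is assumed standardized;
#' the intercept is the training mean of `y` and is unpenalized.
#'
#' @param X samples x predictors matrix (standardized).
#' @param y response vector.
#' @param penalty_grid positive penalties to search (default 13 log-spaced
#'   values over 1e-3..1e3).
#' @param n_folds_inner inner CV folds.
#' @param seed integer seed for the inner fold assignment.
#' @return object of class `ridge_fit`: `coef`, `intercept`, `penalty`,
#'   `cv_mse` (per-penalty mean squared error).
#' @export
fit_ridge <- function(X, y, penalty_grid = 10^seq(-3, 3, by = 0.5),
                      n_folds_inner = 10L, seed = 1L) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  if (any(penalty_grid < 0)) stop_input("penalties must be non-negative")
  penalty_grid <- sort(penalty_grid)
  n <- nrow(X)
  ridge_solve <- function(Xtr, ytr, lambdas) {
    ybar <- mean(ytr)
    sv <- svd(Xtr)
    uty <- crossprod(sv$u, ytr - ybar)
    lapply(lambdas, function(lam) {
      shrink <- sv$d / (sv$d^2 + lam)
      if (lam == 0 && any(sv$d < 1e-10)) return(NULL)  # singular at zero penalty
      list(coef = drop(sv$v %*% (shrink * uty)), intercept = ybar)
    })
  }
  folds <- with_seed(seed, sample(rep_len(seq_len(max(2L, min(n_folds_inner, n))), n)))
  k <- max(folds)
  mse <- matrix(NA_real_, k, length(penalty_grid))
  for (f in seq_len(k)) {
    tr <- folds != f
    fits <- ridge_solve(X[tr, , drop = FALSE], y[tr], penalty_grid)
    for (li in seq_along(penalty_grid)) {
      if (is.null(fits[[li]])) next
      pred <- drop(X[!tr, , drop = FALSE] %*% fits[[li]]$coef) + fits[[li]]$intercept
      mse[f, li] <- mean((y[!tr] - pred)^2)
    }
  }
  cv_mse <- colMeans(mse)
  best <- which.min(cv_mse)
  fit <- ridge_solve(X, y, penalty_grid[best])[[1]]
  structure(list(coef = setNames(fit$coef, colnames(X)),
                 intercept = fit$intercept, penalty = penalty_grid[best],
                 cv_mse = setNames(cv_mse, format(penalty_grid))),
            class = "ridge_fit")
}

#' @export
predict.ridge_fit <- function(object, newdata, ...) {
  stopifnot(is.matrix(newdata))
  drop(newdata %*% object$coef) + object$intercept
}

align_xy <- function(expr, auc, drug) {
  if (!drug %in% rownames(auc)) stop_input("drug '%s' absent from AUC matrix", drug)
  y <- auc[drug, ]
  shared <- intersect(rownames(expr), names(y)[is.finite(y)])
  if (length(shared) < 3L) stop_input("drug '%s': fewer than 3 samples with response", drug)
  list(x = expr[shared, , drop = FALSE], y = y[shared])
}

#' Cross-study prediction of one drug's response, with optional GRD covariate
#'
#' Trains a ridge model of drug `drug`'s response on the training study and
#' evaluates on the test study, under one of four covariate modes: gene
#' expression alone (`"expr"`), expression plus the test study's own observed
#' general response across drugs (`"expr_plus_observed_grd"`), expression
#' plus a GRD predicted from expression by a ridge model trained on the
#' training study (`"expr_plus_predicted_grd"`), or the GRD covariate alone
#' (`"grd_only"`). The evaluated drug is always excluded from both the
#' observed and predicted GRD (leave-drug-out), so its own responses never
#' leak into its covariate.
#'
#' @param train_expr,test_expr samples x genes standardized expression, same
#'   gene order.
#' @param train_auc,test_auc drugs x samples AUC matrices (columns matching
#'   the expression sample names).
#' @param drug drug id, present in both AUC matrices.
#' @param mode covariate mode (see above).
#' @param min_drugs minimum observed drugs per sample for GRD.
#' @param penalty_grid,seed passed to [fit_ridge()].
#' @return data frame with `drug_id`, `covariate_mode`, `r`, `p`, `n_test`.
#' @export
cross_study_evaluate <- function(train_expr, train_auc, test_expr, test_auc,
                                 drug,
                                 mode = c("expr", "expr_plus_predicted_grd",
                                          "expr_plus_observed_grd", "grd_only"),
                                 min_drugs = 10L,
                                 penalty_grid = 10^seq(-3, 3, by = 0.5),
                                 seed = 1L) {
  mode <- match.arg(mode)
  if (!identical(colnames(train_expr), colnames(test_expr)))
    stop_input("train and test expression are not on the same gene order")
  tr <- align_xy(train_expr, train_auc, drug)
  te <- align_xy(test_expr, test_auc, drug)

  grd_col <- function(expr, auc) {
    g <- compute_grd(auc, exclude_drug = drug, min_drugs = min_drugs)
    g <- g[rownames(expr)]
    if (any(!is.finite(g)))
      stop_input("GRD undefined for %d sample(s); lower min_drugs or filter samples",
                 sum(!is.finite(g)))
    zscore(g)
  }
  xtr <- tr$x; xte <- te$x
  if (mode %in% c("expr_plus_observed_grd", "grd_only")) {
    gtr <- grd_col(tr$x, train_auc)
    gte <- grd_col(te$x, test_auc)
  } else if (mode == "expr_plus_predicted_grd") {
    gtr <- grd_col(tr$x, train_auc)
    # expression-based GRD model trained on the training study (drug excluded
    # from its target), applied to the test study's expression
    grd_target <- compute_grd(train_auc, exclude_drug = drug, min_drugs = min_drugs)
    grd_target <- grd_target[is.finite(grd_target)]
    gsam <- intersect(rownames(train_expr), names(grd_target))
    grd_model <- fit_ridge(train_expr[gsam, , drop = FALSE],
                           zscore(grd_target[gsam]),
                           penalty_grid = penalty_grid, seed = seed)
    gte <- zscore(predict(grd_model, te$x))
  }
  if (mode == "grd_only") {
    xtr <- matrix(gtr, ncol = 1, dimnames = list(rownames(tr$x), "GRD"))
    xte <- matrix(gte, ncol = 1, dimnames = list(rownames(te$x), "GRD"))
  } else if (mode != "expr") {
    xtr <- cbind(tr$x, GRD = gtr)
    xte <- cbind(te$x, GRD = gte)
  }
  fit <- fit_ridge(xtr, tr$y, penalty_grid = penalty_grid, seed = seed)
  pred <- predict(fit, xte)
  ct <- cor_with_p(te$y, pred)
  data.frame(drug_id = drug, covariate_mode = mode, r = ct$r, p = ct$p,
             n_test = ct$n, stringsAsFactors = FALSE)
}

#' Paired one-sided comparison of two models' per-drug performance
#'
#' One-sided paired Wilcoxon signed-rank test of whether model B's per-drug
#' correlations exceed model A's. Zero differences are dropped per the usual
#' convention; the exact distribution is used for small samples without ties
#' and the normal approximation with continuity correction otherwise.
#'
#' @param results_a,results_b data frames with columns `drug_id` and `r`,
#'   covering the same drugs.
#' @return the one-sided p-value (small means B > A).
#' @export
compare_models <- function(results_a, results_b) {
  stopifnot(is.data.frame(results_a), is.data.frame(results_b))
  if (!setequal(results_a$drug_id, results_b$drug_id) ||
      nrow(results_a) != nrow(results_b))
    stop_input("the two result sets cover different drugs")
  a <- results_a$r[order(results_a$drug_id)]
  b <- results_b$r[order(results_b$drug_id)]
  d <- (b - a)[b != a]  # zero differences dropped per convention
  if (length(d) == 0L) return(1)
  n <- length(d)
  if (n <= 25L) {
    # exact null distribution of the signed-rank statistic, valid under tied
    # |differences| (average ranks doubled to stay integer)
    r2 <- as.integer(round(2 * rank(abs(d))))
    v <- sum(r2[d > 0])
    total <- sum(r2)
    dist <- numeric(total + 1L); dist[1] <- 1  # P(sum = s) * 2^n, s = 0..total
    for (r in r2) {
      shifted <- c(rep(0, r), dist[seq_len(total + 1L - r)])
      dist <- dist + shifted
    }
    sum(dist[(v + 1L):(total + 1L)]) / 2^n
  } else {
    suppressWarnings(
      wilcox.test(b, a, paired = TRUE, alternative = "greater",
                  exact = FALSE, correct = TRUE)$p.value)
  }
}

#' Rank drugs by GRD-independent predictability
#'
#' For each drug, the gain `delta_r = r(expression + GRD) - r(GRD only)`;
#' drugs whose expression signal adds most beyond the general response are
#' ranked first and flagged GRD-independent.
#'
#' @param results_expr_grd,results_grd_only data frames with `drug_id`, `r`.
#' @param delta_min gain above which a drug is flagged `grd_independent`.
#' @return data frame ordered by decreasing `delta_r`.
#' @export
drug_specificity <- function(results_expr_grd, results_grd_only,
                             delta_min = 0.1) {
  if (!setequal(results_expr_grd$drug_id, results_grd_only$drug_id))
    stop_input("mismatched drug lists")
  m <- merge(results_expr_grd[, c("drug_id", "r")],
             results_grd_only[, c("drug_id", "r")],
             by = "drug_id", suffixes = c("_expr_grd", "_grd_only"))
  m$delta_r <- m$r_expr_grd - m$r_grd_only
  m$grd_independent <- m$delta_r > delta_min
  m[order(-m$delta_r), , drop = FALSE]
}
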