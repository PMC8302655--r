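test_that("ridge closed forms hold on orthonormal designs", {
  set.seed(1)
  n <- 50
  q <- qr.Q(qr(matrix(rnorm(n * 5), n, 5))) * sqrt(n)  # X'X = n I
  colnames(q) <- paste0("g", 1:5)
  y <- drop(q %*% c(2, -1, 0.5, 0, 0)) + rnorm(n, 0, 0.3)
  ols <- drop(solve(crossprod(q), crossprod(q, y - mean(y))))
  for (lam in c(0.5, 5, 50)) {
    fit <- fit_ridge(q, y, penalty_grid = lam, n_folds_inner = 5, seed = 2)
    expect_equal(unname(fit$coef), unname(ols) * n / (n + lam), tolerance = 1e-8)
  }
  # penalty -> infinity limit: coefficients vanish
  big <- fit_ridge(q, y, penalty_grid = 1e9, n_folds_inner = 5, seed = 2)
  expect_lt(max(abs(big$coef)), 1e-4)
})

test_that("zero penalty on a full-rank design reproduces least squares", {
  set.seed(3)
  x <- matrix(rnorm(40 * 4), 40, 4, dimnames = list(NULL, paste0("g", 1:4)))
  x <- sweep(x, 2, colMeans(x))  # the solver's no-intercept convention
  y <- drop(x %*% c(1, 2, -1, 0)) + rnorm(40, 0, 0.2)
  fit <- fit_ridge(x, y, penalty_grid = c(0, 1), n_folds_inner = 5, seed = 4)
  ols <- coef(lm(y ~ x))
  pred_ols <- drop(cbind(1, x) %*% ols)
  expect_equal(predict(fit, x), pred_ols,
               tolerance = if (fit$penalty == 0) 1e-8 else 0.05)
  if (fit$penalty == 0)
    expect_equal(unname(fit$coef), unname(ols[-1]), tolerance = 1e-8)
})

test_that("closed-form ridge agrees with glmnet at a matched penalty", {
  skip_if_not_installed("glmnet")
  set.seed(5)
  n <- 60; p <- 10
  x <- scale(matrix(rnorm(n * p), n, p))
  attr(x, "scaled:center") <- attr(x, "scaled:scale") <- NULL
  colnames(x) <- paste0("g", 1:p)
  y <- drop(x %*% rnorm(p)) + rnorm(n)
  lam <- 3
  ours <- fit_ridge(x, y, penalty_grid = lam, n_folds_inner = 5, seed = 1)
  # glmnet's ridge objective is 1/(2n)||y - Xb||^2 + lambda/2 ||b||^2
  gn <- glmnet::glmnet(x, y, alpha = 0, lambda = lam / n,
                       standardize = FALSE, intercept = TRUE, thresh = 1e-12)
  expect_gt(cor(drop(coef(gn))[-1], unname(ours$coef)), 0.999)
})

test_that("cross-study evaluation separates covariate modes as designed", {
  pair <- make_grd_pair(seed = 3)
  # responses are pure general-response structure: GRD-only should match
  # expr+observed-GRD, both clearly predictive
  r_grd <- cross_study_evaluate(pair[[1]]$expr, pair[[1]]$auc,
                                pair[[2]]$expr, pair[[2]]$auc,
                                drug = "drug01", mode = "grd_only",
                                min_drugs = 5, seed = 1)
  r_both <- cross_study_evaluate(pair[[1]]$expr, pair[[1]]$auc,
                                 pair[[2]]$expr, pair[[2]]$auc,
                                 drug = "drug01", mode = "expr_plus_observed_grd",
                                 min_drugs = 5, seed = 1)
  expect_gt(r_grd$r, 0.5)
  expect_gt(r_both$r, 0.5)
  expect_lt(abs(r_grd$r - r_both$r), 0.35)
  expect_error(cross_study_evaluate(pair[[1]]$expr, pair[[1]]$auc,
                                    pair[[2]]$expr, pair[[2]]$auc,
                                    drug = "nope"), "absent")
})

test_that("a drug-specific signal orthogonal to GRD needs expression", {
  set.seed(6)
  n1 <- 90; n2 <- 70; g <- 60
  beta <- c(rep(1.5, 3), rep(0, g - 3))
  mk <- function(n) {
    x <- matrix(rnorm(n * g), n, g,
                dimnames = list(sprintf("s%03d", 1:n), sprintf("g%02d", 1:g)))
    y <- drop(x %*% beta) + rnorm(n, 0, 1)
    # 11 drugs: the first carries the expression signal, the rest pure noise
    auc <- rbind(matrix(y / 10 + 0.5, 1), matrix(rnorm(10 * n, 0.5, 0.1), 10))
    dimnames(auc) <- list(sprintf("drug%02d", 1:11), rownames(x))
    list(expr = x, auc = auc)
  }
  a <- mk(n1); b <- mk(n2)
  r_expr <- cross_study_evaluate(a$expr, a$auc, b$expr, b$auc, "drug01",
                                 mode = "expr", min_drugs = 5, seed = 1)
  r_grd <- cross_study_evaluate(a$expr, a$auc, b$expr, b$auc, "drug01",
                                mode = "grd_only", min_drugs = 5, seed = 1)
  expect_gt(r_expr$r, 0.6)
  expect_lt(abs(r_grd$r), 0.3)
  spec_tab <- drug_specificity(
    data.frame(drug_id = c("drug01", "drug02"), r = c(r_expr$r, 0.1)),
    data.frame(drug_id = c("drug01", "drug02"), r = c(r_grd$r, 0.1)))
  expect_identical(spec_tab$drug_id[1], "drug01")
  expect_true(spec_tab$grd_independent[1])
  expect_equal(spec_tab$delta_r[spec_tab$drug_id == "drug02"], 0)
})

test_that("identical training and test studies are almost perfectly predicted", {
  set.seed(7)
  n <- 80; g <- 40
  x <- matrix(rnorm(n * g), n, g,
              dimnames = list(sprintf("s%03d", 1:n), sprintf("g%02d", 1:g)))
  y <- drop(x %*% c(rep(1, 4), rep(0, g - 4)))   # no noise
  auc <- rbind(matrix(y, 1), matrix(rnorm(9 * n, 0, 1), 9))
  dimnames(auc) <- list(sprintf("drug%02d", 1:10), rownames(x))
  r <- cross_study_evaluate(x, auc, x, auc, "drug01", mode = "expr",
                            min_drugs = 5, seed = 1)
  expect_gt(r$r, 0.99)
})

test_that("paired signed-rank comparison matches its exact distribution", {
  a <- data.frame(drug_id = sprintf("d%02d", 1:10), r = seq(0.1, 0.55, by = 0.05))
  b <- a; b$r <- a$r + 0.1
  expect_equal(compare_models(a, b), 1 / 1024, tolerance = 1e-12)
  expect_equal(compare_models(a, a), 1)
  # swapping the arguments lands in the complementary tail
  p_fwd <- compare_models(a, b)
  p_rev <- compare_models(b, a)
  expect_gt(p_rev, 0.999)
  expect_lt(p_fwd + 1e-6, p_rev)
  expect_error(compare_models(a, b[1:5, ]), "different drugs")
})
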