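# Unit tests for the hierarchical sampler run on small problems so the whole
# file stays fast; full-scale recovery is exercised in test-acceptance.R.

quiet_fit <- function(...) suppressWarnings(fit_bmsr(...))

small_null <- function(seed = 1, n = 40, g = 15) {
  set.seed(seed)
  x <- matrix(rnorm(n * g), n, g,
              dimnames = list(sprintf("s%02d", 1:n), sprintf("g%02d", 1:g)))
  source_dataset(apply(x, 2, function(v) (v - mean(v)) / sd(v)),
                 setNames(rep(0, n), rownames(x)), dataset_id = "null")
}

test_that("null responses shrink every shared coefficient to zero", {
  src <- list(small_null(1), small_null(2, n = 30))
  src[[2]]$dataset_id <- "null2"
  fit <- quiet_fit(src, bmsr_spec(p0 = 3), mcmc_config(seed = 11))
  bm <- colMeans(fit$beta)
  expect_lt(max(abs(bm)), 0.05)
  ci <- apply(fit$beta, 2, quantile, c(0.025, 0.975))
  covers <- ci[1, ] <= 0 & ci[2, ] >= 0
  expect_gte(mean(covers), 0.9)
})

test_that("a strong single-gene signal matches the least-squares oracle", {
  set.seed(3)
  n <- 60
  x <- qr.Q(qr(matrix(rnorm(n * 2), n, 2))) * sqrt(n)  # orthonormal-ish columns
  colnames(x) <- c("gSig", "gNull")
  rownames(x) <- sprintf("s%02d", 1:n)
  y <- setNames(drop(x %*% c(1, 0)) + rnorm(n, 0, 0.3), rownames(x))
  src <- list(source_dataset(x, y, dataset_id = "one"))
  fit <- quiet_fit(src, bmsr_spec(p0 = 1), mcmc_config(seed = 4))
  ols <- coef(lm(y ~ x - 1))
  # the study-level coefficients carry the likelihood information; the shared
  # vector is attenuated by the offset channel when only one study is present
  bsrc <- colMeans(fit$beta_source[, , 1])
  mcse <- sd(fit$beta_source[, "gSig", 1]) / sqrt(100)  # conservative ESS
  expect_lt(abs(bsrc["gSig"] - ols[1]), max(3 * mcse, 0.05))
  expect_lt(abs(bsrc["gNull"]), abs(ols[2]) + 0.02)
  expect_lt(abs(colMeans(fit$beta)["gNull"]), 0.02)
})

test_that("scale draws are positive and tau0 matches its formula per draw", {
  src <- list(small_null(5, n = 25, g = 8), small_null(6, n = 20, g = 8))
  src[[2]]$dataset_id <- "b"
  fit <- quiet_fit(src, bmsr_spec(p0 = 2), mcmc_config(seed = 2,
                                                       n_samples = 100,
                                                       n_burnin = 200))
  expect_true(all(fit$sigma > 0))
  expect_true(all(fit$lambda > 0))
  expect_true(all(fit$tau > 0))
  g <- length(fit$gene_ids)
  nd <- c(25, 20)
  tau0_manual <- (2 / (g - 2)) * (fit$sigma[, 1] / sqrt(nd[1]) +
                                  fit$sigma[, 2] / sqrt(nd[2]))
  expect_lt(max(abs(tau0_manual - fit$tau0)), 1e-10)
  expect_equal(nrow(fit$beta), 100 * 2)
})

test_that("shrinkage strengthens as the prior active-gene count decreases", {
  src <- list(small_null(7, n = 40, g = 20))
  f_tight <- quiet_fit(src, bmsr_spec(p0 = 2), mcmc_config(seed = 3))
  f_loose <- quiet_fit(src, bmsr_spec(p0 = 18), mcmc_config(seed = 3))
  expect_lt(mean(abs(colMeans(f_tight$beta))), mean(abs(colMeans(f_loose$beta))))
})

test_that("per-source coefficients stay close to the shared vector", {
  sim <- simulate_multisource(sim_config(n_samples = c(50, 40), n_genes = 60,
                                         n_active = 4, target_r2 = 0.6, seed = 8))
  fit <- quiet_fit(harmonize_sim(sim), bmsr_spec(p0 = 4), mcmc_config(seed = 5))
  for (d in 1:2) {
    gap <- mean(abs(colMeans(fit$beta_source[, , d]) - colMeans(fit$beta)))
    expect_lt(gap, 1.0)
  }
})

test_that("with weak global shrinkage a well-conditioned fit approaches ridge", {
  set.seed(9)
  n <- 80; g <- 8
  x <- matrix(rnorm(n * g), n, g, dimnames = list(NULL, sprintf("g%d", 1:g)))
  x <- apply(x, 2, function(v) (v - mean(v)) / sd(v))
  rownames(x) <- sprintf("s%02d", 1:n)
  beta_true <- c(1, -0.8, 0.6, -0.4, 0.3, 0, 0, 0)
  y <- drop(x %*% beta_true) + rnorm(n, 0, 0.5)
  y <- setNames((y - mean(y)) / sd(y), rownames(x))
  src <- list(source_dataset(x, y, dataset_id = "a"))
  fit <- quiet_fit(src, bmsr_spec(p0 = 7), mcmc_config(seed = 6))
  ridge <- solve(crossprod(x) + 1 * diag(g), crossprod(x, y))
  expect_gte(cor(colMeans(fit$beta), drop(ridge)), 0.95)
})

test_that("prediction is a deterministic linear read-out of the posterior", {
  sim <- simulate_multisource(sim_config(n_samples = c(40, 30), n_genes = 30,
                                         n_active = 3, target_r2 = 0.7, seed = 10))
  src <- harmonize_sim(sim)
  fit <- quiet_fit(src, bmsr_spec(p0 = 3), mcmc_config(seed = 7))
  x0 <- matrix(0, 5, 30, dimnames = list(paste0("z", 1:5),
                                         colnames(src[[1]]$expression)))
  expect_equal(unname(predict(fit, x0)), rep(0, 5))
  p1 <- predict(fit, src[[1]]$expression, source = "source1")
  expect_identical(p1, predict(fit, src[[1]]$expression, source = "source1"))
  expect_error(predict(fit, src[[1]]$expression, source = "nope"), "unknown source")
  # in-sample correlation beats held-out correlation
  r_in <- cor(src[[1]]$response, p1)
  x_new <- matrix(rnorm(200 * 30), 200, 30,
                  dimnames = list(NULL, colnames(src[[1]]$expression)))
  set.seed(99)
  y_new <- drop(x_new %*% sim$truth$beta_source[, 1]) + rnorm(200, 0, sim$truth$noise_sd[1])
  r_out <- cor(y_new, predict(fit, x_new, source = "source1"))
  expect_gte(r_in, r_out - 0.02)
  pi <- predict(fit, x0[1:2, ], interval = TRUE)
  expect_true(all(pi$lwr <= pi$fit & pi$fit <= pi$upr))
})

test_that("cross-validation folds are stratified, reproducible, and scored", {
  sim <- simulate_multisource(sim_config(n_samples = c(40, 25), n_genes = 25,
                                         n_active = 3, noise_sd = 0.05, seed = 12))
  src <- harmonize_sim(sim)
  cv1 <- suppressWarnings(crossvalidate(src, bmsr_spec(p0 = 3),
                                        mcmc_config(seed = 3, n_samples = 150,
                                                    n_burnin = 250), k = 5, seed = 21))
  cv2 <- suppressWarnings(crossvalidate(src, bmsr_spec(p0 = 3),
                                        mcmc_config(seed = 3, n_samples = 150,
                                                    n_burnin = 250), k = 5, seed = 21))
  expect_identical(cv1$folds, cv2$folds)
  expect_equal(nrow(cv1$folds), 5L)
  expect_equal(sum(cv1$folds$n_test), 65)
  # near-noiseless simulation predicts almost perfectly
  expect_gt(cv1$median_r, 0.9)
  expect_error(crossvalidate(src, k = 30), "< 3 test samples")
})

test_that("Stouffer combination follows its closed forms", {
  both <- stouffer_combine(c(1.96, 1.96))
  expect_equal(both$z, 2.772, tolerance = 1e-3)
  expect_equal(both$p, 0.00556, tolerance = 1e-2)
  expect_equal(stouffer_combine(c(2, -2))$z, 0)
  expect_equal(stouffer_combine(c(2, -2))$p, 1)
})

test_that("biomarker prioritization selects concordant extremal genes", {
  sim <- simulate_multisource(sim_config(n_samples = c(60, 40), n_genes = 80,
                                         n_active = 4, target_r2 = 0.8, seed = 14))
  src <- harmonize_sim(sim)
  fit <- quiet_fit(src, bmsr_spec(p0 = 4), mcmc_config(seed = 8))
  tab <- prioritize_biomarkers(fit, p_threshold = 0.01)
  act_ids <- colnames(sim$sources[[1]]$expression)[sim$truth$active]
  expect_true(all(act_ids %in% tab$gene_id[tab$selected]))
  false_hits <- setdiff(tab$gene_id[tab$selected], act_ids)
  expect_lte(length(false_hits), 2)
  # closed-form check of the combination on the table itself
  manual <- rowSums(tab[, startsWith(names(tab), "z_")]) / sqrt(2)
  expect_equal(tab$combined_z, unname(manual), tolerance = 1e-12)
  single <- quiet_fit(src[1], bmsr_spec(p0 = 4), mcmc_config(seed = 8))
  expect_error(prioritize_biomarkers(single), ">= 2 sources")
})
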