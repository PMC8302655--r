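# Independent oracles used by the tests. These are deliberately written as
# plain, step-by-step computations (loops, brute force) so they share no code
# with the package implementations they check.

# Harmonize a simulate_multisource() result into fit-ready sources.
harmonize_sim <- function(sim) {
  harmonize_sources(lapply(sim$sources, function(s) t(s$expression)),
                    lapply(sim$sources, `[[`, "response"))
}

# Brute-force log-logistic RSS over a parameter grid.
ll_grid_best_rss <- function(x, y, b_grid, c_grid, d_grid, e_grid) {
  best <- Inf
  for (b in b_grid) for (cc in c_grid) for (d in d_grid) for (e in e_grid) {
    pred <- cc + (d - cc) / (1 + exp(b * (log(x) - log(e))))
    rss <- sum((pred - y)^2)
    if (rss < best) best <- rss
  }
  best
}

# Dense-trapezoid AUC oracle on the fitted curve, clipped to [0, 100].
trapezoid_auc <- function(fit, conc_range, n = 1e5) {
  t <- seq(log10(conc_range[1]), log10(conc_range[2]), length.out = n)
  f <- fit$c + (fit$d - fit$c) / (1 + exp(fit$b * (log(10^t) - log(fit$e))))
  f <- pmin(pmax(f, 0), 100)
  sum((f[-1] + f[-n]) / 2 * diff(t)) / (100 * (t[n] - t[1]))
}

# Step-by-step single-sample enrichment oracle following the kernel-CDF /
# symmetric-rank / weighted-random-walk recipe, all in explicit loops.
gsva_oracle <- function(expr, set_genes, tau = 1, bw_factor = 4) {
  p <- nrow(expr); n <- ncol(expr)
  z <- matrix(0, p, n)
  for (i in 1:p) {
    h <- sd(expr[i, ]) / bw_factor
    if (!is.finite(h) || h <= 0) h <- 1e-8
    for (j in 1:n) {
      acc <- 0
      for (k in 1:n) acc <- acc + pnorm((expr[i, j] - expr[i, k]) / h)
      z[i, j] <- acc / n
    }
  }
  in_set <- rownames(expr) %in% set_genes
  m <- sum(in_set)
  scores <- numeric(n)
  for (j in 1:n) {
    r <- rank(z[, j], ties.method = "average")
    ord <- order(z[, j], decreasing = TRUE)
    num <- 0; den <- 0
    for (g in which(in_set)) den <- den + abs(r[g] - p / 2)^tau
    walk <- numeric(p); level <- 0
    for (k in 1:p) {
      g <- ord[k]
      if (in_set[g]) level <- level + abs(r[g] - p / 2)^tau / den
      else level <- level - 1 / (p - m)
      walk[k] <- level
    }
    scores[j] <- max(c(0, walk)) + min(c(0, walk))
  }
  setNames(scores, colnames(expr))
}

# Cross-study pair with a shared expression-predictable general-response
# factor: AUC(s, drug) = 0.5 + g_s + m_drug + eps, with g_s proportional to a
# sparse linear signal in that study's expression.
make_grd_pair <- function(n_drugs = 20L, grd_sd = 0.1, drug_sd = 0.05,
                          eps_sd = 0.05, expr_r2 = 0.5, seed = 1L) {
  sim <- simulate_multisource(sim_config(
    n_sources = 2L, n_samples = c(100L, 80L), n_genes = 150L, n_active = 5L,
    effect_sd = 1, source_perturb_sd = 0.05, block_size = 10L, block_rho = 0.3,
    noise_sd = 1, seed = seed))
  set.seed(seed + 1000L)
  out <- list()
  for (d in 1:2) {
    x <- sim$sources[[d]]$expression
    mu <- drop(x %*% sim$truth$beta_source[, d])
    lat <- sqrt(expr_r2) * scale(mu)[, 1] + sqrt(1 - expr_r2) * rnorm(nrow(x))
    g <- grd_sd * lat
    m <- rnorm(n_drugs, 0, drug_sd)
    auc <- 0.5 + outer(m, g, `+`) +
      matrix(rnorm(n_drugs * nrow(x), 0, eps_sd), n_drugs)
    auc <- pmin(pmax(auc, 0), 1)
    dimnames(auc) <- list(sprintf("drug%02d", 1:n_drugs), rownames(x))
    xs <- apply(x, 2, function(v) (v - mean(v)) / sd(v))
    rownames(xs) <- rownames(x)
    out[[d]] <- list(expr = xs, auc = auc, g = setNames(g, rownames(x)))
  }
  out
}
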