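#' Model specification for multi-source regression
#'
#' @param p0 a-priori number of active genes; anchors the global shrinkage
#'   scale `tau0 = p0/(G - p0) * sum_d sigma_d / sqrt(N_d)`.
#' @param source_perturb_scale scale of the per-study coefficient prior
#'   `beta^(d) ~ N(beta, scale)`.
#' @param interpret_scale_as whether `source_perturb_scale` and the task
#'   weight prior scale are standard deviations (`"sd"`, the probabilistic-
#'   programming convention) or variances (`"variance"`).
#' @param noise_prior `c(alpha, beta)` of the inverse-gamma prior on the
#'   per-study noise standard deviation.
#' @param task_weight_prior `c(location, scale)` of the normal prior on the
#'   per-drug weight in the multi-task model.
#' @param tau0_grouping `"per_source"` scales each study's noise by its own
#'   `sqrt(N_d)`; `"pooled"` divides the summed noise by the square root of
#'   the total sample count.
#' @param source_coupling how the per-study offset prior scale is applied.
#'   `"scaled"` (default) rides on each coefficient's own shrinkage scale,
#'   `beta_g^(d) ~ N(beta_g, (scale * lambda_g * tau)^2)`, so offsets of
#'   irrelevant genes are shrunk along with their coefficients and studies
#'   share both the active set and the direction of effects. `"fixed"` uses
#'   the literal constant scale `beta^(d) ~ N(beta, scale^2)`; note that with
#'   many genes this gives each study an essentially unregularized dense
#'   channel that can absorb the signal and decouple the studies.
#' @param slab_scale optional regularized-horseshoe slab scale; `NULL` (the
#'   default) uses the plain horseshoe.
#' @return object of class `bmsr_spec`.
#' @export
bmsr_spec <- function(p0 = 10, source_perturb_scale = 0.5,
                      interpret_scale_as = c("sd", "variance"),
                      noise_prior = c(1, 1), task_weight_prior = c(0.5, 0.5),
                      tau0_grouping = c("per_source", "pooled"),
                      source_coupling = c("scaled", "fixed"),
                      slab_scale = NULL) {
  interpret_scale_as <- match.arg(interpret_scale_as)
  tau0_grouping <- match.arg(tau0_grouping)
  source_coupling <- match.arg(source_coupling)
  check_positive(p0, "p0", strict = TRUE)
  check_positive(source_perturb_scale, "source_perturb_scale", strict = TRUE)
  structure(list(p0 = p0, source_perturb_scale = source_perturb_scale,
                 interpret_scale_as = interpret_scale_as,
                 noise_prior = noise_prior, task_weight_prior = task_weight_prior,
                 tau0_grouping = tau0_grouping, source_coupling = source_coupling,
                 slab_scale = slab_scale),
            class = "bmsr_spec")
}

#' MCMC configuration
#'
#' @param n_samples posterior draws per chain.
#' @param n_burnin warmup (adaptation) iterations per chain, discarded.
#' @param n_chains number of chains.
#' @param seed integer seed; chain `c` uses `seed + c - 1`.
#' @param target_accept dual-averaging acceptance target.
#' @param max_treedepth maximum doublings per NUTS iteration.
#' @return object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_samples = 500L, n_burnin = 500L, n_chains = 2L,
                        seed = 1L, target_accept = 0.95, max_treedepth = 9L) {
  structure(list(n_samples = check_count(n_samples, "n_samples"),
                 n_burnin = check_count(n_burnin, "n_burnin"),
                 n_chains = check_count(n_chains, "n_chains"),
                 seed = check_count(seed, "seed", min = 0L),
                 target_accept = target_accept,
                 max_treedepth = check_count(max_treedepth, "max_treedepth")),
            class = "mcmc_config")
}

check_harmonized <- function(sources) {
  if (length(sources) < 1L) stop_input("need at least one source")
  genes <- colnames(sources[[1]]$expression)
  for (s in sources) {
    if (!inherits(s, "source_dataset")) stop_input("sources must be source_dataset objects")
    if (!identical(colnames(s$expression), genes))
      stop_input("sources are not harmonized: gene order differs")
  }
  genes
}

# Assemble the C++ model state shared by fit_bmsr and fit_bmsmtr.
# `tasks` is a list of list(d, drug, rows, y) on the standardized scale.
build_model <- function(sources, tasks, n_drugs, spec, w_free) {
  genes <- check_harmonized(sources)
  g <- length(genes)
  if (spec$p0 >= g) stop_input("p0 must be < number of genes (%d)", g)
  sd_mode <- spec$interpret_scale_as == "sd"
  s0 <- if (sd_mode) spec$source_perturb_scale else sqrt(spec$source_perturb_scale)
  vw <- if (sd_mode) spec$task_weight_prior[2]^2 else spec$task_weight_prior[2]
  data <- list(
    X = lapply(sources, `[[`, "expression"),
    tasks = tasks, m = as.integer(n_drugs), s0 = s0, vw = vw,
    w_loc = spec$task_weight_prior[1], p0 = spec$p0,
    a_sig = spec$noise_prior[1], b_sig = spec$noise_prior[2],
    slab = if (is.null(spec$slab_scale)) -1 else spec$slab_scale,
    grouping = if (spec$tau0_grouping == "per_source") 0L else 1L,
    coupling = if (identical(spec$source_coupling, "fixed")) 1L else 0L,
    Nd = vapply(sources, function(s) nrow(s$expression), numeric(1)),
    w_free = isTRUE(w_free))
  list(ptr = bmsr_model_build(data), genes = genes, g = g,
       D = length(sources), m = as.integer(n_drugs), data = data)
}

run_sampler <- function(model, mcmc, drug_ids = NULL, source_ids = NULL) {
  ptr <- model$ptr
  P <- bmsr_model_npar(ptr)
  g <- model$g; D <- model$D; m <- model$m
  w_free <- model$data$w_free
  lp_grad <- function(theta) bmsr_lp_grad(ptr, theta)

  n_iter <- mcmc$n_samples
  chains <- vector("list", mcmc$n_chains)
  for (ch in seq_len(mcmc$n_chains)) {
    theta0 <- with_seed(mcmc$seed + ch - 1L, {
      th <- rnorm(P, 0, 0.1)
      off <- g * (1 + D)
      th[off + seq_len(g)] <- rnorm(g, 0, 0.3)      # log lambda
      th[off + g + 1L] <- log(0.01)                  # log tau: start well shrunk
      th[off + g + 2L - 1L + seq_len(D)] <- rnorm(D, 0, 0.1)  # log sigma
      if (w_free) th[(P - m + 1L):P] <- model$data$w_loc + rnorm(m, 0, 0.05)
      th
    })
    chains[[ch]] <- nuts_chain(lp_grad, theta0, mcmc$n_burnin, n_iter,
                               seed = mcmc$seed + ch - 1L,
                               max_treedepth = mcmc$max_treedepth,
                               target_accept = mcmc$target_accept)
  }

  # constrained draws, per chain then pooled
  n_tot <- n_iter * mcmc$n_chains
  beta <- matrix(NA_real_, n_tot, g)
  beta_source <- array(NA_real_, c(n_tot, g, D))
  lambda <- matrix(NA_real_, n_tot, g)
  tau <- numeric(n_tot); tau0 <- numeric(n_tot)
  sigma <- matrix(NA_real_, n_tot, D)
  w <- matrix(NA_real_, n_tot, m)
  chain_id <- rep(seq_len(mcmc$n_chains), each = n_iter)
  for (ch in seq_len(mcmc$n_chains)) {
    for (i in seq_len(n_iter)) {
      k <- (ch - 1L) * n_iter + i
      cs <- bmsr_constrain(ptr, chains[[ch]]$draws[i, ])
      beta[k, ] <- cs$beta
      beta_source[k, , ] <- cs$beta_source
      lambda[k, ] <- cs$lambda
      tau[k] <- cs$tau; tau0[k] <- cs$tau0
      sigma[k, ] <- cs$sigma
      w[k, ] <- cs$w
    }
  }
  colnames(beta) <- model$genes
  dimnames(beta_source) <- list(NULL, model$genes, source_ids)
  if (!is.null(drug_ids)) colnames(w) <- drug_ids
  if (!is.null(source_ids)) colnames(sigma) <- source_ids

  # diagnostics on the shared coefficients and global scale
  rhat_beta <- vapply(seq_len(g), function(j)
    split_rhat(matrix(beta[, j], n_iter, mcmc$n_chains)), numeric(1))
  rhat_tau <- split_rhat(matrix(tau, n_iter, mcmc$n_chains))
  n_div <- sum(vapply(chains, `[[`, integer(1), "n_divergent"))
  div_frac <- n_div / (mcmc$n_chains * (mcmc$n_burnin + n_iter))
  ess_tau <- ess_basic(matrix(tau, n_iter, mcmc$n_chains))
  warn <- FALSE
  if (div_frac > 0.1 || (is.finite(max(rhat_beta, na.rm = TRUE)) &&
                         max(rhat_beta, na.rm = TRUE) > 1.1)) {
    warn <- TRUE
    warning(sprintf(paste0("sampler diagnostics outside recommended bounds ",
                           "(divergent fraction %.3f, max shared-beta Rhat %.3f); ",
                           "interpret the posterior with care"),
                    div_frac, max(rhat_beta, na.rm = TRUE)), call. = FALSE)
  }
  structure(list(
    beta = beta, beta_source = beta_source, lambda = lambda, tau = tau,
    tau0 = tau0, sigma = sigma, w = if (w_free) w else NULL,
    chain_id = chain_id, gene_ids = model$genes, source_ids = source_ids,
    drug_ids = drug_ids, n_chains = mcmc$n_chains, n_samples = n_iter,
    diagnostics = list(rhat_beta = rhat_beta, rhat_tau = rhat_tau,
                       ess_tau = ess_tau, n_divergent = n_div,
                       divergent_fraction = div_frac,
                       step_size = vapply(chains, `[[`, numeric(1), "step_size"),
                       treedepth_mean = mean(unlist(lapply(chains, `[[`, "treedepth"))),
                       warning = warn)),
    class = "bmsr_posterior")
}

#' Fit the Bayesian multi-source regression (BMSR)
#'
#' Jointly regresses one response per study on a common gene space. Each
#' study's coefficient vector is a Gaussian perturbation of a shared vector,
#' and the shared vector carries a Finnish horseshoe prior whose global scale
#' is anchored to an a-priori number of active genes. Inference is by the
#' package's No-U-Turn Hamiltonian Monte Carlo sampler on a non-centered
#' parameterization.
#'
#' @param sources list of harmonized [source_dataset()] objects (identical
#'   gene order; standardized expression and response — see
#'   [harmonize_sources()]).
#' @param spec a [bmsr_spec()].
#' @param mcmc an [mcmc_config()].
#' @return a `bmsr_posterior`: pooled draws of the shared coefficients
#'   (`beta`), per-study coefficients (`beta_source`), local/global shrinkage
#'   scales (`lambda`, `tau`, `tau0`), noise sds (`sigma`), plus convergence
#'   diagnostics (split-Rhat, effective sample size, divergence counts).
#' @export
fit_bmsr <- function(sources, spec = bmsr_spec(), mcmc = mcmc_config()) {
  genes <- check_harmonized(sources)
  tasks <- lapply(seq_along(sources), function(d) {
    y <- sources[[d]]$response
    if (any(!is.finite(y))) stop_input("source %d has non-finite responses", d)
    if (length(y) != nrow(sources[[d]]$expression))
      stop_input("source %d: response/expression dimension mismatch", d)
    list(d = d, drug = 1L, rows = seq_along(y), y = unname(y))
  })
  model <- build_model(sources, tasks, n_drugs = 1L, spec = spec, w_free = FALSE)
  run_sampler(model, mcmc,
              source_ids = vapply(sources, `[[`, "", "dataset_id"))
}

#' Fit the Bayesian multi-source multi-task regression (BMSMTR)
#'
#' Extends [fit_bmsr()] to a set of drugs assayed in every study: drug `i`'s
#' response in study `d` is modeled as `X^(d) beta^(d) w^(i)` with a scalar
#' weight `w^(i) ~ N(0.5, 0.5)` per drug, so the shared coefficients describe
#' the biomarker profile common to the drug set.
#'
#' @param sources list of harmonized [source_dataset()] objects; their
#'   `response` slots are ignored in favor of `responses_per_drug`.
#' @param responses_per_drug list (one element per source) of named lists
#'   mapping drug id to a named per-sample response vector; samples missing a
#'   drug's response are dropped for that drug only. Responses across drugs
#'   must be on a comparable scale (the per-drug weight captures relative
#'   response magnitude).
#' @param spec,mcmc as in [fit_bmsr()].
#' @param allow_single permit a single-drug set, in which case the weight is
#'   fixed at 1 and the model reduces exactly to [fit_bmsr()].
#' @return a `bmsr_posterior` additionally carrying per-drug weight draws `w`.
#' @export
fit_bmsmtr <- function(sources, responses_per_drug, spec = bmsr_spec(),
                       mcmc = mcmc_config(), allow_single = FALSE) {
  genes <- check_harmonized(sources)
  if (length(responses_per_drug) != length(sources))
    stop_input("responses_per_drug must have one element per source")
  drug_ids <- Reduce(intersect, lapply(responses_per_drug, names))
  if (length(drug_ids) < 2L && !allow_single)
    stop_input("fewer than 2 drugs shared by all sources; use fit_bmsr for a single response")
  if (length(drug_ids) < 1L) stop_input("no drug shared by all sources")
  tasks <- list()
  for (d in seq_along(sources)) {
    samp <- rownames(sources[[d]]$expression)
    for (i in seq_along(drug_ids)) {
      y <- responses_per_drug[[d]][[drug_ids[i]]]
      if (is.null(names(y))) {
        if (length(y) != length(samp))
          stop_input("source %d drug %s: unnamed response of wrong length", d, drug_ids[i])
        names(y) <- samp
      }
      y <- y[names(y) %in% samp]
      y <- y[is.finite(y)]
      if (length(y) < 3L)
        stop_input("source %d drug %s: fewer than 3 samples", d, drug_ids[i])
      tasks[[length(tasks) + 1L]] <-
        list(d = d, drug = i, rows = match(names(y), samp), y = unname(y))
    }
  }
  model <- build_model(sources, tasks, n_drugs = length(drug_ids), spec = spec,
                       w_free = length(drug_ids) >= 2L)
  run_sampler(model, mcmc, drug_ids = drug_ids,
              source_ids = vapply(sources, `[[`, "", "dataset_id"))
}

#' @export
print.bmsr_posterior <- function(x, ...) {
  cat(sprintf("bmsr_posterior: %d genes, %d sources, %d draws (%d chains)\n",
              length(x$gene_ids), dim(x$beta_source)[3],
              nrow(x$beta), x$n_chains))
  d <- x$diagnostics
  cat(sprintf("  max Rhat(beta) = %.3f, Rhat(tau) = %.3f, divergent = %d (%.1f%%)\n",
              max(d$rhat_beta, na.rm = TRUE), d$rhat_tau, d$n_divergent,
              100 * d$divergent_fraction))
  if (!is.null(x$w))
    cat(sprintf("  posterior mean drug weights: %s\n",
                paste(sprintf("%s=%.2f", colnames(x$w), colMeans(x$w)),
                      collapse = ", ")))
  invisible(x)
}

#' Predict responses from a fitted posterior
#'
#' Posterior-mean linear prediction `X %*% E[beta]`, using a named study's
#' coefficients or the shared vector. For multi-task fits a drug id may be
#' given to scale by that drug's posterior-mean weight.
#'
#' @param object a `bmsr_posterior`.
#' @param newdata samples x genes matrix in the training gene order.
#' @param source study id, or `"shared"` for the shared coefficients.
#' @param drug optional drug id (multi-task fits only).
#' @param interval if `TRUE`, also return 2.5/97.5% posterior predictive-mean
#'   quantiles per sample.
#' @param ... unused.
#' @return numeric vector of predictions (or a data frame when
#'   `interval = TRUE`).
#' @export
predict.bmsr_posterior <- function(object, newdata, source = "shared",
                                   drug = NULL, interval = FALSE, ...) {
  stopifnot(is.matrix(newdata))
  if (!is.null(colnames(newdata)) &&
      !identical(colnames(newdata), object$gene_ids))
    stop_input("newdata gene columns do not match the training gene order")
  if (ncol(newdata) != length(object$gene_ids))
    stop_input("newdata has %d genes; model has %d", ncol(newdata),
               length(object$gene_ids))
  if (identical(source, "shared")) {
    draws <- object$beta
  } else {
    d <- match(source, object$source_ids)
    if (is.na(d)) stop_input("unknown source id '%s'", source)
    draws <- object$beta_source[, , d]
  }
  wfac <- 1
  if (!is.null(drug)) {
    if (is.null(object$w)) stop_input("posterior has no drug weights")
    i <- match(drug, colnames(object$w))
    if (is.na(i)) stop_input("unknown drug id '%s'", drug)
    wfac <- object$w[, i]
  }
  coef_mean <- colMeans(draws * wfac)
  yhat <- drop(newdata %*% coef_mean)
  names(yhat) <- rownames(newdata)
  if (!interval) return(yhat)
  pred_draws <- newdata %*% t(draws * wfac)   # samples x draws
  qs <- t(apply(pred_draws, 1L, quantile, c(0.025, 0.975)))
  data.frame(sample_id = rownames(newdata) %||% seq_along(yhat),
             fit = yhat, lwr = qs[, 1], upr = qs[, 2], row.names = NULL)
}

#' Source-stratified k-fold cross-validation of BMSR
#'
#' Splits each study's samples into k folds (so every fold preserves the
#' study proportions), refits on the remaining samples, and scores held-out
#' predictions — pooled across studies within a fold, each sample predicted
#' with its own study's coefficients — by Pearson correlation. The
#' median-performing fold is identified, mirroring how cross-validated
#' performance is conventionally reported for this model.
#'
#' @param sources harmonized [source_dataset()] list.
#' @param spec,mcmc as in [fit_bmsr()].
#' @param k number of folds.
#' @param seed integer seed for the fold assignment.
#' @return list with `folds` (data frame: fold, r, p, n_test) and
#'   `median_fold` (the fold whose r is the median).
#' @export
crossvalidate <- function(sources, spec = bmsr_spec(), mcmc = mcmc_config(),
                          k = 5L, seed = 1L) {
  check_harmonized(sources)
  k <- check_count(k, "k", min = 2L)
  assign_folds <- with_seed(seed, lapply(sources, function(s) {
    n <- nrow(s$expression)
    sample(rep_len(seq_len(k), n))
  }))
  res <- data.frame(fold = integer(0), r = numeric(0), p = numeric(0),
                    n_test = integer(0))
  for (fold in seq_len(k)) {
    train <- test_x <- test_y <- list()
    for (d in seq_along(sources)) {
      idx <- assign_folds[[d]] == fold
      if (sum(idx) < 3L) stop_input("fold %d has < 3 test samples in source %d", fold, d)
      s <- sources[[d]]
      train[[d]] <- source_dataset(s$expression[!idx, , drop = FALSE],
                                   s$response[!idx], dataset_id = s$dataset_id)
      test_x[[d]] <- s$expression[idx, , drop = FALSE]
      test_y[[d]] <- s$response[idx]
    }
    fit <- fit_bmsr(train, spec, mcmc)
    preds <- unlist(lapply(seq_along(sources), function(d)
      predict(fit, test_x[[d]], source = sources[[d]]$dataset_id)))
    obs <- unlist(test_y)
    ct <- cor_with_p(obs, preds)
    res <- rbind(res, data.frame(fold = fold, r = ct$r, p = ct$p, n_test = ct$n))
  }
  ord <- order(res$r)
  median_fold <- res$fold[ord[ceiling(nrow(res) / 2)]]
  list(folds = res, median_fold = median_fold,
       median_r = res$r[res$fold == median_fold])
}

#' Stouffer-combined biomarker prioritization
#'
#' Standardizes each study's posterior-mean coefficients across genes to
#' z-scores, combines them across studies by Stouffer's method
#' (`z = sum_d z_d / sqrt(D)`), and flags genes whose two-sided normal p-value
#' falls below the threshold — genes with extremal coefficients in the same
#' direction across studies.
#'
#' @param posterior a `bmsr_posterior` fitted on at least two studies.
#' @param p_threshold selection threshold on the combined two-sided p-value.
#' @return data frame (one row per gene, ordered by combined p): per-study
#'   z-scores, `combined_z`, `p`, `selected`.
#' @export
prioritize_biomarkers <- function(posterior, p_threshold = 0.01) {
  stopifnot(inherits(posterior, "bmsr_posterior"))
  D <- dim(posterior$beta_source)[3]
  if (D < 2L)
    stop_input("prioritization needs >= 2 sources; rank per-source coefficients directly")
  zmat <- vapply(seq_len(D), function(d) {
    b <- colMeans(posterior$beta_source[, , d])
    (b - mean(b)) / sd(b)
  }, numeric(length(posterior$gene_ids)))
  colnames(zmat) <- paste0("z_", posterior$source_ids %||% paste0("source", seq_len(D)))
  combined_z <- rowSums(zmat) / sqrt(D)
  p <- 2 * pnorm(-abs(combined_z))
  out <- data.frame(gene_id = posterior$gene_ids, zmat, combined_z = combined_z,
                    p = p, selected = p < p_threshold, row.names = NULL,
                    check.names = FALSE)
  out[order(out$p, -abs(out$combined_z)), , drop = FALSE]
}

#' Save / load a fitted posterior
#'
#' Serializes the draw arrays, identifiers and diagnostics to a single
#' portable file (RDS), so prioritization and prediction can run later or on
#' another machine.
#'
#' @param posterior a `bmsr_posterior`.
#' @param path file path.
#' @export
save_posterior <- function(posterior, path) {
  stopifnot(inherits(posterior, "bmsr_posterior"))
  saveRDS(posterior, path)
  invisible(path)
}

#' @rdname save_posterior
#' @export
load_posterior <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "bmsr_posterior")) stop_input("%s is not a saved posterior", path)
  obj
}

#' Combine per-study z-scores by Stouffer's method
#'
#' `z = sum(z_d)/sqrt(D)` with a two-sided standard-normal p-value.
#'
#' @param z numeric vector of per-study z-scores for one gene.
#' @return list with `z` and `p`.
#' @export
stouffer_combine <- function(z) {
  if (any(!is.finite(z))) stop_input("z-scores must be finite")
  zc <- sum(z) / sqrt(length(z))
  list(z = zc, p = 2 * pnorm(-abs(zc)))
}
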