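#' Configuration for the multi-source regression simulator
#'
#' Bundles the generative parameters of the multi-source linear model used to
#' emulate cross-study pharmacogenomic data: several studies ("sources") share
#' a sparse coefficient vector over genes, each study's coefficients are a
#' small perturbation of the shared vector, gene expression has equicorrelated
#' blocks (co-expressed modules), and responses are linear in expression plus
#' Gaussian noise.
#'
#' @param n_sources number of studies D.
#' @param n_samples integer vector of per-study sample counts (recycled to
#'   `n_sources`).
#' @param n_genes number of genes G.
#' @param n_active number of genes with nonzero shared coefficient.
#' @param effect_sd scale of the nonzero shared coefficients. Nonzero entries
#'   are `effect_sd` in magnitude with a random sign (the equal-magnitude
#'   planted-signal convention), so every active gene carries the same
#'   identifiable effect.
#' @param source_perturb_sd standard deviation of the per-study coefficient
#'   perturbation around the shared vector.
#' @param block_size size of each correlated gene block (last block may be
#'   shorter); `1` disables correlation.
#' @param block_rho within-block equicorrelation in `[0, 1)`.
#' @param noise_sd residual standard deviation per study (recycled). Ignored
#'   when `target_r2` is given.
#' @param target_r2 optional in-sample R-squared; when set, each study's noise
#'   standard deviation is chosen as `sd(X beta^(d)) * sqrt((1 - R2)/R2)`.
#' @param seed integer seed; the generator is a pure function of the
#'   configuration including the seed.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_sources = 2L, n_samples = c(120L, 60L), n_genes = 300L,
                       n_active = 8L, effect_sd = 1, source_perturb_sd = 0.1,
                       block_size = 10L, block_rho = 0.5, noise_sd = 1,
                       target_r2 = NULL, seed = 1L) {
  n_sources <- check_count(n_sources, "n_sources")
  n_genes <- check_count(n_genes, "n_genes")
  n_active <- check_count(n_active, "n_active", min = 0L)
  if (n_active > n_genes) stop_input("n_active (%d) exceeds n_genes (%d)", n_active, n_genes)
  n_samples <- vapply(rep_len(n_samples, n_sources), check_count, integer(1), name = "n_samples", min = 3L)
  check_positive(effect_sd, "effect_sd")
  check_positive(source_perturb_sd, "source_perturb_sd")
  block_size <- check_count(block_size, "block_size")
  if (!is.numeric(block_rho) || block_rho < 0 || block_rho >= 1)
    stop_input("block_rho must be in [0, 1)")
  noise_sd <- check_positive(rep_len(noise_sd, n_sources), "noise_sd")
  if (!is.null(target_r2) && (target_r2 <= 0 || target_r2 >= 1))
    stop_input("target_r2 must be in (0, 1)")
  structure(list(n_sources = n_sources, n_samples = n_samples, n_genes = n_genes,
                 n_active = n_active, effect_sd = effect_sd,
                 source_perturb_sd = source_perturb_sd, block_size = block_size,
                 block_rho = block_rho, noise_sd = noise_sd, target_r2 = target_r2,
                 seed = check_count(seed, "seed", min = 0L)),
            class = "sim_config")
}

# Block-equicorrelated standard-normal design: each block shares a latent
# factor, x = sqrt(rho) f_block + sqrt(1 - rho) eps, so marginal variance is 1
# and within-block correlation is rho.
sim_design <- function(n, g, block_size, rho) {
  x <- matrix(rnorm(n * g), n, g)
  if (rho > 0 && block_size > 1L) {
    blocks <- split(seq_len(g), ceiling(seq_len(g) / block_size))
    for (idx in blocks) {
      f <- rnorm(n)
      x[, idx] <- sqrt(rho) * f + sqrt(1 - rho) * x[, idx]
    }
  }
  x
}

#' Simulate aligned multi-study expression/response data
#'
#' Draws the generative counterpart of the multi-source regression model:
#' a shared sparse coefficient vector over genes, per-study coefficients
#' perturbed around it, block-correlated standard-normal expression, and
#' Gaussian response noise.
#'
#' @param config a [sim_config()].
#' @return a list with `sources` (one [source_dataset()] per study) and
#'   `truth` (shared `beta`, per-source `beta_source`, `active` gene indices,
#'   per-source `noise_sd`).
#' @export
simulate_multisource <- function(config) {
  if (!inherits(config, "sim_config")) stop_input("`config` must be a sim_config")
  with_seed(config$seed, {
    g <- config$n_genes
    gene_ids <- sprintf("g%04d", seq_len(g))
    # Actives are placed in distinct correlation blocks when possible, so the
    # planted support is identifiable (co-located actives in an equicorrelated
    # block can cancel or swap credit, which would confound recovery checks).
    blocks <- split(seq_len(g), ceiling(seq_len(g) / config$block_size))
    active <- if (config$n_active == 0L) integer(0)
      else if (config$block_rho > 0 && length(blocks) >= config$n_active) {
        chosen <- sample(blocks, config$n_active)
        sort(vapply(chosen, function(idx) idx[sample.int(length(idx), 1L)], 0L))
      } else sort(sample.int(g, config$n_active))
    beta <- numeric(g)
    if (length(active))
      beta[active] <- sample(c(-1, 1), length(active), replace = TRUE) *
        config$effect_sd
    beta_source <- vapply(seq_len(config$n_sources),
                          function(d) beta + rnorm(g, 0, config$source_perturb_sd),
                          numeric(g))
    noise_sd <- config$noise_sd
    sources <- vector("list", config$n_sources)
    for (d in seq_len(config$n_sources)) {
      n <- config$n_samples[d]
      x <- sim_design(n, g, config$block_size, config$block_rho)
      dimnames(x) <- list(sprintf("s%d_%03d", d, seq_len(n)), gene_ids)
      mu <- drop(x %*% beta_source[, d])
      if (!is.null(config$target_r2)) {
        s_mu <- sd(mu)
        noise_sd[d] <- if (s_mu > 0) s_mu * sqrt((1 - config$target_r2) / config$target_r2) else 1
      }
      y <- mu + rnorm(n, 0, noise_sd[d])
      names(y) <- rownames(x)
      sources[[d]] <- source_dataset(expression = x, response = y,
                                     dataset_id = sprintf("source%d", d))
    }
    list(sources = sources,
         truth = list(beta = setNames(beta, gene_ids),
                      beta_source = structure(beta_source, dimnames = list(gene_ids, NULL)),
                      active = active, noise_sd = noise_sd))
  })
}

#' Simulate replicated dose-response series from a log-logistic curve
#'
#' Evaluates a 4-parameter log-logistic curve at the given concentrations and
#' adds iid Gaussian noise per replicate. Optionally injects a non-monotone
#' artifact by swapping the lowest- and highest-concentration responses,
#' producing fixtures that downstream quality control should flag.
#'
#' @param b,c,d,e log-logistic parameters (slope, lower asymptote, upper
#'   asymptote, inflection concentration); dose-inhibition curves that rise
#'   with dose have `b < 0`.
#' @param concentrations strictly increasing positive concentrations.
#' @param noise_sd response noise standard deviation.
#' @param n_replicates number of replicate series.
#' @param seed integer seed.
#' @param artifact if `TRUE`, swap the first and last response of each
#'   replicate after adding noise.
#' @param sample_id,patient_id,drug_id identifiers stamped on the series.
#' @return a list of `dose_response_series` objects (one per replicate).
#' @export
simulate_dose_response <- function(b = -1, c = 0, d = 100, e = 0.1,
                                   concentrations = 10^seq(-3, 0, by = 0.5),
                                   noise_sd = 0, n_replicates = 1L, seed = 1L,
                                   artifact = FALSE, sample_id = "S1",
                                   patient_id = sample_id, drug_id = "D1") {
  if (any(concentrations <= 0)) stop_input("concentrations must be positive")
  if (is.unsorted(concentrations, strictly = TRUE))
    stop_input("concentrations must be strictly increasing")
  check_positive(noise_sd, "noise_sd")
  n_replicates <- check_count(n_replicates, "n_replicates")
  mu <- ll4(concentrations, b, c, d, e)
  with_seed(seed, {
    lapply(seq_len(n_replicates), function(r) {
      resp <- mu + rnorm(length(mu), 0, noise_sd)
      if (artifact && length(resp) >= 2L) {
        k <- length(resp)
        resp[c(1L, k)] <- resp[c(k, 1L)]
      }
      dose_response_series(sample_id = sample_id, patient_id = patient_id,
                           drug_id = drug_id, replicate_id = sprintf("rep%d", r),
                           concentrations = concentrations, responses = resp)
    })
  })
}

#' Simulate an AUC matrix with additive sample and drug effects
#'
#' Generates `AUC(s, d) = clamp01(mu + g_s + m_d + eps)` where `g_s` is a
#' per-sample general-response effect, `m_d` a per-drug potency effect, and
#' `eps` cell noise — the additive structure behind the general response
#' across drugs (GRD) statistic.
#'
#' @param n_samples,n_drugs matrix dimensions.
#' @param grd_sd,drug_sd,noise_sd standard deviations of the sample effect,
#'   drug effect, and cell noise.
#' @param mu baseline AUC.
#' @param missing_frac fraction of cells set missing (exact count
#'   `floor(missing_frac * n_cells)`, placed uniformly at random).
#' @param seed integer seed.
#' @return a list with `auc` (drugs x samples matrix, `NA` for missing) and
#'   `truth` (`sample_effect`, `drug_effect`).
#' @export
simulate_grd_structure <- function(n_samples = 100L, n_drugs = 60L,
                                   grd_sd = 0.1, drug_sd = 0.1, noise_sd = 0.02,
                                   mu = 0.5, missing_frac = 0, seed = 1L) {
  n_samples <- check_count(n_samples, "n_samples")
  n_drugs <- check_count(n_drugs, "n_drugs")
  check_positive(c(grd_sd, drug_sd, noise_sd), "sds")
  if (missing_frac < 0 || missing_frac > 1) stop_input("missing_frac must be in [0, 1]")
  with_seed(seed, {
    g_s <- rnorm(n_samples, 0, grd_sd)
    m_d <- rnorm(n_drugs, 0, drug_sd)
    eps <- matrix(rnorm(n_drugs * n_samples, 0, noise_sd), n_drugs, n_samples)
    auc <- pmin(pmax(mu + outer(m_d, g_s, `+`) + eps, 0), 1)
    dimnames(auc) <- list(sprintf("drug%03d", seq_len(n_drugs)),
                          sprintf("sample%03d", seq_len(n_samples)))
    n_miss <- floor(missing_frac * length(auc))
    if (n_miss > 0) auc[sample.int(length(auc), n_miss)] <- NA_real_
    list(auc = auc,
         truth = list(sample_effect = setNames(g_s, colnames(auc)),
                      drug_effect = setNames(m_d, rownames(auc))))
  })
}

#' Simulate an expression cohort with a latent monocytic gradient
#'
#' Signature genes load on a per-sample latent score (e.g., monocytic
#' differentiation); all other genes are pure noise. Used to validate
#' single-sample enrichment scoring.
#'
#' @param n_samples,n_genes cohort dimensions.
#' @param signature_genes character vector of gene ids that carry the latent
#'   signal; must be a subset of `gene_ids`.
#' @param gene_ids gene identifiers (default `g0001 ...`, with the signature
#'   genes substituted in front if not already present).
#' @param gradient_sd standard deviation of the latent score across samples.
#' @param loading effect of the latent score on each signature gene.
#' @param noise_sd expression noise standard deviation.
#' @param seed integer seed.
#' @return a list with `expression` (genes x samples) and `latent`
#'   (per-sample latent score).
#' @export
simulate_signature_cohort <- function(n_samples = 40L, n_genes = 200L,
                                      signature_genes, gene_ids = NULL,
                                      gradient_sd = 1, loading = 1,
                                      noise_sd = 0.5, seed = 1L) {
  n_samples <- check_count(n_samples, "n_samples")
  n_genes <- check_count(n_genes, "n_genes")
  if (is.null(gene_ids)) {
    gene_ids <- sprintf("g%04d", seq_len(n_genes))
    missing <- setdiff(signature_genes, gene_ids)
    if (length(missing)) {
      slots <- which(!(gene_ids %in% signature_genes))[seq_along(missing)]
      gene_ids[slots] <- missing
    }
  }
  if (length(gene_ids) != n_genes || anyDuplicated(gene_ids))
    stop_input("gene_ids must be %d unique ids", n_genes)
  if (!all(signature_genes %in% gene_ids))
    stop_input("unknown signature gene id(s): %s",
               paste(setdiff(signature_genes, gene_ids), collapse = ", "))
  check_positive(c(gradient_sd, noise_sd), "sds")
  with_seed(seed, {
    latent <- rnorm(n_samples, 0, gradient_sd)
    expr <- matrix(rnorm(n_genes * n_samples, 0, max(noise_sd, 1e-12)),
                   n_genes, n_samples,
                   dimnames = list(gene_ids, sprintf("sample%03d", seq_len(n_samples))))
    sig_rows <- match(signature_genes, gene_ids)
    expr[sig_rows, ] <- expr[sig_rows, , drop = FALSE] +
      matrix(rep(latent * loading, each = length(sig_rows)), length(sig_rows))
    list(expression = expr, latent = setNames(latent, colnames(expr)))
  })
}
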