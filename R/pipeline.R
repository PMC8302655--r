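#' Load a run configuration
#'
#' JSON configuration binding dataset paths, thresholds and sampler settings
#' for [run_pipeline()]. All referenced paths must exist at load time and a
#' seed is mandatory (every stochastic step draws from it).
#'
#' @param path JSON file.
#' @return named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$seed)) stop_input("config must declare a seed")
  cfg$seed <- check_count(cfg$seed, "seed", min = 0L)
  for (field in intersect(names(cfg), c("expression", "dose_response", "auc", "gmt"))) {
    for (p in unlist(cfg[[field]]))
      if (!file.exists(p)) stop_input("config path does not exist: %s", p)
  }
  structure(cfg, class = c("run_config", "list"))
}

pipeline_log <- function(out_dir, command, cfg, outputs) {
  hashes <- vapply(unlist(outputs), function(p)
    unname(tools::md5sum(p)), "")
  log <- list(command = command, seed = cfg$seed,
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
              package_version = as.character(utils::packageVersion("bmsr")),
              outputs = as.list(hashes))
  write_truth_json(log, file.path(out_dir, paste0(command, "_log.json")))
}

#' Run one pipeline command from a configuration
#'
#' Thin, reproducible glue over the package functions. Supported commands:
#' `"simulate"` (write synthetic fixtures: expression TSVs, responses, AUC
#' CSV, dose-response CSV, truth JSON), `"fit-curves"` (dose-response CSV ->
#' AUC matrix + QC report), `"grd"` (AUC CSV -> GRD/MRP TSV), `"fit"`
#' (expression + responses -> saved posterior + biomarker table), `"cv"`
#' (source-stratified cross-validation report), and `"score-signature"`
#' (expression -> monocytic signature scores). Every
#' command writes a JSON log with output hashes and the seed; outputs are
#' deterministic given the configuration.
#'
#' @param config a `run_config` (or path to one).
#' @param command one of the commands above.
#' @param out_dir output directory (created if needed).
#' @return invisible character vector of output paths.
#' @export
run_pipeline <- function(config, command = c("simulate", "fit-curves", "grd",
                                             "fit", "cv", "score-signature"),
                         out_dir = config$out_dir %||% ".") {
  if (is.character(config)) config <- read_run_config(config)
  command <- match.arg(command)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  ok <- FALSE
  on.exit(if (!ok) unlink(outputs))  # remove partial outputs on failure

  if (command == "simulate") {
    cfg <- do.call(sim_config, c(config$sim %||% list(), list(seed = config$seed)))
    sim <- simulate_multisource(cfg)
    for (d in seq_along(sim$sources)) {
      p <- file.path(out_dir, sprintf("expression_source%d.tsv", d))
      write_expression(t(sim$sources[[d]]$expression), p)
      outputs <- c(outputs, p)
      p <- file.path(out_dir, sprintf("response_source%d.csv", d))
      write.table(data.frame(sample_id = names(sim$sources[[d]]$response),
                             value = sim$sources[[d]]$response),
                  p, sep = ",", quote = FALSE, row.names = FALSE)
      outputs <- c(outputs, p)
    }
    grd_sim <- simulate_grd_structure(seed = config$seed)
    p <- file.path(out_dir, "auc.csv"); write_auc_matrix(grd_sim$auc, p)
    outputs <- c(outputs, p)
    series <- simulate_dose_response(n_replicates = 2L, noise_sd = 2,
                                     seed = config$seed)
    p <- file.path(out_dir, "dose_response.csv"); write_dose_response(series, p)
    outputs <- c(outputs, p)
    p <- file.path(out_dir, "truth.json")
    write_truth_json(list(beta = sim$truth$beta, active = sim$truth$active,
                          sample_effect = grd_sim$truth$sample_effect,
                          drug_effect = grd_sim$truth$drug_effect), p)
    outputs <- c(outputs, p)
  } else if (command == "fit-curves") {
    series <- read_dose_response(config$dose_response,
                                 isTRUE(config$response_is_viability))
    qc <- qc_concentration_range(series)
    kept <- select_patient_sample(qc$kept)
    flags <- flag_outliers(kept,
                           delta = config$delta %||% 0.2,
                           rho = config$rho %||% 0.3)
    auc <- build_response_matrix(data.frame(
      drug_id = flags$drug_id, sample_id = flags$sample_id,
      replicate_id = flags$replicate_id, auc = flags$auc_ll4))
    p <- file.path(out_dir, "auc.csv"); write_auc_matrix(auc, p)
    outputs <- c(outputs, p)
    p <- file.path(out_dir, "qc_report.tsv")
    report <- rbind(
      data.frame(sample_id = qc$excluded$sample_id, drug_id = qc$excluded$drug_id,
                 replicate_id = qc$excluded$replicate_id,
                 reason = qc$excluded$reason),
      data.frame(sample_id = flags$sample_id[nzchar(flags$flags)],
                 drug_id = flags$drug_id[nzchar(flags$flags)],
                 replicate_id = flags$replicate_id[nzchar(flags$flags)],
                 reason = flags$flags[nzchar(flags$flags)]))
    write.table(report, p, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <- c(outputs, p)
  } else if (command == "grd") {
    auc <- read_auc_matrix(config$auc)
    grd <- compute_grd(auc, min_drugs = config$min_drugs %||% 10L)
    mrp <- compute_mrp(auc)
    p <- file.path(out_dir, "grd.tsv")
    write.table(data.frame(sample_id = names(grd), grd = grd), p,
                sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <- c(outputs, p)
    p <- file.path(out_dir, "mrp.tsv")
    write.table(data.frame(drug_id = names(mrp), mrp = mrp), p,
                sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <- c(outputs, p)
  } else if (command %in% c("fit", "cv")) {
    exprs <- lapply(unlist(config$expression), read_expression)
    responses <- lapply(unlist(config$response), function(p) {
      df <- read.table(p, sep = ",", header = TRUE, stringsAsFactors = FALSE)
      setNames(df$value, df$sample_id)
    })
    exprs <- lapply(exprs, filter_genes,
                    min_expression_quantile = config$min_expression_quantile %||% 0,
                    min_variance_quantile = config$min_variance_quantile %||% 0)
    sources <- harmonize_sources(exprs, responses)
    spec <- do.call(bmsr_spec, config$bmsr %||% list())
    mcmc <- do.call(mcmc_config, c(config$mcmc %||% list(), list(seed = config$seed)))
    if (command == "cv") {
      cv <- crossvalidate(sources, spec, mcmc, k = config$k %||% 5L,
                          seed = config$seed)
      p <- file.path(out_dir, "cv_folds.tsv")
      write.table(cv$folds, p, sep = "\t", quote = FALSE, row.names = FALSE)
      outputs <- c(outputs, p)
    } else {
      fit <- fit_bmsr(sources, spec, mcmc)
      tab <- prioritize_biomarkers(fit)
      p <- file.path(out_dir, "biomarkers.tsv")
      write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
      outputs <- c(outputs, p)
      p <- file.path(out_dir, "posterior.rds")
      save_posterior(fit, p)
      outputs <- c(outputs, p)
      p <- file.path(out_dir, "posterior_summary.json")
      write_truth_json(list(beta_mean = colMeans(fit$beta),
                            sigma_mean = colMeans(fit$sigma),
                            tau_mean = mean(fit$tau),
                            diagnostics = fit$diagnostics[c("rhat_tau", "n_divergent",
                                                            "divergent_fraction")]), p)
      outputs <- c(outputs, p)
    }
  } else if (command == "score-signature") {
    expr <- read_expression(config$expression[[1]])
    scores <- monocyte_signature(expr)
    p <- file.path(out_dir, "signature_scores.tsv")
    write.table(data.frame(sample_id = names(scores), score = scores), p,
                sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <- c(outputs, p)
  }

  pipeline_log(out_dir, command, config, outputs)
  ok <- TRUE
  invisible(outputs)
}
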