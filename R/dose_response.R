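#' A single dose-response series
#'
#' One drug assayed on one sample in one replicate: paired concentrations and
#' responses. Responses are percent inhibition (nominally 0-100, rising with
#' dose); viability data should be converted as `100 - viability` upstream.
#'
#' @param sample_id,patient_id,drug_id,replicate_id identifiers.
#' @param concentrations strictly increasing positive concentrations.
#' @param responses numeric responses, same length as `concentrations`.
#' @return an object of class `dose_response_series`.
#' @export
dose_response_series <- function(sample_id, patient_id, drug_id, replicate_id,
                                 concentrations, responses) {
  if (length(concentrations) != length(responses))
    stop_input("concentrations and responses differ in length")
  if (any(concentrations <= 0)) stop_input("concentrations must be positive")
  if (is.unsorted(concentrations, strictly = TRUE))
    stop_input("concentrations must be strictly increasing")
  if (any(!is.finite(responses))) stop_input("responses must be finite")
  structure(list(sample_id = as.character(sample_id),
                 patient_id = as.character(patient_id),
                 drug_id = as.character(drug_id),
                 replicate_id = as.character(replicate_id),
                 concentrations = as.numeric(concentrations),
                 responses = as.numeric(responses)),
            class = "dose_response_series")
}

#' Four-parameter log-logistic curve
#'
#' `f(x) = c + (d - c) / (1 + exp(b * (log(x) - log(e))))`. With `d > c` the
#' curve rises with dose when `b < 0`; `e` is the inflection concentration.
#'
#' @param x concentrations.
#' @param b,c,d,e curve parameters.
#' @export
ll4 <- function(x, b, c, d, e) c + (d - c) / (1 + exp(b * (log(x) - log(e))))

# Deterministic multi-start grid for the Levenberg-Marquardt fits.
ll_start_grid <- function(conc) {
  b0 <- c(-0.5, -1, -2, -5, 0.5, 1)
  e0 <- exp(seq(log(min(conc)), log(max(conc)), length.out = 4L))
  expand.grid(b = b0, e = e0, KEEP.OUT.ATTRS = FALSE)
}

#' Fit a 3- or 4-parameter log-logistic curve
#'
#' Least-squares fit of the log-logistic model by Levenberg-Marquardt descent
#' from a fixed multi-start grid of slope and inflection values; the best
#' local optimum is returned, so fits are deterministic. The 3-parameter
#' variant (LL3) constrains the low-dose asymptote to zero response (`c = 0`).
#'
#' @param series a [dose_response_series()].
#' @param model `"LL4"` or `"LL3"`.
#' @return an object of class `ll_fit` with elements `model`, `b`, `c`, `d`,
#'   `e`, `rss`, `converged`, `qc_flags` (a character vector; `"degenerate"`
#'   marks flat fits) and the series identifiers.
#' @export
fit_log_logistic <- function(series, model = c("LL4", "LL3")) {
  model <- match.arg(model)
  stopifnot(inherits(series, "dose_response_series"))
  x <- series$concentrations
  y <- series$responses
  if (any(!is.finite(y))) stop_input("non-finite responses")
  need <- if (model == "LL3") 3L else 4L
  if (length(unique(x)) < need)
    stop_input("%s fit needs >= %d distinct concentrations, got %d",
               model, need, length(unique(x)))

  resid_fun <- function(par) {
    r <- if (model == "LL3") ll4(x, par[1], 0, par[2], exp(par[3])) - y
         else ll4(x, par[1], par[2], par[3], exp(par[4])) - y
    # keep the optimizer inside finite territory when a step overflows
    r[!is.finite(r)] <- 1e6
    r
  }
  starts <- ll_start_grid(x)
  d0 <- max(y); c0 <- min(y)
  # box constraints on the percent-inhibition scale: asymptotes within a
  # generous physical range, inflection within two decades of the tested range
  log_e_lim <- c(log(min(x)) - log(100), log(max(x)) + log(100))
  lower <- if (model == "LL3") c(-20, -50, log_e_lim[1]) else c(-20, -150, -50, log_e_lim[1])
  upper <- if (model == "LL3") c(20, 200, log_e_lim[2]) else c(20, 150, 200, log_e_lim[2])
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    par0 <- if (model == "LL3") c(starts$b[i], d0, log(starts$e[i]))
            else c(starts$b[i], c0, d0, log(starts$e[i]))
    par0 <- pmin(pmax(par0, lower), upper)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = par0, fn = resid_fun, lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(maxiter = 500,
                                                              maxfev = 2000)),
      error = function(e) NULL)
    # info 1-4: proper convergence; 5: iteration budget reached, keep the
    # best-effort optimum (a model that cannot represent the data, e.g. LL3
    # on a non-zero low-dose plateau, still needs its least-squares curve)
    if (is.null(fit) || !fit$info %in% 1:5 || !all(is.finite(fit$par))) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss - 1e-12) best <- list(par = fit$par, rss = rss)
  }
  if (is.null(best)) {
    out <- list(model = model, b = NA_real_, c = if (model == "LL3") 0 else NA_real_,
                d = NA_real_, e = NA_real_, rss = NA_real_, converged = FALSE,
                qc_flags = character(0))
  } else {
    p <- best$par
    if (model == "LL3") p <- c(p[1], 0, p[2], p[3])
    out <- list(model = model, b = p[1], c = if (model == "LL3") 0 else p[2],
                d = p[3], e = exp(p[4]), rss = best$rss, converged = TRUE,
                qc_flags = if (abs(p[3] - (if (model == "LL3") 0 else p[2])) < 1e-6 ||
                               sd(y) == 0) "degenerate" else character(0))
  }
  out[c("sample_id", "patient_id", "drug_id", "replicate_id")] <-
    series[c("sample_id", "patient_id", "drug_id", "replicate_id")]
  out$concentrations <- x
  structure(out, class = "ll_fit")
}

#' Normalized area under a fitted dose-response curve
#'
#' Integrates the fitted curve (clipped to 0-100 percent inhibition) over
#' log10 concentration and normalizes by `100 * log10-range width`, giving an
#' AUC in `[0, 1]`: 0 for no inhibition anywhere, 1 for complete inhibition
#' across the tested range.
#'
#' @param fit an `ll_fit`.
#' @param conc_range length-2 positive `(low, high)` concentration range;
#'   defaults to the fitted series' own range.
#' @return AUC in `[0, 1]`.
#' @export
compute_auc <- function(fit, conc_range = NULL) {
  stopifnot(inherits(fit, "ll_fit"))
  if (!isTRUE(fit$converged)) stop_input("cannot compute AUC of an unconverged fit")
  if (is.null(conc_range)) conc_range <- range(fit$concentrations)
  if (length(conc_range) != 2L || conc_range[1] <= 0 || conc_range[2] <= conc_range[1])
    stop_input("conc_range must be (low, high) with 0 < low < high")
  lo <- log10(conc_range[1]); hi <- log10(conc_range[2])
  f <- function(t) pmin(pmax(ll4(10^t, fit$b, fit$c, fit$d, fit$e), 0), 100)
  val <- integrate(f, lo, hi, rel.tol = 1e-9, abs.tol = 1e-9,
                   subdivisions = 500L)$value
  val / (100 * (hi - lo))
}

series_key <- function(s) paste(s$sample_id, s$drug_id, s$replicate_id, sep = "\r")

#' Exclude series whose concentration design deviates from the drug's modal one
#'
#' For each drug, the modal `(min, max, n_points)` concentration tuple across
#' series is identified; ties are broken toward the lexicographically smaller
#' tuple. Series with a different range or a different number of points
#' (e.g., a missing interior concentration) are excluded.
#'
#' @param collection list of [dose_response_series()].
#' @return list with `kept` (the surviving series), `excluded` (a data frame
#'   of identifiers and reason codes) and `modal_range` (per-drug tuples).
#' @export
qc_concentration_range <- function(collection) {
  if (length(collection) == 0L) stop_input("empty series collection")
  info <- data.frame(
    drug_id = vapply(collection, `[[`, "", "drug_id"),
    sample_id = vapply(collection, `[[`, "", "sample_id"),
    replicate_id = vapply(collection, `[[`, "", "replicate_id"),
    cmin = vapply(collection, function(s) min(s$concentrations), 0),
    cmax = vapply(collection, function(s) max(s$concentrations), 0),
    npts = vapply(collection, function(s) length(s$concentrations), 0L),
    stringsAsFactors = FALSE)
  modal <- lapply(split(seq_len(nrow(info)), info$drug_id), function(idx) {
    tup <- info[idx, c("cmin", "cmax", "npts")]
    key <- sprintf("%.12g\r%.12g\r%d", tup$cmin, tup$cmax, tup$npts)
    tab <- table(key)
    winners <- names(tab)[tab == max(tab)]
    win <- sort(winners)[1L]  # lexicographic tie-break
    list(key = win, tuple = tup[match(win, key), ])
  })
  keys <- sprintf("%.12g\r%.12g\r%d", info$cmin, info$cmax, info$npts)
  modal_keys <- vapply(modal, `[[`, "", "key")[info$drug_id]
  keep <- keys == modal_keys
  excluded <- cbind(info[!keep, c("sample_id", "drug_id", "replicate_id")],
                    reason = rep("incomplete_range", sum(!keep)))
  rownames(excluded) <- NULL
  list(kept = collection[keep], excluded = excluded,
       modal_range = lapply(modal, `[[`, "tuple"))
}

#' Keep one sample per patient
#'
#' When a patient contributed several samples, keeps the sample assayed
#' across the most distinct drugs; ties are broken toward the
#' lexicographically first sample id.
#'
#' @param collection list of [dose_response_series()].
#' @return the filtered collection.
#' @export
select_patient_sample <- function(collection) {
  if (length(collection) == 0L) return(collection)
  pat <- vapply(collection, `[[`, "", "patient_id")
  samp <- vapply(collection, `[[`, "", "sample_id")
  drug <- vapply(collection, `[[`, "", "drug_id")
  keep_samples <- unlist(lapply(split(seq_along(collection), pat), function(idx) {
    counts <- tapply(drug[idx], samp[idx], function(d) length(unique(d)))
    best <- max(counts)
    sort(names(counts)[counts == best])[1L]
  }))
  collection[samp %in% keep_samples]
}

#' Flag outlying dose-response fits
#'
#' Applies the three-criterion outlier annotation: (1) `non_monotone` if the
#' fitted 4-parameter curve decreases anywhere on the tested concentration
#' range by more than `mono_tol`; (2) `ll3_ll4_divergent` if the normalized
#' AUCs of the zero-asymptote (LL3) and free-asymptote (LL4) fits differ by
#' more than `delta`; (3) `replicate_discordant` if any two replicates of the
#' same sample-drug pair have LL4 AUCs differing by more than `rho`. Flags
#' annotate; exclusion is the caller's choice.
#'
#' @param collection list of [dose_response_series()].
#' @param delta,rho,mono_tol thresholds (normalized-AUC units for `delta` and
#'   `rho`).
#' @param conc_range optional common `(low, high)` range for the AUCs;
#'   defaults to each series' own range.
#' @return a data frame with one row per series: identifiers, LL4/LL3 AUCs,
#'   logical flag columns, and a `flags` string column; the LL4 and LL3 fits
#'   are attached as attributes `fits_ll4` / `fits_ll3`.
#' @export
flag_outliers <- function(collection, delta = 0.2, rho = 0.3, mono_tol = 1e-6,
                          conc_range = NULL) {
  fits4 <- lapply(collection, fit_log_logistic, model = "LL4")
  fits3 <- lapply(collection, fit_log_logistic, model = "LL3")
  n <- length(collection)
  auc4 <- auc3 <- rep(NA_real_, n)
  non_mono <- divergent <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (isTRUE(fits4[[i]]$converged)) {
      rng <- if (is.null(conc_range)) range(collection[[i]]$concentrations) else conc_range
      auc4[i] <- compute_auc(fits4[[i]], rng)
      grid <- 10^seq(log10(rng[1]), log10(rng[2]), length.out = 101L)
      fv <- ll4(grid, fits4[[i]]$b, fits4[[i]]$c, fits4[[i]]$d, fits4[[i]]$e)
      non_mono[i] <- any(diff(fv) < -mono_tol)
      if (isTRUE(fits3[[i]]$converged)) {
        auc3[i] <- compute_auc(fits3[[i]], rng)
        divergent[i] <- abs(auc3[i] - auc4[i]) > delta
      }
    }
  }
  out <- data.frame(
    sample_id = vapply(collection, `[[`, "", "sample_id"),
    patient_id = vapply(collection, `[[`, "", "patient_id"),
    drug_id = vapply(collection, `[[`, "", "drug_id"),
    replicate_id = vapply(collection, `[[`, "", "replicate_id"),
    auc_ll4 = auc4, auc_ll3 = auc3,
    non_monotone = non_mono, ll3_ll4_divergent = divergent,
    replicate_discordant = FALSE, stringsAsFactors = FALSE)
  for (grp in split(seq_len(n), paste(out$sample_id, out$drug_id, sep = "\r"))) {
    if (length(grp) < 2L) next
    a <- auc4[grp]
    for (i in seq_along(grp)) {
      others <- a[-i]
      if (any(is.finite(others)) && is.finite(a[i]) &&
          any(abs(a[i] - others) > rho, na.rm = TRUE))
        out$replicate_discordant[grp[i]] <- TRUE
    }
  }
  out$flags <- apply(out[, c("non_monotone", "ll3_ll4_divergent", "replicate_discordant")],
                     1L, function(z) paste(c("non_monotone", "ll3_ll4_divergent",
                                             "replicate_discordant")[z], collapse = ";"))
  attr(out, "fits_ll4") <- fits4
  attr(out, "fits_ll3") <- fits3
  out
}

#' Assemble a drugs-by-samples AUC matrix
#'
#' Replicate AUCs of the same sample-drug pair are averaged; excluded series
#' (rows with `excluded = TRUE`, if present) become missing cells.
#'
#' @param auc_table data frame with columns `drug_id`, `sample_id`,
#'   `replicate_id` (optional), `auc`, and optionally `excluded`.
#' @return a numeric drugs x samples matrix with `NA` for missing cells.
#' @export
build_response_matrix <- function(auc_table) {
  stopifnot(is.data.frame(auc_table),
            all(c("drug_id", "sample_id", "auc") %in% names(auc_table)))
  tab <- auc_table
  if (!is.null(tab$excluded)) tab <- tab[!tab$excluded, , drop = FALSE]
  if (is.null(tab$replicate_id)) tab$replicate_id <- "rep1"
  key <- paste(tab$drug_id, tab$sample_id, tab$replicate_id, sep = "\r")
  if (anyDuplicated(key))
    stop_input("duplicate (drug, sample, replicate) entries in AUC table")
  drugs <- sort(unique(auc_table$drug_id))
  samples <- sort(unique(auc_table$sample_id))
  m <- matrix(NA_real_, length(drugs), length(samples),
              dimnames = list(drugs, samples))
  agg <- tapply(tab$auc, list(factor(tab$drug_id, drugs),
                              factor(tab$sample_id, samples)),
                mean, na.rm = TRUE)
  m[] <- agg
  m
}
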