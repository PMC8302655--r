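make_series <- function(b, c, d, e, conc = 10^seq(-3, 0, by = 0.5),
                        noise = 0, seed = 1, id = "S1", drug = "D1",
                        rep_id = "rep1", patient = id) {
  set.seed(seed)
  dose_response_series(id, patient, drug, rep_id, conc,
                       ll4(conc, b, c, d, e) + rnorm(length(conc), 0, noise))
}

test_that("noiseless curves are recovered to high relative accuracy", {
  ser <- make_series(b = -1, c = 0, d = 100, e = 0.1)
  fit <- fit_log_logistic(ser, "LL4")
  expect_true(fit$converged)
  expect_lt(abs(fit$b - (-1)) / 1, 0.001)
  expect_lt(abs(fit$d - 100) / 100, 0.001)
  expect_lt(abs(fit$e - 0.1) / 0.1, 0.001)
  # LL3 on c = 0 data agrees with LL4 within optimizer tolerance
  fit3 <- fit_log_logistic(ser, "LL3")
  expect_lt(abs(fit3$d - fit$d), 1e-3)
  expect_lt(abs(fit3$e - fit$e) / fit$e, 1e-3)
})

test_that("fitted RSS beats a brute-force parameter grid", {
  ser <- make_series(b = -1.5, c = 5, d = 85, e = 0.07, noise = 4, seed = 3)
  fit <- fit_log_logistic(ser, "LL4")
  x <- ser$concentrations; y <- ser$responses
  oracle <- ll_grid_best_rss(x, y,
                             b_grid = seq(-4, 1, length.out = 10),
                             c_grid = seq(-10, 30, length.out = 10),
                             d_grid = seq(50, 120, length.out = 10),
                             e_grid = 10^seq(-3, 0, length.out = 10))
  expect_lte(fit$rss, oracle + 1e-9)
})

test_that("constant-zero responses give a flat degenerate fit", {
  ser <- dose_response_series("S1", "S1", "D1", "rep1",
                              10^seq(-2, 0, by = 0.5), rep(0, 5))
  fit <- fit_log_logistic(ser, "LL4")
  expect_lt(abs(fit$d - fit$c), 1e-4)
  expect_true("degenerate" %in% fit$qc_flags)
})

test_that("fit preconditions are enforced", {
  ser <- dose_response_series("S1", "S1", "D1", "rep1", c(0.1, 1), c(0, 50))
  expect_error(fit_log_logistic(ser, "LL3"), "distinct concentrations")
  expect_error(dose_response_series("S", "S", "D", "r", c(1, 0.5), c(0, 1)),
               "increasing")
  expect_error(dose_response_series("S", "S", "D", "r", c(0.5, 1), c(0, NaN)),
               "finite")
})

test_that("AUC matches closed forms and a dense trapezoid oracle", {
  flat100 <- fit_log_logistic(dose_response_series(
    "S", "S", "D", "r", 10^seq(-2, 0, by = 0.5), rep(100, 5)), "LL4")
  expect_equal(compute_auc(flat100, c(0.01, 1)), 1, tolerance = 1e-9)
  flat0 <- fit_log_logistic(dose_response_series(
    "S", "S", "D", "r", 10^seq(-2, 0, by = 0.5), rep(0, 5)), "LL4")
  expect_equal(compute_auc(flat0, c(0.01, 1)), 0, tolerance = 1e-9)

  set.seed(42)
  for (i in 1:10) {
    fit <- structure(list(model = "LL4", b = runif(1, -3, 3),
                          c = runif(1, -20, 30), d = runif(1, 40, 130),
                          e = 10^runif(1, -3, 0), rss = 0, converged = TRUE,
                          concentrations = c(0.001, 1)), class = "ll_fit")
    expect_lt(abs(compute_auc(fit, c(0.001, 1)) - trapezoid_auc(fit, c(0.001, 1))),
              1e-4)
  }
})

test_that("AUC is monotone in the upper asymptote and shift-invariant in units", {
  base <- function(d) structure(list(model = "LL4", b = -1, c = 0, d = d,
                                     e = 0.1, rss = 0, converged = TRUE,
                                     concentrations = c(0.001, 1)),
                                class = "ll_fit")
  aucs <- vapply(c(40, 60, 80, 100), function(d) compute_auc(base(d), c(0.001, 1)), 0)
  expect_true(all(diff(aucs) > 0))
  # rescaling concentration units rescales e and the range identically
  f1 <- base(80)
  f2 <- f1; f2$e <- f1$e * 1000
  expect_equal(compute_auc(f1, c(0.001, 1)), compute_auc(f2, c(1, 1000)),
               tolerance = 1e-9)
  expect_error(compute_auc(structure(list(converged = FALSE), class = "ll_fit")),
               "unconverged")
})

test_that("series outside the modal concentration design are excluded", {
  common <- 10^seq(-3, 0, by = 0.5)
  coll <- c(
    lapply(1:9, function(i) make_series(-1, 0, 90, 0.1, conc = common,
                                        id = paste0("S", i))),
    list(make_series(-1, 0, 90, 0.1, conc = 10^seq(-2, 1, by = 0.5), id = "S10")),
    # series with a missing interior concentration
    list(dose_response_series("S11", "S11", "D1", "rep1", common[-4],
                              ll4(common[-4], -1, 0, 90, 0.1))))
  qc <- qc_concentration_range(coll)
  expect_length(qc$kept, 9)
  expect_setequal(qc$excluded$sample_id, c("S10", "S11"))
  expect_true(all(qc$excluded$reason == "incomplete_range"))
  expect_error(qc_concentration_range(list()), "empty")
})

test_that("modal-range ties break toward the lexicographically smaller tuple", {
  a <- lapply(1:2, function(i) make_series(-1, 0, 90, 0.1,
                                           conc = c(0.01, 0.1, 1), id = paste0("A", i)))
  b <- lapply(1:2, function(i) make_series(-1, 0, 90, 0.1,
                                           conc = c(0.02, 0.2, 2), id = paste0("B", i)))
  qc <- qc_concentration_range(c(a, b))
  expect_setequal(vapply(qc$kept, `[[`, "", "sample_id"), c("A1", "A2"))
})

test_that("one sample per patient is kept, preferring broader drug coverage", {
  mk <- function(sample, patient, drug)
    make_series(-1, 0, 90, 0.1, id = sample, patient = patient, drug = drug)
  coll <- c(lapply(c("d1", "d2", "d3"), function(d) mk("P1_s1", "P1", d)),
            lapply(c("d1", "d2"), function(d) mk("P1_s2", "P1", d)),
            list(mk("P2_s1", "P2", "d1")),
            lapply(c("d1", "d2"), function(d) mk("P3_s2", "P3", d)),
            lapply(c("d1", "d3"), function(d) mk("P3_s1", "P3", d)))
  kept <- select_patient_sample(coll)
  ids <- unique(vapply(kept, `[[`, "", "sample_id"))
  expect_setequal(ids, c("P1_s1", "P2_s1", "P3_s1"))  # P3 tie -> lexicographic
})

test_that("outlier flags catch planted artifacts and spare clean series", {
  clean <- simulate_dose_response(b = -1.5, c = 0, d = 95, e = 0.1,
                                  noise_sd = 1, n_replicates = 2, seed = 2)
  swapped <- simulate_dose_response(b = -1.5, c = 0, d = 95, e = 0.1,
                                    noise_sd = 1, seed = 3, artifact = TRUE,
                                    sample_id = "S2")
  flags <- flag_outliers(c(clean, swapped))
  expect_false(any(flags$non_monotone[flags$sample_id == "S1"]))
  expect_true(all(flags$non_monotone[flags$sample_id == "S2"]))
  # identical replicates are never replicate-discordant
  expect_false(any(flags$replicate_discordant[flags$sample_id == "S1"]))
  # flagging is idempotent
  flags2 <- flag_outliers(c(clean, swapped))
  expect_identical(flags$flags, flags2$flags)
})

test_that("LL3/LL4 divergence is flagged when the free asymptote changes the AUC", {
  # strong negative lower asymptote: the free-asymptote fit spends half the
  # range below zero (clipped), while the zero-constrained fit cannot, so the
  # normalized AUCs separate by more than the 0.2 default
  conc <- 10^seq(-3, 0, by = 0.5)
  y <- ll4(conc, -4, -120, 100, 0.1)
  ser <- dose_response_series("S1", "S1", "D1", "rep1", conc, y)
  flags <- flag_outliers(list(ser), delta = 0.2)
  expect_true(flags$ll3_ll4_divergent[1])
  expect_gt(abs(flags$auc_ll3[1] - flags$auc_ll4[1]), 0.2)
})

test_that("response matrices assemble with provenance for exclusions", {
  tab <- data.frame(drug_id = rep(c("d1", "d2", "d3"), each = 2),
                    sample_id = rep(c("s1", "s2"), 3),
                    replicate_id = "rep1",
                    auc = seq(0.1, 0.6, by = 0.1),
                    excluded = FALSE)
  m <- build_response_matrix(tab)
  expect_equal(dim(m), c(3L, 2L))
  expect_equal(m["d2", "s1"], 0.3)
  tab$excluded[4] <- TRUE
  m2 <- build_response_matrix(tab)
  expect_equal(sum(is.na(m2)), 1L)
  expect_true(is.na(m2["d2", "s2"]))
  dup <- rbind(tab, tab[1, ])
  expect_error(build_response_matrix(dup), "duplicate")
  # replicates of the same cell are averaged
  reps <- data.frame(drug_id = "d1", sample_id = "s1",
                     replicate_id = c("rep1", "rep2"), auc = c(0.2, 0.4))
  expect_equal(build_response_matrix(reps)["d1", "s1"], 0.3)
})

test_that("simulate -> fit -> AUC round trip reproduces generating response levels", {
  conc <- 10^seq(-3, 0, by = 0.5)
  true_auc <- c(strong = NA, weak = NA)
  tabs <- list()
  for (nm in names(true_auc)) {
    d <- if (nm == "strong") 95 else 30
    fitpar <- structure(list(model = "LL4", b = -1.2, c = 0, d = d, e = 0.05,
                             rss = 0, converged = TRUE, concentrations = conc),
                        class = "ll_fit")
    true_auc[nm] <- compute_auc(fitpar, range(conc))
    ser <- simulate_dose_response(b = -1.2, c = 0, d = d, e = 0.05,
                                  concentrations = conc, noise_sd = 1.5,
                                  seed = 5, sample_id = "s1", drug_id = nm)
    fit <- fit_log_logistic(ser[[1]], "LL4")
    tabs[[nm]] <- data.frame(drug_id = nm, sample_id = "s1",
                             auc = compute_auc(fit, range(conc)))
  }
  m <- build_response_matrix(do.call(rbind, tabs))
  expect_equal(m[names(true_auc), "s1"], true_auc, tolerance = 0.05,
               ignore_attr = TRUE)
})
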