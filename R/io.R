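# Readers/writers for the package's plain-text formats: expression TSV
# (genes x samples), long dose-response CSV, AUC CSV (drugs x samples), GMT
# gene sets, and JSON truth/diagnostics records. All files are UTF-8 with '.'
# decimal separator and a mandatory header; missing cells may be empty or
# "NA" on input and are written as "NA".

check_rect <- function(path, sep) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L) stop_input("%s: need a header and at least one row", path)
  width <- lengths(strsplit(lines, sep, fixed = TRUE))
  bad <- which(width != width[1])
  if (length(bad))
    stop_input("%s: ragged row at line %d (%d fields, expected %d)",
               path, bad[1], width[bad[1]], width[1])
  invisible(length(lines))
}

#' Read a genes x samples expression matrix from TSV
#'
#' First column: gene id; remaining columns: samples; values log-scale.
#'
#' @param path TSV file path.
#' @return numeric matrix with gene row names and sample column names.
#' @export
read_expression <- function(path) {
  check_rect(path, "\t")
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   colClasses = NA, stringsAsFactors = FALSE, quote = "")
  if (anyDuplicated(df[[1]]))
    stop_input("%s: duplicate gene id '%s' (first at data line %d)",
               path, df[[1]][anyDuplicated(df[[1]])], anyDuplicated(df[[1]]) + 1L)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(df[-1], is.numeric, TRUE))[1] + 1L
    stop_input("%s: non-numeric values in column %d", path, bad)
  }
  rownames(m) <- df[[1]]
  if (anyDuplicated(colnames(m))) stop_input("%s: duplicate sample ids", path)
  m
}

#' Write a genes x samples expression matrix to TSV
#' @param expr matrix with dimnames.
#' @param path output path.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a long-format dose-response CSV
#'
#' Columns: `sample_id,patient_id,drug_id,replicate_id,concentration,response`.
#' Rows are grouped into one [dose_response_series()] per
#' (sample, drug, replicate); duplicated concentration rows within a series
#' are an error.
#'
#' @param path CSV file path.
#' @param response_is_viability if `TRUE`, responses are converted to percent
#'   inhibition as `100 - response`.
#' @return list of [dose_response_series()].
#' @export
read_dose_response <- function(path, response_is_viability = FALSE) {
  check_rect(path, ",")
  df <- read.table(path, sep = ",", header = TRUE, stringsAsFactors = FALSE)
  need <- c("sample_id", "patient_id", "drug_id", "replicate_id",
            "concentration", "response")
  if (!all(need %in% names(df)))
    stop_input("%s: missing column(s) %s", path,
               paste(setdiff(need, names(df)), collapse = ", "))
  if (!is.numeric(df$concentration) || !is.numeric(df$response))
    stop_input("%s: concentration and response must be numeric", path)
  key4 <- paste(df$sample_id, df$drug_id, df$replicate_id, df$concentration)
  if (anyDuplicated(key4))
    stop_input("%s: duplicated (sample, drug, replicate, concentration) row at data line %d",
               path, anyDuplicated(key4))
  if (response_is_viability) df$response <- 100 - df$response
  groups <- split(df, paste(df$sample_id, df$drug_id, df$replicate_id, sep = "\r"))
  out <- lapply(groups, function(gd) {
    gd <- gd[order(gd$concentration), , drop = FALSE]
    dose_response_series(gd$sample_id[1], gd$patient_id[1], gd$drug_id[1],
                         gd$replicate_id[1], gd$concentration, gd$response)
  })
  names(out) <- NULL
  out
}

#' Write dose-response series to long-format CSV
#' @param collection list of [dose_response_series()].
#' @param path output path.
#' @export
write_dose_response <- function(collection, path) {
  df <- do.call(rbind, lapply(collection, function(s)
    data.frame(sample_id = s$sample_id, patient_id = s$patient_id,
               drug_id = s$drug_id, replicate_id = s$replicate_id,
               concentration = s$concentrations, response = s$responses)))
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a drugs x samples AUC matrix from CSV
#' @param path CSV path; first column drug id, remaining columns samples.
#' @return numeric matrix (`NA` for missing cells).
#' @export
read_auc_matrix <- function(path) {
  check_rect(path, ",")
  df <- read.table(path, sep = ",", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE, quote = "")
  if (anyDuplicated(df[[1]])) stop_input("%s: duplicate drug ids", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  m
}

#' Write a drugs x samples AUC matrix to CSV
#' @param auc matrix with dimnames.
#' @param path output path.
#' @export
write_auc_matrix <- function(auc, path) {
  df <- data.frame(drug_id = rownames(auc), auc, check.names = FALSE)
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Tab-separated lines: set name, description, then gene ids.
#'
#' @param path GMT path.
#' @return list of [gene_set()] objects, named by set name.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stop_input("%s: line %d has fewer than 3 fields", path, i)
    gene_set(f[1], f[-(1:2)], description = f[2])
  })
  names(sets) <- vapply(sets, `[[`, "", "name")
  sets
}

#' Write gene sets to a GMT file
#' @param sets list of [gene_set()] objects.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s)
    paste(c(s$name, s$description, s$gene_ids), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Write a truth/diagnostics record as JSON
#' @param x list of numeric vectors/matrices.
#' @param path output path.
#' @export
write_truth_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
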