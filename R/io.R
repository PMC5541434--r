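# Delimiter auto-detection: a tab in the header wins, otherwise comma.
detect_sep <- function(path) {
  header <- readLines(path, n = 1L, warn = FALSE)
  if (length(header) == 0L) stop("empty file: ", path)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

read_labelled_table <- function(path, na_token = "NA") {
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          row.names = 1L, na.strings = na_token,
                          check.names = FALSE, comment.char = "",
                          colClasses = NA, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("table has no data rows: ", path)
  for (j in seq_along(df)) {
    col <- df[[j]]
    if (!is.numeric(col)) {
      bad <- which(!is.na(col) & is.na(suppressWarnings(as.numeric(col))))
      if (length(bad) > 0L)
        stop(sprintf("non-numeric value '%s' at row '%s', column '%s' of %s",
                     col[bad[1]], rownames(df)[bad[1]], colnames(df)[j], path))
      df[[j]] <- as.numeric(col)
    }
  }
  as.matrix(df)
}

write_labelled_table <- function(mat, path, sep = ",", na_token = "NA",
                                 corner = "id") {
  df <- data.frame(mat, check.names = FALSE)
  df <- cbind(stats::setNames(data.frame(rownames(mat)), corner), df)
  utils::write.table(df, path, sep = sep, quote = FALSE, na = na_token,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a drug x cell-line response matrix from delimited text
#'
#' Expects a header row of cell-line ids and a leading column of drug
#' ids; comma or tab delimited (auto-detected from the header line).
#' Cells equal to `na_token` become unobserved entries in the mask.
#'
#' @param path file path.
#' @param direction `"lower_is_sensitive"` for log-IC50-style responses,
#'   `"higher_is_sensitive"` for activity area.
#' @param na_token string marking a missing response (default `"NA"`).
#' @param transpose set `TRUE` if the file is cell lines x drugs.
#' @return a [response_matrix()].
#' @export
read_response_matrix <- function(path,
                                 direction = c("lower_is_sensitive",
                                               "higher_is_sensitive"),
                                 na_token = "NA", transpose = FALSE) {
  direction <- match.arg(direction)
  mat <- read_labelled_table(path, na_token = na_token)
  if (transpose) mat <- t(mat)
  response_matrix(mat, direction = direction)
}

#' Write a response matrix to delimited text
#'
#' Missing entries are written as `na_token`; the file round-trips
#' through [read_response_matrix()].
#'
#' @param R a `response_matrix`.
#' @param path output path.
#' @param sep field separator (`","` or `"\t"`).
#' @param na_token string for missing entries.
#' @export
write_response_matrix <- function(R, path, sep = ",", na_token = "NA") {
  stopifnot(inherits(R, "response_matrix"))
  write_labelled_table(R$values, path, sep = sep, na_token = na_token,
                       corner = "drug")
}

#' Write a completed prediction matrix alongside its observation mask
#'
#' Writes the dense predicted matrix to `path` and the original
#' observed-entry mask to `paste0(path, ".mask")`, so predicted and
#' measured entries stay distinguishable.  The prediction file
#' round-trips through [read_response_matrix()] with zero missing cells.
#'
#' @param R the `response_matrix` the predictions belong to (supplies
#'   ids and the mask).
#' @param predicted dense numeric matrix of the same dimensions.
#' @param path output path for the predictions.
#' @param sep field separator.
#' @return invisibly, the two paths written.
#' @export
write_predictions <- function(R, predicted, path, sep = ",") {
  stopifnot(inherits(R, "response_matrix"))
  if (!is.matrix(predicted) || !all(dim(predicted) == dim(R$values)))
    stop("`predicted` dimensions do not match the response matrix")
  if (any(!is.finite(predicted)))
    stop("`predicted` contains non-finite entries")
  dimnames(predicted) <- dimnames(R$values)
  write_labelled_table(predicted, path, sep = sep, corner = "drug")
  mask_path <- paste0(path, ".mask")
  write_labelled_table(R$mask + 0, mask_path, sep = sep, corner = "drug")
  invisible(c(path, mask_path))
}

#' Read a binary fingerprint bit table (drugs x bits)
#'
#' @param path delimited file with drug row labels and bit column labels;
#'   entries must be 0/1.
#' @return numeric 0/1 matrix with drug row names.
#' @export
read_fingerprint_matrix <- function(path) {
  mat <- read_labelled_table(path)
  if (any(is.na(mat)) || !all(mat %in% c(0, 1)))
    stop("fingerprint entries must be 0 or 1 with no missing values")
  if (anyDuplicated(rownames(mat)))
    stop("duplicate drug ids in fingerprint table")
  mat
}

#' Read a gene x cell-line expression matrix
#'
#' @param path delimited file with gene row labels and cell-line columns.
#' @return numeric matrix, genes in rows.
#' @export
read_expression_matrix <- function(path) {
  mat <- read_labelled_table(path)
  if (any(!is.finite(mat)))
    stop("expression entries must all be finite")
  if (anyDuplicated(rownames(mat)) || anyDuplicated(colnames(mat)))
    stop("duplicate gene or cell-line ids in expression table")
  mat
}

#' Read a precomputed similarity matrix
#'
#' @param path delimited square table with matching row/column ids.
#' @return a [similarity_matrix()].
#' @export
read_similarity_matrix <- function(path) {
  similarity_matrix(read_labelled_table(path))
}

#' Write a similarity matrix as a square delimited table
#'
#' @param S a `similarity_matrix`.
#' @param path output path.
#' @param sep field separator.
#' @export
write_similarity_matrix <- function(S, path, sep = ",") {
  stopifnot(inherits(S, "similarity_matrix"))
  write_labelled_table(unclass(S), path, sep = sep)
}

#' Read a binary mutation/amplification profile (cell lines x genes)
#'
#' @param path delimited file, cell-line rows, gene columns, 0/1 entries.
#' @return a [mutation_profile()].
#' @export
read_mutation_profile <- function(path) {
  mutation_profile(read_labelled_table(path))
}

#' Persist fitted latent factors
#'
#' Writes `U` (drug rows) and `V` (cell-line rows) as delimited tables
#' plus a small key-value metadata file recording K, the lambdas, the
#' scaling constant, seed, iterations run and final objective.
#'
#' @param fit an `srmf_fit` object.
#' @param dir output directory (created if needed).
#' @param sep field separator.
#' @return invisibly, the directory.
#' @export
write_factors <- function(fit, dir, sep = ",") {
  stopifnot(inherits(fit, "srmf_fit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_labelled_table(fit$U, file.path(dir, "U.csv"), sep = sep,
                       corner = "drug")
  write_labelled_table(fit$V, file.path(dir, "V.csv"), sep = sep,
                       corner = "cell")
  cfg <- fit$config
  meta <- c(sprintf("K = %d", cfg$K),
            sprintf("lambda_l = %.17g", cfg$lambda_l),
            sprintf("lambda_d = %.17g", cfg$lambda_d),
            sprintf("lambda_c = %.17g", cfg$lambda_c),
            sprintf("scale = %.17g", fit$scale),
            sprintf("seed = %d", cfg$seed),
            sprintf("iterations = %d", fit$trace$iterations_run),
            sprintf("converged = %s", fit$trace$converged),
            sprintf("objective = %.17g", utils::tail(fit$trace$objective_values, 1)))
  writeLines(meta, file.path(dir, "metadata.txt"))
  invisible(dir)
}
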