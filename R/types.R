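#' Construct a drug x cell-line response matrix
#'
#' The central data container: an `m x n` numeric matrix of drug responses
#' with `NA` marking unassayed drug/cell-line pairs, a binary observation
#' mask derived from (or supplied alongside) the values, and a sensitivity
#' direction flag.  Log-IC50 responses are *lower-is-sensitive*; activity
#' area responses are *higher-is-sensitive*.
#'
#' @param values numeric matrix, drugs in rows, cell lines in columns,
#'   with row and column names.  `NA` entries are treated as unobserved.
#' @param direction one of `"lower_is_sensitive"` (IC50-like) or
#'   `"higher_is_sensitive"` (activity-area-like).
#' @param mask optional logical/0-1 matrix of the same shape; `TRUE`/1
#'   marks an observed entry.  Defaults to `!is.na(values)`.  Entries
#'   masked out are set to `NA` in the stored values.
#' @return an object of class `response_matrix`: a list with elements
#'   `values`, `mask` (logical), `direction`, `drug_ids`, `cell_ids`.
#' @examples
#' y <- matrix(c(1, 2, NA, 4), 2, 2,
#'             dimnames = list(c("d1", "d2"), c("c1", "c2")))
#' r <- response_matrix(y, "lower_is_sensitive")
#' sum(r$mask)  # 3 observed entries
#' @export
response_matrix <- function(values,
                            direction = c("lower_is_sensitive",
                                          "higher_is_sensitive"),
                            mask = NULL) {
  direction <- match.arg(direction)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have drug row names and cell-line column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate drug ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate cell-line ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (is.null(mask)) {
    mask <- !is.na(values)
  } else {
    if (!all(dim(mask) == dim(values)))
      stop("`mask` dimensions do not match `values`")
    mask <- matrix(as.logical(mask), nrow(values), ncol(values))
    values[!mask] <- NA_real_
  }
  if (any(!is.finite(values[mask])))
    stop("observed entries must be finite")
  dimnames(mask) <- dimnames(values)
  structure(list(values = values,
                 mask = mask,
                 direction = direction,
                 drug_ids = rownames(values),
                 cell_ids = colnames(values)),
            class = "response_matrix")
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("response_matrix: %d drugs x %d cell lines (%s)\n",
              nrow(x$values), ncol(x$values), x$direction))
  n_obs <- sum(x$mask)
  cat(sprintf("  %d observed, %d missing (%.2f%% missing)\n",
              n_obs, length(x$mask) - n_obs,
              100 * (1 - n_obs / length(x$mask))))
  invisible(x)
}

#' @export
dim.response_matrix <- function(x) dim(x$values)

#' Construct a square similarity matrix
#'
#' Validates and wraps a symmetric similarity matrix over drugs or cell
#' lines: symmetric to 1e-12, unit diagonal, matching row/column ids.
#'
#' @param values square numeric matrix with identical row and column names.
#' @param kind optional label recorded on the object (e.g. `"jaccard"`,
#'   `"pearson"`); purely informational.
#' @return a numeric matrix of class `similarity_matrix` with an `ids`
#'   attribute.
#' @export
similarity_matrix <- function(values, kind = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (nrow(values) != ncol(values))
    stop("similarity matrix must be square")
  if (is.null(rownames(values)))
    stop("similarity matrix must carry ids as dimnames")
  if (!identical(rownames(values), colnames(values)))
    stop("row and column ids of a similarity matrix must match")
  if (any(!is.finite(values)))
    stop("similarity entries must be finite")
  if (max(abs(values - t(values))) > 1e-12)
    stop("similarity matrix is not symmetric (tolerance 1e-12)")
  if (max(abs(diag(values) - 1)) > 1e-8)
    stop("similarity matrix diagonal must equal 1")
  structure(values, kind = kind, ids = rownames(values),
            class = c("similarity_matrix", "matrix", "array"))
}

#' Construct a binary mutation/amplification profile
#'
#' Cell line x gene 0/1 status table used by the association tests.
#'
#' @param status 0/1 (or logical) matrix, cell lines in rows, genes in
#'   columns, with dimnames.
#' @return object of class `mutation_profile`.
#' @export
mutation_profile <- function(status) {
  if (!is.matrix(status)) stop("`status` must be a matrix")
  if (is.null(rownames(status)) || is.null(colnames(status)))
    stop("`status` must have cell-line row names and gene column names")
  st <- matrix(as.numeric(status), nrow(status), ncol(status),
               dimnames = dimnames(status))
  if (any(is.na(st)) || !all(st %in% c(0, 1)))
    stop("mutation status entries must be 0 or 1")
  structure(list(status = st,
                 cell_ids = rownames(st),
                 gene_ids = colnames(st)),
            class = "mutation_profile")
}
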