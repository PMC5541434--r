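#' Jaccard (Tanimoto) similarity between drug fingerprints
#'
#' For binary fingerprint vectors the Jaccard coefficient is
#' `|A intersect B| / |A union B|` over the set bits.  This is the
#' standard chemical-structure similarity for PubChem-style fingerprint
#' bit tables.
#'
#' @param F drugs x bits 0/1 matrix with drug row names (e.g. from
#'   [read_fingerprint_matrix()]).
#' @return a [similarity_matrix()] over drugs with entries in `[0, 1]`
#'   and unit diagonal.
#' @examples
#' f <- rbind(a = c(1, 1, 0), b = c(1, 0, 1))
#' colnames(f) <- paste0("bit", 1:3)
#' jaccard_similarity(f)["a", "b"]  # 1/3
#' @export
jaccard_similarity <- function(F) {
  if (!is.matrix(F) || is.null(rownames(F)))
    stop("`F` must be a matrix with drug row names")
  if (any(is.na(F)) || !all(F %in% c(0, 1)))
    stop("fingerprint entries must be 0 or 1")
  rs <- rowSums(F)
  if (any(rs == 0))
    stop("Jaccard similarity undefined for all-zero fingerprint of drug(s): ",
         paste(rownames(F)[rs == 0], collapse = ", "))
  inter <- tcrossprod(F)                       # |A n B|
  uni <- outer(rs, rs, "+") - inter            # |A u B|
  S <- inter / uni
  S <- (S + t(S)) / 2                          # kill float asymmetry
  diag(S) <- 1
  dimnames(S) <- list(rownames(F), rownames(F))
  similarity_matrix(S, kind = "jaccard")
}

#' Per-gene z-score normalization across cell lines
#'
#' Centers and scales each gene's expression values to mean 0, sd 1
#' across cell lines.  Genes with zero variance are left centered only.
#'
#' @param E gene x cell-line expression matrix.
#' @return normalized matrix of the same shape.
#' @export
normalize_expression <- function(E) {
  mu <- rowMeans(E)
  sd <- apply(E, 1L, stats::sd)
  sd[sd == 0] <- 1
  (E - mu) / sd
}

#' Pearson similarity between cell-line expression profiles
#'
#' Correlates each pair of cell-line columns over all genes; the
#' conventional expression-based cell-line similarity.
#'
#' @param E gene x cell-line expression matrix (at least 2 genes).
#' @param normalize if `TRUE`, apply per-gene z-scoring across cell
#'   lines ([normalize_expression()]) first.  Pairwise correlations are
#'   not invariant to this (it reweights genes), so it is an explicit
#'   flag, off by default.
#' @return a [similarity_matrix()] over cell lines with entries in
#'   `[-1, 1]`.
#' @export
pearson_similarity <- function(E, normalize = FALSE) {
  if (!is.matrix(E) || nrow(E) < 2L)
    stop("`E` must be a matrix with at least 2 genes (rows)")
  if (is.null(colnames(E)))
    stop("`E` must have cell-line column names")
  if (normalize) E <- normalize_expression(E)
  v <- apply(E, 2L, stats::var)
  if (any(v == 0))
    stop("zero-variance expression profile for cell line(s): ",
         paste(colnames(E)[v == 0], collapse = ", "))
  S <- stats::cor(E)
  S <- (S + t(S)) / 2
  diag(S) <- 1
  similarity_matrix(S, kind = "pearson")
}

#' Hierarchically cluster drugs by fingerprint distance
#'
#' Clusters drugs on the distance `1 - Jaccard(fingerprints)` and cuts
#' the dendrogram at `distance_threshold` (0.29 is the conventional
#' cut for PubChem fingerprints of the GDSC drug panel).
#'
#' @param F drugs x bits 0/1 fingerprint matrix.
#' @param distance_threshold cut height in `[0, 1]`.
#' @param linkage one of `"average"` (default), `"single"`, `"complete"`.
#' @return named integer vector of cluster labels, one per drug.
#' @export
cluster_drugs <- function(F, distance_threshold = 0.29,
                          linkage = c("average", "single", "complete")) {
  linkage <- match.arg(linkage)
  if (!is.numeric(distance_threshold) || length(distance_threshold) != 1L ||
      is.na(distance_threshold) ||
      distance_threshold < 0 || distance_threshold > 1)
    stop("`distance_threshold` must lie in [0, 1]")
  S <- jaccard_similarity(F)
  d <- stats::as.dist(1 - unclass(S))
  hc <- stats::hclust(d, method = linkage)
  stats::cutree(hc, h = distance_threshold)
}

#' Within- vs between-group similarity comparison
#'
#' Partitions the strictly-lower-triangular entries of a similarity (or
#' correlation) matrix into pairs whose two members share a group label
#' ("within") and pairs that do not ("between"), and tests the one-sided
#' alternative that within-group values are larger, by the exact
#' Mann-Whitney U test ([mwu_test()]).  This is the standard check that,
#' e.g., cell lines of the same cancer type have more similar expression
#' profiles, or drugs in the same structural cluster have more similar
#' sensitivity profiles.
#'
#' @param S a [similarity_matrix()] (or plain symmetric matrix with ids).
#' @param groups named vector of group labels covering the ids of `S`.
#' @return list with `within` and `between` value vectors, group counts,
#'   `U` and one-sided `p_value` (within > between).
#' @export
group_correlation_comparison <- function(S, groups) {
  ids <- rownames(S)
  if (is.null(ids)) stop("`S` must carry ids as dimnames")
  if (is.null(names(groups)) || !all(ids %in% names(groups)))
    stop("`groups` must be a named vector covering all ids of `S`")
  g <- as.character(groups[ids])
  if (length(unique(g)) < 2L)
    stop("need at least 2 groups to compare within vs between")
  lower <- which(lower.tri(S), arr.ind = TRUE)
  same <- g[lower[, 1]] == g[lower[, 2]]
  vals <- S[lower]
  within <- vals[same]
  between <- vals[!same]
  if (length(within) == 0L)
    stop("no within-group pairs: every group has fewer than 2 members")
  if (length(between) == 0L)
    stop("no between-group pairs")
  test <- mwu_test(within, between, alternative = "greater")
  list(within = within, between = between,
       n_within = length(within), n_between = length(between),
       U = test$U, p_value = test$p_value, method = test$method)
}
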