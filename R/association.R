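#' Test a genotype against drug sensitivity
#'
#' Splits one drug's response values by a gene's mutation/amplification
#' status and tests, with the one-sided Mann-Whitney U test
#' ([mwu_test()]), whether mutated cell lines are more sensitive
#' (`alternative = "sensitive"`) or more resistant
#' (`alternative = "resistant"`).  The response direction determines
#' which tail "sensitive" means: lower values for log-IC50, higher for
#' activity area.  The sidedness is a required argument, not a default.
#'
#' @param responses named numeric vector of response values, names are
#'   cell-line ids.
#' @param mutation a [mutation_profile()] covering those cell lines.
#' @param gene gene id (column of the profile).
#' @param direction `"lower_is_sensitive"` or `"higher_is_sensitive"`.
#' @param alternative `"sensitive"` (mutated cells more sensitive) or
#'   `"resistant"`.
#' @return list with `gene`, `n_mut`, `n_wt`, `median_mut`,
#'   `median_wt`, `U`, `p_value`, `method`, `alternative`.
#' @export
genotype_response_test <- function(responses, mutation, gene,
                                   direction = c("lower_is_sensitive",
                                                 "higher_is_sensitive"),
                                   alternative = c("sensitive",
                                                   "resistant")) {
  direction <- match.arg(direction)
  alternative <- match.arg(alternative)
  stopifnot(inherits(mutation, "mutation_profile"))
  if (is.null(names(responses)))
    stop("`responses` must be named by cell-line id")
  if (!gene %in% mutation$gene_ids)
    stop("gene '", gene, "' absent from the mutation profile")
  unknown <- setdiff(names(responses), mutation$cell_ids)
  if (length(unknown) > 0L)
    stop("cell line(s) absent from the mutation profile: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  status <- mutation$status[names(responses), gene]
  mut <- responses[status == 1]
  wt <- responses[status == 0]
  if (length(mut) == 0L)
    stop("no mutated cell lines for gene '", gene, "'")
  if (length(wt) == 0L)
    stop("no wild-type cell lines for gene '", gene, "'")
  # "more sensitive" means lower responses under lower_is_sensitive
  lower_tail <- (direction == "lower_is_sensitive") ==
    (alternative == "sensitive")
  test <- mwu_test(mut, wt, alternative = if (lower_tail) "less" else "greater")
  list(gene = gene, n_mut = length(mut), n_wt = length(wt),
       median_mut = stats::median(mut), median_wt = stats::median(wt),
       U = test$U, p_value = test$p_value, method = test$method,
       alternative = alternative)
}

#' Genotype test on observed values alone vs observed plus predicted
#'
#' Runs [genotype_response_test()] twice — once on the assayed
#' responses only, once on their concatenation with model-predicted
#' responses for unassayed cell lines — so the gain in association
#' signal contributed by matrix completion can be inspected directly.
#'
#' @param observed named numeric vector of assayed responses.
#' @param predicted named numeric vector of predicted responses for
#'   *unassayed* cell lines; its names must be disjoint from
#'   `observed`'s.
#' @param mutation a [mutation_profile()].
#' @param gene gene id.
#' @param direction,alternative as in [genotype_response_test()].
#' @return list with elements `observed` and `combined`, each a
#'   [genotype_response_test()] record.
#' @export
combined_vs_observed_test <- function(observed, predicted, mutation, gene,
                                      direction = c("lower_is_sensitive",
                                                    "higher_is_sensitive"),
                                      alternative = c("sensitive",
                                                      "resistant")) {
  direction <- match.arg(direction)
  alternative <- match.arg(alternative)
  overlap <- intersect(names(observed), names(predicted))
  if (length(overlap) > 0L)
    stop("predicted set overlaps observed set: ",
         paste(utils::head(overlap, 5), collapse = ", "))
  obs_rec <- genotype_response_test(observed, mutation, gene,
                                    direction, alternative)
  comb_rec <- genotype_response_test(c(observed, predicted), mutation, gene,
                                     direction, alternative)
  list(observed = obs_rec, combined = comb_rec)
}

#' Scan a gene panel for genotype-sensitivity associations
#'
#' Applies [genotype_response_test()] to every gene of the profile for
#' one drug's responses, skipping genes where either group is empty.
#' Benjamini-Hochberg adjusted p-values are reported when
#' `adjust = "BH"`; no correction is applied by default, matching the
#' single-gene reporting convention.
#'
#' @param responses named numeric vector of responses.
#' @param mutation a [mutation_profile()].
#' @param direction,alternative as in [genotype_response_test()].
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data frame with columns gene, n_mut, n_wt, median_mut,
#'   median_wt, U, p (and p_adj when requested).
#' @export
association_scan <- function(responses, mutation,
                             direction = c("lower_is_sensitive",
                                           "higher_is_sensitive"),
                             alternative = c("sensitive", "resistant"),
                             adjust = c("none", "BH")) {
  direction <- match.arg(direction)
  alternative <- match.arg(alternative)
  adjust <- match.arg(adjust)
  recs <- lapply(mutation$gene_ids, function(g) {
    tryCatch(genotype_response_test(responses, mutation, g,
                                    direction, alternative),
             error = function(e) NULL)
  })
  recs <- Filter(Negate(is.null), recs)
  if (length(recs) == 0L) stop("no testable genes in the profile")
  out <- do.call(rbind, lapply(recs, function(r)
    data.frame(gene = r$gene, n_mut = r$n_mut, n_wt = r$n_wt,
               median_mut = r$median_mut, median_wt = r$median_wt,
               U = r$U, p = r$p_value, stringsAsFactors = FALSE)))
  if (adjust == "BH") out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}
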