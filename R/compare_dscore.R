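# D-score differential abundance of functional categories between two
# metagenome fractions.
#
# The D-score is the pooled two-proportion z statistic on a category's
# frequency in the two fractions; the conventional significance threshold
# |D| > 2.33 corresponds to a one-sided normal tail of ~0.0099 (p < 0.009
# as usually quoted). No multiple-testing correction is applied by default,
# matching the fixed-threshold convention; `p_adjust` switches one on.

#' D-score for one category
#'
#' Signed normalized difference between a category's frequencies in two
#' fractions: positive when sample 1 is enriched. Same kernel as
#' [percentage_test()]; antisymmetric under swapping the samples; defined
#' as 0 when both proportions are degenerate.
#'
#' @param x1,n1 Category count and total for fraction 1.
#' @param x2,n2 Category count and total for fraction 2.
#' @return Signed real z statistic.
#' @export
#' @examples
#' dscore(30, 1000, 10, 1000)  # ~ +3.19, significant at 2.33
dscore <- function(x1, n1, x2, n2) {
  prop_z(x1, n1, x2, n2)
}

# Long table of per-category counts from semicolon-separated annotations.
category_count_table <- function(hits) {
  cats <- hits$categories
  cats <- cats[!is.na(cats)]
  if (length(cats) == 0L) {
    return(tibble::tibble(category_id = character(0), n = integer(0)))
  }
  ids <- unlist(strsplit(cats, ";", fixed = TRUE), use.names = FALSE)
  tab <- table(ids)
  tibble::tibble(category_id = names(tab), n = as.integer(tab))
}

#' D-score table over a category universe
#'
#' One row per functional category, comparing fraction A against fraction
#' B. Totals default to the annotated peptide counts of each fraction;
#' supply `n1`/`n2` explicitly for genome-equivalent-scaled or otherwise
#' normalized totals. Rows are flagged significant iff
#' `|dscore| > threshold` and returned sorted by descending D-score, so
#' the strongest A-enrichments rank first.
#'
#' @param hits_a,hits_b Peptide-hit tibbles for the two fractions
#'   (non-empty).
#' @param category_universe Character vector of category IDs to score;
#'   default the union of categories seen in either fraction.
#' @param threshold Significance threshold on `|dscore|` (default 2.33).
#' @param n1,n2 Totals; default `nrow(hits_a)` and `nrow(hits_b)`.
#' @param p_adjust Optional p-value adjustment method passed to
#'   [stats::p.adjust()] (e.g. `"BH"`); when set, significance is
#'   `adjusted p < 2 * (1 - pnorm(threshold))` instead of the raw
#'   threshold. Default `NULL` (fixed threshold, no correction).
#' @return Tibble with columns `category_id`, `x1`, `n1`, `x2`, `n2`,
#'   `dscore`, `p`, `significant`.
#' @export
drank_table <- function(hits_a, hits_b, category_universe = NULL,
                        threshold = 2.33,
                        n1 = nrow(hits_a), n2 = nrow(hits_b),
                        p_adjust = NULL) {
  if (nrow(hits_a) == 0L || nrow(hits_b) == 0L) {
    stop("both fractions must be non-empty", call. = FALSE)
  }
  ca <- category_count_table(hits_a)
  cb <- category_count_table(hits_b)
  if (is.null(category_universe)) {
    category_universe <- sort(union(ca$category_id, cb$category_id))
  }
  if (length(category_universe) == 0L) {
    return(tibble::tibble(category_id = character(0), x1 = integer(0),
                          n1 = integer(0), x2 = integer(0), n2 = integer(0),
                          dscore = numeric(0), p = numeric(0),
                          significant = logical(0)))
  }
  x1 <- stats::setNames(rep(0L, length(category_universe)),
                        category_universe)
  x1[ca$category_id[ca$category_id %in% category_universe]] <-
    ca$n[ca$category_id %in% category_universe]
  x2 <- stats::setNames(rep(0L, length(category_universe)),
                        category_universe)
  x2[cb$category_id[cb$category_id %in% category_universe]] <-
    cb$n[cb$category_id %in% category_universe]
  d <- mapply(prop_z, x1, MoreArgs = list(n1 = n1, n2 = n2), x2 = x2)
  p <- ifelse(d == 0, 1, 2 * stats::pnorm(-abs(d)))
  if (is.null(p_adjust)) {
    sig <- abs(d) > threshold
  } else {
    sig <- stats::p.adjust(p, method = p_adjust) <
      2 * (1 - stats::pnorm(threshold))
  }
  out <- tibble::tibble(category_id = category_universe,
                        x1 = as.integer(x1), n1 = as.integer(n1),
                        x2 = as.integer(x2), n2 = as.integer(n2),
                        dscore = unname(as.numeric(d)),
                        p = unname(as.numeric(p)),
                        significant = unname(sig))
  out[order(-out$dscore, out$category_id), ]
}
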