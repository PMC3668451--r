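# SSU rRNA composition, dereplication and alignment-depth OTU estimation.

#' Filter rRNA hits by E-value
#'
#' Keeps hits with `e_value <= e_max` (inclusive cutoff).
#'
#' @param hits rRNA-hit tibble.
#' @param e_max Maximum E-value (default 1e-30).
#' @return Surviving rows.
#' @export
filter_rrna <- function(hits, e_max = 1e-30) {
  hits[hits$e_value <= e_max, ]
}

#' SSU rRNA phylotype composition
#'
#' Percentage of each phylotype (the annotated lineage string) among all
#' SSU rRNA reads of each fraction column.
#'
#' @param hits rRNA-hit tibble (after E-value filtering).
#' @param meta Fraction metadata tibble; its rows define the columns.
#' @return An [abundance_matrix()] with `denominator_mode =
#'   "total_ssu_rrna"`; errors on a column with no rRNA hits.
#' @export
rrna_composition <- function(hits, meta) {
  keys <- fraction_key(meta$sample_id, meta$size_fraction)
  key <- fraction_key(hits$sample_id, hits$size_fraction)
  totals <- table(factor(key, levels = keys))
  if (any(totals == 0)) {
    stop(sprintf("no SSU rRNA hits for column(s): %s",
                 paste(keys[totals == 0], collapse = ", ")), call. = FALSE)
  }
  phylotypes <- sort(unique(hits$lineage))
  tab <- table(factor(hits$lineage, levels = phylotypes),
               factor(key, levels = keys))
  values <- sweep(matrix(as.numeric(tab), nrow = length(phylotypes),
                         dimnames = list(phylotypes, keys)),
                  2, as.numeric(totals), "/") * 100
  abundance_matrix(values, rank = "phylotype",
                   denominator_mode = "total_ssu_rrna")
}

# Percent identity between two placed fragments: matching positions within
# their reference-coordinate overlap, divided by the shorter fragment's
# length. Disjoint fragments score 0.
fragment_identity <- function(seq_a, start_a, end_a,
                              seq_b, start_b, end_b) {
  ws <- max(start_a, start_b)
  we <- min(end_a, end_b)
  if (we < ws) return(0)
  sub_a <- substr(seq_a, ws - start_a + 1L, we - start_a + 1L)
  sub_b <- substr(seq_b, ws - start_b + 1L, we - start_b + 1L)
  matches <- sum(utf8ToInt(sub_a) == utf8ToInt(sub_b))
  100 * matches / min(nchar(seq_a), nchar(seq_b))
}

#' Dereplicate rRNA fragments below an identity radius
#'
#' Greedy longest-first clustering, the standard OTU-radius heuristic: the
#' fragments are scanned from longest to shortest; each fragment joins the
#' first existing representative with which it shares at least `threshold`
#' percent identity (matching positions within the reference-coordinate
#' overlap, over the shorter fragment's length), otherwise it founds a new
#' representative. The returned representatives are pairwise below the
#' threshold, so the operation is idempotent.
#'
#' @param fragments Tibble with columns `read_id`, `seq`, `ref_start`,
#'   `ref_end` (plus any others, preserved).
#' @param threshold Identity radius in percent (default 97, the
#'   conventional species-level OTU radius).
#' @return The representative rows of `fragments` (longest member of each
#'   cluster), in decreasing length order.
#' @export
dereplicate <- function(fragments, threshold = 97) {
  if (!all(c("seq", "ref_start", "ref_end") %in% names(fragments))) {
    stop("`fragments` needs columns seq, ref_start, ref_end", call. = FALSE)
  }
  n <- nrow(fragments)
  if (n == 0L) return(fragments)
  ord <- order(-nchar(fragments$seq), fragments$read_id)
  fragments <- fragments[ord, ]
  rep_idx <- integer(0)
  for (i in seq_len(n)) {
    joined <- FALSE
    for (j in rep_idx) {
      id <- fragment_identity(fragments$seq[j], fragments$ref_start[j],
                              fragments$ref_end[j],
                              fragments$seq[i], fragments$ref_start[i],
                              fragments$ref_end[i])
      if (id >= threshold) {
        joined <- TRUE
        break
      }
    }
    if (!joined) rep_idx <- c(rep_idx, i)
  }
  fragments[rep_idx, ]
}

#' OTU estimate from maximum alignment depth
#'
#' Estimates OTU richness as the maximum number of (dereplicated) fragments
#' covering any single position of the full-length reference gene.
#'
#' @param representatives Dereplicated rRNA-hit tibble with `ref_start`,
#'   `ref_end`.
#' @param ref_length Reference gene length in bp.
#' @param group Group label (e.g. `"MGI"`, `"SAR11"`).
#' @param n_fragments_in Number of fragments before dereplication (for the
#'   record; default `nrow(representatives)`).
#' @param total_group_hits Total rRNA hits for the group, the denominator
#'   of normalized diversity (default `n_fragments_in`).
#' @return Object of class `otu_estimate` with fields `group`,
#'   `n_fragments_in`, `n_dereplicated`, `otu_count`, `total_group_hits`,
#'   `normalized_diversity`.
#' @export
otu_count_by_depth <- function(representatives, ref_length, group = "group",
                               n_fragments_in = nrow(representatives),
                               total_group_hits = n_fragments_in) {
  if (nrow(representatives) > 0 &&
      (any(representatives$ref_start < 1) ||
       any(representatives$ref_end > ref_length))) {
    stop("fragment interval outside the reference gene", call. = FALSE)
  }
  depth <- interval_depth(representatives$ref_start,
                          representatives$ref_end, ref_length)
  otu <- if (nrow(representatives) == 0L) 0L else max(depth)
  structure(list(
    group = group,
    n_fragments_in = n_fragments_in,
    n_dereplicated = nrow(representatives),
    otu_count = as.integer(otu),
    total_group_hits = total_group_hits,
    normalized_diversity = if (total_group_hits > 0)
      otu / total_group_hits else NA_real_
  ), class = "otu_estimate")
}

#' @export
print.otu_estimate <- function(x, ...) {
  cat(sprintf(paste0("otu_estimate [%s]: %d OTUs (max depth) from %d ",
                     "representatives of %d fragments\n",
                     "  normalized diversity %.4g (/%d group hits)\n"),
              x$group, x$otu_count, x$n_dereplicated, x$n_fragments_in,
              x$normalized_diversity, x$total_group_hits))
  invisible(x)
}

#' Full rRNA OTU pipeline: filter, dereplicate, depth
#'
#' Convenience wrapper running the E-value filter, the <`threshold`
#' dereplication and the maximum-alignment-depth OTU count on a fragment
#' table with sequences.
#'
#' @param fragments rRNA-hit tibble with a `seq` column (e.g. from
#'   [simulate_rrna_fragments()]).
#' @param ref_length Reference gene length.
#' @param group Group label.
#' @param e_max E-value cutoff (default 1e-30).
#' @param threshold Dereplication radius in percent (default 97).
#' @param raw_depth If `TRUE`, count depth on the filtered (not
#'   dereplicated) fragments; default `FALSE`.
#' @return An `otu_estimate`.
#' @export
estimate_otus <- function(fragments, ref_length, group = "group",
                          e_max = 1e-30, threshold = 97,
                          raw_depth = FALSE) {
  kept <- filter_rrna(fragments, e_max)
  reps <- if (raw_depth) kept else dereplicate(kept, threshold)
  otu_count_by_depth(reps, ref_length, group = group,
                     n_fragments_in = nrow(kept),
                     total_group_hits = nrow(kept))
}

#' Percent difference of normalized diversity between two groups
#'
#' `100 * (a - b) / b` on the normalized diversities (OTU count per total
#' group rRNA hit) of two OTU estimates.
#'
#' @param a,b `otu_estimate` objects; `b` is the baseline.
#' @return Percent difference (positive when `a` is more diverse).
#' @export
diversity_ratio <- function(a, b) {
  stopifnot(inherits(a, "otu_estimate"), inherits(b, "otu_estimate"))
  if (!is.finite(b$normalized_diversity) || b$normalized_diversity <= 0) {
    stop("baseline normalized diversity must be > 0", call. = FALSE)
  }
  100 * (a$normalized_diversity - b$normalized_diversity) /
    b$normalized_diversity
}
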