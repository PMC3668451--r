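# Tiered filtering, abundance matrices and percentage tests.

#' Identity-tier specification
#'
#' A stringency tier for annotated peptide hits: minimum percent amino-acid
#' identity (conventionally 30, 60 or 90, controlling taxonomic resolution
#' from domain/phylum through family/genus to genus/species) over a minimum
#' fraction of the read's peptide length (default 0.70). Both cutoffs are
#' inclusive.
#'
#' @param min_identity Minimum percent identity in \[0, 100\].
#' @param min_align_fraction Minimum alignment fraction in \[0, 1\].
#' @return An object of class `tier_spec`.
#' @export
#' @examples
#' tier_spec(60)
tier_spec <- function(min_identity = 30, min_align_fraction = 0.70) {
  stopifnot(min_identity >= 0, min_identity <= 100,
            min_align_fraction >= 0, min_align_fraction <= 1)
  structure(list(min_identity = min_identity,
                 min_align_fraction = min_align_fraction),
            class = "tier_spec")
}

#' @export
print.tier_spec <- function(x, ...) {
  cat(sprintf("tier_spec: >=%g%% identity over >=%g%% of alignment length\n",
              x$min_identity, 100 * x$min_align_fraction))
  invisible(x)
}

#' Filter peptide hits by identity tier
#'
#' Keeps hits with `pct_identity >= min_identity` and
#' `align_fraction >= min_align_fraction` (both inclusive). Monotone:
#' raising the identity cutoff never adds hits, so the 90 percent tier is a
#' subset of the 60 percent tier, which is a subset of the 30 percent tier.
#'
#' @param hits Peptide-hit tibble.
#' @param tier A [tier_spec()] (or a bare numeric identity cutoff).
#' @return The surviving rows of `hits`.
#' @export
filter_hits <- function(hits, tier = tier_spec()) {
  if (is.numeric(tier)) tier <- tier_spec(tier)
  stopifnot(inherits(tier, "tier_spec"))
  hits[hits$pct_identity >= tier$min_identity &
         hits$align_fraction >= tier$min_align_fraction, ]
}

#' Construct an abundance matrix (taxa x fractions, percent)
#'
#' `abundance_matrix()` wraps a numeric matrix of percentages with its
#' taxonomic rank and the denominator convention used to compute it.
#'
#' @param values Numeric matrix, taxa in rows, `(sample:fraction)` columns,
#'   percent in \[0, 100\].
#' @param rank Taxonomic rank label of the rows.
#' @param denominator_mode One of `"post_qc_reads"`,
#'   `"prokaryotic_peptides"`, `"bacterial_peptides"`,
#'   `"eukaryotic_peptides"`, `"total_ssu_rrna"`.
#' @return An `abundance_matrix` object (a matrix with attributes).
#' @export
abundance_matrix <- function(values, rank, denominator_mode) {
  stopifnot(is.matrix(values))
  denominator_mode <- match.arg(denominator_mode, DENOMINATOR_MODES)
  if (any(values < -1e-9 | values > 100 + 1e-9)) {
    stop("abundance values must lie in [0, 100]", call. = FALSE)
  }
  structure(values, rank = rank, denominator_mode = denominator_mode,
            class = c("abundance_matrix", "matrix"))
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("abundance_matrix: %d %s taxa x %d fractions (%% of %s)\n",
              nrow(x), attr(x, "rank"), ncol(x),
              attr(x, "denominator_mode")))
  print(unclass(x), ...)
  invisible(x)
}

# Denominator per fraction column for a given mode.
column_denominators <- function(hits, meta, denominator_mode, keys) {
  count_by_key <- function(subset_hits) {
    tab <- table(fraction_key(subset_hits$sample_id,
                              subset_hits$size_fraction))
    out <- stats::setNames(rep(0, length(keys)), keys)
    out[names(tab)[names(tab) %in% keys]] <-
      as.numeric(tab[names(tab) %in% keys])
    out
  }
  switch(denominator_mode,
    post_qc_reads = stats::setNames(as.numeric(meta$post_qc_reads), keys),
    prokaryotic_peptides = count_by_key(
      hits[!is.na(hits$domain) & hits$domain %in% c("Bacteria", "Archaea"), ]),
    bacterial_peptides = count_by_key(
      hits[!is.na(hits$domain) & hits$domain == "Bacteria", ]),
    eukaryotic_peptides = count_by_key(
      hits[!is.na(hits$domain) & hits$domain == "Eukaryota", ]),
    total_ssu_rrna = count_by_key(hits)
  )
}

#' Relative abundance of taxa at a rank
#'
#' For each fraction column, `100 * (hits assigned to the taxon at the
#' requested rank) / denominator`. The default denominator is the
#' fraction's post-QC read total from the metadata; alternatives use the
#' hit table itself (total prokaryotic, bacterial or eukaryotic peptides).
#' Hits lacking the requested rank are pooled into an explicit
#' `"unclassified"` row rather than dropped.
#'
#' @param hits Peptide-hit tibble (already filtered to the desired tier).
#' @param rank One of `"domain"` ... `"species"`.
#' @param meta Fraction metadata tibble; its rows define the columns.
#' @param denominator_mode See [abundance_matrix()].
#' @return An [abundance_matrix()].
#' @export
taxon_abundance <- function(hits, rank, meta,
                            denominator_mode = "post_qc_reads") {
  rank <- match.arg(rank, RANKS)
  denominator_mode <- match.arg(denominator_mode, DENOMINATOR_MODES)
  keys <- fraction_key(meta$sample_id, meta$size_fraction)
  denom <- column_denominators(hits, meta, denominator_mode, keys)
  if (any(denom <= 0)) {
    stop(sprintf("zero denominator (%s) for column(s): %s", denominator_mode,
                 paste(keys[denom <= 0], collapse = ", ")), call. = FALSE)
  }
  taxon <- hits[[rank]]
  taxon[is.na(taxon)] <- "unclassified"
  key <- fraction_key(hits$sample_id, hits$size_fraction)
  in_cols <- key %in% keys
  taxa <- sort(unique(taxon[in_cols]))
  if (length(taxa) == 0L) taxa <- "unclassified"
  counts <- matrix(0, nrow = length(taxa), ncol = length(keys),
                   dimnames = list(taxa, keys))
  if (any(in_cols)) {
    tab <- table(factor(taxon[in_cols], levels = taxa),
                 factor(key[in_cols], levels = keys))
    counts[] <- as.numeric(tab)
  }
  if (!"unclassified" %in% rownames(counts)) {
    counts <- rbind(counts, unclassified = 0)
  }
  values <- sweep(counts, 2, denom, "/") * 100
  abundance_matrix(values, rank = rank, denominator_mode = denominator_mode)
}

# Pooled two-proportion z kernel shared by percentage_test() and dscore().
prop_z <- function(x1, n1, x2, n2) {
  stopifnot(n1 > 0, n2 > 0, x1 >= 0, x1 <= n1, x2 >= 0, x2 <= n2)
  p1 <- x1 / n1
  p2 <- x2 / n2
  pbar <- (x1 + x2) / (n1 + n2)
  if (pbar <= 0 || pbar >= 1) return(0)
  (p1 - p2) / sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n2))
}

#' Significance test between two percentages
#'
#' Compares a taxon's (or category's) relative abundance between two
#' metagenomes. Because the percentages have known count denominators, the
#' default is the pooled two-proportion z-test:
#' `z = (p1 - p2) / sqrt(pbar (1 - pbar) (1/n1 + 1/n2))` with `pbar` the
#' pooled proportion, and a two-sided normal p-value. A Welch-style t
#' variant (unpooled variance, normal reference) is available via
#' `method = "welch"`. When the pooled proportion is degenerate (0 or 1)
#' the statistic is defined as 0 with p = 1. Antisymmetric under swapping
#' the two samples.
#'
#' @param x1,n1 Count and total for sample 1.
#' @param x2,n2 Count and total for sample 2.
#' @param method `"pooled"` (default) or `"welch"`.
#' @return List with elements `z` and `p`.
#' @export
#' @examples
#' percentage_test(30, 1000, 10, 1000)  # z ~ 3.19, p < 0.005
percentage_test <- function(x1, n1, x2, n2, method = c("pooled", "welch")) {
  method <- match.arg(method)
  if (method == "pooled") {
    z <- prop_z(x1, n1, x2, n2)
  } else {
    stopifnot(n1 > 0, n2 > 0, x1 >= 0, x1 <= n1, x2 >= 0, x2 <= n2)
    p1 <- x1 / n1; p2 <- x2 / n2
    v <- p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2
    z <- if (v <= 0) 0 else (p1 - p2) / sqrt(v)
  }
  list(z = z, p = if (z == 0) 1 else 2 * stats::pnorm(-abs(z)))
}

#' Select families above an abundance threshold
#'
#' Returns the taxa whose abundance strictly exceeds `threshold` percent in
#' at least one fraction column, in stable order: descending maximum
#' abundance, ties broken alphabetically. The `"unclassified"` pool is
#' never selected (it is not a family).
#'
#' @param matrix An [abundance_matrix()], conventionally at family rank.
#' @param threshold Percent threshold (strict `>`); default 0.1.
#' @return Character vector of selected taxon labels.
#' @export
select_families <- function(matrix, threshold = 0.1) {
  m <- unclass(matrix)
  m <- m[rownames(m) != "unclassified", , drop = FALSE]
  if (nrow(m) == 0L) return(character(0))
  mx <- apply(m, 1, max)
  sel <- mx > threshold
  ord <- order(-mx[sel], rownames(m)[sel])
  rownames(m)[sel][ord]
}
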