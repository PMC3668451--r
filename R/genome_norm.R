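# Effective genome size and per-genome-equivalent normalization.
#
# Model: for an average bacterial genome of size S Mbp at gene density d
# genes/Mbp carrying m single-copy markers, the expected marker fraction
# among bacterial peptides is m / (S * d). Genome equivalents are marker
# hits / m, and the effective genome size (EGS) follows as
#   EGS = bacterial_peptides / (genome_equivalents * d).
# The density d is a transparent calibration constant (default 1000
# genes/Mbp) recoverable by simulation; alternative calibrations can be
# supplied via `genes_per_mbp`.

#' Genome equivalents from single-copy marker density
#'
#' Counts marker-gene hits among bacterial peptide hits and converts them
#' to bacterial genome equivalents (`marker_hits / marker_count`) and a
#' marker density (`marker_hits / bacterial_peptides`).
#'
#' If a `domain` column is present, hits are restricted to
#' `domain == "Bacteria"`; otherwise all rows are taken as bacterial
#' peptides (the caller has pre-filtered).
#'
#' @param hits Peptide-hit tibble at the configured tier.
#' @param marker_count Size of the single-copy marker set (default 35).
#' @param genes_per_mbp Gene-density calibration (genes per Mbp,
#'   default 1000).
#' @return Object of class `genome_norm` with fields `marker_hits`,
#'   `bacterial_peptides`, `marker_density`, `genome_equivalents`,
#'   `egs_mbp` (NA when no marker hits) and `genes_per_mbp`.
#' @export
genome_equivalents <- function(hits, marker_count = 35,
                               genes_per_mbp = 1000) {
  if ("domain" %in% names(hits)) {
    hits <- hits[!is.na(hits$domain) & hits$domain == "Bacteria", ]
  }
  n_bact <- nrow(hits)
  if (n_bact == 0L) stop("zero bacterial peptides", call. = FALSE)
  marker_hits <- sum(!is.na(hits$marker_id))
  ge <- marker_hits / marker_count
  res <- structure(list(
    marker_hits = marker_hits,
    bacterial_peptides = n_bact,
    marker_density = marker_hits / n_bact,
    genome_equivalents = ge,
    egs_mbp = NA_real_,
    genes_per_mbp = genes_per_mbp
  ), class = "genome_norm")
  if (ge > 0) res$egs_mbp <- effective_genome_size(res)
  res
}

#' @export
print.genome_norm <- function(x, ...) {
  cat(sprintf(paste0("genome_norm: %d marker hits / %d bacterial peptides ",
                     "(density %.4g)\n  %.1f genome equivalents"),
              x$marker_hits, x$bacterial_peptides, x$marker_density,
              x$genome_equivalents))
  if (is.finite(x$egs_mbp)) {
    cat(sprintf("; effective genome size %.2f Mbp\n", x$egs_mbp))
  } else {
    cat("; effective genome size undefined (no marker hits)\n")
  }
  invisible(x)
}

#' Effective genome size in Mbp
#'
#' `EGS = bacterial_peptides / (genome_equivalents * genes_per_mbp)`:
#' the average bacterial genome length consistent with the observed
#' single-copy marker density. Monotone decreasing in marker density at a
#' fixed peptide count, and invariant under scaling all counts.
#'
#' @param result A `genome_norm` object from [genome_equivalents()].
#' @return Effective genome size in Mbp.
#' @export
effective_genome_size <- function(result) {
  stopifnot(inherits(result, "genome_norm"))
  if (result$genome_equivalents <= 0) {
    stop("effective genome size undefined: zero marker hits", call. = FALSE)
  }
  result$bacterial_peptides /
    (result$genome_equivalents * result$genes_per_mbp)
}

#' Count hits carrying a functional category
#'
#' @param hits Peptide-hit tibble with a semicolon-separated `categories`
#'   column.
#' @param category_id Namespaced category ID (e.g. `"COG0810"` or
#'   `"EC:3.2.1.24"`).
#' @return Integer count of hits carrying the category.
#' @export
category_hits <- function(hits, category_id) {
  cats <- hits$categories
  # delimiter-padded fixed match avoids regex metacharacters in IDs
  sum(!is.na(cats) &
        grepl(paste0(";", category_id, ";"), paste0(";", cats, ";"),
              fixed = TRUE))
}

#' Per-genome-equivalent abundance of a functional category
#'
#' Number of hits carrying `category_id` divided by the number of
#' bacterial genome equivalents — the "hits per average bacterial genome"
#' scale on which 1.0 means about one gene copy per genome.
#'
#' @param hits Peptide-hit tibble.
#' @param category_id Functional category ID.
#' @param result A `genome_norm` object for the same fraction.
#' @return Hits per genome equivalent (real, >= 0).
#' @export
category_per_genome <- function(hits, category_id, result) {
  stopifnot(inherits(result, "genome_norm"))
  if (result$genome_equivalents <= 0) {
    stop("zero genome equivalents: per-genome abundance undefined",
         call. = FALSE)
  }
  category_hits(hits, category_id) / result$genome_equivalents
}
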