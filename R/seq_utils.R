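# Small sequence and environmental-metadata utilities.

as_seq_character <- function(reads) {
  if (methods::is(reads, "XStringSet")) {
    stats::setNames(as.character(reads), names(reads))
  } else if (is.character(reads)) {
    reads
  } else {
    stop("`reads` must be a character vector or a Biostrings XStringSet",
         call. = FALSE)
  }
}

# Ungapped, prefix-anchored percent identity of two nucleotide strings,
# computed over the shorter read's length.
ungapped_identity <- function(a, b) {
  la <- nchar(a); lb <- nchar(b)
  n <- min(la, lb)
  if (n == 0L) return(0)
  ai <- utf8ToInt(substr(a, 1L, n))
  bi <- utf8ToInt(substr(b, 1L, n))
  100 * sum(ai == bi) / n
}

#' Remove artificial replicate reads
#'
#' Greedy single-pass filter for 454-style artificial replicates: a read is
#' removed iff it begins with the same three nucleotides as an earlier
#' *kept* read and shares more than `min_identity` percent nucleotide
#' identity with it (ungapped, prefix-anchored, over the shorter read's
#' length). The first occurrence is always kept, so the filter is
#' idempotent.
#'
#' @param reads Nucleotide sequences: a named character vector or a
#'   [Biostrings::DNAStringSet].
#' @param min_identity Identity threshold in percent; replicates share
#'   *more than* this (strict). Default 90.
#' @return A list with `kept` (same class as the input) and `removed`
#'   (integer count).
#' @export
#' @examples
#' remove_replicate_reads(c(a = "ACGTACGT", b = "ACGTACGT", c = "TTTTACGT"))
remove_replicate_reads <- function(reads, min_identity = 90) {
  seqs <- as_seq_character(reads)
  n <- length(seqs)
  if (n == 0L) {
    return(list(kept = reads, removed = 0L))
  }
  prefix <- substr(seqs, 1L, 3L)
  keep <- logical(n)
  kept_idx <- integer(0)
  for (i in seq_len(n)) {
    dup <- FALSE
    for (j in kept_idx) {
      if (prefix[j] == prefix[i] &&
          ungapped_identity(seqs[[j]], seqs[[i]]) > min_identity) {
        dup <- TRUE
        break
      }
    }
    if (!dup) {
      keep[i] <- TRUE
      kept_idx <- c(kept_idx, i)
    }
  }
  list(kept = reads[keep], removed = sum(!keep))
}

#' GC content of a read set
#'
#' Pooled GC percentage over all records: `100 * (G + C) / (A + C + G + T)`.
#' Ambiguous bases (N and other IUPAC codes) are excluded from both
#' numerator and denominator. Case-insensitive.
#'
#' @param reads Character vector or [Biostrings::DNAStringSet] of
#'   nucleotide sequences.
#' @return GC content in percent (unrounded).
#' @export
#' @examples
#' gc_content(c("GGCC", "ATAT"))  # 50
gc_content <- function(reads) {
  seqs <- toupper(as_seq_character(reads))
  if (length(seqs) == 0L) stop("no sequences supplied", call. = FALSE)
  counts <- c(A = 0, C = 0, G = 0, T = 0)
  for (b in names(counts)) {
    counts[b] <- sum(vapply(
      seqs, function(s) lengths(regmatches(s, gregexpr(b, s, fixed = TRUE))),
      numeric(1)))
  }
  denom <- sum(counts)
  if (denom == 0) stop("no unambiguous A/C/G/T bases in input", call. = FALSE)
  100 * (counts[["G"]] + counts[["C"]]) / denom
}

#' Percentage of photosynthetically active chlorophyll a
#'
#' `100 * [chl a] / ([chl a] + [phaeophytin a])`, the share of intact
#' (undegraded) chlorophyll a in the summed chlorophyll + phaeopigment
#' pool. Both concentrations in micrograms per litre. When both
#' concentrations are zero (e.g. aphotic deep water) the percentage is
#' defined as 0, with a warning.
#'
#' @param chl_a Chlorophyll a concentration (ug/L), non-negative.
#' @param phaeophytin_a Phaeophytin a concentration (ug/L), non-negative.
#' @return Percent in \[0, 100\] (unrounded; report rounded to integer).
#' @export
#' @examples
#' round(percent_active_chla(5.15, 1.83))  # 74
percent_active_chla <- function(chl_a, phaeophytin_a) {
  if (any(chl_a < 0) || any(phaeophytin_a < 0)) {
    stop("pigment concentrations must be non-negative", call. = FALSE)
  }
  total <- chl_a + phaeophytin_a
  out <- ifelse(total == 0, 0, 100 * chl_a / total)
  if (any(total == 0)) {
    warning("chl a and phaeophytin a both zero; returning 0%", call. = FALSE)
  }
  out
}

#' Particulate organic carbon to nitrogen ratio
#'
#' @param poc Particulate organic carbon (ug/L).
#' @param pon Particulate organic nitrogen (ug/L), strictly positive.
#' @return POC/PON ratio (unrounded).
#' @export
#' @examples
#' round(poc_pon_ratio(44.7, 3), 2)  # 14.9
poc_pon_ratio <- function(poc, pon) {
  if (any(pon <= 0)) stop("`pon` must be > 0", call. = FALSE)
  poc / pon
}
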