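# Annotated-hit table I/O and validation.
#
# All tables are plain TSV with a fixed header; lines starting with '#' are
# provenance comments and are skipped on read. Missing lineage ranks,
# categories and marker IDs are written as the empty string and represented
# as NA in memory. All coordinates are 1-based inclusive.

PEPTIDE_COLS <- c("read_id", "sample_id", "size_fraction", RANKS,
                  "pct_identity", "align_fraction", "categories", "marker_id")
RRNA_COLS <- c("read_id", "sample_id", "size_fraction", "lineage", "e_value",
               "ref_id", "ref_start", "ref_end", "pct_identity")
RECRUIT_COLS <- c("read_id", "sample_id", "size_fraction", "ref_genome",
                  "start", "end", "pct_identity")
META_COLS <- c("sample_id", "size_fraction", "habitat", "post_qc_reads")

fail_rows <- function(bad, what) {
  if (any(bad)) {
    rows <- which(bad)
    stop(sprintf("%s in row(s) %s", what,
                 paste(utils::head(rows, 5L), collapse = ", ")),
         call. = FALSE)
  }
}

check_header <- function(found, expected, path, exact = TRUE) {
  need <- if (exact) setdiff(expected, found) else setdiff(expected, found)
  if (length(need) > 0) {
    stop(sprintf("'%s': missing column(s): %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)
  }
}

read_table_checked <- function(path, col_types) {
  if (!file.exists(path)) stop(sprintf("file '%s' does not exist", path),
                               call. = FALSE)
  # parsing problems are escalated to errors below, so silence the
  # intermediate readr warning
  x <- suppressWarnings(
    readr::read_tsv(path, col_types = col_types, na = "", comment = "#",
                    progress = FALSE))
  pr <- readr::problems(x)
  if (nrow(pr) > 0) {
    stop(sprintf("'%s': malformed value in line %d (%s)", path,
                 pr$row[1] + 1L, pr$expected[1]), call. = FALSE)
  }
  x
}

#' Validate a peptide hit table
#'
#' Checks the range invariants of an annotated peptide-hit table:
#' percent identity in \[0, 100\], alignment fraction in \[0, 1\],
#' size fraction one of `"0.1"`, `"0.8"`, `"3.0"`, and (when a marker set is
#' given) marker IDs drawn from that set.
#'
#' @param hits Tibble of peptide hits.
#' @param marker_set Optional character vector of permitted marker IDs.
#' @return `hits`, invisibly, on success; errors name offending rows.
#' @export
validate_peptide_hits <- function(hits, marker_set = NULL) {
  check_header(names(hits), PEPTIDE_COLS, "peptide hits")
  fail_rows(is.na(hits$pct_identity) | hits$pct_identity < 0 |
              hits$pct_identity > 100,
            "pct_identity out of [0, 100]")
  fail_rows(is.na(hits$align_fraction) | hits$align_fraction < 0 |
              hits$align_fraction > 1,
            "align_fraction out of [0, 1]")
  fail_rows(!hits$size_fraction %in% SIZE_FRACTIONS,
            "size_fraction not one of 0.1/0.8/3.0")
  if (!is.null(marker_set)) {
    fail_rows(!is.na(hits$marker_id) & !hits$marker_id %in% marker_set,
              "marker_id not in the configured marker set")
  }
  invisible(hits)
}

peptide_col_types <- function() {
  readr::cols(
    read_id = readr::col_character(),
    sample_id = readr::col_character(),
    size_fraction = readr::col_character(),
    domain = readr::col_character(), phylum = readr::col_character(),
    class = readr::col_character(), order = readr::col_character(),
    family = readr::col_character(), genus = readr::col_character(),
    species = readr::col_character(),
    pct_identity = readr::col_double(),
    align_fraction = readr::col_double(),
    categories = readr::col_character(),
    marker_id = readr::col_character()
  )
}

#' Read and write annotated peptide hit tables
#'
#' One row per annotated read: positional lineage (domain through species,
#' missing ranks empty), percent amino-acid identity of the top reference
#' hit, fraction of the read's peptide length covered by the alignment,
#' semicolon-separated namespaced functional category IDs (`COG:`/`PFAM:`/
#' `EC:` style), and an optional single-copy marker ID.
#'
#' @param path Path to a TSV file with header
#'   `read_id sample_id size_fraction domain phylum class order family genus
#'   species pct_identity align_fraction categories marker_id`.
#' @param hits Tibble of peptide hits as returned by `read_peptide_hits()`
#'   or [simulate_peptide_hits()].
#' @param header_lines Optional character vector of provenance comment lines
#'   (each will be prefixed with `# `).
#' @return `read_peptide_hits()` returns a tibble with one row per hit;
#'   `write_peptide_hits()` returns `path` invisibly.
#' @export
read_peptide_hits <- function(path) {
  x <- read_table_checked(path, peptide_col_types())
  check_header(names(x), PEPTIDE_COLS, path)
  x <- x[PEPTIDE_COLS]
  validate_peptide_hits(x)
  x
}

write_table_with_header <- function(x, path, header_lines = NULL) {
  if (!is.null(header_lines)) {
    writeLines(paste0("# ", header_lines), path)
    readr::write_tsv(x, path, na = "", append = TRUE, col_names = TRUE,
                     progress = FALSE)
  } else {
    readr::write_tsv(x, path, na = "", progress = FALSE)
  }
  invisible(path)
}

#' @rdname read_peptide_hits
#' @export
write_peptide_hits <- function(hits, path, header_lines = NULL) {
  write_table_with_header(hits[PEPTIDE_COLS], path, header_lines)
}

#' Read and write SSU rRNA hit tables
#'
#' One row per predicted SSU rRNA read: annotated lineage string, alignment
#' E-value, and the 1-based inclusive alignment interval on a full-length
#' reference gene.
#'
#' @param path TSV with header `read_id sample_id size_fraction lineage
#'   e_value ref_id ref_start ref_end pct_identity`.
#' @param hits Tibble of rRNA hits.
#' @param header_lines Optional provenance comment lines.
#' @return A tibble of hits, or (for the writer) `path` invisibly.
#' @export
read_rrna_hits <- function(path) {
  x <- read_table_checked(path, readr::cols(
    read_id = readr::col_character(), sample_id = readr::col_character(),
    size_fraction = readr::col_character(), lineage = readr::col_character(),
    e_value = readr::col_double(), ref_id = readr::col_character(),
    ref_start = readr::col_integer(), ref_end = readr::col_integer(),
    pct_identity = readr::col_double()
  ))
  check_header(names(x), RRNA_COLS, path)
  x <- x[RRNA_COLS]
  validate_rrna_hits(x)
  x
}

#' @rdname read_rrna_hits
#' @export
write_rrna_hits <- function(hits, path, header_lines = NULL) {
  write_table_with_header(hits[RRNA_COLS], path, header_lines)
}

#' @rdname validate_peptide_hits
#' @export
validate_rrna_hits <- function(hits) {
  check_header(names(hits), RRNA_COLS, "rRNA hits")
  fail_rows(is.na(hits$e_value) | hits$e_value <= 0, "e_value not > 0")
  fail_rows(is.na(hits$ref_start) | is.na(hits$ref_end) |
              hits$ref_start < 1 | hits$ref_start > hits$ref_end,
            "invalid alignment interval (need 1 <= ref_start <= ref_end)")
  fail_rows(is.na(hits$pct_identity) | hits$pct_identity < 0 |
              hits$pct_identity > 100, "pct_identity out of [0, 100]")
  invisible(hits)
}

#' Read and write recruitment hit tables
#'
#' One row per metagenome peptide hit placed on a reference chromosome:
#' 1-based inclusive coordinates plus percent identity of the alignment.
#'
#' @param path TSV with header `read_id sample_id size_fraction ref_genome
#'   start end pct_identity`.
#' @param hits Tibble of recruitment hits.
#' @param header_lines Optional provenance comment lines.
#' @return A tibble of hits, or (for the writer) `path` invisibly.
#' @export
read_recruitment_hits <- function(path) {
  x <- read_table_checked(path, readr::cols(
    read_id = readr::col_character(), sample_id = readr::col_character(),
    size_fraction = readr::col_character(),
    ref_genome = readr::col_character(),
    start = readr::col_integer(), end = readr::col_integer(),
    pct_identity = readr::col_double()
  ))
  check_header(names(x), RECRUIT_COLS, path)
  x <- x[RECRUIT_COLS]
  fail_rows(is.na(x$start) | is.na(x$end) | x$start < 1 | x$start > x$end,
            "invalid interval (need 1 <= start <= end)")
  fail_rows(is.na(x$pct_identity) | x$pct_identity < 0 | x$pct_identity > 100,
            "pct_identity out of [0, 100]")
  x
}

#' @rdname read_recruitment_hits
#' @export
write_recruitment_hits <- function(hits, path, header_lines = NULL) {
  write_table_with_header(hits[RECRUIT_COLS], path, header_lines)
}

#' Read and write per-fraction metadata tables
#'
#' One row per (sample, size fraction): habitat label, post-QC read count
#' (the default abundance denominator) and any number of numeric
#' environmental columns (chlorophyll a, phaeophytin a, POC, PON, salinity,
#' oxygen, ...).
#'
#' @param path TSV with header starting `sample_id size_fraction habitat
#'   post_qc_reads`, followed by environmental measurement columns.
#' @param meta Tibble of fraction metadata.
#' @param header_lines Optional provenance comment lines.
#' @return A tibble, or (for the writer) `path` invisibly.
#' @export
read_fraction_meta <- function(path) {
  x <- read_table_checked(path, readr::cols(
    sample_id = readr::col_character(),
    size_fraction = readr::col_character(),
    habitat = readr::col_character(),
    .default = readr::col_double()
  ))
  check_header(names(x), META_COLS, path)
  fail_rows(is.na(x$post_qc_reads) | x$post_qc_reads < 0,
            "post_qc_reads must be a non-negative count")
  fail_rows(!x$size_fraction %in% SIZE_FRACTIONS,
            "size_fraction not one of 0.1/0.8/3.0")
  x
}

#' @rdname read_fraction_meta
#' @export
write_fraction_meta <- function(meta, path, header_lines = NULL) {
  write_table_with_header(meta, path, header_lines)
}

# "<sample_id>:<size_fraction>" column keys used by all matrices.
fraction_key <- function(sample_id, size_fraction) {
  paste(sample_id, size_fraction, sep = ":")
}
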