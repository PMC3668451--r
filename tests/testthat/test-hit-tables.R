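test_that("peptide hit tables round-trip through TSV exactly", {
  hits <- random_peptide_table(50, seed = 3)
  hits$pct_identity <- pmin(hits$pct_identity, 100)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_peptide_hits(hits, path, header_lines = c("provenance", "seed=3"))
  back <- read_peptide_hits(path)
  expect_equal(as.data.frame(back), as.data.frame(hits))
})

test_that("all four table types round-trip and validate", {
  rr <- tibble::tibble(read_id = c("a", "b"), sample_id = "GSA",
                       size_fraction = "0.1", lineage = "MGI",
                       e_value = c(1e-40, 1e-35), ref_id = "ref",
                       ref_start = c(1L, 10L), ref_end = c(200L, 300L),
                       pct_identity = c(99, 88.5))
  p1 <- withr::local_tempfile(); write_rrna_hits(rr, p1)
  expect_equal(as.data.frame(read_rrna_hits(p1)), as.data.frame(rr))

  rec <- tibble::tibble(read_id = "x", sample_id = "GSA",
                        size_fraction = "3.0", ref_genome = "NC_1",
                        start = 5L, end = 105L, pct_identity = 91.2)
  p2 <- withr::local_tempfile(); write_recruitment_hits(rec, p2)
  expect_equal(as.data.frame(read_recruitment_hits(p2)), as.data.frame(rec))

  meta <- tibble::tibble(sample_id = "GSA", size_fraction = "0.1",
                         habitat = "plume", post_qc_reads = 1000,
                         chl_a = 14.72, phaeophytin_a = 0.32)
  p3 <- withr::local_tempfile(); write_fraction_meta(meta, p3)
  expect_equal(as.data.frame(read_fraction_meta(p3)), as.data.frame(meta))
})

test_that("out-of-range and malformed rows are rejected with row context", {
  hits <- random_peptide_table(3)
  hits$pct_identity[2] <- 101
  path <- withr::local_tempfile()
  write_peptide_hits(hits, path)
  expect_error(read_peptide_hits(path), "pct_identity.*row")

  hits2 <- random_peptide_table(3)
  hits2$align_fraction[1] <- 1.5
  expect_error(validate_peptide_hits(hits2), "align_fraction")

  writeLines(c(paste(fracprof:::PEPTIDE_COLS, collapse = "\t"),
               "only\tthree\tfields"), path)
  expect_error(read_peptide_hits(path), "line")

  rr <- tibble::tibble(read_id = "a", sample_id = "s", size_fraction = "0.1",
                       lineage = "L", e_value = 0, ref_id = "r",
                       ref_start = 1L, ref_end = 5L, pct_identity = 50)
  expect_error(validate_rrna_hits(rr), "e_value")
})

test_that("replicate filter matches all-pairs oracle and is idempotent", {
  set.seed(42)
  base <- vapply(1:12, function(i) random_dna_str(60), character(1))
  reads <- character(0)
  for (b in base) {
    reads <- c(reads, b)
    # plant near-replicates: same start, few substitutions
    if (runif(1) < 0.7) {
      m <- strsplit(b, "")[[1]]
      pos <- sample(4:60, 3)
      m[pos] <- sample(c("A", "C", "G", "T"), 3, replace = TRUE)
      reads <- c(reads, paste(m, collapse = ""))
    }
    # and a distinct read sharing only the 3-nt prefix
    reads <- c(reads, paste0(substr(b, 1, 3), random_dna_str(57)))
  }
  reads <- sample(reads)  # shuffle arrival order
  names(reads) <- sprintf("r%02d", seq_along(reads))
  res <- remove_replicate_reads(reads)
  expect_equal(names(res$kept), names(reads)[oracle_replicate_kept(reads)])
  expect_equal(res$removed, length(reads) - length(res$kept))
  again <- remove_replicate_reads(res$kept)
  expect_equal(again$removed, 0L)
  expect_equal(names(again$kept), names(res$kept))
})

test_that("replicate filter boundary cases follow the >90% / 3-nt rule", {
  expect_equal(remove_replicate_reads(c(a = "ACGTACGTAC",
                                        b = "ACGTACGTAC"))$removed, 1L)
  # same first 3 nt but only 85% identical: both kept (not > 90%)
  a <- paste0("ACG", strrep("T", 17))
  bchars <- strsplit(a, "")[[1]]
  bchars[c(5, 9, 13)] <- "G"
  b <- paste(bchars, collapse = "")
  expect_equal(oracle_pair_identity(a, b), 85)
  expect_equal(remove_replicate_reads(c(x = a, y = b))$removed, 0L)
  # empty input
  empty <- remove_replicate_reads(character(0))
  expect_equal(empty$removed, 0L)
  expect_length(empty$kept, 0L)
  # DNAStringSet input preserves class
  ss <- Biostrings::DNAStringSet(c(a = "ACGTACGT", b = "ACGTACGT"))
  out <- remove_replicate_reads(ss)
  expect_s4_class(out$kept, "DNAStringSet")
  expect_equal(length(out$kept), 1L)
})

test_that("gc_content matches character-tally oracle and handles ambiguity", {
  expect_equal(gc_content("GGCC"), 100)
  expect_equal(gc_content("ATAT"), 0)
  set.seed(7)
  s <- random_dna_str(1000)
  expect_equal(gc_content(s), oracle_gc(s))
  # ambiguous bases excluded from numerator and denominator
  expect_equal(gc_content("GCNNAT"), 50)
  expect_error(gc_content("NNNN"), "unambiguous")
})

test_that("pigment and POC/PON metrics reproduce the field formulas", {
  expect_equal(round(percent_active_chla(5.15, 1.83)), 74)
  expect_equal(round(percent_active_chla(14.72, 0.32)), 98)
  expect_warning(z <- percent_active_chla(0, 0), "zero")
  expect_equal(z, 0)
  expect_error(percent_active_chla(-1, 2), "non-negative")
  # monotone increasing in chl_a at fixed phaeophytin
  chl <- seq(0.1, 20, length.out = 50)
  v <- percent_active_chla(chl, 1.5)
  expect_true(all(diff(v) > 0))
  expect_true(all(v >= 0 & v <= 100))

  expect_equal(round(poc_pon_ratio(44.7, 3), 2), 14.90)
  expect_equal(round(poc_pon_ratio(1667.5, 215), 2), 7.76)
  expect_equal(poc_pon_ratio(3.3, 3.3), 1)
  expect_error(poc_pon_ratio(10, 0), "pon")
})
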