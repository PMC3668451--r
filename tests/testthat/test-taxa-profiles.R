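test_that("tier filtering is inclusive at both cutoffs and matches a scan", {
  hits <- random_peptide_table(1e4, seed = 5)
  boundary <- hits[1:2, ]
  boundary$pct_identity <- c(29.9, 30.0)
  boundary$align_fraction <- c(0.9, 0.70)
  kept <- filter_hits(boundary, tier_spec(30, 0.7))
  expect_equal(kept$read_id, boundary$read_id[2])

  tier <- tier_spec(60, 0.7)
  got <- filter_hits(hits, tier)
  manual <- hits[vapply(seq_len(nrow(hits)), function(i) {
    hits$pct_identity[i] >= 60 && hits$align_fraction[i] >= 0.7
  }, logical(1)), ]
  expect_equal(got, manual)
})

test_that("tier filtering is monotone: 90 within 60 within 30", {
  hits <- random_peptide_table(5000, seed = 8)
  t30 <- filter_hits(hits, tier_spec(30))$read_id
  t60 <- filter_hits(hits, tier_spec(60))$read_id
  t90 <- filter_hits(hits, tier_spec(90))$read_id
  expect_true(all(t90 %in% t60))
  expect_true(all(t60 %in% t30))
})

test_that("taxon abundance uses the requested denominator and pools unclassified", {
  hits <- tibble::tibble(
    read_id = sprintf("r%03d", 1:300),
    sample_id = "GSA", size_fraction = "0.1",
    domain = "Bacteria", phylum = "P", class = NA, order = NA,
    family = c(rep("F", 200), rep(NA, 100)),
    genus = NA, species = NA,
    pct_identity = 80, align_fraction = 0.9,
    categories = NA_character_, marker_id = NA_character_)
  meta <- tibble::tibble(sample_id = "GSA", size_fraction = "0.1",
                         habitat = "plume", post_qc_reads = 400L)
  m <- taxon_abundance(hits, "family", meta)
  expect_equal(m["F", 1], 50)
  expect_equal(m["unclassified", 1], 25)
  expect_equal(attr(m, "denominator_mode"), "post_qc_reads")

  # exhaustive exclusive taxa + unclassified sum to exactly 100 when the
  # denominator is the hit universe itself
  m2 <- taxon_abundance(hits, "family", meta,
                        denominator_mode = "bacterial_peptides")
  expect_equal(sum(m2[, 1]), 100)

  # no hits at all: zero matrix, but post_qc denominator still valid
  none <- hits[0, ]
  m3 <- taxon_abundance(none, "family", meta)
  expect_equal(unname(m3["unclassified", 1]), 0)
  # zero denominator errors naming the column
  expect_error(taxon_abundance(none, "family", meta,
                               denominator_mode = "bacterial_peptides"),
               "GSA:0.1")
})

test_that("simulated two-taxon abundances recover truth within 3 SE", {
  w <- c(0.6, 0.4)
  n <- 5e4
  s <- simulate_peptide_hits(two_taxon_truth(w), n, seed = 31)
  m <- taxon_abundance(s$hits, "family", s$meta)
  se <- 100 * sqrt(w[1] * (1 - w[1]) / n)
  expect_lt(abs(m["PelA", 1] - 100 * w[1]), 3 * se)
})

test_that("percentage test matches the pooled two-proportion statistic", {
  r <- percentage_test(30, 1000, 10, 1000)
  expect_equal(r$z, 3.1944, tolerance = 1e-4)
  expect_lt(r$p, 0.005)
  # cross-check against the chi-squared equivalent without continuity
  pt <- suppressWarnings(stats::prop.test(c(30, 10), c(1000, 1000),
                                          correct = FALSE))
  expect_equal(r$z^2, unname(pt$statistic), tolerance = 1e-10)
  expect_equal(r$p, pt$p.value, tolerance = 1e-10)

  # equal proportions and degenerate pools
  expect_equal(percentage_test(5, 50, 10, 100), list(z = 0, p = 1))
  expect_equal(percentage_test(0, 50, 0, 100), list(z = 0, p = 1))
  expect_equal(percentage_test(50, 50, 100, 100), list(z = 0, p = 1))

  # antisymmetry under swapping samples
  a <- percentage_test(37, 812, 61, 955)
  b <- percentage_test(61, 955, 37, 812)
  expect_equal(a$z, -b$z)
  expect_equal(a$p, b$p)

  w <- percentage_test(30, 1000, 10, 1000, method = "welch")
  expect_gt(w$z, 3)
})

test_that("family selection is strict, stable and equals a column-max scan", {
  set.seed(19)
  vals <- matrix(runif(60, 0, 0.5), nrow = 10,
                 dimnames = list(paste0("F", sprintf("%02d", 1:10)),
                                 paste0("GS", 1:6, ":0.1")))
  vals["F03", ] <- 0.1        # max exactly at threshold: excluded
  vals["F05", ] <- 0
  vals["F05", 2] <- 0.2       # single-column exceedance: included
  m <- abundance_matrix(vals, "family", "prokaryotic_peptides")
  sel <- select_families(m, 0.1)
  expect_false("F03" %in% sel)
  expect_true("F05" %in% sel)
  brute <- rownames(vals)[apply(vals, 1, max) > 0.1]
  expect_setequal(sel, brute)
  mx <- apply(vals[sel, , drop = FALSE], 1, max)
  expect_true(all(diff(mx) <= 0))  # descending max abundance
})
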