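make_marker_hits <- function(n_bact, n_marker, domain = "Bacteria") {
  tibble::tibble(
    read_id = sprintf("r%06d", seq_len(n_bact)),
    sample_id = "GSA", size_fraction = "0.1",
    domain = domain, phylum = NA, class = NA, order = NA,
    family = NA, genus = NA, species = NA,
    pct_identity = 80, align_fraction = 0.9,
    categories = NA_character_,
    marker_id = c(rep("COG0012", n_marker),
                  rep(NA_character_, n_bact - n_marker)))
}

test_that("genome equivalents and marker density follow their definitions", {
  gn <- genome_equivalents(make_marker_hits(10000, 350))
  expect_equal(gn$genome_equivalents, 10)
  expect_equal(gn$marker_density, 0.035)
  expect_equal(gn$bacterial_peptides, 10000)

  gn0 <- genome_equivalents(make_marker_hits(100, 0))
  expect_equal(gn0$genome_equivalents, 0)
  expect_true(is.na(gn0$egs_mbp))
  expect_error(effective_genome_size(gn0), "undefined")
  expect_error(genome_equivalents(make_marker_hits(10, 0,
                                                   domain = "Eukaryota")),
               "zero bacterial")
})

test_that("effective genome size inverts the marker-density model", {
  # marker fraction exactly 35/(S*d) gives EGS = S
  S <- 1.6; d <- 1000
  n_bact <- 64000
  n_marker <- round(n_bact * 35 / (S * d))  # 1400
  gn <- genome_equivalents(make_marker_hits(n_bact, n_marker),
                           genes_per_mbp = d)
  expect_equal(effective_genome_size(gn), S, tolerance = 1e-12)

  # worked magnitude example: 430k bacterial peptides, 11585 marker hits
  gn2 <- genome_equivalents(make_marker_hits(430000, 11585))
  expect_equal(gn2$genome_equivalents, 331, tolerance = 0.01)
  expect_equal(gn2$egs_mbp, 1.30, tolerance = 0.01)

  # scale invariance: doubling all counts changes nothing
  gn3 <- genome_equivalents(make_marker_hits(860000, 23170))
  expect_equal(gn3$marker_density, gn2$marker_density)
  expect_equal(gn3$egs_mbp, gn2$egs_mbp)

  # monotone decreasing in marker density at fixed peptide count
  egs <- vapply(c(500, 1000, 2000, 4000), function(m) {
    genome_equivalents(make_marker_hits(1e5, m))$egs_mbp
  }, numeric(1))
  expect_true(all(diff(egs) < 0))
})

test_that("EGS parameter recovery from simulated communities", {
  one <- community_truth("Bacteria;P;C;O;F", 1, 2, 80, 8)
  s <- simulate_peptide_hits(one, 1e5, seed = 17)
  gn <- genome_equivalents(s$hits)
  expect_equal(gn$marker_density, 35 / 2000,
               tolerance = 3 * sqrt(0.0175 * (1 - 0.0175) / 1e5) / 0.0175)
  expect_lt(abs(gn$egs_mbp - 2) / 2, 0.10)

  # equal-read-share mixture of 1 and 3 Mbp genomes: EGS between 1 and 3,
  # near the read-share harmonic mean 1.5
  mix <- two_taxon_truth(w = c(0.5, 0.5), sizes = c(1, 3))
  sm <- simulate_peptide_hits(mix, 1e5, seed = 18)
  egs <- genome_equivalents(sm$hits)$egs_mbp
  expect_gt(egs, 1); expect_lt(egs, 3)
  expect_lt(abs(egs - 1.5) / 1.5, 0.10)
})

test_that("per-genome category abundance equals count over equivalents", {
  hits <- make_marker_hits(7000, 70)  # 2 genome equivalents
  hits$categories[1:2] <- "COG0810;COG1653"
  hits$categories[3] <- "EC:3.2.1.24"
  gn <- genome_equivalents(hits)
  expect_equal(category_per_genome(hits, "COG0810", gn), 1)
  expect_equal(category_per_genome(hits, "EC:3.2.1.24", gn), 0.5)
  expect_equal(category_per_genome(hits, "COG9999", gn), 0)
  # brute-force quotient on a random table
  rnd <- random_peptide_table(2000, seed = 23)
  rnd$domain <- "Bacteria"
  rnd$marker_id <- c(rep("COG0012", 35), rep(NA, nrow(rnd) - 35))
  g2 <- genome_equivalents(rnd)
  id <- "COG105"
  brute <- sum(vapply(strsplit(rnd$categories, ";"),
                      function(z) id %in% z, logical(1)), na.rm = TRUE)
  expect_equal(category_per_genome(rnd, id, g2),
               brute / g2$genome_equivalents)
  expect_error(category_per_genome(rnd, id, genome_equivalents(
    make_marker_hits(100, 0))), "undefined|zero")
})
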