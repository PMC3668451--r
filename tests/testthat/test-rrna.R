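frag_row <- function(read_id, seq, s, e, evalue = 1e-40) {
  tibble::tibble(read_id = read_id, sample_id = "GSA", size_fraction = "0.1",
                 lineage = "MGI", e_value = evalue, ref_id = "ref",
                 ref_start = as.integer(s), ref_end = as.integer(e),
                 pct_identity = 95, seq = seq)
}

test_that("E-value filter is inclusive at the cutoff", {
  h <- dplyr::bind_rows(frag_row("a", "ACGT", 1, 4, 1e-30),
                        frag_row("b", "ACGT", 1, 4, 1e-29),
                        frag_row("c", "ACGT", 1, 4, 1e-45))
  kept <- filter_rrna(h)
  expect_setequal(kept$read_id, c("a", "c"))
  set.seed(66)
  ev <- 10^-runif(500, 20, 40)
  rnd <- frag_row(sprintf("r%03d", 1:500), "A", 1, 1, ev)
  expect_equal(filter_rrna(rnd)$read_id, rnd$read_id[ev <= 1e-30])
})

test_that("rRNA composition is a percentage of total SSU reads per column", {
  h <- dplyr::bind_rows(
    frag_row(sprintf("a%02d", 1:30), "A", 1, 1),
    frag_row(sprintf("b%02d", 1:70), "A", 1, 1))
  h$lineage <- c(rep("SAR11", 30), rep("MGI", 70))
  meta <- tibble::tibble(sample_id = "GSA", size_fraction = "0.1",
                         habitat = "deep", post_qc_reads = 1000L)
  m <- rrna_composition(h, meta)
  expect_equal(m["SAR11", 1], 30)
  expect_equal(m["MGI", 1], 70)
  expect_equal(attr(m, "denominator_mode"), "total_ssu_rrna")
  meta2 <- dplyr::bind_rows(meta,
                            tibble::tibble(sample_id = "GSB",
                                           size_fraction = "0.1",
                                           habitat = "deep",
                                           post_qc_reads = 10L))
  expect_error(rrna_composition(h, meta2), "GSB:0.1")
})

test_that("dereplication collapses >=97% fragments and not 96% ones", {
  s <- random_dna_str(200)
  # identical pair -> one representative
  two <- dplyr::bind_rows(frag_row("a", s, 101, 300),
                          frag_row("b", s, 101, 300))
  expect_equal(nrow(dereplicate(two)), 1)
  # 96% identity (8 mismatches in 200) stays separate
  chars <- strsplit(s, "")[[1]]
  pos <- seq(5, 200, length.out = 8)
  chars[pos] <- vapply(chars[pos], function(b) {
    setdiff(c("A", "C", "G", "T"), b)[1]
  }, character(1))
  s96 <- paste(chars, collapse = "")
  expect_equal(oracle_fragment_identity(s, 101, 300, s96, 101, 300), 96)
  pair <- dplyr::bind_rows(frag_row("a", s, 101, 300),
                           frag_row("b", s96, 101, 300))
  expect_equal(nrow(dereplicate(pair)), 2)
  # idempotence
  reps <- dereplicate(pair)
  expect_identical(dereplicate(reps), reps)
})

test_that("planted clusters match the all-pairs dereplication oracle", {
  fr <- simulate_rrna_fragments(20, 3, seed = 91)
  reps <- dereplicate(fr)
  expect_equal(nrow(reps), oracle_dereplicate_count(fr))
  expect_equal(nrow(reps), 20)
  # representatives are pairwise below the radius
  for (i in seq_len(nrow(reps) - 1)) {
    for (j in (i + 1):nrow(reps)) {
      expect_lt(oracle_fragment_identity(
        reps$seq[i], reps$ref_start[i], reps$ref_end[i],
        reps$seq[j], reps$ref_start[j], reps$ref_end[j]), 97)
    }
  }
})

test_that("OTU count is the maximum per-position alignment depth", {
  # 5 fragments overlapping one position
  olap <- dplyr::bind_rows(lapply(1:5, function(i) {
    frag_row(paste0("f", i), strrep("A", 100), 50 + 10 * i, 149 + 10 * i)
  }))
  est <- otu_count_by_depth(olap, 500)
  expect_equal(est$otu_count, 5L)
  # 3 pairwise-disjoint fragments: depth never exceeds 1
  disj <- dplyr::bind_rows(frag_row("a", "AC", 1, 2),
                           frag_row("b", "AC", 10, 11),
                           frag_row("c", "AC", 20, 21))
  expect_equal(otu_count_by_depth(disj, 100)$otu_count, 1L)
  # empty input
  expect_equal(otu_count_by_depth(disj[0, ], 100)$otu_count, 0L)
  # random intervals match the per-position brute-force maximum
  set.seed(71)
  st <- sample(1:900, 300, replace = TRUE)
  en <- pmin(st + sample(5:80, 300, replace = TRUE), 1000)
  rnd <- frag_row(sprintf("r%03d", 1:300), "A", 1, 1)
  rnd$ref_start <- st; rnd$ref_end <- en
  expect_equal(otu_count_by_depth(rnd, 1000)$otu_count,
               max(oracle_depth(st, en, 1000)))
  # adding a disjoint fragment never decreases the estimate
  plus <- dplyr::bind_rows(disj, frag_row("d", "AC", 50, 51))
  expect_gte(otu_count_by_depth(plus, 100)$otu_count,
             otu_count_by_depth(disj, 100)$otu_count)
})

test_that("full pipeline recovers planted OTU counts and diversity ratio", {
  for (k in c(1, 5)) {
    fr <- simulate_rrna_fragments(k, 6, seed = 200 + k)
    expect_equal(estimate_otus(fr, 1478)$otu_count, k)
  }
  a <- otu_count_by_depth(frag_row(paste0("a", 1:3), "A", 1, 1)[0, ], 10,
                          n_fragments_in = 0, total_group_hits = 230)
  # arithmetic on constructed estimates: 23/230 vs 5/75 -> +50%
  est_a <- structure(list(group = "deep", otu_count = 23,
                          total_group_hits = 230,
                          normalized_diversity = 23 / 230),
                     class = "otu_estimate")
  est_b <- structure(list(group = "hyp", otu_count = 5,
                          total_group_hits = 75,
                          normalized_diversity = 5 / 75),
                     class = "otu_estimate")
  expect_equal(diversity_ratio(est_a, est_b), 50)
  expect_equal(diversity_ratio(est_b, est_b), 0)
  bad <- structure(list(normalized_diversity = 0), class = "otu_estimate")
  expect_error(diversity_ratio(est_a, bad), "> 0")
})
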