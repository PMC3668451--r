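# In-code fixtures shared across tests.

random_peptide_table <- function(n, seed = 1) {
  set.seed(seed)
  fams <- paste0("Fam", sprintf("%02d", 1:12))
  tibble::tibble(
    read_id = sprintf("r%05d", seq_len(n)),
    sample_id = sample(c("GSA", "GSB"), n, replace = TRUE),
    size_fraction = sample(c("0.1", "0.8", "3.0"), n, replace = TRUE),
    domain = sample(c("Bacteria", "Archaea", "Eukaryota", NA), n,
                    replace = TRUE, prob = c(0.6, 0.1, 0.2, 0.1)),
    phylum = sample(c("P1", "P2", NA), n, replace = TRUE),
    class = NA_character_, order = NA_character_,
    family = sample(c(fams, NA), n, replace = TRUE),
    genus = NA_character_, species = NA_character_,
    pct_identity = round(runif(n, 0, 100), 2),
    align_fraction = round(runif(n), 3),
    categories = ifelse(runif(n) < 0.3, NA_character_,
                        paste0("COG", sample(100:120, n, replace = TRUE))),
    marker_id = ifelse(runif(n) < 0.02, "COG0012", NA_character_)
  )
}

two_taxon_truth <- function(w = c(0.7, 0.3), sizes = c(2, 2),
                            means = c(80, 65)) {
  community_truth(
    c("Bacteria;Proteobacteria;Alphaproteobacteria;Pelagibacterales;PelA",
      "Bacteria;Bacteroidetes;Flavobacteriia;Flavobacteriales;FlaB"),
    weights = w, genome_size_mbp = sizes,
    identity_mean = means, identity_sd = c(8, 10))
}

# Two fractions drawn from the same multinomial over `k` categories:
# hit tables carrying one category per read.
null_category_fractions <- function(k = 1000, n = 2e5, seed = 1) {
  set.seed(seed)
  ids <- sprintf("COG%04d", seq_len(k))
  p <- rep(1 / k, k)
  x1 <- as.integer(stats::rmultinom(1, n, p))
  x2 <- as.integer(stats::rmultinom(1, n, p))
  list(
    a = tibble::tibble(categories = rep(ids, x1)),
    b = tibble::tibble(categories = rep(ids, x2)),
    universe = ids
  )
}
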