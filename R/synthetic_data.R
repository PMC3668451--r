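# Synthetic annotated-hit generators.
#
# These emulate the *post-annotation* tables an annotation pipeline would
# emit for a known ground-truth community, so every downstream stage can be
# exercised against recoverable truth without any external data. They do
# not simulate raw reads (no homopolymer errors, no chimeras).

#' Define a ground-truth community
#'
#' Describes the unobserved community behind a simulated metagenome: taxon
#' lineages with relative abundance weights, per-taxon genome sizes and
#' identity models, gene density, per-taxon functional category profiles
#' and the size of the single-copy marker set.
#'
#' @param lineages Character vector of semicolon-separated lineage paths
#'   (`domain;phylum;class;order;family;genus;species`, trailing ranks may
#'   be omitted).
#' @param weights Relative abundance weights (non-negative, normalized to
#'   sum to 1).
#' @param genome_size_mbp Per-taxon genome size in Mbp (> 0).
#' @param identity_mean,identity_sd Per-taxon mean and spread of percent
#'   identity to reference annotations (truncated-normal model on
#'   \[30, 100\]).
#' @param genes_per_mbp Gene density used to tie marker incidence to genome
#'   size (genes per Mbp, default 1000).
#' @param category_profiles Optional list (one element per taxon) of named
#'   numeric vectors: per-read probability that a read carries each
#'   functional category ID.
#' @param marker_set Character vector of marker IDs (default
#'   [default_marker_set()], 35 IDs).
#' @return An object of class `community_truth`.
#' @export
#' @examples
#' community_truth(
#'   c("Bacteria;Proteobacteria;Alphaproteobacteria;Pelagibacterales;Pelagibacteraceae",
#'     "Bacteria;Bacteroidetes;Flavobacteriia;Flavobacteriales;Flavobacteriaceae"),
#'   weights = c(0.7, 0.3), genome_size_mbp = c(1.3, 3.0),
#'   identity_mean = c(85, 65), identity_sd = c(10, 12))
community_truth <- function(lineages, weights, genome_size_mbp,
                            identity_mean, identity_sd,
                            genes_per_mbp = 1000,
                            category_profiles = NULL,
                            marker_set = default_marker_set()) {
  k <- length(lineages)
  if (k == 0L) stop("`lineages` must name at least one taxon", call. = FALSE)
  stopifnot(length(weights) == k, length(genome_size_mbp) == k,
            length(identity_mean) == k, length(identity_sd) == k)
  if (any(weights < 0) || sum(weights) <= 0) {
    stop("`weights` must be non-negative and sum to a positive value",
         call. = FALSE)
  }
  if (any(genome_size_mbp <= 0)) stop("`genome_size_mbp` must be > 0",
                                      call. = FALSE)
  if (genes_per_mbp <= 0) stop("`genes_per_mbp` must be > 0", call. = FALSE)
  parts <- strsplit(lineages, ";", fixed = TRUE)
  nr <- length(RANKS)
  mat <- t(vapply(parts, function(p) {
    c(p, rep(NA_character_, nr - length(p)))[seq_len(nr)]
  }, character(nr)))
  colnames(mat) <- RANKS
  lineage_tbl <- tibble::as_tibble(mat)
  if (!is.null(category_profiles)) stopifnot(length(category_profiles) == k)
  structure(list(
    lineage = lineage_tbl,
    weights = weights / sum(weights),
    genome_size_mbp = genome_size_mbp,
    identity_mean = identity_mean,
    identity_sd = identity_sd,
    genes_per_mbp = genes_per_mbp,
    category_profiles = category_profiles,
    marker_set = marker_set
  ), class = "community_truth")
}

#' @export
print.community_truth <- function(x, ...) {
  cat(sprintf("community_truth: %d taxa, gene density %g genes/Mbp\n",
              length(x$weights), x$genes_per_mbp))
  cat(sprintf("  genome sizes %s Mbp; weights %s\n",
              paste(signif(x$genome_size_mbp, 3), collapse = "/"),
              paste(signif(x$weights, 3), collapse = "/")))
  invisible(x)
}

# Inverse-CDF truncated normal on [lo, hi], vectorized over mean/sd.
rtruncnorm <- function(n, mean, sd, lo, hi) {
  p_lo <- stats::pnorm(lo, mean, sd)
  p_hi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, p_lo, p_hi), mean, sd)
}

#' Simulate an annotated peptide-hit table
#'
#' Draws reads multinomially from the truth's taxon weights; percent
#' identity from each taxon's truncated-normal identity model on
#' \[30, 100\]; alignment fraction from a two-component uniform mixture
#' with mass `frac_low_align` below 0.7; marker-gene status with
#' per-read probability `m / (S * d)` for a taxon of genome size `S` Mbp,
#' gene density `d` genes/Mbp and an `m`-gene marker set (so marker density
#' encodes genome size); and functional categories by per-category
#' Bernoulli draws from the taxon's profile.
#'
#' @param truth A [community_truth()].
#' @param n_reads Number of annotated reads to draw (> 0).
#' @param seed Integer seed; output is a pure function of
#'   (parameters, seed).
#' @param sample_id,size_fraction,habitat Labels for the generated
#'   fraction.
#' @param frac_low_align Fraction of reads with alignment fraction below
#'   0.7 (default 0.15), i.e. reads failing the standard length cutoff.
#' @param post_qc_reads Post-QC read total recorded in the metadata row
#'   (default `n_reads`, i.e. every post-QC read annotated).
#' @param env Optional named list of environmental measurements for the
#'   metadata row.
#' @return List with `hits` (peptide-hit tibble) and `meta` (one-row
#'   fraction metadata tibble).
#' @export
simulate_peptide_hits <- function(truth, n_reads, seed,
                                  sample_id = "SIM1", size_fraction = "0.1",
                                  habitat = "other",
                                  frac_low_align = 0.15,
                                  post_qc_reads = n_reads,
                                  env = NULL) {
  stopifnot(inherits(truth, "community_truth"))
  if (n_reads <= 0) stop("`n_reads` must be > 0", call. = FALSE)
  k <- length(truth$weights)
  with_seed(seed, {
    taxon <- sample.int(k, n_reads, replace = TRUE, prob = truth$weights)
    pct_identity <- rtruncnorm(n_reads, truth$identity_mean[taxon],
                               truth$identity_sd[taxon], 30, 100)
    low <- stats::runif(n_reads) < frac_low_align
    align_fraction <- ifelse(low, stats::runif(n_reads, 0, 0.7),
                             stats::runif(n_reads, 0.7, 1))
    p_marker <- length(truth$marker_set) /
      (truth$genome_size_mbp * truth$genes_per_mbp)
    is_marker <- stats::runif(n_reads) < p_marker[taxon]
    marker_id <- rep(NA_character_, n_reads)
    n_mark <- sum(is_marker)
    if (n_mark > 0) {
      marker_id[is_marker] <- sample(truth$marker_set, n_mark, replace = TRUE)
    }
    categories <- rep(NA_character_, n_reads)
    if (!is.null(truth$category_profiles)) {
      cat_list <- vector("list", n_reads)
      for (t in seq_len(k)) {
        idx <- which(taxon == t)
        prof <- truth$category_profiles[[t]]
        if (length(idx) == 0L || length(prof) == 0L) next
        draws <- matrix(stats::runif(length(idx) * length(prof)) <
                          rep(prof, each = length(idx)),
                        nrow = length(idx))
        cat_list[idx] <- apply(draws, 1, function(z) names(prof)[z],
                               simplify = FALSE)
      }
      categories <- vapply(cat_list, function(z) {
        if (is.null(z) || length(z) == 0L) NA_character_ else
          paste(z, collapse = ";")
      }, character(1))
    }
    hits <- tibble::tibble(
      read_id = sprintf("%s_%s_r%06d", sample_id, size_fraction,
                        seq_len(n_reads)),
      sample_id = sample_id,
      size_fraction = size_fraction,
      truth$lineage[taxon, ],
      pct_identity = pct_identity,
      align_fraction = align_fraction,
      categories = categories,
      marker_id = marker_id
    )
    meta <- tibble::tibble(sample_id = sample_id,
                           size_fraction = size_fraction,
                           habitat = habitat,
                           post_qc_reads = as.integer(post_qc_reads))
    if (!is.null(env)) meta <- tibble::as_tibble(c(meta, env))
    list(hits = hits, meta = meta)
  })
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_seq <- function(seq, rate) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- stats::runif(length(chars)) < rate
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1L)
    }, character(1))
  }
  paste(chars, collapse = "")
}

#' Simulate SSU rRNA gene fragments with planted OTU structure
#'
#' Builds `n_otus` distinct sequence clusters tiled onto a full-length
#' reference gene. Each OTU has its own full-length sequence variant
#' (variants are mutually random, hence far below the 97 percent species
#' radius); within an OTU, fragments are subintervals of the OTU's longest
#' fragment with a small per-base substitution rate, so within-OTU identity
#' stays at or above 97 percent. All fragments cover a common anchor
#' position, so the true OTU count is recoverable as the maximum alignment
#' depth after dereplication.
#'
#' @param n_otus Number of planted OTUs (>= 1).
#' @param reads_per_otu Fragments per OTU; scalar or vector of length
#'   `n_otus`.
#' @param ref_length Reference gene length in bp (default 1478, a typical
#'   archaeal 16S rRNA gene length).
#' @param seed Integer seed.
#' @param group Taxonomic group label recorded in `lineage`.
#' @param sample_id,size_fraction Labels for the generated fraction.
#' @param frag_len Range of fragment lengths in bp (default 200-450,
#'   pyrosequencing-scale).
#' @param mutation_rate Within-OTU per-base substitution rate
#'   (default 0.005).
#' @return Tibble of rRNA hits with an extra `seq` column holding the
#'   fragment sequence (drop it or use [write_rrna_hits()], which writes
#'   only the standard columns).
#' @export
simulate_rrna_fragments <- function(n_otus, reads_per_otu,
                                    ref_length = 1478, seed,
                                    group = "MGI",
                                    sample_id = "SIM1",
                                    size_fraction = "0.1",
                                    frag_len = c(200, 450),
                                    mutation_rate = 0.005) {
  if (n_otus < 1) stop("`n_otus` must be >= 1", call. = FALSE)
  if (length(reads_per_otu) == 1L) {
    reads_per_otu <- rep(reads_per_otu, n_otus)
  }
  stopifnot(length(reads_per_otu) == n_otus, all(reads_per_otu >= 1))
  if (max(frag_len) > ref_length) {
    stop("fragment length exceeds reference length: placement infeasible",
         call. = FALSE)
  }
  anchor <- ref_length %/% 2L
  with_seed(seed, {
    rows <- vector("list", n_otus)
    for (o in seq_len(n_otus)) {
      variant <- random_dna(ref_length)
      m <- reads_per_otu[o]
      lens <- sort(round(stats::runif(m, frag_len[1], frag_len[2])),
                   decreasing = TRUE)
      # longest fragment first; anchor-covering placement
      l1 <- lens[1]
      s1 <- sample(max(1L, anchor - l1 + 1L):min(anchor, ref_length - l1 + 1L),
                   1L)
      e1 <- s1 + l1 - 1L
      starts <- integer(m); ends <- integer(m); seqs <- character(m)
      starts[1] <- s1; ends[1] <- e1
      seqs[1] <- substr(variant, s1, e1)
      if (m > 1) {
        for (j in 2:m) {
          lj <- lens[j]
          lo <- max(s1, anchor - lj + 1L)
          hi <- min(anchor, e1 - lj + 1L)
          sj <- if (lo >= hi) lo else sample(lo:hi, 1L)
          starts[j] <- sj; ends[j] <- sj + lj - 1L
          seqs[j] <- mutate_seq(substr(variant, sj, ends[j]), mutation_rate)
        }
      }
      rows[[o]] <- tibble::tibble(
        read_id = sprintf("%s_otu%02d_f%03d", group, o, seq_len(m)),
        sample_id = sample_id, size_fraction = size_fraction,
        lineage = group,
        e_value = 10^-stats::runif(m, 31, 60),
        ref_id = paste0(group, "_16S_ref"),
        ref_start = starts, ref_end = ends,
        pct_identity = 100 * (1 - mutation_rate) -
          stats::runif(m, 0, 2),
        seq = seqs
      )
    }
    dplyr::bind_rows(rows)
  })
}

#' Simulate recruitment-plot hits on a reference chromosome
#'
#' Places hit intervals uniformly on a reference chromosome with uniform
#' lengths in `len_range`, assigning each hit to the high-identity
#' (\[90, 100\]) or low-identity (\[30, 90)) tier with the given mixture
#' weights. Expected per-tier coverage depth is analytically
#' `n * weight * mean_length / ref_length`.
#'
#' @param n_hits Number of hits.
#' @param ref_length Reference chromosome length in bp.
#' @param identity_mixture Length-2 weights for the (>= 90, 30-90) tiers;
#'   must sum to 1.
#' @param seed Integer seed.
#' @param len_range Hit length range in bp (default 150-450).
#' @param ref_genome,sample_id,size_fraction Labels.
#' @return Tibble of recruitment hits.
#' @export
simulate_recruitment <- function(n_hits, ref_length,
                                 identity_mixture = c(0.2, 0.8), seed,
                                 len_range = c(150, 450),
                                 ref_genome = "REF",
                                 sample_id = "SIM1",
                                 size_fraction = "0.1") {
  if (abs(sum(identity_mixture) - 1) > 1e-8) {
    stop("`identity_mixture` weights must sum to 1", call. = FALSE)
  }
  if (max(len_range) > ref_length) {
    stop("hit length exceeds reference length", call. = FALSE)
  }
  with_seed(seed, {
    high <- stats::runif(n_hits) < identity_mixture[1]
    pct <- ifelse(high, stats::runif(n_hits, 90, 100),
                  stats::runif(n_hits, 30, 90))
    len <- round(stats::runif(n_hits, len_range[1], len_range[2]))
    start <- floor(stats::runif(n_hits, 1, ref_length - len + 1))
    tibble::tibble(
      read_id = sprintf("%s_%s_h%06d", sample_id, size_fraction,
                        seq_len(n_hits)),
      sample_id = sample_id, size_fraction = size_fraction,
      ref_genome = ref_genome,
      start = as.integer(start), end = as.integer(start + len - 1),
      pct_identity = pct
    )
  })
}
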