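# End-to-end pipeline: simulate -> profile -> egs/normalize -> dscore ->
# recruit -> rrna-otu -> cluster, with provenance-headed TSV outputs.

#' Pipeline run configuration
#'
#' Bundles thresholds, seed and output directory for [run_pipeline()]. All
#' literature-convention thresholds are defaults here, never hard-coded in
#' the stages.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed driving every stochastic stage.
#' @param n_reads Annotated reads per simulated fraction.
#' @param tiers Identity tiers (percent) profiled.
#' @param min_align_fraction Alignment-length cutoff (default 0.70).
#' @param dscore_threshold Significance threshold on |D| (default 2.33).
#' @param family_threshold Family-selection threshold in percent
#'   (default 0.1).
#' @param derep_threshold rRNA dereplication radius in percent
#'   (default 97).
#' @param e_max rRNA E-value cutoff (default 1e-30).
#' @param meta_path Optional path to a fraction-metadata TSV for the
#'   env-metrics stage; default the bundled coastal-margin sample table.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir, seed = 1L, n_reads = 5000L,
                       tiers = c(30, 60, 90),
                       min_align_fraction = 0.70,
                       dscore_threshold = 2.33,
                       family_threshold = 0.1,
                       derep_threshold = 97,
                       e_max = 1e-30,
                       meta_path = system.file("extdata",
                                              "coastal_margin_fraction_meta.tsv",
                                              package = "fracprof")) {
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 n_reads = as.integer(n_reads), tiers = tiers,
                 min_align_fraction = min_align_fraction,
                 dscore_threshold = dscore_threshold,
                 family_threshold = family_threshold,
                 derep_threshold = derep_threshold,
                 e_max = e_max, meta_path = meta_path),
            class = "run_config")
}

provenance_header <- function(config) {
  c(sprintf("fracprof %s", as.character(utils::packageVersion("fracprof"))),
    sprintf("seed=%d", config$seed),
    sprintf(paste0("thresholds: align_fraction>=%.2f |D|>%.2f ",
                   "family>%.2f%% derep<%g%% e<=%g"),
            config$min_align_fraction, config$dscore_threshold,
            config$family_threshold, config$derep_threshold, config$e_max))
}

# Ground-truth communities for the demo's four habitats. Weights and
# genome sizes sketch the study system: small-genome free-living clades
# (SAR11-like), bloom-associated Flavobacteria and roseobacters,
# ammonia-oxidizing archaea in dark/low-oxygen water, anaerobes in the
# deep sample, and a terrigenous/riverborne component in the estuary.
demo_truths <- function() {
  lineages <- c(
    "Bacteria;Proteobacteria;Alphaproteobacteria;Pelagibacterales;Pelagibacteraceae;Pelagibacter",
    "Bacteria;Bacteroidetes;Flavobacteriia;Flavobacteriales;Flavobacteriaceae;Polaribacter",
    "Bacteria;Proteobacteria;Alphaproteobacteria;Rhodobacterales;Rhodobacteraceae;Roseobacter",
    "Bacteria;Proteobacteria;Gammaproteobacteria;Cellvibrionales;Halieaceae;Haliea",
    "Archaea;Thaumarchaeota;Nitrososphaeria;Nitrosopumilales;Nitrosopumilaceae;Nitrosopumilus",
    "Bacteria;Proteobacteria;Deltaproteobacteria;Desulfobacterales;Desulfobacteraceae;Desulfobacter",
    "Bacteria;Actinobacteria;Actinomycetia;Actinomycetales;Microbacteriaceae;Candidatus Planktophila",
    "Eukaryota;Bacillariophyta;Coscinodiscophyceae;Thalassiosirales;Thalassiosiraceae;Thalassiosira")
  sizes <- c(1.3, 3.2, 4.1, 3.0, 1.6, 4.5, 1.4, 30)
  imean <- c(88, 72, 70, 68, 80, 60, 75, 55)
  isd <- c(8, 10, 10, 10, 9, 10, 9, 10)
  profiles <- list(
    Pelagibacter = c(COG0810 = 0.004, COG1653 = 0.01),
    Polaribacter = c(COG0810 = 0.03, "EC:3.2.1.24" = 0.01),
    Roseobacter = c(COG0810 = 0.015, COG0738 = 0.008),
    Haliea = c(COG0810 = 0.012),
    Nitrosopumilus = c("EC:1.7.2.1" = 0.006),
    Desulfobacter = c(COG2221 = 0.01, "EC:1.2.7.3" = 0.008),
    Planktophila = c(COG1653 = 0.012),
    Thalassiosira = c(COG0056 = 0.005))
  weight_sets <- list(
    hypoxic = list(`0.1` = c(30, 14, 8, 8, 19, 2, 2, 17),
                   `0.8` = c(15, 22, 18, 10, 6, 3, 3, 23),
                   `3.0` = c(6, 22, 14, 8, 3, 5, 2, 40)),
    deep = list(`0.1` = c(22, 8, 6, 6, 28, 12, 2, 16),
                `0.8` = c(12, 12, 10, 8, 14, 18, 2, 24),
                `3.0` = c(6, 10, 8, 6, 8, 22, 2, 38)),
    plume = list(`0.1` = c(28, 18, 12, 12, 2, 1, 4, 23),
                 `0.8` = c(12, 24, 20, 12, 1, 1, 4, 26),
                 `3.0` = c(5, 20, 14, 8, 1, 2, 2, 48)),
    etm = list(`0.1` = c(16, 14, 10, 8, 2, 4, 24, 22),
               `0.8` = c(10, 20, 16, 10, 2, 6, 12, 24),
               `3.0` = c(5, 16, 10, 6, 2, 18, 4, 39)))
  lapply(weight_sets, function(fracs) {
    lapply(fracs, function(w) {
      community_truth(lineages, weights = w, genome_size_mbp = sizes,
                      identity_mean = imean, identity_sd = isd,
                      category_profiles = unname(profiles))
    })
  })
}

#' Environmental metrics from a fraction metadata table
#'
#' Derived per-row metrics: percentage of photosynthetically active
#' chlorophyll a and the POC/PON ratio.
#'
#' @param meta Fraction metadata tibble with columns `chl_a`,
#'   `phaeophytin_a`, `poc`, `pon`.
#' @return Tibble with `sample_id`, `size_fraction`, `pct_active_chla`
#'   (rounded to integer, the reporting convention) and `poc_pon`
#'   (2 decimals).
#' @export
env_metrics <- function(meta) {
  need <- c("chl_a", "phaeophytin_a", "poc", "pon")
  if (!all(need %in% names(meta))) {
    stop(sprintf("metadata lacks column(s): %s",
                 paste(setdiff(need, names(meta)), collapse = ", ")),
         call. = FALSE)
  }
  tibble::tibble(
    sample_id = meta$sample_id,
    size_fraction = meta$size_fraction,
    pct_active_chla = round(suppressWarnings(
      percent_active_chla(meta$chl_a, meta$phaeophytin_a))),
    poc_pon = round(poc_pon_ratio(meta$poc, meta$pon), 2)
  )
}

#' Run the full analysis pipeline on a simulated design
#'
#' Executes simulate, profile, effective-genome-size/normalize, D-score,
#' recruitment, rRNA-OTU, clustering and env-metrics stages over a
#' 4-habitat x 3-size-fraction design, writing provenance-headed TSVs to
#' `config$out_dir`. Byte-identical across runs for a fixed seed. On any
#' stage failure, files created by the run are removed and the error names
#' the failing stage.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory stage results and
#'   `files` (paths written).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- provenance_header(config)
  written <- character(0)
  emit <- function(x, name) {
    path <- file.path(config$out_dir, name)
    write_table_with_header(x, path, hdr)
    written <<- c(written, path)
    path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  results <- list()

  # -- simulate -------------------------------------------------------
  sims <- stage("simulate", {
    truths <- demo_truths()
    samples <- c(hypoxic = "GS310", deep = "GS311", plume = "GS312",
                 etm = "GS313")
    out <- list(hits = list(), meta = list())
    i <- 0L
    for (hab in names(truths)) {
      for (frac in names(truths[[hab]])) {
        i <- i + 1L
        sim <- simulate_peptide_hits(
          truths[[hab]][[frac]], n_reads = config$n_reads,
          seed = config$seed + i, sample_id = samples[[hab]],
          size_fraction = frac, habitat = hab)
        out$hits[[fraction_key(samples[[hab]], frac)]] <- sim$hits
        out$meta[[fraction_key(samples[[hab]], frac)]] <- sim$meta
      }
    }
    out
  })
  hits_all <- dplyr::bind_rows(sims$hits)
  meta_all <- dplyr::bind_rows(sims$meta)
  emit(hits_all, "peptide_hits.tsv")
  emit(meta_all, "fraction_meta.tsv")
  results$meta <- meta_all

  # -- profile --------------------------------------------------------
  results$profiles <- stage("profile", {
    lapply(stats::setNames(config$tiers, paste0("tier", config$tiers)),
           function(tt) {
      kept <- filter_hits(hits_all,
                          tier_spec(tt, config$min_align_fraction))
      mat <- taxon_abundance(kept, "family", meta_all,
                             denominator_mode = "prokaryotic_peptides")
      emit(tibble::as_tibble(unclass(mat), rownames = "family"),
           sprintf("family_abundance_tier%d.tsv", tt))
      mat
    })
  })

  # -- egs / normalize ------------------------------------------------
  results$egs <- stage("egs", {
    kept <- filter_hits(hits_all,
                        tier_spec(30, config$min_align_fraction))
    keys <- fraction_key(meta_all$sample_id, meta_all$size_fraction)
    rows <- lapply(seq_len(nrow(meta_all)), function(i) {
      h <- kept[fraction_key(kept$sample_id, kept$size_fraction) ==
                  keys[i], ]
      gn <- genome_equivalents(h)
      tibble::tibble(sample_id = meta_all$sample_id[i],
                     size_fraction = meta_all$size_fraction[i],
                     bacterial_peptides = gn$bacterial_peptides,
                     marker_hits = gn$marker_hits,
                     genome_equivalents = gn$genome_equivalents,
                     egs_mbp = gn$egs_mbp,
                     tonb_per_genome = category_per_genome(h, "COG0810",
                                                           gn))
    })
    tab <- dplyr::bind_rows(rows)
    emit(tab, "genome_size.tsv")
    tab
  })

  # -- dscore ---------------------------------------------------------
  results$dscore <- stage("dscore", {
    kept <- filter_hits(hits_all,
                        tier_spec(30, config$min_align_fraction))
    key <- fraction_key(kept$sample_id, kept$size_fraction)
    out <- list()
    for (sid in unique(meta_all$sample_id)) {
      a <- kept[key == fraction_key(sid, "0.1"), ]
      b <- kept[key == fraction_key(sid, "3.0"), ]
      tab <- drank_table(a, b, threshold = config$dscore_threshold)
      tab <- tibble::tibble(sample_id = sid, tab)
      out[[sid]] <- tab
    }
    all <- dplyr::bind_rows(out)
    emit(all, "dscore_0.1_vs_3.0.tsv")
    all
  })

  # -- recruit --------------------------------------------------------
  results$recruitment <- stage("recruit", {
    ref_len <- 50000L
    rec_deep <- simulate_recruitment(2000, ref_len,
                                     identity_mixture = c(0.1, 0.9),
                                     seed = config$seed + 101,
                                     ref_genome = "SCM1_like",
                                     sample_id = "GS311")
    rec_hyp <- simulate_recruitment(4000, ref_len,
                                    identity_mixture = c(0.3, 0.7),
                                    seed = config$seed + 102,
                                    ref_genome = "SCM1_like",
                                    sample_id = "GS310")
    prof_deep <- recruit(rec_deep, ref_len)
    prof_hyp <- recruit(rec_hyp, ref_len)
    window <- c(21000L, 21830L)  # amoA-style locus window
    summ <- dplyr::bind_rows(
      tibble::tibble(sample_id = "GS311",
                     recruitment_summary(prof_deep),
                     locus_hits = locus_hits(rec_deep, window)),
      tibble::tibble(sample_id = "GS310",
                     recruitment_summary(prof_hyp),
                     locus_hits = locus_hits(rec_hyp, window)))
    emit(summ, "recruitment_summary.tsv")
    contrast <- identity_contrast(rec_hyp, rec_deep)
    list(deep = prof_deep, hypoxic = prof_hyp, summary = summ,
         contrast = contrast)
  })

  # -- rrna-otu -------------------------------------------------------
  results$otus <- stage("rrna-otu", {
    frag_deep <- simulate_rrna_fragments(23, 10, seed = config$seed + 201,
                                         group = "MGI",
                                         sample_id = "GS311")
    frag_hyp <- simulate_rrna_fragments(5, 15, seed = config$seed + 202,
                                        group = "MGI",
                                        sample_id = "GS310")
    est_deep <- estimate_otus(frag_deep, 1478, group = "MGI_deep",
                              e_max = config$e_max,
                              threshold = config$derep_threshold)
    est_hyp <- estimate_otus(frag_hyp, 1478, group = "MGI_hypoxic",
                             e_max = config$e_max,
                             threshold = config$derep_threshold)
    tab <- tibble::tibble(
      group = c(est_deep$group, est_hyp$group),
      n_fragments = c(est_deep$n_fragments_in, est_hyp$n_fragments_in),
      n_dereplicated = c(est_deep$n_dereplicated, est_hyp$n_dereplicated),
      otu_count = c(est_deep$otu_count, est_hyp$otu_count),
      normalized_diversity = c(est_deep$normalized_diversity,
                               est_hyp$normalized_diversity))
    emit(tab, "rrna_otu.tsv")
    list(deep = est_deep, hypoxic = est_hyp, table = tab,
         diversity_excess_pct = diversity_ratio(est_deep, est_hyp))
  })

  # -- cluster --------------------------------------------------------
  results$cluster <- stage("cluster", {
    mat60 <- results$profiles[["tier60"]]
    if (is.null(mat60)) mat60 <- results$profiles[[1]]
    fams <- select_families(mat60, threshold = config$family_threshold)
    sub <- unclass(mat60)[fams, , drop = FALSE]
    cl <- hier_cluster_2d(sub)
    emit(tibble::as_tibble(cl$matrix, rownames = "family"),
         "family_clustered.tsv")
    trees <- file.path(config$out_dir, "family_trees.nwk")
    writeLines(c(cluster_newick(cl$row_hclust),
                 cluster_newick(cl$col_hclust)), trees)
    written <<- c(written, trees)
    pca <- pca_profiles(sub)
    emit(tibble::as_tibble(pca$scores, rownames = "fraction"),
         "pca_scores.tsv")
    list(selected_families = fams, clustering = cl, pca = pca)
  })

  # -- env-metrics ----------------------------------------------------
  results$env <- stage("env-metrics", {
    meta <- read_fraction_meta(config$meta_path)
    tab <- env_metrics(meta)
    emit(tab, "env_metrics.tsv")
    tab
  })

  results$files <- written
  invisible(results)
}
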