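# Independent brute-force oracles. These deliberately re-derive each
# quantity by the most literal method available (per-position loops,
# all-pairs scans, naive agglomeration) and share no code with the
# package implementations they check.

# Per-position depth by explicit loop over hits.
oracle_depth <- function(starts, ends, ref_length) {
  depth <- integer(ref_length)
  for (i in seq_along(starts)) {
    idx <- starts[i]:ends[i]
    depth[idx] <- depth[idx] + 1L
  }
  depth
}

# Interval-overlap count by explicit per-hit test.
oracle_locus_hits <- function(starts, ends, win) {
  n <- 0L
  for (i in seq_along(starts)) {
    if (max(starts[i], win[1]) <= min(ends[i], win[2])) n <- n + 1L
  }
  n
}

# Character-tally GC content.
oracle_gc <- function(seqs) {
  chars <- unlist(strsplit(toupper(paste(seqs, collapse = "")), ""))
  tab <- table(factor(chars, levels = c("A", "C", "G", "T")))
  100 * (tab[["G"]] + tab[["C"]]) / sum(tab)
}

# Position-wise identity over the shorter read, via split characters.
oracle_pair_identity <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- min(length(ca), length(cb))
  if (n == 0) return(0)
  100 * mean(ca[seq_len(n)] == cb[seq_len(n)])
}

# Greedy replicate filter driven by a precomputed all-pairs identity
# matrix (the package scans sequences directly).
oracle_replicate_kept <- function(seqs, min_identity = 90) {
  n <- length(seqs)
  pre <- substr(seqs, 1, 3)
  idm <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    idm[i, j] <- oracle_pair_identity(seqs[i], seqs[j])
  }
  kept <- integer(0)
  for (i in seq_len(n)) {
    dup <- any(vapply(kept, function(j) {
      pre[j] == pre[i] && idm[j, i] > min_identity
    }, logical(1)))
    if (!dup) kept <- c(kept, i)
  }
  kept
}

# Fragment identity from an alignment laid out on the reference axis.
oracle_fragment_identity <- function(sa, s1, e1, sb, s2, e2) {
  ref_len <- max(e1, e2)
  row1 <- rep(NA_character_, ref_len)
  row2 <- rep(NA_character_, ref_len)
  row1[s1:e1] <- strsplit(sa, "")[[1]]
  row2[s2:e2] <- strsplit(sb, "")[[1]]
  both <- !is.na(row1) & !is.na(row2)
  100 * sum(row1[both] == row2[both]) / min(nchar(sa), nchar(sb))
}

# All-pairs greedy dereplication from a precomputed identity matrix.
oracle_dereplicate_count <- function(frags, threshold = 97) {
  n <- nrow(frags)
  ord <- order(-nchar(frags$seq), frags$read_id)
  frags <- frags[ord, ]
  idm <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    idm[i, j] <- oracle_fragment_identity(
      frags$seq[i], frags$ref_start[i], frags$ref_end[i],
      frags$seq[j], frags$ref_start[j], frags$ref_end[j])
  }
  reps <- integer(0)
  for (i in seq_len(n)) {
    if (!any(vapply(reps, function(j) idm[j, i] >= threshold, logical(1)))) {
      reps <- c(reps, i)
    }
  }
  length(reps)
}

# Naive O(n^3) complete-linkage agglomeration; returns the cophenetic
# distance matrix (which determines the dendrogram) and the merge heights.
oracle_complete_linkage <- function(d) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  members <- as.list(seq_len(n))
  active <- rep(TRUE, n)
  coph <- matrix(0, n, n)
  heights <- numeric(0)
  cd <- dm
  for (step in seq_len(n - 1)) {
    idx <- which(active)
    best <- c(NA, NA); bestd <- Inf
    for (a in idx) for (b in idx) {
      if (a < b && cd[a, b] < bestd) { bestd <- cd[a, b]; best <- c(a, b) }
    }
    a <- best[1]; b <- best[2]
    for (i in members[[a]]) for (j in members[[b]]) {
      coph[i, j] <- coph[j, i] <- bestd
    }
    heights <- c(heights, bestd)
    for (k in idx) {
      if (k != a && k != b) cd[a, k] <- cd[k, a] <- max(cd[a, k], cd[b, k])
    }
    members[[a]] <- c(members[[a]], members[[b]])
    active[b] <- FALSE
  }
  dimnames(coph) <- dimnames(dm)
  list(cophenetic = coph, heights = heights)
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
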