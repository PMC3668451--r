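# Recruitment-plot computation: per-position depth by identity tier,
# X-coverage, locus-window hit counts and mean-identity contrasts.

DEFAULT_TIERS <- list("30-90" = c(30, 90), ">=90" = c(90, 100))

# 1-based inclusive interval depth via difference-array accumulation.
interval_depth <- function(starts, ends, ref_length) {
  if (length(starts) == 0L) return(integer(ref_length))
  add <- tabulate(starts, nbins = ref_length)
  sub <- tabulate(ends + 1L, nbins = ref_length)
  cumsum(add - sub)
}

#' Recruitment profile of hits on a reference chromosome
#'
#' Assigns each hit to an identity tier (default: low tier \[30, 90),
#' high tier \[90, 100\] — a hit at exactly 90 percent goes to the high
#' tier), accumulates per-position depth over the hit's 1-based inclusive
#' interval, and summarizes each tier by X-coverage (summed aligned length
#' divided by reference length), hit count and mean percent identity.
#'
#' @param hits Recruitment-hit tibble (`start`, `end`, `pct_identity`,
#'   `read_id`; see [read_recruitment_hits()]).
#' @param ref_length Reference chromosome length in bp.
#' @param tiers Named list of `c(lower, upper)` identity intervals; the
#'   lower bound is inclusive, the upper exclusive except for the final
#'   tier, which is closed at 100.
#' @return Object of class `recruitment_profile`: `ref_genome`,
#'   `ref_length`, and per-tier `depth` (integer vector of length
#'   `ref_length`), `mean_depth`, `hit_count`, `mean_identity`.
#' @export
recruit <- function(hits, ref_length, tiers = DEFAULT_TIERS) {
  bad <- hits$start < 1 | hits$end > ref_length | hits$start > hits$end
  if (any(bad)) {
    stop(sprintf("hit(s) outside [1, %d]: %s", ref_length,
                 paste(utils::head(hits$read_id[bad], 3), collapse = ", ")),
         call. = FALSE)
  }
  lo <- vapply(tiers, `[`, numeric(1), 1)
  hi <- vapply(tiers, `[`, numeric(1), 2)
  top <- which.max(hi)
  assign_tier <- function(pct) {
    idx <- rep(NA_integer_, length(pct))
    for (t in seq_along(tiers)) {
      sel <- pct >= lo[t] & (pct < hi[t] | (t == top & pct <= hi[t]))
      idx[sel] <- t
    }
    idx
  }
  tier_idx <- assign_tier(hits$pct_identity)
  if (anyNA(tier_idx)) {
    warning(sprintf("%d hit(s) below the lowest tier were ignored",
                    sum(is.na(tier_idx))), call. = FALSE)
    hits <- hits[!is.na(tier_idx), ]
    tier_idx <- tier_idx[!is.na(tier_idx)]
  }
  per_tier <- lapply(seq_along(tiers), function(t) {
    h <- hits[tier_idx == t, ]
    list(
      depth = interval_depth(h$start, h$end, ref_length),
      mean_depth = sum(h$end - h$start + 1) / ref_length,
      hit_count = nrow(h),
      mean_identity = if (nrow(h) > 0) mean(h$pct_identity) else NA_real_
    )
  })
  names(per_tier) <- names(tiers)
  structure(list(
    ref_genome = if (nrow(hits) > 0) hits$ref_genome[1] else NA_character_,
    ref_length = ref_length,
    tiers = per_tier
  ), class = "recruitment_profile")
}

#' @export
print.recruitment_profile <- function(x, ...) {
  cat(sprintf("recruitment_profile: %s (%d bp)\n", x$ref_genome,
              x$ref_length))
  for (nm in names(x$tiers)) {
    t <- x$tiers[[nm]]
    cat(sprintf("  %-6s %6d hits, %.2fX coverage, mean identity %.1f%%\n",
                nm, t$hit_count, t$mean_depth, t$mean_identity))
  }
  invisible(x)
}

#' Tier summary of a recruitment profile as a tibble
#'
#' @param profile A `recruitment_profile`.
#' @return Tibble with one row per tier: `tier`, `hit_count`, `mean_depth`,
#'   `mean_identity`.
#' @export
recruitment_summary <- function(profile) {
  stopifnot(inherits(profile, "recruitment_profile"))
  tibble::tibble(
    tier = names(profile$tiers),
    hit_count = vapply(profile$tiers, `[[`, numeric(1), "hit_count"),
    mean_depth = vapply(profile$tiers, `[[`, numeric(1), "mean_depth"),
    mean_identity = vapply(profile$tiers, `[[`, numeric(1), "mean_identity")
  )
}

#' Hits overlapping a locus window
#'
#' Counts hits overlapping the window by at least one position (1-based
#' inclusive coordinates).
#'
#' @param hits Recruitment-hit tibble.
#' @param window Length-2 integer vector `c(start, end)`, `start <= end`.
#' @return Integer count.
#' @export
locus_hits <- function(hits, window) {
  if (length(window) != 2L || window[1] > window[2]) {
    stop("`window` must be c(start, end) with start <= end", call. = FALSE)
  }
  sum(hits$start <= window[2] & hits$end >= window[1])
}

#' Mean-identity contrast between two hit sets
#'
#' Per-set mean percent identity and a two-sample Welch t-test on the
#' identities, for contrasting how closely two metagenomes recruit to the
#' same reference.
#'
#' @param hits_a,hits_b Recruitment-hit tibbles with at least 2 hits each.
#' @return List with `mean_a`, `mean_b`, `p`.
#' @export
identity_contrast <- function(hits_a, hits_b) {
  if (nrow(hits_a) < 2L || nrow(hits_b) < 2L) {
    stop("both hit sets need at least 2 hits for a Welch t-test",
         call. = FALSE)
  }
  if (stats::sd(hits_a$pct_identity) == 0 &&
      stats::sd(hits_b$pct_identity) == 0) {
    p <- if (mean(hits_a$pct_identity) == mean(hits_b$pct_identity)) 1 else 0
  } else {
    p <- stats::t.test(hits_a$pct_identity, hits_b$pct_identity)$p.value
  }
  list(mean_a = mean(hits_a$pct_identity),
       mean_b = mean(hits_b$pct_identity),
       p = p)
}
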