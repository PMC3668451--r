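# 2D hierarchical clustering and PCA of abundance matrices.

cluster_dist <- function(m, distance) {
  if (distance == "correlation") {
    if (any(apply(m, 1, stats::sd) == 0)) {
      stop(paste("constant row/column under correlation distance;",
                 "use distance = \"euclidean\""), call. = FALSE)
    }
    stats::as.dist(1 - stats::cor(t(m)))
  } else {
    stats::dist(m)
  }
}

#' Two-dimensional hierarchical clustering of an abundance matrix
#'
#' Clusters rows (taxa) and columns (fractions) independently with
#' agglomerative hierarchical clustering (complete linkage by default)
#' under `1 - Pearson correlation` distance (the heatmap-clustering
#' convention; Euclidean available). Rows and columns of the input are
#' first sorted by label so the result is invariant under input
#' permutation, with deterministic tie-breaking by label order.
#'
#' @param matrix An [abundance_matrix()] or plain numeric matrix with at
#'   least 2 rows and 2 columns and no missing values.
#' @param distance `"correlation"` (default) or `"euclidean"`.
#' @param linkage Agglomeration method for [stats::hclust()]
#'   (default `"complete"`).
#' @return List of class `hier_cluster_2d` with `row_hclust`,
#'   `col_hclust` ([stats::hclust] objects) and `matrix` (the input
#'   reordered by both dendrogram orders).
#' @export
hier_cluster_2d <- function(matrix, distance = c("correlation", "euclidean"),
                            linkage = "complete") {
  distance <- match.arg(distance)
  m <- unclass(matrix)
  if (nrow(m) < 2L || ncol(m) < 2L) {
    stop("need at least 2 rows and 2 columns", call. = FALSE)
  }
  if (anyNA(m)) stop("missing values not allowed", call. = FALSE)
  m <- m[order(rownames(m)), order(colnames(m)), drop = FALSE]
  row_hc <- stats::hclust(cluster_dist(m, distance), method = linkage)
  col_hc <- stats::hclust(cluster_dist(t(m), distance), method = linkage)
  structure(list(
    row_hclust = row_hc,
    col_hclust = col_hc,
    matrix = m[row_hc$order, col_hc$order, drop = FALSE],
    distance = distance,
    linkage = linkage
  ), class = "hier_cluster_2d")
}

#' @export
print.hier_cluster_2d <- function(x, ...) {
  cat(sprintf("hier_cluster_2d: %d x %d matrix, %s linkage, %s distance\n",
              nrow(x$matrix), ncol(x$matrix), x$linkage, x$distance))
  invisible(x)
}

#' Serialize a dendrogram to Newick
#'
#' Branch lengths are merge-height differences, so root-to-leaf path
#' lengths equal merge heights.
#'
#' @param hc A [stats::hclust] object.
#' @return A single Newick string (with trailing semicolon).
#' @export
cluster_newick <- function(hc) {
  ape::write.tree(ape::as.phylo(hc))
}

#' Principal component analysis of fraction profiles
#'
#' Centered (optionally unit-scaled) PCA of the fraction columns, using the
#' taxa as variables. The sign of each component is fixed so that its
#' largest-magnitude loading is positive, making results reproducible
#' across platforms.
#'
#' @param matrix An [abundance_matrix()] or numeric matrix (taxa x
#'   fractions, >= 2 columns).
#' @param n_components Number of components to keep; truncated with a
#'   warning if it exceeds what the data support.
#' @param scale. Unit-scale the taxa before decomposition (default
#'   `FALSE`).
#' @return List with `scores` (fractions x components), `loadings`
#'   (taxa x components) and `variance_fraction`.
#' @export
pca_profiles <- function(matrix, n_components = 2, scale. = FALSE) {
  m <- unclass(matrix)
  if (ncol(m) < 2L) stop("need at least 2 columns", call. = FALSE)
  if (scale.) {
    keep <- apply(m, 1, stats::sd) > 0
    m <- m[keep, , drop = FALSE]
  }
  pc <- stats::prcomp(t(m), center = TRUE, scale. = scale.)
  avail <- ncol(pc$rotation)
  if (n_components > avail) {
    warning(sprintf("only %d components available; truncating", avail),
            call. = FALSE)
    n_components <- avail
  }
  rot <- pc$rotation[, seq_len(n_components), drop = FALSE]
  sco <- pc$x[, seq_len(n_components), drop = FALSE]
  for (k in seq_len(n_components)) {
    if (rot[which.max(abs(rot[, k])), k] < 0) {
      rot[, k] <- -rot[, k]
      sco[, k] <- -sco[, k]
    }
  }
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = sco, loadings = rot,
       variance_fraction = vf[seq_len(n_components)])
}
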