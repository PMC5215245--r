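#' Stack abundance profiles into a relative-abundance matrix
#'
#' Rows are pipelines, columns the union of rank-level taxa across
#' pipelines (absent taxa 0). The reserved `"unclassified"` key is
#' dropped and each row renormalized to sum to 1 — cross-pipeline
#' comparisons operate on the composition of classified reads.
#'
#' @param profiles Named list of abundance profiles (named numeric
#'   vectors) at a common rank.
#' @param relative Renormalize rows to relative abundances (default);
#'   `FALSE` keeps raw counts.
#' @return Numeric matrix, pipelines x taxa.
#' @export
build_profile_matrix <- function(profiles, relative = TRUE) {
  if (length(profiles) < 1L) stop("no profiles given")
  if (is.null(names(profiles)))
    names(profiles) <- paste0("pipeline", seq_along(profiles))
  cleaned <- lapply(profiles, classified_profile)
  empty <- vapply(cleaned, length, 0L) == 0L
  if (any(empty))
    stop("profile(s) entirely unclassified: ",
         paste(names(profiles)[empty], collapse = ", "))
  taxa <- sort(unique(unlist(lapply(cleaned, names))))
  mat <- matrix(0, length(profiles), length(taxa),
                dimnames = list(names(profiles), taxa))
  for (i in seq_along(cleaned)) {
    p <- cleaned[[i]]
    mat[i, names(p)] <- p
    if (relative) mat[i, ] <- mat[i, ] / sum(mat[i, ])
  }
  mat
}

#' Average-linkage (UPGMA) clustering of pipelines on Euclidean distances
#'
#' Euclidean distances between profile rows, clustered with average
#' linkage. Rows are sorted by label first so tie-breaking is
#' deterministic and permutation-invariant. Merge heights are
#' non-decreasing (UPGMA is monotone).
#'
#' @param matrix Pipelines x taxa matrix from [build_profile_matrix()].
#' @return List: `hclust` (the [stats::hclust()] tree, `$height` = merge
#'   heights as average distances), `newick` (ultrametric newick string;
#'   branch lengths are height differences, leaf depth = merge
#'   height / 2).
#' @export
euclidean_upgma <- function(matrix) {
  if (nrow(matrix) < 2L) stop("clustering needs >= 2 pipelines")
  matrix <- matrix[order(rownames(matrix)), , drop = FALSE]
  hc <- stats::hclust(stats::dist(matrix, method = "euclidean"),
                      method = "average")
  phy <- ape::as.phylo(hc)
  list(hclust = hc, newick = ape::write.tree(phy))
}

#' Bray-Curtis dissimilarity matrix between profile rows
#'
#' `d(u, v) = 1 - 2 sum_i min(u_i, v_i) / (sum u + sum v)`, in `[0, 1]`:
#' 0 for identical compositions, 1 for disjoint supports.
#'
#' @param matrix Pipelines x taxa non-negative matrix.
#' @return Symmetric zero-diagonal distance matrix with row/col labels.
#' @export
bray_curtis_matrix <- function(matrix) {
  n <- nrow(matrix)
  d <- matrix(0, n, n, dimnames = list(rownames(matrix), rownames(matrix)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    u <- matrix[i, ]; v <- matrix[j, ]
    d[i, j] <- d[j, i] <- 1 - 2 * sum(pmin(u, v)) / (sum(u) + sum(v))
  }
  d
}

#' Principal coordinates analysis (classical metric scaling)
#'
#' Double-centers `-D^2/2` and eigendecomposes (via
#' [stats::cmdscale()]); axes with positive eigenvalues are kept, sorted
#' by decreasing eigenvalue, and each axis's share of the
#' positive-eigenvalue variance is reported. Negative eigenvalues (from
#' non-Euclidean distances such as Bray-Curtis) are dropped, not
#' corrected; their magnitudes are returned so the distortion can be
#' judged.
#'
#' @param dist Symmetric distance matrix (or `dist`).
#' @return List: `coordinates` (items x axes), `eigenvalues` (positive,
#'   descending), `variance_explained` (fractions of positive variance),
#'   `negative_eigenvalues`.
#' @export
pcoa <- function(dist) {
  d <- as.matrix(dist)
  n <- nrow(d)
  if (n < 2L) stop("PCoA needs >= 2 items")
  # cmdscale warns when fewer than k eigenvalues are positive; that case
  # (non-Euclidean input, duplicated points) is handled below
  sc <- suppressWarnings(
    stats::cmdscale(stats::as.dist(d), k = n - 1L, eig = TRUE))
  eig <- sc$eig
  tol <- max(abs(eig)) * 1e-9
  pos <- which(eig > tol)
  if (length(pos) == 0L) {
    return(list(coordinates = matrix(0, n, 0,
                                     dimnames = list(rownames(d), NULL)),
                eigenvalues = numeric(0),
                variance_explained = numeric(0),
                negative_eigenvalues = eig[eig < -tol]))
  }
  coords <- sc$points[, pos, drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_along(pos))
  rownames(coords) <- rownames(d)
  list(coordinates = coords,
       eigenvalues = eig[pos],
       variance_explained = eig[pos] / sum(eig[pos]),
       negative_eigenvalues = eig[eig < -tol])
}

#' Two-sided Mann-Whitney-Wilcoxon rank-sum test
#'
#' Exact null enumeration when the combined sample size is at most 12 and
#' there are no ties; otherwise the normal approximation with tie
#' correction and continuity correction. The U statistic is reported for
#' `group_a` (number of (a, b) pairs with a > b, ties counted half).
#'
#' @param group_a,group_b Numeric vectors (each non-empty).
#' @return List: `U`, `p_value` (two-sided), `exact` (logical).
#' @export
rank_sum_test <- function(group_a, group_b) {
  if (length(group_a) == 0L || length(group_b) == 0L)
    stop("both groups must be non-empty")
  ties <- anyDuplicated(c(group_a, group_b)) > 0L
  exact <- (length(group_a) + length(group_b)) <= 12L && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, alternative = "two.sided",
                       exact = exact, correct = TRUE))
  # wilcox.test's W equals U for group_a only without ties; recompute
  # U directly so ties count half
  r <- rank(c(group_a, group_b))
  ra <- sum(r[seq_along(group_a)])
  u <- ra - length(group_a) * (length(group_a) + 1) / 2
  list(U = unname(u), p_value = min(1, wt$p.value), exact = exact)
}

#' Keep the n most abundant taxa of a profile, pool the rest
#'
#' The `"unclassified"` key is preserved as its own entry; everything
#' beyond the top `n` classified taxa pools into `"other"` (present even
#' when empty). Ties at the cutoff break by taxon id. Totals are
#' conserved.
#'
#' @param profile Named numeric abundance profile.
#' @param n Number of taxa to keep (>= 1).
#' @return Reduced profile with at most `n + 2` keys.
#' @export
top_n_taxa <- function(profile, n) {
  if (n < 1L) stop("n must be >= 1")
  uncls <- profile[names(profile) == "unclassified"]
  p <- classified_profile(profile)
  ord <- order(-p, names(p))
  keep <- utils::head(ord, n)
  rest <- setdiff(seq_along(p), keep)
  out <- c(p[keep], other = sum(p[rest]))
  if (length(uncls)) out <- c(out, uncls)
  out
}
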