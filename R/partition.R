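#' Information-theoretic agreement between two read partitions
#'
#' Compares a predicted read partition (taxon labels, with unclassified
#' reads forming one dedicated cluster) against the ground-truth
#' partition, from their contingency table:
#'
#' * `nmi = I(U;V) / max(H(U), H(V))` — normalized mutual information
#'   under the max normalization;
#' * `one_minus_nid = 1 - NID = I / max(H(U), H(V))` — identical to NMI
#'   under this normalization, reported separately for interface
#'   compatibility;
#' * `ami = (I - E[I]) / (max(H(U), H(V)) - E[I])` — adjusted for chance
#'   under the permutation (hypergeometric) model; negative values are
#'   clamped to 0.
#'
#' Degenerate cases: identical single-cluster partitions on both sides
#' score 1 for all three metrics; a single cluster on only one side
#' scores 0. Entropies use natural logarithms.
#'
#' @param truth_labels Vector of per-read truth labels (length >= 2).
#' @param pred_labels Vector of per-read predicted labels, same length;
#'   `NA` marks unclassified reads and is pooled into one extra cluster.
#' @return Named numeric vector `nmi`, `ami`, `one_minus_nid`, each in
#'   `[0, 1]`.
#' @export
partition_agreement <- function(truth_labels, pred_labels) {
  if (length(truth_labels) != length(pred_labels))
    stop("label vectors must have the same length")
  if (length(truth_labels) < 2L)
    stop("partition agreement needs at least 2 items")
  u <- as.character(truth_labels)
  v <- as.character(pred_labels)
  v[is.na(v)] <- ".unclassified"
  if (anyNA(u)) stop("truth labels must not be missing")

  tab <- table(u, v)
  n <- sum(tab)
  a <- rowSums(tab); b <- colSums(tab)
  hu <- entropy_nats(a / n)
  hv <- entropy_nats(b / n)

  if (hu == 0 && hv == 0) {
    return(c(nmi = 1, ami = 1, one_minus_nid = 1))
  }
  if (hu == 0 || hv == 0) {
    return(c(nmi = 0, ami = 0, one_minus_nid = 0))
  }

  mi <- mutual_information(tab)
  hmax <- max(hu, hv)
  nmi <- mi / hmax
  emi <- expected_mi(a, b, n)
  denom <- hmax - emi
  ami <- if (abs(denom) < 1e-12) 0 else (mi - emi) / denom
  ami <- min(1, max(0, ami))
  c(nmi = nmi, ami = ami, one_minus_nid = nmi)
}

entropy_nats <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

mutual_information <- function(tab) {
  n <- sum(tab)
  a <- rowSums(tab); b <- colSums(tab)
  mi <- 0
  for (i in seq_along(a)) for (j in seq_along(b)) {
    nij <- tab[i, j]
    if (nij > 0)
      mi <- mi + nij / n * log(n * nij / (a[[i]] * b[[j]]))
  }
  max(0, mi)
}

# Expected mutual information under the permutation model with fixed
# marginals (hypergeometric expectation), in nats. Factorials via lgamma.
expected_mi <- function(a, b, n) {
  emi <- 0
  lg <- function(x) lgamma(x + 1)
  for (ai in a) for (bj in b) {
    lo <- max(1, ai + bj - n)
    hi <- min(ai, bj)
    if (lo > hi) next
    for (nij in lo:hi) {
      term <- nij / n * log(n * nij / (ai * bj))
      lp <- lg(ai) + lg(bj) + lg(n - ai) + lg(n - bj) -
        lg(n) - lg(nij) - lg(ai - nij) - lg(bj - nij) -
        lg(n - ai - bj + nij)
      emi <- emi + term * exp(lp)
    }
  }
  emi
}

#' Partition labels for reads from truth and assignments at a rank
#'
#' Helper producing the two label vectors [partition_agreement()]
#' consumes: truth taxa and predicted taxa at `rank`, with unclassified
#' reads labelled `NA` (one dedicated predicted cluster) and discarded
#' reads excluded from both sides.
#'
#' @param truth Truth data.frame (`read_id`, `taxid`).
#' @param pred Assignment table.
#' @param tree A `taxonomy_tree`.
#' @param rank Rank label.
#' @return List of `truth_labels` and `pred_labels`, aligned by read.
#' @export
partition_labels <- function(truth, pred, tree, rank) {
  pred_norm <- normalize_assignments(tree, as_assignment_table(pred), rank)
  idx <- match(truth$read_id, pred_norm$read_id)
  status <- ifelse(is.na(idx), "discarded", pred_norm$status[idx])
  keep <- status != "discarded"
  truth_rank <- ancestor_at_rank(tree, truth$taxid[keep], rank)
  ptax <- pred_norm$taxid[idx][keep]
  ptax[status[keep] != "classified"] <- NA_integer_
  list(truth_labels = truth_rank, pred_labels = ptax)
}
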