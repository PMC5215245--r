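#' Read-level confusion counts at a taxonomic rank
#'
#' Scores one pipeline's per-read assignments against the simulation
#' ground truth at `family` or `genus` (any rank present in the tree).
#' Per read: a discarded or unclassified(-at-rank) call is a false
#' negative; a classified call equal to the truth's rank projection is a
#' true positive; a different classified call is a false positive. Reads
#' present in the truth but absent from the assignment table are injected
#' as discarded.
#'
#' With `drop_singletons = TRUE` the protocol's singleton rule applies
#' after rank projection and before TP/FP counting: predicted taxa
#' supported by exactly one read are removed and their reads recounted as
#' false negatives (clustering-first pipelines discard singleton OTUs by
#' default; the rule is applied to every pipeline for comparability).
#'
#' @param truth Truth data.frame from [simulate_dataset()] (needs
#'   `read_id`, `taxid`).
#' @param pred Assignment table (`read_id`, `status`, `taxid`).
#' @param tree A `taxonomy_tree` resolving both sides.
#' @param rank Rank label to evaluate at.
#' @param drop_singletons Apply the singleton-as-FN rule.
#' @return A `confusion_counts` list: `TP`, `FP`, `FN`, `rank`,
#'   `n_reads`; always `TP + FP + FN == n_reads`.
#' @export
confusion_at_rank <- function(truth, pred, tree, rank,
                              drop_singletons = FALSE) {
  pred <- as_assignment_table(pred)
  extra <- setdiff(pred$read_id, truth$read_id)
  if (length(extra))
    stop("assignment table has read(s) absent from truth: ",
         paste(utils::head(extra, 5L), collapse = ", "))

  truth_rank <- ancestor_at_rank(tree, truth$taxid, rank)
  if (anyNA(truth_rank))
    stop("truth taxa must resolve at rank '", rank, "'")
  names(truth_rank) <- truth$read_id

  pred_norm <- normalize_assignments(tree, pred, rank)
  idx <- match(truth$read_id, pred_norm$read_id)
  status <- ifelse(is.na(idx), "discarded", pred_norm$status[idx])
  ptax <- ifelse(is.na(idx), NA_integer_, pred_norm$taxid[idx])

  if (drop_singletons) {
    cls <- status == "classified"
    tab <- table(ptax[cls])
    single <- as.integer(names(tab)[tab == 1L])
    hit <- cls & ptax %in% single
    status[hit] <- "unclassified"
    ptax[hit] <- NA_integer_
  }

  cls <- status == "classified"
  tp <- sum(cls & ptax == truth_rank, na.rm = TRUE)
  fp <- sum(cls & ptax != truth_rank, na.rm = TRUE)
  fn <- sum(!cls)

  structure(list(TP = tp, FP = fp, FN = fn, rank = rank,
                 n_reads = nrow(truth)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion at %s: TP=%d FP=%d FN=%d (n=%d)\n",
              x$rank, x$TP, x$FP, x$FN, x$n_reads))
  invisible(x)
}

#' Precision, recall and F-measure from confusion counts
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`,
#' `F = 2PR/(P+R)`. Zero denominators (and hence `TP = 0`) give 0.
#'
#' @param counts A `confusion_counts` object or list with `TP`, `FP`,
#'   `FN`.
#' @return Named numeric vector `precision`, `recall`, `f_measure`.
#' @export
f_measure <- function(counts) {
  tp <- counts$TP; fp <- counts$FP; fn <- counts$FN
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f_measure = f)
}

#' Merge an OTU table into a rank-level abundance profile
#'
#' The taxonomic-merging step that makes clustering-first output
#' comparable to assignment-first output: all OTUs assigned to the same
#' rank-projected taxon pool their sizes into one taxonomic unit;
#' unclassified OTUs (and OTUs whose lineage misses the rank) pool into
#' the reserved `"unclassified"` key.
#'
#' @param otus data.frame with `otu_id`, `size`, `taxid` (`NA` =
#'   unclassified).
#' @param tree A `taxonomy_tree`.
#' @param rank Rank label.
#' @return Abundance profile: named numeric vector of read counts, keys =
#'   taxids at `rank` (plus possibly `"unclassified"`).
#' @export
merge_otus <- function(otus, tree, rank) {
  if (any(otus$size < 1L)) stop("OTU sizes must be >= 1")
  proj <- rep(NA_integer_, nrow(otus))
  has <- !is.na(otus$taxid)
  if (any(has)) proj[has] <- ancestor_at_rank(tree, otus$taxid[has], rank)
  key <- ifelse(is.na(proj), "unclassified", as.character(proj))
  tapply_sum <- tapply(otus$size, key, sum)
  profile_sorted(as.numeric(tapply_sum), names(tapply_sum))
}

#' Abundance profile of per-read assignments at a rank
#'
#' Counts reads per rank-projected taxon. Unclassified(-at-rank) reads
#' pool under `"unclassified"`; discarded reads are excluded (they never
#' reach a pipeline's final table).
#'
#' @param pred Assignment table.
#' @param tree A `taxonomy_tree`.
#' @param rank Rank label.
#' @return Named numeric profile as in [merge_otus()].
#' @export
profile_from_assignments <- function(pred, tree, rank) {
  norm <- normalize_assignments(tree, as_assignment_table(pred), rank)
  norm <- norm[norm$status != "discarded", , drop = FALSE]
  if (nrow(norm) == 0L) stop("no retained reads to profile")
  key <- ifelse(norm$status == "classified", as.character(norm$taxid),
                "unclassified")
  counts <- table(key)
  profile_sorted(as.numeric(counts), names(counts))
}

#' Rank-level abundance profile of the simulation ground truth
#' @param truth Truth data.frame (`taxid` per read).
#' @param tree A `taxonomy_tree`.
#' @param rank Rank label.
#' @return Named numeric profile; its length is the ground-truth richness.
#' @export
truth_profile <- function(truth, tree, rank) {
  proj <- ancestor_at_rank(tree, truth$taxid, rank)
  if (anyNA(proj)) stop("truth taxa must resolve at rank '", rank, "'")
  counts <- table(proj)
  profile_sorted(as.numeric(counts), names(counts))
}

profile_sorted <- function(counts, keys) {
  ord <- order(keys != "unclassified", suppressWarnings(as.integer(keys)),
               keys)
  stats::setNames(counts[ord], keys[ord])
}

# taxa of a profile with the reserved pooling key removed
classified_profile <- function(profile) {
  profile[names(profile) != "unclassified" & profile > 0]
}

#' Chao1 abundance-based richness estimator
#'
#' Bias-corrected by default:
#' `S_chao1 = S_obs + f1 (f1 - 1) / (2 (f2 + 1))` with `f1`/`f2` the
#' numbers of taxa observed exactly once/twice (the mothur/QIIME default
#' form). `variant = "classic"` gives `S_obs + f1^2 / (2 f2)`, falling
#' back to `S_obs + f1 (f1 - 1) / 2` when `f2 = 0`. The `"unclassified"`
#' key is excluded before estimation.
#'
#' @param profile Named numeric abundance profile (counts >= 1).
#' @param variant `"bias-corrected"` (default) or `"classic"`.
#' @return Estimated richness (>= observed richness).
#' @export
chao1 <- function(profile, variant = c("bias-corrected", "classic")) {
  variant <- match.arg(variant)
  p <- classified_profile(profile)
  if (length(p) == 0L) stop("empty abundance profile")
  s_obs <- length(p)
  f1 <- sum(p == 1)
  f2 <- sum(p == 2)
  if (variant == "bias-corrected") {
    s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  } else {
    if (f2 > 0) s_obs + f1^2 / (2 * f2)
    else s_obs + f1 * (f1 - 1) / 2
  }
}

#' Signed Chao1 error percent against ground-truth richness
#'
#' `(estimated - truth) / truth * 100`; positive values are richness
#' overestimation.
#'
#' @param estimate Estimated richness (e.g. from [chao1()]).
#' @param truth_richness Ground-truth richness (> 0): the number of
#'   distinct rank-level taxa among the dataset's truth reads.
#' @return Signed percentage.
#' @export
chao1_error_percent <- function(estimate, truth_richness) {
  if (truth_richness <= 0) stop("truth richness must be > 0")
  (estimate - truth_richness) / truth_richness * 100
}

#' Shannon and Inverse Simpson diversity of a profile
#'
#' With `p_i = count_i / total` over classified taxa:
#' Shannon `H = -sum p_i log(p_i)` (natural log by default) and Inverse
#' Simpson `1 / sum p_i^2` (the effective number of equally-abundant
#' taxa). The `"unclassified"` key is excluded.
#'
#' @param profile Named numeric abundance profile.
#' @param base Logarithm base for Shannon (default `exp(1)`).
#' @return Named numeric vector `shannon`, `inverse_simpson`.
#' @export
diversity_indices <- function(profile, base = exp(1)) {
  p <- classified_profile(profile)
  if (length(p) == 0L) stop("empty abundance profile")
  p <- p / sum(p)
  c(shannon = -sum(p * log(p, base = base)),
    inverse_simpson = 1 / sum(p^2))
}
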