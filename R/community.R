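#' Build a weighted community design
#'
#' A community design is the weighted genome composition a dataset is drawn
#' from. Three named complexity patterns mirror the classic mock-community
#' layouts: `LC` (low complexity) gives one dominant genome 30% of reads,
#' `MC` (medium) gives four dominant genomes 20% each, and `HC` (high)
#' distributes all genomes equally. Non-dominant genomes share the
#' remaining mass equally.
#'
#' @param genome_ids Character vector of genome identifiers.
#' @param complexity One of `"LC"`, `"MC"`, `"HC"`, `"custom"`.
#' @param dominant_ids Genome ids taking the dominant share: exactly 1 for
#'   LC, exactly 4 for MC; ignored for HC. Defaults to the first ids.
#' @param weights For `complexity = "custom"`: per-genome weights, summing
#'   to 1.
#' @return A `community_design`: data.frame of `genome_id`, `weight` with a
#'   `complexity` attribute.
#' @examples
#' design <- community_design(paste0("g", 1:8), "LC")
#' design$weight[1]  # 0.3
#' @export
community_design <- function(genome_ids,
                             complexity = c("HC", "LC", "MC", "custom"),
                             dominant_ids = NULL, weights = NULL) {
  complexity <- match.arg(complexity)
  genome_ids <- as.character(genome_ids)
  if (anyDuplicated(genome_ids)) stop("duplicate genome ids in design")
  n <- length(genome_ids)
  if (n < 1L) stop("community design needs at least one genome")

  w <- switch(complexity,
    HC = rep(1 / n, n),
    LC = dominated_weights(genome_ids, dominant_ids, n_dom = 1L, share = 0.30),
    MC = dominated_weights(genome_ids, dominant_ids, n_dom = 4L, share = 0.20),
    custom = {
      if (is.null(weights) || length(weights) != n)
        stop("custom design needs one weight per genome")
      weights
    }
  )
  if (any(w < 0)) stop("negative weights in design")
  if (abs(sum(w) - 1) > 1e-9) stop("design weights must sum to 1")
  if (all(w == 0)) stop("design needs at least one positive weight")

  structure(
    data.frame(genome_id = genome_ids, weight = w, stringsAsFactors = FALSE),
    complexity = complexity,
    class = c("community_design", "data.frame")
  )
}

dominated_weights <- function(genome_ids, dominant_ids, n_dom, share) {
  if (is.null(dominant_ids)) dominant_ids <- genome_ids[seq_len(n_dom)]
  if (length(dominant_ids) != n_dom)
    stop("this complexity takes exactly ", n_dom, " dominant genome(s)")
  if (!all(dominant_ids %in% genome_ids))
    stop("dominant_ids not in genome_ids")
  n_rest <- length(genome_ids) - n_dom
  if (n_rest < 1L) stop("design needs non-dominant genomes")
  w <- rep((1 - n_dom * share) / n_rest, length(genome_ids))
  w[genome_ids %in% dominant_ids] <- share
  w
}

#' Deterministically allocate reads to genomes
#'
#' Largest-remainder (Hamilton) apportionment of `n_reads` over the design
#' weights: each genome gets `floor(weight * n_reads)` and the leftover
#' reads go to the largest fractional remainders, ties broken by
#' lexicographic genome id. Counts always sum exactly to `n_reads` and the
#' result is deterministic.
#'
#' @param design A `community_design` (or data.frame with `genome_id`,
#'   `weight`).
#' @param n_reads Total read count (positive integer).
#' @return Named integer vector of per-genome read counts.
#' @export
allocate_reads <- function(design, n_reads) {
  if (n_reads < 1L) stop("n_reads must be >= 1")
  w <- design$weight
  if (all(w == 0)) stop("all design weights are zero")
  w <- w / sum(w)
  exact <- w * n_reads
  base <- floor(exact)
  leftover <- as.integer(round(n_reads - sum(base)))
  counts <- as.integer(base)
  if (leftover > 0L) {
    frac <- exact - base
    pick <- order(-frac, design$genome_id)[seq_len(leftover)]
    counts[pick] <- counts[pick] + 1L
  }
  stats::setNames(counts, design$genome_id)
}
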