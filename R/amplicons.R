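#' Define a PCR primer pair
#'
#' Both primers are written 5'->3' as synthesized: the forward primer
#' matches the forward strand, the reverse primer matches the reverse
#' strand (so its reverse complement is searched downstream on the forward
#' strand). IUPAC degeneracy codes are allowed and expanded during
#' matching.
#'
#' @param forward,reverse IUPAC nucleotide strings, 5'->3'.
#' @param name Label, e.g. `"200(V3)"` or `"400(V4-V5)"`.
#' @return A `primer_pair` object.
#' @examples
#' v3 <- primer_pair("CCTACGGGAGGCAGCAG", "ATTACCGCGGCTGCTGG", "200(V3)")
#' @export
primer_pair <- function(forward, reverse, name = "primer_pair") {
  ok <- function(p) {
    nzchar(p) && all(strsplit(toupper(p), "")[[1]] %in%
                       names(Biostrings::IUPAC_CODE_MAP))
  }
  if (!ok(forward) || !ok(reverse))
    stop("primers must be non-empty IUPAC nucleotide strings")
  structure(
    list(forward = toupper(forward), reverse = toupper(reverse), name = name),
    class = "primer_pair"
  )
}

#' @export
print.primer_pair <- function(x, ...) {
  cat("primer_pair", x$name, ": fwd", x$forward, "/ rev", x$reverse, "\n")
  invisible(x)
}

# Exact degenerate matches of a primer on one strand. Pattern ambiguities
# are expanded; subject ambiguities (N in the genome) stay literal, so an N
# in the template never satisfies a primer base.
primer_sites <- function(primer, subject) {
  m <- Biostrings::matchPattern(Biostrings::DNAString(primer), subject,
                                fixed = "subject")
  as.data.frame(IRanges::ranges(m))[, c("start", "end"), drop = FALSE]
}

# Amplicons on one strand, 0-based half-open coordinates on that strand.
scan_strand <- function(seq, primers, max_product) {
  fwd <- primer_sites(primers$forward, seq)
  if (nrow(fwd) == 0L) return(NULL)
  rc_rev <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(primers$reverse)))
  rev <- primer_sites(rc_rev, seq)
  if (nrow(rev) == 0L) return(NULL)

  out <- vector("list", nrow(fwd))
  for (i in seq_len(nrow(fwd))) {
    s <- fwd$start[i]
    # shortest valid product: nearest reverse site whose start lies at or
    # beyond the end of the forward site (primers must not overlap)
    cand <- rev[rev$start > fwd$end[i] &
                  rev$end - s + 1L <= max_product, , drop = FALSE]
    if (nrow(cand) == 0L) next
    e <- min(cand$end)
    out[[i]] <- data.frame(start = s - 1L, end = e)  # 0-based half-open
  }
  out <- do.call(rbind, out)
  if (is.null(out) || nrow(out) == 0L) NULL else out
}

#' Find primer-delimited amplicons in a genome (in-silico PCR)
#'
#' Scans both strands for exact (mismatch-free) degenerate matches of the
#' forward primer with the reverse primer's reverse complement downstream;
#' each forward site yields at most one product, the shortest one within
#' `max_product`. Amplicon sequences are primer-inclusive and reported
#' 5'->3' from the forward primer; coordinates are 0-based half-open on the
#' genome's forward strand. No match is not an error: genomes a primer
#' pair fails to amplify simply return an empty list.
#'
#' @param genome A `DNAString`/`DNAStringSet` element or character string
#'   over `A,C,G,T,N`.
#' @param primers A [primer_pair()].
#' @param genome_id Identifier stored in the result.
#' @param max_product Maximum product length guard (default 5000 nt).
#' @return data.frame with columns `genome_id`, `start`, `end`, `strand`,
#'   `sequence`; zero rows when nothing amplifies.
#' @export
find_amplicons <- function(genome, primers, genome_id = "genome",
                           max_product = 5000L) {
  if (is.character(genome)) genome <- Biostrings::DNAString(genome)
  if (methods::is(genome, "DNAStringSet")) genome <- genome[[1L]]
  L <- length(genome)
  empty <- data.frame(genome_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      sequence = character(0), stringsAsFactors = FALSE)

  plus <- scan_strand(genome, primers, max_product)
  rc <- Biostrings::reverseComplement(genome)
  minus <- scan_strand(rc, primers, max_product)

  rows <- list()
  if (!is.null(plus)) {
    rows[[1L]] <- data.frame(
      genome_id = genome_id, start = plus$start, end = plus$end,
      strand = "+",
      sequence = as.character(Biostrings::extractAt(
        genome, IRanges::IRanges(plus$start + 1L, plus$end))),
      stringsAsFactors = FALSE
    )
  }
  if (!is.null(minus)) {
    # map coordinates from the reverse-complement back onto the forward
    # strand: rc [s, e) -> forward [L - e, L - s)
    rows[[2L]] <- data.frame(
      genome_id = genome_id,
      start = L - minus$end, end = L - minus$start,
      strand = "-",
      sequence = as.character(Biostrings::extractAt(
        rc, IRanges::IRanges(minus$start + 1L, minus$end))),
      stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$start, out$strand), , drop = FALSE]
}
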