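#' Ion Torrent-style error model parameters
#'
#' Per-base event probabilities for an indel-dominated single-end error
#' model. `length_sd` is the standard deviation (bp) of the read length
#' around the amplicon length; `end_bias` controls a linear ramp that
#' concentrates errors toward the 3' end of reads (0 = uniform placement,
#' 1 = errors ramp from ~0x at the 5' end to ~2x at the 3' end). The ramp
#' is mean-normalized, so realized event rates match the nominal rates
#' whatever the bias.
#'
#' The defaults are the published Ion Torrent amplicon settings: 0.01
#' deletions, 0.005 insertions, 0.005 substitutions per base and a 20 bp
#' length spread.
#'
#' @param deletion_rate,insertion_rate,substitution_rate Per-base event
#'   probabilities in `[0, 1]`, jointly at most 1.
#' @param length_sd Read-length standard deviation in bp, `>= 0`.
#' @param end_bias Non-negative ramp coefficient; values above 1 are
#'   allowed (the ramp is floored at zero and renormalized).
#' @return An `error_model_params` object.
#' @export
error_model_params <- function(deletion_rate = 0.01,
                               insertion_rate = 0.005,
                               substitution_rate = 0.005,
                               length_sd = 20,
                               end_bias = 1) {
  rates <- c(deletion_rate, insertion_rate, substitution_rate)
  if (any(rates < 0 | rates > 1)) stop("event rates must lie in [0, 1]")
  if (sum(rates) > 1) stop("event rates must sum to at most 1")
  if (length_sd < 0) stop("length_sd must be >= 0")
  if (end_bias < 0) stop("end_bias must be >= 0")
  structure(
    list(deletion_rate = deletion_rate, insertion_rate = insertion_rate,
         substitution_rate = substitution_rate, length_sd = length_sd,
         end_bias = end_bias),
    class = "error_model_params"
  )
}

#' Error-free model (identity on amplicons)
#' @return `error_model_params` with all rates and spread zero.
#' @export
error_free_params <- function() {
  error_model_params(0, 0, 0, length_sd = 0, end_bias = 0)
}

# Position weights over a read of length m: mean-1 linear ramp from 5' to
# 3'. Floored at 0 (relevant only for end_bias > 1) and renormalized so
# realized rates stay nominal.
position_weights <- function(m, end_bias) {
  if (end_bias == 0 || m == 1L) return(rep(1, m))
  w <- 1 + end_bias * (2 * (seq_len(m) - 1L) / (m - 1L) - 1)
  w <- pmax(w, 0)
  w / mean(w)
}

DNA_BASES4 <- c("A", "C", "G", "T")

#' Corrupt one sequence with the read-length and error model
#'
#' A target read length is drawn from `Normal(|sequence|, length_sd)` and
#' rounded (floored at 1). Shorter targets truncate the amplicon at its 3'
#' end; longer targets keep the full amplicon and extend it with uniform
#' random bases, emulating sequencing past the amplicon into adapter.
#' Then, for each base, at most one event (deletion / insertion-after /
#' substitution) is drawn with position-dependent probability
#' `rate * w(i)`, where `w` is the mean-normalized 3' ramp (see
#' [error_model_params()]). Substitutions draw uniformly from the 3
#' alternative bases; insertions add one uniform base after the position.
#'
#' Uses the current RNG stream; seed upstream for reproducibility.
#'
#' @param sequence Non-empty nucleotide string.
#' @param params An [error_model_params()].
#' @return List: `read` (corrupted string), `n_del`, `n_ins`, `n_sub`
#'   (event counts), `template_length` (bases subjected to the per-base
#'   model, after length adjustment and before indels).
#' @export
apply_error_model <- function(sequence, params) {
  L <- nchar(sequence)
  if (L == 0L) stop("empty sequence")

  target <- if (params$length_sd > 0) {
    max(1L, as.integer(round(stats::rnorm(1L, L, params$length_sd))))
  } else L
  bases <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  if (target < L) {
    bases <- bases[seq_len(target)]
  } else if (target > L) {
    bases <- c(bases, sample(DNA_BASES4, target - L, replace = TRUE))
  }
  m <- length(bases)

  w <- position_weights(m, params$end_bias)
  p_del <- params$deletion_rate * w
  p_ins <- params$insertion_rate * w
  p_sub <- params$substitution_rate * w
  u <- stats::runif(m)
  ev <- integer(m)                       # 0 none, 1 del, 2 ins, 3 sub
  ev[u < p_del] <- 1L
  ev[u >= p_del & u < p_del + p_ins] <- 2L
  ev[u >= p_del + p_ins & u < p_del + p_ins + p_sub] <- 3L

  sub_idx <- which(ev == 3L)
  if (length(sub_idx)) {
    # uniform among the 3 alternatives of each original base
    alt <- vapply(bases[sub_idx], function(b)
      sample(setdiff(DNA_BASES4, b), 1L), "")
    bases[sub_idx] <- alt
  }
  ins_idx <- which(ev == 2L)
  ins_bases <- if (length(ins_idx))
    sample(DNA_BASES4, length(ins_idx), replace = TRUE) else character(0)

  keep <- ev != 1L
  pieces <- character(m)
  pieces[keep] <- bases[keep]
  if (length(ins_idx))
    pieces[ins_idx] <- paste0(pieces[ins_idx], ins_bases)
  read <- paste(pieces, collapse = "")

  list(read = read,
       n_del = sum(ev == 1L), n_ins = length(ins_idx),
       n_sub = length(sub_idx), template_length = m)
}
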