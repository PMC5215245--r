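#' Simulate a ground-truthed amplicon sequencing dataset
#'
#' End-to-end generator: in-silico PCR on every designed genome
#' ([find_amplicons()]), deterministic read allocation over the community
#' weights ([allocate_reads()]), uniform draw of the source amplicon among
#' each genome's marker copies, and per-read corruption with the
#' Ion Torrent-style model ([apply_error_model()]). Genomes the primer
#' pair fails to amplify are dropped with a warning and the remaining
#' weights renormalized. The FASTQ carries a constant placeholder quality
#' (`I`, Q40); the protocol never consumes qualities.
#'
#' Fully reproducible: the same `(seed, inputs)` produce byte-identical
#' FASTQ and truth table.
#'
#' @param genomes A named `DNAStringSet` (or named character vector) of
#'   genome sequences; names are genome ids.
#' @param design A [community_design()] over (a subset of) those ids.
#' @param primers A [primer_pair()].
#' @param n_reads Total reads to emit.
#' @param params An [error_model_params()]; use [error_free_params()] for
#'   the error-free series.
#' @param seed Integer master seed.
#' @param genome_taxids Optional named integer vector genome_id -> source
#'   taxid, recorded in the truth table (`NA` when absent).
#' @param fastq_path Output FASTQ path; defaults to a tempfile.
#' @return List: `fastq` (path), `truth` (data.frame: `read_id`,
#'   `genome_id`, `taxid`, `start`, `end`, `strand`, `n_del`, `n_ins`,
#'   `n_sub`; coordinates 0-based half-open on the source genome),
#'   `amplicons` (the in-silico PCR table), `dropped` (ids that failed to
#'   amplify).
#' @export
simulate_dataset <- function(genomes, design, primers, n_reads, params,
                             seed, genome_taxids = NULL,
                             fastq_path = tempfile(fileext = ".fastq")) {
  if (is.character(genomes))
    genomes <- Biostrings::DNAStringSet(genomes)
  if (is.null(names(genomes)) || anyDuplicated(names(genomes)))
    stop("genomes must carry unique names (genome ids)")
  missing_ids <- setdiff(design$genome_id, names(genomes))
  if (length(missing_ids))
    stop("designed genome(s) absent from FASTA: ",
         paste(missing_ids, collapse = ", "))

  amps <- do.call(rbind, lapply(design$genome_id, function(gid)
    find_amplicons(genomes[[gid]], primers, genome_id = gid)))
  amplified <- unique(amps$genome_id)
  dropped <- setdiff(design$genome_id[design$weight > 0], amplified)
  if (length(dropped) == length(design$genome_id))
    stop("no designed genome amplifies with primer pair ", primers$name)
  if (length(dropped)) {
    warning(length(dropped), " genome(s) not amplified by ", primers$name,
            " and dropped from the design: ",
            paste(dropped, collapse = ", "))
  }
  kept <- design[design$genome_id %in% amplified & design$weight > 0, ,
                 drop = FALSE]
  kept$weight <- kept$weight / sum(kept$weight)

  counts <- allocate_reads(kept, n_reads)

  set.seed(as.integer(seed))
  amps_by_genome <- split(seq_len(nrow(amps)), amps$genome_id)

  total <- sum(counts)
  reads <- character(total)
  src <- integer(total)                 # amplicon row per read
  n_del <- integer(total); n_ins <- integer(total); n_sub <- integer(total)

  k <- 0L
  for (gid in names(counts)) {
    n_g <- counts[[gid]]
    if (n_g == 0L) next
    rows <- amps_by_genome[[gid]]
    pick <- if (length(rows) == 1L) rep.int(rows, n_g) else
      sample(rows, n_g, replace = TRUE)
    for (j in seq_len(n_g)) {
      k <- k + 1L
      a <- pick[[j]]
      res <- apply_error_model(amps$sequence[[a]], params)
      reads[k] <- res$read
      src[k] <- a
      n_del[k] <- res$n_del; n_ins[k] <- res$n_ins; n_sub[k] <- res$n_sub
    }
  }

  read_id <- sprintf("read_%07d", seq_len(total))
  taxid <- if (is.null(genome_taxids)) rep(NA_integer_, total) else
    unname(genome_taxids[amps$genome_id[src]])
  truth <- data.frame(
    read_id = read_id, genome_id = amps$genome_id[src],
    taxid = as.integer(taxid),
    start = amps$start[src], end = amps$end[src],
    strand = amps$strand[src],
    n_del = n_del, n_ins = n_ins, n_sub = n_sub,
    stringsAsFactors = FALSE
  )

  write_fastq(reads, read_id, fastq_path)
  list(fastq = fastq_path, truth = truth, amplicons = amps,
       dropped = dropped)
}

# Constant-quality FASTQ writer ('I' = Q40 placeholder).
write_fastq <- function(reads, ids, path) {
  seqs <- Biostrings::DNAStringSet(reads)
  names(seqs) <- ids
  quals <- Biostrings::BStringSet(vapply(nchar(reads), function(n)
    strrep("I", n), ""))
  Biostrings::writeXStringSet(seqs, path, format = "fastq",
                              qualities = quals)
  invisible(path)
}

#' Write a truth table as TSV (1-based inclusive coordinates)
#'
#' Internally coordinates are 0-based half-open; the export is 1-based
#' inclusive, stated in a `#` header line.
#'
#' @param truth Truth data.frame from [simulate_dataset()].
#' @param path Output TSV path.
#' @export
write_truth_table <- function(truth, path) {
  out <- truth
  out$start <- out$start + 1L          # 1-based inclusive
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coordinates are 1-based inclusive on the source genome",
             con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a truth table TSV back into internal coordinates
#' @param path TSV written by [write_truth_table()].
#' @return Truth data.frame, 0-based half-open coordinates.
#' @export
read_truth_table <- function(path) {
  truth <- utils::read.delim(path, comment.char = "#",
                             stringsAsFactors = FALSE)
  truth$start <- truth$start - 1L
  truth
}

#' Write a dataset manifest (JSON provenance record)
#'
#' @param path Output JSON path.
#' @param seed Master seed used.
#' @param params [error_model_params()] used.
#' @param primers [primer_pair()] used.
#' @param design [community_design()] used.
#' @param n_reads Throughput.
#' @param files Named character vector of artifact paths; their md5 sums
#'   are recorded.
#' @export
write_manifest <- function(path, seed, params, primers, design, n_reads,
                           files = character(0)) {
  manifest <- list(
    tool = "ampliconbench",
    version = as.character(utils::packageVersion("ampliconbench")),
    seed = seed,
    n_reads = n_reads,
    primer = list(name = primers$name, forward = primers$forward,
                  reverse = primers$reverse),
    error_model = unclass(params),
    design = list(
      complexity = attr(design, "complexity"),
      entries = data.frame(genome_id = design$genome_id,
                           weight = design$weight)
    ),
    checksums = as.list(vapply(files, function(f)
      unname(tools::md5sum(f)), ""))
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
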