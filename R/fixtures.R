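#' Built-in primer pair for fixture genomes
#'
#' The conserved marker flanks embedded by
#' [generate_fixture_collection()]: the classic V3 region primers 341F /
#' 534R (~17-mers), non-degenerate here so fixture amplification is exact
#' by construction.
#'
#' @return A [primer_pair()].
#' @export
fixture_primers <- function() {
  primer_pair("CCTACGGGAGGCAGCAG", "ATTACCGCGGCTGCTGG", "fixture(V3)")
}

random_dna <- function(n) {
  paste(sample(DNA_BASES4, n, replace = TRUE), collapse = "")
}

mutate_dna <- function(seq, n_mut) {
  b <- strsplit(seq, "", fixed = TRUE)[[1L]]
  pos <- sample(length(b), min(n_mut, length(b)))
  b[pos] <- vapply(b[pos], function(x) sample(setdiff(DNA_BASES4, x), 1L), "")
  paste(b, collapse = "")
}

#' Generate a synthetic marker-bearing genome collection with taxonomy
#'
#' Stands in for a real reference genome set: each synthetic genome embeds
#' 1..k copies of a marker gene built as conserved primer sites flanking a
#' taxon-specific variable region. Variable regions are derived
#' hierarchically — one template per family, lightly mutated per genus,
#' more lightly again per species — so sequence divergence is larger
#' across families than within genera. Markers are placed on either strand
#' inside random background sequence and are recoverable exactly by
#' [find_amplicons()] with [fixture_primers()].
#'
#' The companion taxonomy is a compact rooted tree: root / superkingdom /
#' families / genera / species, one species per genome.
#'
#' @param n_families,genera_per_family,species_per_genus Tree shape
#'   (all `>= 1`); one genome per species.
#' @param copies_range Integer interval (length-2) of marker copies per
#'   genome, e.g. `c(1, 3)`.
#' @param seed Integer seed; fixed seed gives a byte-identical collection.
#' @param variable_length Length of the marker's variable region (nt).
#' @param background_length Length of background sequence between/around
#'   markers (nt).
#' @return List: `genomes` (named `DNAStringSet`), `taxonomy` (compact-TSV
#'   lines, loadable via [load_taxonomy()]), `genome_taxids` (named
#'   integer vector genome_id -> species taxid), `tree` (the loaded
#'   `taxonomy_tree`).
#' @examples
#' fx <- generate_fixture_collection(2, 2, 1, c(1, 1), seed = 1)
#' length(fx$genomes)  # 4
#' @export
generate_fixture_collection <- function(n_families = 3L,
                                        genera_per_family = 2L,
                                        species_per_genus = 2L,
                                        copies_range = c(1L, 3L),
                                        seed = 1L,
                                        variable_length = 150L,
                                        background_length = 400L) {
  stopifnot(n_families >= 1L, genera_per_family >= 1L,
            species_per_genus >= 1L, all(copies_range >= 1L),
            copies_range[1L] <= copies_range[2L])
  set.seed(as.integer(seed))
  primers <- fixture_primers()
  rev_site <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(primers$reverse)))

  # compact taxonomy: root=1, superkingdom=2, then families/genera/species
  tax <- list(c(1L, 1L, "no rank", "root"),
              c(2L, 1L, "superkingdom", "Bacteria"))
  next_id <- 3L
  genomes <- character(0)
  genome_taxids <- integer(0)

  for (f in seq_len(n_families)) {
    fam_id <- next_id; next_id <- next_id + 1L
    fam_name <- sprintf("Family%02daceae", f)
    tax[[length(tax) + 1L]] <- c(fam_id, 2L, "family", fam_name)
    fam_template <- random_dna(variable_length)
    for (g in seq_len(genera_per_family)) {
      gen_id <- next_id; next_id <- next_id + 1L
      gen_name <- sprintf("Genus%02d_%02d", f, g)
      tax[[length(tax) + 1L]] <- c(gen_id, fam_id, "genus", gen_name)
      # ~10% divergence between genera, ~2% between species
      gen_template <- mutate_dna(fam_template,
                                 ceiling(0.10 * variable_length))
      for (s in seq_len(species_per_genus)) {
        sp_id <- next_id; next_id <- next_id + 1L
        sp_name <- sprintf("Genus%02d_%02d species%02d", f, g, s)
        tax[[length(tax) + 1L]] <- c(sp_id, gen_id, "species", sp_name)
        variable <- mutate_dna(gen_template,
                               ceiling(0.02 * variable_length))
        marker <- paste0(primers$forward, variable, rev_site)
        n_copies <- if (copies_range[1L] == copies_range[2L])
          copies_range[1L] else
          sample(seq(copies_range[1L], copies_range[2L]), 1L)
        pieces <- random_dna(background_length)
        for (cp in seq_len(n_copies)) {
          placed <- if (stats::runif(1L) < 0.5) marker else
            as.character(Biostrings::reverseComplement(
              Biostrings::DNAString(marker)))
          pieces <- paste0(pieces, placed, random_dna(background_length))
        }
        gid <- sprintf("genome_F%02dG%02dS%02d", f, g, s)
        genomes[[gid]] <- pieces
        genome_taxids[[gid]] <- sp_id
      }
    }
  }

  tax_lines <- c("taxid\tparent\trank\tname",
                 vapply(tax, paste, "", collapse = "\t"))
  tf <- tempfile(fileext = ".tsv")
  writeLines(tax_lines, tf)
  tree <- load_taxonomy(tf)
  unlink(tf)

  list(genomes = Biostrings::DNAStringSet(genomes),
       taxonomy = tax_lines,
       genome_taxids = genome_taxids,
       tree = tree)
}
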