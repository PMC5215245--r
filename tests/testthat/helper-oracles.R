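# Shared fixtures and independent oracles for the test suite.

# Small hand-written taxonomy: root / Bacteria / 2 families, 3 genera,
# 4 species, plus an order-level node with no family on its path.
toy_taxonomy_lines <- function() {
  c("taxid\tparent\trank\tname",
    "1\t1\tno rank\troot",
    "2\t1\tsuperkingdom\tBacteria",
    "20\t2\torder\tOrphanales",          # order with no family below
    "21\t20\tspecies\tOrphanus unicus",  # species whose lineage skips family
    "10\t2\tfamily\tAlphaceae",
    "11\t10\tgenus\tAlphus",
    "12\t10\tgenus\tAlphoides",
    "13\t11\tspecies\tAlphus primus",
    "14\t11\tspecies\tAlphus secundus",
    "15\t12\tspecies\tAlphoides tertius",
    "30\t2\tfamily\tBetaceae",
    "31\t30\tgenus\tBetus",
    "32\t31\tspecies\tBetus quartus")
}

toy_tree <- function() {
  tsv <- withr::local_tempfile(fileext = ".tsv",
                               .local_envir = parent.frame())
  writeLines(toy_taxonomy_lines(), tsv)
  load_taxonomy(tsv)
}

# Brute-force LCA oracle: intersect full root paths, take the deepest.
oracle_lca <- function(tree, taxids) {
  paths <- lapply(taxids, function(tx) {
    p <- tx
    while (tree$parent_of[[as.character(p[length(p)])]] != p[length(p)])
      p <- c(p, tree$parent_of[[as.character(p[length(p)])]])
    p
  })
  common <- Reduce(intersect, paths)
  depths <- vapply(common, function(tx) {
    d <- 0L
    while (tree$parent_of[[as.character(tx)]] != tx) {
      tx <- tree$parent_of[[as.character(tx)]]
      d <- d + 1L
    }
    d
  }, 0L)
  common[which.max(depths)]
}

# All set partitions of n items as label vectors (restricted growth
# strings): canonical enumeration, 1, 2, 5, 15, 52, 203 for n = 1..6.
all_partitions <- function(n) {
  out <- list()
  recurse <- function(labels, k) {
    i <- length(labels) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- labels
      return(invisible(NULL))
    }
    for (lab in seq_len(k + 1L))
      recurse(c(labels, lab), max(k, lab))
  }
  recurse(integer(0), 0L)
  out
}

# Loop-based entropy/MI oracle on two label vectors (natural log),
# written independently of the package's contingency path.
oracle_nmi <- function(u, v) {
  n <- length(u)
  pu <- table(u) / n
  pv <- table(v) / n
  hu <- -sum(pu * log(pu))
  hv <- -sum(pv * log(pv))
  if (hu == 0 && hv == 0) return(list(nmi = 1, mi = 0, hu = hu, hv = hv))
  if (hu == 0 || hv == 0) return(list(nmi = 0, mi = 0, hu = hu, hv = hv))
  mi <- 0
  for (cu in unique(u)) for (cv in unique(v)) {
    pj <- sum(u == cu & v == cv) / n
    if (pj > 0)
      mi <- mi + pj * log(pj / ((sum(u == cu) / n) * (sum(v == cv) / n)))
  }
  list(nmi = max(0, mi) / max(hu, hv), mi = max(0, mi), hu = hu, hv = hv)
}

# Permutation-model expected MI by full enumeration over all n!
# relabelings of v (depends only on the cluster-size vectors).
oracle_emi_permutation <- function(u, v) {
  n <- length(u)
  perms <- all_permutations(n)
  mean(vapply(perms, function(p) oracle_nmi(u, v[p])$mi, 0))
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- list()
  for (p in sub) for (pos in seq_len(n)) {
    out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
  }
  out
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp_str <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# A truth-copying assignment table (the "perfect pipeline").
perfect_assignments <- function(truth) {
  data.frame(read_id = truth$read_id, status = "classified",
             taxid = truth$taxid, stringsAsFactors = FALSE)
}
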