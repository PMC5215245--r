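test_that("compact TSV and dmp dialect load to identical trees", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("taxid\tparent\trank\tname",
               "1\t1\tno rank\troot",
               "10\t1\tfamily\tExamplaceae",
               "11\t10\tgenus\tExamplus"), tsv)
  tree_tsv <- load_taxonomy(tsv)
  expect_equal(nrow(tree_tsv$nodes), 3L)
  expect_equal(tree_tsv$root, 1L)
  # genus reaches root by parent traversal
  expect_equal(unname(tree_tsv$depth_of[["11"]]), 2L)

  nodes <- withr::local_tempfile(fileext = ".dmp")
  names_f <- withr::local_tempfile(fileext = ".dmp")
  writeLines(c("1\t|\t1\t|\tno rank\t|",
               "10\t|\t1\t|\tfamily\t|",
               "11\t|\t10\t|\tgenus\t|"), nodes)
  writeLines(c("1\t|\troot\t|\t\t|\tscientific name\t|",
               "10\t|\tExamplaceae\t|\t\t|\tscientific name\t|",
               "10\t|\tsome synonym\t|\t\t|\tsynonym\t|",
               "11\t|\tExamplus\t|\t\t|\tscientific name\t|"), names_f)
  tree_dmp <- load_taxonomy(nodes, names_f)

  ord <- function(tr) tr$nodes[order(tr$nodes$taxid),
                               c("taxid", "parent", "rank", "name")]
  expect_equal(ord(tree_dmp), ord(tree_tsv), ignore_attr = TRUE)
})

test_that("structural defects are rejected", {
  bad_parent <- withr::local_tempfile()
  writeLines(c("taxid\tparent\trank\tname",
               "1\t1\tno rank\troot",
               "10\t99\tfamily\tExamplaceae"), bad_parent)
  expect_error(load_taxonomy(bad_parent), "dangling")

  cyclic <- withr::local_tempfile()
  writeLines(c("taxid\tparent\trank\tname",
               "1\t1\tno rank\troot",
               "10\t11\tfamily\tA",
               "11\t10\tgenus\tB"), cyclic)
  expect_error(load_taxonomy(cyclic), "cycle")

  empty <- withr::local_tempfile()
  writeLines(character(0), empty)
  expect_error(load_taxonomy(empty), "empty")
})

test_that("ancestor_at_rank walks inclusively and returns NA above rank", {
  tree <- toy_tree()
  expect_equal(ancestor_at_rank(tree, 13L, "family"), 10L)
  expect_equal(ancestor_at_rank(tree, 13L, "genus"), 11L)
  expect_equal(ancestor_at_rank(tree, 10L, "family"), 10L)  # inclusive
  expect_true(is.na(ancestor_at_rank(tree, 1L, "family")))  # root
  # species under the family-less order has no family ancestor
  expect_true(is.na(ancestor_at_rank(tree, 21L, "family")))
  expect_error(ancestor_at_rank(tree, 999L, "family"), "unknown taxid")
})

test_that("ancestor_at_rank is idempotent on its own output", {
  tree <- toy_tree()
  for (tx in tree$nodes$taxid) {
    for (rank in c("family", "genus")) {
      a <- ancestor_at_rank(tree, tx, rank)
      if (!is.na(a)) expect_equal(ancestor_at_rank(tree, a, rank), a)
    }
  }
})

test_that("LCA matches the brute-force root-path oracle on all small subsets", {
  tree <- toy_tree()
  ids <- tree$nodes$taxid
  expect_equal(lowest_common_ancestor(tree, 13L), 13L)       # singleton
  expect_equal(lowest_common_ancestor(tree, c(13L, 14L)), 11L)
  expect_equal(lowest_common_ancestor(tree, c(13L, 1L)), 1L) # root wins
  expect_error(lowest_common_ancestor(tree, integer(0)), "empty")

  set.seed(1)
  for (k in 2:4) {
    for (rep in 1:30) {
      s <- sample(ids, k)
      expect_equal(lowest_common_ancestor(tree, s), oracle_lca(tree, s))
    }
  }
  # commutative/associative over set union
  s1 <- c(13L, 15L); s2 <- c(32L, 14L)
  expect_equal(lowest_common_ancestor(tree, c(s1, s2)),
               lowest_common_ancestor(
                 tree, c(lowest_common_ancestor(tree, s1),
                         lowest_common_ancestor(tree, s2))))
})

test_that("normalize_assignments projects, downgrades and conserves rows", {
  tree <- toy_tree()
  raw <- data.frame(
    read_id = paste0("r", 1:5),
    status = c("classified", "classified", "classified",
               "unclassified", "discarded"),
    taxid = c(13L, 20L, 15L, NA, NA),   # species, order-level call, species
    stringsAsFactors = FALSE)
  out <- normalize_assignments(tree, raw, "family")
  expect_equal(nrow(out), 5L)
  expect_equal(out$taxid[1], 10L)
  # order-level call carries no information at family rank
  expect_equal(out$status[2], "unclassified")
  expect_equal(out$taxid[3], 10L)
  expect_equal(out$status[4:5], c("unclassified", "discarded"))

  # status counts only ever shift classified -> unclassified
  before <- table(factor(raw$status,
                         c("classified", "unclassified", "discarded")))
  after <- table(factor(out$status,
                        c("classified", "unclassified", "discarded")))
  expect_equal(sum(before), sum(after))
  expect_true(after[["classified"]] <= before[["classified"]])
  expect_equal(after[["discarded"]], before[["discarded"]])
})

test_that("name resolution is case-insensitive, shallowest-on-ambiguity", {
  tree <- toy_tree()
  expect_equal(resolve_name(tree, "alphus PRIMUS"), 13L)
  expect_true(is.na(resolve_name(tree, "No Such Taxon")))
  expect_error(resolve_name(tree, "No Such Taxon", strict = TRUE),
               "unresolvable")

  raw <- data.frame(read_id = "r1", status = "classified",
                    taxid = NA_integer_, name = "Betus quartus",
                    stringsAsFactors = FALSE)
  out <- normalize_assignments(tree, raw, "genus")
  expect_equal(out$taxid, 31L)
})

test_that("merged.dmp remapping resolves retired taxids", {
  nodes <- withr::local_tempfile()
  merged <- withr::local_tempfile()
  writeLines(c("1\t|\t1\t|\tno rank\t|",
               "10\t|\t1\t|\tfamily\t|"), nodes)
  writeLines("99\t|\t10\t|", merged)
  tree <- load_taxonomy(nodes, merged_source = merged)
  expect_equal(resolve_taxid(tree, 99L), 10L)
  expect_equal(resolve_taxid(tree, 10L), 10L)
  expect_true(is.na(resolve_taxid(tree, 1234L)))
})
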