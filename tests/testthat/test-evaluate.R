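# Truth: 10 reads, species under two families of the toy tree.
toy_truth <- function() {
  data.frame(
    read_id = paste0("r", sprintf("%02d", 1:10)),
    genome_id = "g",
    taxid = c(rep(13L, 5), rep(14L, 2), rep(15L, 2), 32L),
    stringsAsFactors = FALSE)
}

test_that("a perfect pipeline scores TP only; conservation holds", {
  tree <- toy_tree()
  truth <- toy_truth()
  cc <- confusion_at_rank(truth, perfect_assignments(truth), tree, "family")
  expect_equal(c(cc$TP, cc$FP, cc$FN), c(10L, 0L, 0L))
  expect_equal(cc$TP + cc$FP + cc$FN, cc$n_reads)
  expect_equal(unname(f_measure(cc)), c(1, 1, 1))
})

test_that("wrong, unclassified, discarded and missing reads are scored per rule", {
  tree <- toy_tree()
  truth <- toy_truth()
  pred <- perfect_assignments(truth)
  pred$taxid[1] <- 32L                        # wrong family -> FP
  pred$status[2] <- "unclassified"; pred$taxid[2] <- NA  # FN
  pred$status[3] <- "discarded"; pred$taxid[3] <- NA     # FN
  pred <- pred[-4, ]                          # missing read -> injected FN
  cc <- confusion_at_rank(truth, pred, tree, "family")
  expect_equal(c(cc$TP, cc$FP, cc$FN), c(6L, 1L, 3L))
  expect_equal(cc$TP + cc$FP + cc$FN, nrow(truth))
})

test_that("the singleton rule recounts single-read taxa as FN before TP/FP", {
  tree <- toy_tree()
  # 9 reads correct to family Alphaceae, 1 correct to family Betaceae
  truth <- toy_truth()
  pred <- perfect_assignments(truth)
  keep <- confusion_at_rank(truth, pred, tree, "family",
                            drop_singletons = FALSE)
  expect_equal(c(keep$TP, keep$FP, keep$FN), c(10L, 0L, 0L))
  drop <- confusion_at_rank(truth, pred, tree, "family",
                            drop_singletons = TRUE)
  expect_equal(c(drop$TP, drop$FP, drop$FN), c(9L, 0L, 1L))
})

test_that("confusion conservation holds across ranks and singleton flags", {
  fxl <- generate_fixture_collection(2, 2, 2, c(1, 2), seed = 31)
  design <- community_design(names(fxl$genomes), "HC")
  ds <- simulate_dataset(fxl$genomes, design, fixture_primers(), 120L,
                         error_free_params(), seed = 8,
                         genome_taxids = fxl$genome_taxids)
  set.seed(9)
  pred <- perfect_assignments(ds$truth)
  scramble <- sample(nrow(pred), 30)
  pred$taxid[scramble[1:10]] <- sample(fxl$tree$nodes$taxid[
    fxl$tree$nodes$rank == "species"], 10, replace = TRUE)
  pred$status[scramble[11:20]] <- "unclassified"
  pred$taxid[scramble[11:20]] <- NA
  pred$status[scramble[21:30]] <- "discarded"
  pred$taxid[scramble[21:30]] <- NA
  for (rank in c("family", "genus")) for (flag in c(TRUE, FALSE)) {
    cc <- confusion_at_rank(ds$truth, pred, fxl$tree, rank,
                            drop_singletons = flag)
    expect_equal(cc$TP + cc$FP + cc$FN, nrow(ds$truth))
  }
})

test_that("f_measure follows its closed forms and degenerate conventions", {
  expect_equal(unname(f_measure(list(TP = 0, FP = 5, FN = 5))), c(0, 0, 0))
  out <- f_measure(list(TP = 80, FP = 20, FN = 0))
  expect_equal(unname(out["precision"]), 0.8)
  expect_equal(unname(out["recall"]), 1.0)
  expect_equal(unname(out["f_measure"]), 2 * 0.8 / 1.8)
  # F = P when P = R; F bounded by min(2P, 2R)
  out2 <- f_measure(list(TP = 6, FP = 2, FN = 2))
  expect_equal(unname(out2["f_measure"]), unname(out2["precision"]))
  set.seed(10)
  for (i in 1:20) {
    cts <- as.list(stats::setNames(sample(0:20, 3, TRUE),
                                   c("TP", "FP", "FN")))
    v <- f_measure(cts)
    expect_lte(v["f_measure"], min(2 * v["precision"], 2 * v["recall"]) + 1e-12)
  }
})

test_that("merge_otus pools sizes per projected taxon with unclassified key", {
  tree <- toy_tree()
  otus <- data.frame(otu_id = paste0("otu", 1:3), size = c(5L, 3L, 2L),
                     taxid = c(13L, 14L, 15L))
  prof <- merge_otus(otus, tree, "family")
  expect_equal(prof, c(`10` = 10))
  # species under 2 genera at genus rank -> 2 keys
  prof_g <- merge_otus(otus, tree, "genus")
  expect_equal(prof_g, c(`11` = 8, `12` = 2))
  # unclassified OTU pools; order-level OTU misses the family rank
  otus2 <- rbind(otus,
                 data.frame(otu_id = c("otu4", "otu5"), size = c(4L, 6L),
                            taxid = c(NA, 20L)))
  prof2 <- merge_otus(otus2, tree, "family")
  expect_equal(prof2[["unclassified"]], 10)
  expect_lte(length(prof2), nrow(otus2))        # merging never adds units
})

test_that("chao1 matches its closed forms and stays >= observed richness", {
  expect_equal(chao1(c(A = 5, B = 4, C = 3)), 3)          # no singletons
  expect_equal(chao1(c(A = 1, B = 1, C = 2)), 3.5)        # 3 + 2*1/(2*2)
  expect_equal(chao1(c(A = 1)), 1)                        # f1=1 term vanishes
  expect_equal(chao1(c(A = 1, B = 1, C = 2), variant = "classic"),
               3 + 2^2 / (2 * 1))                         # 3 + f1^2/(2 f2)
  expect_error(chao1(c(unclassified = 5)), "empty")
  set.seed(11)
  for (i in 1:30) {
    n_taxa <- sample(2:12, 1)
    p <- stats::setNames(sample(1:5, n_taxa, TRUE), paste0("t", 1:n_taxa))
    est <- chao1(p)
    f1 <- sum(p == 1)
    expect_gte(est, length(p))
    if (f1 * (f1 - 1) == 0) expect_equal(est, length(p))
  }
  # unclassified key excluded before estimation
  expect_equal(chao1(c(A = 1, B = 1, C = 2, unclassified = 7)), 3.5)
})

test_that("chao1 agrees with vegan's bias-corrected estimator", {
  set.seed(12)
  for (i in 1:10) {
    counts <- sample(1:6, 15, TRUE)
    est <- chao1(stats::setNames(counts, paste0("t", 1:15)))
    # estimateR may warn (NaN in its SE term when doubletons are absent);
    # only the point estimate is compared
    ref <- unname(suppressWarnings(vegan::estimateR(counts))["S.chao1"])
    expect_equal(est, ref, tolerance = 1e-10)
  }
})

test_that("chao1_error_percent is the signed relative deviation x 100", {
  expect_equal(chao1_error_percent(50, 50), 0)
  expect_equal(chao1_error_percent(54, 50), 8.0)
  expect_equal(chao1_error_percent(45, 50), -10.0)
  expect_error(chao1_error_percent(10, 0), "> 0")
})

test_that("diversity indices match closed forms, vegan, and their bounds", {
  expect_equal(unname(diversity_indices(c(A = 50, B = 50))["shannon"]),
               log(2))
  expect_equal(unname(diversity_indices(c(A = 75, B = 25))["inverse_simpson"]),
               1.6)
  expect_equal(
    unname(diversity_indices(stats::setNames(rep(7, 6),
                                             paste0("t", 1:6)))["inverse_simpson"]),
    6)
  set.seed(13)
  for (i in 1:10) {
    counts <- sample(1:40, 8, TRUE)
    p <- stats::setNames(counts, paste0("t", 1:8))
    d <- diversity_indices(p)
    expect_equal(unname(d["shannon"]),
                 unname(vegan::diversity(counts, "shannon")))
    expect_equal(unname(d["inverse_simpson"]),
                 unname(vegan::diversity(counts, "invsimpson")))
    expect_gte(d[["inverse_simpson"]], 1)
    expect_lte(d[["inverse_simpson"]], length(p) + 1e-12)
  }
  expect_equal(unname(diversity_indices(c(A = 9))["inverse_simpson"]), 1)
})

test_that("profiles from truth and assignments agree for a perfect pipeline", {
  tree <- toy_tree()
  truth <- toy_truth()
  pt <- truth_profile(truth, tree, "genus")
  pa <- profile_from_assignments(perfect_assignments(truth), tree, "genus")
  expect_equal(pt, pa)
  expect_equal(sum(pt), nrow(truth))
})
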