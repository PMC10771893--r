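test_that("distance models follow their closed forms and flag saturation", {
  same <- msa(c(a = "ACGTACGTAC", b = "ACGTACGTAC"))
  for (model in c("p", "JC", "K2P")) {
    expect_equal(unname(distance_matrix(same, model)[1, 2]), 0)
  }
  one <- msa(c(a = "ACGTACGTAC", b = "ACGTACGTAT"))
  expect_equal(unname(distance_matrix(one, "p")[1, 2]), 0.1)
  expect_equal(unname(distance_matrix(one, "JC")[1, 2]), -0.75 * log(1 - 0.4 / 3))
  expect_equal(round(unname(distance_matrix(one, "JC")[1, 2]), 4), 0.1073)

  sat <- msa(c(a = "AAAACCCCGGGGTTTT", b = "CCCCGGGGTTTTAAAA"))  # p = 1
  d <- distance_matrix(sat, "JC")
  expect_true(is.na(d[1, 2]))
  expect_equal(attr(d, "saturated")[1, ], c("a", "b"))
})

test_that("distances agree with ape::dist.dna under pairwise deletion", {
  aln <- related_msa(6, 400, sub_prob = 0.15, gap_prob = 0.05, seed = 31)
  bin <- ape::as.DNAbin(do.call(rbind, strsplit(tolower(unname(aln$seqs)), "")))
  rownames(bin) <- aln$ids
  for (pair in list(c("p", "raw"), c("JC", "JC69"), c("K2P", "K80"))) {
    mine <- unclass(distance_matrix(aln, pair[1]))[aln$ids, aln$ids]
    ref <- as.matrix(ape::dist.dna(bin, model = pair[2],
                                   pairwise.deletion = TRUE))[aln$ids, aln$ids]
    ok <- is.finite(ref)
    expect_true(all(ok[lower.tri(ok)]))  # divergences chosen below saturation
    expect_equal(unname(mine[ok]), unname(ref[ok]), tolerance = 1e-9)
  }
})

test_that("three-taxon NJ uses the exact three-point formulas", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- neighbor_joining(D)
  expect_equal(write_newick(tree), "(A:1.0,B:2.0,C:3.0);")
})

test_that("NJ recovers additive 4- and 5-taxon matrices exactly", {
  # 4 taxa, branch lengths {1, 2, 3, 4, 5}
  true4 <- read_newick("((A:1,B:2):5,C:3,D:4);")
  D4 <- ape::cophenetic.phylo(true4)
  nj4 <- neighbor_joining(D4)
  expect_setequal(names(tree_bipartitions(nj4)), names(tree_bipartitions(true4)))
  expect_lt(max(abs(ape::cophenetic.phylo(nj4)[rownames(D4), colnames(D4)] - D4)), 1e-9)

  set.seed(8)
  for (rep in 1:5) {
    true5 <- ape::rtree(5, br = function(n) runif(n, 0.5, 4))
    true5 <- ape::unroot(true5)
    D5 <- ape::cophenetic.phylo(true5)
    nj5 <- neighbor_joining(D5)
    expect_setequal(names(tree_bipartitions(nj5)), names(tree_bipartitions(true5)))
    expect_lt(max(abs(ape::cophenetic.phylo(nj5)[rownames(D5), colnames(D5)] - D5)), 1e-9)
  }
})

test_that("NJ matches ape::nj topologies on random alignments and ignores input order", {
  aln <- related_msa(7, 300, sub_prob = 0.12, seed = 12)
  D <- distance_matrix(aln, "JC")
  mine <- neighbor_joining(D)
  ref <- ape::nj(stats::as.dist(unclass(D)))
  expect_setequal(names(tree_bipartitions(mine)), names(tree_bipartitions(ref)))

  perm <- c(4, 1, 7, 3, 6, 2, 5)
  Dp <- unclass(D)[perm, perm]
  expect_equal(write_newick(neighbor_joining(Dp)), write_newick(mine))
})

test_that("NJ recovers the generating 9-taxon topology from long simulated CDS", {
  truth <- sort(names(tree_bipartitions(mammal_tree())))
  hits <- 0L
  for (s in 1:20) {
    sim <- simulate_cds(mammal_config(seed = 100 + s, scenario = "null",
                                      n_codons = 2000))
    nj <- neighbor_joining(distance_matrix(sim$nt, "JC"))
    hits <- hits + identical(sort(names(tree_bipartitions(nj))), truth)
  }
  expect_gte(hits, 19L)  # >= 95% of 20 seeds
})

test_that("bootstrap supports are replicate fractions and match an independent tally", {
  # every column supports AB|CD: support 1 at any n_reps
  cols <- c(a = "AAGGCCTTAACC", b = "AAGGCCTTAACC", c = "GGAATTCCCCAA", d = "GGAATTCCCCAA")
  four <- msa(cols)
  bs1 <- bootstrap_support(four, n_reps = 1, seed = 5)
  expect_true(all(bs1$support %in% c(0, 1)))
  bs7 <- bootstrap_support(four, n_reps = 7, seed = 5)
  expect_equal(unname(bs7$support[split_key_for(four$ids, c("c", "d"))]), 1)

  sim <- simulate_cds(mammal_config(seed = 5, scenario = "null", n_codons = 300))
  bs <- bootstrap_support(sim$nt, n_reps = 50, seed = 9, model = "p")
  expect_equal(bs$n_used + bs$n_skipped, 50L)
  counts <- ape::prop.clades(bs$tree, bs$replicates, rooted = FALSE)
  ntip <- length(bs$tree$tip.label)
  splits <- tree_bipartitions(bs$tree)
  for (k in seq_along(splits)) {
    expect_equal(bs$support[[k]] * bs$n_used, counts[splits[[k]] - ntip])
  }
  # determinism
  bs2 <- bootstrap_support(sim$nt, n_reps = 50, seed = 9, model = "p")
  expect_identical(bs$support, bs2$support)
})

test_that("majority-rule consensus keeps exactly the splits above the cutoff", {
  set.seed(6)
  t1 <- ape::unroot(ape::rtree(6))
  cons_same <- majority_rule_consensus(list(t1, t1, t1))
  expect_setequal(names(tree_bipartitions(cons_same)), names(tree_bipartitions(t1)))
  labs0 <- cons_same$node.label[nzchar(cons_same$node.label)]
  expect_true(all(as.numeric(labs0) == 1))

  # 5 leaves: two copies of T1 plus one conflicting T2
  t1 <- read_newick("((A,B),(C,D),E);")
  t2 <- read_newick("((A,C),(B,D),E);")
  cons <- majority_rule_consensus(list(t1, t1, t2))
  expect_setequal(names(tree_bipartitions(cons)), names(tree_bipartitions(t1)))
  labs <- cons$node.label[nzchar(cons$node.label)]
  expect_true(all(abs(as.numeric(labs) - 2 / 3) < 1e-6))  # 6-digit printing

  # a split in 2 of 5 trees is dropped at cutoff 0.5
  trees5 <- list(t1, t1, t1, t2, t2)
  cons5 <- majority_rule_consensus(trees5, cutoff = 0.5)
  expect_false(split_key_for(t1$tip.label, c("A", "C")) %in%
                 names(tree_bipartitions(cons5)))
  expect_true(split_key_for(t1$tip.label, c("A", "B")) %in%
                names(tree_bipartitions(cons5)))

  t3 <- ape::rtree(4)
  expect_error(majority_rule_consensus(list(t1, t3)), "same leaf set")
})

test_that("Fitch scores match exhaustive enumeration and an independent implementation", {
  same <- msa(c(a = "ACGT", b = "ACGT", c = "ACGT", d = "ACGT"))
  quartet <- read_newick("((a,b),(c,d));")
  expect_equal(fitch_score(quartet, same), 0L)

  one_col <- msa(c(a = "A", b = "A", c = "G", d = "G"))
  expect_equal(fitch_score(quartet, one_col), 1L)

  set.seed(14)
  for (rep in 1:3) {
    tree <- ape::rtree(5)
    tree$tip.label <- paste0("t", 1:5)
    aln <- random_msa(5, 6, alphabet = c("A", "C", "G"), seed = 50 + rep)
    expect_equal(fitch_score(tree, aln), bf_fitch(tree, aln))
    chars <- do.call(rbind, strsplit(unname(aln$seqs), ""))
    rownames(chars) <- aln$ids
    ph <- phangorn::phyDat(chars, type = "USER", levels = c("A", "C", "G"))
    expect_equal(fitch_score(tree, aln),
                 as.integer(phangorn::parsimony(tree, ph)))
  }
})

test_that("Fitch score is invariant under re-rooting and handles gaps as missing", {
  aln <- random_msa(6, 40, seed = 9)
  tree <- ape::rtree(6)
  tree$tip.label <- paste0("t", 1:6)
  s0 <- fitch_score(tree, aln)
  expect_equal(fitch_score(ape::unroot(tree), aln), s0)
  for (tip in c("t2", "t5")) {
    rerooted <- ape::root(ape::unroot(tree), outgroup = tip, resolve.root = TRUE)
    expect_equal(fitch_score(rerooted, aln), s0)
  }

  gappy <- msa(c(a = "A-", b = "AA", c = "GA", d = "GA"))
  expect_equal(fitch_score(read_newick("((a,b),(c,d));"), gappy), 1L)
})

test_that("a longer terminal branch is recovered as longer by NJ", {
  tree <- read_newick("((H:0.06,C:0.01):0.05,(X:0.1,Y:0.1):0.05);")
  hits <- 0L
  for (s in 1:20) {
    sim <- simulate_cds(simulation_config(tree, n_codons = 1500, seed = 600 + s))
    nj <- neighbor_joining(distance_matrix(sim$nt, "JC"))
    term <- setNames(nj$edge.length[nj$edge[, 2] <= 4], nj$tip.label[nj$edge[nj$edge[, 2] <= 4, 2]])
    hits <- hits + (term[["H"]] > term[["C"]])
  }
  expect_gte(hits, 18L)  # >= 90% of 20 seeds
})
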