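test_that("Jukes-Cantor distance follows the closed form", {
  a <- strrep("A", 10)
  aln <- sequence_alignment(c("x", "y"), c(a, a))
  expect_equal(unname(jc_distance(aln)["x", "y"]), 0)
  # p = 0.1: one mismatch over ten compared columns
  b <- paste0("C", strrep("A", 9))
  d <- jc_distance(sequence_alignment(c("x", "y"), c(a, b)))
  expect_equal(unname(d["x", "y"]), -0.75 * log(13 / 15), tolerance = 1e-12)
  # monotone in p below saturation
  ps <- seq(0.05, 0.7, by = 0.05)
  ds <- -0.75 * log(1 - 4 * ps / 3)
  expect_true(all(diff(ds) > 0))
})

test_that("saturated pairs error by default and can be capped", {
  x <- "AAAA"
  y <- "CCCA"  # p = 0.75
  expect_error(jc_distance(sequence_alignment(c("x", "y"), c(x, y))),
               "saturated")
  D <- jc_distance(sequence_alignment(c("x", "y"), c(x, y)),
                   on_saturation = "cap", cap = 5)
  expect_equal(unname(D["x", "y"]), 5)
  expect_identical(attr(D, "saturated_pairs")[1, ], c("x", "y"))
})

test_that("gap and N columns are excluded pairwise", {
  aln <- sequence_alignment(c("x", "y"), c("ACGTACGTA-", "ACGTACGTNC"))
  expect_equal(unname(jc_distance(aln)["x", "y"]), 0)  # 8 comparable, 0 diff
  aln2 <- sequence_alignment(c("x", "y"), c("CCGTACGTA-", "ACGTACGTNC"))
  expect_equal(unname(jc_distance(aln2)["x", "y"]),
               -0.75 * log(1 - 4 * (1 / 8) / 3), tolerance = 1e-12)
})

test_that("JC distances agree with ape's estimator on a simulated alignment", {
  set.seed(13)
  tree <- ape::rtree(8)
  tree$edge.length <- tree$edge.length * 0.15
  aln <- evolve_sequences(tree, 600, seed = 14)
  D <- jc_distance(aln)
  D_ape <- as.matrix(ape::dist.dna(aln_to_dnabin(aln), model = "JC69",
                                   pairwise.deletion = TRUE))
  expect_equal(D[rownames(D_ape), colnames(D_ape)], D_ape,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("neighbor joining reconstructs an additive 4-taxon matrix exactly", {
  truth <- ape::read.tree(text = "((A:0.1,B:0.2):0.05,C:0.15,D:0.08);")
  D <- ape::cophenetic.phylo(truth)
  tr <- neighbor_joining(D)
  expect_equal(ape::dist.topo(tr, truth)[1], 0, ignore_attr = TRUE)
  patristic <- ape::cophenetic.phylo(tr)[rownames(D), colnames(D)]
  expect_lt(max(abs(patristic - D)), 1e-10)
  expect_identical(attr(tr, "clamped"), 0L)
})

test_that("neighbor joining handles 2- and 3-taxon cases by the closed forms", {
  D2 <- matrix(c(0, 0.2, 0.2, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  t2 <- neighbor_joining(D2)
  expect_equal(sum(t2$edge.length), 0.2)
  # equidistant 3 taxa: each pendant edge is d/2
  d <- 0.3
  D3 <- matrix(d, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  diag(D3) <- 0
  t3 <- neighbor_joining(D3)
  expect_equal(t3$edge.length, rep(d / 2, 3))
  expect_error(neighbor_joining(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("negative branch estimates are clamped to zero and counted", {
  D <- matrix(c(0, 0.1, 0.1,
                0.1, 0, 0.5,
                0.1, 0.5, 0), 3, byrow = TRUE,
              dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  tr <- neighbor_joining(D)
  expect_true(all(tr$edge.length >= 0))
  expect_gte(attr(tr, "clamped"), 1L)
})

test_that("NJ topology is invariant to taxon input order", {
  set.seed(17)
  truth <- ape::rtree(7)
  truth$edge.length <- runif(nrow(truth$edge), 0.05, 0.2)
  D <- ape::cophenetic.phylo(truth)
  base <- neighbor_joining(D)
  for (i in 1:5) {
    perm <- sample(nrow(D))
    tr <- neighbor_joining(D[perm, perm])
    expect_equal(ape::dist.topo(tr, base)[1], 0, ignore_attr = TRUE)
  }
})

test_that("NJ matches ape's implementation on random (non-additive) distances", {
  set.seed(19)
  for (i in 1:5) {
    n <- 8
    pts <- matrix(runif(n * 3), n)
    D <- as.matrix(dist(pts))
    dimnames(D) <- list(paste0("t", 1:n), paste0("t", 1:n))
    mine <- neighbor_joining(D)
    theirs <- ape::nj(as.dist(D))
    expect_equal(ape::dist.topo(mine, theirs)[1], 0, ignore_attr = TRUE)
  }
})

test_that("bootstrap supports behave at the extremes", {
  # alignment where every informative column supports the split AB|CD
  block <- function(ch, n) strrep(ch, n)
  seqs <- c(A = paste0(block("A", 30), block("T", 70)),
            B = paste0(block("A", 30), block("T", 70)),
            C = paste0(block("C", 30), block("T", 70)),
            D = paste0(block("C", 30), block("T", 70)))
  aln <- sequence_alignment(names(seqs), seqs)
  tr <- bootstrap_support(aln, n_replicates = 50, seed = 1)
  s <- attr(tr, "support")
  expect_true(all(s == 100))
  # a single replicate can only give 0 or 100
  tr1 <- bootstrap_support(aln, n_replicates = 1, seed = 2)
  expect_true(all(attr(tr1, "support") %in% c(0, 100)))
  expect_error(bootstrap_support(sequence_alignment(c("a", "b"),
                                                    c("ACGT", "ACGA")), 10),
               "4 taxa")
})

test_that("bootstrap supports are seeded and bit-reproducible", {
  tree <- ape::read.tree(
    text = "((A:0.05,B:0.05):0.15,(C:0.05,D:0.05):0.15,(E:0.05,F:0.05):0.15);")
  aln <- evolve_sequences(tree, 452, seed = 8)
  t1 <- bootstrap_support(aln, n_replicates = 100, seed = 5)
  t2 <- bootstrap_support(aln, n_replicates = 100, seed = 5)
  expect_identical(attr(t1, "support"), attr(t2, "support"))
  expect_identical(write_newick(t1), write_newick(t2))
  # with long internal edges the true bipartitions are strongly supported
  expect_equal(ape::dist.topo(t1, tree)[1], 0, ignore_attr = TRUE)
  expect_true(all(attr(t1, "support")[-1] >= 80))
  expect_true(all(high_support_edges(t1)[-1]))
})

test_that("Newick writing and reading round-trip trees", {
  set.seed(23)
  for (i in 1:20) {
    tr <- ape::rtree(sample(4:12, 1))
    txt <- write_newick(tr)
    back <- read_newick(txt)
    # re-serialising the parsed tree must reproduce the text exactly
    expect_identical(write_newick(back), txt)
    expect_equal(sort(back$edge.length), sort(tr$edge.length),
                 tolerance = 1e-8)
    expect_setequal(back$tip.label, tr$tip.label)
  }
  cherry <- read_newick("(A:0.1,B:0.1);")
  expect_identical(ape::Ntip(cherry), 2L)
  expect_equal(cherry$edge.length, c(0.1, 0.1))
  expect_error(read_newick("((A:0.1,B:0.1);"), "unbalanced")
  expect_error(read_newick("(A:0.1,B:0.1));"), "offset")
})
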