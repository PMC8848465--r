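make_related_alignment <- function(n = 5, len = 300, seed = 3) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  root <- sample(bases, len, replace = TRUE)
  rows <- vapply(seq_len(n), function(i) {
    x <- root
    at <- sample(len, 10 * i)
    x[at] <- vapply(x[at], function(b) sample(setdiff(bases, b), 1), "")
    paste(x, collapse = "")
  }, "")
  dna_alignment(sprintf("s%d", seq_len(n)), rows)
}

test_that("sequence distances match an independent implementation", {
  aln <- make_related_alignment()
  chars <- strsplit(tolower(aln$rows), "")
  db <- as.matrix(ape::as.DNAbin(stats::setNames(chars, aln$labels)))
  for (pair in list(c("p", "raw"), c("JC69", "JC69"), c("K80", "K80"))) {
    mine <- seq_distance_matrix(aln, pair[1])
    ref <- as.matrix(ape::dist.dna(db, model = pair[2], pairwise.deletion = TRUE))
    expect_equal(mine, ref[rownames(mine), colnames(mine)], tolerance = 1e-12)
  }
})

test_that("JC69 closed form and saturation boundary behave as stated", {
  # p = 3/40 = 0.075 -> -(3/4) log(1 - 0.1) = 0.0790
  a <- dna_alignment(c("x", "y"),
                     c(strrep("A", 40), paste0(strrep("A", 37), "GGG")))
  expect_equal(round(seq_distance_matrix(a, "JC69")[1, 2], 4), 0.0790)
  expect_equal(seq_distance_matrix(a, "p")[1, 2], 0.075)
  # identical sequences: zero under every model
  b <- dna_alignment(c("x", "y"), c("ACGTACGT", "ACGTACGT"))
  for (m in c("p", "JC69", "K80"))
    expect_equal(seq_distance_matrix(b, m)[1, 2], 0)
  # p = 0.75 saturates the correction
  s <- dna_alignment(c("x", "y"), c("AAAA", "CCCG"))
  expect_error(seq_distance_matrix(s, "JC69"), "saturated")
})

test_that("neighbor joining is exact on additive matrices", {
  for (seed in c(11, 22, 33)) {
    fix <- random_additive_matrix(n = 8, seed = seed)
    t2 <- nj_tree(fix$D)
    D2 <- tree_distance_matrix(t2)[rownames(fix$D), colnames(fix$D)]
    expect_equal(D2, fix$D, tolerance = 1e-8)
    # same unrooted topology as an independent implementation
    ref <- ape::nj(stats::as.dist(fix$D))
    expect_equal(ape::dist.topo(ape::unroot(t2), ape::unroot(ref)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("three taxa solve the three-point closed form", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- nj_tree(D)
  expect_equal(ape::Ntip(t3), 3)
  # pendant lengths: (3+4-5)/2 = 1, (3+5-4)/2 = 2, (4+5-3)/2 = 3
  lens <- stats::setNames(t3$edge.length[t3$edge[, 2] <= 3], t3$tip.label)
  expect_equal(lens[c("a", "b", "c")], c(a = 1, b = 2, c = 3))
  expect_error(nj_tree(D[1:2, 1:2]), "at least 3")
})

test_that("NJ ties resolve deterministically regardless of input order", {
  # ultrametric with two equidistant cherries (a,b) and (c,d)
  D <- matrix(c(0, 2, 4, 4,
                2, 0, 4, 4,
                4, 4, 0, 2,
                4, 4, 2, 0), 4,
              dimnames = list(letters[1:4], letters[1:4]))
  t_ref <- nj_tree(D)
  for (perm in list(c(2, 1, 4, 3), c(4, 3, 2, 1), c(3, 1, 4, 2))) {
    t_p <- nj_tree(D[perm, perm])
    expect_equal(ape::dist.topo(ape::unroot(t_ref), ape::unroot(t_p)), 0,
                 ignore_attr = TRUE)
    Dr <- tree_distance_matrix(t_p)[letters[1:4], letters[1:4]]
    expect_equal(Dr, D, tolerance = 1e-9)
  }
})

test_that("bootstrap replicates are seed-reproducible and skip degenerates", {
  aln <- make_related_alignment(n = 6, len = 200, seed = 9)
  r1 <- bootstrap_replicates(aln, B = 5, seed = 42)
  r2 <- bootstrap_replicates(aln, B = 5, seed = 42)
  expect_equal(length(r1), 5)
  expect_identical(lapply(r1, ape::write.tree), lapply(r2, ape::write.tree))
  # invariant alignment: every replicate degenerates and is skipped
  flat <- dna_alignment(sprintf("s%d", 1:4), rep("ACGTACGT", 4))
  r3 <- bootstrap_replicates(flat, B = 3, seed = 1)
  expect_length(r3, 0)
  expect_equal(attr(r3, "skipped"), 3)
  expect_length(attr(r3, "skip_messages"), 3)
  expect_error(bootstrap_replicates(aln, B = 0, seed = 1), "B")
})

test_that("clade support counts bipartition frequencies and the median", {
  t1 <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  t3 <- ape::read.tree(text = "((a:1,c:1):1,(b:1,d:1):1);")
  all_same <- clade_support(t1, list(t1, t1, t1))
  expect_true(all(attr(all_same, "support") == 100, na.rm = TRUE))
  mixed <- clade_support(t1, c(rep(list(t1), 48), rep(list(t3), 52)))
  expect_equal(sort(unique(stats::na.omit(attr(mixed, "support")))), 48)
  expect_equal(stats::median(c(40, 50, 60)), 50)  # convention used for medians
  t_other <- ape::read.tree(text = "((a:1,b:1):1,(c:1,e:1):1);")
  expect_error(clade_support(t1, list(t_other)), "tip set")
})

test_that("support values are invariant to replicate order", {
  aln <- make_related_alignment(n = 6, len = 300, seed = 4)
  main <- nj_tree(seq_distance_matrix(aln))
  reps <- bootstrap_replicates(aln, B = 20, seed = 7)
  s1 <- attr(clade_support(main, reps), "support")
  s2 <- attr(clade_support(main, rev(reps)), "support")
  expect_equal(s1, s2)
})

test_that("the maximum clade credibility tree maximizes summed split frequency", {
  t1 <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  t3 <- ape::read.tree(text = "((a:1,c:1):1,(b:1,d:1):1);")
  # all identical -> that tree
  same <- mcc_tree(list(t1, t1))
  expect_equal(ape::dist.topo(ape::unroot(same), ape::unroot(t1)), 0,
               ignore_attr = TRUE)
  # two of three share a topology -> one of the majority pair wins
  m <- mcc_tree(list(t3, t1, t1))
  expect_equal(ape::dist.topo(ape::unroot(m), ape::unroot(t1)), 0,
               ignore_attr = TRUE)
  expect_equal(attr(m, "score"), 2 / 3)
  # majority-rule consensus reported alongside
  cons <- attr(m, "majority_consensus")
  expect_s3_class(cons, "phylo")
  expect_error(mcc_tree(list()), "empty")
})

test_that("outgroup rooting places the root, with a monophyly fallback", {
  tr <- ape::unroot(ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):2);"))
  r1 <- root_with_outgroup(tr, "a")
  expect_true(ape::is.rooted(r1))
  r2 <- root_with_outgroup(tr, c("c", "d"))
  expect_true(ape::is.rooted(r2))
  expect_true(ape::is.monophyletic(r2, c("c", "d")))
  expect_warning(r3 <- root_with_outgroup(tr, c("a", "c")), "not monophyletic")
  expect_true(ape::is.rooted(r3))
  expect_error(root_with_outgroup(tr, c("a", "z")), "subset")
  expect_error(root_with_outgroup(tr, letters[1:4]), "all tips")
})

test_that("tree distances: patristic and nodal modes", {
  # sister tips with pendant lengths 1 and 2
  sis <- ape::read.tree(text = "((a:1,b:2):1,c:4);")
  Dbl <- tree_distance_matrix(sis, "branch_length")
  expect_equal(Dbl["a", "b"], 3)
  Dn <- tree_distance_matrix(sis, "nodal")
  expect_equal(Dn["a", "b"], 1)  # one internal node between sisters
  # worked 4-taxon example: nodal distances 1,2,3,2,3,2
  Dfig <- tree_distance_matrix(fig3_tree(), "nodal")
  expect_equal(Dfig["A", "B"], 1)
  expect_equal(Dfig["A", "C"], 2)
  expect_equal(Dfig["A", "D"], 3)
  expect_equal(Dfig["B", "C"], 2)
  expect_equal(Dfig["B", "D"], 3)
  expect_equal(Dfig["C", "D"], 2)
  expect_true(all(Dfig == round(Dfig)))
})

test_that("patristic matrices satisfy the four-point condition", {
  for (seed in c(2, 9)) {
    set.seed(seed)
    tr <- ape::rtree(7)
    D <- tree_distance_matrix(tr, "branch_length")
    labs <- rownames(D)
    combs <- utils::combn(labs, 4)
    for (k in seq_len(ncol(combs))) {
      q <- combs[, k]
      sums <- sort(c(D[q[1], q[2]] + D[q[3], q[4]],
                     D[q[1], q[3]] + D[q[2], q[4]],
                     D[q[1], q[4]] + D[q[2], q[3]]))
      expect_lte(sums[3] - sums[2], 1e-9)
    }
  }
})

test_that("Newick round trip preserves topology, lengths, and labels", {
  aln <- make_related_alignment(n = 7, len = 250, seed = 13)
  main <- clade_support(nj_tree(seq_distance_matrix(aln)),
                        bootstrap_replicates(aln, B = 10, seed = 2))
  path <- tempfile(fileext = ".nwk")
  write_newick(main, path)
  back <- read_newick(path)
  expect_equal(sort(back$tip.label), sort(main$tip.label))
  expect_equal(ape::dist.topo(ape::unroot(back), ape::unroot(main)), 0,
               ignore_attr = TRUE)
  expect_equal(sort(back$edge.length), sort(main$edge.length), tolerance = 1e-9)
  expect_equal(back$node.label, main$node.label)
  # multi-tree files round trip too
  write_newick(list(main, main), path)
  expect_length(read_newick(path), 2)
})
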