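test_that("p-distance counts mismatches over comparable sites", {
  expect_equal(p_distance("ACGT", "ACGT"), 0)
  expect_equal(p_distance("AAAA", "AATT"), 0.5)
  # pairwise deletion: gapped sites are excluded
  expect_equal(p_distance("AA--", "AAAA"), 0)
  expect_equal(p_distance("AA-T", "AAAA"), 1 / 3)
  expect_error(p_distance("AAA", "AAAA"), "equal length")
  expect_error(p_distance("--", "AA"), "no comparable sites")
})

test_that("distance corrections evaluate their closed forms", {
  expect_equal(correct_distance(0), 0)
  expect_equal(correct_distance(0, "nucleotide_k2p", Q = 0), 0)
  expect_equal(correct_distance(0, "p_raw"), 0)
  expect_equal(correct_distance(0.1), -log(1 - 0.1 - 0.2 * 0.01))
  expect_equal(correct_distance(0.2, "nucleotide_k2p", Q = 0.1),
               -0.5 * log(1 - 0.4 - 0.1) - 0.25 * log(1 - 0.2))
  expect_error(correct_distance(0.5, "nucleotide_k2p", Q = 0), "saturation")
  expect_error(correct_distance(0.9), "saturation")
  # monotone increasing on the domain
  p <- seq(0, 0.8, by = 0.05)
  expect_true(all(diff(correct_distance(p)) > 0))
})

test_that("neighbor joining resolves 3 taxa by the closed form", {
  d <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(d)
  len <- stats::setNames(tr$edge.length[match(seq_along(tr$tip.label),
                                              tr$edge[, 2])], tr$tip.label)
  expect_equal(len[["a"]], (3 + 5 - 6) / 2, tolerance = 1e-9)
  expect_equal(len[["b"]], (3 + 6 - 5) / 2, tolerance = 1e-9)
  expect_equal(len[["c"]], (5 + 6 - 3) / 2, tolerance = 1e-9)
})

test_that("neighbor joining reproduces additive matrices exactly", {
  # hand-drawn 4-taxon tree: ((a:1,b:3):2,(c:2,d:4))
  # ((a:1,b:3):2,(c:2,d:4)) => ab=4, ac=5, ad=7, bc=7, bd=9, cd=6
  d <- matrix(c(0, 4, 5, 7,
                4, 0, 7, 9,
                5, 7, 0, 6,
                7, 9, 6, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- neighbor_joining(d)
  expect_equal(max(abs(ape::cophenetic.phylo(tr)[letters[1:4], letters[1:4]] - d)),
               0, tolerance = 1e-9)
  pairs <- terminal_pairs(tr)
  expect_setequal(paste(pairs$leaf_a, pairs$leaf_b), c("a b", "c d"))

  # larger random additive matrices: path metric of a random tree
  set.seed(7)
  for (rep in 1:5) {
    rt <- ape::rtree(8)
    dd <- ape::cophenetic.phylo(rt)
    dd <- dd[sort(rownames(dd)), sort(rownames(dd))]
    tr2 <- neighbor_joining(dd)
    expect_equal(max(abs(ape::cophenetic.phylo(tr2)[rownames(dd), rownames(dd)] - dd)),
                 0, tolerance = 1e-8)
    # independent cross-check: same topology as the reference NJ implementation
    expect_equal(ape::dist.topo(ape::unroot(tr2), ape::unroot(ape::nj(dd))), 0,
                 ignore_attr = TRUE)
  }
})

test_that("degenerate distances produce a zero-length cherry", {
  d <- matrix(c(0, 0, 5, 0, 0, 5, 5, 5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(d)
  len <- stats::setNames(tr$edge.length[match(seq_along(tr$tip.label),
                                              tr$edge[, 2])], tr$tip.label)
  expect_equal(len[["a"]], 0)
  expect_equal(len[["b"]], 0)
  expect_error(neighbor_joining(matrix(c(0, 1, 2, 0), 2, 2)), "at least 3")
  bad <- matrix(c(0, 1, 2, 3, 0, 4, 2, 4, 0), 3, 3)
  expect_error(neighbor_joining(bad), "symmetric")
})

test_that("bootstrap supports are deterministic and saturate for clean cherries", {
  aln <- c(a = "TTTTTTAAAACCCC", b = "TTTTTTAAAACCCC",
           c = "GGGGGGAAAACCCC", d = "GGGGGGTTTTCCCC",
           e = "CCCCCCTTTTGGGG")
  t1 <- bootstrap_support(aln, n_reps = 30, seed = 5, model = "p_raw")
  t2 <- bootstrap_support(aln, n_reps = 30, seed = 5, model = "p_raw")
  expect_identical(attr(t1, "support"), attr(t2, "support"))
  # the identical pair (a,b) is a cherry in every replicate
  pairs <- terminal_pairs(t1)
  ab_node <- which(vapply(seq_len(nrow(pairs)), function(k) {
    setequal(c(pairs$leaf_a[k], pairs$leaf_b[k]), c("a", "b"))
  }, logical(1)))
  expect_length(ab_node, 1)
  sup <- attr(t1, "support")
  expect_true(any(abs(sup - 1) < 1e-12))

  single <- bootstrap_support(aln, n_reps = 1, seed = 9, model = "p_raw")
  expect_true(all(attr(single, "support") %in% c(0, 1) |
                    is.na(attr(single, "support"))))
})

test_that("bootstrap supports are invariant to taxon order", {
  aln <- c(a = "TTTTTTAAAACCCC", b = "TTTTTTAAAACCCC",
           c = "GGGGGGAAAACCCC", d = "GGGGGGTTTTCCCC",
           e = "CCCCCCTTTTGGGG")
  t1 <- bootstrap_support(aln, n_reps = 40, seed = 5, model = "p_raw")
  t2 <- bootstrap_support(aln[c(3, 5, 1, 4, 2)], n_reps = 40, seed = 5,
                          model = "p_raw")
  # compare supports attached to matching bipartitions via the cherry (a,b)
  s1 <- sort(attr(t1, "support"))
  s2 <- sort(attr(t2, "support"))
  expect_equal(s1[s1 == 1], s2[s2 == 1])
  expect_equal(length(s1), length(s2))
})

test_that("terminal pairs enumerate cherries and warn on 3-taxon stars", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  pairs <- terminal_pairs(ape::unroot(tr))
  expect_setequal(paste(pairs$leaf_a, pairs$leaf_b), c("a b", "c d"))

  cat5 <- ape::unroot(ape::read.tree(text = "((((a:1,b:1):1,c:1):1,d:1):1,e:1);"))
  p5 <- terminal_pairs(cat5)
  expect_setequal(paste(p5$leaf_a, p5$leaf_b), c("a b", "d e"))

  star <- ape::read.tree(text = "(a:1,b:1,c:1);")
  expect_warning(p3 <- terminal_pairs(star), "cherry")
  expect_equal(nrow(p3), 0L)
})
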