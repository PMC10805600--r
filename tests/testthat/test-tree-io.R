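test_that("parse_newick reads topology, branch lengths and polytomies", {
  tr <- tree_cherry3()
  expect_s3_class(tr, "phylo")
  expect_equal(ape::Ntip(tr), 3)
  expect_equal(max(ape::node.depth.edgelength(tr)), 2)

  poly <- tree_poly4()
  nchild <- tabulate(poly$edge[, 1])
  expect_equal(max(nchild), 3)  # the (A,B,C) node
})

test_that("write/parse round-trip preserves topology and branch lengths", {
  for (nwk in c("((A:1,B:1):1,C:2);", "(((A:1,B:1):1,C:2):3,D:5);",
                "((A:1,B:1,C:1):1,D:2);")) {
    tr <- parse_newick(nwk)
    back <- parse_newick(write_newick(tr))
    expect_equal(write_newick(back), write_newick(tr))
    expect_equal(sort(back$tip.label), sort(tr$tip.label))
    expect_lt(max(abs(sort(back$edge.length) - sort(tr$edge.length))), 1e-9)
  }
})

test_that("parse_newick rejects malformed input with informative errors", {
  expect_error(parse_newick("((A:1,B:1):1,C:2"), "unclosed")
  expect_error(parse_newick("(A:1,B:2)"), "missing terminal ';'")
  expect_error(parse_newick("(A:1,B:1)):1;"), "character 10")
  expect_error(parse_newick("((A:1,B),C:2);"), "missing branch length.*tip 'B'")
  expect_error(parse_newick("((A:1,B:-1):1,C:2);"), "negative branch length")
  expect_error(parse_newick("((A:1,A:1):1,C:2);"), "duplicate tip label")
})

test_that("node_ages matches hand-computed crown and stem ages", {
  tr <- tree_cherry3()
  ages <- node_ages(tr)
  root <- 4; cherry <- 5
  expect_equal(ages$crown_age[root], 2)
  expect_equal(ages$crown_age[cherry], 1)
  expect_equal(ages$stem_age[cherry], 2)
  expect_true(is.na(ages$stem_age[root]))

  one <- node_ages(parse_newick("(A:5,B:5);"))
  expect_equal(one$crown_age[3], 5)

  ch <- tree_chain4()
  ages <- node_ages(ch)
  abc <- ape::getMRCA(ch, c("A", "B", "C"))
  expect_equal(ages$crown_age[abc], 2)
  expect_equal(ages$stem_age[abc], 5)
})

test_that("node_ages agrees with ape::branching.times on a simulated tree", {
  tr <- simulate_bd_clade(0.25, 0.1, 12, seed = 7)
  ages <- node_ages(tr)
  bt <- ape::branching.times(tr)
  ids <- as.integer(names(bt))
  expect_equal(ages$crown_age[ids], unname(bt), tolerance = 1e-10)
})

test_that("non-ultrametric trees are refused with the worst tip pair named", {
  expect_error(node_ages(parse_newick("((A:1,B:3):1,C:2);")),
               "not ultrametric.*B.*C|not ultrametric.*'B'")
})

test_that("clade_tips returns the tip set (richness) of a node", {
  tr <- tree_cherry3()
  expect_setequal(clade_tips(tr, 5), c("A", "B"))
  expect_setequal(clade_tips(tr, 4), c("A", "B", "C"))
  expect_equal(clade_tips(tr, 3), "C")  # a tip represents itself
  poly <- tree_poly4()
  abc <- ape::getMRCA(poly, c("A", "B", "C"))
  expect_length(clade_tips(poly, abc), 3)
  expect_error(clade_tips(tr, 99), "unknown node id")
})

test_that("detect_artifacts flags polytomies and zero branches per subtree", {
  poly <- tree_poly4()
  art <- detect_artifacts(poly)
  abc <- ape::getMRCA(poly, c("A", "B", "C"))
  expect_true(art$in_polytomy[abc])
  expect_true(art$in_polytomy[ape::Ntip(poly) + 1])  # root subtree contains it
  expect_false(any(art$has_zero_branch))

  z <- tree_zero3()
  art <- detect_artifacts(z)
  ab <- ape::getMRCA(z, c("A", "B"))
  expect_true(art$has_zero_branch[ab])
  expect_equal(node_ages(z)$crown_age[ab], 0)

  clean <- tree_chain4()
  art <- detect_artifacts(clean)
  expect_false(any(art$in_polytomy))
  expect_false(any(art$has_zero_branch))
})

test_that("polytomy scope 'crown' only inspects the node itself", {
  poly <- tree_poly4()
  art <- detect_artifacts(poly, scope = "crown")
  abc <- ape::getMRCA(poly, c("A", "B", "C"))
  expect_true(art$in_polytomy[abc])
  expect_false(art$in_polytomy[ape::Ntip(poly) + 1])  # root itself bifurcates
})

test_that("reduced_tree keeps one representative per clade with source distances", {
  tr <- tree_cherry3()
  red <- reduced_tree(tr, c(5, 3))  # clade (A,B) and tip C
  expect_equal(write_newick(red), "(A:2,C:2);")
  expect_equal(unname(attr(red, "representatives")), c("A", "C"))

  f <- small_forest(10)
  nodes <- f$truth$node[!is.na(f$truth$node)]
  red <- reduced_tree(f$tree, nodes)
  expect_true(is_ultrametric(red))
  expect_equal(ape::Ntip(red), length(nodes))
})

test_that("the representative choice does not change pairwise distances", {
  f <- small_forest(10)
  nodes <- f$truth$node[!is.na(f$truth$node)]
  red1 <- reduced_tree(f$tree, nodes)
  # alternative representative: lexicographically largest tip of each clade
  alt <- vapply(nodes, function(id)
    rev(sort(clade_tips(f$tree, id), method = "radix"))[1], character(1))
  red2 <- ape::keep.tip(f$tree, alt)
  d1 <- ape::cophenetic.phylo(red1)
  d2 <- ape::cophenetic.phylo(red2)
  # align by clade: representative i of red1 corresponds to alt[i] of red2
  reps <- attr(red1, "representatives")[as.character(nodes)]
  expect_equal(unname(d1[reps, reps]), unname(d2[alt, alt]), tolerance = 1e-9)
})

test_that("reduced_tree refuses nested clades", {
  ch <- tree_chain4()
  abc <- ape::getMRCA(ch, c("A", "B", "C"))
  ab <- ape::getMRCA(ch, c("A", "B"))
  expect_error(reduced_tree(ch, c(abc, ab)), "nested")
})

test_that("drop_tips_random subsamples reproducibly and keeps ultrametricity", {
  f <- small_forest(10)
  tr <- f$tree
  expect_identical(drop_tips_random(tr, 1), tr)

  n <- ape::Ntip(tr)
  sub <- drop_tips_random(tr, 0.1, seed = 3)
  expect_equal(ape::Ntip(sub), floor(0.1 * n))
  expect_true(is_ultrametric(sub))
  expect_identical(write_newick(drop_tips_random(tr, 0.1, seed = 3)),
                   write_newick(sub))

  # surviving pairwise distances are untouched
  keep <- sub$tip.label
  expect_equal(dist_among(sub, keep), dist_among(tr, keep), tolerance = 1e-9)

  expect_error(drop_tips_random(tr, 1 / n), "at least 2")
})
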