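# Small fixture trees and generators shared across test files.

tree_cherry3 <- function() parse_newick("((A:1,B:1):1,C:2);")
tree_poly4   <- function() parse_newick("((A:1,B:1,C:1):1,D:2);")
tree_chain4  <- function() parse_newick("(((A:1,B:1):1,C:2):3,D:5);")
tree_zero3   <- function() parse_newick("((A:0,B:0):2,C:2);")
tree_bal4    <- function() parse_newick("((A:1,B:1):1,(C:1,D:1):1);")

# balanced bifurcating topology with 2^k tips (no branch lengths needed)
tree_balanced <- function(k) ape::stree(2^k, type = "balanced")

# pectinate (caterpillar) ultrametric tree with n tips, depth n - 1
tree_caterpillar <- function(n) {
  nwk <- "(T1:1,T2:1)"
  for (i in 3:n) nwk <- sprintf("(%s:1,T%d:%d)", nwk, i, i - 1)
  parse_newick(paste0(nwk, ";"))
}

# small clade forest for pipeline tests
small_forest <- function(n_clades = 12, preset = "age_driven", seed = 42, ...) {
  simulate_clade_forest(scenario_config(n_clades = n_clades,
                                        scenario_preset = preset,
                                        seed = seed, ...))
}

# brute-force ancestor test: is `a` an ancestor of `b` in `tree`?
is_ancestor <- function(tree, a, b) {
  root <- ape::Ntip(tree) + 1L
  parent <- integer(ape::Ntip(tree) + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  p <- b
  while (p != root) {
    p <- parent[p]
    if (p == a) return(TRUE)
  }
  a == root
}

# pairwise tip distance matrix restricted to a label set, in sorted order
dist_among <- function(tree, labels) {
  d <- ape::cophenetic.phylo(tree)
  labels <- sort(labels)
  d[labels, labels]
}
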