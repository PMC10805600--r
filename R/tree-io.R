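# Reading, writing and interrogating time-calibrated trees.
#
# Trees are ordinary ape "phylo" objects: tips are numbered 1..Ntip in the
# order they appear in the Newick string, the root is Ntip + 1 and further
# internal nodes follow in ape's deterministic parse order, so node ids are
# reproducible across runs for a given Newick string. Branch lengths are in
# millions of years (Myr).

.ULTRA_TOL <- 1e-6   # ultrametricity tolerance, Myr
.ZERO_TOL  <- 1e-9   # zero-length-branch tolerance, Myr

# minimal syntactic scan so malformed strings fail with a character offset
.check_newick_syntax <- function(txt) {
  chars <- strsplit(txt, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop_f("malformed Newick: unmatched ')' at character %d", i)
    }
  }
  if (depth > 0L)
    stop_f("malformed Newick: %d unclosed '(' (string ends at character %d)",
           depth, length(chars))
  if (!grepl(";\\s*$", txt))
    stop_f("malformed Newick: missing terminal ';' (string ends at character %d)",
           nchar(txt))
  invisible(TRUE)
}

.node_label <- function(tree, id) {
  if (id <= length(tree$tip.label)) sprintf("tip '%s'", tree$tip.label[id])
  else sprintf("internal node %d", id)
}

#' Parse a Newick string into a time-calibrated tree
#'
#' Wraps [ape::read.tree()] with strict validation: every non-root edge must
#' carry a non-negative branch length and tip labels must be unique and
#' non-empty. Syntax errors are reported with the character offset of the
#' first offending parenthesis.
#'
#' @param text a single Newick string, branch lengths in Myr.
#' @return an object of class `"phylo"`.
#' @seealso [write_newick()], [node_ages()]
#' @export
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' ape::Ntip(tr)
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  txt <- trimws(text)
  .check_newick_syntax(txt)
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) stop_f("malformed Newick: %s", conditionMessage(e)))
  if (is.null(tree)) stop_f("malformed Newick: ape could not parse the string")
  if (is.null(tree$edge.length))
    stop_f("missing branch lengths: no edge in the tree has a length")
  bad <- which(!is.finite(tree$edge.length))
  if (length(bad))
    stop_f("missing branch length on the edge(s) leading to %s",
           paste(vapply(tree$edge[bad, 2], function(i) .node_label(tree, i),
                        character(1)), collapse = ", "))
  if (any(tree$edge.length < 0))
    stop_f("negative branch length on the edge leading to %s",
           .node_label(tree, tree$edge[which(tree$edge.length < 0)[1], 2]))
  if (anyDuplicated(tree$tip.label))
    stop_f("duplicate tip label '%s'", tree$tip.label[duplicated(tree$tip.label)][1])
  if (any(!nzchar(tree$tip.label)))
    stop_f("empty tip label at tip %d", which(!nzchar(tree$tip.label))[1])
  tree
}

#' Write a tree as a Newick string
#'
#' Branch lengths are written with 9 significant digits; labels containing
#' spaces are handled by [ape::write.tree()]'s underscore convention.
#'
#' @param tree a `"phylo"` object.
#' @param file optional path; when `NULL` the string is returned.
#' @param digits significant digits for branch lengths.
#' @return the Newick string (invisibly when written to a file).
#' @export
write_newick <- function(tree, file = NULL, digits = 9) {
  if (is.null(file)) return(ape::write.tree(tree, digits = digits))
  ape::write.tree(tree, file = file, digits = digits)
  invisible(ape::write.tree(tree, digits = digits))
}

#' Is a tree ultrametric within tolerance?
#'
#' @param tree a `"phylo"` object.
#' @param tol tolerance in Myr on the spread of root-to-tip path lengths.
#' @return logical scalar.
#' @export
is_ultrametric <- function(tree, tol = .ULTRA_TOL) {
  d <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  (max(d) - min(d)) <= tol
}

#' Crown and stem ages of every node
#'
#' In an ultrametric tree the crown age of a node is its depth (distance to
#' any descendant tip) and its stem age is the crown age of its parent, i.e.
#' the time the clade split from its sister lineage. Ages of tips are 0.
#'
#' @param tree an ultrametric `"phylo"` object.
#' @param tol ultrametricity tolerance in Myr.
#' @return data.frame with columns `node`, `crown_age`, `stem_age`
#'   (`stem_age` is `NA` for the root).
#' @export
#' @examples
#' node_ages(parse_newick("((A:1,B:1):1,C:2);"))
node_ages <- function(tree, tol = .ULTRA_TOL) {
  n_tip <- ape::Ntip(tree)
  depth <- ape::node.depth.edgelength(tree)
  tipd <- depth[seq_len(n_tip)]
  if ((max(tipd) - min(tipd)) > tol) {
    hi <- which.max(tipd); lo <- which.min(tipd)
    stop_f(paste0("tree is not ultrametric: root-to-tip depths differ by %g Myr ",
                  "(worst pair: '%s' at %g vs '%s' at %g)"),
           max(tipd) - min(tipd), tree$tip.label[hi], tipd[hi],
           tree$tip.label[lo], tipd[lo])
  }
  total <- max(tipd)
  age <- total - depth
  age[seq_len(n_tip)] <- 0
  parent <- integer(n_tip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- n_tip + 1L
  stem <- ifelse(seq_along(age) == root, NA_real_, age[pmax(parent, 1L)])
  data.frame(node = seq_along(age), crown_age = age, stem_age = stem)
}

#' Tip labels descending from a node
#'
#' The size of the returned set is the clade's species richness in the tree;
#' for a tip node the singleton set containing its own label.
#'
#' @param tree a `"phylo"` object.
#' @param node_id a node id (1..Ntip for tips, Ntip+1.. for internal nodes).
#' @return character vector of tip labels.
#' @export
clade_tips <- function(tree, node_id) {
  n_all <- ape::Ntip(tree) + tree$Nnode
  if (!is.numeric(node_id) || length(node_id) != 1L || node_id < 1 || node_id > n_all)
    stop_f("unknown node id %s (tree has nodes 1..%d)", format(node_id), n_all)
  node_id <- as.integer(node_id)
  if (node_id <= ape::Ntip(tree)) return(tree$tip.label[node_id])
  tree$tip.label[phangorn::Descendants(tree, node_id, type = "tips")[[1]]]
}

#' Flag structural artifacts below every node
#'
#' `in_polytomy` marks nodes whose subtree contains a multifurcation
#' (>2 children); with `scope = "crown"` only the node itself is inspected,
#' since "a clade in a polytomy" can be read either way. `has_zero_branch`
#' marks nodes with any effectively zero-length branch (<= `zero_tol`) inside
#' their subtree, the signature of near-identical sequences in supertrees.
#'
#' @param tree a `"phylo"` object.
#' @param scope `"any"` (default): any multifurcation inside the subtree;
#'   `"crown"`: only the node itself.
#' @param zero_tol branch lengths at or below this count as zero (Myr).
#' @return data.frame with columns `node`, `in_polytomy`, `has_zero_branch`
#'   (tips are always `FALSE`/`FALSE`).
#' @export
detect_artifacts <- function(tree, scope = c("any", "crown"), zero_tol = .ZERO_TOL) {
  scope <- match.arg(scope)
  n_tip <- ape::Ntip(tree)
  n_all <- n_tip + tree$Nnode
  nchild <- tabulate(tree$edge[, 1], nbins = n_all)
  multi <- nchild > 2L
  poly <- multi
  zero <- rep(FALSE, n_all)
  po <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1]; ch <- po$edge[k, 2]
    if (po$edge.length[k] <= zero_tol) zero[p] <- TRUE
    zero[p] <- zero[p] || zero[ch]
    if (scope == "any") poly[p] <- poly[p] || poly[ch]
  }
  poly[seq_len(n_tip)] <- FALSE
  zero[seq_len(n_tip)] <- FALSE
  data.frame(node = seq_len(n_all), in_polytomy = poly, has_zero_branch = zero)
}

#' Build a reduced tree with one representative tip per clade
#'
#' The representative of each clade is its lexicographically smallest tip
#' label (C-locale ordering), so the choice is deterministic; in an
#' ultrametric tree any choice yields the same pairwise path lengths, which
#' is all PGLS uses. Clades must be mutually non-nested.
#'
#' @param tree a `"phylo"` object.
#' @param clade_node_ids node ids of the clades (tips allowed: a tip
#'   represents itself).
#' @return a `"phylo"` object with one tip per clade; the attribute
#'   `"representatives"` maps clade id (as character) to its tip label.
#' @export
reduced_tree <- function(tree, clade_node_ids) {
  clade_node_ids <- as.integer(clade_node_ids)
  if (length(clade_node_ids) < 2L)
    stop_f("need at least 2 clades to build a reduced tree")
  sets <- lapply(clade_node_ids, function(id) clade_tips(tree, id))
  for (i in seq_along(sets)) {
    for (j in seq_len(i - 1L)) {
      if (length(intersect(sets[[i]], sets[[j]])))
        stop_f("clades %d and %d are nested; resolve nesting first",
               clade_node_ids[j], clade_node_ids[i])
    }
  }
  reps <- vapply(sets, function(s) sort(s, method = "radix")[1], character(1))
  out <- ape::keep.tip(tree, reps)
  names(reps) <- as.character(clade_node_ids)
  attr(out, "representatives") <- reps
  out
}

#' Randomly subsample tips from a tree
#'
#' Retains `floor(Ntip * keep_fraction)` tips chosen uniformly at random and
#' re-prunes the tree (degree-2 nodes collapsed, branch lengths summed), as
#' when emulating highly incomplete taxon sampling.
#'
#' @param tree a `"phylo"` object.
#' @param keep_fraction fraction of tips to retain, in (0, 1].
#' @param seed optional integer seed (RNG state is restored afterwards).
#' @return a `"phylo"` object.
#' @export
drop_tips_random <- function(tree, keep_fraction, seed = NULL) {
  stopifnot(is.numeric(keep_fraction), length(keep_fraction) == 1L,
            keep_fraction > 0, keep_fraction <= 1)
  n_tip <- ape::Ntip(tree)
  n_keep <- floor(n_tip * keep_fraction)
  if (n_keep >= n_tip) return(tree)
  if (n_keep < 2L)
    stop_f("keep_fraction %g leaves %d tip(s); at least 2 are required",
           keep_fraction, n_keep)
  keep <- with_seed(seed, sample(tree$tip.label, n_keep))
  ape::keep.tip(tree, keep)
}
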