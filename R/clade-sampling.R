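# Random, optionally stratified sampling of candidate clades, nesting
# resolution and the exclusion filters that produce analysis-ready records.

#' List candidate clades of a tree
#'
#' Candidates are all internal nodes except the root, in ascending node-id
#' order. Tips are excluded (a one-species clade has no crown age) and the
#' root is excluded (sampling the whole tree is degenerate). A star tree
#' therefore has no candidates.
#'
#' @param tree a `"phylo"` object.
#' @return integer vector of node ids (possibly empty).
#' @export
list_candidate_clades <- function(tree) {
  n_tip <- ape::Ntip(tree)
  if (tree$Nnode < 1L) stop_f("tree has no internal nodes")
  setdiff((n_tip + 1L):(n_tip + tree$Nnode), n_tip + 1L)
}

#' Randomly sample clades, optionally stratified
#'
#' Uniform sampling without replacement from the candidate list, or — when
#' `strata` is given — independently within each stratum (a named vector of
#' counts whose names are the node ids of the stratum roots; candidates are
#' the proper descendants of each stratum root). Stratified counts are taken
#' exactly as given; they are not re-normalised.
#'
#' @param tree a `"phylo"` object.
#' @param m number of clades to draw (ignored when `strata` is given).
#' @param seed optional integer seed.
#' @param strata optional named numeric vector: `c("<node id>" = count, ...)`.
#' @param candidates optional explicit candidate pool (node ids) replacing
#'   [list_candidate_clades()]; used e.g. to sample only the planted clades
#'   of a simulated forest.
#' @return integer vector of sampled node ids.
#' @export
sample_clades <- function(tree, m, seed = NULL, strata = NULL, candidates = NULL) {
  cand <- as.integer(candidates %||% list_candidate_clades(tree))
  with_seed(seed, {
    if (is.null(strata)) {
      if (m > length(cand))
        stop_f("requested %d clades but only %d candidates exist", m, length(cand))
      if (m == length(cand)) return(cand)
      return(sample(cand, m))
    }
    roots <- as.integer(names(strata))
    out <- integer(0)
    for (k in seq_along(roots)) {
      below <- intersect(cand, phangorn::Descendants(tree, roots[k], type = "all"))
      if (strata[k] > length(below))
        stop_f("stratum at node %d has %d candidate clades, fewer than the %d requested",
               roots[k], length(below), strata[k])
      out <- c(out, if (strata[k] == length(below)) below else sample(below, strata[k]))
    }
    out
  })
}

#' Exclude the younger clade of every nested pair
#'
#' Two sampled clades of the same tree are either disjoint or nested. For
#' every nested pair the clade with the smaller crown age is excluded (ties
#' broken by excluding the larger node id), applied transitively until no
#' nesting remains, so of a nested chain only the oldest clade survives.
#'
#' @param tree a `"phylo"` object.
#' @param clade_ids node ids of sampled clades.
#' @return list with integer vectors `retained` and `excluded`.
#' @export
resolve_nesting <- function(tree, clade_ids) {
  clade_ids <- as.integer(clade_ids)
  if (!length(clade_ids)) return(list(retained = integer(0), excluded = integer(0)))
  ages <- node_ages(tree)
  crown <- ages$crown_age[clade_ids]
  tipsets <- lapply(clade_ids, function(id)
    if (id <= ape::Ntip(tree)) id else phangorn::Descendants(tree, id, type = "tips")[[1]])
  ord <- order(-crown, clade_ids)   # oldest first; ties: smaller id wins
  kept <- integer(0)
  kept_tips <- integer(0)
  excluded <- integer(0)
  for (k in ord) {
    if (length(intersect(tipsets[[k]], kept_tips))) {
      excluded <- c(excluded, clade_ids[k])
    } else {
      kept <- c(kept, clade_ids[k])
      kept_tips <- c(kept_tips, tipsets[[k]])
    }
  }
  list(retained = sort(kept), excluded = sort(excluded))
}

#' Build clade records for a set of clades
#'
#' One row per clade: crown and stem ages, species richness in the tree, and
#' structural-artifact flags from [detect_artifacts()].
#'
#' @param tree an ultrametric `"phylo"` object.
#' @param clade_ids internal node ids.
#' @param polytomy_scope passed to [detect_artifacts()].
#' @return data.frame with columns `node_id`, `crown_age`, `stem_age`,
#'   `n_tips`, `in_polytomy`, `has_zero_branch`.
#' @export
clade_records <- function(tree, clade_ids, polytomy_scope = "any") {
  clade_ids <- as.integer(clade_ids)
  if (any(clade_ids <= ape::Ntip(tree)))
    stop_f("clade records require internal nodes; got tip id %d",
           clade_ids[which(clade_ids <= ape::Ntip(tree))[1]])
  ages <- node_ages(tree)
  art <- detect_artifacts(tree, scope = polytomy_scope)
  n <- vapply(phangorn::Descendants(tree, clade_ids, type = "tips"),
              length, integer(1))
  data.frame(node_id = clade_ids,
             crown_age = ages$crown_age[clade_ids],
             stem_age = ages$stem_age[clade_ids],
             n_tips = n,
             in_polytomy = art$in_polytomy[clade_ids],
             has_zero_branch = art$has_zero_branch[clade_ids])
}

#' Apply the exclusion filters to rate-filled clade records
#'
#' Drops, in this order of recorded reason, clades with an effectively zero
#' crown age, clades in polytomies, and clades with extreme diversification
#' rates (above `max_rate`, default 1 species/Myr). Setting `max_rate = Inf`
#' and both flags to `FALSE` reproduces an "all clades included" sensitivity
#' run. Retained + excluded always partition the input.
#'
#' @param records data.frame from [fill_rates()].
#' @param max_rate maximum admissible diversification rate, species/Myr.
#' @param exclude_polytomy drop clades flagged `in_polytomy`?
#' @param exclude_zero_crown drop clades with zero crown age?
#' @return list with data.frames `retained` and `excluded` (the latter with
#'   a `reason` column: `"zero_crown"`, `"polytomy"` or `"rate"`).
#' @export
apply_filters <- function(records, max_rate = 1.0, exclude_polytomy = TRUE,
                          exclude_zero_crown = TRUE) {
  reason <- rep(NA_character_, nrow(records))
  if (exclude_zero_crown)
    reason[is.na(reason) & records$zero_crown] <- "zero_crown"
  if (exclude_polytomy)
    reason[is.na(reason) & records$in_polytomy] <- "polytomy"
  reason[is.na(reason) & !is.na(records$rate) & records$rate > max_rate] <- "rate"
  excluded <- records[!is.na(reason), , drop = FALSE]
  excluded$reason <- reason[!is.na(reason)]
  list(retained = records[is.na(reason), , drop = FALSE], excluded = excluded)
}
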