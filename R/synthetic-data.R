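# Constant-rate birth-death simulation of clade forests with known truth.
#
# The generator exists so the sampling, estimation and regression stages can
# be exercised end to end with fully known clade ages and rates: a single
# ultrametric "forest" tree carries many monophyletic clades, each grown by a
# forward-time constant-rate birth-death process with its own speciation and
# extinction rates, hung from a deep backbone whose joins lie below every
# clade's stem.

# one forward-time Gillespie attempt from 2 crown lineages; returns NULL when
# either side of the crown split leaves no extant descendant
.bd_attempt <- function(lambda, mu, total_time, max_tips) {
  cap <- 256L
  parent <- integer(cap); t_start <- numeric(cap); t_end <- numeric(cap)
  spec <- logical(cap); ext <- logical(cap); side <- integer(cap)
  grow <- function(need) {
    old <- cap
    while (need > cap) cap <<- cap * 2L
    add <- cap - old
    parent <- c(parent, integer(add)); parent <<- parent
    t_start <- c(t_start, numeric(add)); t_start <<- t_start
    t_end <- c(t_end, numeric(add)); t_end <<- t_end
    spec <- c(spec, logical(add)); spec <<- spec
    ext <- c(ext, logical(add)); ext <<- ext
    side <- c(side, integer(add)); side <<- side
  }
  parent[1:2] <- 0L; t_start[1:2] <- 0; side[1:2] <- 1:2
  nxt <- 3L
  alive <- c(1L, 2L)
  n_alive <- 2L
  t <- 0
  rate_total <- lambda + mu
  p_birth <- lambda / rate_total
  repeat {
    t <- t + stats::rexp(1L, rate_total * n_alive)
    if (t >= total_time) break
    i <- sample.int(n_alive, 1L)
    id <- alive[i]
    t_end[id] <- t
    if (stats::runif(1L) < p_birth) {
      if (nxt + 1L > cap) grow(nxt + 1L)
      c1 <- nxt; c2 <- nxt + 1L; nxt <- nxt + 2L
      parent[c(c1, c2)] <- id; t_start[c(c1, c2)] <- t; side[c(c1, c2)] <- side[id]
      spec[id] <- TRUE
      alive[i] <- c1
      n_alive <- n_alive + 1L
      alive[n_alive] <- c2
      if (n_alive > max_tips)
        stop_f("birth-death simulation exceeded %d extant lineages; rates too high for this crown age", max_tips)
    } else {
      ext[id] <- TRUE
      alive[i] <- alive[n_alive]
      n_alive <- n_alive - 1L
      if (n_alive == 0L) return(NULL)
    }
  }
  surv <- alive[seq_len(n_alive)]
  if (!any(side[surv] == 1L) || !any(side[surv] == 2L)) return(NULL)
  t_end[surv] <- total_time
  n_lin <- nxt - 1L
  list(parent = parent[seq_len(n_lin)], t_start = t_start[seq_len(n_lin)],
       t_end = t_end[seq_len(n_lin)], spec = spec[seq_len(n_lin)],
       ext = ext[seq_len(n_lin)])
}

# assemble an ape phylo from a lineage table; each lineage is one edge
.bd_to_phylo <- function(sim) {
  is_tip <- !sim$spec
  n_tip <- sum(is_tip)
  tipno <- integer(length(is_tip)); tipno[is_tip] <- seq_len(n_tip)
  intno <- integer(length(is_tip)); intno[sim$spec] <- n_tip + 1L + seq_len(sum(sim$spec))
  nodemap <- ifelse(is_tip, tipno, intno)
  parent_node <- ifelse(sim$parent == 0L, n_tip + 1L, nodemap[pmax(sim$parent, 1L)])
  tree <- list(edge = cbind(parent_node, nodemap, deparse.level = 0),
               edge.length = sim$t_end - sim$t_start,
               tip.label = paste0("t", seq_len(n_tip)),
               Nnode = 1L + sum(sim$spec))
  class(tree) <- "phylo"
  extinct_tips <- tipno[is_tip & sim$ext]
  if (length(extinct_tips)) tree <- ape::drop.tip(tree, extinct_tips)
  tree$tip.label <- paste0("t", seq_len(ape::Ntip(tree)))
  ape::reorder.phylo(tree, "cladewise")
}

#' Simulate one constant-rate birth-death clade
#'
#' Forward-time simulation started from two lineages at the crown and run for
#' `crown_age` Myr, conditioned by rejection on both crown lineages leaving
#' extant descendants (hence >= 2 extant tips and tree depth exactly equal to
#' `crown_age`). Extinct lineages are pruned.
#'
#' @param lambda speciation rate, /Myr (> `mu`).
#' @param mu extinction rate, /Myr (>= 0).
#' @param crown_age crown age in Myr (> 0).
#' @param seed optional integer seed.
#' @param max_rejections abort after this many failed attempts, which signals
#'   parameters under which the crown survives with negligible probability.
#' @param max_tips hard cap on extant lineages, guarding against explosive
#'   parameter choices.
#' @return an ultrametric `"phylo"` object with tips `t1, t2, ...`.
#' @export
#' @examples
#' tr <- simulate_bd_clade(0.2, 0.05, 15, seed = 1)
#' is_ultrametric(tr)
simulate_bd_clade <- function(lambda, mu, crown_age, seed = NULL,
                              max_rejections = 1e5, max_tips = 1e5) {
  stopifnot(lambda > mu, mu >= 0, crown_age > 0)
  with_seed(seed, {
    for (k in seq_len(max_rejections)) {
      sim <- .bd_attempt(lambda, mu, crown_age, max_tips)
      if (!is.null(sim)) return(.bd_to_phylo(sim))
    }
    stop_f(paste0("no surviving crown after %d attempts; lambda=%g, mu=%g imply ",
                  "near-certain extinction over %g Myr"),
           max_rejections, lambda, mu, crown_age)
  })
}

#' Configuration for the synthetic clade-forest generator
#'
#' Per-clade speciation rates are drawn from a lognormal distribution with
#' the given median; extinction is `epsilon_true * lambda` for every clade.
#' Stem ages are uniform on `stem_age_range` and each crown age is a uniform
#' fraction (`crown_fraction_range`) of its stem age. Two presets encode the
#' contrasting regimes of interest:
#' \describe{
#'   \item{`"age_driven"`}{near-shared rates, widely dispersed ages: richness
#'     differences among clades are driven by time.}
#'   \item{`"rate_driven"`}{narrow ages, widely dispersed rates: richness
#'     differences are driven by diversification rate.}
#' }
#'
#' @param n_clades number of planted clades (>= 2).
#' @param stem_age_range ordered positive bounds (Myr) for uniform stem ages.
#' @param lambda_median median speciation rate, species/Myr.
#' @param lambda_sdlog lognormal sdlog of speciation rates across clades.
#' @param epsilon_true generating extinction fraction mu/lambda in [0, 1).
#' @param scenario_preset optional `"age_driven"` or `"rate_driven"`;
#'   overrides `stem_age_range`, `lambda_median` and `lambda_sdlog` unless
#'   those are supplied explicitly.
#' @param polytomy_fraction fraction of internal nodes collapsed into their
#'   parent, in [0, 1].
#' @param zero_branch_fraction fraction of cherries whose tip branches are
#'   set to zero length, in [0, 1].
#' @param sampling_fraction fraction of tips retained, in (0, 1].
#' @param crown_fraction_range uniform bounds for crown age / stem age.
#' @param seed integer master seed; per-clade seeds are derived with
#'   [split_seed()] so clade simulations are order-independent.
#' @return a list of class `"scenario_config"`.
#' @export
scenario_config <- function(n_clades = 50,
                            stem_age_range = c(2, 60),
                            lambda_median = 0.1,
                            lambda_sdlog = 0.05,
                            epsilon_true = 0,
                            scenario_preset = NULL,
                            polytomy_fraction = 0,
                            zero_branch_fraction = 0,
                            sampling_fraction = 1,
                            crown_fraction_range = c(0.5, 0.95),
                            seed = 1) {
  if (!is.null(scenario_preset)) {
    scenario_preset <- match.arg(scenario_preset, c("age_driven", "rate_driven"))
    preset <- switch(scenario_preset,
      age_driven  = list(stem_age_range = c(2, 60), lambda_median = 0.1,
                         lambda_sdlog = 0.05),
      rate_driven = list(stem_age_range = c(8, 12), lambda_median = 0.15,
                         lambda_sdlog = 0.5))
    if (missing(stem_age_range)) stem_age_range <- preset$stem_age_range
    if (missing(lambda_median))  lambda_median  <- preset$lambda_median
    if (missing(lambda_sdlog))   lambda_sdlog   <- preset$lambda_sdlog
  }
  stopifnot(n_clades >= 2,
            length(stem_age_range) == 2, all(stem_age_range > 0),
            stem_age_range[1] <= stem_age_range[2],
            lambda_median > 0, lambda_sdlog >= 0,
            epsilon_true >= 0, epsilon_true < 1,
            polytomy_fraction >= 0, polytomy_fraction <= 1,
            zero_branch_fraction >= 0, zero_branch_fraction <= 1,
            sampling_fraction > 0, sampling_fraction <= 1,
            length(crown_fraction_range) == 2,
            all(crown_fraction_range > 0), all(crown_fraction_range < 1))
  structure(list(n_clades = as.integer(n_clades),
                 stem_age_range = stem_age_range,
                 lambda_median = lambda_median,
                 lambda_sdlog = lambda_sdlog,
                 epsilon_true = epsilon_true,
                 scenario_preset = scenario_preset,
                 polytomy_fraction = polytomy_fraction,
                 zero_branch_fraction = zero_branch_fraction,
                 sampling_fraction = sampling_fraction,
                 crown_fraction_range = crown_fraction_range,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' Simulate an ultrametric clade forest with known truth
#'
#' Builds a single rooted ultrametric tree: `n_clades` monophyletic
#' birth-death clades (tips labelled `c001_t1`, `c001_t2`, ...) hang from a
#' pectinate backbone whose joins all lie deeper than the oldest stem age,
#' at fixed intervals of 5% of that age (the backbone's shape only has to
#' keep clades non-overlapping; the analyses see clade path structure only).
#' Structural artifacts and incomplete sampling are then injected per the
#' configuration.
#'
#' @param config a [scenario_config()] object.
#' @return an object of class `"clade_forest"`: a list with `tree` (phylo),
#'   `truth` (data.frame: `clade`, `lambda`, `mu`, `r_true`, `stem_age` drawn,
#'   `attach_depth` realized parent depth, `crown_age`, `n_tips`, `node`) and
#'   `config`. `node` is `NA` for clades whose tips were all removed by
#'   artifact injection.
#' @export
simulate_clade_forest <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  n <- config$n_clades
  lab <- sprintf("c%03d", seq_len(n))
  stem <- numeric(n); crown <- numeric(n); lambda <- numeric(n)
  subtrees <- vector("list", n)
  for (i in seq_len(n)) {
    with_seed(split_seed(config$seed, i), {
      stem[i] <- stats::runif(1, config$stem_age_range[1], config$stem_age_range[2])
      crown[i] <- stem[i] * stats::runif(1, config$crown_fraction_range[1],
                                         config$crown_fraction_range[2])
      lambda[i] <- stats::rlnorm(1, meanlog = log(config$lambda_median),
                                 sdlog = config$lambda_sdlog)
      tr <- simulate_bd_clade(lambda[i], config$epsilon_true * lambda[i], crown[i])
      tr$tip.label <- paste0(lab[i], "_", tr$tip.label)
      subtrees[[i]] <- tr
    })
  }
  mu <- config$epsilon_true * lambda
  # pectinate backbone: join k (k = 1 deepest) at depth s_max * (1 + 0.05 * (n - k))
  s_max <- max(stem)
  joins <- s_max * (1 + 0.05 * (n - seq_len(n - 1)))
  sub_nwk <- vapply(subtrees, function(tr) sub(";$", "", write_newick(tr, digits = 12)),
                    character(1))
  fmt <- function(x) sprintf("%.12g", x)
  attach_depth <- c(joins, joins[n - 1])
  cur <- sprintf("(%s:%s,%s:%s)", sub_nwk[n - 1], fmt(joins[n - 1] - crown[n - 1]),
                 sub_nwk[n], fmt(joins[n - 1] - crown[n]))
  for (k in rev(seq_len(n - 2))) {
    cur <- sprintf("(%s:%s,%s:%s)", sub_nwk[k], fmt(joins[k] - crown[k]),
                   cur, fmt(joins[k] - joins[k + 1]))
  }
  tree <- parse_newick(paste0(cur, ";"))
  tree <- inject_artifacts(tree,
                           polytomy_fraction = config$polytomy_fraction,
                           zero_branch_fraction = config$zero_branch_fraction,
                           sampling_fraction = config$sampling_fraction,
                           seed = split_seed(config$seed, 0L))
  nodes <- marked_clade_nodes(tree)
  n_tips <- vapply(lab, function(l)
    sum(startsWith(tree$tip.label, paste0(l, "_"))), integer(1))
  truth <- data.frame(clade = lab, lambda = lambda, mu = mu,
                      r_true = lambda * (1 - config$epsilon_true),
                      stem_age = stem, attach_depth = attach_depth,
                      crown_age = crown, n_tips = n_tips,
                      node = unname(nodes[lab]))
  structure(list(tree = tree, truth = truth, config = config),
            class = "clade_forest")
}

#' Locate the planted clades of a forest tree
#'
#' Tips of a simulated forest are labelled `<clade>_<tip>`; this recovers,
#' for every clade prefix with at least two surviving tips, the node id of
#' its most recent common ancestor in the (possibly pruned) tree.
#'
#' @param tree a forest `"phylo"` object.
#' @return named integer vector, clade prefix -> node id; prefixes with
#'   fewer than 2 surviving tips map to `NA`.
#' @export
marked_clade_nodes <- function(tree) {
  pref <- sub("_.*$", "", tree$tip.label)
  out <- vapply(sort(unique(pref)), function(p) {
    idx <- which(pref == p)
    if (length(idx) < 2L) return(NA_integer_)
    as.integer(ape::getMRCA(tree, idx))
  }, integer(1))
  out
}

#' Inject structural artifacts into an ultrametric tree
#'
#' Emulates the defects of empirical supertrees while conserving total tree
#' depth: a fraction of internal non-root nodes are collapsed into their
#' parent (their subtending branch is set to zero, its length pushed onto
#' their children, then zero-length edges are merged into polytomies with
#' [ape::di2multi()]); a fraction of cherries have both tip branches set to
#' zero length (the removed length donated to the cherry's stem edge), the
#' signature of species with near-identical sequences; and tips are randomly
#' subsampled to the given sampling fraction.
#'
#' @param tree a `"phylo"` object.
#' @param polytomy_fraction fraction of internal non-root nodes collapsed.
#' @param zero_branch_fraction fraction of cherries zeroed.
#' @param sampling_fraction fraction of tips retained.
#' @param seed optional integer seed.
#' @return a `"phylo"` object with an `"artifact_log"` attribute listing
#'   `collapsed_nodes` (pre-collapse node ids) and `zeroed_cherry_tips`
#'   (tip labels of zeroed cherries).
#' @export
inject_artifacts <- function(tree, polytomy_fraction = 0,
                             zero_branch_fraction = 0,
                             sampling_fraction = 1, seed = NULL) {
  stopifnot(polytomy_fraction >= 0, polytomy_fraction <= 1,
            zero_branch_fraction >= 0, zero_branch_fraction <= 1,
            sampling_fraction > 0, sampling_fraction <= 1)
  log <- list(collapsed_nodes = integer(0), zeroed_cherry_tips = character(0))
  with_seed(seed, {
    n_tip <- ape::Ntip(tree)
    if (polytomy_fraction > 0 && tree$Nnode > 1L) {
      cand <- (n_tip + 2L):(n_tip + tree$Nnode)
      n_pick <- round(polytomy_fraction * length(cand))
      if (n_pick > 0) {
        pick <- if (n_pick == length(cand)) cand else sample(cand, n_pick)
        depth <- ape::node.depth.edgelength(tree)
        for (v in pick[order(depth[pick])]) {    # top-down so chains collapse fully
          e_v <- which(tree$edge[, 2] == v)
          L <- tree$edge.length[e_v]
          ch <- which(tree$edge[, 1] == v)
          tree$edge.length[ch] <- tree$edge.length[ch] + L
          tree$edge.length[e_v] <- 0
        }
        tree <- ape::di2multi(tree, tol = 1e-8)
        log$collapsed_nodes <- sort(pick)
        n_tip <- ape::Ntip(tree)
      }
    }
    if (zero_branch_fraction > 0) {
      is_tip_child <- tree$edge[, 2] <= n_tip
      kids_all_tips <- tapply(is_tip_child, tree$edge[, 1], all)
      nkids <- tabulate(tree$edge[, 1], nbins = n_tip + tree$Nnode)
      cherries <- as.integer(names(kids_all_tips))[kids_all_tips]
      cherries <- cherries[nkids[cherries] == 2L & cherries != n_tip + 1L]
      n_pick <- round(zero_branch_fraction * length(cherries))
      if (n_pick > 0) {
        pick <- if (n_pick == length(cherries)) cherries else sample(cherries, n_pick)
        for (v in pick) {
          kid_e <- which(tree$edge[, 1] == v)
          L <- max(tree$edge.length[kid_e])
          tree$edge.length[kid_e] <- 0
          e_v <- which(tree$edge[, 2] == v)
          tree$edge.length[e_v] <- tree$edge.length[e_v] + L
          log$zeroed_cherry_tips <- c(log$zeroed_cherry_tips,
                                      tree$tip.label[tree$edge[kid_e, 2]])
        }
      }
    }
    if (sampling_fraction < 1) tree <- drop_tips_random(tree, sampling_fraction)
  })
  attr(tree, "artifact_log") <- log
  tree
}
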