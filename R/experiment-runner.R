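# Orchestration of the replicated clade-set analyses: sample clades, resolve
# nesting, compute ages/richness/rates, filter, build the reduced tree and
# fit the four regressions, repeated over independently seeded replicates,
# plus the incomplete-sampling and described-richness experiments.

.MODELS <- list(
  richness_vs_age      = log_richness ~ age,
  richness_vs_rate     = log_richness ~ rate,
  rate_vs_age          = rate ~ age,
  richness_vs_age_rate = log_richness ~ age + rate
)

#' Configuration of a replicated clade-sampling run
#'
#' Defaults reproduce the headline design: 50 randomly selected clades per
#' replicate, 10 replicates, crown ages, the crown method-of-moments
#' estimator at epsilon = 0.5, PGLS with ML Pagel's lambda, and the standard
#' exclusion filters (rate > 1 species/Myr, polytomies, zero crown ages).
#'
#' @param m_clades clades sampled per replicate.
#' @param n_replicates number of independent replicates.
#' @param epsilon relative extinction fraction for the rate estimator.
#' @param age_basis `"crown"` or `"stem"`.
#' @param engine `"pgls"` or `"ols"`.
#' @param max_rate rate filter threshold, species/Myr (`Inf` disables).
#' @param exclude_polytomy,exclude_zero_crown filter switches.
#' @param strata optional named vector of per-stratum counts (see
#'   [sample_clades()]); overrides `m_clades`.
#' @param candidates optional explicit candidate pool of node ids.
#' @param seed integer master seed; replicate i uses `split_seed(seed, i)`.
#' @return a list of class `"run_config"`.
#' @export
run_config <- function(m_clades = 50, n_replicates = 10, epsilon = 0.5,
                       age_basis = c("crown", "stem"),
                       engine = c("pgls", "ols"), max_rate = 1.0,
                       exclude_polytomy = TRUE, exclude_zero_crown = TRUE,
                       strata = NULL, candidates = NULL, seed = 1) {
  structure(list(m_clades = as.integer(m_clades),
                 n_replicates = as.integer(n_replicates),
                 epsilon = epsilon, age_basis = match.arg(age_basis),
                 engine = match.arg(engine), max_rate = max_rate,
                 exclude_polytomy = exclude_polytomy,
                 exclude_zero_crown = exclude_zero_crown,
                 strata = strata, candidates = candidates,
                 seed = as.integer(seed)),
            class = "run_config")
}

.fit_models <- function(df, tree, engine) {
  lapply(.MODELS, function(fm) {
    tryCatch({
      if (engine == "pgls") pgls_fit(fm, df, tree) else ols_fit(fm, df)
    }, error = function(e) e)
  })
}

#' Run replicated clade-set regressions
#'
#' For each replicate: sample clades, exclude nested ones, compute ages,
#' richness and diversification rates, apply the exclusion filters (without
#' re-drawing replacements, so replicate sizes vary), build the reduced
#' one-tip-per-clade tree and fit the four relationships
#' (log10 richness ~ age, log10 richness ~ rate, rate ~ age, and the
#' multiple regression log10 richness ~ age + rate). Replicates retaining
#' fewer than 4 clades are skipped with a warning and excluded from the
#' summary means. Fully reproducible from the config seed.
#'
#' @param tree an ultrametric `"phylo"` object.
#' @param config a [run_config()] object.
#' @return an object of class `"clade_experiment"`: list with `replicates`
#'   (one row per replicate x model: `r2`, `adj_r2`, `p`, `lambda`, slope,
#'   `n_clades`), `summary` (see [summarize_replicates()]), `details`
#'   (per-replicate records and exclusion logs) and `config`.
#' @export
run_replicates <- function(tree, config) {
  stopifnot(inherits(config, "run_config"))
  rows <- list(); details <- list()
  for (i in seq_len(config$n_replicates)) {
    seed_i <- split_seed(config$seed, i)
    ids <- sample_clades(tree, m = config$m_clades, seed = seed_i,
                         strata = config$strata, candidates = config$candidates)
    nest <- resolve_nesting(tree, ids)
    recs <- clade_records(tree, nest$retained)
    recs <- fill_rates(recs, age_basis = config$age_basis,
                       epsilon = config$epsilon)
    filt <- apply_filters(recs, max_rate = config$max_rate,
                          exclude_polytomy = config$exclude_polytomy,
                          exclude_zero_crown = config$exclude_zero_crown)
    ret <- filt$retained
    details[[i]] <- list(sampled = ids, nested_out = nest$excluded,
                         retained = ret, excluded = filt$excluded)
    if (nrow(ret) < 4L) {
      warning(sprintf("replicate %d retained %d clade(s) (< 4); skipped",
                      i, nrow(ret)), call. = FALSE)
      next
    }
    rtree <- reduced_tree(tree, ret$node_id)
    reps_map <- attr(rtree, "representatives")[as.character(ret$node_id)]
    df <- data.frame(log_richness = log10(ret$n_tips),
                     age = if (config$age_basis == "crown") ret$crown_age
                           else ret$stem_age,
                     rate = ret$rate, row.names = reps_map)
    fits <- .fit_models(df, rtree, config$engine)
    for (mod in names(fits)) {
      f <- fits[[mod]]
      if (inherits(f, "error")) {
        warning(sprintf("replicate %d, model %s failed: %s", i, mod,
                        conditionMessage(f)), call. = FALSE)
        next
      }
      slope <- f$coefficients$estimate[match("age", f$coefficients$term)]
      if (is.na(slope))
        slope <- f$coefficients$estimate[match("rate", f$coefficients$term)]
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = i, model = mod, r2 = f$r_squared, adj_r2 = f$adj_r_squared,
        p = f$p_value, lambda = f$lambda, slope = slope, n_clades = nrow(ret))
    }
  }
  replicates <- if (length(rows)) do.call(rbind, rows) else
    data.frame(replicate = integer(0), model = character(0), r2 = numeric(0),
               adj_r2 = numeric(0), p = numeric(0), lambda = numeric(0),
               slope = numeric(0), n_clades = integer(0))
  structure(list(replicates = replicates,
                 summary = summarize_replicates(replicates),
                 details = details, config = config),
            class = "clade_experiment")
}

#' Summarize replicate regressions per relationship
#'
#' Means are taken over completed replicates only; `pct_significant` is the
#' percentage of completed replicates with model p < 0.05; `n_clades_total`
#' sums retained clades over the completed replicates (mirroring the
#' "n of 500" accounting of a 10 x 50 design).
#'
#' @param replicates the per-replicate table from [run_replicates()].
#' @return data.frame with one row per model: `mean_r2`, `mean_adj_r2`,
#'   `mean_p`, `pct_significant`, `n_replicates`, `n_clades_total`.
#' @export
summarize_replicates <- function(replicates) {
  do.call(rbind, lapply(names(.MODELS), function(mod) {
    d <- replicates[replicates$model == mod, , drop = FALSE]
    if (!nrow(d))
      return(data.frame(model = mod, mean_r2 = NA_real_, mean_adj_r2 = NA_real_,
                        mean_p = NA_real_, pct_significant = NA_real_,
                        n_replicates = 0L, n_clades_total = 0L))
    data.frame(model = mod, mean_r2 = mean(d$r2), mean_adj_r2 = mean(d$adj_r2),
               mean_p = mean(d$p), pct_significant = 100 * mean(d$p < 0.05),
               n_replicates = nrow(d), n_clades_total = sum(d$n_clades))
  }))
}

#' Incomplete-sampling experiment: full versus subsampled tree
#'
#' Runs the identical replicate machinery on the full tree and on a randomly
#' subsampled copy retaining `keep_fraction` of the tips (independent seeds
#' derived from the config seed), to test whether the relative support for
#' the clade-age and diversification-rate hypotheses survives highly
#' incomplete taxon sampling.
#'
#' @param tree an ultrametric `"phylo"` object.
#' @param keep_fraction fraction of tips kept in the reduced tree.
#' @param config a [run_config()] object. An explicit `candidates` pool is
#'   dropped for the reduced tree (node ids do not carry over); the planted
#'   clades of a forest are relocated via [marked_clade_nodes()] when the
#'   tree's tips follow the forest labelling.
#' @return list with elements `full` and `reduced` (each a
#'   `"clade_experiment"`), `paired` (per-model r2 side by side) and
#'   `keep_fraction`.
#' @export
subsampling_experiment <- function(tree, keep_fraction = 0.1, config) {
  stopifnot(inherits(config, "run_config"))
  full <- run_replicates(tree, config)
  sub <- drop_tips_random(tree, keep_fraction, seed = split_seed(config$seed, 10007L))
  cfg2 <- config
  cfg2$seed <- split_seed(config$seed, 20011L)
  if (!is.null(config$candidates)) {
    marked <- marked_clade_nodes(sub)
    cfg2$candidates <- unname(marked[!is.na(marked)])
  }
  n_cand <- length(cfg2$candidates %||% list_candidate_clades(sub))
  need <- if (is.null(cfg2$strata)) cfg2$m_clades else sum(cfg2$strata)
  if (n_cand < need)
    stop_f("reduced tree has only %d candidate clades; use m_clades <= %d",
           n_cand, n_cand)
  reduced <- run_replicates(sub, cfg2)
  paired <- merge(full$summary[, c("model", "mean_r2", "pct_significant")],
                  reduced$summary[, c("model", "mean_r2", "pct_significant")],
                  by = "model", suffixes = c("_full", "_reduced"))
  list(full = full, reduced = reduced, paired = paired,
       keep_fraction = keep_fraction)
}

#' Substitute described species richness into clade records
#'
#' Replaces each clade's in-tree richness by described richness summed over
#' the sampled taxa at the appropriate rank: a clade spanning two or more
#' taxa at some rank (genus, family, ...) gets the summed described counts
#' of its sampled taxa at the *highest* rank where it spans at least two;
#' a clade confined to a single genus keeps its sampled tip count (unsampled
#' species cannot be assigned below genus level). Diversification rates are
#' recomputed from the adjusted richness.
#'
#' @param tree the source `"phylo"` object.
#' @param records clade records (need `node_id`, ages).
#' @param richness_table data.frame with columns `taxon`, `n_described`.
#' @param taxonomy data.frame with column `tip` plus one column per rank.
#' @param ranks rank column names ordered from lowest (genus) upward.
#' @param age_basis,epsilon passed to the rate estimator.
#' @return `records` with `n_described` and recomputed `rate` columns.
#' @export
described_richness_merge <- function(tree, records, richness_table, taxonomy,
                                     ranks = c("genus", "family", "order"),
                                     age_basis = "crown", epsilon = 0.5) {
  stopifnot(all(c("taxon", "n_described") %in% names(richness_table)),
            "tip" %in% names(taxonomy), all(ranks %in% names(taxonomy)))
  miss_tip <- setdiff(tree$tip.label, taxonomy$tip)
  adj <- integer(nrow(records))
  for (k in seq_len(nrow(records))) {
    tips <- clade_tips(tree, records$node_id[k])
    if (length(setdiff(tips, taxonomy$tip)))
      stop_f("taxonomy is missing tip(s): %s",
             paste(setdiff(tips, taxonomy$tip), collapse = ", "))
    tax <- taxonomy[match(tips, taxonomy$tip), , drop = FALSE]
    use_rank <- NA_character_
    for (r in rev(ranks)) if (length(unique(tax[[r]])) >= 2L) { use_rank <- r; break }
    if (is.na(use_rank)) {
      adj[k] <- length(tips)
    } else {
      taxa <- unique(tax[[use_rank]])
      missing <- setdiff(taxa, richness_table$taxon)
      if (length(missing))
        stop_f("described-richness table is missing taxa: %s",
               paste(missing, collapse = ", "))
      adj[k] <- sum(richness_table$n_described[match(taxa, richness_table$taxon)])
    }
  }
  records$n_described <- adj
  age <- if (age_basis == "crown") records$crown_age else records$stem_age
  ok <- age > .ZERO_TOL
  records$rate <- NA_real_
  if (any(ok)) {
    records$rate[ok] <- if (age_basis == "crown")
      ms_crown_rate(adj[ok], age[ok], epsilon)
    else ms_stem_rate(adj[ok], age[ok], epsilon)
  }
  records
}

#' Paired comparison of two sets of r-squared values
#'
#' Two-sided paired (or two-sample) t-test on r2 differences, with an
#' explicit degenerate branch: when the differences have (near-)zero
#' variance the t statistic is undefined and p = 1 is returned with a flag.
#'
#' @param set_a,set_b numeric vectors of r2 values (equal length, >= 3).
#' @param paired logical.
#' @return list with `statistic`, `df`, `p_value`, `mean_diff`, `degenerate`.
#' @export
compare_r2_sets <- function(set_a, set_b, paired = TRUE) {
  stopifnot(length(set_a) == length(set_b), length(set_a) >= 3)
  if (paired) {
    d <- set_a - set_b
    if (stats::sd(d) < 1e-12) {
      warning("zero variance of paired differences; t undefined, p set to 1",
              call. = FALSE)
      return(list(statistic = NA_real_, df = length(d) - 1L, p_value = 1,
                  mean_diff = mean(d), degenerate = TRUE))
    }
    tt <- stats::t.test(set_a, set_b, paired = TRUE)
  } else {
    if (stats::sd(set_a) < 1e-12 && stats::sd(set_b) < 1e-12) {
      warning("zero variance in both sets; t undefined, p set to 1",
              call. = FALSE)
      return(list(statistic = NA_real_, df = NA_real_, p_value = 1,
                  mean_diff = mean(set_a) - mean(set_b), degenerate = TRUE))
    }
    tt <- stats::t.test(set_a, set_b, paired = FALSE)
  }
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_diff = unname(mean(set_a) - mean(set_b)),
       degenerate = FALSE)
}
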