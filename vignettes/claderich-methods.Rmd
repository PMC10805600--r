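---
title: "Clade age, diversification rate, and richness: the claderich methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clade age, diversification rate, and richness: the claderich methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(claderich)
```

## The question

Why do some clades hold vastly more species than others? Two non-exclusive
hypotheses compete. Under the *clade-age hypothesis*, older clades are richer
simply because they have had more time to accumulate species. Under the
*diversification-rate hypothesis*, richer clades diversify faster — their net
rate of speciation minus extinction is higher — regardless of age. Studies
that compare named taxa of a fixed rank (family with family, order with
order) constrain the spread of clade ages and can therefore be biased against
the clade-age hypothesis. claderich implements the alternative design:
sample clades *uniformly at random* from the internal nodes of a
time-calibrated, ultrametric, species-level phylogeny, so sampled clades span
the full range of ages the tree offers (in practice mostly young ones, since
extant-species trees contain far more shallow nodes than deep ones).

The unit of analysis is a clade record: crown age \(t\) (depth of the clade's
root node, Myr), stem age (depth of its parent node), richness \(n\) (tips in
the tree), and an estimated net diversification rate \(\hat r\)
(species/Myr). The three pairwise relationships — \(\log_{10} n\) versus
\(t\), \(\log_{10} n\) versus \(\hat r\), and \(\hat r\) versus \(t\) — plus
the multiple regression \(\log_{10} n \sim t + \hat r\) are fitted by
phylogenetic generalized least squares (PGLS) on each of several replicate
clade sets, and summarised as mean \(r^2\), mean \(p\), and the percentage of
replicates significant at \(p < 0.05\).

## Sampling and exclusion rules

Candidate clades are all internal nodes except the root (tips have no crown
age). Each replicate draws `m_clades` (default 50) candidates uniformly
without replacement; drawing is optionally stratified by subtree with exact
per-stratum counts (e.g. 45/4/1 across three domains of a tree of life).
Replication (default 10 sets) guards against the particular selection of
clades driving the result.

Three exclusion rules are applied after sampling, and excluded clades are
*not* replaced, so replicate sizes vary:

1. **Nesting.** Two sampled clades are either disjoint or nested; a clade
   nested in another sampled clade would mechanically support the clade-age
   hypothesis (the inner clade is both younger and necessarily poorer). Of
   every nested pair the younger clade is excluded, transitively; ties are
   broken against the larger node id so runs are deterministic.
2. **Zero crown ages and polytomies.** Supertrees carry zero-length branches
   (near-identical sequences from misidentified or introgressed species)
   and unresolved multifurcations. Clades with an effectively zero crown age
   (\(\le 10^{-9}\) Myr) get no rate and are dropped; clades whose subtree
   contains a polytomy are dropped. Because "a clade in a polytomy" is
   ambiguous, the polytomy flag is configurable: `scope = "any"` (default)
   flags a multifurcation anywhere inside the clade, `scope = "crown"` only
   the crown node itself.
3. **Extreme rates.** Clades with \(\hat r > 1\) species/Myr (typically very
   young two-species clades, where the estimator explodes as \(1/t\)) are
   dropped. Setting `max_rate = Inf` with both flags off reproduces an
   "all clades included" sensitivity analysis.

The exclusion log records exactly one reason per dropped clade, in the order
zero-crown, polytomy, rate; retained plus excluded always partition the
sample.

## Rate estimators

Net diversification is estimated by the method-of-moments (MS) estimators
from a clade's richness and age, conditional on an assumed relative
extinction fraction \(\varepsilon = \mu/\lambda \in [0, 1)\), which is a
fixed assumption, never estimated. Standard practice uses
\(\varepsilon \in \{0, 0.5, 0.9\}\), with 0.5 the headline choice. The stem
form is

\[\hat r = \frac{\log\big(n(1-\varepsilon) + \varepsilon\big)}{t_{stem}},\]

and the crown form

\[\hat r = \frac{1}{t}\left[\log\left(\tfrac{1}{2} n (1-\varepsilon^2) +
2\varepsilon + \tfrac{1}{2}(1-\varepsilon)\sqrt{n\,(n\varepsilon^2 -
8\varepsilon + 2n\varepsilon + n)}\right) - \log 2\right].\]

At \(\varepsilon = 0\) these reduce to \(\log(n)/t\) and \(\log(n/2)/t\); at
\(n = 2\) the crown form is identically 0 for every \(\varepsilon\) (the
bracketed term equals 2 algebraically), which the implementation enforces
exactly rather than leaving to floating-point round-off. The discriminant is
evaluated with its terms grouped exactly as written, which avoids
cancellation even for \(n\) in the millions. Natural logs throughout; the
\(\log_{10}\) transform belongs only to the regression response.

Using richness both to build \(\hat r\) and as the response is not circular:
nothing in the construction forces \(\log_{10} n\) and \(\hat r\) to
correlate (the age-driven simulations below show the relationship can be
weak), and the estimator's value is its established correlation with true
rates, which the package verifies on its own simulations. For users with
branch-heterogeneous speciation-rate output (e.g. ClaDS2 summaries),
`clads_diversification()` applies the post-processing
\((1-\varepsilon)\,\bar\lambda_i\); the Bayesian inference itself is out of
scope — its summaries are accepted as input.

## PGLS and the definition of r²

Clades share history, so residuals of cross-clade regressions are not
independent. The error covariance is the Brownian-motion matrix \(C\) of the
*reduced tree*, built by keeping one representative tip per retained clade:
entry \((i, j)\) is the shared root-to-tip path length of representatives
\(i\) and \(j\). In an ultrametric tree every choice of representative gives
identical pairwise path lengths, so the representative is fixed
deterministically as the lexicographically smallest tip label.

Phylogenetic signal in the residuals is modelled by Pagel's \(\lambda\):
off-diagonal entries of \(C\) are multiplied by \(\lambda \in [0, 1]\)
(\(\lambda = 0\) a star phylogeny, i.e. OLS; \(\lambda = 1\) full Brownian
structure), with the branch-length exponents \(\delta\) and \(\kappa\) fixed
at 1. \(\lambda\) is profiled by maximum likelihood (not REML) with bounded
scalar optimisation on \([0,1]\) at tolerance \(10^{-6}\); both endpoints
are evaluated explicitly so boundary optima are never missed by the interior
search. GLS itself is solved by whitening with the Cholesky factor of the
transformed covariance; slope \(p\)-values are two-sided \(t\)-tests on
\(n - p - 1\) degrees of freedom and the model \(p\)-value is the F-test of
all slopes, which coincides with the slope test in the single-predictor
models.

PGLS has no canonical \(r^2\); the choice matters when comparing the
strength of relationships. claderich reports
\(r^2 = 1 - RSS_w / TSS_w\) on the *whitened* scale, where \(TSS_w\) comes
from the GLS intercept-only model fitted under the same covariance — the
conventional GLS coefficient of determination, invariant to scaling of
\(C\). Because some published analyses report an OLS-style \(r^2\) on the
raw residuals instead, that variant is also computed and carried on every
fit object as `r_squared_raw`. The multiple regression is summarised by the
adjusted \(r^2 = 1 - (1 - r^2)(n-1)/(n-p-1)\).

The GLS path is validated three ways: against OLS under an identity
covariance (agreement to \(10^{-10}\)), against brute-force matrix algebra
on a four-taxon worked example, and against `nlme::gls` with
`ape::corPagel` at fixed \(\lambda\) (coefficients, standard errors,
\(p\)-values and log-likelihood agree to \(10^{-8}\)). The \(\lambda\)
profile is validated by recovery: responses simulated by Brownian motion on
the reduced tree yield median \(\hat\lambda > 0.8\), and i.i.d. responses
median \(\hat\lambda < 0.1\). `corPagel`'s own free-\(\lambda\) optimiser is
unbounded above 1 and was not used as an oracle.

## The synthetic forest generator

The generator produces a single ultrametric tree carrying `n_clades`
monophyletic clades with fully known parameters, so every downstream stage
can be tested against truth.

* **Per-clade process.** Each clade is grown by a forward-time, constant-rate
  birth–death simulation started from two lineages at the crown and run for
  its crown age, conditioned by rejection on both crown lineages surviving
  (this makes the realized depth exactly the nominal crown age). Rejection
  is the simplest unbiased conditioning scheme at these scales; a safety cap
  errors out when parameters imply near-certain extinction, and a hard cap
  of \(10^5\) extant lineages guards against explosive parameter choices.
* **Rates.** Per-clade speciation rates are lognormal around a configurable
  median (lognormality gives strictly positive, dispersed rates);
  extinction is \(\varepsilon_{true}\lambda\) with a single clade-wide
  \(\varepsilon_{true}\). The truth table records
  \(r = \lambda(1 - \varepsilon_{true})\).
* **Ages.** Stem ages are uniform on `stem_age_range`; each crown age is a
  uniform fraction (0.5–0.95) of its stem age, a generic waiting-time gap
  between origination and first surviving split.
* **Backbone.** Clades hang from a pectinate backbone whose joins all lie
  deeper than the oldest stem age, at fixed intervals of 5% of that age.
  The backbone's shape is irrelevant to the analyses — only the path
  structure among clade representatives enters PGLS — so the simplest
  non-overlapping arrangement is used. Consequently the realized parent-node
  depth of each clade (`attach_depth` in the truth table) is deeper than its
  drawn stem age; analyses use crown ages.
* **Seeding.** A single master seed expands to per-clade seeds through a
  counter-based splitter (`split_seed`), so each clade's simulation is
  reproducible independently of the order in which clades are generated.
* **Artifacts.** To emulate supertree defects, a fraction of internal nodes
  can be collapsed into their parent (branch zeroed, length pushed to the
  children, zero edges merged into polytomies), a fraction of cherries can
  have both tip branches zeroed (length donated to the cherry's stem, the
  signature of near-identical sequences; crown age becomes 0), and tips can
  be randomly subsampled. All three conserve total tree depth or pairwise
  distances among survivors.

Two presets pin down the regimes the pipeline must distinguish.
`age_driven` (stem ages U(2, 60) Myr, \(\lambda\) median 0.1/Myr, sdlog
0.05) makes time the only systematic source of richness variation;
`rate_driven` (stem ages U(8, 12) Myr, \(\lambda\) median 0.15/Myr, sdlog
0.5) makes rate variation the source. The medians keep expected clade sizes
in the tens-to-hundreds so that a forest of 80 clades stays in the
low-thousands of tips — large enough for stable regressions, small enough
that the full validation suite runs in well under a minute. Under the
age-driven preset replicated PGLS finds \(r^2(\text{richness} \sim
\text{age}) > r^2(\text{richness} \sim \text{rate})\) in at least 8 of 10
replicates, and the rate-driven preset reverses the inequality — the
qualitative engine behind interpreting such tables on real trees.

What the generator does *not* emulate: heritable within-clade rate shifts,
time-varying rates, fossilised lineages, and the taxonomically biased
(non-random) incompleteness of real supertrees. Passing tests on these
simulations therefore shows the machinery is correct and the design can
distinguish the two regimes; it does not by itself certify conclusions
about any empirical tree.

## Validation experiments and problem sizes

* **Estimator recovery.** 200 pure-birth clades with crown ages U(5, 50) Myr
  and per-clade rates lognormal around 0.2/Myr (sdlog 0.5). A shared rate
  would make the true–estimated correlation undefined, so rates must vary;
  \((\lambda, t)\) pairs are redrawn until \(\lambda t \le 8\), bounding
  expected richness near \(2e^8 \approx 6000\) tips so the experiment stays
  a few seconds. The crown estimator at \(\varepsilon = 0\) achieves
  Pearson correlation > 0.8 with the true rates and median relative error
  < 15%.
* **Scenario contrast.** One 80-clade forest per preset, 10 replicates of 50
  planted clades each (sampling from the planted pool keeps replicates
  non-nested by construction and leaves room for distinct samples).
* **\(\lambda\) recovery.** 200 Brownian and 200 i.i.d. responses on a
  50-clade reduced tree.
* **Structural invariants.** A 10-replicate run over a forest injected with
  polytomies and zeroed cherries, brute-force checking non-nesting, filter
  enforcement, crown \(\le\) stem, and sample conservation in every
  replicate.

## Numerical choices and degenerate inputs

* Ultrametricity tolerance \(10^{-6}\) Myr (supertrees carry rounding
  noise); zero-branch tolerance \(10^{-9}\) Myr. Non-ultrametric input is
  refused with the worst-offending tip pair named.
* Newick output uses 9 significant digits; internal forest assembly uses 12
  so truth-table crown ages survive the string round trip.
* The covariance is checked positive semi-definite
  (\(\min \text{eig} \ge -10^{-8}\,\mathrm{tr}\,C\)); singular transformed
  covariances and rank-deficient designs are errors, not silent drops.
* Replicates retaining fewer than 4 clades are skipped with a warning and
  excluded from summary means (PGLS needs residual degrees of freedom);
  they are never redrawn.
* Paired \(r^2\) comparisons with (near-)zero variance of differences
  return \(p = 1\) with a degeneracy flag instead of an undefined \(t\).
* No multiple-testing correction is applied: per-replicate \(p\)-values are
  reported raw against the 0.05 threshold, and the replicate percentage is
  the summary of evidence.

## Known limitations

Candidate enumeration treats every internal node as one clade; taxonomy-aware
(named-rank) selection — the design the random-sampling approach is meant to
replace — is only possible by passing an explicit id list. The
described-richness substitution assigns unsampled species at or above the
genus level only, and so inherits the coarseness of the supplied taxonomy.
The MS estimators assume the chosen \(\varepsilon\) applies to every clade;
results should be (and in the orchestrator can be) reported across
\(\varepsilon \in \{0, 0.5, 0.9\}\). Incomplete sampling is emulated as
uniform random tip loss, which is more benign than the clustered
incompleteness of real supertrees; the subsampling experiment measures
robustness only against the former.
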