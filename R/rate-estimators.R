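# Method-of-moments net diversification estimators (Magallon-Sanderson style)
# and post-processing of branch-speciation-rate summaries.
#
# Both estimators condition on an assumed relative extinction fraction
# epsilon = mu / lambda in [0, 1); epsilon is a fixed assumption, never
# estimated. Rates are in species per Myr and use natural logs; the log10
# transform belongs to the regression response only.

.check_epsilon <- function(epsilon) {
  if (any(epsilon < 0) || any(epsilon >= 1))
    stop_f("epsilon must lie in [0, 1); got %s", paste(epsilon, collapse = ", "))
}

#' Stem-group method-of-moments net diversification rate
#'
#' \deqn{\hat r = \log(n (1 - \epsilon) + \epsilon) / t_{stem}}
#' which reduces to \eqn{\log(n)/t} at \eqn{\epsilon = 0}. Vectorised over
#' all arguments.
#'
#' @param n clade species richness (>= 1).
#' @param t_stem stem age in Myr (> 0).
#' @param epsilon assumed relative extinction fraction in [0, 1).
#' @return net diversification rate, species/Myr.
#' @references Magallon S. & Sanderson M.J. (2001) Absolute diversification
#'   rates in angiosperm clades. Evolution 55, 1762-1780.
#' @export
#' @examples
#' ms_stem_rate(100, 20, 0.9)
ms_stem_rate <- function(n, t_stem, epsilon = 0.5) {
  .check_epsilon(epsilon)
  if (any(n < 1)) stop_f("richness n must be >= 1 for the stem estimator")
  if (any(t_stem <= 0)) stop_f("stem age must be > 0")
  log(n * (1 - epsilon) + epsilon) / t_stem
}

#' Crown-group method-of-moments net diversification rate
#'
#' \deqn{\hat r = \frac{1}{t}\left[\log\!\left(\tfrac{1}{2} n (1-\epsilon^2)
#'   + 2\epsilon + \tfrac{1}{2}(1-\epsilon)
#'   \sqrt{n (n\epsilon^2 - 8\epsilon + 2n\epsilon + n)}\right)
#'   - \log 2\right]}
#' which reduces to \eqn{\log(n/2)/t} at \eqn{\epsilon = 0} and is exactly 0
#' at \eqn{n = 2} for every \eqn{\epsilon} (the bracketed term equals 2
#' identically, enforced explicitly to avoid round-off). The discriminant is
#' grouped exactly as written to avoid cancellation at large `n`.
#'
#' @inheritParams ms_stem_rate
#' @param t_crown crown age in Myr (> 0).
#' @return net diversification rate, species/Myr.
#' @export
#' @examples
#' ms_crown_rate(4, 10, 0)        # log(2)/10
#' ms_crown_rate(2, 7, 0.9)       # exactly 0
ms_crown_rate <- function(n, t_crown, epsilon = 0.5) {
  .check_epsilon(epsilon)
  if (any(n < 2)) stop_f("richness n must be >= 2 for the crown estimator")
  if (any(t_crown <= 0)) stop_f("crown age must be > 0")
  disc <- n * (n * epsilon^2 - 8 * epsilon + 2 * n * epsilon + n)
  if (any(disc < 0))
    stop_f("negative discriminant in crown estimator (n=%s, epsilon=%s)",
           n[which(disc < 0)[1]], epsilon[min(which(disc < 0)[1], length(epsilon))])
  term <- 0.5 * n * (1 - epsilon^2) + 2 * epsilon + 0.5 * (1 - epsilon) * sqrt(disc)
  r <- (log(term) - log(2)) / t_crown
  r[n == 2] <- 0
  r
}

#' Net diversification from a mean branch-specific speciation rate
#'
#' Post-processes the output of a branch-heterogeneous speciation-rate model
#' (e.g. ClaDS2) into a clade-level net diversification rate:
#' `(1 - epsilon) * lambda_imean`, where `epsilon` is the clade-wide turnover
#' mu/lambda and `lambda_imean` the mean branch-specific speciation rate.
#'
#' @param lambda_imean mean branch-specific speciation rate, /Myr (>= 0).
#' @param epsilon clade-wide turnover mu/lambda in [0, 1).
#' @return net diversification rate, species/Myr.
#' @export
clads_diversification <- function(lambda_imean, epsilon) {
  .check_epsilon(epsilon)
  if (any(lambda_imean < 0)) stop_f("lambda_imean must be >= 0")
  (1 - epsilon) * lambda_imean
}

#' Fill diversification rates into a clade-record table
#'
#' Adds a `rate` column computed with the chosen method-of-moments estimator
#' from each record's richness and age. Records whose age is effectively zero
#' are flagged `zero_crown` and get no rate (`NA`); they are removed later by
#' [apply_filters()]. With several `epsilon` values one column
#' `rate_eps<value>` is added per value and `rate` is taken from the first.
#'
#' @param records data.frame with columns `n_tips`, `crown_age`, `stem_age`
#'   (from [clade_records()]).
#' @param age_basis `"crown"` (default) or `"stem"`.
#' @param epsilon one or more relative extinction fractions in [0, 1).
#' @param zero_tol ages at or below this count as zero (Myr).
#' @return `records` with `rate` (and per-epsilon) columns and a `zero_crown`
#'   logical column.
#' @export
fill_rates <- function(records, age_basis = c("crown", "stem"), epsilon = 0.5,
                       zero_tol = .ZERO_TOL) {
  age_basis <- match.arg(age_basis)
  .check_epsilon(epsilon)
  age <- if (age_basis == "crown") records$crown_age else records$stem_age
  ok <- age > zero_tol
  est <- function(eps) {
    r <- rep(NA_real_, nrow(records))
    if (any(ok)) {
      r[ok] <- if (age_basis == "crown")
        ms_crown_rate(records$n_tips[ok], age[ok], eps)
      else
        ms_stem_rate(records$n_tips[ok], age[ok], eps)
    }
    r
  }
  records$zero_crown <- !ok
  records$rate <- est(epsilon[1])
  if (length(epsilon) > 1L) {
    for (eps in epsilon) records[[paste0("rate_eps", eps)]] <- est(eps)
  }
  records
}
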