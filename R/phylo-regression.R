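# Ordinary and phylogenetic generalized least squares with Brownian-motion
# covariance and maximum-likelihood Pagel's lambda.
#
# The GLS algebra is deliberately explicit (whitening through the Cholesky
# factor of the covariance) because the coefficient of determination must be
# pinned down: r^2 is computed on the whitened scale against the GLS
# intercept-only null fitted under the same covariance — the conventional
# GLS r^2. An OLS-style r^2 on the raw residuals is also carried along
# (`r_squared_raw`) since published analyses do not always say which of the
# two they report.

#' Brownian-motion covariance matrix of a reduced tree
#'
#' Entry (i, j) is the shared root-to-tip path length of tips i and j in Myr
#' (the Brownian covariance); the diagonal holds tip depths. The matrix is
#' checked to be positive semi-definite up to `-1e-8 * trace`.
#'
#' @param tree a `"phylo"` object with >= 3 tips.
#' @return named square matrix in tip-label order.
#' @export
phylo_covariance <- function(tree) {
  if (ape::Ntip(tree) < 3L) stop_f("covariance needs a reduced tree with >= 3 tips")
  C <- ape::vcv.phylo(tree)
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * sum(diag(C)))
    stop_f("covariance is not positive semi-definite (min eigenvalue %g)", min(ev))
  C
}

#' Pagel's lambda transform of a covariance matrix
#'
#' Multiplies off-diagonal entries by `lambda` and leaves the diagonal
#' untouched: `lambda = 1` is the full Brownian structure, `lambda = 0` a
#' star phylogeny (independent errors).
#'
#' @param C covariance matrix.
#' @param lambda value in [0, 1].
#' @return transformed matrix.
#' @export
pagel_transform <- function(C, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0 || lambda > 1)
    stop_f("lambda must be a single value in [0, 1]")
  Cp <- C * lambda
  diag(Cp) <- diag(C)
  Cp
}

.new_fit <- function(coef_table, r2, adj_r2, p_model, lambda, n, ll, df_resid,
                     engine, r2_raw = NA_real_, formula = NULL) {
  structure(list(coefficients = coef_table, r_squared = r2,
                 adj_r_squared = adj_r2, p_value = p_model,
                 lambda = lambda, n_obs = n, log_likelihood = ll,
                 df_residual = df_resid, engine = engine,
                 r_squared_raw = r2_raw, formula = formula),
            class = "claderich_fit")
}

#' Generalized least squares with a fixed error covariance
#'
#' Fits `y = X beta + e`, `e ~ N(0, sigma^2 C)`, by whitening with the
#' Cholesky factor of `C`: `beta = (X' C^-1 X)^-1 X' C^-1 y`. Slope p-values
#' are two-sided t-tests on `n - p - 1` degrees of freedom; the model
#' p-value is the F-test of all slopes against the GLS intercept-only null
#' under the same `C` (for a single slope the two coincide). The reported
#' log-likelihood uses the maximum-likelihood variance.
#'
#' @param X design matrix whose first column is the intercept.
#' @param y response vector.
#' @param C error covariance (positive definite), rows aligned with `X`.
#' @return an object of class `"claderich_fit"`.
#' @export
gls_fit <- function(X, y, C) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- length(y)
  stopifnot(nrow(X) == n, nrow(C) == n, ncol(C) == n)
  if (is.null(colnames(X)))
    colnames(X) <- c("(Intercept)", paste0("x", seq_len(ncol(X) - 1)))[seq_len(ncol(X))]
  R <- tryCatch(chol(C), error = function(e)
    stop_f("covariance is singular or not positive definite (condition number %g): %s",
           kappa(C), conditionMessage(e)))
  Xw <- backsolve(R, X, transpose = TRUE)
  yw <- backsolve(R, y, transpose = TRUE)
  qx <- qr(Xw)
  if (qx$rank < ncol(X))
    stop_f("design matrix is rank deficient (rank %d < %d columns)", qx$rank, ncol(X))
  beta <- qr.coef(qx, yw)
  res_w <- yw - Xw %*% beta
  rss <- sum(res_w^2)
  ones_w <- backsolve(R, rep(1, n), transpose = TRUE)
  mu0 <- sum(ones_w * yw) / sum(ones_w^2)        # GLS intercept-only fit
  tss <- sum((yw - ones_w * mu0)^2)
  p_slopes <- ncol(X) - 1L
  df_resid <- n - ncol(X)
  if (df_resid < 1L) stop_f("need at least %d observations for %d coefficients",
                            ncol(X) + 1L, ncol(X))
  sigma2 <- rss / df_resid
  XtX_inv <- chol2inv(qr.R(qx))
  se <- sqrt(sigma2 * diag(XtX_inv))
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df_resid)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  adj_r2 <- if (!is.na(r2)) 1 - (1 - r2) * (n - 1) / df_resid else NA_real_
  p_model <- if (p_slopes >= 1L && rss > 0) {
    f <- ((tss - rss) / p_slopes) / (rss / df_resid)
    stats::pf(f, p_slopes, df_resid, lower.tail = FALSE)
  } else if (p_slopes >= 1L) 0 else NA_real_
  sigma2_ml <- rss / n
  ll <- -0.5 * (n * log(2 * pi) + n * log(sigma2_ml) + 2 * sum(log(diag(R))) + n)
  fitted_raw <- as.numeric(X %*% beta)
  tss_raw <- sum((y - mean(y))^2)
  r2_raw <- if (tss_raw > 0) 1 - sum((y - fitted_raw)^2) / tss_raw else NA_real_
  coef_table <- data.frame(term = colnames(X), estimate = as.numeric(beta),
                           std_error = se, t_value = as.numeric(tval),
                           p_value = as.numeric(pval), row.names = NULL)
  .new_fit(coef_table, r2, adj_r2, p_model, NA_real_, n, ll, df_resid,
           engine = "gls", r2_raw = r2_raw)
}

#' Ordinary least-squares regression
#'
#' Thin wrapper around [stats::lm()] returning the same result shape as
#' [gls_fit()]/[pgls_fit()], with `lambda` absent (`NA`).
#'
#' @param formula model formula.
#' @param data data.frame of variables.
#' @return an object of class `"claderich_fit"`.
#' @export
ols_fit <- function(formula, data) {
  fit <- stats::lm(formula, data = data)
  if (any(is.na(stats::coef(fit))))
    stop_f("design matrix is rank deficient: coefficient(s) %s not estimable",
           paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", "))
  s <- summary(fit)
  ct <- stats::coef(s)
  coef_table <- data.frame(term = rownames(ct), estimate = ct[, 1],
                           std_error = ct[, 2], t_value = ct[, 3],
                           p_value = ct[, 4], row.names = NULL)
  p_model <- if (!is.null(s$fstatistic))
    unname(stats::pf(s$fstatistic[1], s$fstatistic[2], s$fstatistic[3],
                     lower.tail = FALSE))
  else NA_real_
  .new_fit(coef_table, s$r.squared, s$adj.r.squared, p_model, NA_real_,
           length(stats::residuals(fit)), as.numeric(stats::logLik(fit)),
           fit$df.residual, engine = "ols", r2_raw = s$r.squared,
           formula = formula)
}

#' Phylogenetic generalized least squares with ML Pagel's lambda
#'
#' Builds the Brownian covariance from the reduced tree, profiles the
#' likelihood over Pagel's lambda on [0, 1] by bounded scalar optimisation
#' (tolerance 1e-6, endpoints checked explicitly), and refits at the
#' optimum. Branch-length exponents delta and kappa are fixed at 1; only the
#' off-diagonal multiplier lambda is free, estimated by ML (not REML).
#'
#' @param formula model formula; variables looked up in `data`.
#' @param data data.frame whose row names are tip labels of `tree`.
#' @param tree reduced `"phylo"` object, one tip per clade.
#' @param lambda `"ML"` (default) to profile, or a fixed value in [0, 1].
#' @return an object of class `"claderich_fit"` with `lambda` set.
#' @export
pgls_fit <- function(formula, data, tree, lambda = "ML") {
  if (nrow(data) < 4L) stop_f("PGLS needs at least 4 observations")
  if (is.null(rownames(data)) || !all(rownames(data) %in% tree$tip.label))
    stop_f("row names of data must be tip labels of the reduced tree")
  C_full <- phylo_covariance(tree)[rownames(data), rownames(data)]
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  fit_at <- function(l) gls_fit(X, y, pagel_transform(C_full, l))
  if (is.numeric(lambda)) {
    out <- fit_at(lambda)
    out$lambda <- lambda
  } else {
    ll_at <- function(l) tryCatch(fit_at(l)$log_likelihood,
                                  error = function(e) -Inf)
    opt <- tryCatch(stats::optimize(ll_at, c(0, 1), maximum = TRUE, tol = 1e-6),
                    error = function(e) NULL)
    cand_l <- c(0, 1, if (!is.null(opt)) opt$maximum)
    cand_ll <- vapply(cand_l, ll_at, numeric(1))
    if (all(!is.finite(cand_ll)))
      stop_f("lambda profile failed: log-likelihood not finite at lambda = %s",
             paste(signif(cand_l, 3), collapse = ", "))
    l_hat <- cand_l[which.max(cand_ll)]
    out <- fit_at(l_hat)
    out$lambda <- l_hat
  }
  out$engine <- "pgls"
  out$formula <- formula
  out
}

#' @export
print.claderich_fit <- function(x, ...) {
  cat(sprintf("<%s fit>  n = %d, r^2 = %.4f (adj %.4f), model p = %.4g",
              toupper(x$engine), x$n_obs, x$r_squared, x$adj_r_squared,
              x$p_value))
  if (!is.na(x$lambda)) cat(sprintf(", Pagel's lambda = %.3f", x$lambda))
  cat("\n")
  print(x$coefficients, digits = 4)
  invisible(x)
}
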