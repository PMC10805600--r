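test_that("phylo_covariance holds shared path lengths", {
  tr <- tree_cherry3()
  C <- phylo_covariance(tr)
  expect_equal(C["A", "B"], 1)
  expect_equal(C["A", "C"], 0)
  expect_equal(unname(diag(C)), rep(2, 3))
  expect_error(phylo_covariance(parse_newick("(A:1,B:1);")), ">= 3 tips")
})

test_that("pagel_transform scales off-diagonals only", {
  C <- phylo_covariance(tree_cherry3())
  expect_equal(pagel_transform(C, 1), C)
  C0 <- pagel_transform(C, 0)
  expect_equal(C0[upper.tri(C0)], rep(0, 3))
  expect_equal(diag(C0), diag(C))
  expect_equal(pagel_transform(C, 0.5)["A", "B"], 0.5)
  expect_error(pagel_transform(C, 1.2), "lambda")
})

test_that("GLS with identity covariance reproduces OLS to machine precision", {
  set.seed(1)
  for (p in 1:2) {
    X <- cbind(1, matrix(rnorm(30 * p), 30))
    colnames(X) <- c("(Intercept)", paste0("x", seq_len(p)))
    y <- X %*% c(1, rep(0.5, p)) + rnorm(30)
    g <- gls_fit(X, y, diag(30))
    d <- as.data.frame(X[, -1, drop = FALSE]); d$y <- as.numeric(y)
    o <- ols_fit(y ~ ., d)
    expect_equal(g$coefficients$estimate, o$coefficients$estimate, tolerance = 1e-10)
    expect_equal(g$coefficients$p_value, o$coefficients$p_value, tolerance = 1e-10)
    expect_equal(g$r_squared, o$r_squared, tolerance = 1e-10)
    expect_equal(g$adj_r_squared, o$adj_r_squared, tolerance = 1e-10)
    expect_equal(g$p_value, o$p_value, tolerance = 1e-10)
  }
})

test_that("an exact linear relation is recovered under any PSD covariance", {
  tr <- tree_bal4()
  C <- phylo_covariance(tr)
  x <- c(1, 2, 3, 4)
  y <- 2 * x + 1
  f <- gls_fit(cbind(1, x), y, C)
  expect_equal(f$coefficients$estimate, c(1, 2), tolerance = 1e-10)
  expect_equal(f$r_squared, 1)
})

test_that("GLS matches brute-force matrix algebra on a 4-taxon example", {
  tr <- tree_bal4()                     # balanced, depth 2
  C <- phylo_covariance(tr)
  x <- c(1, 3, 2, 5)
  y <- c(2, 4, 3, 9)
  X <- cbind(1, x)
  f <- gls_fit(X, y, C)
  # independent route: closed-form GLS expressions via explicit inverses
  Ci <- solve(C)
  beta <- solve(t(X) %*% Ci %*% X) %*% t(X) %*% Ci %*% y
  expect_equal(f$coefficients$estimate, as.numeric(beta), tolerance = 1e-10)
  res <- y - X %*% beta
  rss <- as.numeric(t(res) %*% Ci %*% res)
  sigma2 <- rss / (4 - 2)
  se <- sqrt(diag(sigma2 * solve(t(X) %*% Ci %*% X)))
  expect_equal(f$coefficients$std_error, unname(se), tolerance = 1e-10)
  mu0 <- as.numeric(solve(t(rep(1, 4)) %*% Ci %*% rep(1, 4)) %*%
                      t(rep(1, 4)) %*% Ci %*% y)
  res0 <- y - mu0
  tss <- as.numeric(t(res0) %*% Ci %*% res0)
  expect_equal(f$r_squared, 1 - rss / tss, tolerance = 1e-10)
  tval <- unname(beta[2] / se[2])
  expect_equal(f$coefficients$p_value[2], 2 * pt(-abs(tval), 2), tolerance = 1e-10)
})

test_that("r-squared is invariant to scaling the covariance", {
  set.seed(3)
  tr <- reduced_tree(small_forest(10)$tree, small_forest(10)$truth$node)
  C <- phylo_covariance(tr)
  n <- nrow(C)
  X <- cbind(1, rnorm(n)); y <- rnorm(n)
  f1 <- gls_fit(X, y, C)
  f2 <- gls_fit(X, y, 7.3 * C)
  expect_equal(f1$r_squared, f2$r_squared, tolerance = 1e-12)
  expect_equal(f1$coefficients$estimate, f2$coefficients$estimate, tolerance = 1e-10)
})

test_that("rank-deficient designs and singular covariances are refused", {
  X <- cbind(1, 1:10, 2 * (1:10))
  expect_error(gls_fit(X, rnorm(10), diag(10)), "rank deficient")
  C <- matrix(1, 5, 5)
  expect_error(gls_fit(cbind(1, rnorm(5)), rnorm(5), C), "singular|positive definite")
})

test_that("OLS matches hand-computed least squares on the 5-point toy set", {
  d <- data.frame(x = 1:5, y = c(1, 3, 2, 5, 4))
  f <- ols_fit(y ~ x, d)
  # normal equations by hand: slope = Sxy/Sxx = 8/10, intercept = 3 - 0.8*3
  expect_equal(f$coefficients$estimate, c(0.6, 0.8), tolerance = 1e-12)
  expect_equal(f$r_squared, 0.64, tolerance = 1e-12)
  expect_true(is.na(f$lambda))

  exact <- suppressWarnings(ols_fit(y ~ x, data.frame(x = 1:5, y = 1:5)))
  expect_equal(exact$coefficients$estimate, c(0, 1), tolerance = 1e-12)
  expect_equal(exact$r_squared, 1)

  orth <- ols_fit(y ~ x, data.frame(x = c(-1, 0, 1), y = c(5, 2, 5) - 4))
  expect_equal(orth$coefficients$estimate[2], 0, tolerance = 1e-12)
  expect_equal(orth$r_squared, 0, tolerance = 1e-12)
})

test_that("PGLS at fixed lambda agrees with nlme::gls + ape::corPagel", {
  skip_if_not_installed("nlme")
  f <- small_forest(30, seed = 2)
  rt <- reduced_tree(f$tree, f$truth$node)
  C <- phylo_covariance(rt); L <- t(chol(C)); n <- nrow(C)
  set.seed(5)
  x <- rnorm(n)
  y <- 1 + 0.5 * x + as.numeric(L %*% rnorm(n)) * 0.1
  d <- data.frame(y = y, x = x, species = rownames(C), row.names = rownames(C))
  mine <- pgls_fit(y ~ x, d, rt, lambda = 0.7)
  ref <- nlme::gls(y ~ x, data = d, method = "ML",
                   correlation = ape::corPagel(0.7, phy = rt, form = ~species,
                                               fixed = TRUE))
  tt <- summary(ref)$tTable
  expect_equal(mine$coefficients$estimate, unname(coef(ref)), tolerance = 1e-8)
  expect_equal(mine$coefficients$std_error, unname(tt[, 2]), tolerance = 1e-8)
  expect_equal(mine$coefficients$p_value, unname(tt[, 4]), tolerance = 1e-8)
  expect_equal(mine$log_likelihood, as.numeric(logLik(ref)), tolerance = 1e-8)
})

test_that("the lambda profile optimum beats both endpoints", {
  f <- small_forest(20, seed = 8)
  rt <- reduced_tree(f$tree, f$truth$node)
  C <- phylo_covariance(rt); L <- t(chol(C)); n <- nrow(C)
  set.seed(21)
  d <- data.frame(y = as.numeric(L %*% rnorm(n)) + rnorm(n, sd = 2),
                  x = rnorm(n), row.names = rownames(C))
  fit <- pgls_fit(y ~ x, d, rt)
  for (l in c(0, 1)) {
    alt <- pgls_fit(y ~ x, d, rt, lambda = l)
    expect_gte(fit$log_likelihood + 1e-8, alt$log_likelihood)
  }
  expect_true(fit$lambda >= 0 && fit$lambda <= 1)
})

test_that("PGLS on a star phylogeny collapses to OLS", {
  star <- parse_newick("(A:2,B:2,C:2,D:2,E:2);")
  set.seed(9)
  d <- data.frame(y = rnorm(5), x = rnorm(5),
                  row.names = c("A", "B", "C", "D", "E"))
  p <- pgls_fit(y ~ x, d, star, lambda = 1)  # C is already diagonal
  o <- ols_fit(y ~ x, d)
  expect_equal(p$coefficients$estimate, o$coefficients$estimate, tolerance = 1e-10)
  expect_equal(p$r_squared, o$r_squared, tolerance = 1e-10)
})

test_that("GLS slope estimates are unbiased under Brownian errors", {
  f <- small_forest(50, seed = 14)
  rt <- reduced_tree(f$tree, f$truth$node)
  C <- phylo_covariance(rt)
  L <- t(chol(C)); n <- nrow(C)
  set.seed(7)
  slopes <- vapply(seq_len(500), function(i) {
    x <- rnorm(n)
    y <- 1 + x + as.numeric(L %*% rnorm(n)) * 0.3
    gls_fit(cbind(1, x), y, C)$coefficients$estimate[2]
  }, numeric(1))
  expect_lt(abs(mean(slopes) - 1), 0.05)
})
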