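test_that("lambda transform rescales shared paths only", {
  C <- shared_path_matrix(read_newick("((A:1,B:1):0.5,C:1.5);"))
  expect_equal(lambda_cov(C, 1), C)
  expect_equal(lambda_cov(C, 0), diag(diag(C)), ignore_attr = TRUE)
  half <- lambda_cov(C, 0.5)
  expect_equal(half["A", "B"], C["A", "B"] / 2)
  expect_equal(diag(half), diag(C))
  expect_error(lambda_cov(C, 1.2), "\\[0, 1\\]")
})

test_that("GLS reduces to OLS under identity covariance and matches a direct optimiser", {
  set.seed(5)
  n <- 10
  X <- cbind(intercept = 1, ad_present = rep(c(0, 1), each = 5))
  y <- 3 + 2 * X[, 2] + rnorm(n)
  f <- gls_fit(y, X, diag(n))
  ols <- stats::lm(y ~ X[, 2])
  expect_equal(unname(f$coefficients), unname(coef(ols)), tolerance = 1e-10)

  expect_error(gls_fit(y, cbind(X, X[, 2]), diag(n)), "rank deficient")

  # optimiser oracle: maximise the multivariate-normal likelihood directly
  tr <- simulate_yule(10, 1, seed = 15)
  V <- lambda_cov(shared_path_matrix(tr), 0.6)
  yv <- as.numeric(MASS::mvrnorm(1, rep(5, 10), V))
  Xv <- cbind(intercept = 1, ad_present = rep(c(0, 1), 5))
  f2 <- gls_fit(yv, Xv, V)
  nll <- function(par) {
    mu <- Xv %*% par[1:2]
    -mvtnorm_lnl(yv, as.numeric(mu), exp(par[3]) * V)
  }
  mvtnorm_lnl <- function(y, mu, S) {
    L <- chol(S)
    z <- backsolve(L, y - mu, transpose = TRUE)
    -0.5 * (length(y) * log(2 * pi) + 2 * sum(log(diag(L))) + sum(z^2))
  }
  opt <- stats::optim(c(0, 0, 0), nll, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
  expect_equal(unname(f2$coefficients), opt$par[1:2], tolerance = 1e-5)
  expect_equal(f2$lnl, -opt$value, tolerance = 1e-6)
})

test_that("Student-t arithmetic is symmetric and correct", {
  expect_equal(student_t_pvalue(0, 10), 1)
  expect_equal(student_t_pvalue(2.5, 17), student_t_pvalue(-2.5, 17))
  expect_equal(student_t_pvalue(1.96, 1e6), 0.05, tolerance = 1e-3)
  expect_error(student_t_pvalue(1, 0), "df")
})

test_that("the phylogenetic t-test collapses to classic t-tests without signal", {
  # star tree: GLS equals the pooled-variance two-sample t-test
  star <- read_newick(paste0("(", paste0("t", 1:12, ":1", collapse = ","), ");"))
  gr <- setNames(rep(c(0, 1), each = 6), paste0("t", 1:12))
  tab <- simulate_lambda_trait(star, 0, 30, 6, gr, seed = 31)
  res <- phylogenetic_t_test(star, tab)
  ct <- stats::t.test(latitude ~ ad_present, data = tab, var.equal = TRUE)
  expect_equal(abs(res$t), abs(unname(ct$statistic)), tolerance = 1e-8)
  expect_equal(res$p, ct$p.value, tolerance = 1e-8)
  expect_equal(res$df, 10L)
  expect_equal(unname(res$group_means$raw),
               unname(tapply(tab$latitude, tab$ad_present, mean)),
               ignore_attr = TRUE)

  # lambda forced to 0 on a structured tree: same as independent observations
  tr <- simulate_yule(14, 1, seed = 32)
  g2 <- setNames(rep(c(0, 1), 7), tr$tip.label)
  tab2 <- simulate_lambda_trait(tr, 0, 40, 5, g2, seed = 32)
  C <- shared_path_matrix(tr, order = tab2$taxon)
  f0 <- gls_fit(tab2$latitude, cbind(intercept = 1, ad_present = tab2$ad_present),
                lambda_cov(C, 0))
  t0 <- unname(f0$coefficients["ad_present"]) /
    sqrt(f0$vcov["ad_present", "ad_present"])
  ct2 <- stats::t.test(latitude ~ ad_present, data = tab2, var.equal = TRUE)
  # equal-depth tips: lambda = 0 gives iid errors up to a common scale
  expect_equal(abs(t0), abs(unname(ct2$statistic)), tolerance = 1e-8)
})

test_that("group labels can be swapped with a sign flip", {
  tr <- simulate_yule(16, 1, seed = 33)
  g <- setNames(rep(c(0, 1), 8), tr$tip.label)
  tab <- simulate_lambda_trait(tr, 0.5, 50, 7, g, seed = 33)
  res <- phylogenetic_t_test(tr, tab)
  tab_swap <- tab
  tab_swap$ad_present <- 1 - tab$ad_present
  res_swap <- phylogenetic_t_test(tr, tab_swap)
  expect_equal(res_swap$beta1, -res$beta1, tolerance = 1e-8)
  expect_equal(res_swap$lambda_hat, res$lambda_hat, tolerance = 1e-6)
  expect_equal(res_swap$p, res$p, tolerance = 1e-8)
})

test_that("lambda estimation agrees with nlme::gls with corPagel", {
  tr <- simulate_yule(40, 1, seed = 34)
  g <- setNames(rep(c(0, 1), 20), tr$tip.label)
  tab <- simulate_lambda_trait(tr, 0.5, 60, 6, g, seed = 34)
  res <- phylogenetic_t_test(tr, tab)
  rownames(tab) <- tab$taxon
  ref <- nlme::gls(latitude ~ ad_present, data = tab,
                   correlation = ape::corPagel(0.5, phy = tr, form = ~taxon),
                   method = "ML")
  expect_equal(res$lambda_hat,
               as.numeric(ref$modelStruct$corStruct[[1]]), tolerance = 1e-4)
  expect_equal(res$t, unname(summary(ref)$tTable["ad_present", "t-value"]),
               tolerance = 1e-4)
  expect_gte(res$lnl_at_lambda_hat, res$lnl_at_lambda0 - 1e-9)
  # profile optimum dominates the search grid
  C <- shared_path_matrix(tr, order = tab$taxon)
  X <- cbind(intercept = 1, ad_present = tab$ad_present)
  for (l in seq(0, 1, by = 0.1))
    expect_gte(res$lnl_at_lambda_hat,
               gls_fit(tab$latitude, X, lambda_cov(C, l))$lnl - 1e-8)

  expect_error(phylogenetic_t_test(tr, tab[tab$ad_present == 0, ]), "group")
})
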