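# Lambda-scaled phylogenetic GLS "t-test": latitude regressed on a
# dummy-coded androdioecy indicator under a Brownian covariance whose
# off-diagonal (shared-path) entries are multiplied by Pagel's lambda.

#' Apply Pagel's lambda transform to a shared-path matrix
#'
#' Multiplies the off-diagonal entries by `lam`, leaving the diagonal
#' unchanged. `lam = 0` collapses the model to independent observations (an
#' ordinary t-test); `lam = 1` keeps the full Brownian structure.
#'
#' @param C Symmetric PSD matrix from [shared_path_matrix()].
#' @param lam Lambda in `[0, 1]`.
#' @return Transformed matrix.
#' @export
lambda_cov <- function(C, lam) {
  if (lam < 0 || lam > 1) stop("lambda must lie in [0, 1]")
  V <- lam * C
  diag(V) <- diag(C)
  V
}

#' Generalized least squares fit with ML variance
#'
#' Computes `beta = (X' V^-1 X)^-1 X' V^-1 y`, the ML variance scale
#' `sigma2_ml` (residual quadratic form / n), the multivariate-normal
#' log-likelihood at the optimum, and the coefficient covariance. The
#' covariance is reported under both the ML scale and the unbiased
#' `(n - p)` denominator; t statistics use the latter.
#'
#' @param y Response vector.
#' @param X Design matrix (rows match `y`).
#' @param V Positive-definite covariance structure (scale-free; the overall
#'   variance is profiled out).
#' @return List: `coefficients`, `sigma2_ml`, `sigma2_unbiased`, `lnl`,
#'   `vcov` (unbiased scale), `vcov_ml`, `fitted`, `residuals`, `n`, `p`.
#' @export
gls_fit <- function(y, X, V) {
  X <- as.matrix(X)
  n <- length(y)
  if (nrow(X) != n || nrow(V) != n) stop("dimension mismatch")
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  L <- tryCatch(chol(V), error = function(e) stop("covariance matrix not positive definite"))
  # whiten: solve L' z = . (V = L'L with chol upper triangular R: V = R'R)
  wy <- backsolve(L, y, transpose = TRUE)
  wX <- backsolve(L, X, transpose = TRUE)
  colnames(wX) <- colnames(X)
  fit <- stats::lm.fit(wX, wy)
  beta <- fit$coefficients
  r <- wy - wX %*% beta
  rss <- sum(r^2)
  sigma2_ml <- rss / n
  p <- ncol(X)
  sigma2_ub <- rss / (n - p)
  logdetV <- 2 * sum(log(diag(L)))
  lnl <- -0.5 * (n * log(2 * pi * sigma2_ml) + logdetV + n)
  XtVX_inv <- chol2inv(chol(crossprod(wX)))
  dimnames(XtVX_inv) <- list(colnames(X), colnames(X))
  list(coefficients = beta, sigma2_ml = sigma2_ml, sigma2_unbiased = sigma2_ub,
       lnl = lnl, vcov = sigma2_ub * XtVX_inv, vcov_ml = sigma2_ml * XtVX_inv,
       fitted = as.vector(X %*% beta), residuals = as.vector(y - X %*% beta),
       n = n, p = p)
}

# profiled log-likelihood in lambda for fixed data/design
pgls_profile_lnl <- function(lam, y, design, C)
  gls_fit(y, design, lambda_cov(C, lam))$lnl

#' Two-tailed Student-t p-value
#'
#' @param t Test statistic.
#' @param df Degrees of freedom (>= 1).
#' @return Two-tailed p, symmetric in the sign of `t`.
#' @export
student_t_pvalue <- function(t, df) {
  if (df < 1) stop("df must be >= 1")
  2 * stats::pt(-abs(t), df)
}

#' Phylogenetic t-test of a continuous trait against a binary group
#'
#' GLS regression of the trait (here: absolute latitude) on an intercept and
#' a 0/1 group indicator (androdioecy presence) under a lambda-scaled
#' Brownian covariance. Lambda is estimated by ML over `[0, 1]` (21-point
#' grid refined by golden-section search); at the optimum the group effect is
#' tested with `t = beta1 / SE(beta1)` on `n - 2` degrees of freedom (SE on
#' the unbiased variance scale), and phylogenetic signal is tested by a
#' df = 1 chi-squared LRT of lambda-hat against lambda = 0.
#'
#' @param tree Rooted `"phylo"` with branch lengths covering all trait taxa.
#' @param traits Data frame with columns `taxon`, `latitude`, `ad_present`
#'   (0/1), or a named latitude vector plus `groups`.
#' @param groups Optional named 0/1 vector when `traits` is a vector.
#' @return A `"pgls_ttest"`: `beta0`, `beta1`, `t`, `df`, `p`, `lambda_hat`,
#'   `lnl_at_lambda_hat`, `lnl_at_lambda0`, `lambda_lrt`, `group_means`
#'   (raw and GLS-fitted per-group means), `n`.
#' @export
phylogenetic_t_test <- function(tree, traits, groups = NULL) {
  if (is.data.frame(traits)) {
    need <- c("taxon", "latitude", "ad_present")
    if (!all(need %in% names(traits)))
      stop("traits must have columns: ", paste(need, collapse = ", "))
    y <- setNames(traits$latitude, traits$taxon)
    g <- setNames(traits$ad_present, traits$taxon)
  } else {
    if (is.null(groups)) stop("supply `groups` with a trait vector")
    y <- traits; g <- groups[names(y)]
  }
  if (anyNA(y) || anyNA(g)) stop("missing trait or group values")
  if (!all(names(y) %in% tree$tip.label))
    stop("taxa absent from tree: ",
         paste(setdiff(names(y), tree$tip.label), collapse = ", "))
  if (!all(g %in% c(0, 1))) stop("groups must be coded 0/1")
  if (length(unique(g)) < 2L) stop("both groups must be non-empty")
  n <- length(y)
  if (n < 4L) stop("need at least 4 taxa")
  C <- shared_path_matrix(tree, order = names(y))
  X <- cbind(intercept = 1, ad_present = as.numeric(g))
  yv <- as.numeric(y)

  prof <- function(l) pgls_profile_lnl(l, yv, X, C)
  grid <- seq(0, 1, length.out = 21)
  lnls <- vapply(grid, prof, numeric(1))
  i <- which.max(lnls)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(prof, lower = lo, upper = hi,
                         maximum = TRUE, tol = 1e-8)
  if (opt$objective >= lnls[i]) {
    lambda_hat <- opt$maximum; lnl_hat <- opt$objective
  } else {
    lambda_hat <- grid[i]; lnl_hat <- lnls[i]
  }
  # snap to the boundary when it is at least as good (optimize never
  # evaluates the endpoints themselves)
  for (b in c(0, 1)) {
    lb <- pgls_profile_lnl(b, yv, X, C)
    if (lb >= lnl_hat) { lambda_hat <- b; lnl_hat <- lb }
  }
  fit <- gls_fit(yv, X, lambda_cov(C, lambda_hat))
  se1 <- sqrt(fit$vcov["ad_present", "ad_present"])
  tstat <- unname(fit$coefficients["ad_present"] / se1)
  df <- n - 2L
  lnl0 <- pgls_profile_lnl(0, yv, X, C)
  structure(list(
    beta0 = unname(fit$coefficients["intercept"]),
    beta1 = unname(fit$coefficients["ad_present"]),
    se1 = se1, t = tstat, df = df, p = student_t_pvalue(tstat, df),
    lambda_hat = lambda_hat,
    lnl_at_lambda_hat = lnl_hat, lnl_at_lambda0 = lnl0,
    lambda_lrt = lrt_result(max(0, 2 * (lnl_hat - lnl0)), 1L),
    group_means = list(
      raw = c(g0 = mean(yv[g == 0]), g1 = mean(yv[g == 1])),
      fitted = c(g0 = unname(fit$coefficients["intercept"]),
                 g1 = unname(sum(fit$coefficients)))),
    n = n, fit = fit
  ), class = "pgls_ttest")
}

#' @export
print.pgls_ttest <- function(x, ...) {
  cat("Phylogenetic t-test (lambda-GLS)\n")
  cat(sprintf("  group effect: %.3f (SE %.3f), t = %.3f, df = %d, p = %.4g\n",
              x$beta1, x$se1, x$t, x$df, x$p))
  cat(sprintf("  lambda-hat = %.3f; signal LRT: D = %.3f, df = 1, p = %.4g\n",
              x$lambda_hat, x$lambda_lrt$D, x$lambda_lrt$p))
  cat(sprintf("  group mean trait (raw): %.3f vs %.3f\n",
              x$group_means$raw["g0"], x$group_means$raw["g1"]))
  invisible(x)
}

#' Read a trait table
#'
#' Tab-separated columns `taxon`, `latitude`, `ad_present`.
#' @param path Path to TSV.
#' @return Data frame.
#' @export
read_trait_table <- function(path) {
  df <- utils::read.delim(path, comment.char = "#")
  need <- c("taxon", "latitude", "ad_present")
  if (!all(need %in% names(df)))
    stop("trait table must have columns: ", paste(need, collapse = ", "))
  df
}
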