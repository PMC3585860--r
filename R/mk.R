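# Two-state continuous-time Markov (Mk2) model of sexual-system evolution.
# States: 1 = G (gonochorism), 2 = A (androdioecy); q_ga and q_ag are the
# G -> A and A -> G transition rates per unit branch length.

#' Mk2 transition-probability matrix
#'
#' Closed form for the 2-state chain: with `s = q_ga + q_ag`,
#' `P(G -> G) = (q_ag + q_ga exp(-s t)) / s` and symmetrically; the matrix
#' degenerates to the identity when `s = 0`.
#'
#' @param q_ga,q_ag Non-negative transition rates.
#' @param t Non-negative branch length.
#' @return 2x2 stochastic matrix with dimnames `G`, `A`.
#' @export
mk2_transition_matrix <- function(q_ga, q_ag, t) {
  if (q_ga < 0 || q_ag < 0 || t < 0) stop("rates and branch length must be >= 0")
  s <- q_ga + q_ag
  if (s == 0) {
    P <- diag(2)
  } else {
    e <- exp(-s * t)
    P <- matrix(c(q_ag + q_ga * e, q_ga - q_ga * e,
                  q_ag - q_ag * e, q_ga + q_ag * e),
                2, 2, byrow = TRUE) / s
  }
  dimnames(P) <- list(c("G", "A"), c("G", "A"))
  P
}

mk_tip_partial <- function(code) {
  switch(code,
    "G" = c(1, 0),
    "A" = c(0, 1),
    c(1, 1))  # "GA" and "?" both enter as full ambiguity
}

mk_root_prior <- function(root_prior, q_ga, q_ag) {
  root_prior <- match.arg(root_prior, c("uniform", "stationary"))
  if (root_prior == "uniform") return(c(0.5, 0.5))
  s <- q_ga + q_ag
  if (s == 0) c(0.5, 0.5) else c(q_ag, q_ga) / s
}

# pruning pass: per-node partial likelihoods with per-node rescaling;
# returns partials, log scaling factors and per-edge transition matrices
mk2_prune <- function(tree, states, q_ga, q_ag) {
  if (!ape::is.rooted(tree)) stop("Mk likelihood needs a rooted tree")
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("missing branch lengths")
  states <- validate_tip_states(tree, states)
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  partial <- matrix(1, nn, 2)
  for (i in seq_len(ntip)) partial[i, ] <- mk_tip_partial(states[[i]])
  logscale <- numeric(nn)
  po <- ape::postorder(tree)
  P_edge <- vector("list", nrow(tree$edge))
  for (e in po) {
    p <- tree$edge[e, 1]; v <- tree$edge[e, 2]
    # v's subtree is complete here (postorder): rescale before folding up
    m <- max(partial[v, ])
    if (m > 0 && m != 1) {
      partial[v, ] <- partial[v, ] / m
      logscale[v] <- logscale[v] + log(m)
    }
    P <- mk2_transition_matrix(q_ga, q_ag, tree$edge.length[e])
    P_edge[[e]] <- P
    partial[p, ] <- partial[p, ] * as.vector(P %*% partial[v, ])
    logscale[p] <- logscale[p] + logscale[v]
  }
  list(partial = partial, logscale = logscale, P_edge = P_edge, po = po,
       states = states)
}

# loop-free-as-possible pruning core: precomputed traversal, closed-form P
# entries as scalars, conditional rescaling. `tip1`/`tip2` are the tip
# partials for states G and A.
mk2_loglik_core <- function(edge, elen, po, tip1, tip2, nn, q_ga, q_ag, pi) {
  s <- q_ga + q_ag
  if (s == 0) {
    e <- rep(1, length(elen))
  } else {
    e <- exp(-s * elen)
  }
  # P[G,G], P[G,A], P[A,G], P[A,A] per edge
  if (s == 0) {
    p11 <- p22 <- rep(1, length(elen)); p12 <- p21 <- rep(0, length(elen))
  } else {
    p11 <- (q_ag + q_ga * e) / s; p12 <- 1 - p11
    p22 <- (q_ga + q_ag * e) / s; p21 <- 1 - p22
  }
  f1 <- c(tip1, rep(1, nn - length(tip1)))
  f2 <- c(tip2, rep(1, nn - length(tip2)))
  logscale <- numeric(nn)
  for (i in seq_along(po)) {
    ed <- po[i]
    p <- edge[ed, 1]; v <- edge[ed, 2]
    v1 <- f1[v]; v2 <- f2[v]
    m <- max(v1, v2)
    if (m > 0 && m < 1e-10) {
      v1 <- v1 / m; v2 <- v2 / m
      logscale[v] <- logscale[v] + log(m)
    }
    f1[p] <- f1[p] * (p11[ed] * v1 + p12[ed] * v2)
    f2[p] <- f2[p] * (p21[ed] * v1 + p22[ed] * v2)
    logscale[p] <- logscale[p] + logscale[v]
  }
  root <- edge[po[length(po)], 1]
  lik <- unname(pi[1] * f1[root] + pi[2] * f2[root])
  if (lik <= 0 || !is.finite(lik)) return(-Inf)
  log(lik) + logscale[root]
}

#' Mk2 log-likelihood by Felsenstein pruning
#'
#' Tip partial likelihoods come from the tip state sets (`"GA"` and `"?"`
#' both contribute 1 for each state); the log-likelihood is the log of the
#' root-prior-weighted sum of root partials, with per-node rescaling for
#' numerical stability.
#'
#' @param tree Rooted `"phylo"` with branch lengths.
#' @param states Named tip coding (`"G"`, `"A"`, `"GA"`, `"?"`).
#' @param q_ga,q_ag Transition rates.
#' @param root_prior `"uniform"` (default) or `"stationary"`.
#' @return Log-likelihood.
#' @export
mk2_loglik <- function(tree, states, q_ga, q_ag, root_prior = "uniform") {
  if (q_ga < 0 || q_ag < 0) stop("rates must be >= 0")
  if (!ape::is.rooted(tree)) stop("Mk likelihood needs a rooted tree")
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("missing branch lengths")
  states <- validate_tip_states(tree, states)
  ntip <- ape::Ntip(tree)
  tp <- vapply(states, mk_tip_partial, numeric(2))
  mk2_loglik_core(tree$edge, tree$edge.length, ape::postorder(tree),
                  tp[1, ], tp[2, ], ntip + tree$Nnode, q_ga, q_ag,
                  mk_root_prior(root_prior, q_ga, q_ag))
}

#' Fit the Mk2 model under a transition-rate constraint
#'
#' Maximum likelihood over the free rate(s) on the log scale (bounds
#' `[1e-8, 1e4]` per unit branch length), with 8 deterministic starts spread
#' over the bound range; the reported fit is the best of all starts and
#' `converged` is `FALSE` when restarts disagree by more than `1e-4` lnL.
#'
#' Constraints: `"UNRESTRICTED"` (two free rates), `"EQUAL_RATES"` (one rate,
#' `q_ga = q_ag`), `"GA_ZERO"` (G to A forbidden), `"AG_ZERO"` (A to G
#' forbidden).
#'
#' @param tree Rooted `"phylo"` with branch lengths.
#' @param states Tip coding; at least one tip must carry a definite state.
#' @param constraint Model constraint (see above).
#' @param root_prior `"uniform"` or `"stationary"`.
#' @return An `"mk_fit"`: `q_ga`, `q_ag`, `lnl`, `constraint`, `root_prior`,
#'   `n_params`, `converged`.
#' @export
fit_mk2 <- function(tree, states,
                    constraint = c("UNRESTRICTED", "EQUAL_RATES",
                                   "GA_ZERO", "AG_ZERO"),
                    root_prior = "uniform") {
  constraint <- match.arg(constraint)
  st <- validate_tip_states(tree, states)
  if (all(st %in% c("GA", "?")))
    stop("all tips ambiguous: no information to fit rates")
  if (!any(st == "G") || !any(st == "A"))
    warning("only one definite state observed; rate estimates lie on the boundary")
  lb <- log(1e-8); ub <- log(1e4)
  rates_of <- function(par) switch(constraint,
    UNRESTRICTED = c(exp(par[1]), exp(par[2])),
    EQUAL_RATES  = rep(exp(par[1]), 2),
    GA_ZERO      = c(0, exp(par[1])),
    AG_ZERO      = c(exp(par[1]), 0))
  np <- if (constraint == "UNRESTRICTED") 2L else 1L
  root_prior <- match.arg(root_prior, c("uniform", "stationary"))
  ntip <- ape::Ntip(tree)
  tp <- vapply(st, mk_tip_partial, numeric(2))
  po <- ape::postorder(tree)
  nn <- ntip + tree$Nnode
  negll <- function(par) {
    q <- rates_of(par)
    ll <- mk2_loglik_core(tree$edge, tree$edge.length, po, tp[1, ], tp[2, ],
                          nn, q[1], q[2], mk_root_prior(root_prior, q[1], q[2]))
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  starts <- seq(log(1e-3), log(500), length.out = 8)
  best <- NULL; lnls <- numeric(0)
  for (s0 in starts) {
    par0 <- rep(s0, np)
    fit <- tryCatch(
      stats::optim(par0, negll, method = "L-BFGS-B",
                   lower = rep(lb, np), upper = rep(ub, np),
                   control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    lnls <- c(lnls, -fit$value)
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("Mk2 optimisation failed from every start")
  q <- rates_of(best$par)
  structure(list(q_ga = q[1], q_ag = q[2], lnl = -best$value,
                 constraint = constraint, root_prior = root_prior,
                 n_params = np,
                 converged = diff(range(lnls)) <= 1e-4),
            class = "mk_fit")
}

#' @export
print.mk_fit <- function(x, ...) {
  cat(sprintf("Mk2 fit [%s, %s root]: lnL = %.4f, q_GA = %.4g, q_AG = %.4g%s\n",
              x$constraint, x$root_prior, x$lnl, x$q_ga, x$q_ag,
              if (!x$converged) "  (restarts disagree)" else ""))
  invisible(x)
}

#' Likelihood-ratio test between nested Mk2 fits
#'
#' @param general,restricted `"mk_fit"` objects (or anything with `lnl`),
#'   restricted nested within general.
#' @param df Degrees of freedom: difference in number of estimated
#'   parameters (default inferred from the fits when available).
#' @return A `"lrt_result"` (`D`, `df`, `p`).
#' @export
compare_models <- function(general, restricted, df = NULL) {
  lg <- general$lnl; lr <- restricted$lnl
  if (lg < lr - 1e-6)
    stop(sprintf("general model lnL (%.6f) below restricted (%.6f): not nested or failed fit",
                 lg, lr))
  if (is.null(df)) {
    df <- if (!is.null(general$n_params) && !is.null(restricted$n_params))
      general$n_params - restricted$n_params else 1L
  }
  if (df < 1) stop("df must be >= 1")
  lrt_result(max(0, 2 * (lg - lr)), df)
}

#' Marginal ancestral-state probabilities under fitted rates
#'
#' For every internal node, the probability of each state given all tip data,
#' computed from the product of downward (subtree) and upward (rest-of-tree)
#' partial likelihoods under the fitted rates and root prior.
#'
#' @param tree Rooted `"phylo"` with branch lengths.
#' @param states Tip coding.
#' @param fit An `"mk_fit"` (or list with `q_ga`, `q_ag`, `root_prior`).
#' @return Matrix (internal nodes x 2) of probabilities, columns `G`, `A`,
#'   rows named by node number; rows sum to 1.
#' @export
marginal_asr <- function(tree, states, fit) {
  q_ga <- fit$q_ga; q_ag <- fit$q_ag
  root_prior <- if (is.null(fit$root_prior)) "uniform" else fit$root_prior
  pr <- mk2_prune(tree, states, q_ga, q_ag)
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  root <- ntip + 1L
  pi <- mk_root_prior(root_prior, q_ga, q_ag)
  up <- matrix(0, nn, 2)           # outside partials (unnormalised)
  up[root, ] <- pi
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  for (e in rev(pr$po)) {          # preorder
    p <- tree$edge[e, 1]; v <- tree$edge[e, 2]
    sib_edges <- setdiff(children[[as.character(p)]], e)
    contrib <- up[p, ]
    for (se in sib_edges) {
      wv <- tree$edge[se, 2]
      contrib <- contrib * as.vector(pr$P_edge[[se]] %*% pr$partial[wv, ])
    }
    up[v, ] <- as.vector(t(pr$P_edge[[e]]) %*% contrib)
    m <- max(up[v, ])
    if (m > 0) up[v, ] <- up[v, ] / m
  }
  nodes <- seq.int(root, nn)
  res <- t(vapply(nodes, function(v) {
    w <- pr$partial[v, ] * up[v, ]
    w / sum(w)
  }, numeric(2)))
  dimnames(res) <- list(nodes, c("G", "A"))
  res
}
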