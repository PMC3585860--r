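# Single-threshold generalized mixed Yule-coalescent (GMYC) model.
#
# The model describes the branching times of an ultrametric tree. A threshold
# time T splits the timeline: lineages crossing T define entities; branching
# older than T belongs to a diversification (Yule-like) class, branching
# younger than T to within-entity coalescence. During any inter-event
# interval the total branching rate is
#
#   b = lambda_div * n_d^p_div + lambda_coal * sum_j (n_j (n_j - 1))^p_coal
#
# with n_d the number of diversification lineages (the lineage count above T,
# frozen at the number of entities K below T) and n_j the lineage count of
# entity j (singleton entities contribute nothing). The log-likelihood is the
# branching-times density sum_i [log b_i - b_i x_i] over all inter-event
# intervals, each interval taking the rate prefactor of the branching event
# at its older end (the root event included); the interval reaching the
# present carries the youngest event's prefactor and its own exposure. With T
# older than the root the whole tree is one entity and the model reduces to
# the single-process (pure coalescent-class) null.

# Interval bookkeeping for one (tree, threshold) pair: for each inter-event
# interval, duration x, diversification count n_div (0 under the null), and
# the per-entity coalescible pair counts m = n_j (n_j - 1) (entries with
# n_j >= 2 only).
gmyc_intervals <- function(tree, threshold, times = NULL, tol = 1e-5) {
  if (is.null(times)) times <- node_times(tree, tol = tol)
  ntip <- ape::Ntip(tree)
  root_time <- max(times)
  if (threshold <= 0) stop("threshold must be positive")
  null_model <- threshold > root_time * (1 + 1e-12)
  node_ids <- seq.int(ntip + 1L, ntip + tree$Nnode)
  ev_times <- unname(times[as.character(node_ids)])
  ord <- order(ev_times, decreasing = TRUE)
  ev_nodes <- node_ids[ord]
  ev_times <- ev_times[ord]

  if (null_model) {
    entity_of_node <- setNames(rep(1L, length(ev_nodes)), ev_nodes)
    K <- 1L
  } else {
    clusters <- extract_clusters(tree, threshold, times = times)
    K <- length(unique(clusters))
    # entity of an internal node = entity of any descendant tip (meaningful
    # for nodes younger than the threshold, whose tips share one entity)
    first_tip <- first_descendant_tip(tree)
    entity_of_node <- setNames(
      as.integer(factor(clusters, levels = unique(clusters)))[
        match(tree$tip.label[first_tip[ev_nodes]], names(clusters))],
      ev_nodes)
  }

  m_events <- length(ev_nodes)
  # entity lineage counts grow from 1 at the threshold toward the present
  ent_counts <- rep(1L, max(1L, K))
  n_lineages <- 2L  # after the root event
  intervals <- vector("list", m_events)
  for (k in seq_len(m_events)) {
    t_hi <- ev_times[k]
    t_lo <- if (k < m_events) ev_times[k + 1L] else 0
    if (null_model || t_hi <= threshold) {
      j <- entity_of_node[[as.character(ev_nodes[k])]]
      ent_counts[j] <- ent_counts[j] + 1L
    }
    # configuration during the interval below this event
    n_div <- if (null_model) 0L else if (t_lo >= threshold) n_lineages else K
    m <- ent_counts * (ent_counts - 1L)
    intervals[[k]] <- list(x = t_hi - t_lo, n_div = n_div, m = m[m > 0L])
    n_lineages <- n_lineages + 1L
  }
  list(intervals = intervals, n_entities = K, root_time = root_time,
       null_model = null_model)
}

# index of one descendant tip for every node (tips map to themselves)
first_descendant_tip <- function(tree) {
  ntip <- ape::Ntip(tree)
  res <- integer(ntip + tree$Nnode)
  res[seq_len(ntip)] <- seq_len(ntip)
  edge <- tree$edge[ape::postorder(tree), , drop = FALSE]
  for (i in seq_len(nrow(edge))) {
    p <- edge[i, 1]; c <- edge[i, 2]
    if (res[p] == 0L) res[p] <- res[c]
  }
  res
}

# flat per-threshold tables for fast repeated likelihood evaluation
gmyc_eval_table <- function(iv) {
  x <- vapply(iv$intervals, `[[`, numeric(1), "x")
  n_div <- vapply(iv$intervals, `[[`, numeric(1), "n_div")
  m_len <- vapply(iv$intervals, function(i) length(i$m), integer(1))
  list(x = x, n_div = n_div,
       m_long = as.numeric(unlist(lapply(iv$intervals, `[[`, "m"))),
       m_idx = rep(seq_along(iv$intervals), times = m_len),
       n_int = length(iv$intervals))
}

gmyc_eval_loglik <- function(tab, lambda_div, p_div, lambda_coal, p_coal) {
  b <- numeric(tab$n_int)
  keep <- tab$n_div > 0
  if (any(keep)) b[keep] <- lambda_div * tab$n_div[keep]^p_div
  if (length(tab$m_long)) {
    s <- rowsum(tab$m_long^p_coal, tab$m_idx)
    b[as.integer(rownames(s))] <- b[as.integer(rownames(s))] +
      lambda_coal * as.numeric(s)
  }
  if (any(b <= 0)) return(-Inf)
  sum(log(b)) - sum(b * tab$x)
}

#' GMYC log-likelihood at fixed parameters
#'
#' Evaluates the single-threshold GMYC branching-times likelihood: each
#' inter-event interval of duration `x` contributes `log(b) - b * x`, where
#' `b = lambda_div * n_d^p_div + lambda_coal * sum_j (n_j (n_j - 1))^p_coal`
#' is the total branching rate in force during the interval (the rate
#' prefactor belonging to the branching event at the interval's older end).
#' A threshold older than the root yields the single-process null, in which
#' only the coalescent class acts.
#'
#' @param tree Ultrametric rooted `"phylo"` object.
#' @param threshold Threshold time before present in `(0, root time]` (any
#'   larger value gives the null model).
#' @param lambda_div,p_div Rate and scaling exponent of the diversification
#'   class.
#' @param lambda_coal,p_coal Rate and scaling exponent of the coalescent
#'   class.
#' @param tol Ultrametricity tolerance passed to [node_times()].
#' @return Log-likelihood (numeric scalar).
#' @export
gmyc_interval_loglik <- function(tree, threshold, lambda_div, p_div,
                                 lambda_coal, p_coal, tol = 1e-5) {
  if (lambda_div <= 0 || lambda_coal <= 0) stop("rates must be positive")
  iv <- gmyc_intervals(tree, threshold, tol = tol)
  gmyc_eval_loglik(gmyc_eval_table(iv), lambda_div, p_div, lambda_coal, p_coal)
}

# ML fit at one threshold: L-BFGS-B on (log lambda_div, p_div,
# log lambda_coal, p_coal) from one moment-matched start plus
# `restarts` random starts under a deterministic stream.
gmyc_fit_threshold <- function(tree, threshold, times, tol = 1e-5,
                               seed = 1, restarts = 5,
                               rate_bounds = c(1e-8, 1e6),
                               p_bounds = c(-3, 3)) {
  iv <- gmyc_intervals(tree, threshold, times = times, tol = tol)
  tab <- gmyc_eval_table(iv)
  # moment-matched start at p = 1: rate ~ events / exposure per class
  E_div <- sum(tab$x * tab$n_div)
  E_coal <- sum(tab$x[tab$m_idx] * tab$m_long)
  n_ev <- tab$n_int
  l0d <- if (E_div > 0) max(n_ev / E_div, 1e-6) else 1
  l0c <- if (E_coal > 0) max(n_ev / E_coal, 1e-6) else 1
  lb <- c(log(rate_bounds[1]), p_bounds[1], log(rate_bounds[1]), p_bounds[1])
  ub <- c(log(rate_bounds[2]), p_bounds[2], log(rate_bounds[2]), p_bounds[2])
  nll <- function(par)
    -gmyc_eval_loglik(tab, exp(par[1]), par[2], exp(par[3]), par[4])
  starts <- list(c(log(l0d), 1, log(l0c), 1))
  set.seed(derive_seed(seed, "gmyc_restarts"))
  for (r in seq_len(restarts))
    starts[[r + 1L]] <- c(stats::runif(1, log(1e-2), log(1e2)),
                          stats::runif(1, 0, 2),
                          stats::runif(1, log(1e-2), log(1e4)),
                          stats::runif(1, 0, 2))
  best <- NULL
  for (s0 in starts) {
    fit <- tryCatch(
      stats::optim(pmin(pmax(s0, lb), ub), nll, method = "L-BFGS-B",
                   lower = lb, upper = ub, control = list(maxit = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best))
    stop("GMYC optimisation failed at threshold ", signif(threshold, 6))
  list(threshold = threshold, lnl = -best$value,
       lambda_div = exp(best$par[1]), p_div = best$par[2],
       lambda_coal = exp(best$par[3]), p_coal = best$par[4],
       n_entities = iv$n_entities, null_model = iv$null_model)
}

#' Fit the single-threshold GMYC model
#'
#' Profiles the branching-times likelihood over candidate thresholds
#' (midpoints between consecutive distinct node times, one threshold younger
#' than every node, and one older than the root -- the single-process null),
#' fitting the class rates and scaling exponents at each threshold by
#' multi-start bounded quasi-Newton optimisation. The best threshold model is
#' compared to the null by a chi-squared likelihood-ratio test, and the
#' entities are the lineages crossing the maximum-likelihood threshold
#' (singletons count).
#'
#' @param tree Ultrametric rooted `"phylo"` with at least 3 tips.
#' @param lrt_df Degrees of freedom of the LRT (default 3: threshold plus one
#'   extra rate and one extra exponent; the literature is inconsistent).
#' @param tol Ultrametricity tolerance.
#' @param seed Integer seed for the optimiser's random restarts.
#' @param restarts Random restarts per threshold (besides a moment-matched
#'   deterministic start).
#' @return A `"gmyc_result"`: `threshold_time`, `entities` (named vector
#'   tip -> entity id), `n_entities`, `lnl_mixed`, `lnl_null`, fitted
#'   `params`, and `lrt` (a `"lrt_result"`).
#' @export
fit_gmyc <- function(tree, lrt_df = 3, tol = 1e-5, seed = 1, restarts = 5) {
  validate_tree(tree)
  if (ape::Ntip(tree) < 3L) stop("GMYC needs at least 3 tips")
  times <- node_times(tree, tol = tol)
  root_time <- max(times)
  bt <- sort(unique(unname(times[-seq_len(ape::Ntip(tree))])), decreasing = TRUE)
  cand <- numeric(0)
  if (length(bt) > 1L)
    cand <- (bt[-1L] + bt[-length(bt)]) / 2
  cand <- c(cand, bt[length(bt)] / 2)          # every tip its own entity
  null_fit <- gmyc_fit_threshold(tree, root_time * 1.5 + 1, times, tol,
                                 seed = seed, restarts = restarts)
  fits <- lapply(cand, gmyc_fit_threshold, tree = tree, times = times,
                 tol = tol, seed = seed, restarts = restarts)
  fits <- c(fits, list(null_fit))
  lnls <- vapply(fits, `[[`, numeric(1), "lnl")
  thrs <- vapply(fits, `[[`, numeric(1), "threshold")
  # ties broken toward the older threshold (fewer entities)
  best <- fits[[order(-round(lnls, 9), -thrs)[1]]]
  if (best$null_model) {
    entities <- setNames(rep("E1", ape::Ntip(tree)), tree$tip.label)
    threshold_time <- root_time
  } else {
    entities <- extract_clusters(tree, best$threshold, times = times)
    threshold_time <- best$threshold
  }
  D <- max(0, 2 * (best$lnl - null_fit$lnl))
  structure(list(
    threshold_time = threshold_time,
    entities = entities,
    n_entities = length(unique(entities)),
    lnl_mixed = best$lnl,
    lnl_null = null_fit$lnl,
    params = best[c("lambda_div", "p_div", "lambda_coal", "p_coal")],
    lrt = lrt_result(D, lrt_df)
  ), class = "gmyc_result")
}

#' @export
print.gmyc_result <- function(x, ...) {
  cat("GMYC single-threshold fit\n")
  cat(sprintf("  entities: %d   threshold time: %.6g\n", x$n_entities, x$threshold_time))
  cat(sprintf("  lnL mixed: %.4f   lnL null: %.4f\n", x$lnl_mixed, x$lnl_null))
  cat(sprintf("  LRT: D = %.4f, df = %d, p = %.4g\n", x$lrt$D, x$lrt$df, x$lrt$p))
  invisible(x)
}

#' Extract clusters (entities) at a threshold time
#'
#' Two tips share an entity iff their most recent common ancestor is
#' strictly younger than the threshold; a threshold older than the root
#' therefore yields a single entity.
#' Entity ids are stable: numbered by the first member in the tree's tip
#' order.
#'
#' @param tree Ultrametric rooted `"phylo"`.
#' @param threshold Positive time before present.
#' @param times Optional precomputed [node_times()].
#' @param tol Ultrametricity tolerance.
#' @return Named character vector tip label -> entity id (`"E1"`, `"E2"`, ...).
#' @export
extract_clusters <- function(tree, threshold, times = NULL, tol = 1e-5) {
  if (is.null(times)) times <- node_times(tree, tol = tol)
  if (threshold <= 0) stop("threshold must be positive")
  ntip <- ape::Ntip(tree)
  tvec <- unname(times)  # indexed by node number
  parent <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  # entity root: own time < T and parent's time >= T (the root, if younger
  # than T, roots the single entity)
  root_node <- ntip + 1L
  is_entity_root <- function(v) {
    tvec[v] < threshold && (v == root_node || tvec[parent[v]] >= threshold)
  }
  ent <- integer(ntip)
  eroots <- Filter(is_entity_root, seq_len(ntip + tree$Nnode))
  for (r in eroots) {
    tips <- if (r <= ntip) r else descendant_tips(tree, r)
    ent[tips] <- r
  }
  if (any(ent == 0L)) stop("internal error: tips without entity")  # nocov
  ids <- unique(ent[order(seq_len(ntip))])
  setNames(paste0("E", match(ent, ids)), tree$tip.label)
}

descendant_tips <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  if (node <= ntip) return(node)
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, descendant_tips, tree = tree))
}

#' Likelihood-ratio test result
#'
#' @param D Likelihood-ratio statistic `2 * delta lnL` (clamped at 0 for
#'   numerical jitter up to `1e-8`).
#' @param df Degrees of freedom.
#' @return A `"lrt_result"` with fields `D`, `df`, `p` (upper-tail
#'   chi-squared probability).
#' @export
lrt_result <- function(D, df) {
  if (D < 0) {
    if (D < -1e-8) stop("negative LRT statistic: ", D)
    D <- 0
  }
  structure(list(D = D, df = df, p = stats::pchisq(D, df, lower.tail = FALSE)),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT: D = %.4f, df = %d, p = %.4g\n", x$D, x$df, x$p))
  invisible(x)
}
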