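# Unordered-parsimony machinery for the binary sexual-system character.
#
# Tip codings: "G" (gonochoric), "A" (androdioecious), "GA" (polymorphic:
# both systems present in the STU, costing one within-STU step whichever
# state the tip node takes), "?" (unknown or equivocal: free ambiguity).
# Polytomies are handled by dynamic programming over node states (Sankoff
# with unit costs), which generalises the Fitch/Hartigan passes exactly.

MP_STATES <- c("G", "A")

validate_tip_states <- function(tree, states) {
  if (!ape::is.rooted(tree)) stop("parsimony mapping needs a rooted tree")
  missing <- setdiff(tree$tip.label, names(states))
  if (length(missing))
    stop("tips missing from states: ", paste(missing, collapse = ", "))
  states <- states[tree$tip.label]
  bad <- setdiff(unique(states), c("G", "A", "GA", "?"))
  if (length(bad)) stop("invalid state codes: ", paste(bad, collapse = ", "))
  states
}

# per-tip (cost, gains) contribution for tip-node state s; gains count
# within-STU acquisitions of `target` in polymorphic tips
tip_cost <- function(code, target) {
  # rows: state of the tip node (G, A); columns: changes, target gains
  switch(code,
    "G"  = matrix(c(0, 0, Inf, 0), 2, 2, byrow = TRUE),
    "A"  = matrix(c(Inf, 0, 0, 0), 2, 2, byrow = TRUE),
    "?"  = matrix(c(0, 0, 0, 0), 2, 2, byrow = TRUE),
    "GA" = matrix(c(1, as.numeric(target == "A"),
                    1, as.numeric(target == "G")), 2, 2, byrow = TRUE))
}

# Sankoff downward pass with edge cost BIG*[change] + [non-target -> target];
# BIG large enough that total changes dominate total gains lexicographically.
mp_down_pass <- function(tree, states, target = "A", BIG = NULL) {
  states <- validate_tip_states(tree, states)
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  if (is.null(BIG)) BIG <- 4 * nn + 4
  gain_to <- match(target, MP_STATES)
  # edge weight matrix w[s_parent, s_child]
  w <- matrix(0, 2, 2)
  w[1, 2] <- w[2, 1] <- BIG
  w[MP_STATES != target, gain_to] <- w[MP_STATES != target, gain_to] + 1
  down <- matrix(0, nn, 2)
  for (i in seq_len(ntip)) {
    tc <- tip_cost(states[[i]], target)
    down[i, ] <- BIG * tc[, 1] + tc[, 2]
  }
  po <- ape::postorder(tree)
  edge <- tree$edge
  for (e in po) {
    p <- edge[e, 1]; v <- edge[e, 2]
    # min over child state of (edge weight + child subtree cost)
    down[p, ] <- down[p, ] + c(min(w[1, ] + down[v, ]), min(w[2, ] + down[v, ]))
  }
  list(down = down, w = w, BIG = BIG, states = states, po = po)
}

#' Unordered maximum-parsimony ancestral reconstruction
#'
#' Computes the minimum number of character steps (including one within-STU
#' step per polymorphic tip) and, for every internal node, the set of states
#' realised by at least one most-parsimonious reconstruction (MPR). Nodes
#' whose MPR set is `{G, A}` are equivocal.
#'
#' @param tree Rooted `"phylo"` object (polytomies allowed; branch lengths
#'   ignored).
#' @param states Named character vector tip -> `"G"`, `"A"`, `"GA"`
#'   (polymorphic) or `"?"` (unknown).
#' @return An `"mp_result"`: `min_changes`, `node_state_sets` (list over
#'   internal node numbers), `equivocal_nodes` (integer node numbers).
#' @export
fitch_mp <- function(tree, states) {
  dp <- mp_down_pass(tree, states, target = "A")
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  BIG <- dp$BIG
  changes_of <- function(cost) floor((cost + 0.5) / BIG)
  root <- ntip + 1L
  # unit-cost DP values are the weighted ones integer-divided by BIG
  down_ch <- matrix(changes_of(dp$down), nn, 2)
  min_changes <- min(down_ch[root, ])
  # upward (outside-subtree) pass on unit costs
  up <- matrix(0, nn, 2)
  up[root, ] <- 0
  cost1 <- matrix(1, 2, 2) - diag(2)
  children <- split(tree$edge[, 2], tree$edge[, 1])
  for (e in rev(dp$po)) {   # preorder over edges
    p <- tree$edge[e, 1]; v <- tree$edge[e, 2]
    sibs <- setdiff(children[[as.character(p)]], v)
    sib_cost <- c(0, 0)
    for (s in sibs)
      sib_cost <- sib_cost + c(min(cost1[1, ] + down_ch[s, ]),
                               min(cost1[2, ] + down_ch[s, ]))
    tot_p <- up[p, ] + sib_cost
    up[v, ] <- c(min(tot_p + cost1[, 1]), min(tot_p + cost1[, 2]))
  }
  node_ids <- seq.int(ntip + 1L, nn)
  sets <- lapply(node_ids, function(v)
    MP_STATES[down_ch[v, ] + up[v, ] == min_changes])
  names(sets) <- node_ids
  equivocal <- node_ids[vapply(sets, length, integer(1)) == 2L]
  structure(list(min_changes = min_changes, node_state_sets = sets,
                 equivocal_nodes = equivocal),
            class = "mp_result")
}

#' @export
print.mp_result <- function(x, ...) {
  cat(sprintf("MP reconstruction: %d steps, %d equivocal internal nodes\n",
              x$min_changes, length(x$equivocal_nodes)))
  invisible(x)
}

# backtrack one optimal assignment of the weighted DP (min changes, then min
# target gains, the root's own target state counting as one gain)
mp_backtrack <- function(tree, dp, root_gain) {
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  root <- ntip + 1L
  assign <- integer(nn)
  assign[root] <- which.min(dp$down[root, ] + root_gain)
  for (e in rev(dp$po)) {
    p <- tree$edge[e, 1]; v <- tree$edge[e, 2]
    assign[v] <- which.min(dp$w[assign[p], ] + dp$down[v, ])
  }
  assign
}

#' Minimum number of independent origins of a state
#'
#' Over all most-parsimonious reconstructions, the minimum number of
#' independent acquisitions of the target state: branches on which the
#' character changes from non-target to target, within-tip steps at
#' polymorphic STUs, plus one if the root itself carries the target state
#' (an ancestral presence is one origin). Computed exactly by dynamic
#' programming over node states with a lexicographic (total changes, target
#' gains) objective. Tie-broken ACCTRAN-like and DELTRAN-like gain counts
#' are reported for transparency.
#'
#' @param tree Rooted `"phylo"`.
#' @param states Tip coding as in [fitch_mp()].
#' @param target `"A"` (default) or `"G"`.
#' @return An `"origin_count"`: `min_origins`, `min_changes`, `gains` (data
#'   frame of gain locations: `node`, `type` = branch/within_tip/root under
#'   one optimal MPR), `acctran`, `deltran`.
#' @export
count_origins <- function(tree, states, target = "A") {
  target <- match.arg(target, MP_STATES)
  dp <- mp_down_pass(tree, states, target = target)
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  tgt <- match(target, MP_STATES)
  root_gain <- as.numeric(MP_STATES == target)
  best <- min(dp$down[root, ] + root_gain)
  BIG <- dp$BIG
  min_changes <- floor((best + 0.5) / BIG)
  min_origins <- round(best - BIG * min_changes)
  assign <- mp_backtrack(tree, dp, root_gain)
  gains <- list()
  if (assign[root] == tgt)
    gains[[1]] <- data.frame(node = root, type = "root")
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; v <- tree$edge[e, 2]
    if (assign[p] != tgt && assign[v] == tgt)
      gains[[length(gains) + 1L]] <- data.frame(node = v, type = "branch")
  }
  for (i in seq_len(ntip)) {
    if (dp$states[[i]] == "GA" && assign[i] != tgt)
      gains[[length(gains) + 1L]] <- data.frame(node = i, type = "within_tip")
  }
  gains <- if (length(gains)) do.call(rbind, gains)
           else data.frame(node = integer(), type = character())
  structure(list(
    min_origins = min_origins,
    min_changes = min_changes,
    gains = gains,
    assign = assign,
    acctran = tiebreak_gains(tree, states, target, prefer_parent = FALSE),
    deltran = tiebreak_gains(tree, states, target, prefer_parent = TRUE)
  ), class = "origin_count")
}

#' @export
print.origin_count <- function(x, ...) {
  cat(sprintf("Minimum origins: %d (over MPRs with %d steps); ACCTRAN-like %d, DELTRAN-like %d\n",
              x$min_origins, x$min_changes, x$acctran, x$deltran))
  invisible(x)
}

# gains under a unit-cost MPR resolved top-down with a fixed tie-break
# (prefer_parent = TRUE delays changes, FALSE accelerates them)
tiebreak_gains <- function(tree, states, target, prefer_parent) {
  dp <- mp_down_pass(tree, states, target = target)
  ntip <- ape::Ntip(tree)
  BIG <- dp$BIG
  down_ch <- floor((dp$down + 0.5) / BIG)
  cost1 <- matrix(1, 2, 2) - diag(2)
  root <- ntip + 1L
  assign <- integer(ntip + tree$Nnode)
  assign[root] <- which.min(down_ch[root, ])
  for (e in rev(dp$po)) {
    p <- tree$edge[e, 1]; v <- tree$edge[e, 2]
    opts <- cost1[assign[p], ] + down_ch[v, ]
    cand <- which(opts == min(opts))
    assign[v] <- if (length(cand) == 1L) cand
                 else if (prefer_parent && assign[p] %in% cand) assign[p]
                 else if (!prefer_parent && length(setdiff(cand, assign[p])))
                   setdiff(cand, assign[p])[1]
                 else cand[1]
  }
  tgt <- match(target, MP_STATES)
  n <- sum(assign[tree$edge[, 1]] != tgt & assign[tree$edge[, 2]] == tgt)
  n + (assign[root] == tgt) +
    sum(vapply(seq_len(ntip), function(i)
      dp$states[[i]] == "GA" && assign[i] != tgt, logical(1)))
}

#' Decompose origin counts by named clades
#'
#' @param tree Rooted `"phylo"`.
#' @param origins An `"origin_count"` from [count_origins()].
#' @param clades Named list of tip-label vectors. A gain is attributed to a
#'   clade when every tip descending from the gain location belongs to it.
#' @return Named integer vector of per-clade gain counts (gains outside every
#'   clade are dropped).
#' @export
origins_per_clade <- function(tree, origins, clades) {
  stopifnot(inherits(origins, "origin_count"))
  gain_tips <- lapply(origins$gains$node, function(v)
    tree$tip.label[descendant_tips(tree, v)])
  vapply(clades, function(members)
    sum(vapply(gain_tips, function(tp) all(tp %in% members), logical(1))),
    integer(1))
}

#' Sexual-system parsimony coding from STU calls
#'
#' Maps classifier categories to the character coding used by the mapping
#' functions: gonochoric -> `"G"`, androdioecious -> `"A"`, polymorphic ->
#' `"GA"`, equivocal and no-data -> `"?"`.
#'
#' @param calls Data frame from [classify_sexual_systems()].
#' @return Named character vector stu -> state code.
#' @export
sexual_system_states <- function(calls) {
  map <- c(gonochoric = "G", androdioecious = "A", polymorphic = "GA",
           equivocal = "?", no_data = "?")
  setNames(unname(map[calls$category]), calls$stu)
}
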