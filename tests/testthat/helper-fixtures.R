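# shared helpers: small random instances built in code

# random rooted binary tree with uniform topology and exponential branch
# lengths (not ultrametric)
random_phylogram <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n)
  tr$edge.length <- stats::rexp(length(tr$edge.length), rate = 2)
  tr
}

# random tip coding over G/A with optional ambiguity codes
random_states <- function(tree, seed, codes = c("G", "A")) {
  set.seed(seed)
  setNames(sample(codes, ape::Ntip(tree), replace = TRUE), tree$tip.label)
}

# exhaustive minimum-change / minimum-origin search over all full node-state
# assignments; polymorphic ("GA") tips pay one within-tip step and gain the
# complementary state, "?" tips are free
enumerate_mp <- function(tree, states, target = "A") {
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  states <- states[tree$tip.label]
  choice <- lapply(seq_len(nn), function(v) {
    if (v > ntip) return(c("G", "A"))
    switch(states[[v]], G = "G", A = "A", c("G", "A"))
  })
  grid <- as.matrix(expand.grid(choice, stringsAsFactors = FALSE))
  best <- Inf; best_gain <- Inf
  root <- ntip + 1L
  for (r in seq_len(nrow(grid))) {
    asg <- grid[r, ]
    changes <- sum(asg[tree$edge[, 1]] != asg[tree$edge[, 2]])
    gains <- sum(asg[tree$edge[, 1]] != target & asg[tree$edge[, 2]] == target) +
      unname(asg[root] == target)  # ancestral presence is one origin
    for (i in seq_len(ntip)) {
      if (states[[i]] == "GA") {
        changes <- changes + 1L
        if (asg[i] != target) gains <- gains + 1L
      }
    }
    if (changes < best) { best <- changes; best_gain <- gains }
    else if (changes == best) best_gain <- min(best_gain, gains)
  }
  list(min_changes = best, min_origins = best_gain)
}

# brute-force Mk2 likelihood by summing over all internal-node assignments
enumerate_mk2_lik <- function(tree, states, q_ga, q_ag, prior = c(0.5, 0.5)) {
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  states <- states[tree$tip.label]
  idx <- c(G = 1L, A = 2L)
  choice <- lapply(seq_len(nn), function(v) {
    if (v > ntip) return(1:2)
    switch(states[[v]], G = 1L, A = 2L, 1:2)
  })
  grid <- as.matrix(expand.grid(choice))
  root <- ntip + 1L
  P <- lapply(seq_len(nrow(tree$edge)), function(e)
    mk2_transition_matrix(q_ga, q_ag, tree$edge.length[e]))
  tot <- 0
  for (r in seq_len(nrow(grid))) {
    asg <- grid[r, ]
    pr <- prior[asg[root]]
    for (e in seq_len(nrow(tree$edge)))
      pr <- pr * P[[e]][asg[tree$edge[e, 1]], asg[tree$edge[e, 2]]]
    tot <- tot + pr
  }
  tot
}

# brute-force marginal probability of state s at node v
enumerate_mk2_marginal <- function(tree, states, q_ga, q_ag, node,
                                   prior = c(0.5, 0.5)) {
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  states <- states[tree$tip.label]
  choice <- lapply(seq_len(nn), function(v) {
    if (v > ntip) return(1:2)
    switch(states[[v]], G = 1L, A = 2L, 1:2)
  })
  grid <- as.matrix(expand.grid(choice))
  root <- ntip + 1L
  P <- lapply(seq_len(nrow(tree$edge)), function(e)
    mk2_transition_matrix(q_ga, q_ag, tree$edge.length[e]))
  num <- c(0, 0); tot <- 0
  for (r in seq_len(nrow(grid))) {
    asg <- grid[r, ]
    pr <- prior[asg[root]]
    for (e in seq_len(nrow(tree$edge)))
      pr <- pr * P[[e]][asg[tree$edge[e, 1]], asg[tree$edge[e, 2]]]
    tot <- tot + pr
    num[asg[node]] <- num[asg[node]] + pr
  }
  num / tot
}
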