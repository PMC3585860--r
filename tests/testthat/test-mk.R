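test_that("Mk2 transition matrix has the closed form", {
  expect_equal(mk2_transition_matrix(1, 2, 0), diag(2), ignore_attr = TRUE)
  P <- mk2_transition_matrix(1, 1, 0.5)
  expect_equal(P[1, 1], 0.5 * (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(rowSums(P), c(G = 1, A = 1))
  # long-branch limit: rows tend to the stationary distribution
  Pl <- mk2_transition_matrix(1, 3, 1e4)
  expect_equal(unname(Pl[1, ]), c(3, 1) / 4, tolerance = 1e-10)
  expect_equal(unname(Pl[2, ]), c(3, 1) / 4, tolerance = 1e-10)
  expect_error(mk2_transition_matrix(-1, 1, 1), ">= 0")
  expect_error(mk2_transition_matrix(1, 1, -1), ">= 0")
})

test_that("pruning likelihood equals enumeration over internal assignments", {
  # frozen chain: zero rates, uniform root, all tips G
  tr <- read_newick("((t1:1,t2:1):1,(t3:1,t4:1):1);")
  allG <- setNames(rep("G", 4), paste0("t", 1:4))
  expect_equal(mk2_loglik(tr, allG, 0, 0), log(0.5), tolerance = 1e-12)

  for (s in 1:12) {
    tr <- random_phylogram(sample(4:6, 1), seed = 600 + s)
    st <- random_states(tr, seed = 700 + s, codes = c("G", "A", "GA", "?"))
    if (all(st %in% c("GA", "?"))) st[1] <- "G"
    q <- exp(stats::runif(2, -2, 1.5))
    expect_equal(mk2_loglik(tr, st, q[1], q[2]),
                 log(enumerate_mk2_lik(tr, st, q[1], q[2])),
                 tolerance = 1e-10, label = paste("seed", s))
  }
})

test_that("likelihood symmetries hold", {
  tr <- random_phylogram(8, seed = 42)
  st <- random_states(tr, seed = 43, codes = c("G", "A"))
  # relabelling symmetry: swap states and rates
  st_swap <- setNames(ifelse(st == "G", "A", "G"), names(st))
  expect_equal(mk2_loglik(tr, st, 0.7, 1.9), mk2_loglik(tr, st_swap, 1.9, 0.7),
               tolerance = 1e-12)
  # branch-length/rate scale invariance
  tr2 <- tr; tr2$edge.length <- tr$edge.length * 3.7
  expect_equal(mk2_loglik(tr, st, 0.7, 1.9),
               mk2_loglik(tr2, st, 0.7 / 3.7, 1.9 / 3.7), tolerance = 1e-8)
})

test_that("model fits are nested and handle boundary data", {
  tr <- simulate_yule(40, 1, seed = 8)
  st <- simulate_mk2(tr, 1, 2, seed = 8)
  fits <- lapply(c("UNRESTRICTED", "EQUAL_RATES", "GA_ZERO", "AG_ZERO"),
                 function(m) fit_mk2(tr, st, m))
  names(fits) <- c("ARD", "ER", "noGA", "noAG")
  expect_gte(fits$ARD$lnl, fits$ER$lnl - 1e-6)
  expect_gte(fits$ARD$lnl, fits$noGA$lnl - 1e-6)
  expect_gte(fits$ARD$lnl, fits$noAG$lnl - 1e-6)
  expect_equal(fits$ER$q_ga, fits$ER$q_ag)
  expect_equal(fits$noGA$q_ga, 0)
  expect_equal(fits$noAG$q_ag, 0)

  lrt <- compare_models(fits$ARD, fits$ER)
  expect_equal(lrt$df, 1L)
  expect_gte(lrt$D, 0)
  expect_error(compare_models(fits$ER, fits$ARD), "not nested|below")

  # perfectly conserved character: equal-rates ML sits at the lower bound
  # with lnl -> ln(0.5) under the uniform root prior
  allG <- setNames(rep("G", ape::Ntip(tr)), tr$tip.label)
  expect_warning(cons <- fit_mk2(tr, allG, "EQUAL_RATES"), "boundary")
  expect_equal(cons$lnl, log(0.5), tolerance = 1e-4)
  expect_lte(cons$q_ga, 1e-6)
  # the unrestricted fit can only improve on it (loss rate unbounded)
  expect_warning(cons2 <- fit_mk2(tr, allG, "UNRESTRICTED"), "boundary")
  expect_gte(cons2$lnl, cons$lnl - 1e-6)
  expect_lte(cons2$q_ga, 1e-6)

  expect_error(fit_mk2(tr, setNames(rep("?", ape::Ntip(tr)), tr$tip.label)),
               "ambiguous")
})

test_that("fitted likelihoods agree with phytools on definite data", {
  tr <- simulate_yule(30, 1, seed = 77)
  st <- simulate_mk2(tr, 1.5, 2.5, seed = 77)
  f <- fit_mk2(tr, st, "UNRESTRICTED")
  ref <- phytools::fitMk(tr, setNames(factor(st, levels = c("G", "A")),
                                      names(st)),
                         model = "ARD", pi = c(0.5, 0.5))
  # same likelihood at the reference implementation's own rates
  q_ga_ref <- ref$rates[ref$index.matrix[1, 2]]
  q_ag_ref <- ref$rates[ref$index.matrix[2, 1]]
  expect_equal(mk2_loglik(tr, st, q_ga_ref, q_ag_ref),
               as.numeric(stats::logLik(ref)), tolerance = 1e-4)
  expect_gte(f$lnl, as.numeric(stats::logLik(ref)) - 1e-3)
})

test_that("marginal reconstructions match brute-force marginalisation", {
  tr <- read_newick("((t1:0.6,t2:1.1):0.4,(t3:0.8,t4:0.3):0.9);")
  st <- setNames(c("G", "A", "G", "G"), paste0("t", 1:4))
  fit <- list(q_ga = 0.8, q_ag = 1.4, root_prior = "uniform")
  m <- marginal_asr(tr, st, fit)
  expect_equal(unname(rowSums(m)), rep(1, nrow(m)), tolerance = 1e-12)
  for (v in as.integer(rownames(m)))
    expect_equal(unname(m[as.character(v), ]),
                 enumerate_mk2_marginal(tr, st, 0.8, 1.4, v),
                 tolerance = 1e-10)

  # zero rates with uniform data pin every node
  mG <- marginal_asr(tr, setNames(rep("G", 4), paste0("t", 1:4)),
                     list(q_ga = 0, q_ag = 0, root_prior = "uniform"))
  expect_equal(unname(mG[, "G"]), rep(1, 3))

  # symmetric rates and state-symmetric data: root at (0.5, 0.5)
  sym <- marginal_asr(read_newick("((t1:1,t2:1):1,(t3:1,t4:1):1);"),
                      setNames(c("G", "A", "A", "G"), paste0("t", 1:4)),
                      list(q_ga = 1, q_ag = 1, root_prior = "uniform"))
  expect_equal(unname(sym["5", ]), c(0.5, 0.5), tolerance = 1e-10)
})
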