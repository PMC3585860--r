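test_that("generators are seed-deterministic", {
  expect_equal(write_newick(simulate_yule(10, 1, seed = 3)),
               write_newick(simulate_yule(10, 1, seed = 3)))
  expect_false(write_newick(simulate_yule(10, 1, seed = 3)) ==
               write_newick(simulate_yule(10, 1, seed = 4)))
  tr <- simulate_yule(10, 1, seed = 3)
  expect_equal(simulate_mk2(tr, 1, 2, seed = 5), simulate_mk2(tr, 1, 2, seed = 5))
  g <- setNames(rep(c(0, 1), 5), tr$tip.label)
  expect_equal(simulate_lambda_trait(tr, 0.5, 10, 2, g, seed = 6),
               simulate_lambda_trait(tr, 0.5, 10, 2, g, seed = 6))
})

test_that("Yule trees are ultrametric with the requested size", {
  tr <- simulate_yule(17, 0.8, seed = 12)
  expect_equal(ape::Ntip(tr), 17L)
  expect_silent(node_times(tr))  # ultrametricity validated inside
  expect_error(simulate_yule(1, 1, seed = 1), "at least 2")
  # two tips: a single split
  expect_equal(simulate_yule(2, 1, seed = 1)$Nnode, 1L)
})

test_that("species coalescent grafting conserves structure", {
  sp <- simulate_yule(5, 1, seed = 7)
  gt <- simulate_species_coalescent(sp, 4, 0.05, seed = 7)
  expect_equal(ape::Ntip(gt), 20L)
  expect_silent(node_times(gt))  # gene tree stays ultrametric
  # species are monophyletic and shallow relative to the species tree
  for (s in sp$tip.label) {
    tips <- grep(paste0("^", s, "_"), gt$tip.label, value = TRUE)
    expect_equal(length(tips), 4L)
    expect_true(ape::is.monophyletic(gt, tips))
  }
  # single tip per species: the gene tree is the species tree
  gt1 <- simulate_species_coalescent(sp, 1, 0.05, seed = 7)
  expect_equal(ape::Ntip(gt1), 5L)
  expect_true(ape::all.equal.phylo(gt1, sp, use.edge.length = TRUE,
                                   tolerance = 1e-8))
  expect_error(simulate_species_coalescent(sp, 4, 1.5, seed = 1), "< 1")
})

test_that("Mk simulation respects degenerate and stationary regimes", {
  tr <- simulate_yule(12, 1, seed = 14)
  expect_true(all(simulate_mk2(tr, 1e-12, 1e-12, root_state = "A", seed = 1) == "A"))
  # a very long single branch reaches the stationary distribution
  long <- read_newick("(x:200,y:200);")
  hits <- vapply(1:400, function(s)
    simulate_mk2(long, 1, 3, root_state = "G", seed = s)[["x"]] == "G",
    logical(1))
  # stationary P(G) = q_ag / (q_ga + q_ag) = 0.75; binomial 3-sigma band
  expect_lt(abs(mean(hits) - 0.75), 3 * sqrt(0.75 * 0.25 / 400))
})

test_that("lambda traits carry the requested group effect and independence limit", {
  tr <- simulate_yule(10, 1, seed = 16)
  g <- setNames(rep(c(0, 1), 5), tr$tip.label)
  tab <- simulate_lambda_trait(tr, 0.5, 9, 100, g, seed = 16)
  expect_gt(mean(tab$latitude[tab$ad_present == 1]),
            mean(tab$latitude[tab$ad_present == 0]) + 50)
  # lambda = 0: sample covariance between sister tips vanishes over seeds
  pair_tree <- read_newick("((a:0.05,b:0.05):0.95,c:1);")
  gp <- c(a = 0, b = 0, c = 0)
  ab <- t(vapply(1:300, function(s) {
    d <- simulate_lambda_trait(pair_tree, 0, 1, 0, gp, seed = s)
    c(d$latitude[d$taxon == "a"], d$latitude[d$taxon == "b"])
  }, numeric(2)))
  expect_lt(abs(cor(ab[, 1], ab[, 2])), 0.15)
  # lambda = 1 on the same near-identical pair: strong correlation
  ab1 <- t(vapply(1:300, function(s) {
    d <- simulate_lambda_trait(pair_tree, 1, 1, 0, gp, seed = s)
    c(d$latitude[d$taxon == "a"], d$latitude[d$taxon == "b"])
  }, numeric(2)))
  expect_gt(cor(ab1[, 1], ab1[, 2]), 0.8)
  # clamping keeps latitudes in range
  cl <- simulate_lambda_trait(tr, 0.5, 2000, 0, g, seed = 18, clamp = TRUE)
  expect_true(all(cl$latitude >= 0 & cl$latitude <= 90))
})

test_that("fixture studies are self-consistent and byte-reproducible", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  cf <- sim_config(seed = 5, n_species = 30)
  fx <- make_fixture_study(cf, dir = dir1)
  fx2 <- make_fixture_study(cf, dir = dir2)

  # same seed, byte-identical bundle
  for (f in list.files(dir1))
    expect_equal(readLines(file.path(dir1, f)), readLines(file.path(dir2, f)),
                 label = f)

  # classifier recovers the generating sexual systems
  calls <- classify_sexual_systems(read_sex_evidence(fx$paths$evidence))
  truth_cat <- ifelse(fx$truth == "A", "androdioecious", "gonochoric")
  expect_gte(mean(calls$category == truth_cat[calls$stu]), 0.95)

  # supermatrix missingness lands near the configured dropout
  expect_lt(abs(fx$supermatrix$missing_fraction - cf$dropout), 0.05)
  expect_equal(ape::Ntip(fx$gene_tree),
               cf$n_species * cf$tips_per_species)

  # written formats are readable by the package's own readers
  expect_silent(read_newick(file = fx$paths$gene_tree))
  expect_silent(read_trait_table(fx$paths$traits))
  coi <- read_fasta(fx$paths$fasta_coi, gene = "coi")
  expect_equal(length(coi$seqs), cf$n_species)
})

test_that("a strong-effect synthetic study reproduces the headline pattern", {
  hits <- vapply(1:10, function(s) {
    fx <- make_fixture_study(sim_config(seed = 100 + s, n_species = 25,
                                        group_effect = 15, noise_sigma2 = 64))
    res <- phylogenetic_t_test(fx$species_tree, fx$traits)
    res$group_means$raw[["g1"]] > res$group_means$raw[["g0"]] && res$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
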