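# Seed-deterministic generators emulating the statistical structure of the
# study data: deep Yule species divergence with shallow within-species
# coalescence (the GMYC regime), binary characters under the Mk2 process,
# lambda-Brownian latitude traits with a group offset, and full study bundles
# (alignments with taxon dropout, evidence tables, trait tables).

# one pseudo-random stream per operation: sub-seed derived from
# (seed, operation name) so adding operations never perturbs existing draws
derive_seed <- function(seed, op) {
  h <- sum(utf8ToInt(op) * seq_along(utf8ToInt(op)) * 131)
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

#' Simulation configuration for synthetic study bundles
#'
#' Defaults mirror the regimes the analyses assume: 30 species-level units,
#' within-species coalescent depth 2\% of tree height (deep barcode gaps),
#' Mk rates with an A-to-G : G-to-A ratio of 3, moderate phylogenetic signal
#' in latitude (lambda 0.5), a 12-degree androdioecy latitude offset on a
#' gonochoric baseline of 37 degrees, and ~50\% supermatrix dropout.
#'
#' @param seed Integer master seed.
#' @param n_species Number of species (STUs).
#' @param birth_rate Yule speciation rate.
#' @param coalescent_depth_ratio Expected within-species coalescent depth as
#'   a fraction of species-tree height, in `(0, 1)`.
#' @param tips_per_species Sampled haplotypes per species.
#' @param q_ga,q_ag Mk2 transition rates (per unit branch length).
#' @param lambda_true Pagel's lambda of the latitude trait.
#' @param group_effect Androdioecy latitude offset (degrees).
#' @param base_latitude Gonochoric baseline latitude (degrees).
#' @param noise_sigma2 Brownian rate of the latitude trait (degrees^2 per
#'   unit tree height).
#' @param ad_prob Probability a species is androdioecious.
#' @param dropout Target supermatrix missing-data fraction.
#' @param pop_sample Individuals sexed per population.
#' @return A `"sim_config"` list.
#' @export
sim_config <- function(seed = 1, n_species = 30, birth_rate = 1,
                       coalescent_depth_ratio = 0.02, tips_per_species = 4,
                       q_ga = 1, q_ag = 3, lambda_true = 0.5,
                       group_effect = 12, base_latitude = 37,
                       noise_sigma2 = 100, ad_prob = 0.25, dropout = 0.5,
                       pop_sample = 200) {
  stopifnot(n_species >= 2, birth_rate > 0,
            coalescent_depth_ratio > 0, coalescent_depth_ratio < 1,
            tips_per_species >= 1, q_ga > 0, q_ag > 0,
            lambda_true >= 0, lambda_true <= 1, noise_sigma2 > 0,
            dropout >= 0, dropout < 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate an ultrametric Yule (pure-birth) tree
#'
#' @param n_tips Number of tips (>= 2).
#' @param birth_rate Speciation rate.
#' @param seed Integer seed (reproducible per seed).
#' @return Ultrametric `"phylo"`, tips `t1..tn`.
#' @export
simulate_yule <- function(n_tips, birth_rate = 1, seed = 1) {
  if (n_tips < 2) stop("need at least 2 tips")
  set.seed(derive_seed(seed, "yule"))
  tr <- ape::rphylo(n_tips, birth = birth_rate, death = 0)
  tr$tip.label <- paste0("t", seq_len(n_tips))
  tr
}

# random-join Kingman coalescent of k tips with given total depth scale;
# returns newick (no trailing semicolon) and realised depth
sim_coalescent_subtree <- function(labels, theta) {
  k <- length(labels)
  if (k == 1L) return(list(newick = labels, depth = 0))
  sub <- as.list(labels)
  heights <- rep(0, k)
  t <- 0
  while (length(sub) > 1L) {
    j <- length(sub)
    t <- t + stats::rexp(1, rate = j * (j - 1) / 2 / theta)
    pick <- sample.int(j, 2)
    merged <- sprintf("(%s:%.10g,%s:%.10g)",
                      sub[[pick[1]]], t - heights[pick[1]],
                      sub[[pick[2]]], t - heights[pick[2]])
    sub <- c(sub[-pick], merged)
    heights <- c(heights[-pick], t)
  }
  list(newick = sub[[1]], depth = t)
}

#' Graft within-species coalescents onto a species tree
#'
#' Each species tip is replaced by a Kingman coalescent of
#' `tips_per_species` haplotypes (labelled `<species>_1..`), scaled so the
#' expected within-species depth is `coalescent_depth_ratio` times the
#' species-tree height; a realised depth exceeding 90\% of the species'
#' terminal branch is rescaled to fit, keeping the gene tree ultrametric and
#' species monophyletic.
#'
#' @param species_tree Ultrametric `"phylo"`.
#' @param tips_per_species Haplotypes per species.
#' @param coalescent_depth_ratio In `(0, 1)`.
#' @param seed Integer seed.
#' @return Ultrametric gene tree (`"phylo"`) with
#'   `n_species * tips_per_species` tips.
#' @export
simulate_species_coalescent <- function(species_tree, tips_per_species,
                                        coalescent_depth_ratio, seed = 1) {
  if (coalescent_depth_ratio >= 1) stop("coalescent_depth_ratio must be < 1")
  times <- node_times(species_tree)  # validates ultrametricity
  H <- max(times)
  set.seed(derive_seed(seed, "species_coalescent"))
  k <- tips_per_species
  theta <- if (k > 1) coalescent_depth_ratio * H / (2 * (1 - 1 / k)) else 0
  nwk <- ape::write.tree(species_tree, digits = 12)
  # terminal branch length per tip (from the newick we rewrite)
  term <- setNames(species_tree$edge.length[
    match(seq_len(ape::Ntip(species_tree)), species_tree$edge[, 2])],
    species_tree$tip.label)
  for (sp in species_tree$tip.label) {
    sub <- sim_coalescent_subtree(paste0(sp, "_", seq_len(k)), theta)
    depth <- sub$depth
    newick <- sub$newick
    if (k > 1 && depth > 0.9 * term[[sp]]) {
      f <- 0.9 * term[[sp]] / depth
      newick <- rescale_newick_lengths(newick, f)
      depth <- depth * f
    }
    if (k > 1) {
      pat <- sprintf("(?<![A-Za-z0-9_])%s:([0-9.eE+-]+)", sp)
      m <- regexpr(pat, nwk, perl = TRUE)
      stopifnot(m > 0)
      len <- as.numeric(sub("^[^:]*:", "", regmatches(nwk, m)))
      regmatches(nwk, m) <- sprintf("%s:%.12g", newick, len - depth)
    }
  }
  read_newick(text = paste0(nwk, if (!grepl(";\\s*$", nwk)) ";" else ""))
}

# multiply every branch length in a newick fragment by f
rescale_newick_lengths <- function(nwk, f) {
  m <- gregexpr(":[0-9.eE+-]+", nwk)
  regmatches(nwk, m) <- list(sprintf(":%.12g",
    f * as.numeric(sub(":", "", regmatches(nwk, m)[[1]]))))
  nwk
}

#' Simulate a binary character under the Mk2 process
#'
#' Walks the tree from a root state, drawing each node's state from the
#' closed-form transition matrix of its parent edge.
#'
#' @param tree `"phylo"` with branch lengths.
#' @param q_ga,q_ag Transition rates.
#' @param root_state `"G"` or `"A"`.
#' @param seed Integer seed.
#' @return Named character vector tip -> `"G"`/`"A"`.
#' @export
simulate_mk2 <- function(tree, q_ga, q_ag, root_state = "G", seed = 1) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  root_state <- match.arg(root_state, c("G", "A"))
  set.seed(derive_seed(seed, "mk2"))
  ntip <- ape::Ntip(tree)
  state <- integer(ntip + tree$Nnode)
  state[ntip + 1L] <- match(root_state, c("G", "A"))
  for (e in rev(ape::postorder(tree))) {  # preorder
    p <- tree$edge[e, 1]; v <- tree$edge[e, 2]
    P <- mk2_transition_matrix(q_ga, q_ag, tree$edge.length[e])
    state[v] <- sample.int(2, 1, prob = P[state[p], ])
  }
  setNames(c("G", "A")[state[seq_len(ntip)]], tree$tip.label)
}

#' Simulate a lambda-Brownian trait with a binary group offset
#'
#' Draws tip values from a multivariate normal with covariance
#' `noise_sigma2 * lambda_cov(C, lambda_true)` around
#' `base + group_effect * group`.
#'
#' @param tree Rooted `"phylo"` with branch lengths.
#' @param lambda_true Pagel's lambda in `[0, 1]`.
#' @param noise_sigma2 Brownian rate, in trait units squared per unit of
#'   relative tree height (the shared-path matrix is normalised by the tree
#'   height, so a tip's marginal variance is `noise_sigma2` whatever the
#'   tree's absolute depth).
#' @param group_effect Additive offset for group 1.
#' @param groups Named 0/1 vector over all tips.
#' @param seed Integer seed.
#' @param base Baseline trait value.
#' @param clamp If `TRUE`, clamp values into `[0, 90]` (latitudes).
#' @return Data frame `taxon`, `latitude`, `ad_present`.
#' @export
simulate_lambda_trait <- function(tree, lambda_true, noise_sigma2,
                                  group_effect, groups, seed = 1,
                                  base = 37, clamp = FALSE) {
  g <- groups[tree$tip.label]
  if (anyNA(g)) stop("groups must cover all tips")
  set.seed(derive_seed(seed, "lambda_trait"))
  C <- shared_path_matrix(tree)
  C <- C / max(diag(C))
  V <- noise_sigma2 * lambda_cov(C, lambda_true)
  dev <- MASS::mvrnorm(1, mu = rep(0, nrow(V)), Sigma = V)
  y <- base + group_effect * as.numeric(g) + dev
  if (clamp) y <- pmin(90, pmax(0, y))
  data.frame(taxon = tree$tip.label, latitude = unname(y),
             ad_present = as.numeric(g), stringsAsFactors = FALSE)
}

#' Generate a complete synthetic study bundle
#'
#' Produces a self-consistent study in the on-disk formats the analysis
#' functions consume: a Yule species tree; an ultrametric barcode-like gene
#' tree with within-species coalescence; per-gene alignments (random bases;
#' sequence evolution is out of scope) with taxon dropout targeting the
#' configured supermatrix missingness (the first, barcode-like gene is kept
#' complete); a two-population evidence table per species in which gonochoric
#' populations draw male counts around 50\% and androdioecious ones around
#' 10\% with occasional ovotestis/isolation records; and a latitude trait
#' table with the configured lambda, Brownian rate and group offset.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed); `NULL` skips writing.
#' @return List with the species tree, gene tree, gene alignments,
#'   supermatrix, evidence table, true systems, trait table, and file paths
#'   (when written).
#' @export
make_fixture_study <- function(config = sim_config(), dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  sp_tree <- simulate_yule(cf$n_species, cf$birth_rate, seed = cf$seed)
  sp_tree$tip.label <- sprintf("sp%02d", seq_len(cf$n_species))
  gene_tree <- simulate_species_coalescent(sp_tree, cf$tips_per_species,
                                           cf$coalescent_depth_ratio,
                                           seed = cf$seed)
  # true sexual systems: Bernoulli(ad_prob), at least one of each
  set.seed(derive_seed(cf$seed, "true_systems"))
  repeat {
    truth <- ifelse(stats::runif(cf$n_species) < cf$ad_prob, "A", "G")
    if (length(unique(truth)) == 2L) break
  }
  names(truth) <- sp_tree$tip.label

  # evidence: two sexed populations per species
  set.seed(derive_seed(cf$seed, "evidence"))
  ev <- do.call(rbind, lapply(sp_tree$tip.label, function(sp) {
    p_true <- if (truth[[sp]] == "A") 0.10 else 0.50
    males <- stats::rbinom(2, cf$pop_sample, p_true)
    ratio <- sprintf("%.1f", 100 * males / cf$pop_sample)
    ovo <- if (truth[[sp]] == "A") ifelse(stats::runif(2) < 0.5, "yes", "") else ""
    data.frame(stu = sp, population_id = paste0(sp, "_pop", 1:2),
               male_ratio = ratio, repro_isolation = "",
               ovotestis = ovo, stringsAsFactors = FALSE)
  }))

  # gene alignments: barcode gene complete, others with dropout tuned so the
  # overall supermatrix missingness matches the configured target
  set.seed(derive_seed(cf$seed, "alignments"))
  gene_len <- c(coi = 600, g2 = 500, g3 = 450, g4 = 700, g5 = 650,
                g6 = 550, g7 = 800)
  total <- sum(gene_len)
  drop_rate <- min(0.95, cf$dropout * total / (total - gene_len[[1]]))
  genes <- lapply(seq_along(gene_len), function(i) {
    L <- gene_len[[i]]
    present <- if (i == 1L) rep(TRUE, cf$n_species)
               else stats::runif(cf$n_species) > drop_rate
    if (!any(present)) present[sample.int(cf$n_species, 1)] <- TRUE
    taxa <- sp_tree$tip.label[present]
    seqs <- vapply(taxa, function(tx)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
      character(1))
    gene_alignment(seqs, gene = names(gene_len)[i])
  })
  sm <- concatenate_genes(genes)

  traits <- simulate_lambda_trait(sp_tree, cf$lambda_true, cf$noise_sigma2,
                                  cf$group_effect,
                                  groups = setNames(as.numeric(truth == "A"),
                                                    names(truth)),
                                  seed = cf$seed, base = cf$base_latitude)
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      species_tree = file.path(dir, "species_tree.nwk"),
      gene_tree = file.path(dir, "gene_tree.nwk"),
      evidence = file.path(dir, "evidence.tsv"),
      traits = file.path(dir, "traits.tsv"))
    write_newick(sp_tree, paths$species_tree)
    write_newick(gene_tree, paths$gene_tree)
    write.table(ev, paths$evidence, sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(traits, paths$traits, sep = "\t", quote = FALSE, row.names = FALSE)
    for (g in genes) {
      paths[[paste0("fasta_", g$gene)]] <- file.path(dir, paste0(g$gene, ".fasta"))
      write_fasta(g, paths[[paste0("fasta_", g$gene)]])
    }
  }
  list(config = cf, species_tree = sp_tree, gene_tree = gene_tree,
       genes = genes, supermatrix = sm, evidence = ev, truth = truth,
       traits = traits, paths = paths)
}
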