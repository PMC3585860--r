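---
title: "Models and methods: sexual-system lability on phylogenies"
author: "notosex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: sexual-system lability on phylogenies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(notosex)
```

This vignette documents the models the package implements, the assumptions
behind them, the numerical choices made where the design was genuinely open,
and what the synthetic-data generators do and do not emulate. The running
biological question is the evolution of androdioecy (males coexisting with
self-fertile hermaphrodites) against gonochorism (separate sexes) in tadpole
shrimps, but every component is generic over rooted trees and binary
characters.

## 1. GMYC species delimitation

The single-threshold generalized mixed Yule-coalescent model describes the
branching times of an ultrametric barcode tree. A threshold age `T`
partitions events: branching older than `T` belongs to a diversification
class (speciation among the lineages that will cross `T`); branching younger
than `T` is coalescence within the entities defined by the lineages crossing
`T`. During an inter-event interval the total branching rate is

    b = lambda_div * n_d^p_div  +  lambda_coal * sum_j (n_j (n_j - 1))^p_coal

where `n_d` is the diversification lineage count (frozen at the number of
entities K below `T`), `n_j` is entity j's lineage count, and the scaling
exponents `p` interpolate between density-independent (0) and linear-in-the-
canonical-units (1) branching. Singleton entities contribute nothing to the
coalescent sum. The log-likelihood is the branching-times (lineage-through-
time) density `sum_i [log b_i - b_i x_i]` over all inter-event intervals,
each interval carrying the rate in force during it; the interval reaching
the present contributes its exposure with the youngest event's prefactor.
The one-process null is the same likelihood with a threshold older than the
root: one entity, coalescent class only.

We deliberately use the *total* rate `b_i` as each interval's prefactor
rather than the class-specific component of the terminating event. The
alternatives were implemented and rejected on behavioural grounds:
class-specific prefactors let a single flexible class absorb clustered data
(delimitation collapses), while adding labeled-topology ("which pair")
factors lets any threshold trivially match its own clades, so single-process
trees always reject the null. The total-rate form reproduces both hallmarks
of the method: on trees simulated with deep species divergence and shallow
coalescence the modal recovered entity count equals the simulated species
number, and on pure Yule trees the null is accepted at roughly the nominal
rate (the LRT statistic averages about its degrees of freedom).

Numerical choices:

- Candidate thresholds are the midpoints between consecutive distinct node
  ages, plus one younger than every node (every tip its own entity) and one
  older than the root (the null). Ties in likelihood break toward the older
  threshold — conservative splitting.
- At each threshold the four parameters are fitted by bounded L-BFGS-B on
  `(log lambda_div, p_div, log lambda_coal, p_coal)` with rate bounds
  `[1e-8, 1e6]`, exponent bounds `[-3, 3]`, one moment-matched start
  (`p = 1`, rate = events/exposure) and five seeded random restarts; the
  likelihood surface is multimodal in the exponents.
- The LRT against the null uses 3 degrees of freedom by default (threshold
  plus one extra rate and one extra exponent); the literature is
  inconsistent on this, so it is a `fit_gmyc(lrt_df = )` argument.
- Ultrametricity is checked to a relative tolerance of `1e-5` of tree
  height; chronograms from posterior samplers carry rounding noise.

## 2. Supermatrix and distances

`concatenate_genes` unions the taxa over all genes, fills absent taxon–gene
blocks with `?`, and records 1-based inclusive partitions in the RAxML
dialect. The missing-data fraction counts only those absent blocks over
(taxa × total length): alignment gaps (`-`) are indels carried by present
sequences, not missing data, and `N` is ambiguity. For distances,
`p_distance_matrix` applies *complete deletion* — any column holding `-`,
`?` or `N` in any row is removed once, globally — then the uncorrected
proportion of differing sites; between-cluster means average over all
inter-cluster pairs. p-distances are proportions in [0, 1] and do not
satisfy the triangle inequality, which is not asserted anywhere.

## 3. Sexual-system classification

Males are morphologically identifiable, but females and hermaphrodites are
externally identical, so hermaphroditism must be established by histology
(an ovotestis) or by reproduction in isolation (counted only when
reproduction with males was also confirmed, to exclude husbandry failures).
Sex ratios alone are informative because androdioecious populations are
hermaphrodite-biased while gonochoric ones are near 1:1, but the two
distributions overlap in the 35–45% band. The rules are therefore
conservative: a population is androdioecious on hermaphrodite evidence with
at most 45% males (or an unknown ratio), or on a male proportion under 30%
alone; gonochoric above 45% males (or a qualitatively even ratio) without
hermaphrodite evidence; equivocal in the 30–45% band; and a conflict
(ovotestis with >45% males) is flagged equivocal rather than resolved. A
purely hermaphroditic category is never emitted — males can persist at very
low frequencies, so proving their absence would need unrealistic sample
sizes. At the STU level, co-occurrence of gonochoric and androdioecious
populations — or a single ratio interval spanning below 30% and above 45%
with hermaphrodite evidence — yields a polymorphic call; equivocal and
no-data calls never override substantive ones.

One-sided ratio reports are stored as intervals: `<30` is [0, 30), `<45` is
[0, 45), `>45` is (45, 100]; `even` sits in the gonochoric band.

## 4. Parsimony mapping and origin counting

The binary character uses four tip codes: `G`, `A`, `GA` (*polymorphic*:
both systems genuinely present in the STU, costing one within-STU step
whichever state the tip node takes), and `?` (*unknown or equivocal*: free
ambiguity). The distinction matters: under pure ambiguity a polymorphic tip
would silently resolve to its neighbourhood's state and androdioecy within
it would never be counted. Reconstruction is dynamic programming over node
states with unit change costs (the Sankoff recursion, which generalises the
Fitch/Hartigan passes exactly and handles polytomies); MPR state sets come
from a top-down pass, and nodes whose set is `{G, A}` are equivocal.

`count_origins` minimises, over all most-parsimonious reconstructions, the
number of independent acquisitions of a target state: branches changing
non-target → target, within-tip steps at polymorphic STUs, plus one if the
root itself is reconstructed in the target state — an ancestral presence is
one origin. (Without the root term the quantity degenerates: on a symmetric
tree the all-target labeling can tie the minimum with zero "gains".) The
minimisation is exact: a weighted Sankoff pass with cost
`BIG * [change] + [gain]`, `BIG` exceeding any possible gain total, makes
the objective lexicographic. ACCTRAN-like and DELTRAN-like counts from
fixed top-down tie-breaks are reported alongside for transparency; they are
valid MPRs, so they bound the minimum from above.

## 5. The Mk2 model

The two-state continuous-time Markov model has gain rate `q_GA`
(gonochorism → androdioecy) and loss rate `q_AG` per unit branch length,
with the closed-form transition matrix (with `s = q_GA + q_AG`)
`P(G→G) = (q_AG + q_GA e^{-st})/s`, degenerating to identity at `s = 0`.
The likelihood is Felsenstein pruning with per-node rescaling; `GA` and `?`
tips both enter as partials (1, 1) — the Mk model describes a single state
per lineage, so STU-level polymorphism is treated as uncertainty here,
unlike in parsimony. Four constraints are fitted: equal rates (1
parameter), unrestricted (2), and the two unidirectional models (gain-only,
loss-only); nested pairs are compared by `D = 2 Δln L` against chi-squared
with the difference in parameter counts. Marginal ancestral probabilities
combine downward and upward partials under the fitted rates.

Numerical choices: optimisation on the log-rate scale with bounds
`[1e-8, 1e4]` (ML branch lengths are substitutions/site, so realistic rates
can be large) and 8 deterministic starts spread over the range; `converged`
is false when restarts disagree by more than `1e-4` ln L. The root prior
defaults to uniform (0.5, 0.5), with a stationary option; the choice is not
identified by the data and the reference tools do not state theirs. In the
high-rate regime the fitted process mixes quickly, so node marginals
approach the stationary distribution and ancestral states are effectively
unresolved — reported, not "corrected".

## 6. The phylogenetic t-test

Latitude is regressed on an intercept and a dummy-coded androdioecy
indicator by generalized least squares under covariance
`sigma^2 * V(lambda)`, where `V(lambda)` is the shared-path (Brownian)
matrix with off-diagonals multiplied by Pagel's λ. λ is profiled by ML over
[0, 1] (21-point grid refined by golden-section search, endpoints checked
explicitly); at λ = 0 the model collapses to an ordinary two-sample t-test,
at λ = 1 to fully Brownian errors. Two variance conventions coexist by
design: the λ profile and its df = 1 signal LRT use the ML variance
(denominator n), while the coefficient standard error uses the unbiased
denominator `n - 2`, consistent with reporting the group contrast as a
t statistic on `n - 2` degrees of freedom. λ is restricted to [0, 1]; the
PSD upper bound can exceed 1 on non-ultrametric trees, but values above 1
have no interpretation as signal strength. Group means are reported both
raw and as GLS fitted values — they differ whenever λ > 0.

For the Notostraca analysis, STUs with polymorphic calls count as
androdioecy-present, and equivocal/no-data STUs are excluded.

## 7. Synthetic data: what it emulates

All generators draw from one stream per (seed, operation) pair, so adding
an operation never perturbs existing fixtures, and equal seeds give
byte-identical bundles. Defaults in `sim_config` describe the regime the
analyses assume: 30 species-level units; within-species coalescent depth 2%
of tree height (a deep barcode gap, ~50× separation); Mk rates with a 3:1
loss:gain asymmetry; λ = 0.5 (moderate signal) on latitude with Brownian
rate 100 deg² per unit relative tree height (≈10° spread across tips) and a
12° androdioecious offset on a 37° gonochoric baseline — round numbers of
the order reported for this system; gonochoric populations draw male counts
as Binomial(200, 0.5) and androdioecious ones Binomial(200, 0.10), with
ovotestis records on about half the androdioecious rows; ~50% supermatrix
dropout with the barcode gene kept complete. The within-species coalescent
uses equal effective sizes across species; a realised coalescent depth
exceeding 90% of a species' terminal branch is rescaled to fit, keeping the
gene tree ultrametric and species monophyletic — a mild departure from the
multispecies coalescent (no deep coalescence, hence no incomplete lineage
sorting). Alignments contain random bases: sequence evolution is explicitly
out of scope, so alignment content only exercises format handling and the
missing-data accounting, never phylogenetic signal.

Consequently, passing tests show that each estimator recovers the structure
of its own generating model at realistic sizes — not that real barcode
data are free of the things the generators omit: gene-tree/species-tree
discordance, alignment error, rate variation among lineages, sampling
biases in the evidence table.

## 8. Problem sizes and known limitations

The test suite and simulations run at deliberately modest sizes chosen to
exercise the estimators meaningfully: GMYC recovery on 100 replicates of
5 species × 4 tips; Mk rate recovery on 50 replicates of 300-tip trees
scaled to about five expected changes per root-to-tip path; t-test size on
1000 null replicates of 30 tips; λ recovery on 100 replicates of 100 tips.
Two behaviours of the ML λ estimator are worth knowing: it is noticeably
downward-biased with a point mass at 0 on trees of this size (mean λ̂ near
0.42 when the truth is 0.5, agreeing to numerical precision with the
standard GLS implementation it is cross-checked against), and its spread
means roughly a quarter of replicates fall outside [0.3, 0.7]. The GMYC
LRT's degrees of freedom are a convention, not a derived quantity; with
`df = 3` the null simulations are close to nominal but slightly
conservative. Origin counts depend on the input topology's resolution:
collapsing weakly supported branches into polytomies can only decrease the
minimum, so the bundled consensus topology gives a floor, not an estimate.
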