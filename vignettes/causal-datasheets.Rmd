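---
title: "Causal datasheets for discrete Bayesian networks: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Causal datasheets for discrete Bayesian networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(causalsheet)
```

## The problem

Practitioners who fit causal Bayesian networks to categorical survey data
— common in epidemiology and global-health research — rarely have a ground
truth to validate against, so they cannot say how much of the learned
structure, or of the intervention effects simulated from it, deserves
trust. `causalsheet` addresses this by *simulating the study before (or
after) it is run*: it generates synthetic discrete Bayesian networks whose
observable characteristics (number of variables $p$, sample size $n$,
average category count $l$) match the planned or existing dataset, draws
data from them, runs structure-learning algorithms on those draws, and
scores the results against the known generating truth. The aggregated
scores form a "causal datasheet": a lookup table that answers, in the
spirit of a power analysis, *how many samples do I need before V-structure
recall stabilizes?* and *how much should I trust simulated intervention
effects at my current sample size?*

## The generative model

A discrete Bayesian network is a DAG $G$ plus per-node conditional
probability tables: node $i$ with cardinality $r_i$ and parent-level
product $q_i$ holds a $q_i \times r_i$ table whose rows are multinomial
distributions, giving $(r_i - 1)\,q_i$ free parameters per node.

Generation proceeds in four steps per trial:

1. **Topology.** One of five random-graph families: forest fire, a sparse
   order-uniform random DAG, Barabási–Albert preferential attachment,
   Waxman random-geometric, and Watts–Strogatz small world. The families
   differ mainly in their in-degree distributions, which is the property
   that drives learning difficulty (parameters grow multiplicatively in
   parents). Undirected outputs are oriented acyclically along a uniform
   random node permutation. The per-family knobs (burn probability 0.2;
   expected parents 1.5; attachment 1; Waxman intensity 0.4 and scale 0.1
   on the unit square; ring degree 2 with rewiring 0.2) were chosen once
   so that the mean in-degree stays in the sparse 1–2 range at 20–60
   nodes, the regime these families are typically illustrated in; all
   are exposed through `structure_spec()`.
2. **Levels.** Per-node cardinalities drawn integer-uniform on
   $\{2, \dots, M\}$ with $M = 2l - 2$, so the mean is the requested
   average level count $l$.
3. **Parameters.** Every CPT row is drawn from a symmetric Dirichlet with
   concentration $\alpha_i = \alpha / (r_i q_i)$. The global imbalance
   $\alpha$ is the key unobservable: small values give low-entropy
   (skewed) conditionals and therefore strong, detectable dependencies;
   e.g. $\alpha = 12$ for a 3-level node with one binary parent gives
   per-row concentration 2. When $\alpha_i$ underflows the gamma sampler,
   the draw degenerates to the $\alpha_i \to 0$ limit (a one-hot row).
4. **Data.** Ancestral sampling in topological order.

Because the Dirichlet is symmetric, marginals are balanced on average —
real surveys with heavily imbalanced variables are *harder* than these
synthetics, so datasheet estimates are optimistic for such data. That,
and the absence of latent confounding, missingness and continuous
variables, bounds what a passing datasheet can promise about real data.

## Structure learning and scores

Three algorithm families are implemented natively:

* **PC** (constraint-based): order-stable skeleton pruning with the
  mutual-information $G$-test ($G = 2n\,\widehat{MI}$, chi-square
  reference with $(r_x-1)(r_y-1)\prod_z r_z$ degrees of freedom), default
  level 0.05 and conditioning sets up to size 3. Colliders are oriented by
  the *max-p* rule: for each unshielded triple the separating set with the
  largest p-value over both adjacency sides decides, which is markedly
  more stable than trusting the first separator the pruning phase happened
  to find; the classic sepset rule remains available
  (`pc_config(collider_rule = "sepset")`). Orientation is closed under
  the Meek propagation rules.
* **GES** (score-based): greedy equivalence search with the standard
  insert/delete operator validity conditions, alternating forward and
  backward phases to a fixed point, re-closing the state to a CPDAG after
  every operator via a consistent extension.
* **Order-space MCMC** (hybrid): Metropolis–Hastings over topological
  orderings. Candidate parents are seeded by top-$K$ pairwise mutual
  information ($K = 8$) rather than a constraint-based pre-step, then
  greedily expanded while that improves a node's best achievable local
  score; an order is scored by summing each node's best local score over
  candidate subsets (size cap 5) consistent with the order. Proposals mix
  adjacent transpositions and random pair swaps; the best-visited order's
  argmax parent sets form the output DAG (a single structure is what the
  evaluation consumes, so the maximum is used rather than posterior
  averaging). Defaults: 10,000 iterations, 1,000 burn-in, 3 restarts, all
  configurable.

Two decomposable, hyper-parameter-free, score-equivalent scores are
provided: **BIC** (conditional ML log-likelihood minus
$\tfrac{\ln n}{2}(r-1)q$) and **qNML**, the quotient normalized maximum
likelihood, built from exact multinomial NML code lengths:
$\mathrm{qNML}(i) = \log NML_1(\{i\} \cup \Pi_i) - \log NML_1(\Pi_i)$,
where a variable set is collapsed to one categorical variable with the
product cardinality. The NML regret $\log C(n, r)$ uses the exact
linear-in-$r$ recurrence seeded by the exact binomial sum, in log space;
above $n \cdot r = 10^7$ cells (configurable) a Szpankowski-style
asymptotic takes over. Declared cardinalities — not observed distinct
values — define $r$ everywhere, so constant columns are scored
consistently.

## Evaluation metrics

Structural performance is precision/recall of the learned CPDAG's
*skeleton* (undirected adjacencies) and *V-structures* (unshielded
colliders) against the generating truth. Empty denominators yield missing
values that are excluded from aggregation — injecting zeros would bias the
medians for structures that simply have no V-structures.

Interventional performance asks whether simulated intervention effects
point the right way. For the target $A$ (heuristically the node with the
most ancestors, first-node tie-break) and every other variable $B$ and
level pair $b_1 > b_2$, the interventional odds ratio is
$OR = \frac{a/c}{b/d}$ with $a = P(A{=}a_1 \mid do(B{=}b_1))$,
$c = P(A{=}a_1 \mid do(B{=}b_2))$ and $b, d$ their complements, computed
by graph surgery and exact variable elimination (min-degree ordering,
restricted to the target's ancestor closure; a forward-sampling fallback
with $10^5$ draws guards against intractable eliminations, and exact
zeros receive a flagged Haldane $0.5/N$ continuity adjustment). Each OR is
classified protective/neutral/detrimental by whether
$\exp(\log OR \pm 1.96\,SE)$, with the Woolf log-scale standard error
$SE = \sqrt{\sum 1/(p\,N)}$, lies below, across, or above 1. The
**PCOR** — proportion of correct interventional odds ratios — is
$\sum_i \max(f_i \hat f_i, 0) / \sum_i f_i^2$ over the aligned category
vectors; when the truth has no non-neutral effect the score is a flagged
0. Target dichotomies are enumerated as each target level vs. the rest
(binary targets keep only one, the other being its reciprocal).

## The datasheet engine

`run_grid()` iterates the full factorial (variables × samples × structure
types × trials), deriving an independent child seed for every
(cell, trial, purpose) via a counter-based hash so that adding algorithms
or rerunning subsets never perturbs generation; completed rows can be
persisted and resumed. `aggregate_results()` pools medians and IQRs
(type-7 quantiles) across structure types and trials per
(variables, samples, algorithm) cell — pooling, rather than stratifying,
is what a single pivot table per metric implies; per-structure
stratification is available behind `by_structure = TRUE`.
`recommend()` applies the user's PCOR threshold with an IQR cap
(default 0.40, the point beyond which a cell's spread makes its median
unreliable as a planning number) and reports both the smallest qualifying
sample size and the reduce-variables alternative. `render_datasheet()`
writes the Markdown report (collection and existing-dataset layouts), a
JSON of all tables, per-metric pivot CSVs and a long-format CSV ready for
violin plots.

For existing datasets, `characterize_dataset()` extracts $(p, n, l)$,
`existing_data_grid()` expands them with the improve-with-more-samples
($n \times \{1, 1.5, 2, 2.5\}$) and fewer-variables
($p \times \{1, \frac34, \frac12, \frac14\}$) patterns, and
`dataset_similarity()` quantifies real-vs-synthetic closeness as the mean
cosine similarity of information-theoretic meta-feature vectors: four
summary statistics (mean, sd, min, max) of per-column Shannon entropies
normalized by $\log_2$ cardinality, plus the same four of Goodman–Kruskal
$\tau$ over all ordered column pairs. $\tau$ is the standard
"concentration coefficient" of the categorical meta-learning literature;
the composition of the vector is this package's own (documented, fixed
ordering), so similarity values are comparable within `causalsheet` runs
but not across tools with other compositions.

## Numerical and design choices

* **Acyclic orientation** of undirected generator output by a uniform
  random permutation is the standard construction; it preserves the
  degree distribution, which is the property the families are chosen for.
* **Sparse order-uniform DAGs**: a truly uniform draw from DAG space is
  dense (expected in-degree grows linearly in $p$), which would explode
  CPT sizes at 40+ uncapped nodes and contradict the sparse-exemplar
  regime the other four families target. The `ic_dag` family therefore
  draws a uniform topological order and includes each compatible edge
  independently with expected parent count 1.5 (`edge_mean`).
* **In-degree capping** removes surplus parents uniformly at random under
  the same seed stream, preserving the topology family.
* **Consistent extension before MLE**: parameter fitting needs a DAG, so
  a learned CPDAG is oriented by a seeded Dor–Tarsi extension that adds
  no cycle and no new V-structure. Unobserved parent configurations get
  uniform CPT rows (flagged), keeping downstream inference defined.
* **Determinism**: every stochastic step takes an explicit seed; master
  seeds spawn child seeds per purpose. Identical inputs give
  byte-identical outputs, including rendered datasheets.
* **Degenerate inputs**: single-variable data yield empty structures;
  zero-row sampling yields a zero-row dataset; `dof <= 0` independence
  tests return independence with $p = 1$; constant declared-binary
  columns score with their declared cardinality.
* **XOR-type dependencies**: a pure parity relation between balanced
  parents leaves every pair marginally independent, so constraint-based
  pruning removes those edges before any conditional test can see the
  interaction — colliders of this kind are only detectable when the
  parents are imbalanced. The test suite exercises exactly that variant.

## Problem sizes used in the checks

The package's own verification uses scaled-down grids chosen to exercise
the same conditions as the full survey-planning studies: 50 networks
(5 structure types × 10 trials) at 40 variables / 5,000 samples for the
PC skeleton medians, the same count at 30 variables for the V-structure
medians of PC and GES, and a reduced 2-type × 5-trial grid with 2,000
MCMC iterations for the qNML PCOR threshold check. Exhaustive-search
oracles (all 25 three-node and 543 four-node DAGs) back the
score-equivalence and search-optimality properties at sizes where brute
force is exact.

## Known limitations

GES here is a faithful equivalence-class search and, on these synthetic
grids, recovers V-structures far better than the weak GES baseline some
published comparisons report; its relative ranking against order-MCMC is
therefore compressed. The uniform-Dirichlet assumption, the absence of
latent confounders, and the fixed generator knobs mean datasheet numbers
transfer to real data only to the extent those assumptions hold;
`dataset_similarity()` is the built-in check on that transfer.

## A minimal run

```{r, eval = FALSE}
grid <- experiment_grid("collection", variables = c(8, 10),
                        samples = c(500, 1000),
                        structure_types = c("ic_dag", "small_world"),
                        trials = 3, algorithms = c("pc", "ges"),
                        alpha = 20, master_seed = 1)
res <- run_grid(grid, verbose = TRUE)
report <- build_datasheet(grid, res)
render_datasheet(report, "datasheet_out")
```
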