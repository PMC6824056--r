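---
title: "The weighted meta-graph scoring model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The weighted meta-graph scoring model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmgraph)
```

## The problem and the model

`wmgraph` ranks candidate microbes for human diseases by link prediction on
a heterogeneous information network. The guiding assumption is
guilt-by-association: functionally similar microbes tend to interact (or
not interact) with phenotypically similar diseases. The network therefore
has three layers — a disease similarity network, a microbe similarity
network, and the known disease–microbe bipartite network — and a pair's
score accumulates evidence along small template subgraphs (*meta-graphs*)
joining the seed disease to the target microbe.

Six meta-graph patterns are used: the direct association edge (a); one
similarity hop on the disease side (b) or microbe side (c) before/after an
association edge; similarity hops on both sides (d); and the two dual-path
patterns in which two parallel disease-side chains (e) or microbe-side
chains (f) connect the same endpoints. The taxonomy is closed under the
size cap "fewer than five edges or fewer than three intermediate nodes";
`metagraph_patterns()` enumerates it. Patterns differ in *given nodes* —
endpoints incident to the association edge (a: 2, b: 1, c: 1, d: 0,
e: 1, f: 1) — and patterns with more given nodes, or with dual paths,
carry more evidential weight, expressed by the bias vector
λ = (λ₁, …, λ₆). Bias ratings are constant within a pattern type: every
instance of the same pattern gets the same λ.

A single pass of pattern accumulation is the bias-weighted sum of the six
exhaustive index sums (implemented literally in `pattern_contribution()`
and assembled by `brute_force_score()`). Iterating the accumulation gives
the fixed-point update implemented in `propagate()`:

$$P_{t+1} = \mu\big[\lambda_1 P_t + \lambda_2 (DS-I)P_t + \lambda_3 P_t(MS-I)
 + \lambda_4 (DS-I)P_t(MS-I)
 + \lambda_5 ((DS-I)P_t \odot (DS-I)P_t)^{\gamma}
 + \lambda_6 (P_t(MS-I) \odot P_t(MS-I))^{\gamma}\big] + (1-\mu)A.$$

The $(1-\mu)A$ anchor plays the role of the restart term in a random walk
with restart; $\gamma$ damps the dual-path terms, whose raw magnitudes are
products of four edge weights and would otherwise vanish.

## Similarity layers

**Disease semantic similarity.** Each disease may carry a MeSH-style DAG of
ancestor terms (`disease_dag()`). The disease term contributes 1 to itself
and every ancestor contributes $\Delta$ times the largest contribution of
its children, so credit decays along the best path (`semantic_value()`).
Similarity between two diseases is the credit carried by their shared
terms, matched **by label**, normalized by the two total semantic values
(`semantic_similarity()`). When one disease appears inside another's DAG no
special case applies — the label-intersection rule covers it; this is the
literal reading of the shared-credit formula and the simplest one.

**Microbe functional similarity.** For a pair of genomes A and B, gene
families are tagged `A`, `B` or `both`, and similarity is the fraction of
edges joining genome-exclusive families that cross the A/B boundary
(`functional_similarity()`). Edges touching a `both` family are excluded
from numerator and denominator. Two deliberate conventions: a network with
*no* qualifying edges scores 0 (with a warning) rather than NaN, and the
`FS` diagonal is set to 1 — the pairwise construction never evaluates a
microbe against itself, and 1 is the only value consistent with the other
similarity layers. A microbe pair with no gene-family data likewise gets
FS = 0, letting the integrated similarity fall back toward the kernel term.

**Interaction-profile kernels.** `gip_kernel()` computes
$\exp(-\lambda\|IP(i)-IP(j)\|^2)$ with bandwidth
$\lambda = \lambda' / \overline{\|IP\|^2}$; the multipliers $\lambda'_d$,
$\lambda'_m$ default to 1 but are exposed. An all-zero association matrix
leaves the bandwidth undefined and is rejected at this level; see the
degenerate-input rules below for how the pipeline handles it.

**Integration and availability.** `DS = αSS + (1-α)GD` applies only to
pairs where *both* diseases have a DAG; other pairs use `GD` alone. The
condition is availability, not magnitude: two DAG-bearing diseases with
SS = 0 still use the blended formula. `MS = βFS + (1-β)GM` applies
everywhere.

**Normalization.** Before propagation both integrated similarities are
normalized by $S_{ij} / \sqrt{(\sum_l S_{il})(\sum_l S_{lj})}$
(`symmetric_normalize()`), which bounds the spectral radius by 1 and
guarantees convergence of the linear part of the update.

## Numerical choices and degenerate inputs

* **Identity subtraction.** The $(DS-I)$ terms remove the self-similarity
  edge so a node is not its own neighbor. The base similarities have unit
  diagonal, where literal subtraction and diagonal-zeroing coincide — the
  oracle-equivalence tests exercise exactly this case. After normalization
  the diagonal drops below 1, and literal subtraction would leave a
  negative self-loop capable of driving scores negative; the implementation
  therefore zeroes the diagonal, which preserves the index-sum semantics
  ($k \ne i$ exclusions) and keeps all update terms nonnegative.
* **Dual-path diagonal.** The squared matrix forms of patterns e and f
  include the $k = t$ tuple that the exhaustive index sums exclude. The
  production iteration uses the matrix forms; the oracle implements both,
  and `dual_path_diag_correction()` quantifies the gap, which the test
  suite pins on random instances.
* **Initialization.** $P_0$ is the association matrix normalized by its
  global maximum — for binary input, $A$ itself, which matches the anchor
  term's scale. A row-stochastic alternative is available via
  `wmg_params(init = "row-stochastic")` for experimentation; heavier
  normalization of $P_0$ has no effect on the fixed point of the linear
  part but changes early iterates.
* **Convergence.** The iteration stops when the maximum absolute
  elementwise change falls below `tol` (default 1e-6) or after `max_iter`
  (default 1000) iterations; the result records `iterations`, `converged`
  and the final change. On the study-scale problems here convergence takes
  a few dozen iterations.
* **Powers of zero.** $0^\gamma$ is defined as 0 (R's native convention),
  and negative bases cannot occur because every factor is nonnegative —
  asserted at run time.
* **All-zero training matrix.** Cross-validation can zero a dataset down to
  an empty matrix (e.g. LOOCV on a single-association dataset). The kernels
  then carry no information, so the pipeline substitutes identity kernels
  and the blends rest on the prior similarities alone; `gip_kernel()` itself
  still rejects the all-zero input when called directly.
* **Isolated nodes.** A node with zero similarity row sum (possible after
  masking) gets a zero row/column from `symmetric_normalize()` rather than
  NaN.
* **Ties.** Candidate rankings break score ties by ascending microbe index,
  and ROC construction uses midranks, so all results are bit-reproducible.

## Evaluation protocols

`global_loocv()` holds out each known association in turn, zeroes it in the
training matrix, **recomputes the kernels and integrated similarities from
the training matrix** (the semantic and functional layers do not depend on
$A$ and are cached at dataset construction), propagates, and ranks the
held-out pair against the *pooled* set of all unverified pairs. The
per-round normalized rank $u$ (fraction of candidates scoring above the
held-out pair, half credit for ties) gives the pooled AUC as
$\mathrm{mean}(1-u)$ and the ROC curve as the empirical distribution of
$u$. A per-disease candidate-set variant exists behind the `per_disease`
flag but is not the default. `kfold_cv()` repeats the same machinery over
random fold divisions, with repetition $r$ seeded as `seed + r - 1`, and
reports mean ± sd of the per-repetition AUCs. Top-$k$ precision/recall/F1
tables are pooled over rounds (precision at $k$ counts recovered pairs
against $k$ slots per round); a per-disease reading of those tables would
require per-disease candidate sets and is intentionally not the default.
`new_disease_eval()` zeroes a disease's entire row and ranks its microbes;
it refuses diseases without a DAG, since such a disease would have no edge
of any kind into the network.

## The synthetic generator

`planted_spec()`/`planted_dataset()` generate the study conditions used
throughout the tests: 20 diseases × 30 microbes in 2 latent blocks,
within-block association density 0.4 against 0.02 across blocks. Disease
DAGs of depth 3 share block-level ancestors (plus one global root), so
within-block semantic similarity exceeds cross-block similarity; per-pair
gene-family networks of 200 edges have cross-boundary edge fractions
binomially concentrated at 0.7 within blocks and 0.1 across. The depth,
branching, edge-count and functional-similarity levels are fixed, realistic
choices: shallow ontology chains and a few hundred functional links per
genome pair are typical of curated disease terms and bacterial gene-family
networks, and the 0.7/0.1 split gives the functional layer the same block
alignment the association layer has.

The generator emulates the *statistical* structure the model exploits —
block-aligned associations, ontology sharing, functional coherence — and
deliberately nothing else: no realistic taxonomy or term vocabulary, no
heavy-tailed degree distribution, no curation noise or study bias. Passing
the planted-signal tests therefore shows the pipeline recovers structure of
the kind assumed, not that it attains any particular accuracy on real
catalogues.

Null datasets for signal-detection comparisons come from
`permute_associations()`, which re-scatters the known associations
uniformly over the matrix. Permuting row/column *labels* would be too weak
a null here: it leaves the block structure inside $A$ intact, and the
kernels — computed from $A$ — would still support successful propagation.

## Problem sizes

The test suite and the acceptance script run LOOCV on the 20 × 30 planted
dataset (~130 rounds, each a full similarity rebuild and propagation),
5-fold CV with 10 repetitions, and oracle comparisons on 5 × 6 instances;
the full suite completes in well under a minute. These sizes are the
package's own validation design: they are the smallest instances on which
block recovery, protocol correctness and determinism are all measurable
with comfortable margins.

## Known limitations

* Dense matrices throughout; at catalogue scale (tens of diseases, hundreds
  of microbes) the per-round cost $O(n_d n_m (n_d + n_m)^2)$ over a full
  LOOCV is minutes, but the implementation is not built for networks orders
  of magnitude larger.
* Label matching is exact and case-sensitive (the CLI offers
  `--normalize-labels` for lowercase/trim matching); no ontology mapping is
  attempted.
* A disease with neither associations nor a DAG cannot be scored — there is
  no edge connecting it to the network; the new-disease protocol reports
  this explicitly.
* The bias ratings are fixed hyperparameters, not learned; the defaults
  come with the model.
* The association edge-list format cannot represent isolated nodes, so a
  write/read round trip preserves the known pair set but not nodes with no
  associations.
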