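---
title: "Metabolite-mediated random walks for microbe-drug association prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolite-mediated random walks for microbe-drug association prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Microbe-drug association (MDA) prediction is a link-prediction problem on a
bipartite microbe x drug relation for which the labeled data are sparse and
one-sided: only positive associations are recorded, and many microbes and
drugs of interest carry no labels at all. `mmdwalk` addresses it by embedding
microbes and drugs in a *microbe-metabolite-drug* (MMD) heterogeneous graph,
on the premise that metabolites mediate much of the microbe-drug interplay: a
microbe produces or consumes metabolites, a drug shifts metabolite
concentrations, and a shared metabolite neighborhood is evidence for an
association. Because the metabolite space is independent of the labels, nodes
absent from the labeled data still sit in the graph and can be scored.

The graph has three node types (microbes $V_s$, metabolites $V_m$, drugs
$V_d$) and five edge types:

* `sm` — microbe-metabolite production/consumption edges,
* `dm` — drug-metabolite concentration-change edges,
* `mm` — metabolite reaction-pair edges,
* `ss` / `dd` — similarity-gated same-type edges (below).

Labeled microbe-drug pairs are **never** edges; they only supervise the final
classifier, and the test suite asserts this structurally.

### Similarity-gated same-type edges

Each same-type pair is scored by the mean of two aspects:

1. *Gaussian interaction profile (GIP) kernels*
   $GM(v_i, v_j) = \exp(-\eta \lVert I(v_i) - I(v_j)\rVert^2)$ with
   $\eta = \eta' / \tfrac1N \sum_i \lVert I(v_i)\rVert^2$ and $\eta' = 1$,
   computed both from the association matrix $I$ (rows for microbes, columns
   for drugs) and from the metabolite edge matrices (`SM` rows, `DM` rows);
2. *functional similarity* — for microbes the mean of genomic similarity
   ($1 - d_{\text{mash}}$ from a precomputed genome-distance matrix) and
   evolutionary similarity ($1 - d_p/\max d_p$ from patristic distances on a
   phylogeny); for drugs the Tanimoto coefficient between topological
   fingerprints derived from SMILES.

An edge is created when the aggregate lies **strictly above** the threshold
$\alpha$ (default 0.65, the framework's operating point) and carries the
similarity as weight. The two-level equal-weight average is a design choice:
the two *aspects* are fixed, the weighting inside each aspect is not uniquely
determined, so `aggregate_similarity()` exposes weights. During
cross-validation the GIP-from-$I$ component is recomputed per fold from
training positives only — using test associations in a similarity that gates
graph edges would leak labels into training.

### The walk model

Walks start `walks_per_node = 100` times from every node and run to
`walk_length = 10` nodes (9 transitions), the budget used throughout. The
transition law depends on the current node type.

**Metabolite nodes.** With previous node $u$, current metabolite $v$ and
candidate $n$,
$$p(n \mid v, u, M) \propto w_{vn}\, M_{Q(u,v),\,Q(v,n)}\, \alpha_{pq},$$
where $Q$ maps an edge to its type, $\alpha_{pq} = 1$, and $M$ is a symmetric
positive $5\times5$ matrix of edge-type couplings. At a walk start the $M$
factor is 1. $M$ is estimated by an EM loop: trial walks under the current
$M$ (10 per node, length 10, 5 iterations), then
$M_{ij} = \sigma(\mathrm{cor}(c_i, c_j))$ where $c_i$ is the per-walk count
of edge type $i$ and $\sigma$ the logistic function. Zero-variance counts get
correlation 0 (so $M_{ij} = 0.5$); edge types absent from the graph keep
their prior value. The count-correlation/sigmoid recipe follows the
edge-type-transition literature the walk model builds on; the iteration
count, trial budget and correlation measure are configuration knobs.

**Microbe/drug nodes.** A gate
$$\rho(v) = \begin{cases} 1 & T = 0\\ f(S_v^{\max}) & T \neq 0 \end{cases},
\qquad f(x) = \frac{1}{1 + e^{-k (x - t)}},$$
with $T$ the number of metabolite edges of $v$, $k = 100$, $t = 0.85$,
decides between the same-type block (mass $\rho$, split proportionally to
similarity) and the metabolite block (mass $1-\rho$, split uniformly for
unit weights). $S_v^{\max}$ is the best similarity among $v$'s *same-type
graph neighbors* — nodes actually joined by an `ss`/`dd` edge, reading
"neighboring" literally; when $v$ has metabolite edges but no same-type
neighbor, $\rho(v) = 0$. The steepness $k = 100$ makes $f$ a near-threshold:
a node leaves for the metabolite space unless it has a same-type neighbor
more similar than $t$. The biological reading: redundant nodes (a very
similar neighbor exists) can stay in their own stratum, informative nodes
explore their metabolite context.

Each walk draws its random stream from a seed derived from (master seed,
node index, walk index) by two Lehmer steps modulo $2^{31}-1$, so corpora
are bit-reproducible and independent of generation order.

### Embeddings and classification

The corpus feeds a skip-gram model with negative sampling in which, for each
(center, context) pair, negatives are drawn *only from the node type of the
context node* (per-type unigram$^{0.75}$ noise tables, resampling any draw
equal to the context). This type-aware sampling is the model's point — a
generic trainer would contrast a metabolite context against drugs — and is
implemented in C++ (`src/skipgram.cpp`), single-threaded and deterministic
given the seed. Reference dimensions are `dim = 1024`, `window = 9`;
negatives (5), epochs (5), initial learning rate (0.025, linear decay) and
`min_count = 1` follow standard skip-gram practice and are exposed. Only the
input (center) vectors are exported.

A pair is represented by the Hadamard product
$d_{uv}[j] = z_u[j]\, z_v[j]$ — element-wise multiplication, symmetric in
the pair, suited to capturing shared coordinates — and scored by a
gradient-boosted tree ensemble with `K = 564` rounds, binary logistic loss
and the library's default per-tree regularization
$\Omega(f) = \gamma T + \tfrac12 \lambda \lVert w \rVert^2$. Logistic
regression and random forest are drop-in alternates behind the same
interface for ablation. Probabilities are thresholded at 0.5 for
accuracy/F1; that threshold is a package convention, not a claim about the
reference implementation.

## Evaluation protocol

`make_folds()` partitions the labeled positives into $k$ folds (sizes within
1) and samples one negative per positive uniformly from the unlabeled pairs,
disjointly across folds. Training uses the other folds' positives and
negatives; per fold the GIP-from-$I$ similarity, the graph, the transition
matrix, the corpus, the embeddings and the classifier are all rebuilt from
training data only. Metrics: tie-aware rank AUROC, step-integrated AUPR, and
accuracy/precision/recall/F1 from confusion counts.

`make_folds(negative_exclude = ...)` optionally bars a pair set from the
negative universe. The simulation studies pass the planted ground truth so
that held-out positives are scored against true non-associations; without
it, roughly a fifth of sampled "negatives" would be unlabeled planted
positives and the measured AUROC would reflect label contamination rather
than recovery. Real-data use leaves it `NULL` (the truth is unknown there,
which is the usual caveat of negative sampling under positive-unlabeled
data).

## The simulator

`synth_generate()` plants a partition: microbes, metabolites and drugs are
assigned to latent groups; `sm`/`dm` edges appear with probability
`p_in = 0.5` within a group and `p_out = 0.02` across; `mm` edges are
Erdős–Rényi at density 0.05; a (microbe, drug) pair is a true association
iff the two share a group, and half the planted pairs are observed as
labels. The reference sizes are 30 microbes, 40 metabolites, 30 drugs, 3
groups. These are the study conditions of the recovery experiments, chosen
so the planted signal flows through shared metabolites at a size a single
CPU handles in seconds per fold.

Functional similarities are *derived from the sampled metabolite profiles*:
$S = \mathrm{clip}_{[0,1]}(0.5 + 0.5\,\mathrm{cor}(\text{profiles}) +
\mathcal N(0, \sigma^2))$ with $\sigma = 0.05$, symmetrized, unit diagonal.
Under strong planting this approximates a group indicator plus noise and
pushes within-group similarity above $\alpha$; under the null
(`p_in = p_out`) it carries no group signal *by construction*. Injecting a
group indicator directly would break the null control: group-structured
similarity alone lets the classifier recover group combinations from the
labels, and the null would not sit at AUROC 0.5. The null control sets
`p_in = p_out = 0.26`, matching the expected edge density of the planted
configuration.

What the simulator does not emulate: real chemistry (drug similarity is
injected at the similarity-matrix level, not via SMILES), degree
heterogeneity and hub structure of curated databases, correlated noise
between the similarity aspects, and label biases of literature curation.
Passing the recovery tests therefore shows the pipeline recovers
metabolite-mediated block structure under calibrated noise — not that it
attains any particular performance on curated MDA databases.

## Numerical choices and degenerate inputs

* Similarity values exactly equal to $\alpha$ do **not** create an edge
  (strict inequality).
* An all-zero profile matrix leaves the GIP bandwidth undefined; the kernel
  returns the identity with a warning.
* Tanimoto over two empty fingerprints is 1 on the diagonal, 0 off it.
* Isolated nodes are retained (walks from them have length 1; short
  sentences are kept — the skip-gram window simply finds no context), and
  metabolites appearing in no edge table are legal registry members.
* Distributions: every emitted transition law sums to 1 within $10^{-9}$;
  sampling uses cumulative tables and `findInterval`, with the final
  interval clamped against floating-point overshoot.
* Ranking ties are broken by candidate id for stable output.
* All derived seeds stay below $2^{31}$.

## Problem sizes used by the test suite

The recovery experiments run the full pipeline (5-fold CV, EM, 100 walks x
length 10 per node, 64-dimensional embeddings, 100 boosting rounds) on the
100-node reference configuration — about a minute per run on one CPU. Unit
and property tests use smaller graphs (12-60 nodes), 16-32 dimensional
embeddings and 20-50 boosting rounds; the Monte-Carlo law checks use $10^5$
draws. The reference embedding operating point (1024 dimensions, window 9,
K = 564) is the documented default of the user-facing functions but is not
exercised end-to-end by the tests, whose purpose is correctness, not scale.

## Known limitations

* The EM objective for $M$ is a fixed-point heuristic (correlation +
  sigmoid), not a likelihood ascent; it is validated by its properties
  (range, symmetry, coupling of co-occurring types, determinism), not by
  convergence guarantees.
* GIP similarity inherits the sparsity of the association matrix: nodes with
  empty profiles are maximally similar to each other under the kernel
  ($\lVert\Delta\rVert = 0$), which is why the aggregate includes functional
  components.
* Negative sampling treats unlabeled pairs as negatives; under
  positive-unlabeled data the measured metrics are biased accordingly
  unless `negative_exclude` can be supplied.
* The walker is an R loop over precomputed cumulative tables — adequate for
  graphs of a few thousand nodes; larger deployments would move the inner
  loop to C++ like the skip-gram trainer.
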