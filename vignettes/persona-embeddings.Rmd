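---
title: "Multi-role node embeddings from ego-splitting persona graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-role node embeddings from ego-splitting persona graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(persona2vec)
```

## Why multiple vectors per node

Standard graph embeddings assign one vector per node, implicitly assuming a
single structural role.  In many real graphs — protein interaction networks,
collaboration graphs, social networks — most nodes sit in several overlapping
communities at once and play a different role in each.  A single vector is
forced to average those roles, and pairwise similarities computed from it
blur together contexts that the graph keeps separate.

This package learns one vector per *role*.  Each node's ego-network (the
subgraph induced on its neighbours, with the node itself removed) is
partitioned into local clusters; the node is replaced by one *persona* per
cluster, and each persona inherits exactly the edges into its own cluster.

## The persona graph

Plain ego-splitting shatters the graph: the personas of a node are no longer
connected to each other, so random-walk embedding methods cannot relate them.
We therefore add *persona edges*: a complete set of directed edges among the
personas of each node.  A persona with original out-strength $k^o_i$ (the sum
of its inherited edge weights, computed before any persona edges exist) sends
persona edges of weight $\lambda k^o_i$ to each of its $n_p - 1$ siblings.

The weight is proportional to $k^o_i$ for a reason.  A random walker standing
on persona $i$ follows an original edge with probability

$$p_i \;=\; \frac{k^o_i}{k^o_i + (n_p - 1)\,\lambda\, k^o_i}
      \;=\; \frac{1}{1 + (n_p - 1)\lambda},$$

independent of $k^o_i$.  With a constant persona-edge weight instead, hub
personas would almost never visit their siblings and low-degree personas
would almost never explore their own neighbourhood.  `escape_probability()`
computes this ratio exactly and the test suite verifies it empirically with
$10^5$-step walks.  Note that the exponent of the walker's behaviour is set
by the $n_p - 1$ edges each persona actually has; a node that does not split
($n_p = 1$) has no persona edges and $p_i = 1$.

Degenerate cases are handled explicitly: isolated nodes keep one persona with
an empty cluster (walks of length 1), $\lambda = 0$ is refused unless
explicitly overridden (it disconnects the persona graph; zero-weight edges
are then treated as absent by the walker), and self-loops are removed during
canonicalization because an ego-network excludes the ego by construction.

For directed graphs we cluster the undirected view of the ego-network over
the union of in- and out-neighbours, and each directed edge is inherited by
the unique persona of its source that owns the target (and vice versa).
Connectivity everywhere means weak connectivity.

## Local clustering

Any non-overlapping clusterer of the ego-network works.  The default is
connected components — the fastest choice and the right one for sparse
graphs, where ego-networks naturally disconnect.  Louvain and label
propagation are provided for dense graphs (both seeded for reproducibility),
and `local_clusters()` accepts an arbitrary partitioning function.  Clusters
are ordered by their smallest member id and personas are named
`"<node>#<k>"`, so the whole construction is deterministic.

## Embedding: fine-tuning, not retraining

The embedding stage follows a two-step schedule:

1. **Base embedding.** First-order weighted random walks on the original
   graph ($\gamma_b = 10$ walks per node, length $t_b = 40$, window
   $w_b = 5$) train a skip-gram model, giving one vector per node.
2. **Persona fine-tuning.** Every persona's input *and* output vector is
   initialized from its parent node, so all personas of a node start
   identical and the base model's co-occurrence scores are reproduced
   exactly at epoch 0.  Walks on the persona graph ($\gamma_p = 5$,
   $t_p = 80$, window $w_p = 2$) then fine-tune for one epoch.

The products $\gamma_b t_b = \gamma_p t_p = 400$ are kept equal so both
stages see the same amount of trajectory; the narrower fine-tuning window
focuses on the micro-structure the persona graph introduces.  Training the
persona graph from scratch instead of fine-tuning discards the global
structure of the original graph and measurably lowers link-prediction
accuracy (the test suite checks this on planted-overlap graphs).

The skip-gram objective models the co-occurrence probability
$p(v_i \mid v_j) = \exp(\Phi'_{v_i} \cdot \Phi_{v_j}) / \sum_k
\exp(\Phi'_{v_k} \cdot \Phi_{v_j})$; `softmax_cooccurrence()` evaluates this
exact form as a reference.  Training uses negative sampling by default, with
hierarchical softmax (Huffman tree over corpus frequencies) as an
alternative.  Downstream similarities always use the input vectors $\Phi$.

### Numerical choices

* **Negative sampling:** 5 negatives per pair, drawn from the corpus unigram
  distribution raised to $3/4$; a sampled negative equal to the positive
  context is skipped.  These follow word2vec convention.
* **Learning rate:** linear decay from $\alpha = 0.025$ to a floor of
  $\alpha \times 10^{-4}$ over all processed pairs.
* **Window:** all pairs within distance $w$ contribute (no random window
  shrinking), which keeps the objective of the finite-difference gradient
  check exact.
* **Initialization:** without an init, input vectors start uniform in
  $(-0.5/d, 0.5/d)$ and output vectors at zero.  Copying *both* $\Phi$ and
  $\Phi'$ at persona initialization preserves the base model exactly; the
  alternative (zeroing $\Phi'$) would destroy the scores fine-tuning is
  meant to adjust.
* **Determinism:** walks and training are single-threaded C++ driven by one
  integer seed; identical seeds give bit-identical corpora and embeddings.
* **Dead ends** truncate walks; they arise only from isolated personas or
  zero-weight edges.

## Link-prediction evaluation

The benchmark harness holds out a fraction of edges (default 50%) by
rejection sampling: candidates are drawn uniformly without replacement and a
candidate whose removal would disconnect the training graph is rejected, so
the walker always sees a single component.  The held-out count is
`round(test_fraction * |E|)`.  Equally many negatives are drawn uniformly
from the non-edges of the *full* graph — a held-out edge can therefore never
leak in as a negative; for directed graphs the reverse of an existing edge
is a legitimate negative.  Pairs are scored by the maximum dot product over
all persona pairs of the two nodes (`max`/`dot` is the default; `cosine`
pairs better with hierarchical softmax, and `mean`/`min` aggregations are
available).  The ranking quality is summarized by ROC-AUC computed from
midranks, ties counting one half.

Because an edge that is a bridge of the current training graph remains a
bridge after further deletions, rejected candidates are never reconsidered;
if the candidate pool (or a cap of $100|E|$ consecutive rejections) is
exhausted first, the split is infeasible — a tree has no valid split at any
fraction — and the error reports how many removable edges were found.

## The synthetic generator

`planted_overlap_graph()` builds the cleanest graph family with a known
ground truth for multi-role structure: cliques that share designated bridge
nodes.  A bridge belonging to $m$ cliques has an ego-network of exactly $m$
components (its cliques, minus itself), so connected-component ego-splitting
must give it exactly $m$ personas — an exact-recovery regime that the test
suite exploits for parameter-recovery checks.

Exactness needs one subtlety: if two bridges share a clique they are
adjacent, and a third bridge spanning their other two cliques would see its
two ego components merged through that adjacency.  The default assignment
therefore places bridges on cross pairs of a random balanced bipartition of
the cliques, which is triangle-free at the clique level and supports up to
$\lfloor n^2/4 \rfloor$ bridges.  Inter-clique noise edges (probability
`noise_p` between non-bridge nodes) break exactness deliberately when a test
wants realistic contamination.

What the generator does *not* emulate: heavy-tailed degree distributions,
weighted edges, sparse tree-like periphery, and the scale of real benchmark
graphs.  Passing tests on planted overlaps show the machinery is correct and
that persona splitting helps when overlap is present; they do not by
themselves predict absolute accuracy on any real network.

## Problem sizes used by the tests

The suite runs entirely on generated graphs and the packaged 34-node karate
club: conservation laws on 100 random planted graphs (up to ~8 cliques of 8),
escape-rate checks on $10^5$-step walks, and the link-prediction comparison
on ten seeds of a 10-clique × 8-member graph with 8 bridges and 2% noise at
$d = 32$.  These sizes were chosen so the whole suite completes in well under
a minute of training time while keeping every statistical check adequately
powered; the algorithms themselves scale to graphs orders of magnitude
larger (the persona-edge count is bounded by $|E|^{3/2}$ in practice and the
suite logs the observed ratio, which stays around $10^{-1}$ or below even on
these small dense graphs).

## Known limitations

* Only first-order (unbiased) walks are implemented; biased two-parameter
  walk sampling is deliberately out of scope.
* The hierarchical-softmax model stores inner-node vectors in the `output`
  slot of its `embedding_matrix`, so `softmax_cooccurrence()` is only
  meaningful for negative-sampling models.
* Persona ids embed the parent node id with a `#` separator; node ids
  containing `#` remain unambiguous internally (the parent map is explicit)
  but can read confusingly in exports.
* Multi-edges collapse to the first occurrence and self-loops are dropped;
  graphs where those carry meaning need pre-processing.
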