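---
title: "Diffusion-profile compound prioritization on multiscale networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diffusion-profile compound prioritization on multiscale networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multiscaleRWR)
```

## The model

`multiscaleRWR` ranks compounds against a disease by comparing how their
influence propagates through a heterogeneous network of proteins and
biological functions. The model has three parts.

**Network and transition matrix.** Nodes are proteins or biological
functions. Edges come in three classes: protein–protein interactions and
protein–function annotations (undirected relations, traversed both
ways), and a function hierarchy stored child → parent and traversed both
ways. Expanding each edge into its directed moves gives five move
classes — `pp`, `pf`, `fp`, `ff_up`, `ff_down` — each carrying one
scalar weight. For node $i$ with outgoing moves $e$,
$$M_{i,\mathrm{target}(e)} = \frac{w(\mathrm{class}(e))}
  {\sum_{e'} w(\mathrm{class}(e'))},$$
so every row sums to 1 except the all-zero rows of isolated nodes,
which form the dangling set $J$. Normalization is per node, so the
scheme is scale-invariant: only weight *ratios* matter. The default is
the unbiased scheme (all classes 1). Biasing the walk toward the
function layer (raising `pf`, `ff_up`, `ff_down`) is a supported and
sometimes advisable configuration, but no particular bias is hard-coded:
there is no canonical published value to adopt, and the right ratio
depends on the relative densities of the layers in the user's network.

**Diffusion profiles.** For seed set $S$ (a compound's in-network
targets, or the disease proteins) the restart vector $s$ is uniform on
$S$. The profile is the fixed point of
$$r^{k+1} = (1-\alpha)\,s + \alpha\, r^k M
  + \alpha \Big(\sum_{j \in J} r^k_j\Big) s, \qquad r^0 = s .$$
The $\alpha$ factor on the dangling term is forced by mass conservation:
with it, $\sum r^{k+1} = (1-\alpha) + \alpha = 1$ exactly at every
iteration (asserted in debug mode via `checkMass = TRUE`). The update is
an L1-contraction with factor $\alpha$, so residuals shrink
geometrically, the fixed point is unique for $\alpha < 1$, and the
choice $r^0 = s$ affects only the iteration count. Iteration stops when
$\|r^{k+1} - r^k\|_1 \le \varepsilon$; non-convergence within `maxIter`
raises a warning and is flagged in the result, never silent.
Compounds and diseases are represented purely through restart vectors —
they are not inserted as network nodes — because the target/protein sets
are the only entity-level data the method uses.

**Scoring.** The compound–disease score is the Pearson correlation
(centered cosine) of the two profiles,
$$\frac{(r^{(c)} - \bar r^{(c)}) \cdot (r^{(d)} - \bar r^{(d)})}
  {\|r^{(c)} - \bar r^{(c)}\|_2\,\|r^{(d)} - \bar r^{(d)}\|_2} \in [-1, 1].$$
A constant profile (possible only on degenerate networks) makes the
score undefined and raises an error rather than returning 0. Compounds
with fewer than `min_targets = 3` in-network targets are excluded from
ranking by default — predictions from one or two targets are too
unstable to report — but the filter is configurable down to 1, since
small-target compounds can still be of interest for overlap reporting.
Ties in the ranked table are broken by compound id so output files are
byte-reproducible.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.85 | continuation probability; higher spreads influence farther. A conventional restart-walk value, exposed as configuration — it is a choice, not a published constant. |
| `epsilon` | 1e-6 | L1 stopping tolerance of the power iteration. |
| `weights` | all 1 | per-move-class bias of the walk (ratios only). |
| `min_targets` | 3 | minimum in-network targets for a compound to be ranked. |
| `k` | 20 | top-k cutoff per profile for mechanism subnetworks; at this size the selected nodes carry a substantial share of the visitation mass on networks of a few hundred to a few thousand nodes. |
| `universe` | network proteins | universe for the hypergeometric overlap test; configurable because the appropriate universe depends on how the disease list was derived. |

The stopping tolerance bounds the distance to the fixed point by
$\varepsilon\,\alpha/(1-\alpha)$ (about $6\varepsilon$ at
$\alpha=0.85$). Where a test or script needs agreement with the
closed-form solver to 1e-8, it tightens `epsilon` to 1e-12; the default
1e-6 is ample for ranking, where score differences are orders of
magnitude larger.

## Statistics

The overlap test is the upper-tail hypergeometric probability
$P(X \ge k)$ — over-representation is the direction of interest — with
the universe defaulting to all protein-kind nodes. Overlap tests across
compounds are reported unadjusted (they are descriptive, per-compound
quantities); gene-set enrichment is Benjamini–Hochberg adjusted within
each collection. AUROC is the pairwise-concordance (Mann–Whitney) value
with ties half-credited; AUPR is step-wise average precision with tied
blocks processed jointly and no interpolation, which is conservative for
small positive counts. One subtlety worth knowing: under a *random*
ranking the expected average precision is slightly **above** the
prevalence $\pi$ at finite list lengths (e.g. 0.257 vs $\pi = 0.2$ for
10 positives in 50), because early ranks dominate the estimator; the
test suite checks the estimator against the exact order-statistic
expectation, not against $\pi$.

## Mechanism subnetworks

The mechanism view of a pair is the induced subnetwork over the union of
the top-k nodes of both profiles and both seed sets, each node tagged
with its origins and both profile values. Compound-target nodes not
linked to a disease-associated node (disease protein or top-k disease
node) or to any selected function node are omitted, in a single pass;
"linked" means adjacency in the induced subnetwork by default, with a
`maxHops` option for longer-range linkage. The filter can remove only
compound-target-origin nodes — never disease proteins or top-k disease
nodes. Top-k is taken jointly over both node kinds, and the selected
node with the highest compound-profile visitation is flagged as the
primary mechanism candidate, the single entity the profile says the
compound acts through most strongly. Where a top-k set could equally
have been read per profile or per node kind, the union with origin tags
was chosen because it loses nothing: every downstream consumer can
re-partition by tag.

## The synthetic benchmark

The generator emulates the structural features the method actually
exploits, at desk scale:

* a connected, scale-free PPI layer (preferential attachment, 500
  proteins, 2 edges per arriving node by default);
* a rooted function hierarchy (150 functions, branching factor 3, plus
  ~10% extra parent links; acyclic by construction);
* locality-aware annotations (mean 2 per protein): each function anchors
  at a protein and recruits annotations with probability decaying in PPI
  distance from its anchor, so nearby proteins share functions;
* a disease module of 20 proteins grown by snowball sampling, hence
  connected and compact;
* 40 compounds, 8 of them planted positives drawing targets from within
  1 hop of the disease module with a 10% uniformly drawn noise
  fraction; negatives draw uniformly. Positives and negatives share one
  long-tailed (truncated geometric, range 3–30) target-count
  distribution, so recovery cannot be a target-set-size artifact.

These sizes keep a full 10-seed recovery experiment in the tens of
seconds on one CPU while leaving the network large enough for diffusion
locality to matter. A single RNG stream is seeded once per benchmark and
consumed in documented order (network, disease, compounds), with the
generator algorithm recorded in the provenance, so byte-identical
regeneration only requires the configuration.

What the benchmark does *not* emulate: realistic degree correlations of
curated interactomes, annotation biases of real ontologies (study bias,
shallow-term inflation), compound target-set correlations from chemical
similarity, or literature-derived disease lists. Passing the recovery
test therefore shows the machinery responds to network proximity as
designed — it does not certify performance on any particular real
interactome.

## Numerical and degenerate-input choices

* All node orderings are lexicographic by id and fixed at build time;
  every writer sorts deterministically, so identical inputs give
  byte-identical outputs.
* Duplicate input edges are deduplicated with a warning (the network is
  a binary relation); self-loops and kind-inconsistent edges are errors.
* The closed-form solver replaces dangling rows by the restart vector
  and solves the dense linear system; it is guarded to 2000 nodes and
  used as a cross-check, not in the pipeline path.
* Profiles are clipped at 0 and renormalized on return to absorb
  rounding at the 1e-15 level.
* `topKNodes` breaks probability ties by node id; the mechanism filter
  runs once (not iteratively), so a target linked only through another
  omitted target at `maxHops > 1` counts as linked via the induced path
  — a deliberate, documented reading of one-pass filtering.
* Hypergeometric tails, BH adjustment and the Pearson cross-check in the
  tests use the standard `stats` implementations; the diffusion update,
  the correlation score, the AUROC/AUPR estimators and the mechanism
  rules are implemented in this package and verified against
  independent oracles (dense linear solve, exhaustive enumeration,
  pairwise concordance, pROC).

## A small run

```{r example, eval = FALSE}
b  <- generateBenchmark(syntheticConfig(seed = 1))
tm <- buildTransitionMatrix(b@network)
st <- rankCompounds(b@network, tm, b@compounds, b@disease)
head(scoreFrame(st))
evaluateKnownPositives(st, b@labels$compound_id[b@labels$label == 1])
```

## Known limitations

* Per-class (not per-edge) weights: confidence-weighted interactomes
  must be thresholded before import.
* The dense oracle solver does not scale past a few thousand nodes; the
  power iteration itself is sparse and scales to interactome size.
* Evaluation assumes the known-positive list is trustworthy and that
  unlabelled compounds are negatives — the usual, imperfect convention
  for this kind of recapitulation.
* The hypergeometric universe is a genuine degree of freedom: p-values
  move by orders of magnitude with it, which is why it is explicit
  configuration rather than a hidden constant.
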