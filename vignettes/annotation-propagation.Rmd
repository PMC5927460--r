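---
title: "Propagating structure annotations over molecular networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Propagating structure annotations over molecular networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Untargeted MS/MS experiments observe hundreds to thousands of ions, most of
which cannot be matched to a spectral library. In silico fragmentation
tools propose candidate structures for each spectrum and score them, but
the correct structure is often buried far down the candidate list. A
molecular network — a graph whose nodes are consensus MS/MS spectra and
whose edges connect spectra with high modified-cosine similarity — adds an
orthogonal piece of evidence: connected spectra tend to come from
structurally related compounds. `napr` uses that evidence to re-rank each
node's candidate list.

## The scoring model

Every method in the package rescores candidate $c$ of a node as

$$S_c = \alpha f_c + (1-\alpha)\,\frac{1}{M}\sum_{j=1}^{M}
\mathrm{sig}(m_j\,t_{cj}),
\qquad
\mathrm{sig}(x) = \frac{1}{1+e^{\beta(x-\gamma)}}$$

where $f_c \in [0,1]$ is the base in silico score, $m_j$ the cosine of the
edge to neighbor $j$, and $t_{cj}$ the Tanimoto similarity between the
fingerprint of candidate $c$ and the structural information carried by
neighbor $j$:

* **Fusion** — $t_{cj}$ is the similarity to the *spectral-library
  structure* of neighbor $j$. It applies only to nodes with at least one
  library-annotated direct neighbor.
* **Consensus** — $t_{cj}$ is the *maximum* similarity to the top
  `n_first` candidates of neighbor $j$. It applies wherever a neighbor has
  candidates at all, so it reaches regions of the network without any
  library match.
* **Fusion then Consensus** (the default mode) — Fusion runs first; the
  Consensus pass then ranks each neighbor's list by its Fusion score where
  one exists. This chains the two stages, letting library information
  reach nodes two hops from a match in a single sweep. There is
  deliberately no iteration to a fixed point.

Defaults are $\alpha = 0.3$, $\beta = -9$, $\gamma = 0.6$ and
`n_first = 10`, the MetFusion-optimized values. With $\beta < 0$ the
sigmoid is strictly increasing, the only orientation under which higher
structural similarity can raise a score; at $m_j t_{cj} = \gamma$ it
crosses 0.5 and at full similarity it reaches
$1/(1+e^{-3.6}) \approx 0.9734$.

Two modeling choices deserve note. First, the neighbor sum is averaged
over the $M$ neighbors. An unnormalized sum would grow with node degree;
within one node the average is a positive monotone transform of the sum,
so per-node rankings are unchanged and cross-node scores stay in $[0,1]$.
Second, $m_j$ is read from the connecting edge cosine. The alternative
reading — the neighbor's own library-match cosine — is available behind
`scoring_params(use_match_cosine = TRUE)` but off by default, since the
edge cosine is what ties the *pair* of spectra together.

Ties after rescoring are broken by higher base score, then
lexicographically by the candidate's identity key (the stereo-insensitive
first block of its InChIKey), making every ranking reproducible.

## Fingerprints and structure identity

All similarity is computed on hashed linear-path fingerprints (paths up to
7 bonds, ring closures included) folded to 1024 bits, as produced by
OpenBabel's FP2 through ChemmineR/ChemmineOB. Candidate identity — used
for deduplication, truth matching and cluster labeling — is the first
14-character block of the InChIKey, which deliberately ignores
stereochemistry. Two SMILES or InChI spellings of the same constitution
always collapse to one candidate. Tanimoto similarity of two empty bit
sets (single-heavy-atom molecules) is defined as 1; this degenerate case
is logged and cannot affect scoring of real candidate lists.

## Clustering candidates for substructure-level evaluation

Exact-structure accuracy understates what a re-ranked list is good for: a
top candidate sharing the true structure's scaffold still supports a
class-level annotation. The package therefore clusters the candidate pool
(per molecular family, the union of each node's top-`top_k` candidates
plus the known truths — `top_k` defaults to 10):

1. pairwise dissimilarity $1 - $ Tanimoto;
2. classical (metric) MDS into at most 10 dimensions — eigendecomposition,
   not SMACOF, so there is no random initialization; each axis's sign is
   fixed by making its largest-magnitude coordinate positive;
3. Ward linkage (`ward.D2`) on Euclidean distances;
4. an adaptive dynamic branch cut with `min_cluster_size = 2` and
   `deep_split = 2`.

The branch cut walks the dendrogram from the root and splits a branch when
both sub-branches stand out as clusters: size at least
`min_cluster_size`, normalized core scatter below a ceiling, and a
normalized gap to the merge height above a floor. `deep_split` (0–4) maps
to ceilings 0.64/0.73/0.82/0.91/0.95 with the gap floor
$(1-\mathrm{ceiling}) \cdot 3/4$; heights are normalized to the range
between the 5th-percentile merge height and 99% of the dendrogram height.
A sub-branch smaller than `min_cluster_size` that falls away from a
qualifying sibling is left unassigned (label 0) and counts as discordant
in every rate. Labels are renumbered by decreasing cluster size. The
pipeline is fully deterministic; repeated runs give identical labels, and
permuting the input permutes labels only up to renaming.

A node is *correct at substructure level* for a method when the method's
top-ranked candidate and the known truth share a cluster label greater
than 0; *correct class* compares user-supplied chemical-class labels
instead. Chemical-class taxonomies are accepted as an input column — the
package never queries a classification web service. Whether rates are
computed per molecular family (the default here) or over one global pool
is not dictated by the method; per-family pools keep the clustering
problem small and mirror the cross-node comparisons the scenario figures
describe.

## Evaluation protocol

Ranks are *dense*: tied candidates share a position and the next distinct
score takes the next integer (1, 2, 2, 2, 3 — never 1, 2, 2, 2, 5).
Summaries report per method the mean and median rank of the truth, the
percentage at rank 1 and within the top 20, counts improved/worsened
versus the base ranking, and unique-best counts where a method is counted
only when *strictly* better than every other method (ties across methods
are overlap). Nodes whose truth is absent from the candidate list are
excluded from the statistics and reported as "not annotated". The random
baseline draws the truth's rank under uniform permutations of each list
(10,000 draws by default, seeded); for a list of length $L$ its
expectation is $(L+1)/2$, which the test suite checks to Monte-Carlo
precision.

## What the synthetic generator emulates — and what it does not

The generator builds molecular families from twenty drug/natural-product
-like scaffolds, each enumerable into ring-decorated variants (methyl,
hydroxyl, methoxy, acetoxy). Within a family, node truths are variants of
one scaffold, so "structurally related neighbors" is true by construction;
decoys are drawn from the other scaffolds, without replacement across the
family so that no two connected nodes share a decoy molecule — candidate
lists of distinct precursor ions do not repeat structures. Edges chain
consecutive family members with cosines drawn from $[0.6, 0.9]$, the
similarity range typical of molecular-network edges; cosines are
generated, not computed from simulated spectra, because the method
consumes them as givens. The truth is planted at a base rank drawn from
3–8 (never rank 1, so any rank-1 recovery is attributable to propagation),
among 12 decoys per node; base scores are sorted uniform draws, making the
planted rank exact. A configurable fraction of nodes (default 0.3)
receives a library match revealing its truth. Everything is reproducible
from the mandatory seed; the incoherent variant (`coherent = FALSE`) draws
truths and decoys uniformly from all scaffolds, producing neighborhoods
with no structural signal.

Defaults describe the study conditions used throughout the tests and the
acceptance script: 4 families of 5 nodes, 13 candidates per node, 50
seeded networks for the recovery study (1,000 evaluated nodes), 10
networks for the baseline and concordance rates. These sizes keep the full
suite to a few minutes while leaving Monte-Carlo error well below the
effects measured.

Passing tests on these fixtures show that propagation recovers planted
structure *when the coherence assumption holds* and does no systematic
harm when it does not. They do not show performance on real data: real
candidate lists come from fragmentation heuristics with correlated errors,
real cosine edges are noisy functions of fragmentation chemistry, decoys
can be near-isomers of the truth far harder than cross-scaffold decoys,
and spectral libraries contain wrong or analog-only matches. Benchmarks
against reference libraries are out of scope here because the underlying
data are licensed.

## Numerical and degenerate-input choices

* Multi-edges collapse to the maximum cosine (strongest evidence);
  self-loops are dropped with a warning; directed inputs are symmetrized.
* Candidate lists are deduplicated by identity key keeping the maximal
  base score; base scores above 1 trigger a per-node min–max rescale with
  a warning (the expected convention is $f_c \in [0,1]$).
* A library neighbor whose structure does not parse is skipped and the
  neighbor count $M$ decremented; a node's own library match never enters
  its own rescoring.
* Nodes failing a method's preconditions (no annotated neighbor; no
  neighbor with candidates) keep their base scores, flagged per node.
* All-identical embedded points, all-zero dendrogram heights, and
  single-point families short-circuit to one cluster or an error with a
  clear message, as appropriate.
* MCS search is bounded (10 s default); on timeout it reports an empty
  substructure with a flag. MCS is annotation output only and never enters
  scoring.

## Known limitations

Fingerprint families differ across toolkits; FP2-based Tanimoto values are
not bit-compatible with CDK 'extended' fingerprints, so absolute scores
differ from implementations built on CDK even though the ranking machinery
is identical. Propagation is a single sweep by design; evidence does not
travel more than two hops (one Fusion, one Consensus). The dynamic branch
cut implements the hybrid method's core behavior but not its optional
medoid-reassignment (PAM-like) stage; objects it leaves unassigned are
counted conservatively as discordant.
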