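# napr — network annotation propagation for molecular networks

`napr` re-ranks *in silico* fragmentation candidate structures for the
nodes of an MS/MS molecular network. Untargeted metabolomics experiments
leave most observed ions unannotated: spectral libraries cover only a
fraction of chemistry, and fragmentation tools (MetFrag and kin) rarely
put the correct structure at the top of their candidate lists. A molecular
network — nodes are consensus MS/MS spectra, edges carry the spectral
cosine similarity of connected spectra — encodes the expectation that
connected spectra come from structurally related compounds. `napr` turns
that expectation into a re-scoring of every candidate list.

The package is aimed at computational mass-spectrometrists and
metabolomics method developers who have a network (GNPS GraphML or
edge-list TSV), per-node candidate lists with base scores, and optionally
spectral-library matches, and want network-informed rankings plus the
machinery to evaluate them.

## The model

Candidate *c* of a node is rescored as

    Sc = alpha * fc + (1 - alpha) * (1/M) * sum_j sig(m_j * t_cj)
    sig(x) = 1 / (1 + exp(beta * (x - gamma)))

with `fc` the base in silico score, `m_j` the cosine of the edge to
neighbor *j* (of *M* total), and `t_cj` the Tanimoto similarity between
1024-bit path fingerprints of candidate *c* and the neighbor's structural
information. Under **Fusion** that information is the neighbor's
spectral-library structure; under **Consensus** it is the best of the
neighbor's top `n_first` candidates; the default chained mode runs Fusion
first and lets Consensus rank each neighbor's list by its Fusion score, so
library evidence reaches two hops in one sweep. Defaults
`alpha = 0.3, beta = -9, gamma = 0.6, n_first = 10`.

Beyond scoring, the package clusters candidate structures (Tanimoto
dissimilarity → metric MDS → Ward linkage → adaptive dynamic branch cut)
to measure substructure-level correctness, evaluates rankings with dense
(tie-sharing) ranks against a uniform random baseline, and ships a seeded
synthetic-network generator used as the offline test bed. See the
methods vignette (`vignettes/annotation-propagation.Rmd`) for the science
and all numerical choices.

## Worked example

Simulate a small two-family network with planted true structures (truths
sit at base rank 3–8, never rank 1), propagate, and evaluate:

```r
library(napr)

spec <- fixture_spec(n_families = 2, family_size = 4, seed = 11)
fx   <- generate_fixture(spec)
res  <- propagate(fx$network, fx$candidates, fx$library_matches,
                  scoring_params())
res
#> Propagation result (fusion_then_consensus): 8 nodes, 104 candidates;
#> fusion applied to 2, consensus to 8 node(s)

summ <- summarize_rankings(truth_ranks(res, fx$truths))
print(summ$methods, digits = 3)
#>      method n mean_rank median_rank pct_rank1 pct_top improved_vs_base
#> 1      base 8      5.88         5.5       0.0     100                0
#> 2    fusion 8      4.62         4.5      12.5     100                2
#> 3 consensus 8      2.50         2.5      25.0     100                7
#>   worsened_vs_base unique_best
#> 1                0           0
#> 2                0           2
#> 3                0           5

rb <- random_baseline(fx$candidates, fx$truths, n_draws = 10000, seed = 11)
sprintf("random baseline: mean %.2f, median %.0f", rb$mean_rank,
        rb$median_rank)
#> [1] "random baseline: mean 6.99, median 7"
```

Reading the numbers: the base ranking never places a planted truth first
(by construction). One Fusion pass fixes the two nodes adjacent to a
library match; the chained Consensus pass propagates that gain across the
families, improving 7 of 8 nodes and pulling the mean truth rank from 5.9
to 2.5 — against 7.0 for random ordering of the 13-candidate lists.

The same workflow runs from the shell on files:

```sh
Rscript inst/scripts/nap.R simulate --seed 11 --n-families 2 \
    --family-size 4 --out fixtures/
Rscript inst/scripts/nap.R run --graph fixtures/network.graphml \
    --candidates fixtures/candidates.tsv \
    --library-matches fixtures/library_matches.tsv \
    --truths fixtures/truths.tsv --cluster --out out/
```

which writes `reranked_candidates.tsv`, `annotated_network.graphml`,
`truth_ranks.tsv` and `summary.json` (all parameters echoed for
provenance).

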