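---
title: "Methods: neighborhood enrichment encoding and Max-Relevance ranking"
author: "maxrelnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: neighborhood enrichment encoding and Max-Relevance ranking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maxrelnet)
```

## The problem and the model

Given a universe of `N` scorable genes, an undirected protein–protein
interaction (PPI) network, GO-term and KEGG-pathway gene-set collections,
and a small set of validated disease genes, the package ranks the terms by
how well they separate disease genes from the rest of the genome. The
pipeline has three stages.

**Encoding.** A gene's functional context is its network neighborhood
`G2` (its PPI neighbors, size `n`). A term's context is its annotated gene
set `G1` (size `M`). Their association is quantified by the upper-tail
hypergeometric probability of the observed overlap `m = |G1 ∩ G2|`:

$$P(X \ge m) = \sum_{k=m}^{\min(M,n)} \frac{\binom{M}{k}\binom{N-M}{n-k}}{\binom{N}{n}},
\qquad \mathrm{ES} = -\log_{10} P(X \ge m).$$

The raw p-value is used as a score, not as a significance test, so no
multiple-testing correction is applied (or appropriate). Each gene becomes
a vector of ES values over all GO terms followed by all KEGG pathways.

**Ranking.** Each feature column is discretized (below) and scored by its
plug-in mutual information with the binary label, in bits. Features are
sorted by non-increasing MI — the Max-Relevance criterion of mRMR. The
Min-Redundancy half of mRMR is deliberately absent: redundancy elimination
builds compact predictive subsets, whereas here every relevant term is of
interest in its own right (two largely redundant cancer pathways should
both be reported).

**Selection.** The list is cut at an inclusive threshold `tau` applied to
the full-precision MI, not to rounded display values, and the survivors are
reported as per-category tables that keep their global ranks.

## Statistical and numerical choices

* **Tail computation.** `upper_tail_hypergeom_p()` evaluates the tail via
  the hypergeometric survival function at `m - 1`
  (`phyper(m - 1, M, N - M, n, lower.tail = FALSE)`), not literal
  summation: at genome scale (`N` ~ 2·10^4, `choose(N, n)` astronomically
  large) naive binomial-coefficient sums overflow. Tests verify agreement
  with brute-force enumeration to a relative tolerance of 1e-10 for every
  parameter tuple with `N <= 25`. `P(X >= 0) = 1` exactly, so genes with no
  overlap score exactly 0.
* **Universe consistency.** `M`, `n` and `m` are always counted after
  intersecting term sets and neighborhoods with the universe, so a single
  `N` is consistent across the whole feature table. The universe file is
  authoritative: what it lists is scorable, nothing else is.
* **Isolated genes.** An empty neighborhood forces `m = 0`, hence `p = 1`
  and a score of 0 — no NA code. Isolated genes carry no network signal and
  simply look uninformative, which is the honest representation.
* **Underflow floor.** p-values below `p_floor` (default 1e-320, just above
  the smallest representable double) are floored so that scores stay
  finite. The cap is configurable per call; at the shipped scales it is
  unreachable and exists purely as a numerical guard.
* **Discretization.** MI on continuous scores requires a density estimate.
  The package uses the 3-state coding of the classic mRMR implementation:
  `low` below mean − 0.5·sd, `high` above mean + 0.5·sd, else `mid`, with
  the *population* standard deviation. A constant column has zero spread
  and maps to all-`mid`, giving MI 0, as it should. `num_states` and
  `alpha` are configurable (`discretization_rule()`); a 2-state
  split-at-the-mean variant is provided, and more elaborate codings are out
  of scope. Enrichment-score columns are zero-inflated, so in practice the
  `low` cut often falls below 0 and the coding degenerates to an effective
  mid/high split — harmless, since MI handles empty states (0·log 0 = 0).
* **Log base.** MI is reported in bits (log base 2), configurable via
  `mi_log_base`. The base rescales every feature's MI by the same constant
  and cannot change the ranking; it only matters for comparing the absolute
  values to an external threshold such as `tau`.
* **Tie-breaking.** Equal-MI features keep their original column order
  (GO-collection order, then KEGG). This makes rankings deterministic and
  reproducible; no other tie rule is defensible from first principles.
* **Threshold semantics.** "MI at least tau" is an inclusive `>=` on the
  unrounded estimate. Display rounding (tables usually print 2–3 decimals)
  plays no role in selection.

## The synthetic study generator

`generate_study()` builds a complete miniature study so every stage is
testable without downloads; it is first-class, tested code, not a fixture.

| parameter | default | meaning |
|---|---|---|
| `n_genes` | 2000 | universe size |
| `edge_prob` | 0.004 | Erdős–Rényi edge probability (mean degree ≈ 8, the order of a high-confidence PPI network) |
| `n_go_terms`, `n_kegg_terms` | 280, 60 | terms per category |
| `term_size_range` | 10–80 | genes per term, uniform |
| `n_informative` | 10 | planted terms, split across categories proportionally to their sizes (8 GO, 2 KEGG) |
| `n_positives` | 60 | positive genes (3% of the universe, mirroring the rare-positive regime of real disease-gene studies) |
| `rho` | 0.6 | enrichment strength in [0, 1] |
| `seed` | 1 | drives *all* randomness |

The signal mechanism is **edge rewiring**: each positive gene redirects
`max(1, round(rho * degree))` of its edges (one edge is added when the
degree is 0; none at all when `rho = 0`) to members of the planted terms,
assigned round-robin over a random permutation of those terms. Rewiring was
chosen over edge addition so that positives' degrees remain equal to their
background degrees — otherwise degree itself, not term overlap, would be
the separating signal. A consequence is that each positive overlaps a
random subset of roughly `rho · degree` planted terms rather than all of
them; with the defaults each planted term is "hit" by about half the
positives, which is ample: on the default study the 10 planted terms
typically occupy the top 10 ranks out of 340, and across seeds they land in
the top 20 in the overwhelming majority of runs.

What the generator does *not* emulate: the GO DAG (terms are sampled
independently, so term–term overlap is random rather than hierarchical),
scale-free degree distributions, annotation bias toward well-studied genes,
and confidence-weighted edges. Passing the recovery tests therefore shows
the statistical machinery works under a clean null and a clean planted
alternative; it does not certify performance on any particular STRING/GO
release, whose MI values depend on resource versions and are not
reproducible at desk scale.

Two generator conventions deserve a note. The per-category
term counts are totals — the 10 informative terms are planted among the
280 + 60, keeping the default study at 340 features. And `rho = 0` performs
no rewiring whatsoever (the minimum-one-edge rule applies only when
`rho > 0`), so the null study is exactly an Erdős–Rényi network with
labels assigned independently of everything else.

## Pipeline determinism and scale

`run_pipeline()` is deterministic on fixed inputs: the only randomness in
the package lives in `generate_study()`, behind a single seed. Outputs are
TSVs written with `%.17g`, so doubles round-trip exactly and repeated runs
are byte-identical; the JSON run manifest records input MD5 checksums to
make silent input drift detectable. The staged CLI subcommands
(`encode`, `rank`, `select`) compose to the same bytes as `run`.

Feature matrices are computed by sparse adjacency-by-membership
multiplication (one `A %*% T` per block of genes), chunked to bound memory,
so a full genome-scale run (≈ 18,600 genes × 12,750 terms) is feasible;
tests and the bundled examples use synthetic scale (≤ 2,000 genes × ≤ 400
features, seconds per run) and a reduced study (600 genes) for the
multi-seed property tests, which keeps the whole suite under a minute
without changing any of the generator's default *study* parameters. The
`write_feature_matrix` flag exists because a genome-scale matrix TSV runs
to gigabytes; the ranking and selection artifacts are always written.

## Known limitations

* MI absolute values depend on the discretization convention and the class
  balance; only comparisons within one run (and against a threshold chosen
  for that convention) are meaningful.
* With very small positive classes the MI estimator is noisy; the ranking
  is stable but MI differences beyond the second significant digit are not
  interpretable.
* Identifier matching is exact and case-sensitive; alias resolution and id
  mapping are intentionally out of scope, as is live retrieval from
  STRING/GO/KEGG.
* The selection threshold `tau = 0.01` is a convention inherited from the
  published application of this method, not a significance level; users
  with different class balances should recalibrate it, e.g. against the
  rho = 0 null of the synthetic generator.
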