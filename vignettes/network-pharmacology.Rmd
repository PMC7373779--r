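---
title: "Methods: biomarker network pharmacology and the DSWMP index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: biomarker network pharmacology and the DSWMP index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dswmpnet)
```

## The model

The pipeline treats a metabolomics study as three layered bipartite
structures over a panel of differential plasma metabolites (biomarkers
$B_i$, $i = 1..N$):

1. **MEI network.** Curated biomarker–enzyme relations form an unweighted
   bipartite graph. The only topology statistic used is *degree centrality*,
   the raw number of incident edges — deliberately not normalized, because
   the published tables this mirrors report raw degrees. Hubs are nodes with
   degree strictly greater than a cutoff; the biomarker default is 10
   ("more than ten enzymes"), exclusive.
2. **MTI networks.** A docking campaign scores every (biomarker, target)
   pair in pKd units, $\mathrm{pKd} = -\log_{10} K_d$. An edge is retained
   when its score passes the threshold — by default strictly greater than
   5.52 pKd, the affinity of a 3 µM dissociation constant. The binder/
   non-binder classification behind that constant was calibrated for
   thresholds in 4.82–6.11 pKd, so `threshold_rule()` warns (but does not
   refuse) outside that range. Retained edges are restricted to each
   physiological system's target set (nervous, immune, endocrine); a
   biomarker with no surviving edge into a system drops out of that system's
   network, which is why fewer biomarkers appear in MTI networks than were
   docked. Targets are classed by membership multiplicity (1, 2 or 3
   systems) and the three networks intersected for universally shared
   targets.
3. **DSWMP.** For pathway $P_k$ with member targets $TP_k$,
   $$\mathrm{DSWMP}(P_k) = \frac{\sum_i \sum_j DS_{B_i T_j}}{\mathrm{Count}(B_i)},
   \qquad T_j \in TP_k,$$
   summing retained scores only. Targets belonging to several pathways count
   fully in each (pathway membership is many-to-many; no splitting).

### The Count(B_i) ambiguity

The denominator admits three readings, and the defining text does not fix
one. All three are implemented behind `count_mode`, and every report names
the mode used:

* `contributing_biomarkers` (default) — divide by the number of biomarkers
  with at least one retained edge into $TP_k$. Chosen as default because it
  keeps scores on the scale of "mean retained affinity mass per active
  biomarker" and comparable across pathways of very different reach.
* `n_biomarkers` — divide by the total biomarker count of the edge universe.
  The only mode that is additive over disjoint member sets and monotone
  under edge deletion.
* `per_biomarker_edge_count` — each biomarker's pathway sum divided by its
  own pathway edge count (its mean retained affinity), then summed.

A consequence worth stating: *edge-deletion monotonicity holds only in
`n_biomarkers` mode.* In the other two, deleting a weak edge can raise the
score (the denominator shrinks, or a per-biomarker mean rises). The test
suite therefore asserts monotonicity for `n_biomarkers` only, and asserts
oracle equivalence (an independent brute-force double loop) for all three.

### Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `threshold_pkd` | 5.52 | pKd | affinity of $K_d$ = 3 µM; calibrated binder cutoff |
| `comparator` | `greater` | — | the rule is stated as "greater than the threshold"; `greater_equal` available |
| `count_mode` | `contributing_biomarkers` | — | see above |
| `top_k` | 10 | pathways | depth of the per-system ranking tables |
| `hub_min_degree` | 10 | edges | exclusive biomarker hub rule |

Reported means and scores are computed exactly and rounded half-up to two
decimals only for display (`round_half_up()`), matching the printed
precision of the tables this reproduces (17.85, 2.97, 8.23, 2.89); base R's
half-even `round()` would disagree on exact halves.

## What the synthetic generator emulates — and what it does not

Studies of this design typically publish summary tables but not their
relation lists or docking matrices, so `gen_study()` generates bundles with
the stated structure: 36 biomarkers, 350 enzymes whose biomarker-degrees
follow a truncated power law with Zipf-skewed attachment (a few hub
biomarkers accumulate most relations), three overlapping target sets of
sizes 155 / 60 / 125 with nine targets in all three systems (echoing the
reference study's nine shared targets — a modeling convenience, not a claim
of reproduction), 30 pathways of 5–40 members, and a docking matrix from a
two-component truncated-normal mixture: a pair passes with probability
`pass_fraction` (default 0.05, matching the observed ~4% edge retention of
a 36 × 155 matrix yielding 232 edges) and then draws from
N(6.5, 0.5) truncated above the threshold, otherwise from N(4.0, 1.0)
truncated to [0, threshold]. The mixture is the simplest model with a
directly controllable pass fraction; no score distribution is published.

What a green test on synthetic data establishes: the algorithms are correct
on inputs with the right shapes, sparsity and overlap structure, and the
pipeline is deterministic and self-consistent. What it does not establish:
chemistry-aware correlations between similar metabolites, realistic
docking-energy physics, or the reference study's actual scores and pathway
ranks — its Table-3-level numbers depend on undeposited data and are out of
scope. One global seed drives fixed per-component substreams, so adding a
generator component never perturbs earlier draws, and identical spec + seed
is byte-identical on disk.

`gen_fixture_network()` is different in kind: it reproduces *exact* printed
dimensions by construction (a cyclic spanning assignment guarantees no
isolated node, then the remaining edges are sampled uniformly without
replacement), so printed mean-degree arithmetic (232/13 = 17.85) is checked
against networks that really have those dimensions. `attach_scores()`
completes the round trip: edges strictly above threshold, non-edges at or
below, so thresholding reconstructs the fixture exactly.

## Numerical and degenerate-input choices

* Scores are pKd throughout; raw $K_d$ converts at the boundary
  (`pkd_from_kd()`, mutual inverse with `kd_from_pkd()` to ~1e-10 relative
  error over $K_d \in [10^{-12}, 1]$).
* Missing matrix cells mean "no measured interaction" and never pass any
  threshold — NA is not zero, because 0 is a legal pKd.
* Present scores must be finite and ≥ 0; negativity is treated as data
  corruption (the upstream docking service's score floor is not documented;
  the restriction is this package's own).
* Ties: degree tables break by accession ascending; pathway rankings by
  pathway id ascending. Row order of inputs never affects any output.
* Empty networks summarize to flagged zeros rather than dividing by zero;
  an empty pathway member set is an error, distinct from a legal zero score.
* Accession shapes (HMDB, hsa) are validated as warnings, not errors, so
  non-KEGG catalogs pass through; dangling cross references are errors.
* Config files are JSON (jsonlite); no YAML parser is assumed.

## Known limitations

* The reference endocrine MTI figures are internally inconsistent (the
  printed edge count contradicts the printed means), so no endocrine printed
  value is asserted anywhere; both are simply recomputed from data.
* DSWMP scores are not comparable across `count_mode`s, and the package
  deliberately refuses to pick a "true" reading of Count(B_i).
* Degree centrality is the only topology statistic; betweenness, closeness
  and community structure are out of scope, as is any actual docking or
  live database retrieval.
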