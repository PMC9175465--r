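---
title: "Measuring disease co-occurrence: how association measures shape multimorbidity networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring disease co-occurrence: how association measures shape multimorbidity networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A multimorbidity network represents chronic conditions as nodes and
co-occurrence relationships as weighted, undirected edges. Every edge weight
is some scalar function of the 2x2 contingency table of a condition pair —
`a` individuals with both conditions, `b` and `c` with exactly one, `d` with
neither, `n = a + b + c + d` — and there are many defensible choices for
that function. `comorbnet` implements seven in common use and the machinery
to quantify how strongly the choice among them changes the resulting
network: its density, its communities, its most central conditions, and the
kinds of condition pairs (by prevalence) its strongest edges connect.

```{r}
library(comorbnet)
t <- contingency_table(a = 15, b = 5, c = 10, d = 70)
all_measures(t)
```

The seven measures split into families with different intrinsic properties:

* **lift** `n a / ((a+b)(a+c))` and **relative risk** (the maximum of the two
  directional risks, since RR is asymmetric) are ratio measures centred at 1
  under independence. They reward pairs whose joint count far exceeds the
  independence expectation — which is easiest for *rare* conditions.
* **phi** `(ad − bc) / sqrt((a+b)(a+c)(b+d)(c+d))` is the Pearson
  correlation of the two indicators. It is *inversion-invariant*
  (unchanged when presence and absence are flipped, `a↔d`, `b↔c`), so it
  values co-absence as much as co-presence.
* **Jaccard** `a/(a+b+c)`, **cosine** `a/sqrt((a+b)(a+c))` and
  **Kulczynski** `(a/(a+b) + a/(a+c))/2` are *null-invariant*: adding
  disease-free individuals (growing `d`) leaves them unchanged, a desirable
  property for sparse disease-status data. Cosine and Kulczynski are the
  geometric and arithmetic means of the two conditional probabilities
  (confidences), so on every table `kulczynski ≥ cosine ≥ jaccard`, and
  `cosine² = lift × joint prevalence`.
* **joint prevalence** `a/n` simply ranks pairs by how common the
  co-occurrence is.

## The analysis pipeline

`build_association_table()` enumerates all unordered condition dyads
exhaustively (for pairwise rules with unbounded confidence this is identical
to Apriori-style rule mining, without the pruning machinery) and applies
three filters:

1. **Support**: joint frequency `a ≥ 15`. This is the classical floor used
   to limit statistical errors in sparse dyads.
2. **Significance**: `p < 0.01`, from the Pearson chi-square test (1 df, no
   continuity correction) when all four expected cell counts exceed five and
   from the two-sided Fisher exact test otherwise. On a 2x2 table the
   chi-square statistic reduces to `n·phi²`, which is how the package
   computes it; the all-cells-greater-than-five reading of the expected
   frequency rule is Cochran's, and the boundary is strict (an expected
   count of exactly 5 goes to Fisher). Both the correction and the rule are
   deliberately not configurable per-cell: `correct = TRUE` switches the
   whole chi-square branch to the Yates statistic if a user wants it.
3. **Positivity**: `phi > 0`. Co-occurrence analysis is about conditions
   appearing *together*; significant negative associations are excluded. A
   dyad with `phi = 0` exactly cannot be significant, so the strict
   inequality is immaterial.

`build_network()` then builds one weighted graph per measure under three
edge strata: all retained associations, the strongest 50 %
(`floor(0.5·m)` edges — the floor convention is what makes 7845 retained
associations yield a 3922-edge half network), and the strongest 200. Ties at
a stratum boundary are broken by pair label, ascending, so a "top 200"
network always has exactly 200 edges and stratum selections are nested in
`k`. An infinite relative-risk weight (a zero-denominator direction, legal
whenever `b = 0` or `c = 0` with support ≥ 15) ranks above every finite
weight.

Communities come from the weighted Louvain algorithm
(`detect_communities()`, via igraph), with modularity
`Q = Σ_c [W_c/W − (S_c/2W)²]` recomputed by the package's own direct
formula. Louvain needs finite weights, so for detection only, infinite
weights are replaced by ten times the largest finite weight in the network —
dominance preserved on a finite scale. The resolution parameter defaults to
1 (the original algorithm) and one run per seed is performed; a best-of-R
restart option exists but defaults to a single run.

`build_comparison_report()` compares the per-measure networks of a stratum
with three pairwise statistics: the adjusted Rand index between Louvain
partitions, the percent of edges in common, and the percent agreement on the
top-20 degree-central nodes. Because top-k networks built with different
measures generally have different node sets, ARI is computed on the
*intersection* of the two node sets (an alternative would pad the union with
singletons; the intersection is the default because ARI requires both
labelings to be defined on a common set, and edges — hence nodes — outside
the intersection are exactly the disagreement the edge-agreement statistic
already captures). Roll-ups over the 21 unordered measure pairs use the
median and Q1–Q3 with R's default linear-interpolation quantiles (type 7);
no convention for the quantile estimator is standard in this literature, so
the package uses R's.

## The synthetic cohort generator

Real administrative multimorbidity cohorts cannot be redistributed, so the
package ships a generative stand-in with known ground truth. The model is a
**latent-block logistic** model:

1. Conditions are assigned round-robin to `n_blocks` blocks (deterministic,
   so the planted truth is reproducible and every block receives a mix of
   prevalence bands).
2. Each individual independently activates each block with probability
   `block_activation_prob` (default 0.2).
3. Condition `j` is present with probability
   `plogis(logit(p0_j) + block_effect · [block active])`, where the base
   rate `p0_j` is calibrated by deterministic one-dimensional root finding
   (`uniroot` on the monotone marginal equation) so that the
   *pre-restriction* marginal probability equals the target prevalence.
4. Optionally, individuals with fewer than two conditions are dropped and
   prevalence is recomputed on the restricted cohort — mirroring analyses
   that compute prevalence on the multimorbid analysis cohort.

This is the simplest model that simultaneously gives (i) exact control of
the marginal prevalence spectrum, (ii) clustered co-occurrence with tunable
strength, and (iii) exact independence at `block_effect = 0`, which is what
the downstream filter's type-I behaviour is tested against.

Target prevalences come from `make_prevalence_spectrum()`: uniform draws
within the low (0.1–1 %), moderate (1–7 %) and high (7–30 %) bands, with the
band counts set by a mix of fractions. The high band is capped at 30 %
because chronic-condition category spectra rarely exceed the low twenties of
percent. The default mix (45 % low, 45 % moderate, 10 % high) reflects the
shape of large condition-category systems, where only a handful of
categories exceed 7 % prevalence; with many high-prevalence conditions the
high-high pair count would swamp the band-pair composition statistics.

The default benchmark conditions (`mixed_spectrum_config()`) are 200,000
individuals × 120 conditions in 6 blocks, `block_effect = 2.5`, activation
0.2, restricted to multimorbid individuals. The cohort size matters: with a
support floor of 15, a dyad needs joint probability above roughly
`15/n`, and only at `n` in the hundreds of thousands do associated
*rare-rare* pairs clear it — the regime in which lift and relative risk
characteristically promote low-prevalence pairs into the strongest-200
stratum.

## What the generator does and does not emulate

Passing benchmarks on this generator demonstrates that the pipeline's
machinery — calibration, filtering, ranking, community detection,
comparison — behaves correctly and that the measures' *directional*
preferences (lift/RR toward rare-rare pairs, Kulczynski toward
high-low pairs, joint prevalence toward prevalent pairs, with the largest
median prevalence *difference* under Kulczynski and the smallest under
lift) emerge as they do in real cohorts. It does **not** reproduce the
quantitative findings of any real-data study:

* Planted blocks are far cleaner than real disease clusters. All seven
  measures typically recover the same planted partition, so cross-measure
  ARI is near 1 on synthetic data, whereas real cohorts show poor
  community-structure agreement. The ARI machinery is therefore validated
  on hand-computable partitions and against an independent implementation,
  not via the synthetic benchmark.
* Because the block boost is a uniform log-odds shift, a rare condition in
  an active block becomes a near-certain indicator of its block-mates;
  Kulczynski's strongest edges consequently involve high-prevalence nodes
  even more often than joint prevalence's do. Real data instead shows joint
  prevalence with the greatest high-prevalence involvement. The suite
  therefore checks joint prevalence's defining direction — the largest
  median edge joint prevalence — rather than its share of high-band
  endpoints.
* No age/sex structure, care-seeking behaviour, coding noise, or disease
  progression is simulated.

## Numerical and design choices

* Prevalence bands are closed on the left of each upper band: 1 % is
  moderate, 7 % is high.
* "Significant at α = 0.01" is read as strict `p < 0.01`.
* Partition community ids are contiguous from 0, assigned in order of first
  appearance over sorted node labels, making partitions comparable across
  runs.
* Degenerate significance tables (a zero row or column margin) return
  `p = 1` under the Fisher branch rather than erroring, so fully empty or
  saturated dyads are silently excluded by the filter.
* Quantiles everywhere are linear-interpolation (R type 7).
* Determinism: every stochastic step (cohort generation, Louvain node
  order) consumes an explicit seed through `withr::with_seed`, so equal
  configurations reproduce byte-identical artifacts.

## Problem sizes

The shipped analysis scripts and benchmarks use the 200,000 × 120 cohort
(seconds to generate and analyse end-to-end), a 50,000 × 30 three-block
cohort for planted-block recovery, and 20,000 × 20 independent cohorts for
type-I control of the dyad filter. These sizes were chosen so each
benchmark's statistical target (binomial calibration error, a ≤ 2 % false
retention bound at α = 0.01 with positivity halving, ARI ≥ 0.8 recovery)
is comfortably identifiable.

## Limitations

Exact community counts and agreement values from any particular real cohort
are not reproducible from synthetic data and are not targeted; the package
reproduces the *arithmetic* of published global network properties (density
from node and edge counts, stratum sizes) and the directional behaviour of
the measures. Degree is the only centrality implemented — deliberately so,
as weighted centralities embed the very measure-choice sensitivity under
study — and Louvain the only community algorithm.
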