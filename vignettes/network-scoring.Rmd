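---
title: "Scoring transitive chemical-disease inferences by local network topology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring transitive chemical-disease inferences by local network topology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdscore)
library(dplyr)
```

## The problem

Curated toxicogenomic resources such as the Comparative Toxicogenomics
Database (CTD) record three kinds of direct, literature-curated
associations: chemical-gene interactions, gene-disease relationships and
chemical-disease relationships. Whenever a chemical interacts with one or
more genes that are also associated with a disease, a *transitive
chemical-disease inference* can be drawn through that shared gene set.
At database scale this produces hundreds of thousands of inferences per
release — far too many to inspect — and the underlying network is scale
free: a handful of heavily curated hub chemicals, genes and diseases
account for a large share of all edges. An inference supported by nine
hub genes is far less surprising than one supported by nine sparsely
connected genes, so raw gene counts are a poor ranking signal and produce
massive ties.

`cdscore` models the data as a binary tripartite network (nodes are
chemicals, genes and diseases; edges are present/absent associations
within the three permitted layers) and ranks each inference by how
improbable its local neighbourhood would be in a random network with the
same gross connectivity.

## The five statistics

Write $n_x$ and $n_y$ for the total degrees of the chemical $x$ and the
disease $y$, $A$ for the set of connecting genes with $m = |A|$, $n_i$
for the degree of connecting gene $i$, and $N$ for the number of nodes
with at least one edge. All statistics are reported on the $-\log_{10}$
scale, computed in log space throughout: with $N$ in the tens of
thousands and degrees above $10^3$, the underlying probabilities
underflow double precision otherwise.

**Hypergeometric mutual clustering coefficient.** If the neighbourhoods
of $x$ and $y$ were uniform random subsets of the $N$ nodes, the chance
of sharing at least $m$ neighbours is the hypergeometric upper tail

$$C_{xy} = -\log_{10} \sum_{i=m}^{\min(n_x, n_y)}
  \frac{\binom{n_x}{i}\binom{N-n_x}{n_y-i}}{\binom{N}{n_y}},$$

summed to $\min(n_x,n_y)$, the largest combinatorially possible overlap.
The tail is accumulated with log-sum-exp over log-gamma binomials
(`log_choose()`).

**Endpoint common-neighbour statistic.** $p_1$ is the corresponding
point probability of exactly $m$ common neighbours,
$-\log_{10} \binom{n_x}{m}\binom{N-n_x}{n_y-m} / \binom{N}{n_y}$. Since a
point probability can never exceed the tail containing it,
$p_1 \ge C_{xy}$ always. Both statistics penalise hub *endpoints* but are
blind to which genes make the connection.

**Gene-degree statistic.** A gene whose $n_i$ edges land on a uniform
random neighbourhood hits two fixed nodes with probability
$n_i(n_i-1)/\bigl(N(N-1)\bigr)$, so

$$p_2 = -\log_{10} \prod_{i \in A} \frac{n_i (n_i - 1)}{N (N - 1)},$$

additive over disjoint gene subsets and strictly decreasing in every
$n_i$: this is the only statistic that penalises hub *genes*, and it is
what separates two inferences with matched endpoint degrees and equal
$m$ but differently connected gene sets.

**Aggregates.** $p_1$ and $p_2$ are combined as a logarithmic opinion
pool — a weighted product of the probabilities, i.e. a weighted sum on
the $-\log_{10}$ scale, with normalisation constant $k = 1$. The
unweighted aggregate uses $w_1 = w_2 = 1/2$:
$S_{XYA} = (p_1 + p_2)/2$. Because $p_2$ grows roughly linearly in $m$,
$S_{XYA}$ correlates strongly with the raw gene count and lets
hub-dominated inferences with very many genes crowd the top of global
rankings. The weighted aggregate therefore shifts weight onto the
endpoint statistic as the gene count grows:

$$W_{XYA} = w_1(m)\, p_1 + w_2(m)\, p_2, \qquad
  w_2(m) = \bigl(1 - \tfrac{1}{\sqrt{2}}\bigr) 2^{-m}, \quad
  w_1(m) = 1 - w_2(m).$$

At $m = 1$ the gene-degree term carries about 15% of the weight; by
$m = 10$ it is negligible and $W_{XYA} \to p_1$. The weight function was
transcribed by requiring a single $(w_1, w_2)$ pair to reproduce the
package's reference score table (21 five-gene inferences of bisphenol A,
see below) together with the reference aggregate scores at $m = 9$ and at
$m \in \{186, 242, 280\}$; the fifteen internally consistent five-gene
rows pin $w_2(5)$ to $0.00915 \pm 0.0001$, the large-$m$ rows force
$w_2 \to 0$, and the $m = 9$ values select geometric decay with base
$1/2$; $(1 - 1/\sqrt{2})\,2^{-m}$ matches all of these within printed
rounding. Several simple alternatives ($\log_{10}2 \cdot 2^{-m}$,
$1/m^3$, $1/(m\,2^m)$) are excluded by the same data at more than four
standard errors.

**Bonferroni correction.** With $T$ inferences scored in a run, each
score is corrected as $\max(0,\; W - \log_{10} T)$, i.e. the probability
is multiplied by $T$ and capped at one. $T$ defaults to the size of the
current run and can be overridden when a run must be corrected against a
larger family.

## Scale conventions and the reference fixtures

The package ships two plain-text reference fixtures
(`make_fixture()`): the bisphenol-A table of 21 five-gene disease
inferences and the malathion/pioglitazone matched pair, both carrying
degrees and reference statistics from a July 2011 CTD release. Three
facts about these reference values, established by direct recomputation
(see `test-printed-values.R`), matter for interpretation:

* No single documented entity count reproduces them; the universe size
  implied jointly by the 18 distinct clustering-coefficient values in the
  reference table is $N = 38{,}940$ (carried as `snapshot_n` on the
  fixture). With it the $C_{xy}$ and $p_2$ columns are reproduced at
  display precision. `score_inferences()` therefore treats $N$ as a
  property of the network being scored, with an explicit
  `n_override` for pinning a snapshot.
* The reference $p_1$ column is on the *natural*-log scale: it equals
  $\ln 10$ times the package's $-\log_{10}$ point probability. The
  package keeps all five statistics on one $-\log_{10}$ scale — the
  coherent convention, and the one under which the probability-containment
  property $p_1 \ge C_{xy}$ is meaningful — and the fixture tests apply
  the $\ln 10$ factor explicitly when comparing against the reference
  column.
* A minority of reference rows (5 of 21) mix snapshots internally: their
  aggregate columns disagree with their own component columns by more
  than rounding (most visibly, a row whose reference $S$ differs from the
  mean of its reference $p_1, p_2$ by 0.075). Tests gate on that internal
  consistency check before comparing aggregates.

## Ranking, ties and the median-threshold classifier

`rank_inferences()` orders each chemical's (or disease's) inferences the
way the scores are consumed: curated relationships first, then descending
chosen score, with remaining ties broken by larger $m$ and then partner
identifier so the order is total and reproducible. The curated flag
records independent direct evidence; it never filters enumeration or
scoring.

`count_ties()` quantifies how discriminating a statistic is. Two tie
definitions are provided because equality is representation dependent:
`exact_display` counts equality after rounding to the 2-decimal display
precision (the default, matching how tied scores are actually seen), and
`numeric` uses a $10^{-9}$ tolerance. Display ties are always at least as
frequent as numeric ties. $C_{xy}$ and $p_1$ tie whenever two partner
diseases share a degree and gene count; $S$ and $W$ see the gene degrees
and tie far less often.

`median_threshold_classifier()` implements the simple screen for novel
inferences that most resemble curated ones: the threshold is the median
weighted score of curated inferences and novel inferences pass on strict
inequality, which by construction gives 50% sensitivity on odd-sized
distinct-valued curated samples (0% in the degenerate all-equal case —
documented, not special-cased).

## The degree-preserving null model

`shuffle_network()` randomises the chemical-gene layer by repeated edge
swaps: two edges $(c_1, g_1), (c_2, g_2)$ are drawn and their genes
exchanged. Every node's chemical-gene degree is conserved exactly, so the
scale-free degree structure survives while the specific co-association
pattern is destroyed. A proposed swap that would duplicate an edge, or
whose two edges share a chemical or gene (a no-op or duplicate), is
rejected and redrawn *without* counting toward `n_swaps`: counting only
applied swaps makes mixing depth comparable across network densities.
The swap loop aborts if the acceptance rate collapses (more than ~200
attempts per applied swap), rather than spinning on a network too
constrained to randomise.

`compare_real_vs_shuffled()` re-derives inferences from the shuffled
network, matches them to the real table on the (chemical, disease) pair —
gene sets may differ — and reports, per stratum (curated / novel /
total), the mean matched-pair score difference with a Welch
unequal-variance t-test (`stats::t.test`; a paired variant is available
by flag since two-sample versus paired is a genuinely open choice for
matched score lists). An empty match set is flagged explicitly rather
than reported as a zero difference.

## The synthetic generator

`generate_tripartite()` exists so every pipeline stage is testable
without a database download. It emulates the gross topology of curated
content: three binary layers over one universe whose pooled log-log
degree-frequency cloud is convex — a bulk of entities with a handful of
associations and a long sparse tail of curation hubs — with a
least-squares line of slope about $-0.8$ (`fit_powerlaw()`, unit-width
degree bins, zero-frequency degrees dropped before the log transform).

Construction: per node kind, target degrees are drawn from a mixture of
a shifted Poisson bulk ($2 + \text{Poisson}(2)$, reflecting that curated
entities rarely have exactly one edge) and, for a 15% curation-priority
minority, a truncated zeta tail; targets are binomially thinned to the
layer edge budgets, split between each kind's two permitted layers in
proportion to those budgets, and realised by random stub pairing with
duplicate collapse. Because collapse and layer caps steepen the realised
cloud, the sampled tail exponent is set 0.2 below the requested slope
magnitude; this calibration is empirical and is accurate near the default
target of 0.8 at the default densities (roughly 6 chemical-gene edges
per gene), degrading for much smaller or denser networks. Defaults:
`target_exponent = 0.8`, chemical-gene as the dominant layer (6 edges
per gene), and full determinism under `seed`.

Planted inferences (`plant_inference()`) wire $m$ genes from a chosen
degree stratum to a designated chemical and disease, preferring genes not
yet adjacent to either endpoint so both endpoint degrees grow by exactly
$m$; a curated plant also adds the direct edge. Free-endpoint plants
(as used by the shuffle-direction experiments) inherit whatever degrees
their endpoints have, and since $W$ is $p_1$-dominated at small $m$,
contrasts between gene-degree profiles are only informative when the
endpoints are degree-matched — the package's tests therefore plant
matched-endpoint pairs for that contrast, mirroring the classic
matched-pair design of two chemicals with similar degrees, equal $m$ and
very different gene connectivity.

What the generator does *not* emulate: literature and curation bias (hub
identity is random, not correlated with biological importance),
interaction types and directions, reference counts, and cross-layer
degree correlations beyond those induced by the shared budgets. Passing
tests on synthetic networks therefore demonstrate correctness and
directional behaviour of the statistics, not calibrated performance on
real curated content.

## Numerical and design choices

* All probability work is in log space; tails use log-sum-exp;
  `log_choose()` is log-gamma based and matches exact big-integer
  binomials to $10^{-12}$ relative at $n = 1000$.
* Validation is strict, not clamping: $1 \le m \le \min(n_x, n_y)$,
  $N > \max(n_x, n_y, n_i)$, every $n_i \ge 2$ (a connecting gene touches
  both endpoints) are rejected loudly. $m = 0$ is accepted only by
  `c_xy()`, where a tail of "at least zero" is the certain event.
* Monotonicity of $p_1$ in $m$ holds for $m$ at or above the
  hypergeometric mode; association networks operate in the sparse regime
  (expected overlap $n_x n_y / N$ below one), where it holds from
  $m = 1$.
* Scores are kept at full precision internally; the 2-decimal display
  variant is for reading, never for comparison.
* Node identifiers are case-sensitive and whitespace-trimmed; accession
  schemes are case-stable, while stray whitespace is a common copy
  artifact. An identifier appearing under two node kinds is an error.
* The test suite runs its simulation-based checks at deliberately modest
  problem sizes — networks of 300-4,400 nodes, $10^5$ applied swaps on a
  ~$10^4$-edge layer, 10 seeds per directional claim, 200 instances
  against an exact combinatorial oracle at $N \le 500$ — sizes at which
  every probabilistic claim is already well resolved.

## Known limitations

* The enumeration is grouped per chemical (bounded batches) rather than
  fully streamed to disk; at full-database scale (hundreds of thousands
  of inferences) memory stays modest, but the R-level scoring loop is not
  tuned for that scale.
* The weight function $w_2(m)$ is a transcription constrained by
  reference values at $m \in \{5, 9, 186, 242, 280\}$; any smooth
  function agreeing at those points to printed precision is
  observationally equivalent on the available data.
* The power-law fit is the plain least-squares line used by the field for
  this diagnostic, not a maximum-likelihood tail estimator; its value
  depends on the binning convention, which is why the convention is fixed
  and documented.
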