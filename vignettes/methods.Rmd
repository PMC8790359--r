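---
title: "Methods: rank-based condition classification and co-occurrence networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rank-based condition classification and co-occurrence networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

dreamnet compares mentions of medical conditions between two text corpora —
typically a large waking-life corpus (social-media posts) and a much smaller
corpus of dream reports — and models which conditions co-occur within the
same report. This vignette documents the statistical procedures, the
parameters that matter, the synthetic data generator used for validation,
and the numerical and design choices behind the implementation.

## Why ranks, not counts

The two corpora of interest differ in size by orders of magnitude, and both
are collected through self-selecting channels, so absolute mention counts
are not comparable. All cross-corpus comparison in this package therefore
works on *frequency ranks*: within each corpus, conditions are ranked by
descending mention frequency (rank 1 = most frequent; the higher the rank,
the less prevalent). Tied counts receive the average of the positions they
span (fractional ranking), which keeps every downstream computation
deterministic; any other tie-break would make the classifier's output
depend on hash order.

Counting itself differs by corpus type: for mention tables each mention
counts once (a tweet-like record can contribute several mentions), while
for dream reports a condition counts once per report containing it,
because a report is treated as a *set* of conditions throughout.

## Classifying conditions by relative prevalence

`classify_conditions()` partitions conditions into three classes —
typical of the waking corpus, equally prevalent, typical of dreams:

1. A condition absent from one corpus is assigned to the class typical of
   the other corpus. Its rank is undefined where it does not occur, so no
   regression can place it; the provenance flag (`waking_only` /
   `dream_only`) is retained so downstream reports can distinguish
   absent-corpus assignments from regression-based ones.
2. For the conditions present in both corpora, the dream rank
   $r_{dreams}(c_i)$ is regressed on the waking rank $r_{waking}(c_i)$ by
   ordinary least squares. The residual
   $res_i = r_{dreams}(c_i) - \hat r_{dreams}(c_i)$ is the vertical
   distance to the line: a strongly positive residual means the condition
   is far *rarer in dreams* than the overall trend predicts, so it is
   typical of waking discussions; a strongly negative residual marks a
   condition typical of dreams.
3. With $\mu$ and $\sigma$ the mean and standard deviation of the current
   residuals, conditions with $res - \mu \ge k_\sigma\,\sigma$ are labelled
   `TYPICAL_WAKING`, those with $res - \mu \le -k_\sigma\,\sigma$
   `TYPICAL_DREAM`, and both groups are removed. The line is refitted on
   the remainder and the rule reapplied, until an iteration removes
   nothing; the survivors are `EQUAL`. The default threshold is
   $k_\sigma = 1.5$.

Numerical details, all chosen for determinism and graceful degeneracy:

* $\mu$ and $\sigma$ are recomputed each iteration over the surviving
  points only.
* If the residual variance vanishes (all remaining points exactly on one
  line), the loop stops and the remainder is `EQUAL` — a degenerate
  straight line is exactly the stated stopping state.
* If fewer than three shared conditions remain (or exist at all), the
  regression is skipped with a warning and the shared conditions are
  labelled `EQUAL`.
* If the waking ranks are constant, an intercept-only fit is used.
* Termination is guaranteed: each iteration either removes at least one
  point or ends the loop, so there can be no more iterations than shared
  conditions.

### Behaviour to be aware of: the EQUAL class is a conservative core

Because $\sigma$ is recomputed after each trimming pass, the threshold
$1.5\sigma$ shrinks together with the surviving residual spread. On data
whose residuals vary continuously, successive refits keep finding points
beyond the current band, and the iteration continues until the remaining
points are nearly collinear. The practical consequence is that the
procedure trims aggressively: the final `EQUAL` class is a tight,
conservative core of conditions whose rank relationship is almost exactly
linear, not the full set of conditions that are "roughly equal". Users
who want a wider equally-prevalent band can raise `k_sigma`, at the cost
of admitting more marginal outliers. This contraction should be kept in
mind when interpreting class sizes, and it is why validation against the
synthetic generator's planted classes scores the enriched and
absent-corpus classes (recovered essentially perfectly under strong
separation) separately from the equally-prevalent class.

The regression orientation (dream rank as response) follows the residual
definition above; OLS is not symmetric in $x$ and $y$, so swapping the
corpora swaps the two typical classes exactly for absent-corpus
conditions and approximately — not identically — for regression-based
labels.

## The co-occurrence network

`condition_network()` builds a graph on the conditions mentioned in dream
reports: two conditions are joined if they appear in the same report at
least once, with edge weight the number of reports containing both.
With $N$ the number of reports, $P_i$ the number of reports mentioning
condition $i$, and $P_{ij}$ the number mentioning both $i$ and $j$, every
candidate edge receives the statistic set standard in comorbidity-network
analysis:

* relative risk $RR_{ij} = P_{ij} N / (P_i P_j)$, the ratio of observed
  to independence-expected co-occurrence, with log-scale standard error
  $\sigma_{ij} = \sqrt{1/P_{ij} + 1/(P_i P_j) - 1/N - 1/N^2}$ and
  confidence bounds $RR_{ij}\,e^{\pm 2.56\,\sigma_{ij}}$ (a 99%
  interval);
* the phi coefficient
  $\varphi_{ij} = (P_{ij} N - P_i P_j)/\sqrt{P_i P_j (N-P_i)(N-P_j)}$,
  identically the Pearson correlation of the two presence indicators,
  tested with $t = \varphi\sqrt{N-2}/\sqrt{1-\varphi^2}$ on $N-2$
  degrees of freedom (two-sided).

An edge is kept only when $\varphi_{ij} > 0$, $p_\varphi < 0.01$ and
$LB(RR_{ij}) > 1$ — positively associated, significantly so, and with the
whole confidence interval of the relative risk above independence. The
two measures are deliberately redundant ($RR>1 \iff \varphi>0$ is an
algebraic identity for non-degenerate pairs) but their uncertainty
quantifications differ, and the conjunction is conservative: on null
reports with no planted structure the surviving fraction of candidate
edges stays at or below the nominal 0.01, with the $LB(RR)>1$ conjunct
binding. Nodes left without edges (singletons) are discarded, both before
and after filtering.

Choices worth recording:

* **Sidedness.** The t-test is two-sided; the $\varphi > 0$ conjunct
  already enforces direction, and two-sided is the conservative default.
* **2.56.** The confidence multiplier is kept at 2.56 as printed in the
  methodology this package implements, not silently replaced by the
  textbook 2.576; it is exposed as `ci_multiplier`.
* **Degenerate pairs.** If a condition occurs in *every* report,
  $\varphi$ has a zero denominator. Such edges are flagged, excluded
  from filtering, and counted in the run log — a ubiquitous condition is
  a data-quality signal, not a statistical result.
* **Perfect association.** $|\varphi| = 1$ maps to $p = 0$.

On the filtered graph the package computes PageRank centrality (damping
0.85, transition probabilities proportional to edge weights; each
undirected edge acts as a pair of directed edges; weighting can be
disabled), per-class mean PageRank (an empty class is reported as
undefined, never zero), Newman's attribute assortativity over the three
condition classes (the class-mixing matrix of edges; undefined and
reported as `NA` when fewer than two classes meet an edge), connected
components with the giant component, and a min-degree "core": the induced
subgraph on nodes with at least five edges in the *full* filtered
network, computed in a single pass — deliberately not an iterated k-core
decomposition, which would keep removing nodes whose degree drops below
the threshold inside the core.

Assortativity is computed over the three classes; conditions found only
in dream reports enter as `TYPICAL_DREAM` per the absent-corpus rule,
with provenance retained so a four-way breakdown can still be reported.

## The synthetic generator

`generate_corpora()` produces a waking mention corpus, a set of dream
reports and a planted ground truth, emulating the statistical features
that drive the pipeline:

* **Heavy tails.** Base sampling weights follow a Zipf law
  $w_i \propto i^{-s}$ with exponent $s$ = 1.2 by default. At the default
  corpus sizes most appearing conditions occur once or twice, while the
  head is mentioned hundreds of times.
* **Planted prevalence structure.** Each condition is assigned one of
  five classes by largest-remainder apportionment of the class fractions
  (so counts sum exactly to the vocabulary size): equally prevalent,
  present only in one corpus (two classes), or enriched in one corpus
  (two classes). Enrichment divides the condition's sampling weight in
  the non-enriched corpus by $(1+\texttt{rank\_shift})^{s}$; under a
  Zipf law dividing a weight by $F$ multiplies the expected rank by
  $F^{1/s}$, so a condition at base rank $r$ is displaced by about
  $r\cdot\texttt{rank\_shift}$ ranks — multiplicative suppression
  preserves the marginal Zipf shape while displacing ranks.
* **Reports as sets with planted clusters.** Report sizes are
  $1 + \mathrm{Poisson}(\bar m - 1)$ (at least one condition). Each
  condition belongs to one of `n_clusters` clusters; with probability
  `within_cluster_prob` a report draws all its conditions from a single
  cluster (chosen proportionally to cluster weight), otherwise from the
  whole dream-eligible vocabulary, so same-cluster pairs co-occur at an
  elevated rate and cross-cluster pairs at the baseline rate.

Default sizes are chosen so the default spec is a desk-scale corpus with
the mention-to-vocabulary ratios of small health-mention datasets: 500
conditions, 2766 waking mentions (about 5.5 per vocabulary item, the
ratio of a survey-scale social-media corpus) and 833 reports of mean size
1.3 (about 2.2 dream mentions per vocabulary item, the ratio observed in
survey dream corpora). These ratios are what make the generated corpora
majority-rare, as real health-mention data are.

What the generator does **not** emulate: natural language (only condition
labels), bursty or correlated posting behaviour, surface-variant
proliferation ("covid" vs "covid 19"), report-length/vocabulary
correlation, or the far heavier-than-Zipf vocabulary tail of real
extraction output. Tests that pass on this generator therefore validate
the *algorithms* — counting, ranking, regression trimming, edge
statistics, filtering, graph analysis — not the linguistic realism of
any extraction step. The bundled `lexicon_extract()` is demonstration
plumbing (case-insensitive longest-match on word boundaries, longer
phrases suppressing overlapping shorter ones); it is not a medical
named-entity recogniser.

Normalization deliberately stops at lowercasing and whitespace collapse.
Surface variants of the same concept remain distinct conditions because
merging them would change every downstream rank; real pipelines that
want variant merging should do it upstream, explicitly.

## Problem sizes and reproducibility

Every generator function takes an explicit seed and restores the
caller's RNG state, so identical specifications give bit-identical
corpora and the whole pipeline is deterministic given its inputs:
repeated `run_pipeline()` calls on the same configuration produce
byte-identical artifacts. The validation suite exercises the pipeline at
deliberately modest sizes — vocabularies of 30–500 conditions, corpora
of a few thousand mentions, null-model studies of a few hundred
replicates of 500 reports, exhaustive edge-statistic sweeps over all
contingency tables with at most 12 reports — sizes chosen so the full
suite runs in well under a minute while still leaving each statistical
property with enough resolution to fail visibly if broken. The
strong-separation recovery study uses larger corpora (200,000 waking
mentions, 20,000 reports) so that rank noise is small relative to the
planted displacement.

## Known limitations

* The iterative trimming contraction described above: `EQUAL` is a
  conservative core, and its size is not a calibrated estimate of the
  number of equally-prevalent conditions.
* Edge significance uses the phi t-test and a log-normal RR interval;
  for very sparse pairs ($P_{ij} = 1$) both are approximations, which is
  precisely why the conjunctive filter errs on the side of dropping
  edges.
* PageRank weighting is a modelling choice (`weighted = TRUE` by
  default); with heavy-tailed edge weights the two variants can rank
  mid-centrality nodes differently.
* No generalisation beyond two corpora, and no uncertainty
  quantification on class assignments.
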