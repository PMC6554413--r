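---
title: "Neighbourhood degree sequences: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neighbourhood degree sequences: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ndseq)
```

## The model

Every index in this package is a functional of the multiset of
*neighbourhood degree sequences* of a simple undirected graph: for node $i$
of degree $k_i$, $s_i$ is the nondecreasing list of its neighbours' degrees.
The organising idea is *hierarchical equivalence*: two nodes of the same
degree occupy the same level of the degree hierarchy, and comparing their
sequences asks whether they also play equivalent roles in the topology —
irrespective of whether they are connected. This is deliberately different
from assortativity, which correlates degrees *across edges*.

Bookkeeping per degree class $p$: $\mathcal V_p$ (nodes of degree $p$),
$q_p = |\mathcal V_p|$, $\sigma_p$ (the distinct $p$-length sequences),
multiplicities $c_{pj}$ with $\sum_j c_{pj} = q_p$, positional means
$\mu^p(j)$, and $D_2$ = degrees with $q_p \ge 2$. All per-degree indices are
computed on $D_2$ only: with a single sequence in a class there is nothing to
compare.

The five sequence indices:

* **Node heterogeneity** $V_n = \frac{1}{n}\sum_{i:k_i>1}\mathrm{var}(s_i)$.
  The sum skips degree-$\le 1$ nodes (their sequences have no spread) but the
  divisor deliberately counts all non-isolated nodes, as the index is
  conventionally defined; `denominator = "contributing"` averages over
  contributing nodes only, for users who prefer a true mean.
* **Relative node heterogeneity** $\hat V_n = V_n / \mathrm{var}(k)$ — local
  against global heterogeneity; undefined on regular graphs.
* **Neighbourhood similarity** $S$ — the fraction of nodes whose sequence is
  matched by at least one *other* node. A literal reading of the defining
  double-delta expression includes the self-match $j = i$ and is identically
  1 for every graph; the package excludes self-matches (that variant is
  available as `include_self = TRUE` purely for transparency). Any graph
  drawable with mirror or rotational symmetry whose axis pivots on no node
  has $S = 1$, because each node has a symmetric partner with an identical
  sequence — the disjoint double $H \sqcup H$ of any graph is the canonical
  example, and is exercised as a property test over random graphs.
* **Neighbourhood organisation**
  $\Omega = 1 - \frac{1}{|D_2|}\sum_{p \in D_2}\omega_p$ with
  $\omega_p = |\sigma_p|\sum_j (q_p - c_{pj}) / (q_p^2(q_p-1))$. The sum is
  restricted to $D_2$ (where $\omega_p$ is defined); that restriction is also
  what makes $\Omega \in [0,1]$ provable, since each $\omega_p \in [0,1]$.
* **Hierarchical complexity** $R$ and its correction $R_\Omega$ — the mean
  (over $D_2$) positional variance of equal-length sequences, the corrected
  version multiplying each degree's term by $\omega_p$ so that multi-ordered
  degrees (classes whose sequences form few repeated groups) are suppressed.
  $R_\Omega \le R$ always.

### The $\omega_p$ closed form, and a limitation inherited with the formula

Algebraically $\sum_j (q_p - c_{pj}) = q_p(|\sigma_p| - 1)$, so
$\omega_p = |\sigma_p|(|\sigma_p|-1)/(q_p(q_p-1))$ — the implementation uses
this closed form and keeps the literal sum as a cross-checked second route
(`method = "literal"`). A consequence worth knowing: $\omega_p$ depends on
the multiplicities only through their *count* $|\sigma_p|$. The motivating
idea distinguishes a class with multiplicities $(1,1,3)$ (one repeated
pattern) from $(1,2,2)$ (two repeated patterns), but the formula assigns both
the same value; no formula of this shape can realise that distinction. We
implement the formula as defined and note the gap here rather than invent a
different index.

### Two normalisations of $R$

Two mutually inconsistent conventions for hierarchical complexity are in
circulation: the defining equation averages the per-degree terms over $D_2$,
while published per-network tables for this index family report that average
divided additionally by the node count $n$ (verified to reproduce the karate
club reference values 0.296 / 0.190 exactly, where the literal equation
gives $34\times$ those values). `normalisation = "per_node"` (default)
matches the tables; `"equation"` is the literal formula, and the small
worked examples in the tests (e.g. $R(P_5) = 1/12$, $R_\Omega(P_5) = 1/36$)
are stated under it. The report records which was used.

### Variance convention

Whether $\mathrm{var}(\cdot)$ divides by the sequence length or by length
minus one is rarely stated alongside these indices. Both are implemented;
the package default is the population variance (divide by length). The
karate-club reference value $\hat V_n = 1.714$ is reproduced by the *sample*
convention (population gives 1.205), so comparisons against those reference
values pass `variance = "sample"`; every report carries the convention in
its provenance. The same convention is always applied to both numerator and
denominator of $\hat V_n$.

## Degenerate inputs and edge rules

* **Isolated nodes** are excluded from degree classes and from every index
  denominator, with a warning: pairwise comparison of empty sequences is
  meaningless and would make $S$ artificially high. `sequence_table()` still
  lists them (with empty sequences) so nothing is silently lost.
* **Regular graphs**: $\hat V_n$ undefined ($\mathrm{var}(k)=0$); reported
  as `NA` plus a flag, never as 0.
* **$D_2 = \emptyset$** (all degree classes singletons): $\Omega$, $R$,
  $R_\Omega$ undefined, flagged. There is no defensible default value.
* **Multi-edges and self-loops** in inputs are collapsed/dropped with counts
  recorded in the graph's provenance; all formulas assume simple graphs.
* **Density binarisation** keeps the $\lceil d\,n(n-1)/2\rceil$
  heaviest pairs; ties at the cut weight are all kept. This makes the rule
  deterministic and order-independent at the cost of occasionally exceeding
  the requested density slightly — preferable to an RNG tie-break that would
  make preprocessing irreproducible.
* **Characteristic path length** on disconnected graphs averages existing
  (finite) shortest paths only.
* Comparisons against 3-decimal reference values use round-half-even
  (`round()`), stated here once.

## Null models

`configuration_rewire()` randomises by double edge swaps — replace
$(a,b),(c,d)$ with $(a,d),(c,b)$ when the result stays simple — which
preserves every node's degree exactly. The default of 10 attempted swaps per
edge is a common mixing heuristic; it is a tunable, and the karate-club null
mean of $S$ is stable between 10 and 100 swaps per edge in our tests.
Stub-matching samplers with rejection were not implemented: rewiring
suffices for degree-fixed nulls and never needs rejection. Graphs admitting
no valid swap (stars, complete graphs) are returned unchanged with a
warning.

`null_ensemble()` derives one RNG stream per realisation up front from a
single seed, so summaries are independent of evaluation order and
reproducible bit-for-bit. Published workflows in this index family have used
both 10 realisations (per-network tables) and 50 (corpus-level tests); the
default is 10 with the count exposed everywhere.

One statistical caution encoded in the acceptance tests: a null mean quoted
from a 10-realisation ensemble is itself a Monte-Carlo estimate with
non-trivial SE. When checking our 50-realisation mean against such a
reference, the correct error term is the SE of the *difference*,
$\sqrt{s^2/50 + s^2/10}$, not the SE of our estimate alone.

## Statistics

`wilcoxon_paired()` implements the two-sided signed-rank test natively. Zero
differences are dropped (Wilcoxon's original prescription; the count is
reported). The exact branch builds the null distribution of the statistic by
convolution over the (possibly tied, average) ranks — equivalent to
enumerating all $2^n$ sign assignments, which is exactly how the test suite
cross-checks it — and is used up to $n = 25$; beyond that, the normal
approximation with tie correction and continuity correction (identical to
`stats::wilcox.test`'s asymptotic branch) takes over. A native
implementation was needed because the standard library's exact branch
refuses ties, while the corpus comparisons here routinely produce tied
differences.

Effect sizes are matched-pairs rank-biserial correlations,
$(W^+ - W^-)/(W^+ + W^-)$, signed so that "observed exceeds null" is
positive — the convention that makes an index *smaller* in real networks
than in their nulls come out negative. Corpus comparisons pair each network
with the *mean* of its null ensemble (not individual realisations), and
strata with fewer than 5 networks are reported descriptively without a
p-value.

`spearman_matrix()` is rank-then-Pearson with average-rank ties; constant
columns are flagged and left `NA` off-diagonal rather than being assigned a
correlation.

## What the synthetic generators do and do not establish

The test fixtures are built in code: canonical graphs (stars, paths, cycles,
complete graphs), the packaged 34-node/78-edge karate club edge list, the
disjoint-double construction, and *planted multi-ordered graphs* — for
chosen group multiplicities $c_1,\dots,c_g$, each group $j$ is two hubs of a
distinct degree $d_j \ge 3$ joined by $c_j$ parallel length-2 paths, so the
degree-2 class consists of exactly the path midpoints and falls into exactly
$g$ sequence groups with multiplicities $c$. This gives
$\omega_2 = g(g-1)/(q(q-1))$ in closed form, which the tests verify, and a
corpus of such graphs is guaranteed by construction to have higher $\Omega$
than its rewired nulls — the direction, not the magnitude, is the tested
claim.

These generators emulate the *mechanisms* the indices respond to (regularity,
symmetry, planted repetition, degree heterogeneity). They do not emulate
several features of real corpora: heavy-tailed degree distributions combined
with community structure, degree–degree correlations, weighted or directed
interactions, or the scale (up to $10^4$+ nodes) of real repositories. A
green test therefore establishes correctness of the computations and the
forced directions on constructed inputs — it does not reproduce
corpus-level p-values or effect sizes, which depend on hundreds of external
networks out of scope here.

## Known limitations

* All equal-degree comparisons are *exact* in degree; nodes differing by one
  connection land in different classes, which makes the per-degree indices
  brittle on sparse heavy-tailed graphs where many classes are singletons.
* $\omega_p$ cannot distinguish multiplicity profiles with equal
  $|\sigma_p|$ (see above).
* Weighted/directed generalisations of the indices are intentionally absent;
  weights and directions are preprocessing inputs only.
* Subtree signatures stop at height 2; deeper Weisfeiler–Lehman iterations
  and kernel matrices between graphs are out of scope.
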