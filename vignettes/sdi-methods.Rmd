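---
title: "The Subcellular Diversity Index: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Subcellular Diversity Index: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdindex)
```

## The model

A gene's products may localize to one compartment or to many. The GO
Cellular Component ontology (GO-CC) records localization as term
annotations, but because GO-CC is a DAG with *is-a* and *part-of*
inheritance, a gene's term set typically carries heavy redundancy — "nuclear
lumen" adds little beyond "nucleus". The Subcellular Diversity Index (SDI)
quantifies localization diversity after discounting that redundancy.

For a gene with deduplicated term cluster $c$, $|c| = n$:

$$\mathrm{SDI} = \sum_{i=1}^{n} (1 - p_i), \qquad
p_i = \begin{cases} 1 & n = 1 \\
\sqrt{\tfrac{1}{n-1}\sum_{j \ne i} s(i,j)^2} & n > 1 \end{cases}$$

Each term contributes up to one unit of diversity, reduced by its penalty
$p_i$: the root-mean-square of its Wang semantic similarities to the other
terms. A single-term gene has penalty 1 and SDI exactly 0 — one location is
zero diversity — which also forces the genome-wide minimum to 0 whenever any
single-term gene exists. SDI is bounded by $[0, n]$ and is invariant to term
enumeration order.

Wang's measure is the hybrid node/edge similarity: for term $A$ with
ancestor graph $(T_A, E_A)$, the semantic contribution of $t \in T_A$ is

$$S_A(A) = 1, \qquad
S_A(t) = \max\{\, w_e \cdot S_A(t') : t' \text{ a child of } t \text{ in } T_A \,\}$$

with per-edge-type contribution factors $w_e$, and

$$S(A,B) = \frac{\sum_{t \in T_A \cap T_B} (S_A(t) + S_B(t))}
                {SV(A) + SV(B)}, \qquad SV(A) = \sum_{t \in T_A} S_A(t).$$

The recurrence is evaluated by memoized dynamic programming in
reverse-topological order over the ancestor graph; the test suite checks it
against a naive exponential path enumerator ($S_A(t)$ = max product of edge
weights over all upward paths), which is the most implementation-independent
statement of the same quantity.

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| `w_is_a` | 0.8 | contribution factor for *is-a* edges, the value recommended by the measure's authors; unitless decay per edge |
| `w_part_of` | 0.6 | contribution factor for *part-of* edges, same source |
| `aggregator` | `rms` | RMS penalties validated best against human essential genes among RMS / arithmetic / geometric alternatives; the package implements all three |
| `exclude_iea` | `FALSE` | the headline configuration includes all evidence codes, IEA included |
| `exclude_not` | `TRUE` | a NOT qualifier asserts *non*-localization; counting it as a location would contaminate a diversity score |
| perturbation `term_count_range` | 1–45 | the range of actual per-gene GO-CC term counts in human, used when replacing annotations in the robustness analysis |

Because all pairwise similarities lie in $[0,1]$, the power-mean inequality
gives $p^{\mathrm{rms}}_i \ge p^{\mathrm{mean}}_i \ge p^{\mathrm{gmean}}_i$
per term and hence $\mathrm{SDI}^{\mathrm{rms}} \le \mathrm{SDI}^{\mathrm{mean}}
\le \mathrm{SDI}^{\mathrm{gmean}}$ per gene; the suite asserts this with
strictness on at least one gene.

## The evaluation harness

* **ROC/AUC** — the rank statistic (probability a random positive outscores
  a random negative, ties half), asserted *equal* to brute-force pair
  counting, not approximately.
* **Decile enrichment** — genes sorted ascending by score, ties broken by
  gene id, split into ten contiguous groups whose sizes differ by at most
  one (remainder to the lowest groups; group 10 = highest scores); Pearson
  chi-square without continuity correction on the 2×10 table.
* **Spearman correlation** — average-rank ties, two-sided asymptotic p
  (exact p is undefined with ties); display smoothing of scatter plots is a
  plotting concern and deliberately not part of the statistic.
* **CV logistic regression** — stratified k-fold (stratification avoids
  single-class folds; folds redrawn up to 5 times otherwise), model fit on
  training folds, held-out probabilities pooled across folds before one AUC
  is computed.
* **Sensitivity analysis** — per replicate, a random `fraction` of genes has
  its entire term set replaced by a uniformly-sized (1–45) random term set;
  rescoring and AUC re-evaluation across fractions 5/10/20% reproduces the
  robustness-table layout (Group 1..k rows, Average row, baseline column).

## What the synthetic world does and does not establish

`make_ontology()` builds a connected single-rooted DAG by levels (each
non-root term takes 1–2 parents from strictly shallower levels), which
guarantees acyclicity by construction rather than post-hoc checking. Edge
labels are *part-of* with probability `part_of_fraction`. `make_annotations()`
samples uniform-size term sets; `make_labels()` draws positives with
$P(\text{positive}) = \mathrm{logit}^{-1}(\alpha + \beta \cdot \mathrm{SDI})$,
default $\alpha=-2,\ \beta=0.8$ — a weak-to-moderate monotone dependence that
makes parameter recovery non-trivial at $n = 2000$ genes.

The generator emulates the *shape* of real inputs (OBO stanzas, gene2go
columns, term-count ranges), not the scale-free topology, depth profile or
annotation bias of the real GO-CC. A green test therefore establishes
correctness of the algorithms and the stated statistical behavior under a
known mechanism; it does not certify the empirical AUCs or correlations
reported for real human data, which depend on specific historical GO and
gene2go releases and are out of scope here.

## Numerical choices

* Similarities and scores are computed and stored at full double precision;
  the 3-decimal TSV output is display formatting only
  (`--full-precision` disables it).
* `score_genome()` computes each distinct term's profile once and assembles
  all pairwise similarities as one matrix product, so results are
  independent of gene iteration order; per-gene `gene_sdi()` takes the
  pairwise route and the suite cross-checks the two.
* Geometric-mean penalty with a zero similarity returns 0 (limit
  convention); reachable only on disconnected fixture ontologies, since any
  shared root makes all similarities positive.
* Quartiles use the type-7 (linear interpolation) convention by default,
  with type-1 available — the convention behind published summary tables is
  not stated anywhere authoritative.
* Penalty vectors are ordered by lexicographic term order for byte-stable
  output.
* Parallel edges of different relation types between the same child/parent
  pair take the max of both weighted contributions, consistent with the max
  rule of the recurrence.

## Design choices made where the design was open

* **NOT-qualified rows** are dropped by default but restorable
  (`exclude_not = FALSE`), since upstream practice is not documented.
* **Perturbation sizes** are uniform over `term_count_range`; sampling sizes
  from the empirical per-gene term-count distribution is a defensible
  alternative but changes nothing the robustness battery measures, so the
  surface was kept minimal.
* **Decile numbering** is ascending (group 10 = highest SDI), matching the
  rising-enrichment presentation of the decile analysis.
* **CLI provenance** records inputs, parameters, seed and version but no
  timestamp, so identical runs produce identical bytes.

## Known limitations

* OBO parsing covers the go-basic `[Term]` dialect only (no OWL, no
  cross-ontology links); GAF/GPAD annotation formats are not read.
* Identifier systems are taken as-is; no symbol/ID cross-mapping.
* Reported empirical values tied to historical database releases
  (genome-wide summary tables, real AUCs) are version-bound and not
  regenerable from this package alone.
* The evaluation harness computes statistics, not figures; ROC point tables
  are emitted for external plotting.
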