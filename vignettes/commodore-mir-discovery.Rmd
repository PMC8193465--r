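---
title: "Methods: commodore miR discovery in MI co-expression networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: commodore miR discovery in MI co-expression networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(cdremir)
```

## The model

cdremir identifies *commodore miRs*: microRNAs that sit at the centre of
large, non-redundant neighbourhoods in subtype-specific miR-gene
co-expression networks. The analysis has four stages.

**1. Mutual-information networks.** For each sample subtype we score every
miR-gene pair with the plug-in (maximum-likelihood histogram) estimate of
mutual information in bits,

$$\hat I(X;Y) \;=\; \sum_{a,b} \hat p(a,b)\,
  \log_2 \frac{\hat p(a,b)}{\hat p(a)\,\hat p(b)},$$

where the marginal cells are equal-frequency bins of each transcript's
expression values. MI is preferred over correlation because it captures
non-linear and non-monotone dependence; the equal-frequency (rank-based)
binning additionally makes the estimate invariant under any strictly
monotone transform of either variable, so the same network is obtained from
FPKM, log-FPKM, or quantile-normalised input.

A network keeps the top $(1-q)$ fraction of all scored pairs:
with $N$ pairs the threshold is the $m$-th largest score,
$m = \lceil (1-q)\,N \rceil$, and **every** pair whose score ties the
threshold is retained. No tie-breaking is performed — ties reflect genuine
score equality, and dropping an arbitrary subset would make the network
depend on storage order. Edge counts can therefore slightly exceed the
nominal $m$.

**2. Bipartite redundancy.** For a node $v$ with neighbourhood $N(v)$ in the
opposite layer (degree $k = |N(v)|$), the redundancy coefficient is

$$rc(v) \;=\; \frac{\big|\{\,\{u,w\} \subseteq N(v) :
  \exists\, v' \ne v \text{ adjacent to both } u \text{ and } w \,\}\big|}
  {\binom{k}{2}},$$

the fraction of neighbour pairs that would remain co-connected if $v$ were
removed. It is the bipartite analogue of a clustering coefficient:
$rc(v) = 1$ means $v$ is fully dispensable for its neighbourhood's
cohesion, $rc(v) = 0$ means $v$ is the unique hub binding its targets
together. For $k < 2$ the quantity is undefined and reported as `NA` rather
than an arbitrary 0 or 1.

**3. Commodore classification.** A miR is a commodore when it is a large,
non-redundant hub: degree $\ge k_{\min}$ **and** $rc \le rc_{\max}$, both
bounds inclusive. Nodes with undefined $rc$ are never classified (they
cannot pass the degree gate anyway when $k_{\min} \ge 2$).

**4. Functional interpretation.** Each commodore's gene neighbourhood is
tested for over-representation of ontology terms with the hypergeometric
upper tail (`stats::phyper`), the universe being the intersection of
expressed and annotated genes. Terms with zero overlap are skipped before
multiple-testing adjustment so the Benjamini-Hochberg family contains only
testable hypotheses. Significant terms are then condensed into *function
groups*: Wang semantic similarity is computed between all term pairs, terms
are clustered by average-linkage hierarchical clustering on $1 - sim$, and
each cluster is represented by its most significant member.

### Wang similarity

For a term $A$, every ancestor $t$ (including $A$) receives an S-value:
$S_A(A) = 1$ and $S_A(t) = \max \{ w_e \cdot S_A(c) \}$ over edges
$t \xrightarrow{e} c$ on paths from $A$, with contribution weights
$w_{is\_a} = 0.8$ and $w_{part\_of} = 0.6$ (the weights from Wang et al.'s
original formulation). Similarity is

$$sim(A,B) = \frac{\sum_{t \in T_A \cap T_B} S_A(t) + S_B(t)}
  {\sum_{t \in T_A} S_A(t) + \sum_{t \in T_B} S_B(t)}.$$

S-values are computed by dynamic programming in topological order over the
ancestor closure, which is exactly the max-over-paths recursion. Two
sibling terms under a common root have similarity $4/9$, a useful fixed
point for verification.

## Parameters and defaults

| Parameter | Default | Rationale |
|---|---|---|
| `n_bins` | $\lfloor\sqrt{n}\rfloor$ | Standard bias/variance compromise for plug-in MI; keeps expected cell counts $\approx \sqrt{n}$. |
| `quantile` (q) | 0.9999 | Retains ~1 pair in 10,000; at genome scale ($\sim 10^6$–$10^7$ pairs) this yields networks of hundreds to thousands of edges dominated by strong dependence. |
| `k_min` | 100 | A commodore must coordinate a large regulon; 100 targets distinguishes master regulators from locally correlated miRs. |
| `rc_max` | 0.5 | At most half the neighbour pairs may be recoverable without the miR; above this the hub is structurally dispensable. |
| `alpha` | $10^{-3}$ | Adjusted-p cut-off for enrichment; conservative because neighbourhoods are themselves selected for extremeness. |
| `n_groups` | 10 | Upper bound on function groups per commodore; the tree is cut at $\min(n_{groups}, n_{terms})$. |

All bounds are inclusive, and every stochastic step is driven by a single
integer seed, so a run is reproducible byte-for-byte (see
`write_report_bundle()`).

## The synthetic study conditions

`simulate_expression()` generates the package's study conditions: paired
miR and gene expression with known planted structure, against which the
whole pipeline can be validated end to end.

* Every transcript starts as independent log-normal noise
  ($\exp(\mu + \sigma Z)$), mimicking the right-skewed, strictly positive
  shape of FPKM data.
* Within a subtype's samples, a planted *driver* miR shares one latent
  standard-normal factor $f$ with each of its targets: on the log scale
  $z = s f + (1-s)\varepsilon$ with strength $s \in [0,1]$, then
  $\text{expr} = \exp(\mu + \sigma z)$. The link is strictly monotone in
  $z$, so equal-frequency binning sees the full dependence; $s = 0$
  recovers exact mutual independence (not merely weak correlation), which
  is what a null/noise condition must mean for an MI method.
* A planted *redundant group* (by default a trio) shares one latent factor
  with a common target set, so each member is a high-degree hub whose
  neighbours are all co-connected through the other members — the textbook
  $rc \approx 1$ configuration the classifier must reject.

The default conditions are 20,000 genes × 300 miRs × 100 samples per
subtype, with one driver (120 exclusive targets, $s = 0.9$) and one trio
(3 miRs sharing 110 targets) per active subtype. At these dimensions
$q = 0.9999$ keeps $\lceil 10^{-4} \cdot 6\times10^6 \rceil = 600$ edges,
so a driver can reach degree $\ge 100$ while background pairs are crowded
out; the degree gate and the redundancy filter are both genuinely
exercised. (At much smaller gene counts the quantile law would cap the
network below $k_{\min}$ edges and the classifier could never fire — the
dimensions are part of the model, not a tuning knob.)

`simulate_ontology()` builds a single-rooted random DAG in which one "true"
term annotates exactly each driver's target set, plus size-matched random
terms, giving ground truth for the enrichment and aggregation stages.

What the generator does **not** emulate: count noise (no negative-binomial
sampling), batch effects, correlated background modules, or miR-mediated
*repression* (the planted dependence is symmetric; MI is sign-blind, so
this does not affect network construction).

## Numerical choices

* **Binning**: labels are $\lceil r \cdot b / n \rceil$ from minimum ranks,
  so tied values always share a bin; a transcript with fewer distinct
  values than bins still gets a valid (coarser) histogram. Constant
  transcripts carry no information and are dropped with a warning.
* **Threshold**: selected by partial sort of all $N$ scores; the ceiling
  convention and full tie retention make the edge set a deterministic
  function of the score multiset.
* **MI kernel**: computed in C++ with an integer $\log_2$ lookup table over
  contingency counts; results match the definitional R estimator to
  $10^{-12}$ and are clamped at 0 to absorb floating-point negatives.
* **Redundancy**: sparse adjacency algebra (`Matrix::tcrossprod`) counts,
  for each neighbour pair, the co-connections through other same-layer
  nodes; tested for exact equality against a brute-force triple loop on
  exhaustively enumerated small graphs.
* **Enrichment**: upper tail as $P(X \ge k)$ via
  `phyper(k - 1, K, N - K, n, lower.tail = FALSE)`; BH via
  `stats::p.adjust`.
* **Aggregation**: average linkage balances single linkage's chaining and
  complete linkage's sensitivity to one dissimilar pair; representatives
  break ties by adjusted p, then raw p, then lexicographic term id, so
  output never depends on row order.

## Limitations

* The plug-in MI estimator is positively biased at small $n$; with
  $b = \lfloor\sqrt{n}\rfloor$ bins the bias is roughly uniform across
  pairs and largely cancels in the *ranking*, which is all the quantile
  threshold uses — but reported MI values should not be read as unbiased
  dependence estimates.
* Subtypes need enough samples for meaningful binning
  (`split_by_subtype()` enforces $\ge 4$; dozens are advisable).
* The redundancy coefficient is scored on the thresholded network, so it
  inherits the threshold's arbitrariness near the cut.
* Hypergeometric enrichment assumes exchangeable genes; co-expressed
  neighbourhoods violate independence, so adjusted p-values are better
  treated as ranking scores than literal error rates (the default
  $\alpha = 10^{-3}$ is chosen with this in mind).
* Wang similarity depends only on DAG topology, not annotation frequency;
  terms in sparsely structured regions of an ontology may cluster
  coarsely.
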