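---
title: "Inferring node and arc multiplicities in de Bruijn graphs with conditional random fields"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring node and arc multiplicities in de Bruijn graphs with conditional random fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dbgcrf)
```

## The problem

A compacted de Bruijn graph built from short-read sequencing data represents
every k-mer of the read set as part of a unitig (a maximal non-branching
path) and every observed (k+1)-mer as an arc between unitig sides.  The
*multiplicity* of a node or arc is the number of times its k-mer (resp.
k+1-mer) occurs in the underlying genome: multiplicity 0 marks a sequencing
error artifact, 1 a unique genomic sequence, and m >= 2 a repeat of copy
number m.  Coverage reflects multiplicity only noisily: real sequencing runs
are overdispersed, and the coverage distributions of adjacent multiplicities
overlap, so any per-element cutoff rule misclassifies the ambiguous mass.

`dbgcrf` assigns multiplicities by combining two sources of evidence in a
conditional random field (CRF):

* **Coverage evidence.**  Element coverage is modelled by a mixture of
  negative binomial (NB) components, one per multiplicity.  We parameterise
  the NB by its mean $\lambda$ and overdispersion factor $f =
  \mathrm{var}/\mathrm{mean}$ (so $p = (f-1)/f$, $r = \lambda/(f-1)$ in the
  classical parameterisation, and $f \to 1$ is the Poisson limit).  The
  error component has mean $\lambda_0$ and dispersion $f_0$; the component
  for multiplicity $m \ge 1$ has mean $m\lambda$ and dispersion $f$.  Each
  component carries a weight $w_m$, the expected number of elements of that
  multiplicity, so the *singleton factor* of an element with coverage $C$
  scores candidate multiplicity $m$ as $w_m P_m(C)$.
* **Conservation of flow.**  In a correctly labelled graph the multiplicity
  of every node equals the sum of the multiplicities of its incoming arcs,
  and likewise for its outgoing arcs.  Each side of each node contributes a
  *flow factor* that scores an assignment 1 when the side's balance holds
  and a small $\varepsilon$ (default $10^{-7}$) when it is violated.

The posterior over an element's multiplicity is the normalised product of
all factors in a neighbourhood of size $s$ around it, computed exactly by
variable elimination.  At $s = 0$ the method degenerates to the classical
histogram-cutoff rule; growing $s$ lets coverage evidence from the
surrounding subgraph override locally misleading coverage.

## Worked micro-example

A low-coverage node that locally looks like a sequencing error is rescued
by consistent high-coverage context two steps away:

```{r}
g <- dbg_graph(3,
  data.frame(seq = strrep("A", 12), cov_sum = 10 * c(30, 12, 5, 12, 30)),
  data.frame(from = 1:5, from_side = "right", to = c(2:5, 1), to_side = "left",
             k1mer = "AAAA", cov = c(28, 7, 7, 7, 28)))
m <- nb_mixture(lam = 30, f = 1.5, lam0 = 1.5, f0 = 1.5,
                weights = c(1000, 1000, 100, 10, 1, 1))
sapply(0:3, function(s) infer_element(g, m, m, 3, "node", s = s)$map)
```

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `k` | 21 | k-mer size (odd, <= 31); arcs are k+1-mers |
| `abundance_min` | 2 | k-mers seen fewer times are dropped at construction |
| `weighted` | TRUE | q-mer counting: each k-mer occurrence contributes the product of its bases' correctness probabilities $1 - 10^{-Q/10}$ |
| `s` | 3 (inference), 1 (EM) | neighbourhood radius in arcs |
| `alpha` | 2 | candidate multiplicities are restricted to $[\max(0, m_{\mathrm{opt}}-\alpha),\, m_{\mathrm{opt}}+\alpha]$ around the locally most likely value |
| `eps` | 1e-7 | flow-violation factor value |
| `m_max` | 5 | largest explicitly modelled multiplicity; higher coverage maps to a clamped $\mathrm{round}(C/\lambda)$ |
| `max_table` | 1e7 (pipeline) / 1e8 (engine) | cap on intermediate table entries; stage 3 falls back to $s-1$ per element when exceeded |

q-mer weighting matters because erroneous bases tend to carry low quality
scores: weighting shrinks the coverage of error artifacts towards zero and
separates the $m = 0$ component from the rest of the mixture.

## Inference

The CRF for a neighbourhood contains one multiplicity variable per node and
per arc.  Observed coverages are folded into the singleton factors
(conditioning), so only multiplicity variables are ever eliminated.
Nodes with at most $2k$ k-mers get no singleton factor — their average
coverage is nearly determined by their adjacent arcs and would double-count
evidence — but their domain is still centred on their own coverage.  An
*isolated* node (no arcs at all) keeps its singleton factor regardless of
length: the double-counting rationale does not apply, and without it the
node would carry no evidence whatsoever.
Marginals are computed by variable elimination in log space (log-sum-exp)
with the min-neighbours heuristic: at each step the variable with the
fewest neighbours in the induced graph is summed out, ties broken towards
the smallest variable id.  The order affects cost only; the result is exact,
which the test suite verifies against brute-force enumeration of the joint
distribution.

## Parameter estimation

Mixture parameters are fitted separately for nodes (average unitig
coverage) and arcs (raw k+1-mer coverage) by expectation-maximisation on a
fixed random subset (default 10000 + 10000 elements, sampled once).  The
E-step infers multiplicity posteriors with the current models through the
CRF at `s_em = 1`; the M-step applies method-of-moments updates weighted by
those posteriors: $\lambda_0$ and $\lambda$ are posterior-weighted means
(the latter normalised by $\sum_m \gamma_m m$), $f_0$ and $f$
posterior-weighted variance/mean ratios floored at $1 + 10^{-6}$, and the
weights are posterior masses rescaled to the whole graph.  EM stops when
the fraction of subset elements whose MAP multiplicity changed between
consecutive E-steps drops below 0.001, or after 25 iterations
(non-convergence is reported, not hidden).  Initialisation takes $\lambda$
from the highest coverage-histogram bin above a floor of 2, $\lambda_0 =
\max(0.5, \lambda/10)$ and $f = f_0 = 1.5$.

## The synthetic-data generator

`make_genome()` draws an i.i.d. sequence and plants dispersed or tandem
repeat blocks, the structures that create multiplicities >= 2.
`simulate_reads()` draws read starts per position from a negative binomial
with overdispersion `f_sim` (Poisson at 1), emulating the clustered
fragment starts of real libraries; substitution errors occur independently
at `error_rate`, and Phred scores are drawn around 32 for correct and 12
for erroneous bases (sd 3, clipped to [2, 40]).  The effective per-k-mer
depth of such a read set is `depth * (read_len - k + 1) / read_len *
(1 - error_rate)^k`, the quantity the fitted $\lambda$ estimates.
Truth labels come from exact canonical k-mer counting over the genome
(`truth_labels()`), so every graph element has a known multiplicity.

The generator reproduces the features that drive this inference problem —
overdispersed coverage, low-quality error bases, repeats — but not GC bias,
indel errors, paired-end structure, or platform-specific quality profiles.
Validation results on it therefore show correctness of the machinery and
the qualitative behaviour of the method, not absolute accuracies on real
data.  Substitutions only (no indels) keep the truth labelling exact.

## Validation conditions

The packaged checks run at desk scale, chosen to finish in minutes while
leaving the conclusions unambiguous: exactness of variable elimination on
200 random CRFs of up to 12 variables; a perfect-coverage 100 kb genome
with a x2 and a x3 dispersed repeat (every element must be recovered
exactly at `s = 1`); five 1 Mb simulations at 15x read depth, 1 % errors
and `f_sim = 1.5`, with node accuracy measured on a fixed 800-node sample
per seed and required to be non-decreasing over `s in {0, 1, 3}`; and EM
recovery of $\lambda$ (within 5 %) and $f$ (within 20 %) at 30x k-mer
depth over five seeds with 800 + 800-element subsets.  Because errors thin
the observed counts, the reference values for recovery are the effective
depth above and the thinned dispersion $q f_{\mathrm{sim}} + (1 - q)$ with
$q = (1 - e)^{k+1}$.  Both checks use the arc model, whose counts are raw
k+1-mer counts and therefore directly comparable: node coverage is averaged
over unitigs, which attenuates $f$ and ties $\lambda$ to the unitig length
composition (itself correlated with coverage), so the node model estimates
a slightly different population quantity.

## Design choices

Several constructions are not fully determined by the flow-conservation
idea itself; the package resolves them as follows.

* **Dead-end sides.**  A node side with no arcs (a tip or the end of a
  fragmented region) gets *no* flow factor.  The alternative — treating the
  empty sum as forcing multiplicity 0 — would systematically push the ends
  of coverage-fragmented true regions to 0 and make an isolated node's
  posterior depend on $s$.  The `flow_factor()` primitive itself still
  implements the empty-sum convention for callers that want it.
* **Self-loops and hairpins.**  An arc from a node's right side to its own
  left side appears in both of the node's side sums with coefficient 1; an
  arc joining a side to itself contributes coefficient 2 to that side (it
  is traversed both entering and leaving).
* **`s = 0` degeneration.**  The neighbourhood is the centre element alone
  and the CRF holds exactly its variable and (if any) singleton factor, so
  inference reduces to the histogram rule; a short node at `s = 0` has no
  evidence at all and falls back to the smallest candidate multiplicity.
* **Arc-centred neighbourhoods** seed both endpoint nodes at distance 0.
* **Ties** in the MAP, in $m_{\mathrm{opt}}$ and in the elimination order
  always resolve to the smallest value/id, making runs reproducible.
* **Unitig ids** are assigned in canonical-sequence sort order at
  compaction, so identical read sets give byte-identical outputs.
* **EM subset** is drawn once and reused across iterations, which makes the
  "MAP changes between consecutive E-steps" criterion well defined.
* **Histogram fitting ignores the abundance filter**: components are fitted
  to surviving elements as-is, without zero-truncation corrections for the
  k-mers removed by `abundance_min`; at the depths the model targets the
  truncated mass is dominated by errors.

## Numerical choices

All factor tables and the elimination are in log space; normalisation of
the final marginal realises the partition function.  The continuous NB
density (factorials replaced by Gamma functions) is evaluated from
`lgamma`, is exact at integer points, and switches to the Gamma-continuous
Poisson form below $f = 1 + 10^{-9}$.  Overdispersion estimates are floored
at $1 + 10^{-6}$ to keep $p \in (0, 1)$.  Degenerate CRFs (a query with no
factors) return a uniform posterior over the domain.

## Limitations

Multiplicities are non-negative integers: diploid organisms with
heterozygous variants (half-multiplicities) are outside the model, which
will force one allele to 0 and the other to 1.  Inference is exact and
therefore exponential in the treewidth of dense neighbourhoods; the table
cap with per-element fallback to smaller $s$ bounds the cost.  The native
graph builder is an in-memory hash-table construction intended for genomes
up to tens of megabases; larger graphs should be built externally and
imported as GFA1.  No graph cleaning or error correction is performed —
the output is the labelling itself.
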