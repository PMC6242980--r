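---
title: "The similarity-based future common neighbors model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The similarity-based future common neighbors model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfcnlp)
```

## The problem

Link prediction asks: given an observed undirected simple network
$G(V, E)$, which of the $\binom{|V|}{2} - |E|$ unobserved node pairs are
most likely to be missing links, or to form in the future? In a yeast
protein-interaction network most true interactions are still unobserved,
so a ranking that concentrates real links at the top saves laboratory
effort; the same machinery ranks candidate collaborations, friendships,
or trophic links.

Classical *similarity indexes* score a pair $(x, y)$ from its current
common neighbors $\Gamma_x \cap \Gamma_y$. This package implements eight
of them — CN, Salton, RA, HPI, HDI, LHN, LNBRA, LP — and the SFCN model
built on top of them, which additionally credits *future common
neighbors*: nodes that are not yet common neighbors of $(x, y)$ but are
positioned to become one as the network evolves.

## The model

For a target pair $(x, y)$, let $r_{x,i} \in \{0, 1\}$ be the observed
adjacency and $s^{C2}_{x,i}$ the similarity score of $(x, i)$ under a
pluggable base index C2. Four length-$|V|$ vectors are formed — the
connection rows $\Gamma_x, \Gamma_y$ and the score rows $S_x, S_y$ — with
positions $x$ and $y$ forced to zero (non-self-connection rule). The SFCN
score is

$$
s_{x,y} \;=\; \alpha\, s^{C1}_{x,y} \;+\;
\beta \sum_{i=1}^{|V|}\left( r_{x,i}\, s^{C2}_{i,y}
  + s^{C2}_{x,i}\, r_{i,y} + s^{C2}_{x,i}\, s^{C2}_{i,y}\right),
$$

where C1 scores the pair directly (the current common-neighbor term) and
the three summands collect the three classes of future common neighbors:

* **type 1** — nodes already linked to $x$ with nonzero C2 similarity to
  $y$ (one of the two required links exists, on $x$'s side);
* **type 2** — nodes already linked to $y$, symmetric to type 1;
* **type 3** — nodes linked to neither endpoint but with nonzero C2
  similarity to both.

`identify_fcn()` reports the three node sets (type 3 net of types 1–2, so
the report is disjoint) together with the three dot products; a node may
legitimately contribute to more than one summand. The rule literature
states the classification in two places whose type *numbering* disagrees;
we follow the worked example and the figure semantics (type 1 = linked to
x), which is also what the contribution algebra requires.

A deliberate modelling choice, following the operative formula rather
than the looser prose around it: a node that is *already* a current
common neighbor still contributes its $r \cdot s$, $s \cdot r$ and
$s \cdot s$ terms when its C2 scores are nonzero. The alternative
reading — future common neighbors must not currently be common
neighbors — is available as `strict_fcn = TRUE` in `sfcn_config()`,
which zeroes the C2 entries of current common neighbors before the dot
products. The default is the literal formula; with the strict flag the
all-pairs matrix is assembled pair by pair, since the zeroing then
depends on the pair.

### Worked example

The shipped 10-node fixture (target pair (1, 3), C2 = RA) decomposes as:

```{r}
fx <- example1_fixture()
identify_fcn(fx$vectors)
```

The three contributions are exactly $1/6$, $1/5$ and $1/15$; the future
term contributes $13/30 \cdot \beta$ to the pair's score. The fixture
ships the printed vectors (with exact fraction forms) rather than a
reconstructed graph, because the underlying example network is not fully
determined by the vectors; tests consume the vectors directly.

## Parameters

* `alpha` (default 9) and `beta` (default 1): the mixing weights of the
  current and future terms. Both dimensionless; scores are not normalised
  before mixing, so the useful scale of `alpha/beta` depends on the C1/C2
  pair. The defaults are the operating point selected by the grid
  calibration protocol (below) on a dense food-web benchmark; when in
  doubt, rerun `parameter_sweep()` on your own network.
* `c1`, `c2`: any of the eight base indexes. The convention
  `SFCN-<C1>-<C2>` names a configuration, e.g. `sfcn-lnbra-lhn`.
* `lp_epsilon` (default 0.001): the LP index's own weight on length-3
  walks, $s^{LP} = (A^2)_{xy} + \varepsilon (A^3)_{xy}$. Kept distinct
  from `alpha`/`beta`; small positive values interpolate away from pure
  CN. The published comparisons do not state the value they used, so the
  default is the conventional small epsilon of the LP literature.
* LNBRA's role factor $\frac1{k_z}\log_2(\eta R_z)$ uses
  $\eta = \frac{|V|(|V|-1) - 2|E^T|}{2|E^T|}$ and
  $R_z = (N_{\triangle z}+1)/(N_{\triangledown z}+1)$, where
  $N_{\triangle z}$ counts connected and $N_{\triangledown z}$
  disconnected pairs among $\Gamma(z)$. We evaluate the *single*
  logarithm of the product rather than the sum of two logarithms:
  mathematically identical, and it preserves exact cancellation when
  $\eta R_z = 1$ (the toy-graph pair (1, 4) scores exactly 0). $\eta$ is
  likewise computed in the subtraction-free form above. LNBRA scores may
  be negative; an overfull graph (no nonexistent links, $\eta \le 0$) is
  an error.

## Evaluation protocol

`split_edges()` partitions $E$ into a training set $E^T$
($|E^T| = \mathrm{round}(\rho\,|E|)$) and probe set $E^P$ by uniform
seeded sampling; every score matrix used in evaluation is rebuilt on the
training graph only, a contract the tests enforce with a spy scorer.

**AUC** is the probability that a probe link outscores a nonexistent link
($U - E$), ties counted $1/2$. The exact mode compares every probe link
with every nonexistent link via midranks; the sampled mode draws $n$
seeded comparisons and returns $(n' + 0.5\,n'')/n$. Exact mode is the
default — it is deterministic given the split and sidesteps the choice of
$n$. The negative class is the pairs absent from the *full* observed
graph: comparing against training links would be circular.

**Precision@L** ranks all non-training pairs (probe plus nonexistent) by
score, descending, and reports the fraction of the top $L$ (default 100)
that are probe links. Ties at the boundary are broken by ascending
lexicographic node-id pair, making the value deterministic; tie-heavy
indexes (e.g. CN on sparse graphs) are sensitive to this convention, so
treat small precision differences between tie-heavy methods with care.

`run_experiment()` averages both metrics over seeded replicates
(replicate $r$ splits with seed `base_seed + r`); `parameter_sweep()`
implements the a-priori calibration — an outer split at $\rho$, then
replicated inner sub-splits of $E^T$ into $E^{T1}/E^{P1}$, scoring
$E^{P1}$ from $E^{T1}$ over the default $6 \times 6$ grid
$\alpha \in \{0, 3, \dots, 15\}$, $\beta \in \{0, 0.4, \dots, 2\}$ — so
the weights are chosen without touching the probe set. The inner ratio
defaults to the outer one. `ratio_sweep()` repeats the full experiment
over training fractions (e.g. 0.45–0.9) to probe robustness when little
of the network is observed.

## Numerical and degenerate-input choices

* Ratio indexes (Salton, HPI, HDI, LHN) define $0/0 = 0$: an isolated
  endpoint has no common neighbors, so the numerator is already 0.
* All score matrices are symmetric with a fixed zero diagonal; per-pair
  scoring of $x = y$ is an error. The matrix route of the SFCN beta term
  ($A S + S A + S S$) needs no per-pair correction precisely because both
  $A$ and $S$ have zero diagonals — every term excluded by the
  non-self-connection rule multiplies a diagonal entry.
* Average shortest distance on a disconnected graph averages over
  reachable pairs, with a warning. Degree heterogeneity is
  $\langle k^2\rangle / \langle k\rangle^2$; local clustering of
  degree-0/1 nodes is 0; assortativity of a regular graph is undefined
  (`NA`).
* Edgeless graphs yield all-zero score matrices; splits require at least
  one edge on each side.

## What the synthetic benchmarks do and do not show

The generators (`generate_graph()`) cover Erdős–Rényi, Barabási–Albert,
and planted-partition models. The planted-partition benchmark used in the
tests and the acceptance script — 150 nodes, 3 communities of 50,
$p_{in} = 0.15$, $p_{out} = 0.01$, 20 replicates at ratio 0.9 — creates
genuine common-neighbor signal, so it exercises the full pipeline at a
size where the exact AUC is computed over every probe/nonexistent
comparison, and the replicated means are stable to a few hundredths
across seeds. These sizes were chosen as the smallest at which the
community signal dominates replicate noise. Synthetic blocks lack the
degree heterogeneity, clustering gradients and assortativity of real
protein-interaction or food-web data, so passing them demonstrates
correctness of the machinery and the *direction* of the SFCN effect (on
this benchmark SFCN-CN-RA beats CN by roughly 0.1 AUC), not the published
effect sizes on real networks. Full-scale replication needs the original
five benchmark edge lists, which are distributed separately; feed them
through `cmd_evaluate`/`cmd_sweep` with 100 replicates to reproduce that
setting, using `reference_network_stats()` to check the inputs arrived
intact.

## Known limitations

* Unweighted, undirected, static graphs only; no temporal or multi-step
  extension (scores are not iterated).
* Dense score matrices: memory is $O(|V|^2)$, fine for the few-thousand
  node range the method targets.
* The strict-FCN matrix path is quadratic in pairs with a per-pair inner
  loop; use it for inspection, not for large sweeps.
* Whether the published model zeroed C2 entries of current common
  neighbors cannot be settled from the available description (the worked
  example is consistent with both readings at its single zero position);
  both behaviours are provided, with the literal formula as default.
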