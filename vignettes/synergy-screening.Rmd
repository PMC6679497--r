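---
title: "Scoring synergistic drug combinations on a disease network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring synergistic drug combinations on a disease network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synscreen)
```

## The screen and its assumptions

`synscreen` ranks candidate partner drugs for combination with a reference
drug by combining three independent lines of evidence on a disease
signaling network: where the two drugs' targets sit in the network
(`s_tnetwork`), how functionally related the targets are (`s_function`),
and how chemically alike the molecules are (`s_similarity`). The screen
assumes that a good combination partner hits targets that are central hubs
of the disease network, close to (but not identical with) the reference
drug's targets, functionally coherent with them, and carried by a molecule
with related 2D substructure and 3D pharmacophore. None of these is a claim
about mechanism; the composite is a prioritization heuristic whose top
prediction must still be validated experimentally or clinically — the
package therefore also ships the two-proportion statistics used to analyze
such a validation trial.

## The target-network axis

The disease network is the subgraph of a background protein–protein
interaction network induced on a curated disease gene set, with isolated
nodes removed (`induce_subnetwork()`). On it, every node gets a centrality
score `CS = Bn + Cn + Pr` (`compute_centralities()`):

* `Bn`: betweenness, normalized by $(n-1)(n-2)/2$ so it lies in $[0,1]$ and
  CS is comparable across network sizes;
* `Cn`: closeness in the Wasserman–Faust component-scaled convention
  $\frac{|R|}{n-1}\cdot\frac{|R|}{\sum_{u\in R} d(v,u)}$ over the reachable
  set $R$, which remains well-defined if the induced network is
  disconnected;
* `Pr`: PageRank with uniform teleport, damping 0.85 by default.

These conventions are deliberate choices: the combination of three
correlated centralities buys robustness, and none of the published variants
of the screen pins down the normalizations, so we use the standard ones and
expose `damping` in the configuration.

The pair score is a sum of two CS-weighted means of exponential proximity
factors $e^{-D/n^2}$ (see `?s_tnetwork` for the exact form). Two details
deserve emphasis:

* **Exponent sign.** The literal printed form of this score in the
  literature uses $e^{+D/n^2}$, which *rewards distant* targets and
  contradicts its own stated intent (combinations "closely connected" on
  the network). The default is the decaying form; `exponent_sign =
  "literal"` restores the printed one. Under the default the score lies in
  $[0,2]$ and equals 2 exactly for identical mapped target sets.
* **Crossed denominators.** The sum over the first drug's targets scales
  distances by $n^2$, the squared size of the *other* mapped set, and vice
  versa. This is kept exactly as printed.

An unreachable target contributes factor 0 (the $D \to \infty$ limit of the
decay form), so the score degrades continuously on fragmented networks.
Targets outside the scoring network are excluded from the sums; a drug with
no mapped targets is scored 0 on this axis with a structured warning. By
default the scoring network is the disease subnetwork (`scoring_graph =
"disease"`); because drug targets may fall outside it,
`"disease_plus_targets"` (induce on the union) and `"background"` (score on
the full PPI network) are available. Which graph the original screen used is
not recoverable; the disease network is the most conservative reading of
"centrality in the disease signaling network".

## The functional axis

Functional similarity is Lin-type information content over an ontology
DAG. Term probabilities are cumulative: each annotation counts toward its
term and all ancestors, $p(t) = Freq(t)/\max Freq$, so the root of an
annotated rooted DAG has $p = 1$ and probabilities never decrease toward
the root. The similarity of two terms is
$2\log_2 p(A^*) / (\log_2 p(t_1) + \log_2 p(t_2))$ with $A^*$ the common
ancestor with *minimum* $p$ — the most informative common ancestor (MICA).
The literal printed rule ("max p(A)") would always select the root and make
the score identically zero on a rooted DAG; it is preserved behind
`mica_rule = "literal_max"` for inspection, but the MICA rule is the
default because the alternative is degenerate.

Genes may carry several annotations; cross term pairs are aggregated by
`max` by default (options `bma`, `avg`) — the original formulation assumes
exactly one term per target, in which case all three coincide. The target
set score divides the doubled sum of cross-pair similarities by
$(m+n)(m+n-1)$, the number of ordered pairs among the pooled targets, which
bounds it by $2mn/((m+n)(m+n-1)) \le 1$ with equality only at $m=n=1$.
Whether term frequencies should come from the full annotation corpus or
only from the screened drugs' targets is configurable (`corpus_scope`,
default `all_annotations`).

## The chemical axis

2D similarity is LINGOsim: SMILES ring-closure labels are set to `0`
(single digits and `%nn` pairs outside square brackets only — bracket-atom
digits are isotopes, charges, or H counts, not ring labels), the string is
cut into all overlapping `q = 4` character substrings, and the two count
profiles are compared by $\frac{1}{m}\sum_k (1 - |N_{i,k}-N_{j,k}|/(N_{i,k}+N_{j,k}))$.
SMILES must be canonical on input; the package does not canonicalize.

3D similarity is the ratio of cross to maximal self Gaussian overlap of
typed pharmacophore sites (acceptor/donor/hydrophobe/negative/positive/
ring), $O = \sum e^{-d^2/\sigma^2}$ over same-type pairs, with $\sigma$ =
1 Å by default. This is an open surrogate for proprietary volume-overlap
shape scores; conformer generation and alignment are out of scope — site
coordinates must arrive pre-aligned in a shared frame. The ratio is clamped
to $[0,1]$ because the Gaussian cross-sum can exceed the self-overlap for
unbalanced site counts. Candidates without site data score 0 on the 3D
component by default (`missing_3d = "zero"`); `"skip_axis"` lets the
similarity axis fall back to 2D only.

## Ranking

The original description identifies the winner geometrically — the
candidate "away from the origin" along the diagonal of the 3D score plot —
without a formula. We min–max normalize each axis across candidates
(a constant axis maps to 0.5 for everyone, keeping it neutral without
dividing by zero) and project onto the unit diagonal,
$total = (x+y+z)/\sqrt 3$. This orders identically to the normalized sum
(`total_rule = "sum"`); `"euclidean"` is provided for sensitivity checks.
Ties break lexicographically by drug identifier, making the output fully
deterministic. Per-axis failures downgrade the axis to 0 with a structured
warning rather than dropping the candidate, so incomplete inputs never
silently shrink the screen.

## Trial statistics

`risk_difference_ci()`, `wald_proportion_ci()`, `chi_square_2x2()` and
`sample_size_two_proportions()` reproduce a standard two-arm responder
analysis from the 2×2 table. Wald (normal-approximation) intervals are used
throughout, and the chi-square test defaults to *no* continuity correction;
with the reference table (30/51 vs 48/61 responders) these choices
reproduce the published between-group difference −19.9% (−36.8%, −2.9%)
and P ≈ 0.02 exactly at one-decimal rounding, whereas Yates correction
would give P ≈ 0.04. The published single-group intervals differ from Wald
bounds by 0.1 percentage points at the lower ends, so the CI method behind
them was likely not Wald; only the between-group difference is treated as
exactly reproducible. The sample-size formula is the classical pooled
normal approximation, inflated by $1/(1-dropout)$: for a 50% control rate,
26% improvement, two-sided α = 0.05, 80% power and 10% drop-out it plans
59 per group (the motivating trial enrolled 60).

## What the synthetic generator emulates — and what it does not

`simulate_bundle()` builds a scale-free background network (preferential
attachment, 2 edges/node — hubby like real PPI networks, 60 nodes by
default), takes the top third of nodes by degree as disease genes, anchors
the reference drug on the three highest-CS hubs of the disease subnetwork,
and surrounds it with decoy candidates carrying random targets, random
library structures, and random pharmacophores. The optional planted
synergist copies the reference structure, keeps two of its three hub
targets, moves the third to an adjacent hub, and jitters the sites by
0.05 Å — the pattern the screen is designed to reward. The generator
emulates the *shape* of the inputs (hubby network, hub-centered disease
module, long-format target tables, tree ontology with depth-decreasing
annotation frequencies), not their biology: toy SMILES are drawn from a
fixed 12-molecule library, annotations are random, and no real disease
module or chemistry is represented. A green planted-recovery test
establishes that the composite score recovers an obviously good candidate
among random decoys — not that it would reproduce any particular published
screen, whose drug libraries and predicted-target inputs are not public.
All generators are pure functions of their parameters and seed.

## Numerical choices and degenerate inputs

* PageRank is computed by igraph's PRPACK solver; tests cross-check it
  against dense power iteration at $10^{-8}$.
* Self-loops are dropped at parse time (a node seen only in self-loops is
  dropped entirely); duplicate edges collapse; node IDs are opaque
  case-sensitive strings — identifier mapping is the caller's problem.
* An empty target set or one with zero total centrality raises a
  structured `undefined_score` error; the screen catches it and downgrades
  the axis to 0 with a warning.
* Two annotated terms both at $p = 1$ have a vanishing log-denominator;
  their similarity is defined as 0 (they carry no information to share).
  A pair with no common ancestor scores 0 with a warning.
* Ranked-table floats are written at 6 significant digits; re-writing the
  same table is byte-identical.

## Known limitations

The screen is a heuristic built from three bounded scores; absolute values
are not calibrated probabilities of clinical synergy. The 3D component is
only as good as the externally supplied alignment. Weighted or directed
interaction networks, evidence-code filtering of annotations, alternative
semantic similarities (Resnik, Wang), and fingerprint-based 2D similarity
are all out of scope.
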