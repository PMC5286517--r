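---
title: "Refining gene regulatory networks with tree-structured Markov Random Fields"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Refining gene regulatory networks with tree-structured Markov Random Fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grnrefine)
```

## The problem

Expression-based network inference ranks candidate transcription-factor
(TF) → target links by statistical association, and integrative pipelines
intersect those ranks with DNA-binding evidence. The resulting "initial"
network is still noisy: association scores have heavy overlap between true
and spurious links, and binding evidence is both incomplete and
promiscuous. `grnrefine` prunes such an initial network by exploiting a
biological regularity the per-link scores ignore: targets of the same
regulator tend to share biological function. Links are therefore not
accepted or rejected one at a time but *jointly*, as groups of co-regulated
targets coupled through a co-function network (an AraNet/FlyNet-style
gene–gene association network).

## The model

### From links to modules

Every pair of links $l: r \to g$ and $l': r \to g'$ sharing a regulator is
coupled with weight

$$\upsilon_\Delta(l, l') = w_{ff}(g, g') \cdot \bigl(1 - |\upsilon_l - \upsilon_{l'}|\bigr),$$

where $\upsilon_l \in (0, 1]$ is the link's rank-normalized confidence and
$w_{ff} \in [0, 1]$ the co-functionality of the two targets. The coupling
increases with co-function evidence and decreases with the distance
between the two confidences; pairs absent from the co-function network get
$w_{ff} = 0$ (co-function datasets are partial — absent evidence is no
evidence). This product form is the package's chosen combination rule: it
satisfies both monotonicities, maps to $[0,1]$, and reduces to pure
co-functionality at equal confidences. An alternative
$w_{ff} / (1 + |\Delta|)$ with the same qualitative behavior is available
via `meta_edge_weight(rule = "ratio")`.

The resulting "meta network" (links as nodes, couplings as edges) is cut
into modules: each connected component is reduced to its **maximum
spanning tree**, keeping for every group of co-regulated targets only the
strongest coupling backbone. Trees are what make exact probabilistic
inference cheap below; the spanning-tree reduction is the price paid for
exactness. Isolated links become singleton modules, so every link belongs
to exactly one module.

### A binary MRF per module

Each link in a module carries a state $x_l \in \{0, 1\}$ (keep/remove).
With spins $s_l = 2x_l - 1$ the module energy is the Ising form

$$E(x) = -\sum_l (\upsilon_l - \gamma)\, s_l \;-\; \lambda \sum_{(l,l') \in \text{tree}} \upsilon_\Delta(l, l')\, s_l s_{l'},$$

and $p(x) \propto e^{-E(x)}$. The sign and offset convention is the core
modeling assumption, fixed by three requirements: links above the
threshold $\gamma$ are favored; strongly coupled pairs prefer equal
states; and a singleton module reduces exactly to "remove iff
$\upsilon \le \gamma$" (its marginal is the logistic
$\sigma(2(\upsilon - \gamma))$, so retention at $p > 0.5$ is equivalent to
$\upsilon > \gamma$).

Links with $\upsilon > \gamma$ are **clamped** to $x = 1$ (MRFs are closed
under conditioning). Clamping is implemented as evidence messages — a
delta at state 1 — rather than graph surgery, so module topology is
preserved for reporting. Its purpose is asymmetry: a confident link can
rescue coupled weak links, but a crowd of weak links can never drag down a
confident one.

Marginals $p_l$ are computed by two-pass sum-product belief propagation,
exact on trees, in log domain with per-message max-normalization (no
damping; underflow-safe for any $\lambda \le 2.5$ and module size we
generate). A link is retained iff $p_l > 0.5$, strictly; $p_l = 0.5$
(e.g. a free singleton exactly at $\gamma$) removes the link.

### Learning the hyperparameters

$\theta = (\gamma, \lambda)$ is learned against two sparse gold standards:
curated regulatory pairs (precision side) and co-annotated gene pairs
(recall side). A candidate pruned network is scored by

* **precision** $P$: gold regulatory links recovered over predictions,
  restricted by default to predictions whose regulator occurs in the gold
  standard (with a curated map covering a few regulators, unrestricted
  precision is mostly noise; `restrict_to_gold_regulators = FALSE`
  disables this);
* **recall** $R$: co-regulated gene pairs — regulator-set Jaccard
  coefficient strictly above 0.5 — that carry co-function annotation,
  divided by a reference count (next section);
* $f_\beta = (1+\beta^2)\hat P R / (\beta^2 \hat P + R)$ with $\beta = 1$
  by default, where $\hat P = \min(1, P / P_{\max})$ is precision scaled
  by the largest raw precision seen during the grid phase. Scaling lets a
  sparse gold standard reach $\hat P = 1$; freezing $P_{\max}$ through the
  annealing phase keeps the objective stationary.

The search is coarse-to-fine: a grid with $\gamma$ at empirical weight
quantiles and $\lambda$ log-spaced over $[0.001, 2.5]$ (the upper bound
caps the influence of the co-function network and guards against
over-predicting master regulators), then simulated annealing inside the
best cell ± one grid step. Annealing uses Metropolis acceptance on
$-f_\beta$, geometric cooling ($T_0 = 1$, $\alpha = 0.9$, 50 levels × 4
proposals by default), and Gaussian proposals with scale 10 % of the
sub-space width, reflected at the boundaries. Because near-equivalent
optima are common, the final pick is conservative: among all visited
points within 1 % of the best objective, the smallest $\lambda$ (then
smallest $\gamma$) wins. All stages are deterministic given the seed.

### The recall denominator

The recall reference is genuinely open to two readings, and the package
implements both (`recall_cofunctional(anchor = )`):

* `"gold"` (default): all co-annotated pairs whose genes appear as
  targets of the initial network — the reachable annotation universe.
* `"initial"`: the co-annotated co-regulated pairs of the *initial*
  network.

The default is `"gold"` because the initial anchor degenerates exactly
when pruning is most needed. A spurious regulator on one gene of a pair
dilutes the pair's Jaccard coefficient below 0.5, so a noisy initial
network has very few co-regulated pairs; the initial-anchored ratio (capped
at 1, since pruning can *create* co-regulated pairs) then saturates at 1
for essentially every $\theta$, the objective collapses to precision
alone, and the conservative rule drives $\lambda$ to its minimum — the
coupling machinery is never used. Under the gold anchor, recall rewards
pruning that exposes true co-regulons, and learned $\lambda$ values on the
synthetic benchmarks land mid-range (roughly 0.1–2) rather than at the
floor.

The two anchors answer different questions — "where is the planted
confidence boundary?" versus "which pruning best exposes co-functional
structure?". The parameter-recovery property below holds under the first;
the refinement-benefit property under the second.

### The ensemble

To avoid over-fitting the sparse gold standards, $N$ models are trained on
hold-out resamples: each round samples 63.2 % of the *modules* (with the
gold-standard entries that fall in them) as training set, learns
$\theta_n$, and applies it to **all** modules so the vote is defined for
every link. The final network keeps a link iff its vote fraction strictly
exceeds $\varepsilon_p = 0.5$ — more than half of the models; exactly half
is not enough. Per-round seeds derive from the global seed and round
index, so results are order-independent and reproducible. The package
default is $N = 100$; per-round test-set enrichment (gold recovery in the
pruned versus unpruned test modules, one-sided Fisher) is reported
alongside.

## The initial network stage

For completeness the package also builds the initial network: per-target
random-forest regression of expression on all TFs (impurity importance,
i.e. variance reduction summed over splits — the standard tree-ensemble
importance; per-target seeds derive from the global seed and the target
ID, so target order is irrelevant), rank normalization of all importances
by their empirical CDF ($\text{ECDF}(x) = \#\{ \le x\}/n$; ties share a
value and survive or fall together), retention of scores with ECDF above
$1 - 0.05$, and strict intersection with the binding edge list.
Preprocessing averages replicate groups and drops genes below a variance
quantile (linear-interpolation sample quantile; the cutoff is exposed as a
parameter with default 0, i.e. no filtering claimed as canonical).
Self-regulation is excluded from the regression design: it is
unidentifiable from a model that predicts a gene from itself.

## The synthetic benchmarks

Two seeded generators provide planted ground truth:

* `simulate_benchmark()` emulates all five pipeline inputs: a planted
  TF → target network (Poisson-sized regulons, ≥ 2 targets), expression
  as linear regulator combinations with $U(0.5, 1.5)$ effect sizes of
  random sign plus $N(0, 0.5^2)$ noise over 40 conditions (20 TFs, 300
  genes by default), binding = truth plus an equal number of random decoy
  links, co-function weights Beta(5, 2) for pairs sharing a true regulator
  (80 % coverage) and Beta(1.5, 5) for background pairs, and gold
  standards covering 30 % of true links and 50 % of true co-regulon
  pairs.
* `simulate_weighted_grn()` skips the expression stage and plants
  confidence weights directly around a threshold $t = 0.5$: disjoint
  distributions in the `"wide"` regime ($t + (1-t)\text{Beta}(5,2)$ vs.
  $t\,\text{Beta}(2,5)$), crossing ones in `"overlap"` (Beta(6, 3) vs.
  Beta(3, 6)). The overlap regime is where coupling information can beat
  pure confidence ranking, and is the substrate for the refinement-benefit
  checks.

What these generators do **not** emulate: count noise (no negative
binomial), batch effects, indirect regulation chains, TF–TF regulation in
the weighted generator, and realistically structured co-function networks
(real ones have hub structure and module overlap). Passing tests therefore
demonstrate correctness of the machinery and the claimed qualitative
behaviors under the stated generative assumptions — not performance on any
real transcriptome.

## Numerical and degenerate-input choices

* Belief propagation messages live in log space and are shifted by their
  finite maximum; clamped states use $-\infty$ log-potentials, which
  propagate correctly through `logsumexp`.
* Maximum spanning forests use Kruskal's algorithm with a fixed total
  order — weight descending, then the lexicographic (regulator, target,
  target) triple — so module structure is bit-identical across platforms.
* A zero-variance target yields all-zero importances (no error); an empty
  binding intersection warns and returns an empty network; an empty
  recall denominator or an unevaluable precision warns and scores 0.
* Quantile conventions are R's default type-7 (linear interpolation)
  throughout.
* `round(0.632 M)` sizes the training split (R's banker's rounding; 10
  modules → 6/4).

## Problem sizes used by the tests and the acceptance script

Exactness checks enumerate all states: 200 random trees up to 12 nodes
(4096 states) for belief propagation, 100 random graphs up to 7 nodes for
spanning trees, against independent brute-force oracles written in the
test helpers. End-to-end checks run the default weighted benchmarks
(10 TFs, ~160 links) with 10 hold-out rounds, a 6 × 5 grid and 10 × 2
annealing steps — sizes chosen so the whole suite completes in about a
minute while every code path is the production one. The package defaults
(N = 100 rounds, 10 × 10 grid, 50 × 4 annealing) remain those stated
above.

## Known limitations

* The spanning-tree reduction discards intra-module cycles; coupling
  information on the removed edges never influences the marginals.
* Modules are independent given $\theta$; a gene regulated by two TFs
  links their modules only through the shared $\theta$, not through joint
  inference.
* The Jaccard > 0.5 co-regulation rule is brittle for genes with many
  regulators; one extra regulator on one gene of a pair flips the pair.
* $P_{\max}$ scaling makes the objective relative to the current search
  phase; objective values are comparable within one learning run, not
  across datasets.
* The ensemble vote is unweighted; rounds with poor test enrichment count
  as much as good ones.
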