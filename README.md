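# grnrefine

Semi-supervised refinement of gene regulatory networks (GRNs) with
ensembles of tree-structured Markov Random Fields.

## What problem it solves

Integrative GRN inference produces a ranked list of transcription-factor
(TF) → target links from expression association plus DNA-binding
evidence. Per-link confidence scores overlap heavily between true and
spurious links, so thresholding the ranking wastes a strong biological
signal: targets of the same regulator tend to share function. `grnrefine`
prunes an initial network by modeling co-regulated link groups jointly.
Links of a regulator are connected into a meta network weighted by

υ<sub>Δ</sub>(l, l′) = w<sub>ff</sub>(g, g′) · (1 − |υ<sub>l</sub> − υ<sub>l′</sub>|),

where w<sub>ff</sub> is the co-functionality of the two targets (from an
AraNet/FlyNet-style association network) and υ the rank-normalized link
confidences. Each connected component is reduced to its maximum spanning
tree and posed as a binary Ising-type Markov Random Field,

E(x) = − Σ<sub>l</sub> (υ<sub>l</sub> − γ) s<sub>l</sub> − λ Σ<sub>(l,l′)</sub> υ<sub>Δ</sub>(l, l′) s<sub>l</sub> s<sub>l′</sub>,  s<sub>l</sub> = 2x<sub>l</sub> − 1,

with links above the threshold γ clamped to "keep". Exact sum-product
belief propagation on the tree gives each link a retention probability
p<sub>l</sub>; links with p<sub>l</sub> > 0.5 survive. The hyperparameters
θ = (γ, λ) are learned against sparse gold standards — curated regulatory
pairs (precision) and co-annotated gene pairs recovered through Jaccard
co-regulation (recall) — by maximizing a combined f<sub>β</sub> score with
grid search plus simulated annealing. A 0.632 hold-out ensemble of N such
models votes on every link; a strict majority (> 0.5) selects the final
network.

Intended users: computational biologists post-processing a GENIE3-style
or integrative network who have a co-function network and (possibly very
sparse) curated gold standards.

## Worked example

Everything below is seeded and reproducible. The synthetic benchmark
plants a known ground truth whose confidence weights overlap between true
and decoy links — the regime where joint pruning can beat the ranking.

```r
library(grnrefine)

b <- simulate_weighted_grn(separation = "overlap", seed = 42)
nrow(b$network)   # 168 links, half of them true

modules <- extract_modules(build_meta_network(b$network, b$cofn),
                           b$network)
length(modules)   # 10 modules (one per regulator here)

ens <- run_ensemble(modules, b$gold, n_rounds = 10, seed = 42,
                    hyperopt = list(resolution = c(6, 5),
                                    anneal = list(n_levels = 10,
                                                  n_per_level = 2)))
nrow(ens$final)   # 90 links selected by a strict majority of the models

head(ens$rounds[, c("round", "gamma", "lambda", "f_beta", "n_retained")], 3)
#>   round     gamma    lambda    f_beta n_retained
#> 1     1 0.5398753 0.4688875 0.4332357         93
#> 2     2 0.6624561 1.6825559 0.5224878         86
#> 3     3 0.5579004 0.3535534 0.4498393         85
```

Each row is one hold-out round: the learned weight threshold `gamma`, the
learned coupling penalty `lambda` (mid-range values mean the co-function
network is actually being used), the training objective, and the number of
links that round's model retains. Comparing the ensemble with an
equal-size baseline of top-confidence links from the initial network:

```r
ord  <- b$network[order(-b$network$weight), ]
base <- ord[seq_len(nrow(ens$final)), ]
precision_regulatory(ens$final, b$gold$regulatory)  # 0.456
precision_regulatory(base,      b$gold$regulatory)  # 0.389
```

At identical network size, the refined network recovers more of the
regulatory gold standard than the confidence ranking alone (against the
planted truth: 0.889 vs. 0.811 precision). Across 15 fresh seeds of this
benchmark the refinement wins 11 times, ties twice and loses twice by
under 1.5 points — the gain is consistent but modest, as expected from a
prior that only reranks links within co-regulons.

A command-line wrapper covering simulation, initial-network inference
(`ranger` random-forest importances → ECDF top-5 % → binding
intersection), the full pipeline and evaluation is installed under
`inst/scripts/grnrefine`; `run_pipeline()` drives the same stages from a
YAML config and writes all artifacts plus a reproducibility manifest.

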