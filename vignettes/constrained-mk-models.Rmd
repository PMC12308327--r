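---
title: "Constrained Mk models for coloration and diel activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constrained Mk models for coloration and diel activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dielmk)
```

## The question and the model

Moths vary both in anti-predator coloration — camouflaged (cryptic, `Cry`)
or warning-coloured (conspicuous, `Con`) — and in diel activity: diurnal
(`Diu`), nocturnal (`Noc`), active both day and night (`All`), or
crepuscular (`Crep`). Camouflage is compromised by moving in daylight,
while aposematic species can afford diurnality, so the two traits are
expected to evolve jointly. dielmk asks *where* in one trait's state space
the other trait changes: at which diel states do colour transitions
happen, and which diel states are reachable from which within each colour?

The joint character takes eight states (2 colours × 4 diel states), indexed
`4·colour + diel` with `Cry < Con` and `Diu < Noc < All < Crep`. It evolves
along a time-calibrated phylogeny as a continuous-time Markov chain with
generator $Q$: off-diagonal entries are instantaneous transition rates per
unit tree height, rows sum to zero, and branch transition probabilities are
$P(t) = e^{Qt}$.

Hypotheses are expressed as *constraints* on $Q$ — structural zeros, i.e.
paths forbidden by hypothesis rather than estimated near zero:

* **No dual transitions.** A single jump never changes colour and diel
  state together; simultaneous change of two traits is taken as less
  probable than sequential change.
* **Letter (A–G):** the subset of \{`Diu`, `Noc`, `All`\} at which
  `Cry` ↔ `Con` transitions are allowed. A–C are the three singletons, D–F
  the pairs, G the full set (`E` = \{`Diu`, `Noc`\}).
* **Two digits (1–4):** the connectivity of diel transitions among
  \{`Diu`, `Noc`, `All`\} within the cryptic (first digit) and conspicuous
  (second digit) colour. Digit 1 is the complete graph; 2 routes all
  `Diu` ↔ `Noc` change through `All`; 3 routes through `Noc`; 4 through
  `Diu`.
* **Crepuscular plumbing.** Crepuscular species are too few to support
  hypotheses of their own, so every model carries the same 12 bidirectional
  `Crep` ↔ \{`Diu`,`Noc`,`All`\} rates within each colour, and no
  crepuscular colour switch.

Every allowed direction has its own free rate (no irreversibility is
imposed and no equality constraints), which gives
$2\,|S| + r_1 + r_2 + 12$ parameters for colour set $S$ and digit
structures with $r_i \in \{4, 6\}$ rates — between 22 (e.g. A22) and 30
(G11). Crossing 7 letters with $4 \times 4$ digit pairs yields the 112
candidate models `A11` … `G44`:

```{r}
models <- enumerate_models()
nrow(models)
range(models$df)
build_template("E22")
```

The digit semantics are pinned by the two best-supported biological
readings: in an `E22` model `All` is the intermediate stage between `Diu`
and `Noc` in both colours, while in `E23` the conspicuous clade instead
funnels change through `Noc` with no direct `Diu` ↔ `All` path. The precise
assignment of the remaining letters (A/B/C singleton order, D vs F) and of
digits 1 and 4 is a labelling convention: degrees of freedom and the model
set itself are invariant to it, and `colour_letter_sets()` /
`diel_digit_edges()` expose the convention so it can be inspected.

## Likelihood, fitting, selection

The log-likelihood of the tip states is computed by Felsenstein's pruning
algorithm: post-order partial likelihood vectors, per-branch propagation by
$P(t)$, per-node rescaling to avoid underflow, and a root prior over the
eight states (flat by default; stationary and observed-frequency priors are
available, and any length-8 vector is accepted). $P(t)$ is obtained from a
single eigendecomposition of $Q$ per likelihood evaluation, applied as two
matrix–vector products per branch; when the eigenvector matrix is
ill-conditioned (reciprocal condition number below $10^{-10}$) the code
falls back to scaling-and-squaring Padé exponentials per branch. The two
routes agree to machine precision on well-conditioned inputs; the
eigendecomposition route makes a full 112-model sweep practical.

Maximization runs on log-rates with bounded L-BFGS-B, default bounds
$[10^{-6}, 10^3]$ per unit tree height. The upper bound is deliberately
permissive: sparsely informed paths can take very large estimates even
though typical rates are below 1, and clamping them would silently bias
model comparison. One deterministic start (roughly one change per unit of
total tree length) plus random restarts (default 5 total) mitigate the
multimodality that makes some sparse models fail; an optimizer failure is
recorded in the `mk_fit` (`status`, `message`) and surfaced in the
selection table rather than raised, because which models fail is itself a
result. Gradients are finite differences; `gradient = "forward"` halves the
per-iteration cost for large sweeps at a negligible accuracy loss and is
what the package's own large simulation studies use.

Models are ranked by $\mathrm{AIC} = 2k - 2\log L$ and Akaike weights
$w_i = e^{-\Delta_i/2} / \sum_j e^{-\Delta_j/2}$, normalized over the
successfully fitted subset (weights are subset-relative; the subset is
recorded on the table). Model averaging of rates is deliberately not
offered: occasional very large rate estimates from poorly supported models
would dominate any average.

## Ancestral states and stochastic mapping

`marginal_asr()` computes, for every node, the marginal posterior of each
state under one fitted $Q$ — by an up/down pass: the downward partials from
pruning are combined with an outside vector propagated root-to-tips, and
the per-node product is normalized. Marginal (not joint-MAP) reconstruction
is what per-node pie charts display, and reconstruction deliberately
conditions on a single chosen model (by default the AIC-best) rather than a
model average, for the reason above. `marginal_view()` collapses the
8-state marginals to colour-only or diel-only probabilities.

`sample_histories()` draws full character histories conditional on the tip
data: node states from their joint conditional (root first, then each child
given its parent), then each branch interior by exact endpoint-conditioned
path sampling via uniformization with dominating rate $\mu = \max_i
|Q_{ii}|$. Uniformization is exact and remains robust when the endpoint
transition probability is tiny; a rejection sampler exists in the test
suite purely as an independent oracle. Realized transition counts
(`count_transitions()`) are reported with per-sample quantiles, and
crepuscular paths are flagged low-credibility. Estimated rates and realized
counts are kept strictly separate in all output: a high rate supported by
one rapid transition is a real possibility, so the two summaries can
legitimately disagree.

## Synthetic data: what it emulates, what it does not

`sim_study_dataset()` generates the study conditions end to end: a Yule
tree rescaled to unit height (322 tips by default, matching the size of a
curated moth trait dataset), the combined character evolved by exact
Gillespie simulation under a chosen model (default `E22`) from a
cryptic-nocturnal root, and a trait table plus the full true history.
Default rates (per unit tree height) are structured, not arbitrary: they
encode the qualitative pattern the analysis is meant to see. Nocturnality
dominates but diurnal species are common; the `All` state is labile (exit
rate 1.8 against entry 0.5), so it stays a minority and acts as a true
intermediate; colour losses (`Con`→`Cry`, 0.55) run somewhat faster than
gains (0.45); and all crepuscular paths sit at 0.02 so the crepuscular
state stays rare and its origins fall near the tips. Each dataset jitters
these base rates lognormally (sd 0.25 on the log scale) so replicates
differ. Note the time unit: on a unit-height tree a rate of 1 means one
expected event per total tree depth, so values above 1 here are still slow
per branch. The attached diagnostics report tip-state frequencies, the
crepuscular tip fraction and origin depths, and realized transition counts
so these qualitative targets can be checked directly; the test suite
asserts in particular that the crepuscular tip fraction stays below 10%
on average across replicate datasets.

The generator emulates the *statistical* structure the inference assumes —
a clean ultrametric chronogram, one Markov process over the whole tree,
exact species-to-tip matching. It does not emulate classifier disagreement
beyond what `consensus_classify()` models, topological uncertainty,
state-dependent diversification, or rate heterogeneity across clades.
Passing tests on synthetic data therefore validate the machinery and its
statistical calibration, not the biological conclusions one would draw from
any particular empirical dataset.

## Numerical choices and edge cases

* Ultrametry is checked with a relative tip-depth spread tolerance of
  $10^{-6}$; noisier trees warn but are analysed with branch lengths as
  given (chronograms carry numeric noise; refusing them would be
  unhelpful).
* Structural zeros are exact zeros in $Q$, never small numbers; fitted
  matrices preserve them exactly and rows sum to zero by construction.
* Negative round-off in reconstructed $P(t)$ entries is clamped at zero;
  row stochasticity is maintained to $10^{-10}$.
* Ties in AIC are broken by the stable model ordering of the input; the
  selection table keeps failed fits as rows with `NA` scores.
* Degenerate inputs: all-identical tips drive the likelihood to the root
  prior mass of that state as rates approach the lower bound; zero-rate
  generators are valid and yield event-free histories.
* Seeds: every stochastic entry point takes an explicit `seed`; model
  sweeps derive one sub-seed per model so single-model refits reproduce
  sweep results exactly.

## Problem sizes used in the package's own validation

The test suite validates the pruning likelihood and the marginal
reconstruction exactly (to $10^{-8}$) against exhaustive state-assignment
enumeration on trees of up to 5 tips, over a hundred random constrained
rate matrices; the uniformization sampler against a $2 \times 10^4$-path
rejection oracle (total-variation distance below 0.02) and against the
reconstruction marginals over 2000 histories on a 50-tip tree; parameter
recovery by refitting `E22` to a 1000-tip dataset with rates in
$U(0.05, 0.5)$, judged against a 50-replicate calibration envelope of the
estimator's sampling error under identical conditions; and model recovery
by checking that `E22` is AIC-ranked first among the 32 D/E-family models
in the majority of ten 500-tip replicates. These sizes keep the full suite
in the minutes range while leaving each check statistically meaningful.

## Limitations

* The model space is the 112 constrained structures; hidden-rate (HMM)
  expansions, irreversible variants and Bayesian treatments of $Q$ are out
  of scope.
* Crepuscular rates are shared plumbing across all models and their
  estimates should be read as low-credibility throughout.
* Reconstruction and mapping condition on a point estimate of $Q$;
  parameter uncertainty is not propagated.
* Polytomies are accepted by the likelihood machinery but the Yule
  generator produces binary trees only.
* Branch lengths are taken as given; the package does not time-calibrate
  trees.

## A worked run

```{r, eval = FALSE}
sim <- sim_study_dataset(n_tips = 322, seed = 1)
res <- run_mk_analysis(sim$tree, sim$traits,
                       models = c("E22", "E23", "D22", "E33", "G32"),
                       seed = 1, nsim = 1000)
res$tables[[1]]          # AIC / weight table
tidy(res$best_fit)       # MLE rates of the AIC-best model
res$asr                  # marginal ancestral states
res$transition_counts    # realized transitions with credibility flags
```
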