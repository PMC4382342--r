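---
title: "Detecting diversification-rate shifts and trait-dependent speciation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting diversification-rate shifts and trait-dependent speciation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shiftscape)
```

## The problem

Large time-calibrated phylogenies — for example a genus-level tree of
Nymphalidae butterflies spanning ~90 My — rarely diversify at one constant
rate.  Some clades (species-rich genera, hostplant-specialist radiations)
have accumulated far more species than a homogeneous birth–death process
predicts.  `shiftscape` answers three questions about such trees:

1. **Where** did the net diversification rate shift?  (Stepwise AICc search
   over piecewise birth–death models.)
2. **How robust** are those shifts to phylogenetic uncertainty?  (Re-running
   the search over a posterior sample of trees and summarising per-clade
   recovery frequencies.)
3. **Is a binary trait responsible?**  (The binary-state
   speciation–extinction (BiSSE) model, with maximum-likelihood fits,
   likelihood-ratio tests and MCMC.)

Because empirical trees arrive without known truth, the package also ships
forward simulators that *plant* truth — rate shifts, genus-level collapse,
posterior-style tree noise, state-dependent diversification — so every
stage is testable end to end.

## The piecewise birth–death model

### Rates and the clade-size law

Each regime ("piece") has a speciation rate $b$ and extinction rate $d$
(per lineage per My), summarised as net diversification $r = b - d$ and
relative extinction $\varepsilon = d/b$.  Both $d > b$ (declining clades,
$r < 0$) and the pure-birth (Yule) boundary $d = 0$ are supported.

A lineage of age $t$ leaves $N$ extant descendants with
$$\Pr(N = 0) = \alpha(t), \qquad
  \Pr(N = n \mid N > 0) = (1-\beta(t))\,\beta(t)^{\,n-1},$$
where
$$\alpha = \frac{d\,(e^{rt} - 1)}{b\,e^{rt} - d}, \qquad
  \beta = \frac{b\,(e^{rt} - 1)}{b\,e^{rt} - d}$$
are the classical birth–death transition quantities (so
$\alpha = \beta\,d/b$).  `clade_size_lnl()` exposes the geometric law; this
is how a terminal tip standing for an unresolved genus of $n$ species
contributes information: through its stem age and species count rather than
through branching times it does not have.

### The likelihood of a piece

A piece is a set of branches, observed splits, and terminal clades assigned
to one regime.  Writing $W(u) = (1-\alpha(u))(1-\beta(u))$ — the
probability that a lineage of age $u$ leaves exactly one extant descendant
— the piece log-likelihood is assembled from

* a factor $b$ per observed split (the founding split of a piece that
  starts with two lineages, i.e. the global root, is taken as given);
* a factor $W(s)/W(t)$ per branch spanning ages $s$ (older) to $t$: the
  exact per-branch solution of the linearised equation for the density of
  the observed subtree — the same propagation that the BiSSE machinery
  performs numerically, in closed form for the one-state case;
* the *unconditioned* clade-size probability
  $(1-\alpha(s))(1-\beta(s))\beta(s)^{n-1}$ per terminal clade.

All $\alpha$, $\beta$ terms are evaluated in log space, so the $d > b$
regime and extreme optimizer excursions retain their exponential tails
instead of saturating at floating-point clamps.

**Why the unconditioned density?**  This was the one genuinely open design
decision, and two superficially attractive alternatives fail:

* *Conditioning every terminal clade on survival* (using
  $(1-\beta)\beta^{n-1}$ inside the product) divides by the data-dependent
  quantity $\prod_i (1-\alpha(s_i))$.  That is not a constant
  normalisation: the "likelihood" then grows without bound along the
  high-extinction ridge $b \approx d \to \infty$, and the stepwise search
  happily chases it (we observed fitted rates of order $10^{308}$ and
  cascades of spurious shifts on constant-rate test trees).
* *Conditioning the crown piece on root survival* (dividing by
  $(1-\alpha(T))^2$, $T$ the root age) is sound for a whole-tree fit, where
  total branch length always exceeds $2T$ and the conditioning term is
  dominated.  Inside a piecewise model it is not: once accepted shifts
  strip the crown piece below $2T$ of claimed branch length, the term
  $-2\log(1-\alpha(T))$ dominates and the crown fit diverges.

The plain density is the only composition that remains a proper likelihood
for *every* partition the search can visit, and it keeps the model exactly
decomposable: refitting one piece never changes another piece's
contribution.  `resolved_lnl()` still offers classic root-survival
conditioning (and the conditioned tip law) for whole-tree work.

The package treats each piece's $\alpha$, $\beta$ as functions of that
piece's own rates down to the present.  Strictly, survival probabilities
below a piece depend on the rates of the regimes crossed on the way; the
approximation of regime-local survival is what makes the model
decomposable, and is shared by the piecewise-birth–death methods this
package follows.

### Model flavours and information criteria

Every piece is fitted under two flavours — `yule` ($d = 0$, one parameter,
solved in closed form or by a monotone score equation) and `bd` (two
parameters, bounded quasi-Newton iteration over $(\log b, \log d)$ started
from the Yule solution, with a second start in the $d > b$ region so
negative $r$ is reachable) — and the flavour with the better AIC
contribution wins.  The
$(\log b, \log d)$ parameterisation was chosen over $(r, \varepsilon)$
because it covers $d > b$ without a boundary at $\varepsilon = 1$.

Model comparison uses
$$\mathrm{AICc} = -2\ln L + 2k + \frac{2k(k+1)}{n - k - 1},$$
with $n$ the number of terminal taxa and $k$ the summed per-piece parameter
counts plus one location parameter per accepted breakpoint.

## The stepwise search

`stepwise_search()` fits the one-piece model, then repeatedly: scans every
candidate node (under the default `stem` convention a shift claims the
branch subtending its node plus its subtree, so single-genus shifts at
terminal tips are allowed; the `node` convention restricts cuts to internal
nodes), refits only the new piece and its donor (decomposability makes the
incremental total exact — the suite verifies it against full refits to
1e-8), and accepts the best candidate iff AICc improves by more than the
threshold.  Ties are broken by older node age, then lexicographically by
clade key, so results are independent of tip order and file rotation.

The acceptance threshold is a *configuration*, not a formula: the
size-dependent calibration of the original method implementations is not
re-derived here.  `aicc_threshold_for()` takes an explicit override or a
monotone lookup table and refuses to guess.  7.8 AICc units is the
documented value for a ~400-terminal tree and is the package default;
`max_shifts` (default 30) bounds runtime.  The search is forward-only by
construction; removal of earlier shifts after later additions is not
attempted, matching the incremental description of the method this package
re-implements.

Per-candidate results are cached between steps (a candidate is re-evaluated
only when its donor piece changed), which makes scans of ~200-node trees
take a couple of seconds.

## Phylogenetic uncertainty: the multi-tree protocol

A shift found on one summary tree may be an artefact of that topology.
`run_over_sample()` repeats the search independently over a posterior tree
sample (failures logged and excluded, results cacheable per tree);
`match_shifts()` then anchors each reference clade — named by its tip set
(`clade_key`), the only identity that survives topology changes — and
counts a match in tree $T$ whenever a shift of $T$ sits exactly at
`mrca(T, clade)`.  The MRCA rule, not exact clade equality, is essential:
a clade that is monophyletic in only a quarter of the sample can still be
recovered in nearly all trees, because the MRCA of its tips carries the
shift even when extraneous taxa intrude.  The recovery fraction
(`sum_prop`), and the median/mean/sd of the matched per-tree rates, mirror
the published summary tables; `summarize_shifts()` applies the
significance rule `sum_prop >= 0.90` and emits a boxplot-ready rate
matrix.  Conditional frequencies (given monophyly) and shifts matching no
reference clade ("unanchored") are reported rather than discarded.

## Trait-dependent diversification (BiSSE)

For a binary character (e.g. "feeds on Solanaceae", coded from hostplant
records by `code_binary_trait()`, with a recode switch for dubious
records), the BiSSE model gives each state its own speciation, extinction
and transition rates $(\lambda_i, \mu_i, q_{ij})$.  Along each branch the
package integrates the coupled equations for $E_i(t)$ (probability a
lineage in state $i$ leaves no sampled descendants) and $D_i(t)$ (density
of the observed subtree) with an adaptive Cash–Karp RK4(5) integrator
(relative tolerance $10^{-8}$ per branch by default, per-branch
renormalisation with a log accumulator).  Tips start at $D_i = f_i[x = i]$
and $E_i = 1 - f_i$, where $f_i$ is the state-specific sampling fraction —
computable from trait and richness tables via `sampling_fractions()`, or
supplied directly; missing-state tips set $D_i = f_i$ for both states.  At
nodes $D_i \leftarrow D^L_i D^R_i \lambda_i$; at the root, states are
weighted by their relative $D$ values by default ("obs"), with flat or
user-supplied weights and optional survival conditioning as alternatives
(the likelihood is by default the plain density of tree plus character,
consistent with the birth–death module).

Three independent cross-checks pin the implementation down: with one state
unreachable it reproduces the closed-form birth–death density; with
state-independent rates it factorises exactly into (tree density) ×
(two-state Markov character likelihood from an independent pruning
implementation); and on two-tip trees it matches a naive fixed-step RK4
integration to $10^{-6}$.

`bisse_ml()` maximises over $(\log$ rates$)$ by bounded quasi-Newton
iteration, with the equal-speciation constraint ($\lambda_0 = \lambda_1$,
$k = 5$) and a pure-birth variant (`extinction = "none"`, $\mu_i \equiv 0$)
available; `bisse_lrt()` forms $\chi^2 = 2\Delta\ln L$ on 1 df.  Two
practical points matter for a calibrated test.  First, the nested maxima
must be ordered, so the full model should accept the constrained optimum
as a starting point (`init =`).  Second, the $\chi^2_1$ reference assumes
every estimated parameter is interior — and extinction rates estimated
from ~100-tip reconstructed trees collapse to the $\mu = 0$ boundary in
well over half of replicates, which measurably distorts the null
distribution of the equal-speciation statistic (we observed both deflation
and inflation depending on turnover and stop rule).  The suite's
500-replicate calibration therefore uses the boundary-free pure-birth
variant, where the statistic is indistinguishable from $\chi^2_1$;
empirical 6-vs-5-parameter tests remain available but inherit the usual
caveat about weakly identified extinction.  `bisse_mcmc()` is a
coordinate-wise
slice sampler (stepping-out and shrinkage) under independent exponential
priors whose mean defaults to twice a crude whole-tree diversification
estimate — a weakly informative choice that keeps the posterior proper
without dominating trees of a few hundred tips.  The conventional run
length (10000 generations, 7500 burn-in) is the default; chains from a
tree subsample are concatenated post-burn-in by `pool_chains()` with
per-draw provenance.

## The synthetic-data generators

All generators are pure functions of (settings, seed) — byte-identical on
repetition, and they restore the caller's RNG state.

* `sim_bd_tree()` — forward Gillespie simulation from two crown lineages;
  extinct lineages pruned, degree-2 nodes suppressed; rejection until both
  crown lineages survive.  Under the taxa stop rule the present is placed
  just before the event after the target count is reached, so pendant
  branches are strictly positive.
* `sim_shifted_tree()` — plants regime switches: at each planned time a
  uniformly chosen background lineage (with its descendants) adopts new
  rates; rejection guarantees each planted clade survives with a minimum
  tip count, so the truth is always a clade of the output.
* `collapse_genera()` — repeatedly merges random cherries into single
  tips carrying summed species counts: collapsed blocks are monophyletic
  by construction and richness totals are conserved, matching the
  genus-level convention of the empirical data.
* `pseudo_posterior()` — emulates a Bayesian tree sample by lognormal
  multiplicative jitter of node ages (parent-older-than-child restored in
  a postorder pass) plus nearest-neighbour interchanges at a per-edge
  rate.  NNI noise was chosen over model-based resampling because it is
  cheap, controllable, and reproduces the phenomenon that matters for the
  protocol: clade support — and with it shift recovery — decays smoothly
  with the perturbation rate.
* `sim_bisse_tree()` — joint Gillespie simulation of branching,
  extinction and state flips, with optional state-specific subsampling.

What these generators do *not* emulate: correlated age/topology error of
real Bayesian posteriors, non-geometric genus sizes, gradual (non-step)
rate change, and trait-dependent sampling bias.  Green tests therefore
demonstrate internal correctness and recoverability under the stated
generating processes, not robustness to every empirical pathology.

## Study conditions used by the test suite

The suite's experiments fix: false positives on 100-tip pure-birth trees
($b = 0.12$, 100 replicates, threshold 7.8 — observed rate well under the
10% bound); recovery of a 5× speciation increase planted at 20 My on a
background of $b = 0.14$ run to 25 My (clades of ≥15 tips in ~100-tip
trees, 100 replicates, ≥80% required, a hit counted at the planted node or
one branch away, since the regime switches mid-branch); the multi-tree
protocol on pseudo-posteriors of 20–100 trees with topology noise 0–0.5;
BiSSE null calibration with 500 replicates at 100 tips (ODE tolerance
relaxed to $10^{-6}$); and speciation-asymmetry recovery
($\lambda_1 = 2\lambda_0$) at 300 tips.  These sizes keep the full suite
in the tens of minutes on one CPU while leaving the Monte-Carlo margins
comfortable.

## Numerical choices and degenerate inputs

* lnL floors at $-10^{10}$ instead of raising, so optimizers can traverse
  impossible regions; non-finite intermediates never abort a scan.
* A lone unresolved clade cannot identify extinction: its `bd` "fit" is
  defined as the Yule solution (closed form $b = \log(n)/s$), and an
  all-singleton piece legitimately fits $b \to 0$ with lnL $\to 0$ —
  mirroring the zero-rate terminal-pair rows seen in published shift
  tables.
* Ultrametricity is checked to a relative $10^{-3}$ of root age (dated
  Bayesian trees carry rounding noise); violations warn and flag, and node
  ages are rebuilt from branch lengths by maximum path.  Polytomies are
  accepted on input but rejected by every likelihood (binary branching is
  assumed throughout).
* Candidates whose AICc is undefined (parameter count reaching the tip
  count) are skipped rather than compared.

## Known limitations

Rates are constant within a piece (no time-varying or diversity-dependent
models); fossil tips are not supported; the BiSSE module is strictly
binary (no multi-state or hidden-state extensions); and the multi-tree
matching is purely node-based — no tree-distance-weighted alternatives.
The genus-to-nearest-relative richness assignment of the empirical data is
treated as input, validated for completeness but never recomputed.
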