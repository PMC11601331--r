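---
title: "Models and methods: odor manifold geometry in a spiking model of pDp"
author: "pdpmanifold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: odor manifold geometry in a spiking model of pDp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`pdpmanifold` studies how associative learning reshapes the geometry of odor
representations in the posterior zone of the dorsal pallium (pDp), the
zebrafish homolog of piriform cortex.  It contains a spiking network model of
pDp with excitatory/inhibitory (E/I) assemblies, the two distance analyses
(Euclidean and Mahalanobis) used to compare odor manifolds, a mean-field
estimator of manifold capacity with anchor-point effective geometric
measures, synthetic-data generators that stand in for calcium-imaging data,
and the nonparametric group statistics used to compare conditions.

This vignette documents the models, the estimators, their assumptions and
tunable parameters, and the design choices made where the problem was
genuinely open.

## Neural manifolds

A *manifold* here is a labeled point cloud: the set of population activity
vectors evoked by one odor, pooled over trials and time bins, in a state
space with one dimension per neuron.  The imaging-style convention pools a
3 s analysis window sampled at 7.5 Hz over 3 trials (72 points per odor);
the model convention pools a 2 s odor window in 100 ms rate bins over 4
trials (80 points).  `build_manifolds()` performs the pooling from a
`neurons x timebins x trials x odors` rate array.

## The spiking network model of pDp

The network has 1000 excitatory (E) and 250 inhibitory (I) adaptive
leaky integrate-and-fire neurons with conductance synapses, driven by 1500
excitatory mitral cells of the olfactory bulb (OB).  The membrane potential
of neuron $x$ in population $X$ obeys

$$C_X \frac{dV_x}{dt} = g_{rest,X}(E_{rest,X} - V_x)
  + g_{OB,x}(E_{exc} - V_x) + \sum_{P \in \{exc, inh\}} g_{P,x}(E_P - V_x)
  - z_x \,\delta(X = exc),$$

with an adaptation current on E cells,
$\tau_{ad}\, dz/dt = a\,(V - E_{rest}) - z$ and $z \to z + b$ at each
spike.  Synaptic conductances decay exponentially with time constant
$\tau_{syn,P}$ and jump by the connection weight $w_{yx}$ at presynaptic
spikes.  Integration is forward Euler at $dt = 0.1$ ms (0.05 ms in the
convergence tests), with exact exponential decay factors for the
conductances; mitral spikes are drawn as an inhomogeneous Poisson process
with piecewise-constant rates, and one shared OB spike train drives both E
and I targets.

Connections exist independently with probability $p_{xy}$ per population
pair (Bernoulli), and all existing connections of a pair carry the same
weight $w_{xy}$.  The six weights come from one of four predefined
settings A-D (`weight_table()`, shipped as
`inst/extdata/weight_settings.csv`).

### Parameters that are package choices

The membrane, adaptation, spiking-mechanism constants and the connection
probabilities are not part of the weight table; they are configurable
defaults of `pdp_params()`, chosen to place the network in a balanced,
sparse regime (baseline E rate well below 1 Hz, odor-evoked E rates of a
few Hz, inhibition tracking excitation):

| parameter | E | I | units |
|---|---|---|---|
| $C$ | 200 | 100 | pF |
| $g_{rest}$ | 10 | 10 | nS |
| $E_{rest}$ | -70 | -65 | mV |
| $V_{thr}$ | -50 | -50 | mV |
| $V_{reset}$ | -70 | -65 | mV |
| $t_{ref}$ | 2 | 2 | ms |

with $E_{exc} = 0$ mV, $E_{inh} = -85$ mV, $\tau_{syn} = 30/30/10$ ms
(OB/exc/inh), adaptation $a = 2$ nS, $b = 50$ pA, $\tau_{ad} = 200$ ms, and
connection probabilities OB$\to$E 0.085, OB$\to$I 0.05, E$\to$E 0.1,
E$\to$I 0.1, I$\to$E 0.3, I$\to$I 0.2.  All of these can be overridden
through `pdp_params(...)`.

### Olfactory-bulb input

Each virtual odor raises the rate of exactly 150 mitral cells above the
6 Hz baseline and lowers the rate of another 75 cells (to 1 Hz by
default).  Pairwise pattern correlations are tuned by a shared-subset
construction: all odors share a small global core of modulated cells
(tuned by bisection to the across-class target) and odors of one class
share an additional class core (tuned to the within-class target).  The
achieved correlations are computed directly from the returned rate vectors
and must be within 0.05 of the target, otherwise `make_ob_patterns()`
fails naming the offending pair.  The default six-odor panel has two
classes (A1-A3, B1-B3) with within-class correlation 0.5 and across-class
correlation 0; A odors are given a larger response amplitude (+15 Hz on
up-cells versus +12 Hz), reflecting the stronger responses evoked by amino
acids than bile acids.  No attempt is made to fit real imaging
amplitudes; these are labeled package choices.

### E/I assemblies ("learning")

An assembly for an odor comprises the 100 E neurons receiving the most
connections from that odor's up-modulated mitral cells and the 25 I neurons
receiving the most connections from those E neurons (ties broken by lowest
id).  Learning is imposed structurally: the connection density among
assembly members is raised to $\min(g \cdot p_{xy}, 1)$ within the
E-assembly and between the E- and I-assembly (both directions), and an
equal number of connections from non-assembly onto assembly neurons is
removed, so per-pair connection totals are conserved exactly (asserted in
the tests).  The density formulation (rather than a fixed added count)
keeps the operation well defined when assemblies of correlated odors
overlap.

The rewiring magnitudes default to $g_{EE} = 9$, $g_{EI} = 10$,
$g_{IE} = 3.3$ — a nearly complete bipartite E/I loop within the assembly.
This is the regime in which the assembly amplifies its learned odors
selectively (about 2-3 fold within the assembly) while feedback inhibition
prevents ignition for non-learned odors, reproducing the predicted
learning signature: `dE` between learned and other odors increases far
more than among B odors, and `dM` increases selectively in the direction
from learned odors to the other class, partially generalizing to the
related third A odor.

### Distance analysis of model output

Spiking output in 100 ms count bins differs from inferred imaging rates in
two ways that matter for the Mahalanobis distance: it contains exact zeros
(silent neurons) and strongly correlated count fluctuations.  Both
destabilize the inverse of a reference covariance estimated from only 80
points.  `learning_contrast()` therefore (i) restricts the analysis to
neurons with at least 1.5 Hz mean rate in every manifold of both networks
(about 3 spikes in the window, guaranteeing a count-noise floor in every
dimension), (ii) uses 40-neuron subsets for the model (the 70-neuron
protocol remains the default of `distance_matrices()`), and (iii) applies
diagonal shrinkage $S^* = (1-\gamma) S + \gamma\,\mathrm{diag}(S)$ with
$\gamma = 0.3$ to the reference covariances (`shrink` argument, default 0
elsewhere).  Shrinkage suppresses exactly the correlated-fluctuation
component that contaminates the smallest eigenvalues; the reported
contrasts are insensitive to $\gamma$ in the range 0.3-0.7.

## Distances between manifolds

For manifolds $X$ and $Y$ with centers $\mu_X, \mu_Y$ and reference
covariance $S_Y$,

$$d_E(X, Y) = \lVert \mu_X - \mu_Y \rVert, \qquad
  d_M(X \to Y) = \frac{1}{|X|}\sum_{x \in X}
  \sqrt{(x - \mu_Y)^\top S_Y^{-1} (x - \mu_Y)}.$$

Both are implemented in the true-metric (square-root) convention, with a
`squared = TRUE` switch; orderings and asymmetries are invariant to this
monotone choice.  $d_M$ is directional: it measures how far the sample
manifold's points sit from the reference center *in units of the
reference's variability*, so $d_M(X \to Y) \ne d_M(Y \to X)$ whenever the
two covariances differ.  Useful identities, all asserted in the test
suite: scaling all manifolds by a common factor scales $d_E$ and leaves
$d_M$ unchanged (distance and variability co-scale); both are invariant
under global rotations, and $d_M$ under any shared invertible affine map.

`distance_matrices()` implements the subsampling protocol: per repeat one
shared random subset of 70 neurons is drawn (covariance invertibility
requires more points than dimensions), both matrices are computed on that
subset for all pairs, and results are averaged over 50 repeats (means, not
medians).  A ridge $\varepsilon\,(\mathrm{tr}\,S / N)\,I$ with
$\varepsilon = 10^{-6}$ is added only when the condition number exceeds
$10^{10}$; a covariance that remains singular is an error naming the
condition number.

## Mean-field manifold capacity

Manifold capacity $\alpha$ is the critical number of manifolds per state
space dimension at which random binary labelings stop being linearly
separable; it summarizes how "untangled" a representation is.  The
estimator draws zero-mean unit-covariance Gaussian samples $T$ and, for
each label assignment $y$, solves the convex projection program

$$F(T) = \min_{V} \lVert V - T \rVert_2^2 \quad \text{s.t.} \quad
  y_\mu \, V^\top x \ge \kappa \;\; \forall x \in M_\mu,$$

and returns $\alpha = P / \overline{F}$, the reciprocal of the mean optimal
value per manifold.  With the default margin $\kappa = 0$ the program is
always feasible ($V = 0$).  The QP is solved in its dual: with constraint
rows $a_i = y_i x_i$, $G = AA^\top$ and $q = \kappa - AT$, the dual is the
non-negative quadratic program
$\min_{\lambda \ge 0} \tfrac12 \lambda^\top G \lambda - q^\top \lambda$,
solved by cyclic coordinate descent (C++), with convergence declared on
the end-of-sweep KKT residual.  The solver is verified against a
non-negative least-squares oracle (the dual is exactly the projection of
$T$ onto the polar cone).

Two preprocessing flags, both on by default, mirror the data-analysis
convention: *global centering* translates the mean of the manifold centers
to the origin, and *bias* appends a constant coordinate (excluded from
Gaussian sampling) so the separating hyperplane may have an offset.

Label scheme: for a pair of manifolds the single $(+1, -1)$ dichotomy is
used (its mirror is equal in distribution); for $P > 2$ all sign-unique
non-constant dichotomies, capped at `max_dichotomies`.

`manifold_capacity()` is the front end: per repeat it subsamples neurons
and points (700/140 in the juvenile analysis geometry, 400/80 in the adult
one), verifies linear separability (affine independence of the pooled
subsample; rank-deficient draws are rejected and counted), computes
$\alpha$ and the effective measures from the same Gaussian samples, and
computes the shuffle control on the same subsample.

### The shuffle null

The control pools the points of both manifolds and reassigns them at
random into pseudo-manifolds of the original sizes.  For $M$ points per
pseudo-manifold the capacity approaches $2/M$ (a Cover-type counting
argument: $PM$ points in general position stop being separable at
$PM \approx 2N$).  The estimator reproduces this: 0.0143 for the
700-neuron/140-point geometry ($2/140 = 0.0143$) and 0.0252 for
400/80 ($2/80 = 0.025$), essentially independent of the generator's
covariance structure or center separation.  `scripts/acceptance.R`
recomputes both numbers from scratch.

### Anchor points and effective measures

By strong duality, each solved program singles out one point per manifold
— the *anchor point*, the convex combination of that manifold's points
weighted by the active dual multipliers.  The randomness of $T$ induces a
distribution of anchor points on each manifold, and the five effective
measures are moments of that distribution, computed in the original
(un-centered) data coordinates.  With $\tilde{x}^\mu_k$ the anchors of
manifold $\mu$ over samples $k$, $\tilde{c}_\mu$ their mean, and
$\tilde{\Sigma}_\mu$ their covariance:

1. **Effective radius** —
   $\mathrm{mean}_\mu \sqrt{\mathrm{tr}\,\tilde{\Sigma}_\mu} /
   \lVert \tilde{c}_\mu \rVert$: anchor spread normalized by the center
   length.
2. **Effective dimension** — participation ratio
   $(\mathrm{tr}\,\tilde{\Sigma}_\mu)^2 / \mathrm{tr}(\tilde{\Sigma}_\mu^2)$,
   the number of directions the anchor distribution explores.
3. **Center alignment** —
   $\lvert \cos(\tilde{c}_\mu, \tilde{c}_\nu) \rvert$ for each pair.
4. **Axes alignment** —
   $\mathrm{tr}(\tilde{\Sigma}_\mu \tilde{\Sigma}_\nu) /
   (\lVert\tilde{\Sigma}_\mu\rVert_F \lVert\tilde{\Sigma}_\nu\rVert_F)$,
   the cosine between the anchor covariances.
5. **Center-axes alignment** — the fraction of one manifold's anchor
   variance lying along the other's center direction, symmetrized.

The exact closed forms used by the original mean-field theory are not
printed in the sources this package follows; the definitions above are the
package's own anchor-moment construction and are fixed here so results are
reproducible.  They behave as the theory requires: capacity falls when
effective radius, dimension or center alignment rise, and rises with axes
alignment (each verified over one-factor synthetic families in the
acceptance suite); identical centers give center alignment 1 and
orthogonal centers give about 0.

### Validation against an empirical oracle

The estimator is cross-checked against an independent separability
experiment: project the points into $n$ random dimensions, test linear
separability of each dichotomy (a Gilbert minimum-norm-point computation on
the convex difference hull, which terminates with either a separating
certificate or an origin-in-hull certificate), locate the 50% crossing
$n_c$ per dichotomy, and compare $P / \mathrm{mean}(n_c)$ with the
mean-field value.  Conventions must be matched: the crossing is measured
for homogeneous (through-origin) separation and the mean-field run uses
`bias = FALSE`, because an affine oracle shifts the critical dimension by
one (the bias coordinate is excluded from Gaussian sampling).  On small
instances ($P \le 4$, $M \le 10$, $N = 50$) agreement is about 8-9% mean
relative error — a one-sided finite-size deviation (the mean-field value is
an asymptotic quantity; the empirical transition at critical dimensions of
5-20 sits slightly below it) that shrinks with instance size.

## Group statistics

`mann_whitney()` (two-sided; exact for small untied samples, normal
approximation with tie and continuity correction otherwise),
`kruskal_dunn()` (Kruskal-Wallis omnibus plus Dunn's z-tests against a
reference group on the pooled ranking with tie correction,
Bonferroni-adjusted), and `ols_regression()` (slope, $R^2$, slope
p-value) reproduce the statistical toolkit of the analyses, with the
standard significance-star display convention (`significance_label()`).
These wrap `stats::wilcox.test`, `stats::kruskal.test` and `stats::lm`;
Dunn's post hoc statistic is implemented directly (no installed package
provides it) and verified against the rank formula and a type-I-error
simulation.

## What the synthetic generators do and do not emulate

`synthetic_odor_session()` emulates trial-resolved imaging data: correlated
per-neuron odor tuning with two odor classes, a phasic-tonic response time
course (fast rise, exponential decay to a plateau), additive bin noise, and
non-negative rates.  `make_synthetic_manifolds()` draws point clouds with
controllable center, covariance spectrum and axes, with rates clipped at
zero (clip fraction recorded, warning above 1%).  Real imaging data differ
in ways these generators do not capture: spike-inference artifacts,
slow drifts and shared motion components, neuron-specific noise statistics,
and manifold nonlinearity.  Passing tests therefore certify the analysis
machinery and the model's qualitative predictions, not quantitative
properties of real pDp recordings; group values measured on
fish (e.g. capacity near 0.1, its training effects, and
behavior-geometry regressions) require the original imaging data and are
out of scope.

## Numerical choices and problem sizes

The suite runs the shuffle nulls at the full analysis geometries (700/140
and 400/80; 20 shuffles, 60-80 Gaussian samples), the network contrast at
the full network size (1000 E neurons) with 4 connectivity instantiations,
4 trials and a 2 s odor window, the oracle comparison on 20 random small
instances, and the monotonicity sweeps at $N = 150$, $M = 40$.  Determinism
is guaranteed by explicit seeds on every stochastic entry point; all
randomness flows through R's RNG (including the C++ simulator).  Degenerate
inputs fail loudly: non-PSD covariance requests, singular reference
covariances after regularization, infeasible correlation targets,
insufficient removable connections during rewiring, and unstable membrane
trajectories each raise errors naming the offending quantity.

## Known limitations

* The mean-field capacity on a finite instance is an asymptotic estimator:
  at very small critical dimensions it overestimates the empirical
  transition by up to ~10%.
* The membrane/adaptation constants and connection probabilities of the
  network are package defaults, not fitted values; the four weight
  settings A-D are taken as given.
* Mahalanobis analysis of discrete spike counts requires the conditioning
  safeguards described above; with continuous inferred rates the plain
  protocol applies.
* Manifolds are treated as point clouds; no geodesic or otherwise
  nonlinear notion of distance is used.
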