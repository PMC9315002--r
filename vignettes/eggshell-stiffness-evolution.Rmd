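---
title: "Eggshell stiffness and nest evolution: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Eggshell stiffness and nest evolution: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(shellevo)
```

`shellevo` implements a two-part analysis: (i) a mechanical summary of
eggshell stiffness that is comparable across species of very different egg
sizes, and (ii) phylogenetic comparative methods that relate that summary to
nest characteristics — how a nest is attached, where it sits, and how
enclosed its structure is. This vignette is the package's own account of the
models, their assumptions, the tunable parameters, and the numerical and
design choices behind them.

## 1. The C number: dimensionless eggshell stiffness

An egg compressed between two rigid plates along its long axis responds, in
the linear regime, with an absolute stiffness $K$ (N/m): the force per unit
plate-to-plate approach. $K$ confounds shell material and thickness with egg
size and shape, so for interspecific comparison we use the dimensionless

$$C_{\mathrm{long}} = \frac{K}{W}\,\frac{A^2}{B}, \qquad
  C_{\mathrm{short}} = \frac{K}{W}\,\frac{2AB}{A+B},$$

where $W$ is the egg weight (N), $A$ the breadth and $B$ the length (m).
Both forms reduce to $K D / W$ for a sphere of diameter $D$, and both are
invariant to the unit system. A chicken-sized egg
($K = 1.5\times10^5$ N/m, $W = 0.6$ N, $A = 44.3$ mm, $B = 57.0$ mm) gives
$C \approx 8607$, squarely inside the range reported for wild birds.

### The compression model

Axial compression of a surface of revolution is an axisymmetric problem, so
the package replaces a full 3-D shell-plus-contact simulation with
one-dimensional meridian shell elements: Kirchhoff–Love kinematics
(membrane + bending, small strain), with the rigid frictionless plates
entering as concentrated axial loads at the two poles — the limit of the
contact patch as the approach goes to zero. The reported $K$ is the
plate-to-plate stiffness, i.e. the two pole dimples act in series.

The meridian is parametrised by a polar angle $\theta \in [0, \pi]$:
$z = (B/2)(1-\cos\theta)$ and $r = (A/2)\sin\theta\,P(-\cos\theta)/M$, where
$P$ is a shape polynomial (constant $P$ gives a prolate spheroid; its odd
term is the `asymmetry`, its even term the `ellipticity`) and $M$ normalises
the maximum radius to $A/2$. Displacements $u$ (meridian-tangential) and $w$
(normal) are interpolated with Hermite cubics; the strain measures are
$\varepsilon_s = u' - \kappa w$, $\varepsilon_\theta = (u r' + w z')/r$,
$\chi_s = \beta'$, $\chi_\theta = \beta r'/r$ with rotation
$\beta = w' + \kappa u$ and meridian curvature $\kappa$.

Numerical choices that matter:

* **Mesh grading.** The point-load response lives in a boundary layer of
  width $\sim\sqrt{Rt}$ at each pole. Nodes follow
  $\theta = \pi(x - \sin 2\pi x/2\pi)$, which clusters elements
  quadratically at both poles.
* **Pole conditions.** Regularity on the axis forces $u = 0$ and
  $w' = 0$ at both poles; $w = 0$ at the bottom pole grounds the axial
  rigid-body mode.
* **Equilibration.** Membrane ($\propto Et$) and bending ($\propto Et^3$)
  blocks give the raw stiffness matrix a condition number near $10^{15}$;
  a symmetric Jacobi scaling restores solvability without changing the
  solution.
* **Convergence reporting.** Every solve refines the mesh by a factor 1.5
  at least once and reports the relative change; the default tolerance is
  0.5%. The default 150–200 meridian elements resolve $t/R$ down to 0.005.

The solver is validated against the Reissner closed form for a point-loaded
thin spherical shell, $K_{\mathrm{single}} = 4Et^2 / (R\sqrt{3(1-\nu^2)})$
(two dimples in series halve it): agreement is within 2.6% across
$t/R \in \{0.005, 0.01, 0.02\}$, the thickness ratios of real eggshells.
Two properties worth noting: $K$ is exactly linear in $E$, scales nearly as
$t^2$, and *increases* when the egg is elongated at fixed breadth — the
pole curvature radius $(A/2)^2/(B/2)$ shrinks as $B$ grows, stiffening the
dimple. Material defaults are $E = 30$ GPa, $\nu = 0.3$, whole-egg density
1.031 g/cm³ (used when mass is missing), $g = 9.81$; per-species values
rescale $C$ multiplicatively and are configurable.

**Not modelled:** nonlinear buckling, fracture, non-uniform thickness,
image-based profile extraction (profiles or $A$/$B$/$t$ tables are inputs).

## 2. PGLS with Pagel's lambda

Species are related, so log10 C values are not independent. The package
fits $y = X\beta + \varepsilon$,
$\varepsilon \sim N(0, \sigma^2 V(\lambda))$, where $V(1)$ holds the shared
root-to-node path lengths (Brownian motion) and $V(\lambda)$ multiplies its
off-diagonals by $\lambda \in [0,1]$. Choices:

* **ML, not REML.** The analysis compares models with different fixed
  effects by AICc, which requires full ML; the parameter count $k$ includes
  the $\beta$s, $\sigma^2$, and $\lambda$ when estimated.
* **Lambda search.** Bounded scalar maximisation of the profile likelihood
  on $[0,1]$ (tolerance $10^{-6}$), with explicit comparison against the
  boundary values so boundary optima are reported as such.
* **Fast path.** On ultrametric trees $V(\lambda) =
  U(\lambda\Lambda + (1-\lambda)T)U^\top$ for the fixed eigensystem of
  $V$, so each lambda evaluation is a weighted least squares in the rotated
  frame; non-ultrametric trees fall back to a Cholesky per evaluation.
* **Inference.** $t$ statistics use $n - p$ residual degrees of freedom
  (the convention adopted for tests under an estimated lambda).
* **Coding.** Treatment (dummy) coding with the lowest-risk category as
  reference: basal attachment, "others" sites, scrape/platform structure.
  C is log10-transformed before modelling.

Multi-valued nest categories are first collapsed by `recode_nest_risk()` to
the highest-risk category the species uses (lowest stability / highest
enclosure), with risk orders basal < lateral/horizontal < pensile;
others < tree < non-tree vegetation; scrape/platform < cavity < cup < dome.

### Grouping selection

Where a nest character is significant, multiple comparisons are done by
AICc over *every* set-partition of its levels (Bell-number many models,
enumerated as restricted growth strings; at most 6 levels). The winning
partition is displayed as compact letters. Two honest caveats, both
measured in the test suite: under a true null the single-group partition
wins only about 65% of the time (AICc admits a spurious extra group at
roughly the $P(\chi^2_1 > 2)$ rate per competing partition), and with one
well-separated level the exact two-group partition wins about 80–85% of
replicates while the separated level is essentially never merged. These
rates are properties of AICc selection itself, not implementation slack.

## 3. Correlated evolution of two binary traits

Interdependence between stiffness class (high/low, split at the median with
ties to "low") and a binarised nest character is tested with the classical
dependent/independent pair of 4-state continuous-time Markov models on
states $(0,0), (0,1), (1,0), (1,1)$: eight free rates with double
transitions forbidden (dependent), versus four rates with each trait's
gain/loss independent of the other's state. The likelihood is Felsenstein
pruning with per-branch $e^{Qb}$ (one eigendecomposition of $Q$ per
evaluation, scaling-and-squaring fallback), implemented in C++.

* **Root treatment.** Likelihood-weighted root frequencies (FitzJohn-style,
  matching the tool family standard for these models); uniform and
  stationary weights are available.
* **Branch scaling.** Branch lengths are multiplied by 0.001 before the
  likelihood, making rate magnitudes comparable to the exponential prior
  with mean 10 used on all rates.
* **MCMC.** One rate per iteration receives a lognormal multiplier
  proposal (the Hastings ratio includes the Jacobian $q'/q$); the proposal
  scale adapts during burn-in only, so post-burn-in kernels are fixed and
  runs are bitwise reproducible by seed. A data-free mode samples the prior
  exactly (recovering the prior mean 10 to within 0.12 in the suite).
* **Marginal likelihood.** Stepping-stone sampling along
  $\beta_j = (j/K)^{1/0.3}$ from prior to posterior; the prior stone is
  sampled iid, later stones are warm-started chains. A model whose
  likelihood is constant yields the exact answer (log marginal likelihood
  equals the constant), which the suite checks to machine precision via a
  zero-branch-length fixture.
* **Bayes factor.** $BF = 2(\log ML_{dep} - \log ML_{indep})$; above 2
  reads "positive", above 10 "strong". Under matched simulation conditions
  (300 tips; one trait's gain rate 10-fold higher in the other trait's
  derived state) the dependent data give mean BF well above 2 and
  independent data give mean BF below 2.

## 4. Ancestral states and temporal trends

Ancestral log10 C values use the non-directional Brownian ("random walk")
model. Two estimators are provided: a closed-form GLS solution (the
minimiser of the Brownian quadratic form, solved as a sparse linear
system), and an MCMC sampler that Gibbs-draws each internal node from its
Gaussian full conditional and updates $\sigma^2$ by Metropolis-Hastings
under an exponential prior (default mean 0.001, which matches the scale of
log10 C evolution on depth-100 trees). Posterior node means coincide with
the GLS solution; the sampler adds posterior medians and SDs, and
`asr_convergence()` reports across-run SDs of node means. Nodes are
identified by two exemplar tips whose MRCA they are, so estimates can be
matched across trees with different topologies.

The temporal trend is a quantile regression (default $\tau = 0.5$) of
pooled tip values and node posterior medians on node depth, optionally with
a passerine indicator and its depth interaction. Because no linear
programming solver is assumed, the check loss is minimised by an MM/IRLS
scheme with a geometrically decreasing smoothing floor, then polished over
exact-fit bases drawn from the $2p$ smallest residuals (a $\tau$-quantile
solution interpolates $p$ points). On 30-point fixtures the solution
matches exhaustive basis enumeration exactly. Standard errors are seeded
case-resampling bootstraps (default 1000 replicates; the pipeline defaults
use 200–300 for runtime). Display
curves (`spline_trend()`) are B-spline quantile fits at the 5th, 50th and
95th percentiles per group; they are descriptive only.

## 5. The synthetic study

`simulate_study()` fixes the conditions every statistical claim is tested
under: a Yule tree rescaled to depth 100 (the time scale of avian
phylogenies); nest characters evolving by mildly asymmetric Mk processes on
their closed vocabularies (risk-increasing moves 0.6 times as fast, rate
0.01 per unit time, giving a handful of changes per lineage); clutch size
$1 + \mathrm{Poisson}(2.5)$; a passerine clade chosen as the clade closest
to 45% of tips; and log10 C built as intercept 4.10 plus the published
effect scale (clutch +0.017 per egg; lateral/horizontal +0.052, pensile
+0.111; tree +0.050, non-tree vegetation +0.081; cavity +0.066, cup +0.070,
dome +0.136) plus a Pagel's-lambda residual with $\sigma^2 = 2.56\times
10^{-4}$ per unit time (residual SD $\approx$ 0.16 on log10 C, matching the
spread of the published C range) and default $\lambda = 0.5$ (between the
published 0.44–0.49). Egg geometries follow mass–size–thickness allometry
($t \propto m^{0.456}$) with lognormal noise and enforce the thin-shell
regime.

What the generator deliberately does *not* emulate: real avian taxonomy,
body-mass databases, the correlation between nest type and clutch size,
non-ultrametric trees, and measurement error in C itself. Passing tests
therefore show that the estimators recover the generating process they
assume — not that real data satisfy those assumptions.

Problem sizes used by the tests and the acceptance script (chosen as
desk-scale study conditions): PGLS recovery at 400 tips with 200 (tests) or
50 (script) replicates; Bayes factors at 300 tips with 20 or 8 replicates
per regime and 10 stepping stones of 800 iterations; ancestral agreement on
a 50-tip fixture with 20k iterations; prior recovery with 120k iterations
(20,000 retained samples). Full-scale reproduction of the published
coefficients (1350 species, 1000 posterior trees, 5.05M-iteration chains)
requires the archived study data and is outside the package's test scope;
the property-based suite above is the acceptance surface instead.

## 6. Known limitations

* Short-axis compression of a non-spherical egg is not axisymmetric, so
  `solve_axial_stiffness()` handles long-axis stiffness only; the short-axis
  C formula is provided for completeness and uses whatever $K$ it is given.
* The least-squares consensus branch lengths use *mean* patristic distances
  over the tree sample (the distance summary is unstated in the source
  analyses; the mean is deterministic and standard). The two edges at a
  rooted binary root are identifiable only as a sum; the minimum-norm
  (equal) split is returned.
* Stepping-stone estimates with the default desk-scale settings carry
  Monte-Carlo noise of roughly $\pm 0.5$ log units; Bayes factors near the
  "positive" threshold of 2 should be read accordingly.
* AICc grouping selection overfits at the known small rate discussed above;
  the letter display reflects the single best partition, not pairwise
  tests.
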