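---
title: "Methods: structural stability and eco-evolutionary dynamics of mutualistic networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structural stability and eco-evolutionary dynamics of mutualistic networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecoevonet)
```

This vignette documents the model, the parameterization, the numerical
choices, and the known limitations of `ecoevonet`. It is the methods
reference for the package; the README holds a worked end-to-end example.

## The ecological model

The package simulates two mutualistic guilds — plants ($P$) and animals
($A$) — whose abundances follow saturating Lotka–Volterra dynamics. For a
plant $i$ (the animal equations are symmetric):

$$
\frac{dN_i^P}{dt} \;=\; N_i^P \left[\,
  \alpha_i^P \;-\; \sum_{j} \beta_{ij}^P N_j^P \;+\;
  \frac{\sum_{k} \gamma_{ik}^P N_k^A}{1 + h_i^P \sum_{l} \gamma_{il}^P N_l^A}
\right]
$$

* $\alpha_i$ — intrinsic growth rate,
* $\beta_{ij}$ — within-guild competition,
* $\gamma_{ik}$ — mutualistic benefit per unit partner abundance,
* $h_i$ — handling time, saturating the total mutualistic benefit
  (Holling type II).

Competition is mean-field with multiplicative noise:
$\beta_{ij} = \left(\rho + \delta_{ij}(\beta_0 - \rho)\right) b_{ij}$ with
$b_{ij} \sim U[1-\epsilon,\, 1+\epsilon]$, so all interspecific entries sit
near a single value $\rho$ and the diagonal near $\beta_0 = 1$.
Mutualism follows the bipartite incidence matrix $a$:
$\gamma_{ik} = a_{ik}\, \gamma_0\, c_{ik}$ with
$c_{ik} \sim U[1-\epsilon,\, 1+\epsilon]$. Each link carries two
independent directional strengths (plant-side and animal-side draws).

Defaults (`meta_parameters()`): $\gamma_0 = 0.15$, $h = 0.1$,
$\beta_0 = 1$, $\epsilon = 0.1$, $N^* = 1$. These keep assemblies feasible
across the studied competition range $\rho \in [0.0125, 0.15]$ while making
mutualism strong enough to matter for the effective competition.

## Feasible assembly

Rather than integrating from random initial conditions, `assemble_community()`
*prescribes* the equilibrium $N_i = N^* = 1$ for every species and solves the
equilibrium balance for the growth rates:

$$
\alpha_i \;=\; \sum_j \beta_{ij} N^* \;-\;
\frac{\sum_k \gamma_{ik} N^*}{1 + h_i \sum_l \gamma_{il} N^*}.
$$

If any $\alpha_i \le 0$ the noise matrices are redrawn (up to
`feasibility_retries`, default 100); persistent failure raises an
infeasibility error rather than returning a biologically meaningless
community. A useful closed form for testing: the complete $2\times 2$
community with $\epsilon = 0$, $\rho = 0.1$ has
$\alpha = 1.1 - 0.3/1.03 \approx 0.808738$.

## Steady-state integration

`integrate_to_steady_state()` uses `deSolve::lsoda` with a compiled C
right-hand side. Numerical choices:

* **Convergence criterion.** Integration proceeds in chunks (5 time units,
  doubling to a 160 cap, overall horizon 5000). The system is converged when
  the scaled residual $\max_i |dN_i/dt| / \max(N_i, 10^{-8})$ falls below
  `rel_tol` ($10^{-9}$) at the chunk end and one time unit before it (to
  avoid declaring convergence on a slow transversal).
* **Extinction pruning.** Species below the extinction threshold
  ($10^{-8}$) are removed and the reduced system is re-integrated until no
  further extinctions occur. A guild losing all species is a collapse.
* **Divergence.** Non-convergence within the horizon raises a classed
  condition (`ecoevonet_divergence`) carrying the last state; callers such
  as the evolution loop catch it and reject the offending event, so failures
  are logged, never silent.

## Structural stability

The central quantities (`stability_summary()` gathers them all):

* **Effective competition** `effective_competition()`: eliminating one guild
  from the linearization of the steady state folds mutualism into the other
  guild's competition,
  $C^{(P)} = \beta^P - \hat\Gamma^P (\beta^A)^{-1} \hat\Gamma^A$, where
  $\hat\Gamma_{ik} = \gamma_{ik}/(1 + h_i G_i)^2$ and
  $G_i = \sum_l \gamma_{il} N_l$ are the saturation-corrected slopes. With
  $\gamma = 0$ this is exactly $\beta$; with $h = 0$ it is the bilinear
  Schur complement.
* **Effective competition strength** `rho_eff()`:
  $\rho_\mathrm{eff} = (\lambda_1(C) - 1)/(S - 1)$ with $\lambda_1$ the
  (asserted real) Perron root. By default this is computed on the raw
  folded matrix $C$. An alternative rescales $C$ to unit diagonal first
  (`normalize = TRUE`); we deliberately do *not* default to it, because the
  fold lowers self-competition along with interspecific competition, and
  re-inflating the off-diagonal by normalization can push
  $\rho_\mathrm{eff}$ *above* the bare $\rho$, breaking the defining
  property that mutualism reduces effective competition. The raw form
  satisfies $\rho_\mathrm{eff} < \rho$ across the studied parameter range
  (this is part of the test suite) and equals $\rho$ exactly in the
  mean-field no-mutualism limit.
* **Critical competition** `rho_c()`: from the within-guild mutualistic
  overlap $\mu = a a^\top$ (plants) or $a^\top a$ (animals),
  $\rho_c = \sum_{ij} \mu_{ij} / (S \sum_i \mu_{ii})$. Closed forms:
  complete networks give $\rho_c = 1$; perfect matchings give $1/S$ (hence a
  power-law exponent of exactly $-1$ in
  `fit_powerlaw_rho_c_vs_richness()` on a matching family).
* **Regime distance** `regime_distance()`:
  $D = (\rho_c - \rho_\mathrm{eff})/\rho_c$, positive when the system sits
  below its critical competition. Values outside $[-1, 1]$ are clamped with
  a warning and flagged.
* **Critical perturbation.** Analytically (`predict_delta_c()`),
  $\Delta_c = \frac{1}{\eta'}\left(\frac{S_\mathrm{eff}}{S + S_\mathrm{eff}}
  - \eta_0\right)$ with
  $S_\mathrm{eff} = (1-\rho_\mathrm{eff})/\rho_\mathrm{eff}$; the system
  value is the minimum over guilds. The coefficients $(\eta', \eta_0)$
  default to $(1, 0)$ and can be calibrated against numerical estimates with
  `calibrate_delta_c()`, which regresses numerical $\Delta_c$ on
  $S_\mathrm{eff}/(S+S_\mathrm{eff})$ over any ensemble you supply.
  Numerically (`estimate_delta_c_numeric()`), growth rates are perturbed as
  $\alpha_i(\Delta) = \alpha_i(0)(1 + \Delta r_i)$, $r_i \sim U(-1,1)$, over
  a log-spaced $\Delta$ grid (default 40 points in $[0.005, 1]$, 50 draws
  per point); $\Delta_c$ is the first amplitude at which the mean extinction
  fraction reaches a threshold (default 0.5; a threshold of 0 means any
  extinction), refined by one log-scale bisection between bracketing grid
  points.

## Eco-evolutionary dynamics

`run_trajectory()` couples slow link evolution to fast ecological
relaxation (`evolution_step()` is one event):

1. A focal species is drawn uniformly over both guilds; the event kind is a
   link **swap**, **creation**, or **deletion** with probabilities
   $(p,\ (1-p)q,\ (1-p)(1-q))$, defaults $p = q = 0.5$. Kinds infeasible
   for the focal species are resampled. Swaps re-target the partner end,
   keeping the focal species attached. New and re-targeted links get fresh
   directional strengths.
2. Growth rates are perturbed with amplitude $\Delta$ from the *immutable
   assembly-time baseline* — perturbations never compound across steps.
3. The system is integrated to its new steady state with extinction pruning.
4. Under selection, the event is accepted only if the focal species'
   equilibrium biomass strictly increased (an extinct focal species is a
   rejection); without selection all events are accepted. Rejection restores
   the pre-event community and state exactly.

A run halts at *evolutionary persistence* (no extinction over the last
`halt_window` substitutions, default 350), at `max_substitutions`
(default 2000), on collapse, or when no feasible event exists. Only accepted
events (substitutions) are counted. All randomness in a trajectory derives
from a single seed via an internal seed-derivation hash, so trajectories and
grids are bit-reproducible and independent runs can execute concurrently
with results identical to serial execution.

## Experiment scales

The full factorial design (`experiment_grid()` defaults: 7 competition
values × 4 perturbation amplitudes × 2 selection regimes × 50 replicates =
2800 trajectories) is cluster-scale. For desk-scale validation the package's
own test suite fixes a reduced study — a 20+20 network at connectance 0.15,
10 replicates, a 500-substitution cap and the 350-substitution persistence
window — chosen to finish in minutes on one CPU while preserving the
qualitative orderings (diversity decreasing in $\rho$, selection retaining
diversity under perturbation, selection driving $\rho_c$ up and
$\rho_\mathrm{eff}$ down). These scales are configuration, not semantics:
`run_grid()` takes them as overrides.

## Topology metrics

`topology_summary()` reports richness, connectance, nestedness, a
null-normalized nestedness (`nodf_c`, the observed value divided by the mean
over an ensemble of random networks with the same dimensions and link
count), mean Jaccard ecological overlap, degree heterogeneity, degree
assortativity across links, and the number of connected components (via
igraph). The nestedness measure is the shared-partner count among all
within-guild pairs normalized by the number of pairs, *not* the canonical
decreasing-fill NODF of Almeida-Neto et al.; on a complete $2 \times 2$
network it evaluates to 2. Use it for relative comparisons within this
package, not for cross-study comparison with published NODF values.

## Limitations

* Mutualistic networks are binary-structured; interaction strengths are
  uniform noise around a single $\gamma_0$, not empirical weights.
* The mean-field competition structure has no resource mechanism; $\rho$ is
  a phenomenological control parameter.
* The analytic $\Delta_c$ is a one-parameter-family prediction; its
  coefficients are meaningful only after calibration against the numerical
  estimator for the system family of interest.
* Extinction thresholds, integration tolerances and the persistence window
  are simulation conventions; results should be checked for robustness to
  them in any serious application.
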