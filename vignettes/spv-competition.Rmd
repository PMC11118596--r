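---
title: "Mechanically regulated growth and cell competition in a self-propelled Voronoi tissue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanically regulated growth and cell competition in a self-propelled Voronoi tissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spvtissue)
```

## The model

`spvtissue` simulates a confluent epithelial monolayer as a self-propelled
Voronoi (SPV) model. The degrees of freedom are the cell centers
$\mathbf r_i$ on a square periodic box; the cell shapes are the Voronoi cells
of the centers, so the tissue has no gaps by construction. Two cell types
("resident" and "mutant") coexist, and each type carries its own parameters.

The mechanics derive from the standard quadratic area/perimeter energy. In
dimensionless form,

$$ e \;=\; \sum_{\alpha \in \mathrm{res}} \tfrac12 (a_\alpha - a_{r0})^2
      + \tfrac{\bar\Gamma_r}{2} (p_\alpha - p_{r0})^2
   \;+\; \sum_{\alpha \in \mathrm{mut}} \tfrac{\bar K}{2} (a_\alpha - a_{m0})^2
      + \tfrac{\bar\Gamma_m}{2} (p_\alpha - p_{m0})^2 , $$

where $a_\alpha$ and $p_\alpha$ are the Voronoi cell's area and perimeter.
The preferred perimeter $p_0$ is the shape index controlling the
jamming/unjamming transition: around $p_0 \approx 3.3$ the tissue is
solid-like (caged cells, unrelaxed pre-stress), around $p_0 \approx 4$ it is
liquid-like.

**Units.** Lengths are normalized so that the box side is
$\hat L = \sqrt{N_0}$, with $N_0$ the initial cell count. The mean cell area
is then exactly $N_0 / N(t)$ — at $t=0$ it is 1 — which is what ties growth
to geometry below. Energies are normalized by the resident area elasticity
(so $\bar K_r = 1$), and one time unit is 100 integrator steps at the default
$\Delta t = 0.01$. A note on conventions: with lengths normalized by
$L/\sqrt{N_0}$ the dimensionless perimeter is $p = P \sqrt{N_0} / L$; this is
the convention under which the usual shape-index values ($p_0 \approx
3.3\text{--}4$) are meaningful, and the package uses it throughout.

Cell centers obey overdamped active dynamics,

$$ \partial_t \mathbf r_i = \mu \mathbf F_i + v_0 \mathbf n_i , \qquad
   \mathbf F_i = -\partial e / \partial \mathbf r_i , \qquad
   \mathbf n_i = (\cos\theta_i, \sin\theta_i), $$

with the polarization angle diffusing freely,
$\langle \eta_i(t)\eta_j(t')\rangle = 2 D_r \delta_{ij}\delta(t-t')$.
Integration is forward Euler for positions and Euler–Maruyama for angles;
angles are kept unwrapped since only their cosine and sine are consumed.

## Mechanically regulated birth and death

Each cell carries birth and death rates with a clipped linear response to its
mechanical state,

$$ r^b_i = r^{b0} + \lambda\,\max(0, x_i), \qquad
   r^d_i = r^{d0} - \lambda\,\min(0, x_i), $$

where the stimulus $x_i$ is either the area deviation
$x_i = (a_i - a_0) + \beta (p_i - p_0)$ (couplings `"area"` with $\beta = 0$,
`"general_beta"` otherwise) or the pressure deviation
$x_i = \mathcal P_i - \mathcal P^h$ (coupling `"pressure"`), with the
hydrostatic pressure

$$ \mathcal P = -\bar K (a - a_0) - \frac{\bar\Gamma p}{2a} (p - p_0). $$

The clipping keeps both rates non-negative while the net rate is exactly
$g_i = (r^{b0} - r^{d0}) + \lambda x_i$. Because the Voronoi areas partition
the box, the population mean under area coupling obeys the *identity*
$\langle g \rangle = \lambda (N_0/N - a_0)$: growth is self-limiting with
carrying capacity $N_{SS} = N_0 / a_0$, which is what the test-suite checks
at $a_0 = 0.8$, $N_0 = 100$ (steady state 125). Without mechanical coupling
($\lambda = 0$, $r^{b0} = r^{d0} > 0$) the same machinery is a critical
birth-death process: no restoring force, and the cell-number variance grows
linearly in time.

The pressure coupling uses the full nonlinear pressure expression above, not
its linearization in the deviations: the linearized form is equivalent only
to first order, and the full form is exact and no more expensive. Its
homeostatic value $\mathcal P^h$ is calibrated as the population-mean
pressure of the relaxed initial tissue, the unique value at which the initial
mean growth rate vanishes. In the solid-like phase this calibrated value is
negative — a residual pre-stress that gradient descent cannot relax — while
the liquid-like phase relaxes it toward zero.

**Basal rates.** The basal pair $(r^{b0}, r^{d0})$ is exposed explicitly.
A *symmetric* basal rate ($r^{b0} = r^{d0} = r_0$, the `r0` convenience
argument) adds demographic noise but cancels exactly in $g_i$, so it cannot
confer fitness. A basal-rate *mutation* that is selectively meaningful must
be asymmetric; the competition suite therefore models it as an increase of
the mutant's basal birth rate alone, under which the selection coefficient
equals the basal difference exactly.

**Division and extrusion.** A division replaces the parent center by two
children at $\pm d$ along a uniformly random direction, with
$d = 0.05\sqrt{a_\mathrm{parent}}$ by default: small enough that the
children's Voronoi cells approximately bisect the parent, and exposed in the
configuration. Children inherit the parent's type and draw fresh independent
polarization angles (inheriting the parent's angle would inject artificial
persistence correlations). Extrusion deletes the center; the neighbors absorb
exactly the removed area on retessellation. No other information is
exchanged with the neighbors — all mechanical feedback flows through the
tessellation.

**Event sampling.** Rates depend on continuously changing areas, so an exact
event-driven scheme is ill-posed. The package freezes each cell's rates over
one mechanical step $\Delta t$ and samples at most one event per cell per
step with probabilities $r^b \Delta t$ and $r^d \Delta t$ (thinning at the
step scale). This converges to the intended coupled process as
$\Delta t \to 0$; a warning fires when any cell's total rate times
$\Delta t$ exceeds 0.1, where the approximation degrades.

## Competition machinery

An invasion experiment (`invasion_design()` / `run_invasion()`) equilibrates
a resident tissue, labels a droplet of mutants of fraction $f_0$ (the
`ceiling(f0 * N0)` cells nearest a random point), and runs the coupled
dynamics. Under frequency-independent selection the mutant fraction follows
the logistic equation, so $\ln(f/(1-f))$ is linear in time with slope equal
to the selection coefficient $s = g_m - g_r$. The fit averages the logit
across replicates in log space, uses only frames with
$\min(f, 1-f) > 0.02$ (to avoid the logit divergence near fixation and
extinction), and reports a quadratic coefficient alongside as a
frequency-independence diagnostic.

Two fast predictors complement the full experiment:

* **Non-growing mixture** (`mixture_predictor()`): simulate a 50–50 mixture
  with labels frozen and no birth/death, time-average the realized areas per
  type after a burn-in, and set
  $s = \lambda[(\bar a_m - a_{m0}) - (\bar a_r - a_{r0})]$. The sign agrees
  with the invasion outcome; the magnitude differs somewhat because a growing
  tissue also fluctuates in cell number.
* **Mean-field closed forms** (`meanfield_fitness_area()`,
  `meanfield_fitness_perimeter()`): treat the mixture as one average mutant
  and one average resident cell sharing the fixed volume, with the perimeter
  slaved to the area through a slope $c$ ($p \approx p_0 + c\,\delta a$).
  Minimizing the quadratic energy over the single remaining degree of freedom
  gives
  $$ s_{MFA} = -\lambda\,\Delta a_0\,\frac{\Gamma c^2}{1 + \Gamma c^2},
     \qquad
     s_{MFP} = \lambda\,\Delta p_0\,\frac{\Gamma c}{1 + \Gamma c^2}. $$
  A smaller preferred area and a larger preferred perimeter are advantageous;
  $\Gamma$ controls the *rate* of selection but cannot create a difference on
  its own. The test-suite verifies both formulas against a direct numerical
  minimization of the two-cell energy. In the solid phase the default $c$ is
  the regular-hexagon value: from $a = p^2/c_6$ with
  $c_6 = 4 \cdot 6 \tan(\pi/6) \approx 13.86$, the slope at unit area is
  $\sqrt{c_6}/2 \approx 1.861$. In the liquid phase there is no a-priori
  relation and the mixture-fitted slope (`estimate_c()`) should be used; it
  comes out smaller than the solid-phase value, which is why selection on the
  geometric parameters is weaker there.

On the direction of the preferred-perimeter effect: the closed form above and
the sign-concordance tests use the convention that $p_{m0} > p_{r0}$ confers
the advantage, which is the direction consistent with the energy argument.

## The fixture generator

`make_fixture()` is the package's synthetic-data module; experiments consume
no external data. It generates square and near-regular hexagonal lattices
(reference states: all-equal cells, zero force by symmetry, zero energy at
matched parameters), uniformly random tissues (equilibrated by
`relax_tissue()` before use), and labelled droplet/half mixtures. One
geometric subtlety: exactly regular hexagons cannot tile a *square* periodic
box, because the required row/column ratio $2/\sqrt3$ is irrational. The
generator picks the even-row factorization of `n_cells` closest to that
ratio; since the regular hexagon minimizes perimeter at fixed area among
hexagons, the perimeter error is second order in the residual strain (about
$10^{-5}$ relative for 56 cells as 8 rows by 7 columns), and the test-suite
checks the regular-hexagon perimeter $\sqrt{8\sqrt3} \approx 3.722$ at
$10^{-3}$ tolerance.

What the generator emulates: homogeneous disordered monolayers at unit mean
density, with droplet or well-mixed mutant placement. What it does not
emulate: real tissues' polydispersity in cell size and stiffness,
boundaries and external constraints, nutrient or signaling gradients, and
spatially organized fronts. Passing tests therefore validate the model's
internal mechanics and its competition logic, not quantitative agreement with
any particular experimental tissue.

## Numerical choices

* **Tessellation.** The periodic Voronoi diagram is computed per cell by
  half-plane clipping against distance-sorted periodic-image candidates
  (grid-accelerated, with an exact early-exit bound: a candidate farther than
  twice the current polygon radius cannot clip). This is robust to the
  cocircular degeneracies of perfect lattices — the clipping tie-break is
  arbitrary there, but areas and perimeters are continuous across the tie —
  and costs well under a millisecond per step for a few hundred cells.
* **Forces.** Analytic, via the chain rule through the Voronoi vertices:
  each vertex is the circumcenter of its three generators, and implicit
  differentiation of the equidistance conditions gives rank-one vertex
  Jacobians. A finite-difference gradient (`tissue_forces_fd()`) is kept as
  the independent oracle; the suite requires agreement to $10^{-5}$ relative
  on random heterogeneous states. Near-collinear generator triples (vertex
  Jacobian ill-conditioned beyond a $10^{-12}$ determinant cutoff) are
  skipped; they carry vanishing weight in generic configurations.
* **Time step.** $\Delta t = 0.01$ by default, with "1 time unit = 100
  steps" as the reporting convention; `step_tissue()` warns when
  $\Delta t\,\mu |F|$ exceeds 5% of the mean cell spacing. Relaxation
  (`relax_tissue()`) is plain gradient descent ($v_0 = D_r = 0$).
* **Degenerate inputs.** Coincident centers (closer than $10^{-9}$) raise an
  error naming the offending pair; extrusion refuses to drop the tissue below
  3 cells; division re-samples its angle (bounded retries) if a child would
  collide with an existing center; $\beta$ must be finite and non-negative
  because the large-$\beta$ limit rewards perimeter without an area penalty
  and elongates cells without bound.
* **Reproducibility.** All randomness (initialization, angular noise, event
  sampling, division geometry) flows through R's RNG; `derive_seed()` splits
  one root seed into named streams so replicates and subsystems can be
  replayed independently. Identical seeds give bitwise-identical
  trajectories.

## Scales used by the test-suite

The validation experiments run at desk scale, chosen so the whole suite
completes in minutes while keeping the relevant contrasts several standard
errors wide: carrying capacity at $N_0 = 100$, $a_0 = 0.8$ with 5 replicates
of $2\times10^4$ steps; the reference invasion (preferred-area mutant
$a_{m0} = 0.9$, solid phase $p_0 = 3.3$) at $N_0 = 400$, $f_0 = 0.1$, 10
replicates of 25 time units; the single-parameter sign scan at $N_0 = 120$,
$f_0 = 0.25$, 5 replicates of 20 time units each for nine parameter variants
(the $\pm 10\%$ mutants in $\{\Gamma, K, \lambda, v_0, D_r\}$ must stay
within the neutral control's spread; $a_0$, $p_0$ and the basal birth rate
must not). The basal-rate variant uses an additive $r^{b0}_m = 0.05$ since
the resident reference value is 0 and a relative change would be empty. The
mixture predictor runs 100 cells for 30 time units in the $p_0 = 3.63$ solid
phase. Larger boxes and longer horizons sharpen every estimate but change no
conclusion.

## Limitations

* Square periodic boxes in 2D only; no open boundaries, no 3D, no
  Laguerre/weighted tessellations.
* Only the isotropic pressure is computed, not full stress tensors or shear
  response.
* Selection estimates assume the well-mixed, frequency-independent regime;
  at much larger scales growth-induced pressure gradients and traveling
  fronts would require spatially resolved analysis outside this package's
  scope.
* The event sampling is first order in $\Delta t$; with very large rates or
  couplings, reduce $\Delta t$ (the rate warning indicates when).
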