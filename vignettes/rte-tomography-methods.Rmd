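---
title: "Optical tomography with the radiative transfer equation: models, discretization and reconstruction"
author: "rtetomo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optical tomography with the radiative transfer equation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Near-infrared light traversing biological tissue is absorbed and
scattered; the rates are the absorption coefficient $\mu_a(x)$ and the
scattering coefficient $\mu_s(x)$, both in mm$^{-1}$.  Continuous-wave
optical tomography illuminates the tissue boundary with a sequence of
sources and records the emerging light at boundary detectors; the
imaging task is to recover the interior coefficient maps from those
readings.  `rtetomo` models light transport with the radiative transfer
equation (RTE)

$$\omega\cdot\nabla u(x,\omega) + (\mu_a + \mu_s)\, u(x,\omega)
  = \mu_s \int_\Omega k(\omega\cdot\hat\omega)\, u(x,\hat\omega)\,
  d\sigma(\hat\omega), \qquad (x,\omega)\in X\times\Omega,$$

on a two-dimensional disk $X$ with the unit circle $\Omega$ of
directions, and reconstructs the per-element absorption map $\mu_a$
from detector-by-source measurement matrices, assuming $\mu_s$ known.
The RTE is preferred here over the diffusion approximation because the
domain is small (10 mm), sources are collimated, and one phantom has
low scattering, all regimes where diffusion theory degrades.

The scattering kernel is the two-dimensional Henyey–Greenstein density

$$k(c) = \frac{1 - g^2}{2\pi\,(1 + g^2 - 2 g c)},$$

with anisotropy factor $g \in (-1, 1)$; tissue is strongly
forward-peaked, and the bundled experiments use $g = 0.9$ unless
stated.

## Discretization

**Space.**  The disk is triangulated by a deterministic ring
("zipper") generator: concentric rings of nodes, adjacent rings joined
by an angle-merge rule, with ring node counts tuned so the element
count lands within 10% of a requested target, and seed-dependent ring
rotations so different seeds give genuinely different triangulations.
The transport equation is discretized per direction with a
discontinuous Galerkin (DG) method: linear polynomials on each
triangle, upwind numerical flux on interior edges, and weak enforcement
of the inflow boundary condition through the boundary flux term.
Coefficients are piecewise constant per element, which makes the
phantom fields exactly representable.

**Angle.**  Directions are collocated at $n$ equispaced angles with
midpoint-rule weights $2\pi/n$.  On equispaced nodes a mass-lumped
angular finite element discretization coincides with this midpoint
collocation, so the simpler quadrature view is used; it preserves the
circulant structure of the discrete scattering operator.  Each row of
the discrete kernel matrix is renormalized to sum to one: the
continuous kernel is normalized, and without the repair the quadrature
error would break photon conservation, which the test suite checks to
0.5%.

**Sources and detectors.**  A source is a collimated impulse: a hat
profile on one boundary edge (value 1 at the edge midpoint, 0 at its
endpoints) carried by the single discrete direction closest to
"straight inward".  Spreading the impulse over all inflow directions
would change the data magnitudes; the collimated reading matches the
subscripted single-direction notation of the incident condition.  A
detector records the edge-averaged outgoing partial current
$\frac{1}{|e|}\int_e \sum_{\omega\cdot\nu>0} (\omega\cdot\nu)\,
u\, w_\omega\, ds$; the averaging makes readings comparable across mesh
resolutions.  Twelve sources and twelve detectors sit at equispaced
boundary angles, detectors offset by half a spacing so no detector
shares an edge with a source.

## Solving the transport fixed point

One "sweep" solves, for every direction in upwind element order, the
local $3\times 3$ advection–attenuation systems with the scattering
source lagged — algebraically a block Gauss–Seidel iteration in the
direction blocks.  Plain source iteration converges at a rate close to
the scattering albedo $\mu_s/(\mu_a+\mu_s)$, which is $\approx 0.999$
for tissue-like coefficients, so two accelerations are layered on top:

* **GMRES** (default driver): the fixed point is the linear system
  $(I - TS)u = b$; restarted GMRES(40) uses one sweep plus one
  scattering application per Krylov vector.
* **Diffusion synthetic acceleration (DSA)** as a right
  preconditioner: a cell-centred finite-volume diffusion solve with the
  transport-corrected coefficient $D = 1/(3(\mu_a + (1-g)\mu_s))$ and a
  Marshak-style vacuum boundary term approximates the inverse of the
  transport operator on the smooth, near-unit-albedo error modes that
  otherwise stall the iteration.  As a preconditioner it affects only
  the iteration count, never the solution; the direct-assembly oracle
  test pins the solution itself to $10^{-8}$.

A directly assembled sparse form of the fully coupled system
(`assemble_rte_system()` / `solve_rte_direct()`) provides the reference
solution on small problems and a factor-once multi-right-hand-side
driver (`rte_factor()`).

Warm starts matter in the reconstruction loop: the per-source and
per-detector fields change little between outer iterates, and reusing
them as GMRES initial guesses roughly halves the sweep count.

## Sensitivities by the adjoint method

The derivative of reading $M_{j,i}$ with respect to the absorption on
element $k$ is

$$\frac{\partial M_{j,i}}{\partial \mu_{a,k}}
  = -\int_{K_k}\int_\Omega u_i(x,\omega)\,\varphi_j(x,\omega)\,
  d\sigma(\omega)\, dx,$$

where $\varphi_j$ solves the adjoint RTE with a weight supported on
detector $j$.  By the reciprocity of the Boltzmann kernel the adjoint
is computed with the *forward* solver: solve with inflow trace equal to
the constant $1/|e_j|$ on the detector edge and reverse all directions
afterwards.  Two conventions deserve a note because the literature
varies:

* the minus sign above is fixed so the entry is the derivative of the
  reading (absorption can only decrease transmitted light; the test
  suite checks nonpositivity), and
* the adjoint boundary weight is the *constant* $1/|e_j|$ — the
  $(\omega\cdot\nu)$ factor belongs to the measurement functional, not
  to the adjoint trace.  Both choices are validated against a central
  finite-difference Jacobian, which agrees to $10^{-10}$ relative on
  the oracle problems (the discrete adjoint is exact, not merely
  consistent).

One adjoint solve per detector serves every source, so a full Jacobian
costs $s$ forward plus $d$ adjoint solves instead of
$s\times d\times N$ forward solves.

## Reconstruction: split Bregman TV-L1 Levenberg–Marquardt

The inversion minimizes

$$\tfrac12\sum_{i=1}^s \|F_i(\mu_a) - M_i\|^2
 + \alpha\, \mathrm{TV}(\mu_a) + \beta\, \|D\|_1
 \quad\text{s.t. } D = \mu_a,$$

with the constraint relaxed by the split parameter $\eta$ and treated
by Bregman iterations.  For piecewise-constant fields the total
variation is the perimeter-weighted sum of inter-element jumps
$\sum_e |e|\,|\mu_{e^+}-\mu_{e^-}|$, smoothed by $\epsilon$ to
$\sqrt{\text{jump}^2+\epsilon^2}$; its lagged-diffusivity
linearization is an edge-weighted graph Laplacian $L(\mu^n)$ frozen at
the current iterate (one linearization per outer iteration, no inner
Newton loop).  Each outer iteration performs:

1. forward maps and residuals at $\mu_a^n$ (warm-started solves);
2. the adjoint Jacobian;
3. the Levenberg–Marquardt step: solve
   $(\sum_i J_i^TJ_i + \alpha L(\mu^n) + \eta I)\,\delta =
   -\sum_i J_i^T r_i - \alpha L(\mu^n)\mu^n + \eta(D^n - \mu^n - b^n)$
   — the normal equations are derived directly from the quadratic model
   and verified against a numerical quadratic-programming oracle,
   because sign conventions for the $\eta$-term differ across
   write-ups.  A trust-region damping $\lambda I$ (default
   $\lambda = 0.1$ times the peak Gauss–Newton curvature, the
   Levenberg–Marquardt convention) is added to the system without a
   gradient contribution: it shortens each step around the current
   iterate but does not move the outer iteration's stationary point,
   and it is what keeps the weakly-penalized variants (pure L1 most of
   all) from taking wild first steps;
4. projection onto the box $[\mu_{\min},\mu_{\max}]$ (default
   $[10^{-4}, 1]$ mm$^{-1}$), keeping iterates inside the admissible
   set of uniformly positive bounded coefficients;
5. the shrinkage step $D^{n+1} = \mathrm{shrink}(\mu_a^{n+1} + b^n,
   \beta/\eta)$;
6. the Bregman update $b^{n+1} = b^n + \mu_a^{n+1} - D^{n+1}$.

Initialization is the background value ($D^0 = \mu_a^0$, $b^0 = 0$);
iteration stops on relative iterate change below `stop_tol`
(default $10^{-4}$), on a divergence guard (data fidelity increasing
five outer iterations in a row by more than 1%), or at `max_outer`.

### Measurement scaling

Regularization weights are only meaningful relative to the data term.
With raw readings of order $10^{-4}$ the Gauss–Newton curvature is of
order $10^{-10}$ and weights like $\alpha = 10^{-4}$ would drown the
data entirely — no reconstruction could move.  `rtetomo` therefore
normalizes the data term by the peak diagonal of its Gauss–Newton
Hessian at the initial iterate (Marquardt's characteristic curvature),
frozen thereafter so the objective is fixed across iterations: the
tabulated weights ($\alpha, \beta, \eta$ of order
$10^{-4}, 10^{-3}, 10^{-5}$) then act as dimensionless fractions of
the data curvature and transfer across acquisition scales.  The
default fits raw (absolute) readings, matching the plain L2 data
fidelity of the underlying formulation; with this convention the
reconstruction shows the reference dynamics of the method — the
misfit decreases gradually while the lagged-diffusivity weights
anneal, convergence takes tens of outer iterations rather than
collapsing in a few — and no semiconvergent error growth is observed
on the bundled experiments.  `reg_params(scaling = "relative")`
additionally divides each residual entry by its measured magnitude
(equalizing near and far source–detector pairs, natural under the
multiplicative noise model); `scaling = "none"` disables normalization
altogether.

Two related observations, documented rather than hidden: with the
tabulated values the shrinkage threshold $\beta/\eta$ far exceeds any
plausible coefficient value, so the splitting variable stays at zero
and the L1 term acts as a gentle pull toward zero mediated by the
growing Bregman variable — this is what distinguishes the mixed
penalty from pure TV in these runs.  And at a flat (background) start
all jumps vanish, so the lagged-diffusivity weights begin at the large
value $|e|/\epsilon$ and relax as jumps develop: early iterations are
heavily smoothed and the effective TV strength anneals downward, which
is why the pure-TV variant characteristically needs more outer
iterations than the mixed one.

## The synthetic experiments

Phantoms are a homogeneous background with circular inclusions
(membership decided by element centroid).  The bundled presets cover:
one small inclusion (radius 0.5 mm at (7,0), $\mu_a$ doubled to 0.02,
$\mu_s$ doubled to 20 — both maps change, and the true scattering map
is used as the known $\mu_s$ in the inversion); middle (r = 2 at
(5,0)) and big (r = 4 at (3,0)) single inclusions; two and three small
inclusions; one big plus two small; and a high-absorption phantom
(background 0.05/5) with one purely absorbing and one purely
scattering inclusion.  Multiplicative Gaussian noise
$M \leftarrow M(1 + \delta z)$ is applied entrywise with a recorded
seed.

Data are always synthesized on a finer mesh than the inversion mesh
(different seeds, different generators' ring layouts), so the inverse
problem never sees its own discretization — the standard guard
against the inverse crime.  Quality is reported as the unweighted
relative Euclidean errors

$$E_{\mathrm{resi}} = \frac{\|F(\mu_a^n) - F(\mu_a^{\mathrm{true}})\|_2}
    {\|F(\mu_a^{\mathrm{true}})\|_2},\qquad
  E_{\mu_a} = \frac{\|\mu_a^n - \mu_a^{\mathrm{true}}\|_2}
    {\|\mu_a^{\mathrm{true}}\|_2}.$$

### Problem sizes

The full-resolution presets use the tabulated mesh sizes (for example
3616 data / 2488 inversion elements for the two-small-inclusion case)
and 32 directions.  The test suite and the acceptance script run the
same experiments desk-scaled: `preset_experiment(scale = 0.2 .. 0.7)`
shrinks both meshes proportionally and drops to 16 directions, with
8–12 outer iterations and an inner solver tolerance of $10^{-6}$.
These sizes were chosen once as the package's standard small-problem
setting: they keep every reconstruction in the minutes range on a
single core while leaving the physics (albedo, anisotropy, geometry,
noise) untouched.  Mesh-dependent quantities such as $E_{\mu_a}$ shift
at the percent level across resolutions, which is why comparisons to
full-resolution figures should be read with scaled-down tolerances.

## What the synthetic tests do and do not show

The generator emulates the study conditions: exact forward physics on
a finer grid, piecewise-constant targets, collimated sources,
noiseless or multiplicatively noisy readings.  It does not emulate
real acquisition effects — source/detector coupling calibration,
model mismatch in $\mu_s$ (assumed known here), refractive-index
boundary reflections, detector noise floors, or 3D light spread.
Passing tests therefore demonstrate the correctness and stability of
the discretization, sensitivities and optimizer under the stated
model, not clinical performance.

## Numerical choices and degenerate inputs

* Transport tie-breaking: edges with $|\omega\cdot n| \le 10^{-12}$
  are treated as non-coupling in both the upwind ordering and the
  sweep; any ordering cycle that degeneracy could leave is broken by
  sorting leftover elements along the direction.
* `eta = 0` with `beta > 0` is rejected (undefined shrinkage
  threshold); `beta = 0, eta = 0` degenerates cleanly to the pure
  LM-TV iteration.
* The LM system is solved by Cholesky with a symmetric-solve fallback;
  an all-zero regularization with rank-deficient $J^TJ$ is an error
  advising $\eta > 0$.
* Noise-free far-pair readings are tiny but positive; the relative
  scaling floors the per-entry scale at $10^{-8}$ of the largest
  reading.
* `n_dir` must be even for the adjoint direction reversal to be exact
  on the grid.

## Known limitations

Two-dimensional only; absorption reconstruction only (the scattering
map is a known input); no frequency-domain or time-resolved sources;
vacuum (non-reflecting) boundaries; the ring mesh generator cannot
reproduce arbitrary third-party triangulations exactly (it targets
element counts within 10%, and `read_mesh()` imports external
Triangle-format meshes when exact geometry matters).  A scaling
variant that rescales rows by measurement magnitude is the package's
single normalization convention; alternative conventions (log-ratio
data, Rytov transforms) are not implemented.
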