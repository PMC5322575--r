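# rtetomo

Forward and inverse modelling of continuous-wave optical tomography in
two dimensions, built on the radiative transfer equation (RTE) rather
than the diffusion approximation.

Near-infrared light probing biological tissue is absorbed at rate
μ<sub>a</sub>(x) and scattered at rate μ<sub>s</sub>(x) (both
mm<sup>-1</sup>); abnormal tissue shows as contrast in these maps.  The
package is for researchers studying RTE-based image reconstruction: it
provides the full computational chain from phantom definition to
reconstructed absorption maps, with every stage exposed as an ordinary
R function.

## The model and the algorithm

Photon transport is modelled by the RTE on a disk,

> ω·∇u + (μ<sub>a</sub> + μ<sub>s</sub>) u = μ<sub>s</sub> ∫<sub>Ω</sub> k(ω·ω′) u(·, ω′) dω′,

with the 2D Henyey–Greenstein kernel
k(c) = (1 − g²) / (2π (1 + g² − 2gc)).  The discretization is upwind
discontinuous Galerkin (linear elements) in space and an equispaced
direction set in angle; the transport fixed point is solved by source
iteration accelerated with matrix-free GMRES and a diffusion synthetic
acceleration preconditioner.  Boundary measurements are
detector-by-source matrices M<sub>j,i</sub> of outgoing partial
current.

The inverse problem — recover the per-element μ<sub>a</sub> from M
with μ<sub>s</sub> known — is solved by minimizing

> ½ Σ<sub>i</sub> ‖F<sub>i</sub>(μ<sub>a</sub>) − M<sub>i</sub>‖² + α TV(μ<sub>a</sub>) + β ‖D‖₁,  D = μ<sub>a</sub>,

via a split Bregman scheme: a Levenberg–Marquardt linear step with the
lagged-diffusivity TV operator, a shrinkage update for the splitting
variable D, and a Bregman multiplier update.  Sensitivities come from
the adjoint method (one adjoint transport solve per detector, shared
across sources), verified against finite differences to 10<sup>-10</sup>.
Reconstruction quality is reported as the relative errors
E<sub>resi</sub> and E<sub>μa</sub> (Euclidean norms of the
measurement and coefficient mismatch, relative to the truth).

## Worked example

Reconstruct a high-absorption inclusion from synthetic boundary data,
with data generated on a finer mesh than the inversion uses (the
package's guard against the inverse crime):

```r
library(rtetomo)

# disk of radius 10 mm, background mua = 0.05 / mus = 5 mm^-1,
# absorbing inclusion (mua = 0.1) of radius 2 mm at (3.5, 3.5)
cfg <- preset_experiment("sim3_abs_scat", scale = 0.5, seed = 1,
                         params = reg_params(5e-4, 5e-4, 1e-6,
                                             max_outer = 8,
                                             solver_tol = 1e-6))
res <- run_experiment(cfg)
```

Printed summary of this run:

```
inverse mesh: 438 elements | outer iterations: 8
E_mua = 15.2%  (background start: 18.1%)
strongest recovered absorption at:
       x_mm   y_mm    mua
[1,] 4.8674 4.5278 0.0625
```

Reading it: starting from the homogeneous background guess (relative
error 18.1%), eight outer iterations of the TV-L1 reconstruction
reduce the error to about 15% and place the strongest recovered
absorption around (4-5, 4-5) mm with value ≈ 0.06 mm<sup>-1</sup> —
the true inclusion sits at (3.5, 3.5) with 0.1 mm<sup>-1</sup>, so
the location is recovered and the amplitude partially so, the
expected behaviour for a smoothing-regularized method after few
iterations at this resolution.

Other entry points: `mesh_disk()`, `build_angular_grid()`,
`preset_phantom()` + `rasterize()`, `forward_map()` + `add_noise()`
for data synthesis; `solve_rte()` / `solve_rte_direct()` for single
transport solves; `full_jacobian()` for sensitivities;
`reconstruct()` for inversion from any `measurement_set`;
`run_regularization_variant()` to compare the mixed TV-L1 penalty with
pure TV and pure L1 on identical data.  A thin command-line front end
with `mesh` / `simulate` / `reconstruct` / `experiment` / `compare`
subcommands is installed at `inst/cli/rtetomo`.

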