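---
title: "Active-learning structure search for rigid adsorbates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Active-learning structure search for rigid adsorbates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surfsearch)
```

## The problem and the model

Identifying the stable adsorption geometries of a bulky molecule on a metal
surface means finding *all* the minima of a potential energy surface (PES)
whose evaluations — normally density-functional calculations — are far too
expensive for exhaustive scanning. `surfsearch` treats the molecule and the
surface slab as rigid *building blocks*, so the PES lives on the six
rigid-body pose coordinates: fractional surface translations $x, y$ in the
orthogonal surface cell, the adsorption height $z$ of the rotation centre
above the top atomic plane, and intrinsic rotations $\alpha, \beta, \gamma$
applied in the order $R_z(\gamma)\,R_y(\beta)\,R_x(\alpha)$ about the
midpoint of a flagged atom pair. Energies are in eV, lengths in Å and angles
in degrees throughout.

The PES is modelled by Gaussian-process (GP) regression. The covariance is a
product over dimensions of one-dimensional kernels scaled by a signal
variance $\sigma_f^2$:

* squared exponential $\exp(-d^2/2\ell^2)$ on non-periodic dimensions
  ($z$);
* exponentiated sine-squared
  $\exp\!\big(-2\sin^2(\pi d/P)\,/\,(2\pi\ell/P)^2\big)$ on periodic
  dimensions ($x, y$ with period 1; angles with period 360°, or 120° where
  a top-site threefold symmetry curtails the range).

The periodic kernel is parameterized so its lengthscale $\ell$ carries the
coordinate's own units and the small-distance limit coincides with the
squared exponential; that lets a single rule — bounds from 2 % to twice each
dimension's span — govern the marginal-likelihood optimization of every
lengthscale. Exact kernel periodicity guarantees the posterior itself is
exactly periodic, which the test suite asserts to $10^{-9}$.

The prior mean is constant at the *maximum* observed energy. Unexplored
regions therefore look pessimistic, and the lower-confidence-bound
acquisition explores them only through their posterior variance — a common
choice in structure search that avoids spurious "free energy" below the data.
Observation noise is fixed at a floor of $10^{-6}\,\mathrm{eV}^2$ because
backend energies are deterministic; an explicitly smaller value is honoured
for noiseless interpolation studies. Hyperparameters maximize the log
marginal likelihood with five seeded random restarts of L-BFGS in log space;
Cholesky factorizations use jitter escalating from $10^{-8}$ by factors of
ten up to $10^{-4}$ before failing.

## The active-learning loop

Each iteration fits the GP to all stored energies and minimizes the
exploratory lower confidence bound
$\mathrm{eLCB}(p, t) = \mu(p) - \eta(t)\,\sigma(p)$
over the bounded, periodicity-aware space by multistart L-BFGS from a seeded
Latin-hypercube design (plus the incumbent best observation, which makes the
chosen point provably no worse than the incumbent under the acquisition).
The schedule
$\eta(t) = \sqrt{2\log\!\big(t^{d/2+2}\pi^2/(3\delta)\big)}$ with
$\delta = 0.1$ grows slowly with iteration $t$ and dimension $d$ so
exploration never dies out; a constant override is available. No Sobol
generator being bundled, all quasi-random designs are seeded Latin
hypercubes, which serve the same space-filling role and keep runs
bit-reproducible.

Warm starts from lower-dimensional scans are first-class: records missing
dimensions are embedded using declared fill values, wrapped, deduplicated
(tolerance $10^{-6}$ in wrapped coordinates) and merged. Symmetry
augmentation — the half-cell translation
$(x, y) \mapsto (x + \tfrac12, y + \tfrac12)$ and the $\pm 120°$ top-site
rotations with the compensating $\gamma$ shift — multiplies stored records
without spending backend evaluations; images landing outside non-periodic
bounds are dropped with a warning. The published workflow this mirrors
reports 492 low-dimensional points becoming 986 initial points, a
multiplicity that is not an exact factor of two; because the per-point rule
is not stated there, the package instead exposes the op list per record and
leaves the multiplicity to the caller.

Convergence is judged on *all* minima, not only the global one: after each
evaluation a reduced multistart (16 starts) mines the surrogate, and the
search stops when the minima count is stable and every minimum's location
and energy drift over a 10-iteration window stay below tolerance (defaults:
0.02 fractional units in $x, y$; 0.1 Å in $z$; 5° in angles; 0.02 eV in
energy — declared choices, since the reference workflow defers its own 6D
thresholds to supplementary material).

## Mining, verification and barriers

`find_minima()` runs 512 seeded L-BFGS descents (suitable for $d \le 6$) on
the posterior mean — or directly on an analytic surface — with periodic
dimensions widened by a quarter period so basins straddling the wrap are not
split. Endpoints are deduplicated with a wrapped metric (merge when every
normalized component differs by under 0.02, keeping the lowest-energy
representative) and must pass a stationarity certificate: a
positive-definite numeric Hessian (minimum eigenvalue above $10^{-7}$) and a
small gradient. The certificate rejects two failure modes seen on nearly
flat landscapes: descents stalling in regions with vanishing gradient, and
saddle points. Boundary-stuck endpoints on non-periodic dimensions are
likewise dropped. A consequence worth knowing: the GP mean far from data can
carry shallow genuine minima of its own (depths of order $10^{-3}$ eV with
large $\sigma^B$); they are reported honestly, and the attached
$\sigma^B$ — the posterior standard deviation at the minimum — is the tool
for discounting them.

`verify_minimum()` evaluates the backend at each mined location
($E^D$, with $\Delta E^D = E^D - E^B$ measuring surrogate accuracy) and
descends on the backend energy in pose space, the desk-scale counterpart of
a full structural relaxation, giving $E_{rel}$ and
$\Delta E_{rel} = E_{rel} - E^D$.

Translation barriers use a nudged elastic band on a chosen coordinate plane
(typically $x$–$y$): 21 images, shortest-image linear initialization, spring
constant 1 eV per squared unit, perpendicular force projection and FIRE
relaxation. The highest image climbs (inverted parallel force, no springs),
so the band converges onto the saddle instead of straddling it; this is what
lets the $(q^2-1)^2$ double-well barrier come out at $1$ to within
$10^{-3}$ without an image landing on $q = 0$ by luck. Because the band
moves in the rigid-pose space only, barriers are upper bounds to the true
values.

Rotation barriers come from in-place one-dimensional searches: all
coordinates clamped at a minimum, a 15-evaluation active-learning run over
the angle, and the barrier read as the peak-to-valley range of the fitted
1D surrogate mean. This follows the reference workflow's own fallback, which
found raw high-dimensional $\gamma$ profiles overly smooth and instead
rotated the relaxed structures in place.

`classify_minima()` assembles the molecule-on-slab configuration at each
pose and labels the minimum by the element of the molecule atom nearest the
surface (ties broken by atom index), numbering within each class by energy,
most strongly bound first.

## The bundled analytic surfaces

The package ships closed-form stand-ins for the expensive energy backend so
every workflow claim is testable end to end:

* **6D adsorption surface** (`toy_adsorption_pes()`): a Morse well in $z$
  whose depth and equilibrium height interpolate smoothly (via a smoothstep
  in $\cos\beta$) between a deep "O-down" family (−0.96 eV at 4.5 Å) and a
  shallow "H-down" family (−0.65 eV at 5.2 Å); a hexagonal-lattice
  corrugation built from the first star of reciprocal vectors of the
  triangular surface lattice, which is *exactly* invariant under the
  half-cell translation and the top-site threefold rotation; a threefold
  $\gamma$ modulation strongest at the top site; and a single-well $\alpha$
  modulation. Its 24 minima (4 hollows × 2 families × 3 azimuths) are
  analytic and shipped as a manifest. The surface reproduces the
  *phenomenology* of a bulky ketone on a close-packed metal — two bonding
  classes, a steep wall below ~4 Å, weak translational corrugation relative
  to rotations — and deliberately claims nothing about any real material's
  energetics.
* **1D Morse height curve** (−0.847 eV at 4.14 Å) for the height-search
  demonstration.
* **2D two-well landscape** with the exact half-cell degeneracy, for the
  symmetry-augmented search test.
* **2D six-well landscape** with graded depths for certifying the miner
  against a dense-grid oracle.

What passing these tests does *not* show: robustness to DFT noise and
self-consistency failures, conformational flexibility of the molecule,
many-minima landscapes in the full 6D space at realistic corrugation, or
the cost profile of real electronic-structure backends.

## Numerical choices and conventions

* Fractional coordinates are stored on $[-0.5, 0.5)$ and angles on
  $[-180°, 180°)$; wrapping always maps to these canonical intervals.
* $z$ is measured from the mean plane of the topmost layer to the rotation
  centre; the rotation axes are the lab axes aligned with the surface cell.
* RMSD between pre- and post-relaxation structures is computed in the
  common frame *without* superposition, since both share the slab frame;
  whether the reference analysis superposed first is unstated, so this is a
  declared choice.
* Methyl normalization sets every listed C–H bond to the group-average
  length and equalizes H–C–H angles by giving all hydrogens the mean polar
  angle about the local threefold axis and exactly uniform azimuthal
  spacing anchored at the first hydrogen (anchoring at a circular mean is
  degenerate for a symmetric group, so the first-listed hydrogen fixes the
  phase and makes the operation idempotent).
* The hindered-rotor occupancy uses a cosine well
  $V(\varphi) = \tfrac{B}{2}(1 - \cos 2\pi\varphi/P)$ at 298.15 K with
  $k_B = 8.617333\times 10^{-5}$ eV/K — a declared model shape; reference
  statements of this kind used a fitted conformer PES instead, so the
  comparison is directional, not exact. Under this model the 10° and 15°
  windows at a 0.1 eV, 120°-period barrier hold 48.8 % and 66.6 % of the
  population (the package's own quadrature, to $10^{-8}$ relative
  tolerance).
* Rounding for reported tables is half-up (energies 3 decimals, charges 2),
  applied only at serialization.

## Problem sizes

The bundled demonstrations and the test suite run at desk scale by design:
1D searches use 10 total evaluations, the 2D two-well search 30 with
symmetry augmentation, minima mining 512 multistarts, cross-sections
100 × 100 grids, and elastic bands 21 images. These sizes converge the toy
problems comfortably; real applications with expensive backends would raise
the evaluation budget and let the all-minima convergence window terminate
the loop.

## A short example

```{r example, eval = FALSE}
backend <- morse_backend()                     # 1D height curve
settings <- search_settings(backend$space, budget = 8, init_n = 2, seed = 1,
                            track_minima = FALSE)
run <- run_search(backend, settings)
glance(run)
run$minima

cs <- cross_section(toy_adsorption_backend(),
                    fixed = c(z = 4.5, alpha = 0, beta = 0, gamma = 0),
                    free_dims = c("x", "y"))
autoplot(cs)
```

## Known limitations

Exact GP regression is $O(n^3)$; beyond a few thousand stored points the
refits dominate. Acquisition batches, gradient observations and
multi-fidelity sampling are out of scope. The slab builder covers fcc(111)
in the orthogonal two-atom cell only. The elastic band runs on the
surrogate's pose space, so its barriers inherit both the upper-bound bias of
the rigid-body approximation and the surrogate's interpolation error
(quantified pointwise by $\sigma^B$).
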