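# surfsearch

Active-learning structure search for rigid molecular adsorbates on
close-packed metal surfaces.

Finding the stable geometries of a bulky molecule on a surface means
locating **all** the minima of a potential energy surface (PES) whose
evaluations — typically density-functional calculations — cost hours each.
`surfsearch` implements the Bayesian-optimization approach to this problem:
the molecule and the slab are rigid building blocks, the PES is defined over
the six rigid-body pose coordinates
(fractional surface translations *x*, *y*; adsorption height *z*; intrinsic
rotations α, β, γ about the molecule's rotation centre), and a
Gaussian-process surrogate

* with a product kernel — squared exponential in *z*, exponentiated
  sine-squared (exactly periodic) in *x*, *y* and the angles —
* and a pessimistic constant prior mean (the maximum observed energy)

is refined iteratively by minimizing the exploratory lower confidence bound

    eLCB(p, t) = mu(p) − eta(t) · sigma(p),
    eta(t) = sqrt(2 log(t^(d/2+2) π² / (3 δ)))

until every minimum of the surrogate is stable in location, energy and
count. The fitted surrogate is then data-mined: multistart L-BFGS finds the
minima (each certified by a positive-definite Hessian and reported with its
posterior standard deviation σᴮ), a climbing-image nudged elastic band
extracts translation barriers, and 15-evaluation in-place 1D searches give
rotation barriers. Slab building for fcc(111) in the orthogonal two-atom
cell, half-cell/threefold symmetry augmentation of datasets, extended-XYZ
IO, and the bookkeeping arithmetic for adsorption energetics
(E_ads = E_tot − (E_surface + E_molecule), ΔEᴰ columns, per-element Mulliken
charge sums, HOMO–LUMO gaps, hindered-rotor Boltzmann occupancies) are
included. Analytic adsorption-like toy surfaces stand in for the expensive
backend so the whole workflow runs and is certified at desk scale.

Intended users: surface scientists and method developers who want a
reproducible, fully testable implementation of the GP-surrogate structure
search workflow in R — either to drive their own energy backend (any
deterministic function of a pose) or to study the machinery itself.

## Worked example

A one-dimensional height search on the bundled Morse curve (a physisorption
height profile with its minimum at 4.14 Å, −0.847 eV), with a budget of ten
backend evaluations:

```r
library(surfsearch)

backend  <- morse_backend()
settings <- search_settings(backend$space, budget = 8, init_n = 2,
                            seed = 1, track_minima = FALSE)
run <- run_search(backend, settings)
run$minima
#> # A tibble: 2 × 4
#>       z     E_B  sigma_B grad_norm
#>   <dbl>   <dbl>    <dbl>     <dbl>
#> 1  4.16 -0.847  0.000747 0.0000151
#> 2  6.90 -0.0203 0.00485  0.0000161
```

Ten evaluations place the adsorption minimum at *z* = 4.16 Å (true value
4.14 Å) with the correct depth −0.847 eV and a model uncertainty σᴮ below
1 meV; the second, very shallow entry is a genuine minimum of the surrogate
mean in the dispersive tail, and its larger σᴮ is how the model flags it as
poorly constrained.

The reporting arithmetic on the bundled reference energetics of eight
camphor adsorbates on Cu(111):

```r
s <- summarize_minima(reference_adsorbates())
s$aggregates
#> # A tibble: 1 × 5
#>   mean_sigma_B mean_delta_E_rel E_B_min E_B_max     n
#>          <dbl>            <dbl>   <dbl>   <dbl> <int>
#> 1       0.0245           -0.111  -0.961  -0.634     8
```

Half-up rounding at the reporting precision gives a mean σᴮ of 0.025 eV over
the eight minima and a mean relaxation change of −0.11 eV.

A command-line entry point wrapping the same functions (subcommands
`search`, `minima`, `cross-section`, `report`) is installed at
`inst/cli/surfsearch.R`.

## Package layout

| Area | Files |
|---|---|
| Slab / molecule geometry, symmetry ops | `R/lattice.R`, `R/molecule.R`, `R/symmetry.R`, `R/io-xyz.R` |
| GP surrogate | `R/gp.R` |
| Active-learning loop | `R/bo.R` |
| Minima mining, barriers, classification | `R/mining.R` |
| Energy backends (analytic stand-ins) | `R/energy.R`, `R/fixtures.R` |
| Reporting arithmetic and IO | `R/reporting.R`, `R/config.R`, `R/plots.R` |

The methods vignette (`vignettes/structure-search.Rmd`) documents the model,
its tunable parameters, the numerical choices and the limitations.
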