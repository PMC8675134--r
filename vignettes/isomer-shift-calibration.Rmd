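---
title: "Predicting 57Fe Mossbauer isomer shifts from sphere-integrated densities"
author: "mosscalib"
output: rmarkdown::html_document
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mosscalib)
```

## The problem and the model

The isomer shift delta of a 57Fe Mossbauer signal reflects the electron
density the absorber nucleus samples, so it is conventionally predicted from
an electronic-structure calculation through an empirical straight line

    delta = a * rho_Fe(0) + b        [mm/s],

where `rho_Fe(0)` is the computed density at the iron nucleus and `a`, `b`
are determined by least squares against measured shifts. The weakness of
this recipe with ordinary Gaussian (GTO) basis sets is well known: Gaussians
cannot form a cusp at the nucleus, so `rho(0)` is both basis-set-sensitive
and numerically touchy (it even shifts with the number of digits carried in
the Cartesian coordinates). Historically, accurate calibrations required
Slater-type bases or purpose-built, core-polarized Gaussian sets.

`mosscalib` implements the alternative this package is organized around:
replace the point value `rho(0)` with the electron count inside a small
sphere centered on the Fe nucleus,

    <rho>_R = integral over |r - c| <= R of rho(r) dV   [electrons],

with R = 0.06 bohr by default. The sphere is far larger than the nucleus
(~1e-5 bohr) but still inside the K shell, so the descriptor averages away
the cusp-region pathologies of a general-purpose basis while remaining a
strictly local probe of the core density. The package's calibration module
fits exactly the line above with `<rho>_R` in place of `rho(0)`.

Why 0.06 bohr? The Laplacian of the density marks atomic shell boundaries,
and for iron species the charge-depletion maximum that closes the K shell
sits near r = 0.05 bohr. A sphere of that scale captures the K-shell
response to the chemical environment; pushing R much further (say 0.3 bohr)
turns the descriptor into a crude atomic population, which correlates poorly
with isomer shifts. The `sweep_radius()` operation reproduces this
trade-off on any cohort; `laplacian_ray_profile()` exposes the shell
structure directly.

## The quadrature engine

The descriptor is evaluated with a product rule:

* **Radial**: Gauss-Legendre nodes mapped linearly to [0, R], with the
  `r^2` volume element folded into the weights (30 nodes by default). The
  literature behind this approach does not pin down the radial scheme, so
  the package pins correctness to an analytic oracle instead (below);
  at the tabulated precision the choice is immaterial, and 30 mapped
  Gauss-Legendre points integrate the relevant densities to ~1e-15.
* **Angular**: the 110-point Lebedev rule (octahedral symmetry, algebraic
  order 17), the standard angular grid of this size. Rather than
  transcribing node tables, `lebedev_rule()` *solves* the defining moment
  equations for each supported size (6, 14, 26, 38, 50, 110): the orbit
  structure under the octahedral group is fixed, and the free geometric
  parameters and weights are found by Gauss-Newton, with literature values
  used only as starting guesses. The solved rule is cached and verified by
  polynomial-exactness tests to ~1e-14.

Two invariants pin the engine: combined weights sum to the ball volume
`4/3 pi R^3` to relative 1e-12, and every synthetic Gaussian density is
integrated to within 1e-8 of its erf closed form (see below) at the default
30 x 110 grid. Doubling the radial rule moves the descriptor of an
iron-like test density by less than 1e-9 electrons.

## The density engine

Densities come from two sources:

* **Analytic** (canonical): a Molden-dialect wavefunction (geometry,
  contracted GTO shells up to f, MO coefficients and occupations, one or two
  spin channels). Every basis function is expanded into monomial Gaussians
  `x^a y^b z^c exp(-alpha r^2)`, so values, gradients and Laplacians are
  exact term-wise derivatives, and each contracted function is renormalized
  from its analytic self-overlap at load. `rho(0)` is evaluated at the
  nuclear coordinate as given — the density maximum is *not* searched for —
  and coordinates are carried at full double precision, which avoids the
  digit-truncation sensitivity that plagues point-value descriptors.
* **Volumetric** (approximate): a Gaussian cube file, interpolated
  trilinearly or tricubically. Cube grids cannot resolve the K-shell peak,
  so grid-derived descriptors are flagged `approximate` and are not used in
  any published-value reproduction; they exist for sanity checks and
  visualization-grade work.

## The synthetic-data generator

`synthetic_wavefunction()` builds densities of the form
`sum_i w_i (alpha_i/pi)^{3/2} exp(-alpha_i r^2)` for which the electrons in
a sphere have the closed form

    N(R) = sum_i w_i [ erf(sqrt(alpha_i) R)
                       - 2 sqrt(alpha_i/pi) R exp(-alpha_i R^2) ].

These are the package's oracles: the quadrature engine must reproduce
`N(R)` without ever being told it. `synthetic_iron_wavefunction()` adds a
four-shell, 26-electron model whose K-shell exponent (1.5 Z^2 with Z = 26)
places the K-shell density peak near r = 1/Z bohr; its Laplacian
charge-depletion maximum then falls at 0.0497 bohr, matching where real
iron compounds show it. What these synthetic densities deliberately lack:
multi-center character, angular structure, spin polarization, and any
chemistry in the K-shell tail — so passing tests demonstrate the
*quadrature and calibration machinery*, not the quality of any quantum
chemistry. The packaged dataset, conversely, carries real computed
descriptors but no wavefunctions (re-running the underlying DFT is out of
scope).

## The calibration dataset

`load_calibration_dataset()` returns the packaged table of iron complexes:
111 rows, one per Fe site and spin assignment, with experimental 4.2 K
shifts spanning [-0.90, +1.48] mm/s, formal oxidation states +2 to +6,
spins S = 0 to 5, contact densities, sphere descriptors at R = 0.06 bohr,
the published predicted shifts, and crystal-structure codes. Four complexes
(labelled 1a/27a/28a/29a) are alternate-spin recomputations of the same
experimental signals and carry `is_alternate_spin = TRUE`;
`default_signals()` removes them, leaving the 103 distinct signals over 69
complexes. Values are stored exactly as tabulated (2 decimals for shifts,
3 for `rho(0)`, 6 for the descriptor) and the file is checksum-pinned.

One calibration convention deserves a note. `paper_calibration()` fits the
line on the **full 111-row table**, alternate-spin rows included. That
convention — not the 103-row subset — reproduces the published statistics
(r^2 = 0.976, q^2 = 0.975, MAE = 0.055 mm/s) and every tabulated predicted
shift within one unit of the printed last digit; the 103-row fit differs
only in the fourth decimal of r^2 (0.9752 vs 0.9763) but that difference is
visible at the precision the statistics are quoted with. Both conventions
are exposed (`fit_calibration()` on any subset), and the per-signal
quantities are always reported for the 103 distinct signals.

## Validation statistics

* `fit_calibration()` is ordinary least squares; `r_squared` is the
  coefficient of determination, which for a simple line equals the squared
  Pearson correlation (the package tests this identity to 1e-12), and
  `rmsd` uses the divisor n.
* `loocv_calibration()` reports `q^2 = 1 - PRESS/TSS` with TSS over the
  full sample, and the MAE of the held-out predictions (not the training
  residuals). The default path uses the exact hat-matrix identity
  `e_(i) = e_i / (1 - h_i)`; the explicit n-refit loop is implemented as
  well and the two agree to 1e-12 by test.
* `sweep_radius()` fits the line at every radius of a descriptor profile
  (slot R = 0 holding the contact density) and reports the best radius
  with ties broken toward smaller R. No rise-then-fall shape is assumed.

## Quadrupole splittings

For the I = 3/2 excited state,

    Delta E_Q = 1/2 e Q Vzz sqrt(1 + eta^2/3),
    eta = |Vxx - Vyy| / |Vzz|,  with |Vzz| >= |Vxx| >= |Vyy|,

with Q = 0.16 barn by default and the result expressed as a Doppler
velocity through the 14.4125 keV gamma energy. The a.u.-to-mm/s constant
(1.61704 mm/s per a.u. of Vzz at Q = 0.16 barn) is chained from CODATA-2018
constants at call time, never hard-coded, and is cross-checked in the tests
against an independently organized unit chain. The ordering convention
permits a negative `(Vxx - Vyy)/Vzz`; the absolute value keeps eta in
[0, 1], and since the splitting depends on eta only quadratically the
choice is observationally irrelevant (tested on randomized tensors). EFG
tensors are *consumed*, not computed: predicting them from wavefunctions is
out of scope.

## Numerical choices and degenerate inputs

* Quadrature node solving: Gauss-Newton with numerical Jacobian,
  least-squares step via QR, convergence demanded to residual 1e-12 or the
  constructor refuses to return a rule.
* `eta` at `Vzz = 0` is defined as 0 with a warning; asymmetric EFG inputs
  are symmetrized with a warning above 1e-8; non-traceless principal values
  warn but proceed.
* Eigenvalue ties in the EFG sort are broken by descending signed value.
* Cube values are trusted as densities; negatives from file round-off are
  clamped to zero with a warning. MO cubes (negative atom count) and
  Angstrom-axis cubes (negative voxel counts) are rejected outright rather
  than guessed at.
* Degenerate calibrations (constant descriptor, n < 3) and descending
  radius ladders are errors, not NaNs.
* Occupations are validated to [0, 2] per orbital; the synthetic generator
  therefore splits a component carrying w electrons across ceiling(w/2)
  duplicate orbitals.

## Problem sizes used in the checks

The reproduction checks run the 111-row fit and its 111-fold LOOCV
(closed form plus explicit loop), quadrature tests on 30 x 110 and 60 x 110
grids, sweep recovery on 12-compound synthetic cohorts over 7 radii, and
randomized property checks with 10-20 draws per invariant — all chosen as
the smallest sizes that exercise every code path at the tolerances stated
above.

## Known limitations

* The packaged dataset ships descriptors, not wavefunctions; the package
  cannot re-derive the tabulated `<rho>_0.06` values from first principles
  (that requires the original DFT runs, explicitly out of scope).
* The Molden dialect is the package's interchange choice; wfn/wfx/fchk are
  not read, and ECP (effective-core-potential) wavefunctions are
  meaningless here since the descriptor probes the K shell — all-electron
  bases only.
* Cartesian d/f shells are normalized per component; rotational invariance
  of a density is guaranteed for pure-spherical shells (and any s/p basis),
  which is what the supported emitters write for the bases of interest.
* Only orthogonal-axis cubes are interpolated.
* The radius sweep reports calibration quality at tabulated radii; it does
  not interpolate between them.
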