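---
title: "The mechano-polarity model behind epifold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The mechano-polarity model behind epifold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

epifold simulates how a local change of apical-basal polarity can fold an
epithelial monolayer on its own, without external forces. This vignette is
the package's account of the model: the equations it integrates, the
parameters that matter, the numerical choices, and -- importantly -- the
places where the design was genuinely open and what we decided there.

## The biochemical module

Each cell carries a one-dimensional reaction-diffusion system for three
polarity regulators on its membrane: aPKC (`A`, apical), Par-1 (`P`,
basal-lateral) and Bazooka (`B`, which marks the adherens-junction level at
the interface between the two). The spatial coordinate `s` runs along the
membrane *half-perimeter* of a cell cross-section, from the apical centre
(`s = 0`) across the apical face (length `a`), down a lateral side (length
`ell`) and along the basal face to the basal centre (`s = L`, with
`L = a + b + ell`). Membrane species diffuse (all `D = 1e-4` in model units
of 10 um and 1 s) and exchange with a single well-mixed cytosolic pool.
The kinetics implement mutual antagonism between `A` and `P`, inhibition of
`B` by both, and recruitment of `A` by `B`; the cytosol closes a mass
budget through the surface-to-volume ratio `psi`:
`rho_cyto = rho_total - psi * mean(rho)`. Geometry therefore enters the
biochemistry in exactly two ways: through `psi` (how much membrane a unit
of cytosol must feed) and through `L` (how far the pattern has to stretch).

Two consequences define the package's phenomenology:

* **scaling** -- stretching `L` at fixed `psi` leaves the *fractional* peak
  position `s*/L` unchanged;
* **remodeling** -- raising `psi` at fixed `L` shifts the Bazooka peak
  basally.

### Boundary conditions: why "reflect" is the default

The membrane of a cross-section is a closed loop of length `2L`. A loop
that is mirror-symmetric about the apical-basal axis is equivalent to a
zero-flux (reflective) problem on the half-perimeter `[0, L]` -- this is
what `boundary = "reflect"` integrates, and it is the package default. The
alternative reading, wrapping `[0, L]` itself into a periodic ring
(`boundary = "wrap"`, provided as an option), behaves qualitatively
differently: the polarized state then consists of *two* mirror fronts whose
maxima agree to rounding error, so the measured peak jumps between them,
and each front absorbs only half of the dose response -- a 10% Par-1
reduction then shifts the peak by ~3.5% of `L` instead of ~7%. The
reflective reading produces the single interior Bazooka peak that the
polarized profile should have, and dose responses about twice as large. We
consider it the correct interpretation of "periodic boundary conditions on
the membrane" for a mirror-symmetric closed loop.

### Initial condition

Polarization is seeded by a Heaviside step of `B` confined to the apical
half `[0, a/2)` carrying half of the Bazooka pool, with `A` and `P` uniform
(each holding half its pool on the membrane). The step width is a design
choice: the system is bistable at the published parameters, and a step
spread over the whole apical face decays to the unpolarized uniform state
instead of nucleating the polarized branch. Any sufficiently sharp step
converges to the *same* polarized attractor, so nothing downstream depends
on the precise width; what matters is that nucleation succeeds. The
baseline steady state puts the Bazooka peak at `s*/L = 0.315`, i.e. about a
fifth of the way down the lateral membrane.

### Numerics

Forward-time centred-space (FTCS) stepping on a uniform cell-centred grid
(default 512 nodes for fixed-geometry runs), with the stability bound
`max(D) dt / ds^2 <= 0.5` enforced. Steady states are declared when the
maximum nodewise rate of change falls below `1e-7` concentration units per
time unit; the dose-response results are unchanged under `dt` halving and a
ten-fold longer integration. Negative concentrations (possible at FTCS
overshoots) are clamped at zero and counted; the cytosolic pool is likewise
clamped, which only ever triggers during rapid cell shrinkage when `psi`
rises while the membrane amount is conserved.

## The mechanical module

Tissue shape is a 3D vertex model: cells are hexagonal prisms sharing
vertices and lateral faces, and vertices move by overdamped descent
(`eta = 1`) on

```
U = sum_i K_a (P_a - P_o)^2 + sum_i lambda_b A_b + sum_k lambda_l,k A_l,k
    + sum_i K_V (V - V_o)^2
```

with apical-perimeter elasticity, basal and lateral surface tension, and
volume elasticity. The lateral sum runs over *registered faces*: a face
shared by two cells carries the sum of the two owners' tensions, which is
how the published inner tension (0.0414) equals twice the outer one
(0.0207), and which makes the energy of a uniform flat patch exactly
`n_cells` times the single-cell closed form. Forces are central finite
differences of `U` (step `1e-6`), evaluated from the local energy terms
incident to each vertex.

### The reference cell and Table-derived defaults

The published mechanical values (`K_a = 0.0172`, `P_o = 2.16`,
`lambda_b = 0.0477`, `lambda_l = 0.0207`) are, to print precision, the
closed-form balanced-parameter expressions evaluated at a hexagonal prism
of height `h = 1.8` and radius `r = 0.45`:

```
K_a = h r (2 sqrt(3) - 9 h r^2) / (16 (6 r - P_o))
lambda_b = h/4 (2 - 3 sqrt(3) h r^2)
lambda_l = r/4 (2 sqrt(3) - 9 h r^2)
```

The package ships the *unrounded* values of these expressions as defaults,
so a freshly built tissue is exactly stationary (forces at rounding error).
This reference cell (`L = 2.7`, `psi = 6.243`, aspect ratio `a/h = 0.25`,
i.e. columnar) is also the fixed geometry of all 1D polarity runs.
Balanced cells are volumetrically compressed (`V = 0.947 < V_o = 1`); the
resulting pressure is what positive surface tensions push against.

Stability of a balanced prism is read off the 2x2 Hessian of the
single-cell energy in `(h, r)`; `stability_check()` evaluates the
closed-form components and the trace/determinant criterion, and the test
suite verifies both against numeric second differences and against
perturb-and-relax dynamics of the full vertex model. One caveat the test
suite surfaces: the trace/determinant criterion concerns only the two
symmetric prism modes and is necessary but not sufficient for full
stability -- thin columnar shapes with a small positive determinant can be
dynamically unstable through the apex/base-asymmetry (frustum) mode, which
the reduced Hessian cannot see. This is why the balance derivation needs a
separate frustum-suppression condition in the first place.

## The coupling module

The feedback law modulates each cell's normalized surface mechanics
`q = (K_a, P_o, lambda_b, lambda_l) / initial` down the gradient of
`(ell_domain - ell_domain_o)^2`, where `ell_domain` is the apical domain
size -- the membrane distance from the apical centre to the Bazooka peak --
and `ell_domain_o` its homeostatic set point (by default each cell's
pre-perturbation steady-state value). Conversion rates are
`c = c_o (1 + xi)`, with `xi ~ N(0, sigma)` resampled once per coupling
interval (10 iterations) per cell: the noise modulates a rate, not a Wiener
increment, so no `dt^(-1/2)` scaling applies.

Three design decisions here were genuinely open and shape the behaviour:

1. **Where `ell_domain` is measured from.** Measuring from the apical
   centre (`ell = s*`) versus from the apical/lateral junction
   (`max(0, s* - a)`) changes more than an offset: the `-a` term feeds the
   apex size into the feedback error. With the junction convention the
   published folding coupling set `c_o = (0.2, -0.8, 2, 2)` is net
   destabilizing (the preferred-perimeter channel dominates the error
   budget) and runs collapse. With the apical-centre convention that same
   set produces the expected morphogenesis -- preferred perimeter down
   (narrowing apex), basal tension down (widening base), lateral tension up
   (shortening) -- and a deep inward fold. We therefore measure from the
   apical centre; `bazooka_peak_position()` reports the junction depth
   separately.

2. **How the sensitivity `d ell_domain / d q_k` is evaluated.** The
   obvious probe -- displace `q_k`, take one mechanics step, re-measure --
   reports the *transient* response. For the basal-tension channel the
   transient (base shrinks, `ell` falls) has the opposite sign of the
   relaxed response (the cell grows taller, `ell` rises), and the crossover
   takes hundreds of time units, far beyond any affordable probe horizon.
   The default scheme (`probe = "quasistatic"`) therefore computes the
   fully relaxed derivative in closed form, by implicit differentiation of
   the cell's reduced `(h, r)` force balance through the same 2x2 Hessian
   used for stability analysis. A finite-horizon virtual-relaxation probe
   (`probe = "step"`, horizon `probe_dt` in time units with the probed
   cell's vertices relaxed against a frozen neighbourhood) is kept for
   validation; the test suite checks its sign against a brute-force
   long-relaxation oracle.

3. **How fast the modulation may move.** The quasi-static sensitivities
   make the homeostatic drive much faster than the tissue's slow elastic
   relaxation; integrated naively, `q` ratchets against a shape that has
   not caught up and the perturbed cell collapses. Two guards keep the
   dynamics in the quasi-statically tracked regime: each `q` increment is
   capped at `dq_max = 0.002` per update, and `q` is floored at 0.2 so
   that no mechanical term can be modulated out of existence (a floored
   basal tension, for instance, leaves nothing to hold the basal ring
   open). Both are numerics, not biology; the folding endpoint is
   insensitive to `dq_max` within a factor of four.

Each iteration performs, in order: one mechanics step for all vertices;
per-cell geometry re-measurement; rescaling of each cell's membrane field
by `L_prev / L_new` (conserving the molecule number on the membrane); one
reaction-diffusion step at the current `psi` and `L`; and, every coupling
interval, the homeostatic update. The relaxation time `tau` is the first
return of `ell_domain` into the threshold band (5% of the set point by
default); under strong noise the domain settles on a noise-shifted plateau,
and `tau_relaxation(mode = "settle")` measures the approach to the
trajectory's own final level instead, which is finite for every run.

## What the simulated experiments show

With the default coupling set and a 10% Par-1 reduction in the central
cells of a 19-cell patch, the apical domain first expands by a few percent,
then relaxes back to its set point while the perturbed cells shorten
(`L: 2.70 -> ~2.3`), adopt a short frustum shape (apex narrower than base,
height reduced by ~1/3) and pull the tissue into an inward fold about one
cell-height deep. An 80% Bazooka increase folds the tissue similarly. A
line of perturbed cells produces a furrow instead of a pit, and pinning the
rim cells to their plane does not change the picture qualitatively.

One published observation the model as implemented does *not* reproduce:
the surface-to-volume ratio of the perturbed cells ends slightly (~3%)
*below* its initial value rather than above it. With volume elasticity
holding `V` near `V_o`, a shorter cell of equal volume simply has less
surface; a net `psi` increase would require substantially stronger volume
compression at the folding endpoint than the modulation produces here. The
scenario tests assert the published direction and are expected to flag
this discrepancy.

Two further documented gaps, both in the feedback properties: the
refractory regime of the perturbation-deformation curve (cell deformation
*smaller* with feedback at weak mechanical perturbations) does not emerge
-- in this implementation the homeostat restores the apical domain by
recruiting additional basal-lateral shape change, which adds to the cell
deformation rather than suppressing it -- and the deterministic 10% Par-1
dose response computes to 6.6% of `L` against a reported "approximately
10%" (the 80% Bazooka response computes to 9.8%, in range). Both are
robust to the numerics choices above and are reported as measured.

## Problem sizes and runtimes

Fixed-geometry polarity runs use the published 512-node grid; steady state
takes about 15 s each. Coupled tissue runs in the test suite use scaled-down
study conditions chosen to finish in minutes while preserving the
phenomenology: 19-cell patches with 128-node membranes for the folding
scenario (2500 time units, `dt = 0.1`), 7-cell patches for the
perturbation-deformation scan and the noise sweep (up to 6000 time units,
5 replicates per noise level). The command-line `tissue` runner defaults to
a 37-cell patch and the 512-node grid for production-quality runs.

## Known limitations

* No cell rearrangement (T1/T2), division, or curved initial geometry.
* The 1D membrane model ignores the azimuthal dimension (rotational
  symmetry is assumed) and all stochasticity in the biochemistry.
* The quasi-static sensitivity treats each cell as a regular prism in its
  reduced force balance; strongly frustum-shaped cells are handled only
  approximately, and eversion modes (apex/base asymmetry) are invisible to
  it.
* Synthetic tissues are flat hexagonal patches of congruent cells; real
  blastoderm geometry (curvature, cell-size gradients) is out of scope.
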