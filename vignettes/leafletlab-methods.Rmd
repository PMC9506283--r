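---
title: "Models and methods behind leafletlab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind leafletlab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafletlab)
```

leafletlab analyses condensed Langmuir monolayers of the kind used to
model the inner leaflet of the erythrocyte plasma membrane: mixtures of
saturated phospholipids (PC, PE, PS, sphingomyelin) with cholesterol or
its oxidised variant 7-ketocholesterol, spread at the air/water
interface. Four experimental probes and one simulation-analysis track
share a common tabular data model: pressure–area isotherms,
stress-relaxation dilatational rheology, specular X-ray reflectivity
(XRR), grazing-incidence X-ray diffraction (GIXD), and structural
operators for all-atom monolayer trajectories. Because raw instrument
data for such systems are rarely deposited, every input class has a
seeded synthetic generator with known ground truth; the test suite is
built on those generators and on independent numerical oracles.

## Units

Lengths are in Å, areas in Å²/molecule, surface pressures and moduli in
mN/m, scattering vectors in Å⁻¹, electron densities in e⁻/Å³. The
thermal energy in these units is `kT_monolayer(T)` =
1.380649·(T/K) (mN/m)·Å² — 404.5 at 293 K, so a two-dimensional ideal
gas at 40.45 Å²/molecule exerts 10 mN/m. This conversion is worth
stating explicitly: it follows from 1 J/m² = 10²³ (mN/m)/Å², and a
mis-placed factor of ten here silently corrupts every modulus.

## Isotherm mechanics

The static compression modulus is `ε(π) = −A·dπ/dA`, evaluated along
the compression branch (the longest strictly decreasing-area run of
the record; a record stored in the opposite direction is flipped, so ε
does not depend on the sampling direction). The derivative comes from
local polynomial regression in a sliding window (default 11 points,
degree 2) rather than finite differences, because experimental
isotherms are noisy and unevenly gridded; on dense noiseless curves
the estimator agrees with central differences to better than 0.5%.
Points within half a window of the branch ends are dropped — the
derivative is not estimable there — and a constant-pressure plateau
correctly yields ε = 0.

`liftoff_area()` locates the largest area at which the (optionally
running-mean-smoothed) pressure exceeds a threshold, with linear
interpolation between the bracketing samples. The threshold defaults
to 0.5 mN/m — just above typical Wilhelmy-sensor noise; no sharper
criterion is standard, so it is a user parameter.

`segment_gradients()` fits a continuous piecewise-linear model of
π(A) with 1–3 segments to the post-lift-off branch, using a hinge
basis: given breakpoints the model is linear and solved by QR least
squares; breakpoints are found by a coarse quantile grid search
refined with `optimise()`/`optim()`. Slopes are reported as |dπ/dA|
in mN m⁻¹ Å⁻², and breakpoints as the fitted pressure at the slope
change — the form in which phase-transition signatures in condensed
films are quoted (a change from ≈3 to ≈9 mN m⁻¹ Å⁻² at ≈22 mN/m is
the motivating phenomenology). Fit ranges are exposed as parameters
rather than guessed, since published gradients rarely state them.

## Stress-relaxation rheology

A fast small compression (|ΔA/A₀| ≤ 5%) drives the film out of
equilibrium; the pressure then relaxes at constant area as

$$\Delta\pi(t) = \Delta\pi_\infty + \sum_i A_i e^{-t/\tau_i}.$$

`fit_relaxation()` fits this with bounded Levenberg–Marquardt from
multiple starts (initial τ log-spaced over the record) and selects the
mode count 0…3 by the small-sample-corrected Akaike criterion; a flat
transient degrades gracefully to zero modes with Δπ∞ equal to the
mean. The residual sum of squares is floored at numerical precision so
that noiseless data do not produce −∞ likelihoods and the criterion
still prefers the smaller model.

The complex dilatational modulus is obtained analytically, not by FFT
of the raw signal: for a step strain, d ln A/dt = −u·δ(t), the Fourier
quotient E*(ν) = F[dΔπ/dt]/F[d ln A/dt] evaluates to

$$G'(\omega) = \frac{1}{u}\Big(\Delta\pi_\infty + \sum_i A_i
\frac{\omega^2\tau_i^2}{1+\omega^2\tau_i^2}\Big),\qquad
G''(\omega) = \frac{1}{u}\sum_i A_i
\frac{\omega\tau_i}{1+\omega^2\tau_i^2},$$

with ω = 2πν. FFTs of short noisy transients are ill-conditioned at
the low-frequency end, which is exactly where these spectra are read;
fitting first and transforming the model is the stable route, and the
closed form is verified in the tests against a trapezoid-plus-analytic-
tail numerical transform to ≤1%. The strain magnitude uses u =
|ΔA/A₀| by default; the exact u = |ln(1 − ΔA/A₀)| differs by <2.6% at
the 5% perturbation cap and is available via `strain = "log"`.
Compression is stored as positive Δπ with u as a magnitude.

Derived quantities follow their definitions: tan φ = G″/G′, η_D =
G″/(2πν). `cole_cole()` fits the loss-versus-storage curve with a
circle centred on the G′ axis (algebraic least squares, linear in the
two parameters) and reports the RMS radial deviation normalised by the
radius: a single Maxwell element gives an exact semicircle (deviation
≈ 0 to machine precision), while two modes separated by a factor 100
in τ give deviations well above 0.05, the conventional reading of a
"two-step" relaxation. `plateau_modulus()` averages G′ over a band
(default >100 mHz) and flags the result when the relative spread in
the band exceeds 5% — a plateau that is not a plateau is reported as
such rather than silently averaged.

## X-ray reflectivity

The interface is a stack of slabs (tail slab against air, headgroup
slab against water for a monolayer), each with thickness, electron
density and upper-interface Gaussian roughness. Reflectivity is
computed with the Parratt recursion using Névot–Croce roughness
factors on each interface Fresnel coefficient. The dynamical
treatment matters near the critical edge (q_c = 4√(π r_e ρ_e) =
0.0218 Å⁻¹ for water, the 0.154° critical angle at 8 keV); the Born
approximation is not used. Absorption is neglected — an organic film
at 8 keV. Electron density and refractive index are interchangeable
via δ = r_e λ²ρ_e/2π with r_e = 2.818×10⁻⁵ Å. The recursion is tested
against an independently coded transfer-matrix evaluation to 1×10⁻¹⁰
relative, and a zero-contrast stack returns the bare Fresnel curve to
machine precision.

Two properties of the normalised curve R/R_F deserve care. First, for
a sharp (σ = 0) finite stack R/R_F does not converge to 1 at large
q_z: it keeps fringing inside a band set by the interface contrasts,
straddling 1; with roughness it decays. The tests assert the true
band statement. Second, the position of the first R/R_F minimum for a
two-slab monolayer follows the approximate relation q_z⁽¹⁾ ≈
(3π/2)/(d_T + d_H/2). The corresponding printed expression is
typographically ambiguous; this reading reproduces the reported
minimum position from the reported thicknesses to 0.5%, and the
forward model built from d_T = 17.3 Å, d_H = 9.0 Å places the minimum
at 0.2153 Å⁻¹, 0.1% from the published 0.2151 Å⁻¹. The relation is
used as a diagnostic only, never inside the fit. For a single uniform
slab the minimum position depends on the contrast signs (π/d when the
film is less dense than the subphase), so `first_minimum()` always
reads the forward model rather than a formula.

`fit_reflectivity()` minimises residuals on log R with uniform
weights — reflectivity spans many decades and linear-space weighting
would fit only the critical edge. Parameters are bounded (d ∈ [1,
100] Å, ρ ∈ [0.01, 1] e⁻/Å³, σ ∈ [0, 12] Å); estimates at a bound are
flagged with a warning, and any parameter can be frozen. 1σ
uncertainties come from the Gauss–Newton covariance. Water ρ_e is
fixed at 0.334 e⁻/Å³ unless overridden. `density_profile()` returns
the erf-smeared step profile implied by the model (z increasing from
air into the subphase, air/tail interface at z = 0); smearing
conserves the integrated density, which the tests check to 1×10⁻⁶.

## Grazing-incidence diffraction

`angles_to_q()` evaluates q_xy = (4π/λ)sin(2θ_h/2) and q_z =
(2π/λ)sin(α_f) exactly. `fit_peak()` fits one Bragg peak plus a
linear background; the default line shape is Lorentzian (the 2D
powder convention), with Gaussian and pseudo-Voigt (linear mix, not a
true convolution) selectable because the published analyses rarely
state their shape. The lattice spacing d = 2π/q₀ and the Scherrer
coherence length L_c = 0.9·2π/fwhm are stored with propagated
uncertainties; both identities hold exactly on the stored fields.
Instrument-resolution broadening is not deconvolved, matching how
coherence lengths are normally quoted from raw widths. Because the
line shape underlying published widths is unknown, coherence lengths
are validated by round trip on synthetic peaks (median error ≤3%
across fwhm ∈ [0.005, 0.1] Å⁻¹ at 5% noise) rather than against
printed values.

Peak significance uses a two-part gate: the raw background-subtracted
height must exceed 3× the flank noise, and a lightly smoothed curve
must rise 4× above its own suppressed noise — otherwise the extreme
order statistic of several hundred noise samples would pass the naive
3σ test. "Barely visible" peaks therefore fit (with large
uncertainties) while pure-noise patterns are rejected.
`classify_packing()` maps peak multiplicity and Bragg-rod maxima to
hexagonal-untilted / tilted / disordered.

## Trajectory operators

The trajectory model is a tidy atom table (frame, molecule, species,
leaflet, atom, element, x/y/z) with an orthorhombic box, periodic in
x and y; leaflets are labelled by the generator, or assignable by the
sign of z relative to the water midplane.

**Area per lipid** uses a periodic 2-D Voronoi tessellation of
headgroup reference atoms projected on xy — three reference atoms per
phospholipid (P, glycerol C2, N), one per sterol (O3), which captures
the very different footprint of sterol headgroups; a lipid's area is
the sum of its reference-point cells. Cell areas are computed exactly
by half-plane clipping: each cell starts as the half-box rectangle
around its seed (which always contains the periodic cell) and is cut
by perpendicular bisectors against all nine images of all seeds,
visited in distance order with an early exit once no bisector can
reach the polygon. No tessellation library is involved; conservation
of the leaflet area holds to machine precision and a dense-grid
nearest-seed quadrature oracle agrees to 0.5%. Coincident reference
points are jittered by 10⁻⁶ Å with a warning.

**Order parameters**: S_CD = −½⟨3cos²β − 1⟩ per tail carbon, with β
the C–H bond angle to z, averaged over bonds, lipids and frames; the
standard error uses block averaging (default 10 blocks over frames).
Physical methylene geometry confines the mean to [−0.5, 1]; a value
outside that range (e.g. all C–H bonds along z) is geometrically
inconsistent and triggers a warning rather than silent clipping.
Hydrogens must be explicit; none are reconstructed.

**Thicknesses** are |z| distances: tail = terminal C to carbonyl C,
head = carbonyl C to P, total = their sum; sterols, which have no
phosphorus, are excluded with a message. **Electron density
profiles** histogram per-atom electron counts (element-based, H/C/N/
O/P, overridable) over z bins divided by bin volume; `fold = TRUE`
reflects the two leaflets about the water midplane and averages,
doubling the normalising volume so the electron count stays
conserved. **Orientation** angles (sterol C3→C17 axis, or headgroup
P→N) are folded to [0°, 90°] — orientation, not direction — so an
isotropic distribution has mean 1 rad ≈ 57.3°.

**Contacts, hydrogen bonds, RDF, hydration** all use minimum-image
distances (x, y by default; z as well for fully periodic test boxes)
and are tested for exact agreement with brute-force enumeration on
small frames. The contact heatmap counts atom-pair events within
4.0 Å between a sterol and a partner species and normalises the
matrix to sum to 1; normalisation is per total atom-pair events (the
published wording would also admit per-molecule-pair events; the
alternative was considered and documented here, and the chosen
convention is what the matrix-sum invariant tests). Hydrogen bonds
use the geometric criterion d(D···A) < 3.5 Å and ∠D–H–A > 150°. The
RDF is the standard shell-histogram estimator normalised by ρ_β and
shell volumes; the hydration histogram bins each water's minimum
distance to the headgroup heavy atoms (the "surface" set is
configurable — the choice is not standardised) and divides by bulk
water density times the slab volume per bin, with a `sides` argument
distinguishing a water slab bounded by two leaflets from a single
interface. The per-atom hydration map counts frames in which a heavy
atom has a water oxygen within 4.0 Å, normalised to sum to 1 over the
molecule.

## Synthetic generators

Generators are pure functions of their parameters and seed (the RNG
state is restored afterwards), and their noiseless outputs are exact
fixed points of the corresponding analysis stage — the property the
round-trip tests exercise.

* `gen_isotherm()`: ideal-gas, 2-D van-der-Waals-like, or
  piecewise-linear equations of state. The piecewise-linear model
  (slopes 3 then 9 mN m⁻¹ Å⁻², break at 22 mN/m, lift-off 64 Å² as
  defaults in the pipeline stage) reproduces the gradient-change
  phenomenology of oxysterol-containing films. Noise is additive
  Gaussian, defaulting to instrument-realistic 0.05 mN/m in the
  pipeline; published work does not state sensor noise, so this is a
  placeholder, not a calibration.
* `gen_relaxation()`: the multi-exponential model plus additive
  Gaussian noise. Default regime (Δπ∞ = 1 mN/m, A₁ = 0.5 mN/m, τ₁ =
  100 s, u = 0.05) sits in the range implied by published plateau
  moduli of 190–1070 mN/m and relaxations over minutes.
* `gen_reflectivity()`: the slab forward model with multiplicative
  log-normal noise (counting/detector statistics are relative, not
  additive); default stack d_T = 17.3 Å, d_H = 9.0 Å with tail/head
  densities 0.30/0.45 e⁻/Å³ — standard values for condensed saturated
  films.
* `gen_gixd_peak()`: one peak of chosen shape on a linear background
  with additive counting noise.
* `gen_toy_monolayer()`: two leaflets on hexagonal/square/random
  lattices, tails away from a water slab of randomly placed 3-site
  molecules at the pure-water number density 0.0334 Å⁻³ (so RDF and
  hydration normalisations have an analytic reference). All-trans
  chains are built with C–H bonds exactly perpendicular to the chain
  axis, making S_CD closed forms exact (0.5 for vertical chains);
  random-walk chains provide disordered geometry. 100 lipids per
  leaflet is the default system size. The generator makes geometry,
  not physics: no force field, no thermostat, no conformational
  ensemble — so passing tests demonstrate the correctness of the
  operators, not the realism of any particular membrane. Species
  archetypes are simplified (a generic two-tailed phospholipid with a
  7.6 Å headgroup rise and C16 tails; a sterol rod with an O3
  hydroxyl donor), and real-topology systems require a matching
  `toy_topology()`-style definition.

## Problem sizes and numerical choices

The shipped checks use sizes chosen to make every statistical
tolerance comfortable: 500-point isotherms; 900 s transients at 0.5–
1 s sampling with 20-seed recovery runs; 200–250-point reflectivity
curves with 20-seed recovery at 2% noise; 601-point diffraction
patterns across five widths × four seeds; toy monolayers of 8–50
lipids per leaflet for exact-oracle comparisons and 10⁵ random bonds
for angular averages. Nonlinear fits are bounded, multi-start where
the objective is multi-modal (relaxation times, breakpoints), and
degenerate inputs (flat transients, zero-amplitude peaks, all-zero
isotherms, sterols without phosphorus, molecules never hydrated) have
defined behaviour — a smaller model, an error, or an exclusion with a
message, never a silent answer.

## Known limitations

Oscillatory-barrier rheology and exchange-diffusion (Lucassen–van den
Tempel) models are out of scope, as are multi-contrast XRR
co-refinement, free-form profile inversion, full Bragg-rod analysis
and tilt-angle extraction, and any molecular-dynamics integration.
The published experimental headline values that depend on raw
instrument data (ε at given pressures, G′ plateau values, lift-off
areas, printed coherence lengths) are used here only to set realistic
synthetic regimes; the package reproduces desk-reproducible quantities
(table arithmetic, d-spacings from peak positions, the thickness
identity and first-minimum relation) and validates everything else by
construction and oracle agreement.
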