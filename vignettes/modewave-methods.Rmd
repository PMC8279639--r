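---
title: "Time-resolved vibrational analysis with generalized modes and wavelets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-resolved vibrational analysis with generalized modes and wavelets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modewave)
```

## The problem

Ultrafast photochemistry — here the excited-state proton transfer (ESPT) of
a photoacid such as pyranine hydrogen-bonded to water and an acetate
acceptor — is driven by specific low-frequency skeletal vibrations that are
activated by the electronic excitation and decay within a picosecond. A
stationary vibrational spectrum cannot show *when* a mode is active.
`modewave` implements a time-resolved vibrational analysis of molecular
dynamics trajectories that resolves each collective vibration in both
frequency and time, together with the structural diagnostics (radial
distribution functions, distance/dihedral series, proton-hop detection)
needed to connect those vibrations to the proton-transfer events.

The package consumes position + velocity trajectories in extended-XYZ
format; it does not run electronic-structure dynamics itself.

## Generalized modes from the velocity covariance

At any temperature one can define $3N$ *generalized modes* as the collective
coordinates whose velocities are mutually uncorrelated over the trajectory.
With mass-weighted atomic velocities
$\dot q_i = \sqrt{m_i}\, \dot x_i$ (atom-major ordering, units
$\sqrt{\mathrm{amu}}\,\mathrm{\AA/fs}$), form the time-averaged covariance

$$K_{ij} = \langle \dot q_i \dot q_j \rangle_t ,$$

and diagonalize it: the columns of the orthogonal eigenvector matrix
$\mathbf{L}$ are the modes, and the mode velocities are the projection
$\dot{\mathbf{Q}}(t) = \mathbf{L}^\mathsf{T} \dot{\mathbf{q}}(t)$. Unlike
Hessian normal modes this construction assumes no quadratic potential, so
the modes are intrinsically anharmonic. Six of the $3N$ coordinates (five
for a linear molecule) are translations and rotations; these are projected
out of the velocities frame by frame before $K$ is formed
(`remove_global_motion()`), using the instantaneous center-of-mass velocity
and the angular velocity $\boldsymbol\omega = \mathbf{I}^{-1}\mathbf{J}$
from the inertia tensor and angular momentum. For (near-)collinear frames
the inertia tensor is inverted only on its well-conditioned axes, so linear
molecules retain their undefined axial rotation and report five near-zero
modes.

For excited-state dynamics the ground-state $\mathbf{L}$ is applied to
excited-state velocities. This is the central approximation of the method:
near the Franck–Condon region, before the excited-state relaxation has
rearranged the force field, the ground-state mode composition still holds.

Numerical conventions:

* velocities are mean-centered per coordinate before forming $K$ (the means
  are already $\approx 0$ after global-motion removal; centering makes $K$ a
  true covariance);
* eigenvalues are sorted descending and each eigenvector's sign is fixed so
  its largest-magnitude component is positive, making the basis
  deterministic;
* `n_zero` counts eigenvalues below `rel_tol` ($10^{-8}$) times the largest;
  vectors inside that near-zero block are individually arbitrary (only the
  span is defined) and are flagged `degenerate`;
* trace conservation $\sum_\alpha \lambda_\alpha = \mathrm{tr}\,K$ and
  per-frame Parseval $\lVert\dot Q\rVert = \lVert\dot q\rVert$ hold to
  $10^{-10}$ relative and are asserted in the test suite.

Stationary frequencies come from `power_spectrum()`: the periodogram of the
windowed (Hann by default), 4x zero-padded mode-velocity signal, which is
the Fourier transform of the velocity autocorrelation up to windowing
(Wiener–Khinchin). Both window and padding are configurable; the estimator
choice affects leakage, not peak positions, which is all the analysis uses.

## Morlet wavelet spectrograms

Each mode velocity $\dot Q_\alpha(t)$ is decomposed on Morlet daughters

$$\psi_{a,b}(t) = \frac{1}{\sqrt a}\,
  e^{i\omega_0 (t-b)/a}\, e^{-((t-b)/a)^2/2},$$

giving $W_\alpha(\nu, t)$ whose squared magnitude is the time–frequency
intensity map. Design choices:

* $\omega_0 = 6$ by default: the standard balance between time and frequency
  resolution, large enough that the analytic Morlet (correction term
  dropped) is admissible and that the scale–frequency map
  $\nu\,[\mathrm{cm^{-1}}] = \frac{\omega_0}{2\pi a\,[\mathrm{fs}]}\times
  33356.41$ is accurate;
* logarithmic scale grid, 12 voices per octave by default;
* convolution by FFT with symmetric-reflection padding; kernels truncated at
  five Gaussian widths;
* no renormalization beyond the $a^{-1/2}$ of the daughter, so $|W|^2$ is
  comparable across frequencies (intensities are in arbitrary units; only
  peak locations and decays are meaningful);
* the cone of influence (coi) is the per-time frequency below which the
  edge lies within the envelope's e-folding time $\sqrt 2\,a$; `ridge()`
  masks it.

`band_power()` integrates $|W|^2$ over a frequency band (trapezoid rule)
and `decay_time()` reports when the smoothed band power (moving average,
5 samples by default) first falls and stays below $1/e$ of its early
maximum. Two subtleties matter. First, the search for that maximum starts
after the band's coi-clear time $\sqrt2\,a(\nu_{lo})$ — before it the power
is edge-attenuated and using it biases the crossing late by tens of
percent. Second, an amplitude envelope $e^{-t/\tau}$ decays in *power* as
$e^{-2t/\tau}$, so the $1/e$ band-power crossing sits at $\tau/2$ after the
maximum; the damping-recovery tests use the squared envelope's closed-form
crossing as the oracle.

## Solvation and proton-transfer diagnostics

The simulated system is a finite droplet (a ~19 Å sphere of water around
the chromophore), not a periodic box. `rdf()` therefore normalizes the A–B
distance histogram per A atom by the ideal-gas shell count
$\rho_0\,4\pi r^2\,\mathrm{d}r$ with an explicit or automatic reference
density; `rho0 = "auto"` uses count(B) over the volume of B's bounding
sphere, centered on the per-axis midrange (a cheap, nearly unbiased
approximation to the minimal enclosing sphere — a centroid-centered radius
is inflated by the $O(n^{-1/2})$ centroid error and biases $\rho_0$ by a
few percent). Near the droplet edge $g(r) \to 0$ by construction; no
excluded-volume correction is applied. The running integral $n(r)$ gives
coordination numbers ("waters within the first peak") by interpolation.

Proton transfer is operationalized purely by distances, following the
structure of the analysis rather than any energetic criterion: each
hydrogen is assigned to its nearest heavy atom (covalent cutoff
`r_bond = 1.3` Å, ties to the lowest index, mid-hop frames beyond every
cutoff inherit the previous assignment). An assignment change opens an
*excursion*; returning to the donor closes it as one `transient` round-trip
event, while persisting at least `t_permanent = 100 fs` (the hydronium
lifetime scale) to the end of the window or to an onward transfer makes it
`permanent`. An oxygen with exactly three assigned hydrogens is a
hydronium; lifetimes are maximal consecutive runs times the timestep. The
cutoff and persistence threshold are deliberate operational definitions —
the distinction between a brief excursion and a completed transfer is not
sharp in nature — and both are arguments everywhere they appear.

Dihedral series use the signed IUPAC convention (cis = 0°, trans = ±180°,
cross-checked against `bio3d::torsion.xyz`) and are unwrapped by
minimal-jump continuation, so a ring substituent oscillating about
planarity reports a mean near 180° (e.g. 182–183°) instead of jumping
between +180° and −180°. Collinear frames yield flagged `NA`s rather than
being dropped.

All atom indices in the R API and at the CLI are 1-based, the R-ecosystem
convention.

## What the synthetic generators emulate

`make_harmonic()` synthesizes superposed mode oscillations
$q_i(t) = \sum_k A_k L_{ik}\cos(2\pi\nu_k t + \phi_k)\,e^{-t/\tau_k}$ with
analytically consistent velocities on orthonormal mass-weighted patterns
from `internal_mode_vectors()` (random vectors with the global
translation/rotation generators projected out). It emulates exactly the
structure the covariance analysis assumes — independent collective
oscillators — which is what makes analytic ground truth possible; it does
*not* emulate anharmonic coupling, stochastic thermal forcing, or solvent
friction, so passing recovery tests demonstrates correctness of the
analysis chain, not robustness to real-data noise. The demo configuration
uses 110 and 198 cm⁻¹ with ~700 fs damping, the wagging/breathing frequency
range of a pyrene-core photoacid, so documentation output is qualitatively
comparable to a real analysis; tests treat all generator frequencies as
arbitrary inputs.

Amplitude choice matters for the mode-count checks: mode patterns are
defined at the reference geometry, so finite displacement couples them to
the instantaneous rotations at second order, leaking $\sim\varepsilon^2$
relative variance into the nominally zero modes. The translation/rotation
count checks therefore run in the small-oscillation regime
($A = 10^{-5}\,\sqrt{\mathrm{amu}}$ Å on ~1 Å geometries,
$\varepsilon^2 \approx 10^{-10}$, comfortably below the $10^{-8}$
near-zero threshold), which is the regime where the mode/global separation
is defined. Frequency-recovery checks use moderate amplitudes
(0.01–0.03) since peak positions are insensitive to the leakage.

`make_droplet()` draws uniform points in a sphere (independent frames
sharpen RDF statistics); `make_pt_script()` places heavy atoms 2.6 Å apart
with hydrogens 1.0 Å from their parent so covalent assignment flips exactly
at the scripted frame. All generators are seed-deterministic.

## Problem sizes and verification

The test suite validates every stage against independent oracles: direct
summation for the FFT-convolution CWT, quadrature for wavelet
normalization, closed forms for 2×2 eigenproblems, analytic tones and
chirps for spectral estimators, kinetic energy for mass weighting,
brute-force frame-by-frame re-assignment for event detection, and
`bio3d` for the dihedral sign. End-to-end checks use a bent and a linear
triatomic (6000 frames at 0.4 fs) for the mode counts, a 4-atom molecule
over 20 ps at 0.5 fs for 2%-accurate frequency recovery, and
150–400-frame droplets of 4000 points for the RDF ideal-gas null — sizes
chosen so each property is measured well inside its stated tolerance while
the whole suite runs in about a minute.

## Limitations

* The ground-state-basis projection is only meaningful in the ultrafast,
  near-Franck–Condon part of a relaxation.
* Spectrogram intensities are arbitrary units; only peak locations, band
  integrals over time, and decay times are comparable between runs.
* The finite-droplet RDF normalization leaves edge artifacts; interpret
  $g(r)$ only well inside the droplet radius.
* Event detection is geometric; it cannot distinguish chemically distinct
  but geometrically identical assignments (e.g. strongly shared protons
  sitting near the cutoff will flicker — inspect `assign_protons()`
  distances in that case).
* Trajectory velocities are taken as physical; no correction is attempted
  for propagation schemes with fictitious dynamics.
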