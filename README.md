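# modewave

Time-resolved vibrational analysis of molecular dynamics trajectories in R,
built for studying ultrafast photochemistry such as the excited-state proton
transfer (ESPT) of a photoacid (e.g. pyranine) hydrogen-bonded to water and
a carboxylate acceptor.

A stationary vibrational spectrum tells you which modes a molecule has; it
cannot tell you *when* each mode is active during a sub-picosecond
relaxation. `modewave` combines two ideas:

1. **Generalized modes from the velocity covariance.** With mass-weighted
   atomic velocities q̇ᵢ = √mᵢ ẋᵢ, form the time-averaged covariance
   K. The columns of its orthogonal
   eigenvector matrix **L** are collective coordinates whose velocities are
   mutually uncorrelated — anharmonic analogues of normal modes requiring no
   quadratic potential. Mode velocities follow by projection,
   **Q̇**(t) = **L**ᵀ q̇(t); a ground-state basis may be applied to
   excited-state trajectories (valid near the Franck–Condon region).
   Translations and rotations are projected out frame by frame, leaving 6
   near-zero modes (5 for linear molecules).
2. **Morlet continuous-wavelet spectrograms.** Each Q̇\_α(t) is decomposed on
   Morlet daughters ψ\_{a,b}(t) = a^(−1/2) exp(iω₀(t−b)/a) exp(−((t−b)/a)²/2);
   the intensity |W\_α(ν,t)|² localizes each vibration in time *and*
   frequency, so mode activation and decay times can be read off directly.

Around this core the package provides the solvation and proton-transfer
diagnostics used to connect vibrations to chemistry: finite-droplet radial
distribution functions and coordination numbers, distance and (unwrapped)
dihedral time series, nearest-heavy-atom proton assignment with
transient/permanent hop classification, and hydronium lifetime detection.
Synthetic generators (harmonic molecules with analytic modes, uniform
droplets, scripted proton hops) make every stage testable against ground
truth. Trajectories are read from extended-XYZ files carrying velocities;
units are Å, fs, amu, cm⁻¹ throughout.

## Worked example

Synthesize a bent triatomic carrying an undamped 110 cm⁻¹ mode and a
198 cm⁻¹ mode whose amplitude decays with τ = 700 fs, then run the full
analysis chain:

```r
library(modewave)

geom <- rbind(c(0, 0.587, 0), c(0.757, 0, 0), c(-0.757, 0, 0))
m    <- c(15.999, 1.008, 1.008)
mv   <- internal_mode_vectors(geom, m, 2, seed = 1)
spec <- harmonic_spec(geom, m, mv, frequencies = c(110, 198),
                      amplitudes = c(0.02, 0.015), dampings = c(Inf, 700))
traj <- make_harmonic(spec, dt = 0.5, nframes = 8000)   # 4 ps

traj  <- remove_global_motion(traj)
basis <- diagonalize(compute_K(mass_weight(traj)))
basis
#> mode_basis: 9 generalized modes, 6 near-zero (global)
#> leading eigenvalues (amu A^2/fs^2): 8.549e-08 1.372e-08 1.594e-12 1.473e-17 5.067e-24

qd <- project_modes(basis, mass_weight(traj), dt = 0.5)
ps <- power_spectrum(qd$Qdot[, 2], dt = 0.5)
ps$frequencies[which.max(ps$power)]
#> [1] 197.5

sp <- cwt(qd$Qdot[, 2], dt = 0.5, wavelet_params(50, 400))
bp <- band_power(sp, c(150, 250))
decay_time(bp, 0.5)
#> [1] 368
```

Reading the output: the covariance has exactly two excited generalized
modes (the remaining 6 near-zero eigenvalues are the projected-out
translations/rotations plus the unexcited bend direction — here 7 of 9
eigenvalues are tiny, 6 of them below the global-motion threshold). The
second mode's spectrum peaks at 197.5 cm⁻¹, one frequency bin from the
input 198. Its band power decays to 1/e at 368 fs after the early maximum —
an amplitude lifetime of τ ≈ 2 × 368 = 736 fs, recovering the input 700 fs
to 5% (band power decays twice as fast as amplitude).

The same pipeline is scriptable from a shell via the installed umbrella CLI:

```sh
modes synth   --config spec.yaml --out gs.xyz --dt 0.5 --nframes 8000
modes extract --traj gs.xyz --dt 0.5 --out basis.txt
modes project --basis basis.txt --traj es.xyz --dt 0.5 --out qdot.txt
modes wavelet --qdot qdot.txt --dt 0.5 --mode 2 --fmin 50 --fmax 600 --out map.txt
modes rdf --traj solv.xyz --a 1 --b @waters.txt --rmax 6 --bin 0.05 --out rdf.txt
modes ptevents --traj es.xyz --dt 0.5 --hydrogens 4 --heavy 1,2,3 --out events.txt
```

Every subcommand writes a JSON manifest with its parameters and input
checksums next to its outputs.

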