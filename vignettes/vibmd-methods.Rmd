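---
title: "Vibrational analysis of adsorbate MD trajectories: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vibrational analysis of adsorbate MD trajectories: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vibmd)
```

## The problem

Molecules adsorbed in hydrogen-bonded overlayers — the motivating system is
glycinate (the deprotonated glycine anion, NH$_2$–CH$_2$–CO$_2^-$) bound to
Cu{110} — move on flat, multi-minimum potential energy surfaces. A harmonic
normal-mode analysis about any single minimum then misses much of the
physics: the molecule samples several minima at working temperatures, and
its high-frequency stretches are strongly anharmonic. Molecular dynamics at
a thermostated temperature samples all of this directly, and the quantities
of experimental interest can be extracted from the trajectory itself:

* **time-averaged structures**, the proper comparison for diffraction
  probes (LEED averages over space, MD over time);
* **glide-symmetry statistics** — the ($3\times2$) glycinate overlayer is
  glide-symmetric only on time average, so the rms deviation of the mean
  structure from the nearest exactly symmetric structure measures how well
  the dynamics has sampled configuration space;
* **thermal ellipsoids** from the atomic displacement matrix
  $\mathbf{U} = \langle u_i u_j \rangle$, with $u$ the instantaneous
  Cartesian displacement from the mean position;
* the **vibrational density of states** as the power spectral density
  (PSD) of mass-weighted velocity, equivalently the Fourier transform of
  the mass-weighted velocity autocorrelation function (VACF);
* **local-mode spectra**: the same trajectory projected onto chemically
  labelled internal coordinates (NH$_2$ symmetric stretch, CH$_2$ wag, …),
  which makes peak assignment a matter of reading off which local modes
  carry spectral mass under each peak.

The package implements this chain end to end, together with a synthetic
trajectory generator that provides exact ground truth for every stage.

## Units and constants

All internal quantities use Å, fs, amu and K; wavenumbers are cm$^{-1}$ on
output. Energies come out in amu Å$^2$ fs$^{-2}$
($= 1.66\times10^{-17}$ J). CODATA exact values are used for $k_B$ and $c$
(`vib_constants`), so $k_B = 8.31446\times10^{-7}$ amu Å$^2$ fs$^{-2}$
K$^{-1}$. A single conversion point avoids unit bugs; every function
documents its units.

## Trajectory handling

Extended-XYZ is the only supported format (the lingua franca of MD
post-processing): a per-frame comment line carries
`Lattice="..."` and `Properties=species:S:1:pos:R:3[:vel:R:3]`. The cell is
fixed; varying cells are rejected, matching fixed-cell surface MD.
Equilibration trimming removes frames before a cut time (the motivating
protocol discards 1 ps before a 9 ps production window at 0.25 fs steps).
Unwrapping makes consecutive-frame displacements minimum-image so that
means and displacement matrices are well defined under periodic boundaries;
it is idempotent. When files carry only positions, velocities are derived
by central differences, $v(t) = [x(t+\Delta t)-x(t-\Delta t)]/2\Delta t$,
dropping both endpoint frames rather than mixing one-sided estimates (this
preserves spectral symmetry). Central differences are exact for
affine-in-time motion and carry a $O((\omega\Delta t)^2)$ amplitude error
for a mode at $\omega$ — about 0.5% at 3400 cm$^{-1}$ and 0.25 fs, which
rescales intensities slightly but does not move peaks.

## Glide symmetry

A glide operation is a mirror plus an in-plane translation; applied twice
it is a lattice translation, which is why the matched structures must carry
their periodic cell. The matcher takes a candidate mirror axis, plane
offset and glide vector, assigns each atom its nearest same-species image
(greedy, pairing enforced as an involution, ties to the smallest index,
1 Å default cutoff), then refines the translation by least squares — the
mean minimum-image residual, which refines plane offset and glide
translation together. Deviation from perfection is measured against the
*symmetrized* structure (each atom averaged with its back-transformed
partner), i.e. the distance to the nearest exactly symmetric structure;
this halves pair double-counting, and a single atom displaced by $\delta$
among $N$ contributes $\delta/\sqrt{2N}$. The alternative convention —
distance to the partner's raw image — is exactly twice as large for a
perturbed pair; published deviation figures do not always say which is
meant, so the choice here is declared rather than inferred.

## Thermal ellipsoids

$\mathbf{U}$ is accumulated per atom over post-equilibration frames;
glide symmetrization replaces $U_i$ by
$\tfrac12(U_i + R\,U_{\sigma(i)}R^{\mathsf T})$, after which partner
ellipsoids are exact mirror images. Eigen-decomposition gives semiaxes
$s\sqrt{\lambda_n}$ along the eigenvectors, ordered descending, with axis
signs fixed by making the largest component positive (deterministic
output). The default probability scaling $s = 1.5382$ is the 50% surface
of a trivariate Gaussian; the recommended literature scaling encloses
"slightly more than half" the probability without printing a number, so
1.5382 is documented as a configurable stand-in. Shape classification uses
a fractional tolerance (default 5%): prolate when the two small axes agree
but the large one does not, oblate in the mirror case, spherical when all
three agree. ADP export writes CIF `_atom_site_aniso_U_*` in the standard
reciprocal-axis convention $U_{\text{cart}} = A N U^{\text{cif}} N A^{\mathsf T}$
(A columns are cell vectors, N the reciprocal-axis lengths), so the files
interoperate with refinement software; since CIF stores only cell lengths
and angles, round-tripping in the original Cartesian frame requires the
original cell matrix.

## Spectra

The vibrational DOS is the one-sided PSD of mass-weighted velocity, summed
over selected atoms and Cartesian components, Hann-tapered by default, with
per-channel drift removed (this kills the $\nu = 0$ artifact). The
convention constant is fixed by Parseval: the rectangle-rule integral of
the spectrum over wavenumber equals the time mean of $\sum_a m_a |v_a|^2$,
i.e. twice the mean kinetic energy. At equilibrium each mode then carries
spectral weight exactly $k_B T$, so `band_mode_count()` — band integral
over $k_B T$ — reads directly as an effective mode count; this is the
equipartition bookkeeping that lets band areas be compared with the number
of states expected in each spectral region (phonon band below 250
cm$^{-1}$, fingerprint 500–1550, CH$_2$ stretches 2850–3200, NH$_2$
stretches 3200–3650).

The VACF route is provided as an internal consistency oracle. The discrete
Wiener–Khintchine identity is exact: the periodogram equals the cosine
transform of the *biased* full-lag autocorrelation, bin for bin, and the
package reproduces this to machine precision. The default VACF estimator
is the unbiased one (each lag divided by its own sample count), for which
a half-Hann lag taper is available; transformed, it gives a *smoothed*
spectrum which differs from the raw periodogram by design, so equivalence
checks use matched (biased, untapered) settings.

At 0.25 fs sampling the Nyquist wavenumber is ≈ 66,700 cm$^{-1}$, so
nothing in the chemical range can alias.

## Local modes

The 21 internal coordinates of glycinate follow the classic group-frequency
constructions: symmetric/antisymmetric stretches $(\Delta r_1 \pm
\Delta r_2)/\sqrt2$ for NH$_2$, CH$_2$, CO$_2$; CN and CC stretches;
scissors for NH$_2$/CH$_2$/CO$_2$/NCC; methylene wag, rock and twist as the
$(++--)/2$, $(+-+-)/2$ and $(+--+)/2$ combinations of the four flanking
bends (a fixed sign table, since the textbook conventions admit sign
ambiguity); terminal-group rock as the in-plane skeletal-bend difference
and wag as the out-of-plane coordinate of the skeletal bond against the
group plane (this also sidesteps the planar-CO$_2$ bend redundancy);
torsions as the mean of all six dihedrals about the bond. That is
$8+4+3+3+1+2 = 21 = 3N-6$ for $N = 9$.

Projection computes $\dot q_k = \sum_a \mathbf{s}_{k,a}\cdot\mathbf{v}_a$
with Wilson-style s-vectors obtained by central finite differences of the
vectorized primitive-value functions ($h = 10^{-5}$ Å, wrap-aware for
dihedrals), recomputed from the instantaneous geometry of every frame — a
fixed reference would be invalidated by large-amplitude motion at 500 K.
Numerical s-vectors keep the code uniform across primitive types and are
accurate to ~$10^{-10}$, comfortably inside the $10^{-8}$ rigid-rotation
tolerance the tests enforce. Frames within $10^{-3}$ rad of a collinear
bend are flagged and interpolated; more than 1% flagged frames is an
error. Per-mode spectra are unit-area normalized so that "spectral mass
near a peak" is comparable across modes, and are averaged over molecules
when several are supplied.

Peak assignment integrates each unit-area local spectrum within ±25
cm$^{-1}$ of a detected peak (half the crowded-fingerprint peak-spacing
scale; configurable), drops modes below 10% of the top contributor
(reproducing the practice of listing a handful of modes, not all 21), and
sorts the rest descending with alphabetical tie-breaks. Reference
comparison is label-matched, never nearest-frequency — deliberate
reassignments in published tables make frequency matching wrong — and the
rms statistics are reported to 1 cm$^{-1}$ / 0.1%, the precision of the
published comparison they reproduce.

## The synthetic generator

The generator's role is ground truth: every analysis stage is tested
against trajectories whose correct answer is known by construction.

**Harmonic glycinate toy.** A 9-atom glycinate-like geometry (standard
bond lengths, pyramidal NH$_2$, planar carboxylate) carries a quadratic
potential whose normal modes sit *exactly* at 21 requested local-mode
frequencies. The naive route — one spring per local coordinate — is
ill-conditioned because the mass-weighted s-vector directions overlap
through the kinetic metric; instead the package symmetrically (Löwdin)
orthogonalizes those directions, places a spring $\omega_k^2$ on each
orthogonalized coordinate, and a spring $\omega_{\text{ext}}^2$ (default
80 cm$^{-1}$) on the 6-dimensional external complement, which stands in
for the surface tether and puts the frustrated translations/rotations in
the phonon band. Each normal mode remains dominantly its parent local mode
(overlap 0.84–1.0). Default targets sit near the observed 1/3 ML peak
positions of glycinate on Cu{110}; the two modes without published peaks
(CO$_2$ rock, NCC scissor) use typical carboxylate values (530, 330
cm$^{-1}$). The glide-pair layout mirrors the molecule
($y \to -y$ plus a half-cell translation along $x$) in a fixed periodic
cell, with a glide-consistent fixed Cu substrate, and is exactly symmetric
by construction.

**Integrators.** Velocity Verlet (NVE; drift-free to $10^{-5}$ relative
over $10^5$ steps), BAOAB Langevin (the default thermostat — robustly
ergodic for small systems), and a five-link Nosé–Hoover chain (provided to
mirror thermostated first-principles MD practice, but documented as
optional since chains on tiny systems can be weakly ergodic). A step-size
guard warns above a tenth of the fastest period and fails above
period/$\pi$. All randomness sits behind a single seeded generator;
Langevin noise can be supplied explicitly, which is how the tests verify
that mirrored noise drives exactly mirrored glide-pair trajectories.
`thermal_initial_conditions()` draws exact canonical positions and
velocities from the normal modes, so energy-conserving production runs can
start properly thermalized — the analogue of an equilibration phase.

**Morse anharmonicity.** The classical Morse oscillator's frequency falls
with energy, $\omega(E) = \omega_0\sqrt{1-E/D}$; the package predicts the
thermal peak by numerically integrating the orbit period at $E = k_B T$
(midpoint quadrature in the angle variable, which cancels the turning-point
singularities) and validates the closed form to $10^{-6}$. The end-to-end
oracle thermalizes an N–H-like bond ($\tilde\nu_0 = 3400$ cm$^{-1}$,
$D = 4$ eV, reduced mass 0.95 amu, 500 K, $\gamma = 0.002$ fs$^{-1}$) and
compares the spectral peak with the prediction. The transverse degrees of
freedom are pinned stiffly (4500 cm$^{-1}$) because the Morse bond has no
transverse restoring force at equilibrium, and the peak is read in the
2000–4200 cm$^{-1}$ stretch band.

## Numerical and statistical choices

* **Problem sizes.** The trajectory analyses use 9 ps windows at 0.25 fs
  (36,000 frames; grid spacing 3.7 cm$^{-1}$), matching the motivating
  protocol. Band counting uses $2^{16}$ Langevin steps; equipartition
  checks use 200,000 steps with $\gamma = 0.05$ fs$^{-1}$ and batch-mean
  standard errors (25 batches), because at small friction the energy
  decorrelation time $1/\gamma$ makes naive error bars meaningless.
* **Line width versus resolution.** Langevin lines have Lorentzian width
  $\gamma/\pi c$ (≈ 21 cm$^{-1}$ at $\gamma = 0.002$ fs$^{-1}$) on top of
  the thermal width of the Morse line (≈ 18 cm$^{-1}$ at $k_BT/D\approx
  0.011$). The Morse peak is therefore measured on a Welch average of 32
  segments of 2.25 ps (resolution ≈ 15 cm$^{-1}$, matched to the line
  width): resolving far below the physical width only adds argmax jitter.
* **Frequency recovery** uses NVE runs from canonical draws rather than
  Langevin, because harmonic NVE lines are grid-sharp delta functions at
  the exact normal-mode frequencies; averaging six draws removes the risk
  that a strongly mixed coordinate's spectrum is dominated by a
  luckier-energy neighbour mode.
* **Degenerate inputs.** Eigen-order is descending with sign-fixed axes;
  ties in peak thinning keep the taller peak; assignment ties break
  alphabetically; collinear-geometry frames are interpolated, never
  silently kept.

## What the synthetic tests do and do not show

The generator emulates thermostated classical dynamics of a small
adsorbate with known frequencies, optional anharmonicity and exact glide
symmetry. It does not emulate: multi-minimum landscapes (the toy is a
single quadratic basin), mode-mode anharmonic coupling, substrate phonon
baths (the substrate is fixed), dipole intensities (no surface selection
rule — a spectral peak here says nothing about RAIRS visibility), or
quantum effects. Passing tests therefore demonstrate that the *analysis
chain* is correct — frequencies, band areas, ellipsoids and symmetry
statistics are extracted faithfully from trajectories — not that any
particular first-principles trajectory is converged. The published
reconciliation statistics bundled with the package (rms discrepancies of
75/26 cm$^{-1}$, 3.2/2.3%, and the coverage shifts +55/+30/−65/−120
cm$^{-1}$) are recomputed exactly from the printed peak tables by the same
code paths users would run on their own peak lists.

## Known limitations

Only the glycinate family of topologies is built in; other molecules
require a user-supplied primitive list. Only one user-specified
mirror/glide operation is supported — no general space-group detection.
Binary MD formats are out of scope. The exact literature value of the
ellipsoid probability scaling is recorded as an open question; all
results that depend on it scale trivially.
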