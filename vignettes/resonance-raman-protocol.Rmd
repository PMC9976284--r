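---
title: "Simulating resonance Raman spectra from trajectory snapshots"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating resonance Raman spectra from trajectory snapshots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resoraman)
```

## The problem

Resonance Raman (RR) spectroscopy of a flexible chromophore embedded in a
complex environment — a drug intercalated in DNA, a dye in solution — probes
vibrational modes that couple to the resonant electronic transition. Simulating
such spectra from first principles faces two coupled difficulties. First, a
single optimized geometry is not representative: the chromophore explores
several conformational families along a molecular-dynamics (MD) trajectory, so
the spectrum must be a weighted average over structural snapshots. Second,
harmonic vibrational analysis on *unoptimized* snapshot geometries is
ill-behaved: the gradient is nonzero, and large-amplitude (soft) torsional
motions produce imaginary frequencies that contaminate the stiff-mode spectrum.

`resoraman` implements a complete protocol for this situation:

1. decimate the trajectory and cut the environment to a solvent shell;
2. cluster the snapshots into structural families by pairwise minimized RMSD
   and select one representative per family, with the *persistence* (fraction
   of frames absorbed by the family) as its averaging weight;
3. obtain harmonic normal modes of each representative by one of four
   strategies (below);
4. differentiate the complex frequency-dependent polarizability along each
   mode by central finite differences, form the rotational invariants, and
   assemble short-time-approximation RR stick intensities;
5. broaden with a Lorentzian band shape and average with the persistence
   weights, max-normalizing the result.

The electronic-structure step is deliberately *not* part of the package: any
function `(structure, incident_ev, damping_cm) -> 3x3 complex tensor`
satisfies the calculator contract. A built-in analytic resonance-pole model
makes the whole pipeline runnable and testable without any quantum-chemistry
engine.

## Normal-mode strategies

All strategies start from the mass-weighted Cartesian Hessian
$H^{mw} = M^{-1/2} H M^{-1/2}$ (masses in electron masses, curvature in
Hartree/bohr²) whose eigenvalues $\lambda$ map to wavenumbers
$\tilde\nu = \mathrm{sign}(\lambda)\sqrt{|\lambda|}\cdot 219474.63\ \mathrm{cm^{-1}}$;
negative wavenumbers encode imaginary modes, which are reported by
`count_imaginary()` and excluded from RR evaluation (they are data about the
snapshot, never errors).

**A0 — direct diagonalization** (`normal_modes_a0`). The snapshot Hessian is
diagonalized as-is, optionally after Eckart projection of the translation and
infinitesimal-rotation space about the center of mass. The projector rank is
detected from the singular values of the translation/rotation basis, so linear
geometries need no flag. Because snapshots are off-minimum, projection of a
raw MD frame is formally ill-defined (the gradient is nonzero); both paths are
exposed via `project_transrot` and the projected variant is the default.

**PHVA — partial Hessian vibrational analysis** (`phva_modes`). The
$3N_a\times 3N_a$ sub-block of $H^{mw}$ over the *active* atoms is
diagonalized while every environment atom is treated as infinitely heavy.
With all atoms active this reduces exactly to unprojected A0, a limiting case
asserted in the tests. No translation/rotation projection is applied by
default — the frozen environment breaks both invariances — but the three
rigid translations of the active set alone can be removed via
`project_active_translations`.

**A1 — reference-mode rotation** (`superpose` + `rotate_modes`). The modes of
a single reference structure (e.g. the optimized minimum of the dominant
conformer) are carried onto each frame by the best-fit rigid superposition:
the weighted Kabsch problem is solved by SVD of the weighted covariance, the
reflection branch is disabled (det +1 enforced), and every atom's displacement
vector in every mode is rotated by the resulting matrix. The rotation is
orthogonal, so wavenumbers, reduced masses and mass-weighted orthonormality
are preserved exactly; the rotated modes are *not* re-orthogonalized against
the frame's own translation/rotation space — the operation is a pure
rotation. Fitting weights default to unity with a mass-weighted option.

**A2 — soft-coordinate reduction** (`reduced_modes`). User-declared soft
internal coordinates (proper dihedrals: methyl and ammonium torsions,
hydroxyl dihedrals) are removed from the harmonic treatment. Each dihedral
contributes a Wilson B row $B_i = \partial\theta_i/\partial x$ (analytic,
validated against central differences to 1e-6), which is mass-weighted into
$u_i = M^{-1/2}B_i^{\mathsf T}$, orthonormalized together with the
translation/rotation basis by modified Gram–Schmidt with re-orthogonalization
(rank tolerance 1e-8 relative; linear dependence among the declared dihedrals
is an error naming the offending labels), and assembled into the projector
$P = I - \sum_i u_iu_i^{\mathsf T}$. Diagonalizing $PH^{mw}P$ and dropping
the $6+m$ null modes leaves $3N-6-m$ stiff modes. The projection is performed
in mass-weighted Cartesian space — the linearized realization of removing an
internal coordinate, exact for infinitesimal displacements; curvilinear
corrections are beyond scope. Imaginary curvature confined to a declared
torsion disappears from the reduced spectrum, which is the practical point of
the strategy.

## RR intensities

For each real mode $k$ the complex polarizability is evaluated at the two
geometries displaced by $\pm s\, M^{-1/2}L_k$ with $s$ in mass-weighted
atomic units (bohr·$\sqrt{m_e}$), default $s = 0.001$, and differentiated
centrally: $\partial\alpha/\partial Q_k \approx (\alpha_+ - \alpha_-)/2s$.
The electronic lifetime broadening $\Gamma$ (default 500 cm⁻¹) enters
*inside* the calculator through the complex frequency argument, which is what
makes the derivatives complex near resonance. Tensors with antisymmetry
beyond 1e-8 relative are rejected rather than silently symmetrized: the
invariant formulas below assume a symmetric tensor.

From each derivative tensor the rotational invariants are
$a^2 = |\tfrac13(d_{xx}+d_{yy}+d_{zz})|^2$ and
$\gamma^2 = \tfrac12\sum_{pairs}|d_{pp}-d_{qq}|^2 + 3\sum_{p<q}|d_{pq}|^2$,
and the Stokes stick intensity is

$$ I_k \;\propto\; (\tilde\nu_0-\tilde\nu_k)^3\,\tilde\nu_0\,
   \frac{45a_k^2 + 7\gamma_k^2}{\tilde\nu_k}, $$

optionally times the thermal occupation factor
$[1-\exp(-hc\tilde\nu_k/k_BT)]^{-1}$ (off by default; a flag enables it at
any temperature). This is the standard differential Raman cross-section form;
because every final spectrum is scaled so its maximum is one, all constant
prefactors cancel and only the frequency factors matter, so no absolute
cross-section calibration is attempted. Modes at or above the incident
wavenumber are skipped with a warning (anti-Stokes and over-the-excitation
scattering are not modeled), as are numerical-zero modes below 1 cm⁻¹.

Sticks are broadened as
$S(\tilde\nu)=\sum_k I_k\,\frac{1}{\pi}\frac{\gamma}{(\tilde\nu-\tilde\nu_k)^2+\gamma^2}$
with $\gamma$ the HWHM (default 10 cm⁻¹, i.e. 20 cm⁻¹ FWHM, unit area per
unit stick intensity). Per-representative spectra are convolved first, then
averaged pointwise with the persistence weights, then max-normalized. For a
linear convolution the convolve/weight order is immaterial; normalizing last
is a definite choice and is recorded in the spectrum metadata.

## Clustering

`cluster_frames` implements greedy neighbor-count clustering
(GROMOS/Daura style): the frame with the most neighbors within the RMSD
cutoff seeds a family, it and its neighbors are removed, and the procedure
repeats. Ties are broken by the lowest frame index, making the assignment
deterministic and invariant under frame relabeling up to that rule. The
algorithm is greedy — representatives maximize the neighbor count at each
step, not any global objective. The cutoff defaults to 1.0 Å on heavy atoms
(hydrogens excluded via the default selection); both are configuration
parameters, since appropriate values depend on the system's conformational
granularity. The solvent-shell cut in `select_snapshots` is residue-level — a
residue survives when *any* of its atoms is within the cutoff of *any* target
atom — so water molecules are never broken.

## Key parameters

| parameter | default | unit | role |
|---|---|---|---|
| `step` | 0.001 | bohr·√mₑ | finite-displacement along each mode |
| `damping_cm` | 500 | cm⁻¹ | electronic lifetime broadening Γ |
| `incident_ev` | 2.49 | eV | incident photon energy (≈ 498 nm) |
| `hwhm_cm` | 10 | cm⁻¹ | Lorentzian HWHM (FWHM 20 cm⁻¹) |
| `grid` | 1000–2000 × 0.5 | cm⁻¹ | output wavenumber grid |
| `cluster$cutoff` | 1.0 | Å | RMSD neighbor cutoff |
| `drop_tol_cm` | 1 | cm⁻¹ | null-mode residue threshold |

The 0.001 step is interpreted in mass-weighted normal-coordinate units; the
Cartesian-bohr interpretation can be reproduced by rescaling `step` per mode.
No empirical frequency-scaling factor is applied to the harmonic wavenumbers.

## Numerical choices and degenerate inputs

- **Hessian symmetrization.** Input matrices are symmetrized as
  $(H+H^{\mathsf T})/2$; relative asymmetry above 1e-6 warns, above 1e-3
  errors, on the view that an asymmetry that large signals a broken file, not
  round-off.
- **Null-mode identification.** After any projection, the null-space modes
  are those whose eigenvectors overlap the projected basis; they must fall
  below 1 cm⁻¹ in magnitude or the run errors, advising review of the
  projection set. Imaginary counting uses a −1 cm⁻¹ threshold for the same
  reason: translation/rotation residue on noisy Hessians straddles zero.
- **Kabsch degeneracy.** For a collinear atom cloud the rotation about the
  molecular axis is undetermined; the smallest-angle rotation mapping the
  dominant axis of one cloud onto the other is returned with a warning.
  `rmsd_before` is defined after centroid alignment, so
  `rmsd_after <= rmsd_before` holds unconditionally and the fit is invariant
  to pre-translation of either input.
- **Finite-difference regime.** Central differences of the pole model
  converge at second order; the step-halving error ratio reaches its
  asymptotic value of 4 only once `slope × step` is small against the
  detuning, which the toy-model tests respect by construction.
- **Determinism.** Every stochastic stage takes an explicit seed; the run
  manifest records all parameters, so re-running a manifest's configuration
  reproduces outputs bit-exactly.

## The toy models, and what passing tests do not show

`make_harmonic_molecule` synthesizes a Hessian spectrally from a random
mass-weighted-orthonormal basis orthogonal to the translation/rotation space,
so the "true" modes are known exactly — the oracle for every diagonalization
path. `make_synthetic_trajectory` samples classical (not Wigner) Gaussian
normal-coordinate displacements at the equipartition variance
$k_BT/\omega_k^2$, matching the classical-MD provenance of real snapshots,
with an optional random rigid rotation per frame to exercise A1.
`morse_cluster_hessian` provides an analytic geometry-*dependent* Hessian
whose curvature turns negative off-minimum, emulating the imaginary-mode
phenomenology of unoptimized snapshots. The built-in resonance-pole
calculator makes the excitation energy linear in one chosen coordinate, so
exactly one mode is resonance-enhanced — a sharp, predictable signal for
end-to-end tests.

These models validate the *machinery*: unit handling, projections,
superposition, finite differences, clustering, weighting, broadening. They do
not validate harmonicity of a real chromophore, the quality of any electronic
structure method, anharmonic or vibronic (Franck–Condon/Herzberg–Teller)
effects, or mode anharmonic couplings — all outside the short-time
approximation implemented here. Agreement of the four strategies on
near-equilibrium toy frames likewise does not imply agreement on real
off-minimum snapshots; diagnosing *that* disagreement is precisely what the
strategy comparison is for.

Test and validation problem sizes are kept small by design — molecules of 3–6
atoms, trajectories of 6–5000 frames depending on what the statistic needs —
chosen so each check isolates one property with comfortable numerical
headroom.

## Known limitations

- Soft coordinates are proper dihedrals only; bonds and angles are not
  projectable.
- The A1 reference is an explicit input; the package does not decide which
  conformer (global minimum, per-cluster minimum) should serve as reference.
- The selection of soft coordinates for A2 is the user's: the package
  supplies `count_imaginary` and per-mode diagnostics to support the
  workflow of choosing torsions implicated in imaginary modes, but does not
  automate the choice.
- Antisymmetric polarizability contributions (possible exactly at resonance
  for some symmetries) are rejected, not modeled.
- Trajectory input is multi-frame XYZ; binary MD formats should be converted
  upstream.
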