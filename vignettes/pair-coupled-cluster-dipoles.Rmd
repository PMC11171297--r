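---
title: "Pair coupled-cluster response densities and dipole-moment surfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pair coupled-cluster response densities and dipole-moment surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of the science it implements: the
models, their assumptions, the tunable parameters, the numerical choices
made where the design was genuinely open, and the limits of what the test
suite can certify.

## The model chain

`paircc` computes electric dipole moments of closed-shell singlet
molecules from seniority-zero coupled-cluster wave functions:

1. **Restricted Hartree–Fock** supplies the reference determinant
   $|\Phi_0\rangle$.
2. **pCCD** (pair coupled-cluster doubles) applies the exponential ansatz
   $|\Psi\rangle = e^{T_p}|\Phi_0\rangle$ with the cluster operator
   restricted to electron-pair doubles,
   $T_p=\sum_{ia} t_i^a\, a^\dagger_{a\alpha}a^\dagger_{a\bar\beta}
   a_{i\bar\beta}a_{i\alpha}$: both electrons of a spatial orbital move
   together.  The wave function stays in the seniority-zero sector (no
   unpaired electrons), where the electronic Hamiltonian acts as a
   hard-core-boson pairing Hamiltonian: determinant energies on the
   diagonal and the exchange integrals $K_{pq}=(pq|pq)$ as pair-hopping
   elements.  The amplitude equations used here are derived in that
   picture and are quartic polynomials in $t$; they are certified against
   a brute-force determinant-space oracle
   (`projected_residual_check()`).
3. **Orbital optimization (oo-pCCD)** minimizes the pCCD energy over
   orthogonal rotations of the active orbitals.  Unlike conventional CC,
   the pCCD energy is *not* invariant under occupied–occupied or
   virtual–virtual rotations, so all three blocks rotate; frozen-core
   orbitals are excluded from the rotation and folded into the active
   one-electron operator at the AO level.
4. **Linearized CC corrections (LCCD / LCCSD)** add the dynamic
   correlation that the pair ansatz misses.  The correction cluster
   operator $T'$ (doubles, or singles and doubles) *excludes* the pair
   channel — amplitudes and projection rows with $i=j \wedge a=b$ are
   absent, while mixed rows with $i=j, a\neq b$ or $i\neq j, a=b$ are
   retained — and the equations are truncated at terms linear in $T'$:
   $\langle\Phi_{\mathrm{ex}}|(\bar H + [\bar H, T'])|\Phi_0\rangle = 0$
   with $\bar H = e^{-T_p} H e^{T_p}$.  Because the projection manifold
   contains no pair de-excitations, the equations close after the
   quadratic commutator and are affine in $T'$.
5. **Response densities.** Dipoles are energy derivatives.  For the
   non-variational amplitudes this requires the Λ (de-excitation)
   equations: the pair Λ system is the transpose of the pCCD amplitude
   Jacobian; the LCC Λ system is the adjoint of the same affine map as
   the amplitudes, truncated to terms at most linear in $T'$ and
   $\Lambda'$.  The total one-particle density is the sum of the
   *relaxed* oo-pCCD response density (orbital-response terms vanish at
   the variational orbital optimum) and the *unrelaxed* LCC correlation
   density (no orbital or pair-amplitude relaxation for the correction —
   its trace is zero).  The dipole is then
   $\mu_\alpha = \sum_i Z_i R_{i,\alpha} - \mathrm{Tr}(\gamma\, d^\alpha)$
   with the frozen-core density added back.

Every derivative identity in this chain is tested against finite fields:
a response dipole must match the central difference of the corresponding
energy under a uniform field, with orbitals re-optimized only for the
orbital-optimized methods and the LCC reference (orbitals *and* pair
amplitudes) frozen at its zero-field values.

## How the working equations were established

The pCCD residual, Jacobian, and response 1- and 2-RDM blocks were
derived in the hard-core-boson picture in closed form.  The LCC equations
are implemented as a table of spatial spin-adapted contraction patterns;
their coefficients were fixed by exact least-squares against the
determinant-space map
$\langle\Phi_{\mathrm{ex}}|(H+[H,T'])e^{T_p}|\Phi_0\rangle$, evaluated by
explicit operator application on small random Hamiltonians, with a
rank-revealing selection over an enumerated space of candidate
contractions.  The complete $T_1$ sector is obtained without any separate
derivation as the first-order $T_1$-similarity dressing of the (already
verified) driver: occupied creators acquire virtual tails and virtual
annihilators occupied tails, with tensor slots arranged role-correctly
(chemists' slots 1,3 are creation, 2,4 annihilation).  The adjoint maps
and the Fock-derivative pieces of the correlation density reuse the same
term data, so the Λ equations and densities cannot drift from the
amplitude equations.  All of this is re-verified in the test suite
against the oracle on random fixtures to ~1e-10.

## Numerical choices

* **Integrals.** McMurchie–Davidson over contracted Cartesian Gaussians
  through f functions, transformed to real solid harmonics per shell
  quartet and normalized exactly against the Cartesian overlap.  The
  shipped STO-3G file is constructed from the classic three-Gaussian STO
  fits with per-element Slater exponents.  The correlation-consistent
  files are *reconstructions* (marked `.synthetic.gbs`): primitive
  exponents follow the standard tabulations, while the
  general-contraction coefficients are re-derived by a spherically
  averaged fractional-occupation atomic SCF in the uncontracted primitive
  basis — the construction principle of the originals.  Molecular RHF
  energies in the reconstructed sets match literature values to a few
  mHa (hydrogen fluoride aug-cc-pVTZ: −100.0610 Ha at 0.92 Å).
* **Cholesky decomposition** of $(\mu\nu|\lambda\sigma)$ with full
  diagonal pivoting; default threshold 1e−5, which bounds every diagonal
  reconstruction error and (by Schwarz) every element error.
* **pCCD solver:** Newton with the exact analytic Jacobian and a damping
  line search.  The amplitude space (occupied pairs × virtuals) is small
  enough that the Jacobian is cheap, and its transpose solves the pair Λ
  equations exactly — no separate Λ derivation is needed.  Degenerate
  denominators in the perturbative starting guess are shifted by 0.1 Ha.
* **Orbital optimizer:** trust-region Newton-CG on the rotation
  parameters.  Hessian–vector products are formed by forward differences
  of the fixed-amplitude analytic orbital gradient; the inner
  Steihaug-CG iteration is preconditioned by a model Hessian whose
  occupied–virtual block uses semicanonical curvatures
  $4(\varepsilon_a-\varepsilon_i)$ (eigenbases of the occupied and
  virtual Fock blocks, floored at 0.2 Ha) and whose occupied–occupied
  and virtual–virtual blocks use a floored occupation-weighted diagonal,
  and it stops on the trust boundary, which keeps warm-started scan
  points on one solution branch.  Steps that fail to decrease the energy
  shrink the radius and are retried.  Default gradient max-norm target
  1e−6; bond-length scans use 2e−3, which changes dipoles by about
  1e−3 D smoothly in $r$ (verified on hydrogen fluoride by tightening to
  2e−4, which moves turning points by ~1e−3 Å) — far below the
  turning-point resolution.
* **LCC solver:** the affine system is solved by GMRES with early-exit
  Givens residual tracking, right-preconditioned by the exact one-body
  resolvent in the semicanonical basis (orbital-energy denominators
  floored at 0.05 Ha).  The same machinery with the adjoint map solves
  the Λ equations.  Within one scan point the converged LCCD amplitudes
  seed the LCCSD solve; across geometries the amplitudes change too much
  (~25 % per 0.05 Å step) for warm starts to pay, so only orbitals are
  carried over.
* **Scans** propagate orbitals outward from a starting bond length in
  both directions; warm-started orbitals are projected against the new
  frozen core and Löwdin-orthonormalized at each geometry, which keeps
  the optimizer on the same solution branch through the dissociation
  region (oo-pCCD is known to possess multiple local minima there).
  Failed points are flagged, never interpolated.
* **Turning points** are located on the 0.05 Å grid and refined by a
  three-point quadratic fit — deliberately not a higher-order fit, which
  would overfit a sparse grid.
* **Finite-field checks** use a central difference with ε = 1e−4 a.u.;
  the field enters as $+\varepsilon\, d^\alpha$ in the core Hamiltonian,
  so $\mu_\alpha = \mu^{\mathrm{nuc}}_\alpha - dE/d\varepsilon$.

## Units and conventions

Internal quantities are atomic units (bohr, hartree); geometry I/O is in
Ångström (1 bohr = 0.52917721092 Å) and dipoles are reported in Debye
(1 a.u. = 2.5417464519 D) at the reporting layer only.  For diatomics AB
built by the scan driver, A sits at the origin and B on +z, so a
*negative* $\mu_z$ means A⁺B⁻ polarity (hydrogen fluoride: H⁺F⁻,
$\mu_z<0$ with H at the origin).  Dipole integrals default to the
coordinate origin; for charged species the dipole is origin-dependent
and the origin used is recorded in every result object.

## What the synthetic generator emulates

`make_pairing_hamiltonian()` builds the reduced-BCS pairing model —
diagonal level energies with a constant pair-scattering −G — as an
ordinary MO integral set, with the Coulomb elements chosen so that no
spurious density–density interaction arises.  It reproduces two known
limits exactly: zero correlation energy at G = 0 and the closed-form
second-order perturbation sum as G → 0.  It emulates the *pairing
physics* that pCCD is exact for; it does not emulate the one-electron
structure, shell degeneracies, or basis-set effects of real molecules,
so tests on the model certify the seniority-zero algebra, not molecular
accuracy.  Molecular accuracy is probed separately: two-electron systems
(where oo-pCCD is exact full CI in its natural orbitals) and the
hydrogen fluoride dipole surface.

## Problem sizes used in the shipped checks

The test suite works at minimal-basis and cc-pVDZ scale (2–22 basis
functions), where every solver can be compared against dense
determinant-space references.  The dipole-surface checks use hydrogen
fluoride in aug-cc-pVTZ (69 spherical AOs, F 1s frozen, 4 active pairs ×
64 virtuals); the acceptance script covers 0.75–2.50 Å with an
outcome-blind two-stage sampling — a 0.10 Å location pass over the full
range, then 0.05 Å sampling around each method's maximum so the
quadratic refinement runs on the 0.05 Å spacing — while the in-suite
check samples the two turning-point windows and the tail of the same
curves.  These sizes were chosen so that the
complete chain — integrals to Λ equations — runs comfortably on a single
CPU while still probing the physically interesting bond-breaking region.

## Known limitations

* Closed-shell singlets only; no open shells, no UHF/ROHF reference.
* Gaussian basis sets through f functions; no g functions (cc-pVQZ-level
  sets are not supported), no point-group symmetry exploitation, no
  periodic systems, no relativistic Hamiltonians.
* The LCC correction is a posteriori and unrelaxed by construction:
  orbital relaxation of the correction is excluded, which is precisely
  the contract its finite-field validation tests.
* Static embedding enters only as a user-supplied one-electron
  potential; generating such potentials is out of scope.
* At strongly stretched geometries the oo-pCCD energy surface has
  multiple local minima; the scan driver mitigates this with warm starts
  but a cold start far from equilibrium may land on a different branch.
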