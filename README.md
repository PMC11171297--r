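# paircc

Electric dipole moments from pair coupled-cluster wave functions, in R.

`paircc` is a compact electronic-structure package for closed-shell
singlet molecules built around the seniority-zero hierarchy:

* **pCCD** — pair coupled-cluster doubles, the exponential ansatz
  `|Ψ⟩ = exp(T_p)|Φ₀⟩` whose cluster operator moves whole electron pairs,
  `T_p = Σ_ia t_iᵃ a†_{aα} a†_{aβ} a_{iβ} a_{iα}`;
* **oo-pCCD** — the same ansatz with variational optimization of its
  orbital basis (the pCCD energy is not orbital-invariant, so
  occupied–occupied, occupied–virtual and virtual–virtual rotations all
  participate);
* **pCCD-LCCD / pCCD-LCCSD** — a posteriori linearized coupled-cluster
  corrections `⟨Φ_ex|(H̄ + [H̄,T′])|Φ₀⟩ = 0`, `H̄ = e^{-T_p} H e^{T_p}`,
  whose correction operator excludes the pair channel;
* **Λ equations and response densities** for all of the above: the dipole
  is the analytic field derivative,
  `μ_α = Σ_i Z_i R_{i,α} − Tr(γ d^α)`, with `γ` the sum of the relaxed
  oo-pCCD response density and the trace-free unrelaxed LCC correlation
  density.

Around that core the package carries everything needed to run from a
geometry to a dipole-moment surface on one CPU: a McMurchie–Davidson
Gaussian integral engine (through f functions, real solid harmonics),
restricted Hartree–Fock with DIIS, Pipek–Mezey localization, pivoted
Cholesky decomposition of the two-electron integrals, FCIDUMP
input/output, frozen-core folding, static one-electron embedding
potentials, bond-length scan drivers with turning-point detection, and —
deliberately first-class — brute-force determinant-space oracles (dense
FCI/DOCI, exact operator application) against which every solver is
certified.

It is intended for quantum-chemistry practitioners studying how much
dipole physics a pairing ansatz captures: pCCD treats strong (static)
correlation at mean-field cost and is exact for two-electron singlets,
while the linearized corrections add the missing dynamic correlation
without disturbing the reference — a combination whose fingerprints show
up most clearly on dipole-moment surfaces through bond breaking.

## A worked example

Lithium hydride, cc-pVDZ, lithium 1s frozen:

```r
library(paircc)

ao <- build_from_backend(diatomic("Li", "H", 1.595), "cc-pvdz")
ao <- ao_attach_cholesky(ao, 1e-5)

res <- compute_dipole(ao, "oo-pccd-lccsd", nfrozen = 1)
res$dipole
#> oo-pccd-lccsd dipole (Debye): x = -0.000, y = -0.000, z = -5.937  (|mu| = 5.937)

ff <- finite_field_dipole(ao, "oo-pccd-lccsd", axis = "z", nfrozen = 1)
abs(res$dipole$mu[3] - ff)
#> [1] 2.95e-05
```

With lithium at the origin and hydrogen on +z, the negative `μ_z` says
Li⁺H⁻ — the dipole points from the hydride towards the lithium.  The
second number is the package's standing self-check: the response dipole
(from the Λ-equation density) agrees with the finite-field derivative of
the energy to well below 10⁻⁴ D, here with the LCC reference frozen at
its zero-field orbitals and pair amplitudes, which is exactly the
unrelaxed-correction contract.

A dipole-moment surface with turning-point report:

```r
sc <- scan_dms("H", "F", seq(1.20, 1.45, 0.05), "aug-cc-pvtz",
               methods = "oo-pccd", nfrozen = 1, r_start = 1.20)
turning_point(sc$r, sc[["oo-pccd"]])
```

The shipped command-line driver wraps the same functions:

```sh
Rscript inst/cli/paircc --geometry mol.xyz --basis cc-pvdz \
        --method oo-pccd-lccd --out run
Rscript inst/cli/paircc --scan H:F:0.75:2.5:0.05 --basis aug-cc-pvtz \
        --method oo-pccd --out hf_dms
```

## Package layout

| file | contents |
| --- | --- |
| `R/integrals.R`, `src/integrals.cpp`, `R/basis.R` | Gaussian AO integrals, basis library |
| `R/scf.R` | restricted Hartree–Fock, Pipek–Mezey localization |
| `R/mo.R`, `R/cholesky.R`, `R/fcidump.R` | MO transformations, Cholesky factors, FCIDUMP I/O |
| `R/pccd.R`, `R/oopccd.R` | pCCD amplitudes/Λ/densities, orbital optimization |
| `R/lcc.R`, `R/einsum.R` | linearized CC corrections, Λ equations, correlation density |
| `R/properties.R` | dipoles, finite-field checks, scans, turning points, error statistics |
| `R/oracles.R` | determinant-space references (dense FCI/DOCI, projected residuals, pairing model) |
| `R/cli.R`, `inst/cli/paircc` | run configurations, manifests, command-line driver |

The methods vignette (`vignettes/pair-coupled-cluster-dipoles.Rmd`)
documents the models, conventions, numerical choices and limitations in
detail.
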