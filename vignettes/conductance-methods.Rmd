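---
title: "Methods: master-equation conductance of molecules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: master-equation conductance of molecules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(molcond)
```

# The model

`molcond` computes the linear-response conductance of a molecule whose
single-electron structure is given as a real symmetric Hamiltonian `H` (eV)
and overlap matrix `S` over an atomic-orbital basis, typically exported from
a semi-empirical extended-Hückel code. The physical picture is a
single-electron reduced density matrix `ρ^{ij}` in the molecular-orbital
basis, subject to three influences:

1. **Coherent evolution** under the level energies `E_i`.
2. **Phonon relaxation** through a Pauli-blocked operator whose rates
   `γ^{ij} = γ(ω_{ij}) Σ_n |Ψ_n^i|²|Ψ_n^j|²` combine the bath spectral
   density at the transition energy with the spatial overlap of the two
   orbital densities. In the absence of contacts this operator drives the
   occupations to the Fermi–Dirac distribution — the property that makes
   this master equation preferable to Lindblad or Redfield forms for
   conductance work, where the correct equilibrium is essential.
3. **Contacts** on two atomic orbitals L and R with escape strengths
   `Γ_L, Γ_R` (energy units; `Γ/ħ` is a rate), which broaden the levels by
   `Γ^i = Γ_L|Ψ_L^i|² + Γ_R|Ψ_R^i|²` and, under a bias `U`, inject the
   net current matrix `J^{ij} = (eU/2ħ)(Γ_L^{ij} − Γ_R^{ij})(D^i + D^j)`.

The occupancy response `D^i(μ)` is the derivative of the Fermi function
convolved with the level's lifetime-broadened Lorentzian density of states.
Linearizing the evolution around equilibrium produces a superoperator
`L^{ijpq}` over level pairs; the stationary condition `0 = L δρ + ħJ`
yields a closed conductance formula which `conductance_full()` evaluates
with two linear solves against `Lᵀ`. The result is the conductance of the
single-electron (single spin channel) master equation; the time-domain
oracle below confirms this convention numerically.

## Assumptions

- Weak electron–phonon coupling: the rates `γ^{ij}` must be small against
  the electronic energy scales (`transition_rates()` warns when they exceed
  the minimum level spacing).
- Linear response: conductance is defined as the `U → 0` slope; cotunneling
  and nonlinear I–V behavior are outside the model.
- Closed-shell single-electron picture: levels hold two electrons and the
  electron count is even.

# The three-mechanism decomposition

When phonon relaxation is much faster than escape through the contacts, the
full formula reduces to `G = G_LB + G_T + G_M`:

- `G_LB = (2e²/h) T` with the Breit–Wigner transmission `T`. This is the
  coherent Landauer–Büttiker channel. It is temperature independent by
  construction, and for a single symmetric resonant level it reaches the
  conductance quantum exactly (both facts are asserted in the tests).
- `G_T = (2e²/ħ) Z_L Z_R/(Z_L + Z_R)`, thermal-excitation transport. The
  weights `Z` are *rate-like* — they already carry one factor of `Γ` — so
  the prefactor uses `ħ`, not `h`. The printed asymmetry between the `h` of
  `G_LB`/`G_M` (transmission-based) and the `ħ` of `G_T` is therefore
  physical and is kept verbatim; a `harmonize_hbar` flag exists purely for
  sensitivity analysis and is clearly marked as non-standard.
- `G_M`, the mixed channel: tunneling in at one contact, thermal exit at the
  other. It inherits the Lorentzian transmissions `T_{L/R}` and therefore
  plateaus at low temperature instead of freezing out — the feature that
  reproduces the experimentally observed low-temperature saturation of
  protein currents.

The fast-relaxation reduction is validated directly: on level ladders dense
enough that every spacing lies inside the phonon cutoff, with contacts a
hundred times weaker than the relaxation rates, `conductance_full()` and the
three-term sum agree to much better than the 20% band asserted in the test
suite. Outside that regime the two can differ by orders of magnitude (the
README example shows such a case), which is not a defect but the statement
that the decomposition has a validity regime.

# Parameters

| Parameter | Units | Default | Meaning |
|---|---|---|---|
| `eta` | — | 1.46 | Ohmic coupling strength of the phonon bath |
| `hbar_omega_c` | eV | 0.0185 | bath cutoff energy |
| `T` | K | 300 | temperature; `kT = 8.617333262e-5 · T` eV |
| `Gamma_L`, `Gamma_R` | eV | 0.1 | contact escape strengths |
| `mu` | eV | midgap | chemical potential |
| window | levels | HOMO−20 … LUMO+20 | levels kept in conductance sums |
| map window | kT | 5 | levels within 5 kT of HOMO/LUMO enter `Z(r)`, `T(r)` |
| grid spacing | Å | 1.5 | map resolution; 3 Å bounding-box margin |

The bath defaults are typical protein values (the coupling can also be given
as a reorganization energy via `η = 2πE_R/ħω_c`). The ±20-level window is
enough because the Lorentzian and `cosh⁻²` kernels suppress remote levels;
`select_window()` also implements the 5 kT energy rule used for maps.

**Chemical potential.** The electron count fixes the HOMO; `μ` itself is
not determined by the input matrices. The package defaults to the midgap
value `(E_HOMO + E_LUMO)/2` — the unique symmetric choice, and one that
keeps `T(r)` finite since that map diverges if a level sits exactly at `μ`.
Every result echoes whether the default or an explicit `μ` was used
(`mu_is_default`), and `assign_levels()` accepts a `homo_shift` for cases
where the formal electron count is known to be off (e.g. spurious atoms in
a deposited structure).

# Numerical choices

- **Löwdin orthogonalization** `H̃ = S^{-1/2} H S^{-1/2}` via the
  eigendecomposition of `S`; non-positive-definite overlaps are rejected
  with the offending eigenvalue. The generalized spectrum is preserved to
  1e−9 on random instances (tested). Real-space molecular orbitals use the
  back-transformed coefficients `W = S^{-1/2} Ψ`, which are `S`-orthonormal.
- **Eigenvector sign convention**: the largest-magnitude component of each
  eigenvector is made positive (ties broken at the lowest orbital index),
  so serialized results are reproducible across LAPACK builds. Conductance
  is invariant under rotations within degenerate subspaces (tested).
- **`γ(0)`** is set to the analytic limit `η·kT` of the Ohmic form, and the
  whole spectral density is also available in log space, where the detailed
  balance identity `log γ(ω) − log γ(−ω) = −ħω/kT` holds exactly even when
  the linear value underflows (absorption across 1 eV at 10 K is `e^-1160`).
- **Tilded rates** `γ̃^{ij} = γ^{ij}(1−F_i)/(1−F_j)` are evaluated in log
  space via `log(1−F) = log plogis((E−μ)/kT)`; temperatures below 1 K are
  floored to 1 K in these denominators unless `allow_low_T` is set.
- **`D^i` quadrature**: substituting `E = E_i + (Γ^i/2)tanθ` flattens the
  Lorentzian to a uniform measure; the remaining thermal peak is bracketed
  by a geometric ladder of subdivision points so the adaptive rule resolves
  it at any ratio of `Γ` to `kT` (relative tolerance 1e−9). For
  `Γ < 1e−7·kT` the delta-function limit `f(E_i, μ)` is exact to rounding.
- **Superoperator layout**: level pairs are flattened row-major,
  `(i,j) → (i−1)·N_w + j`, matching `kronecker()`; all tests pin this
  convention. The four printed terms are kept as separate components for
  term-by-term testing. The dense superoperator caps at `N_w ≤ 80`
  (`6400²` complex entries); beyond that the three-term path is the tool.
- **Conductance contraction**: the formula weights each term with `D^p`,
  which is asymmetric in the pair `(p,q)`. The antisymmetric part is purely
  imaginary in the contraction, so the real part equals the exactly-real
  symmetrized-`D` contraction; `conductance_full()` verifies this identity
  at 1e−9 on every call and reports the real part. Near-singular
  superoperators get a Tikhonov ridge of `1e−12·max|L|` with a warning.
- **Thermal weights in log space**: `Z_{L/R}` and the branching ratios are
  assembled with log-sum-exp, so the `G_M` plateau at 10 K is reachable
  even when `Z ~ e^{-Δ/2kT}` underflows.
- **Time-domain oracle**: the nonlinear relaxation uses `lsoda` with
  chunked doubling until `max|dρ/dt| < 1e−12`; the linear-response steady
  state is a single uninterrupted `lsoda` run over geometrically spaced
  output times, accepting the first state whose residual `‖Lδρ + ħJ‖`
  drops below 1e−9 of the drive, then requiring agreement with the direct
  linear solve to 1e−8. Internal time is `ħ/eV ≈ 0.658 fs`.
- **Percentile isovalues** use the linear-interpolation quantile (R type 7)
  of the strictly positive voxels; top 5% for `Z(r)`, top 20% for `T(r)`.
- **Volumetric output**: Gaussian cube (default; coordinates converted to
  Bohr as the format requires) and OpenDX (Angstrom); both round-trip to
  better than float32 precision (tested).

# What the synthetic generators emulate

`make_model()` produces collinear tight-binding systems: uniform chains,
donor–bridge–acceptor (dba) wires, seeded disordered wires, and two-level
systems. Defaults place a ~1 eV HOMO–LUMO gap straddling `μ` (a protein-like
frontier scale) at 1.5 Å site spacing so distance sweeps span tens of Å.
`make_toy_sto_system()` adds real-space structure: one 1s Slater orbital per
atom (ζ in 1/Å with an explicit Bohr-conversion flag), the closed-form
1s–1s overlap, and a Wolfsberg–Helmholz Hamiltonian `H_rs = K·S_rs(H_rr +
H_ss)/2`, `K = 1.75` — the standard semi-empirical rule, used here as a
generic toy parameterization.

These toys reproduce the qualitative transport phenomenology: exponential
`G_LB(d)` decay across a barrier, temperature-independent `G_LB`,
Arrhenius-activated `G_T` with slope `gap/2`, a finite `G_M` plateau at
10 K, and a thermal/mixed crossover temperature. What they do *not* emulate:
multi-orbital valence shells, heme cofactors, realistic disorder statistics,
or the ~10⁴-orbital scale of real protein nanowires — so passing tests
validate the *formulas and algorithms*, not any statement about a specific
protein.

Two modeling points deserve emphasis:

- **Distance decay needs spatially decaying states.** The Breit–Wigner
  transmission is an incoherent sum over levels, so extended band states of
  a clean chain contribute a distance-independent background; the textbook
  exponential decay emerges from states that decay between the contacts
  (evanescent frontier states across a barrier, or localized states in
  disordered media — the situation in proteins). The β-fit checks therefore
  use the frontier-level window of a dba wire, where the decay constant has
  the closed form `β = 2·ln λ / a`, `t(λ + 1/λ) = Δ`, recovered by the fit
  to a few percent.
- **The oracle needs a damping path for every excited mode.** With the
  protein-like 18.5 meV bath cutoff, transitions across eV-scale gaps are
  exponentially silenced, so a dba wire's bridge coherences relax only
  through the contacts — physically fine, but the time-domain route then
  needs ~10⁷ internal time units. The oracle-equivalence tests therefore
  use a bath cutoff spanning the level spacings (2 eV) for dba systems;
  the equivalence being verified holds for any bath.

# Known limitations

- Single-particle, linear-response only: no cotunneling, no many-body
  correlation, no finite-bias I–V curves.
- The dense superoperator limits the exact route to ~80 levels; the
  three-term path scales to arbitrary windows but inherits its
  fast-relaxation assumption.
- Slater orbitals are implemented for `l ≤ 1` (s and p); d-orbital bases
  would need an extension of the real spherical harmonics.
- The HDF5 container sometimes used for matrix exchange is not supported;
  the plain-text matrix format plus a TSV orbital-metadata table is the
  interchange path.
- `T = 0` is handled as a limit (emission-only bath; thermal weights return
  exact zeros with a flag), not as a regime where the linearized formulas
  are meaningful.

# Problem sizes used in the validation suite

Random Hamiltonians up to N = 50 for the orthogonalization properties;
master-equation oracles at N_w ≤ 6; the brute-force superoperator
contraction at N_w = 4 (the naive loop is O(N_w⁶)); distance sweeps on
14-site wires; maps on 3–5-atom Slater toys at 1.5 Å resolution. These
sizes keep the full suite and the acceptance script in the seconds range
while exercising every code path at tolerances far tighter than the
sizes' rounding noise.
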