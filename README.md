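# molcond

Linear-response electronic conductance of molecules from a quantum master
equation, with protein nanowires in mind.

Single-molecule transport experiments on proteins show conductances that stay
finite down to tens of Kelvin and decay only weakly with distance — behavior
that neither the coherent Landauer–Büttiker picture nor semiclassical
electron-transfer theory captures alone. `molcond` implements a
Liouville-master-equation treatment that interpolates between those limits:
electrons in a molecule exchange energy with an Ohmic phonon bath that drives
the level occupations toward the Fermi–Dirac distribution, while two contact
orbitals leak electrons to electrodes. The package is aimed at computational
biophysicists and molecular-electronics researchers who have a semi-empirical
(e.g. extended-Hückel) Hamiltonian `H` and overlap `S` for their molecule and
want contact-to-contact conductances and spatial conductivity maps.

## The model

The reduced single-electron density matrix `ρ^{ij}` in the molecular-orbital
basis evolves under

```
dρ^{ij}/dt = -(i/ħ)(E_i - E_j) ρ^{ij}
             - (1/2ħ) Σ_r (Γ^{ir} ρ^{rj} + ρ^{ir} Γ^{rj})
             + R^{ij}(ρ) + J^{ij}
```

where `R(ρ)` is a Pauli-blocked relaxation operator built from phonon
transition rates `γ^{ij} = γ(ω_ij) Σ_n |Ψ_n^i|² |Ψ_n^j|²` with an Ohmic
spectral density `γ(ω) = η ħω e^{-|ω|/ω_c} / (e^{ħω/kT} - 1)`, and `J` is the
net injection from contacts biased by a small voltage `U`. Linearizing around
equilibrium gives a superoperator `L^{ijpq}` whose inversion yields the exact
linear-response conductance between contact orbitals L and R
(`conductance_full()`), evaluated by linear solves, never a dense inverse.

For large systems the package provides the fast-relaxation decomposition into
three mechanisms (`three_term_conductance()`):

- `G_LB = (2e²/h) T` — coherent tunneling with Breit–Wigner transmission
  `T = Σ_k Γ_L Γ_R |Ψ_L^k|²|Ψ_R^k|² / ((μ-E_k)² + (Γ^k/2)²)`;
- `G_T = (2e²/ħ) Z_L Z_R / (Z_L + Z_R)` — thermally activated transport with
  excitation weights `Z_{L/R} = Σ_k Γ_{L/R} |Ψ^k|² / (4kT cosh²((μ-E_k)/2kT))`;
- `G_M = (e²/h) [Z_L T_R + Z_R T_L] / (Z_L + Z_R)` — a mixed
  tunneling-then-thermal channel that survives at low temperature.

Spatial structure is visualized through the coupling-independent maps
`Z(r) = Σ_k |Ψ^k(r)|² / cosh²((μ-E_k)/2kT)` and
`T(r) = Σ_k |Ψ^k(r)|⁴ / (μ-E_k)²` on 3-D grids (`z_map()`, `t_map()`),
written as Gaussian cube or OpenDX files for VMD.

A time-domain integrator of the full nonlinear master equation
(`relax_to_equilibrium()`, `linear_response_G()`) serves as an independent
oracle for every approximation in the package, and synthetic generators
(`make_model()`, `make_toy_sto_system()`) provide chains, donor-bridge-
acceptor wires and Slater-orbital toys with known physics.

## Worked example

```r
library(molcond)

rs  <- make_model("dba_wire", n_sites = 6, t = 0.25, gap = 1, barrier = 3)
es  <- build_structure(rs, rs$n_electrons)   # Löwdin + eigensolve + midgap mu
es
#> electronic_structure: 6 levels ( lowdin basis )
#>   HOMO 1 at -0.5179 eV, LUMO 2 at 0.4750 eV, gap 0.9929 eV
#>   mu = -0.0214 eV (midgap default)

cp  <- contact_pair(1, 6, Gamma_L = 1e-3, Gamma_R = 1e-3)  # eV
g   <- three_term_conductance(es, cp, kT = kT_eV(300))
g
#> conductance_result (three_term): G = 0.154876 nS  (3.99779e-06 e^2/h)
#>   G_LB   = 1.34712e-07 nS
#>   G_T    = 4.27487e-05 nS
#>   G_M    = 0.154833 nS

full <- conductance_full(es, cp, bath_spec(T = 300, hbar_omega_c = 2))
full$G_nS
#> [1] 1.017663e-07
```

The three components say how the 0.15 nS flows in the fast-relaxation
picture: coherent tunneling through the 3 eV bridge is negligible (`G_LB`),
thermal excitation across the ~1 eV gap is rare at 300 K (`G_T`), and the
dominant channel tunnels into a frontier orbital and exits thermally
(`G_M`). The exact superoperator result is far smaller here because this
junction is *not* in the fast-relaxation regime — with Γ = 1 meV the escape
outpaces the phonon relaxation, so the thermal channels never fill; the
decomposition is the right tool only when relaxation is fast (the regime is
checked explicitly in the test suite).

A command-line front-end wraps the same functions:

```sh
Rscript exec/conduct make-model --kind dba_wire --n 6 --out toy
Rscript exec/conduct approx --matrices toy_H.txt toy_S.txt --meta toy_meta.tsv \
        --electrons 2 --contacts 1 6 --gamma 0.001 0.001 --temp 300
Rscript exec/conduct map --matrices toy_H.txt toy_S.txt --meta toy_meta.tsv \
        --electrons 2 --kind t --out toy.cube
```

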