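# polyenedyn

Mixed quantum–classical simulations of photoexcited linear polyenes and
carotenoids in R.

Carotenoids absorb blue-green light into the bright `1^1Bu+` exciton and
then convert, within tens of femtoseconds, into dark covalent singlets —
above all the triplet-pair `2^1Ag-` state that gates singlet fission. The
process couples strong electronic correlation to fast nuclear motion, which
rules out both mean-field electronic structure and frozen-nuclei models.
`polyenedyn` implements a complete simulation chain for this problem at the
level of the extended Hubbard–Peierls (UV–Peierls) model:

```
H = -Σ_n β_n T̂_n + U Σ_n n̂_{n↑} n̂_{n↓} + V Σ_n (n̂_n − 1)(n̂_{n+1} − 1)
    + Σ_n ε_n (n̂_n − 1) + λ Ŝ² + (K/2) Σ_n (u_{n+1} − u_n)²
```

with bond hoppings tied to the geometry through
`β_n = β₀ − α (u_{n+1} − u_n)`. The default parametrisation is the
carotenoid set `U = 7.25 eV`, `V = 3.25 eV`, `β₀ = 2.4 eV`,
`α = 4.593 eV/Å`, `K = 46 eV/Å²`. The site potentials `ε_n` break the
particle-hole and C₂ symmetries of the ideal backbone (donor/acceptor
substituents) and are what allow bright→dark internal conversion at all.

What the package provides:

* **Exact oracle** — full sector-resolved exact diagonalization, Krylov
  propagation, symmetry labels (C₂ and particle-hole), dipole operator,
  entanglement entropies, for chains up to ~10 sites. Every renormalised
  method in the package is tested against it.
* **Static DMRG** — two-site density-matrix renormalization group with
  infinite-lattice warm-up, finite sweeps, Davidson diagonalization,
  multi-state targeting for excited states, Hellmann–Feynman forces and
  geometry relaxation (Peierls dimerization comes out, not in).
* **Adaptive tDMRG** — second-order Suzuki–Trotter time evolution with exact
  two-site link propagators, Schmidt truncation and wavefunction mapping.
* **Ehrenfest dynamics** — damped velocity-Verlet nuclei on the mean
  Hellmann–Feynman force, interleaved with the electronic propagation
  (10 Trotter steps of `δt = 10⁻³ fs` per nuclear step of `Δt = 10⁻² fs`).
* **Lanczos-DMRG transient absorption** — dipole-seeded Krylov spectra with
  lower-state projection and the 25/25/50 multi-state targeting protocol
  (evolving state / eigenstates up to the source / five Lanczos vectors).
* **Population analysis** — adiabatic vs diabatic populations, ionicity
  classification of ionic vs covalent states, a quasi-stationary two-level
  reduction with an oscillation-free "classical" yield, and a Landau–Zener
  scan over the symmetry-breaking strength ζ.
* **Density fitting** — projected-gradient fitting of `ε_n` to target
  (e.g. Mulliken) site densities under a box constraint `|ε_n| ≤ ε_max`.

Results come back as tibbles with `tidy()`, `glance()` and `autoplot()`
methods, so everything composes with the usual dplyr/ggplot2 workflow.

## Worked example

Relax the hexatriene-like `N = 6` ground state, prepare the vertical bright
excitation, and scan the Landau–Zener crossover:

```r
library(polyenedyn)

p <- model_params(n_sites = 6, lambda_spin = 2)
rel <- relax_geometry(p)
rel$chain$bond_hoppings
#> [1] 3.2202 2.7140 3.1750 2.7140 3.2202
```

The alternating hoppings are the Peierls-dimerized ground-state geometry
(total energy −13.7395 eV after 76 relaxation steps). At that geometry the
diabatic states of the symmetric Hamiltonian are

```r
init <- prepare_initial_state(p)
init$diabats[, c("state", "energy", "label", "ionicity")]
#>   state  energy  label ionicity
#> 1     0 -13.739 1^1Ag-   1.1467
#> 2     1  -8.763 1^1Bu+   1.7046
#> 3     2  -8.216 2^1Ag-   0.9468
#> 4     3  -6.829 2^1Bu+   0.9285
#> 5     4  -6.820 1^1Bu-   0.8142
#> 6     5  -5.673 1^1Ag+   1.5952
```

The bright `1^1Bu+` state sits below the dark `2^1Ag-` state vertically and
carries the larger ionicity (1.70 vs 0.95), exactly the configuration from
which internal conversion proceeds: during excited-state relaxation the two
diabats cross. `prepare_initial_state()` picks the adiabat with maximal
`1^1Bu+` projection (here `S1`, overlap 1 since `ε = 0`).

Scanning the symmetry-breaking strength reveals the Landau–Zener crossover
at the first passage through the crossing (probe at 10 fs):

```r
fxz <- make_fixture("lz_mini")
lz_scan(fxz$params, zeta = c(0.1, 1, 2), probe_time = 10, engine = "exact")
#>   zeta    p_s1  p_s2 p_classical min_gap
#> 1  0.1 0.00466 0.995       0.008  0.0291
#> 2  1.0 0.32550 0.674       0.387  0.1516
#> 3  2.0 0.78553 0.214       0.566  0.3244
```

At weak symmetry breaking the system shoots through the barely-avoided
crossing diabatically (it stays `1^1Bu+`, so it ends up on `S2`:
nonadiabatic passage). At strong breaking the gap is wide (0.32 eV), the
passage is adiabatic, the system stays on `S1` while its character turns
`2^1Ag-`, and the classical dark-state yield `p_classical` rises — the
internal-conversion mechanism in miniature.

Trajectories (`run_trajectory()`), transient absorption spectra
(`transient_spectrum()`) and density fits (`projected_gradient_fit()`)
follow the same pattern; see the methods vignette
(`vignettes/polyene-dynamics.Rmd`) for the model assumptions, numerical
choices and limitations, and `inst/cli/polyenedyn.R` for a shell front end
(`relax`, `evolve`, `spectrum`, `lzscan`, `fit-eps`, `fixtures`).

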