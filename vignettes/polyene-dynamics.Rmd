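---
title: "Models and methods behind polyenedyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind polyenedyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the model, the
numerical machinery, the parameters that matter, the design choices made
where several defensible options existed, and the limits of what the tests
demonstrate.

## The model

The π-electrons of a conjugated polyene backbone are described by the
extended Hubbard (UV) model — on-site repulsion `U`, nearest-neighbour
repulsion `V`, hopping `β` — coupled to classical nuclei through the
Peierls mechanism: each bond's hopping depends linearly on its stretch,

```
β_n = β₀ − α (u_{n+1} − u_n),
```

and the lattice carries a harmonic elastic energy
`K/2 Σ (u_{n+1} − u_n)²`. The full electronic Hamiltonian is

```
H = H_UVP + Σ_n ε_n (n̂_n − 1) + λ Ŝ².
```

Key representation choices, and why:

* **Nearest-neighbour Coulomb term.** `V Σ (n̂_n − 1)(n̂_{n+1} − 1)` is the
  only nearest-neighbour density form that is *exactly* particle-hole
  symmetric on an open chain; with plain `n̂ n̂` the chain ends spoil the
  symmetry, and particle-hole parity is the label that separates ionic
  (bright) from covalent (dark) states. The `U` term is written as
  `U Σ n̂_↑ n̂_↓`, which is particle-hole symmetric within any fixed-filling
  sector. The geometry dependence of `V` is neglected; its effect on
  excited-state energies is far smaller than the bond-order coupling `α`.
* **Symmetry-breaking term.** `Σ ε_n (n̂_n − 1)` uses the charge-neutral
  convention; replacing `n̂ − 1` by `n̂` only adds the constant `Σ ε_n` at
  fixed electron count. The sign convention of the Peierls coupling is
  immaterial at the spectrum level: flipping `α` relabels the two degenerate
  dimerization patterns.
* **Elastic energy as a scalar.** The `K` term is carried as a scalar shift
  of the electronic Hamiltonian, so state energies are Born–Oppenheimer
  totals and geometry relaxation can compare energies across geometries
  directly. The bond-stretch (rather than absolute-displacement) form is
  fixed by the phonon scale: with `K = 46 eV/Å²` and `m = 13 amu` the
  dimerization mode comes out at `ħ√(4K/m) ≈ 0.24 eV`, the C=C stretch
  scale; the on-site form would give half that.
* **Spin penalty.** `λ Ŝ²` commutes with every other term, leaves singlets
  untouched, and shifts a spin-`S` multiplet by `λ S(S+1)`. It is a window
  knob, not a physical parameter: λ must exceed half the spread between the
  lowest triplet and the highest singlet of interest. The package default
  is 1 eV; the N = 6 examples and tests use 2 eV because the lowest triplet
  of the short chain otherwise intrudes between the second and third
  singlet. Dynamics are unaffected either way (the evolving states are
  singlets, annihilated by `Ŝ²`).
* **Half filling** (one π-electron per conjugated carbon) is assumed
  throughout, and open boundaries: sites 1..N, bonds 1..N−1.
* **Units.** Energies in eV, lengths in Å, times in fs, `ħ = 0.6582 eV fs`;
  masses in amu with 1 amu = 103.64 eV fs²/Å².

`model_params()` validates all of this (even N, positive λ, `Δt` an integer
multiple of `δt`, `|ε| ≤ ε_max`). The printed carotenoid parametrisation
(`U = 7.25`, `V = 3.25`, `β₀ = 2.4`, `α = 4.593`, `K = 46`) is the default.

## The exact oracle

`sector_basis()` enumerates occupation configurations at fixed electron
count and spin projection; Jordan–Wigner modes are packed site-major so a
configuration word read in base 4 is the chain's local-state string, and a
sector vector embeds into the full Fock vector by index arithmetic alone.
All fermionic signs come from one primitive (bit-counting below a mode), so
the oracle Hamiltonian, the C₂ reversal operator, the particle-hole map and
the spin-raising structure share a single sign convention that the
renormalised machinery is tested against.

Parity labels need a global anchor because operator conventions fix parity
only up to a state-independent sign: the package multiplies the raw
particle-hole parity by an `N`-dependent anchor chosen so the half-filled
symmetric ground state is `1^1Ag-`, the standard experimental-community
convention. Degenerate eigenpairs are rotated within their subspace to
diagonalize the symmetry before labelling.

Propagation uses Lanczos (Krylov) exponentiation of the sparse sector
Hamiltonian with full reorthogonalization; the Hamiltonian's sparsity
pattern is cached per basis so trajectory re-assembly at each geometry is a
vector operation.

## Static DMRG

The engine is the classic two-site algorithm: infinite-lattice warm-up
growing blocks from both chain ends, then finite sweeps, with the
superblock solved by a block Davidson method (residual tolerance 1e-9,
diagonal preconditioning, thick restarts) and the growing block truncated
through the eigenbasis of the targeted reduced density matrix. Internally
the blocks are kept as a matrix-product factorization with MPO
environments — mathematically the same renormalised-operator algebra, and
the asserted contracts (Schmidt/density-matrix truncation, discarded
weight, wavefunction-mapped initial guesses, variational monotonicity) are
the classical ones.

Choices worth recording:

* **Quantum numbers by penalty.** The renormalised basis spans all
  occupation sectors. Instead of symmetry-resolved block bookkeeping the
  working MPO carries `w_N (N̂ − N_e)²` with `w_N = 20 eV`: identically zero
  on the physical sector, pushing every other sector up by at least `w_N`.
  The spin penalty plays the same role for multiplets. Reported energies
  are therefore unbiased for the targeted states.
* **Truncation semantics.** `cutoff = 0` means "keep everything up to
  `max_states`", including numerically zero-weight directions — this is
  what makes warm-up exact in the no-truncation limit and keeps complete
  local bases complete. A positive cutoff discards the smallest density
  eigenvalues up to that total weight.
* **Warm-up seeding.** Each growth step seeds Davidson with the previous
  step's states projected onto the new blocks and expanded over the fresh
  sites, plus unit vectors on the smallest effective-Hamiltonian diagonal
  entries. The latter matter: a structured guess set can span an exact
  *excited* invariant subspace, and a Davidson iteration started inside it
  converges there with a clean residual.
* **Excited states** are obtained by state-averaged multi-state targeting
  (equal weights `κ_i` by default) with k lowest eigenpairs per superblock
  solve; orthogonality is then automatic. Symmetry labels for small chains
  are assigned post hoc against the oracle operators.
* **Convergence**: sweeps stop when the ground energy moves by less than
  1e-8 eV per sweep, or after 8 sweeps.
* **Forces and relaxation.** Hellmann–Feynman forces are analytic in the
  bond-order expectations; both force channels telescope so the total force
  vanishes identically. Relaxation is preconditioned steepest descent
  `u ← u + f/(2K)` to `max|f| < 1e-4 eV/Å`, with step halving as a fallback
  against oscillation, starting from the undistorted chain.

## Adaptive time-dependent DMRG

Time evolution applies the exact 16-dimensional bond propagators
`exp(−i h_n δt/2ħ)` in a left-to-right then right-to-left sweep — a
palindromic factorization, hence second order in `δt` globally (the halving
test in the suite measures the ratio ≈ 4 directly). Truncation after every
gate is the same Schmidt machinery as statics; the state is renormalised
after every full step and the drift logged rather than silently absorbed.
The spin penalty is omitted from the propagator: it commutes with the full
Hamiltonian and annihilates the singlet states being propagated.

## Ehrenfest dynamics

Nuclei follow `du/dt = p/m`, `dp/dt = f − γp` under the damped velocity
Verlet discretisation (half-kick, drift, implicit half-kick dividing by
`1 + γΔt/2`). Per nuclear step `Δt` the electronic state advances by
`Δt/δt` Trotter steps (10 by default) at the new geometry, and the closing
half-kick uses the force of the evolved state — the mean-field (Ehrenfest)
force. The mean force is removed each step and the geometry re-centred:
both channels conserve total force exactly in theory, but truncation can
leave a small centre-of-mass residue that would otherwise accumulate.

The nuclear mass (13 amu, a CH unit) and damping (0.005 fs⁻¹ default; the
Landau–Zener fixture uses 0.05 fs⁻¹) are modelling choices — with them,
absolute relaxation time scales are indicative only, and conservation
tests run at `γ = 0`. Temperature is absent by construction: the relevant
electronic and phonon quanta dwarf `k_B T` on these time scales.

The photoexcited initial condition is the adiabat with the largest squared
projection onto the bright `1^1Bu+` diabat at the relaxed ground-state
geometry — a vertical, dipole-allowed excitation, and the choice that keeps
the mean-field approximation closest to single-surface motion. Ambiguity
(two adiabats within 0.01 of each other) is reported and resolved to the
lower state.

## Populations, the two-level picture and the Landau–Zener scan

Adiabats (eigenstates of the full `H`) and diabats (eigenstates of the
symmetric UV–Peierls `H`) are recomputed at the instantaneous geometry at
each analysis stride — their defining operator depends on `β_n(t)`, so a
frozen reference basis would drift. All reported probabilities are squared
overlap moduli; no phase convention enters. Default stride: every 50
nuclear steps (0.5 fs), a cost choice, with the 6 lowest states tracked.

When two adiabats carry the evolving state, the diabatic populations
oscillate at the instantaneous adiabatic gap over ħ while the adiabatic
amplitudes are quasi-stationary. Averaging over full periods leaves the
"classical" yield

```
P_classical(φ) = Σ_i |ψ_i|² P(S_i; φ),
```

the incoherent mixture of adiabat-on-diabat weights; the synthetic
two-level test verifies both the averaging identity and the gap-frequency
property, and the exact two-level closure makes the φ₁ and φ₂ yields sum
to one. With one populated adiabat it reduces to that adiabat's overlap
with the target diabat. The function flags (but still reports) cases where
the two contributing adiabats hold less than 90% of the state.

The Landau–Zener scan multiplies a base `ε` profile by ζ and probes the
populations after one passage through the crossing. The `lz_mini` fixture
is an engineered six-site miniature of the carotenoid mechanism: `V = 3.25
eV` puts the bright diabat below the dark one vertically while the ordering
flips along the excited-state relaxation path, so the crossing is reached
within ~6 fs; the base profile is a donor–acceptor ramp of amplitude 0.6
eV (breaking both C₂ and particle-hole symmetry, matrix element ≈ 0.02 eV
per unit ζ between the two diabats at the seam), and the probe at 10 fs
catches the first passage before the damped geometry re-crosses. On this
fixture the scan shows the full crossover: diabat-following at ζ = 0.1
(final `P(S2) ≈ 1`), adiabat-following at ζ = 2 (final `P(S1) ≈ 0.79`),
with a strictly positive minimum gap growing linearly in ζ. What the
desk-scale twin does *not* show is the quantitative carotenoid yield curve:
that lives at N = 18 with the fitted substituent potentials of a real
molecule, beyond the oracle-verifiable regime this package targets.

## Lanczos-DMRG transient absorption

The spectrum machinery follows the standard Krylov route: seed
`|g₀⟩ ∝ (1 − Σ_{n ≤ i} |n⟩⟨n|) μ̂ |S_i⟩`, three-term Lanczos recursion with
full reorthogonalization (chains here are ≤ 60 vectors, so ghost
suppression is cheap), line positions from the tridiagonal eigenvalues and
line strengths from the squared first eigenvector components times the
squared seed norm. Projecting out *all* states up to and including the
source keeps the source the lowest state of the Krylov space and restricts
the result to stimulated absorption. Intensities are reported relative to
the lowest retained line, which removes the dipole length scale (the
undistorted spacing 1.4 Å only enters absolute strengths).

Inside a dynamical run the protocol pauses the propagation and performs a
static multi-state targeting sweep whose density-matrix ensemble holds the
evolving state (25%), the eigenstates up to and including the source
(25%, shared equally — the source pool includes `S_i` itself), and the
first five Lanczos vectors (50%). The per-vector share of the Lanczos
weight redistributes the spectral weights of the Krylov eigenstates
through the squared tridiagonal eigenvector components — the natural
transcription of "weighted proportionately by their contribution to the
spectrum" into per-vector numbers. Five vectors are targets; the spectrum
itself is evaluated afterwards with a longer chain (default 30, the
acceptance study uses 60) in the converged targeted basis, where the extra
vectors cost almost nothing. The evolving state is never modified, so
dynamics resume from the saved renormalised basis by construction. A
truncation error drifting above the run's cutoff during targeting flags
the spectrum as low-confidence (`max_discarded` attribute).

## Fitting the symmetry-breaking potentials

`projected_gradient_fit()` minimises `E(ε) = ‖d_opt − d(ε)‖` where `d(ε)`
are ground-state site densities, under `|ε_n| ≤ ε_max` (default 1 eV — an
unconstrained fit drifts into unphysical potential gradients that mix the
ionic and covalent manifolds). The gradient is forward finite differences
(step 1e-3 eV, one ground-state solve per site — the solves use warm
Davidson iterations, not dense diagonalization), the line search backtracks
by factors of 0.5 from 0.2 eV, every trial point is clipped to the box, and
the start is `ε = 0`, the centre of the box. Convergence is measured by the
coefficient of determination `r² = 1 − SS_res/SS_tot`, the reading under
which a published fit quality like `r² = 0.92` is meaningful (a
coefficient-of-variation reading would not approach 1 for good fits).
Target densities are mean-shifted to one electron per site before fitting
(charge neutrality). The fit's acceptance surface is parameter recovery:
densities generated from a known in-box `ε*` are refit to `r² > 0.99`.

## Problem sizes and what the tests show

The test and acceptance suites run at the sizes where the exact oracle is
available and everything finishes on a laptop core: N = 4–6 for
oracle-equivalence of statics, dynamics, spectra and populations; N = 8
for ground-state DMRG at M = 64; N = 10 for the truncation study
(cutoffs 1e-4 → 1e-8 under an M = 64 cap, energy flattening by more than a
factor of five per decade pair); 10 fs trajectories at `δt = 10⁻³ fs`.
These are the package's chosen study conditions, small-scale twins of
production runs at carotenoid lengths. Passing them demonstrates
correctness of the algorithms and their error scaling — not the
convergence of any particular N = 18 observable, which must be established
per run from the logged discarded weights and entropies (the
entropy-to-states relation `m = e^S` gives the floor for the basis size;
production-grade accuracy requires far more than the floor).

## Other limitations

* Long-range (PPP/Ohno) Coulomb tails are outside the model by design; the
  UV parametrisation compensates at the observable level.
* The nuclear dynamics are mean-field Ehrenfest: no surface hopping, no
  decoherence correction, no thermal noise.
* The exact engine stops near 10 sites (sector dimensions ~6e4); beyond
  that the renormalised engines run but their validation becomes
  self-referential (discarded weight, variational monotonicity).
* State/geometry checkpoints are RDS containers; portable outputs
  (trajectories, spectra, site values, configs) are plain text with schema
  headers.
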