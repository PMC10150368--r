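# UV-Peierls lattice model: parameters, chain geometry, local operator algebra,
# bond Hamiltonians and Hilbert-space bookkeeping.

#' Model and run parameters for the UV-Peierls polyene Hamiltonian
#'
#' Collects every Hamiltonian, nuclear and numerical parameter in one
#' validated record. The defaults are the Chandross-Mazumdar-derived
#' parametrisation for carotenoid-length polyenes: `u_coulomb = 7.25` eV,
#' `v_coulomb = 3.25` eV, `beta0 = 2.4` eV, `spring_k = 46` eV/A^2 and
#' `alpha = 4.593` eV/A.
#'
#' @param n_sites Number of conjugated carbon sites `N` (positive even integer).
#' @param u_coulomb On-site Coulomb repulsion `U` (eV).
#' @param v_coulomb Nearest-neighbour Coulomb repulsion `V` (eV).
#' @param beta0 Undistorted hopping integral `beta` (eV, > 0; enters the
#'   Hamiltonian as `-beta_n` times the bond-order operator).
#' @param alpha Electron-nuclear coupling (eV/A); bond hopping is
#'   `beta_n = beta0 - alpha * (u[n+1] - u[n])`.
#' @param spring_k Nuclear spring constant `K` (eV/A^2) of the harmonic
#'   bond-stretch elastic energy `K/2 * sum (u[n+1]-u[n])^2`.
#' @param eps On-site potentials `eps_n` (eV), length `n_sites`. These break
#'   particle-hole and C2 symmetry; the Hamiltonian term is
#'   `sum eps_n (n_n - 1)` (charge-neutral convention).
#' @param lambda_spin Spin penalty `lambda` (eV, > 0) multiplying total S^2,
#'   used to project high-spin states out of the low-energy window.
#' @param gamma Phenomenological nuclear damping rate (1/fs).
#' @param nuclear_mass Nuclear mass per site (amu); 13 amu is a CH unit.
#' @param dt_trotter Suzuki-Trotter electronic time step `dt` (fs).
#' @param dt_nuclear Nuclear (Verlet) time step `Dt` (fs); must be an integer
#'   multiple of `dt_trotter`.
#' @param trunc_cutoff Target DMRG discarded weight per truncation.
#' @param max_states Cap on retained DMRG block states `M_S`.
#' @param eps_max Box bound on `|eps_n|` (eV) used by validation and by the
#'   projected-gradient fit.
#' @param lattice_spacing Undistorted C-C spacing (A), used only to place the
#'   dipole operator; normalised spectra do not depend on it.
#'
#' @return An object of class `uvp_params` (a validated named list).
#' @examples
#' p <- model_params(n_sites = 6)
#' p$v_coulomb
#' @export
model_params <- function(n_sites,
                         u_coulomb = 7.25,
                         v_coulomb = 3.25,
                         beta0 = 2.4,
                         alpha = 4.593,
                         spring_k = 46,
                         eps = rep(0, n_sites),
                         lambda_spin = 1.0,
                         gamma = 0.005,
                         nuclear_mass = 13,
                         dt_trotter = 1e-3,
                         dt_nuclear = 1e-2,
                         trunc_cutoff = 1e-10,
                         max_states = 400L,
                         eps_max = 1.0,
                         lattice_spacing = 1.4) {
  stopifnot(length(n_sites) == 1, n_sites >= 2, n_sites %% 2 == 0)
  eps <- as.numeric(eps)
  if (length(eps) == 1) eps <- rep(eps, n_sites)
  if (length(eps) != n_sites) {
    stop("`eps` must have one on-site energy per site (length ", n_sites, ")")
  }
  vals <- c(u_coulomb, v_coulomb, beta0, alpha, spring_k, eps, lambda_spin,
            gamma, nuclear_mass, dt_trotter, dt_nuclear, trunc_cutoff, eps_max)
  if (!all(is.finite(vals))) stop("all model parameters must be finite")
  if (lambda_spin <= 0) stop("`lambda_spin` must be > 0")
  if (any(abs(eps) > eps_max + 1e-12)) {
    stop("|eps_n| must not exceed `eps_max` = ", eps_max, " eV")
  }
  if (dt_trotter <= 0 || dt_nuclear <= 0) stop("time steps must be positive")
  ratio <- dt_nuclear / dt_trotter
  if (abs(ratio - round(ratio)) > 1e-8) {
    stop("`dt_nuclear` must be an integer multiple of `dt_trotter`")
  }
  structure(
    list(
      n_sites = as.integer(n_sites), u_coulomb = u_coulomb,
      v_coulomb = v_coulomb, beta0 = beta0, alpha = alpha,
      spring_k = spring_k, eps = eps, lambda_spin = lambda_spin,
      gamma = gamma, nuclear_mass = nuclear_mass,
      dt_trotter = dt_trotter, dt_nuclear = dt_nuclear,
      trunc_cutoff = trunc_cutoff, max_states = as.integer(max_states),
      eps_max = eps_max, lattice_spacing = lattice_spacing
    ),
    class = "uvp_params"
  )
}

#' @exportS3Method base::print
print.uvp_params <- function(x, ...) {
  cat("<uvp_params> UV-Peierls model,", x$n_sites, "sites\n")
  cat(sprintf("  U = %.3f eV, V = %.3f eV, beta0 = %.3f eV\n",
              x$u_coulomb, x$v_coulomb, x$beta0))
  cat(sprintf("  alpha = %.3f eV/A, K = %.1f eV/A^2, lambda = %.2f eV\n",
              x$alpha, x$spring_k, x$lambda_spin))
  cat(sprintf("  eps in [%.3f, %.3f] eV, gamma = %.4f /fs, m = %.1f amu\n",
              min(x$eps), max(x$eps), x$gamma, x$nuclear_mass))
  cat(sprintf("  dt = %g fs, Dt = %g fs, cutoff = %g, max states = %d\n",
              x$dt_trotter, x$dt_nuclear, x$trunc_cutoff, x$max_states))
  invisible(x)
}

#' Bond hopping integrals from nuclear displacements
#'
#' Maps site displacements to the `N - 1` bond hopping integrals,
#' `beta_n = beta0 - alpha * (u[n+1] - u[n])`: a compressed bond (negative
#' bond distortion) increases the hopping. Only displacement differences
#' enter, so a rigid translation leaves every hopping at `beta0`.
#'
#' @param params A [model_params()] object.
#' @param displacements Numeric vector of `N` site displacements (A).
#' @return Numeric vector of `N - 1` bond hoppings (eV).
#' @export
hopping_from_geometry <- function(params, displacements) {
  if (length(displacements) != params$n_sites) {
    stop("`displacements` must have length n_sites = ", params$n_sites)
  }
  params$beta0 - params$alpha * diff(displacements)
}

#' Nuclear chain state
#'
#' Displacements, momenta and the bond hoppings they imply. The hoppings are
#' always recomputed from the displacements, so the two can never disagree.
#'
#' @param params A [model_params()] object.
#' @param displacements Site displacements `u_n` (A); scalar recycled.
#' @param momenta Site momenta `p_n` (internal units, eV fs / A); scalar
#'   recycled.
#' @return An object of class `chain_state` with elements `displacements`,
#'   `momenta`, `bond_hoppings`.
#' @export
chain_state <- function(params, displacements = 0, momenta = 0) {
  n <- params$n_sites
  u <- rep_len(as.numeric(displacements), if (length(displacements) == 1) n else length(displacements))
  p <- rep_len(as.numeric(momenta), if (length(momenta) == 1) n else length(momenta))
  if (length(u) != n || length(p) != n) {
    stop("`displacements` and `momenta` must have length n_sites = ", n)
  }
  structure(
    list(displacements = u, momenta = p,
         bond_hoppings = hopping_from_geometry(params, u)),
    class = "chain_state"
  )
}

#' @exportS3Method base::print
print.chain_state <- function(x, ...) {
  cat("<chain_state>", length(x$displacements), "sites\n")
  cat("  max |u| =", signif(max(abs(x$displacements)), 4), "A,",
      "max |p| =", signif(max(abs(x$momenta)), 4), "\n")
  cat("  bond hoppings:", paste(signif(x$bond_hoppings, 5), collapse = " "), "\n")
  invisible(x)
}

#' @describeIn chain_state tidy view: one row per site.
#' @param x A `chain_state`.
#' @param ... Unused.
#' @export
as_tibble.chain_state <- function(x, ...) {
  n <- length(x$displacements)
  tibble::tibble(
    site = seq_len(n),
    displacement = x$displacements,
    momentum = x$momenta,
    bond_hopping = c(x$bond_hoppings, NA_real_)
  )
}

#' Elastic (lattice) energy of a geometry
#'
#' `K/2 * sum over bonds of (u[n+1] - u[n])^2`, the classical harmonic energy
#' carried as a scalar alongside the electronic Hamiltonian so that state
#' energies are Born-Oppenheimer totals.
#'
#' @inheritParams hopping_from_geometry
#' @param chain A [chain_state()].
#' @return Energy in eV.
#' @export
elastic_energy <- function(params, chain) {
  params$spring_k / 2 * sum(diff(chain$displacements)^2)
}

#' Single-site fermionic operator set
#'
#' The 4x4 actions on the site basis \{empty, up, down, doubly occupied\}
#' (in that order, with the doubly occupied state `cdag_up cdag_dn |0>`):
#' annihilators per spin, number operators, Jordan-Wigner parity, and the
#' local spin ingredients. Fermionic anticommutation across sites is carried
#' by the parity operator `parity = (-1)^n`.
#'
#' @return Named list of 4x4 matrices: `c_up`, `c_dn`, `cdag_up`, `cdag_dn`,
#'   `n_up`, `n_dn`, `n_tot`, `parity`, `s_z`, `s_plus`, `s_minus`,
#'   `s2_local`, `ident`.
#' @export
site_operators <- function() {
  c_up <- matrix(0, 4, 4); c_up[1, 2] <- 1; c_up[3, 4] <- 1
  c_dn <- matrix(0, 4, 4); c_dn[1, 3] <- 1; c_dn[2, 4] <- -1
  n_up <- diag(c(0, 1, 0, 1)); n_dn <- diag(c(0, 0, 1, 1))
  par <- diag(c(1, -1, -1, 1))
  s_plus <- t(c_up) %*% c_dn     # cdag_up c_dn
  s_z <- (n_up - n_dn) / 2
  list(
    c_up = c_up, c_dn = c_dn, cdag_up = t(c_up), cdag_dn = t(c_dn),
    n_up = n_up, n_dn = n_dn, n_tot = n_up + n_dn, parity = par,
    s_z = s_z, s_plus = s_plus, s_minus = t(s_plus),
    s2_local = 0.75 * (n_up + n_dn - 2 * n_up %*% n_dn),
    ident = diag(4)
  )
}

# On-site Hamiltonian of site m (4x4): U double occupancy + eps_m (n - 1).
site_hamiltonian <- function(params, m) {
  op <- site_operators()
  params$u_coulomb * op$n_up %*% op$n_dn +
    params$eps[m] * (op$n_tot - diag(4))
}

# Two-site bond-order operator T_n = sum_sigma (cdag_n c_{n+1} + h.c.) as a
# 16x16 matrix in the (site n) x (site n+1) product basis, Jordan-Wigner signs
# absorbed into the parity dressing.
bond_order_two_site <- function() {
  op <- site_operators()
  # site n is the fast (first) index: kronecker(B, A) acts with A on site n
  hop <- function(cdag, cc) {
    a <- kronecker(cc, cdag %*% op$parity)
    a + Conj(t(a))
  }
  hop(op$cdag_up, op$c_up) + hop(op$cdag_dn, op$c_dn)
}

#' Bond Hamiltonian on bond n
#'
#' The two-site operator `h_n` acting on sites `(n, n+1)`: hopping
#' `-beta_n T_n`, nearest-neighbour Coulomb `V (n_n - 1)(n_{n+1} - 1)`, the
#' on-site terms split so that the bond Hamiltonians sum exactly to the full
#' electronic Hamiltonian (interior sites give half their on-site term to each
#' adjacent bond, terminal sites all of it to their single bond), and the
#' bond's share `K/2 (u[n+1]-u[n])^2` of the elastic energy as a scalar.
#' The spin penalty `lambda S^2` is global and is not part of any bond; it is
#' added by [full_hamiltonian()].
#'
#' @param params A [model_params()] object.
#' @param chain A [chain_state()].
#' @param n Bond index, `1 <= n <= N - 1`.
#' @return A 16x16 numeric matrix in the basis `site n (fast) x site n+1`.
#' @export
bond_hamiltonian <- function(params, chain, n) {
  N <- params$n_sites
  if (n < 1 || n > N - 1) stop("bond index out of range 1..", N - 1)
  op <- site_operators()
  wl <- if (n == 1) 1 else 0.5
  wr <- if (n == N - 1) 1 else 0.5
  nm1 <- op$n_tot - diag(4)
  h <- -chain$bond_hoppings[n] * bond_order_two_site() +
    params$v_coulomb * kronecker(nm1, nm1) +
    wl * kronecker(diag(4), site_hamiltonian(params, n)) +
    wr * kronecker(site_hamiltonian(params, n + 1), diag(4))
  delta <- chain$displacements[n + 1] - chain$displacements[n]
  h + params$spring_k / 2 * delta^2 * diag(16)
}

#' Hilbert-space sector dimension
#'
#' Number of electron configurations of a chain with a given electron count
#' and spin projection; up- and down-spin occupation patterns are counted
#' independently, so the dimension is `C(N, n_up) * C(N, n_dn)` with
#' `n_up - n_dn = 2 s_z`. Returned as a double: at carotenoid lengths the
#' count exceeds the integer range (N = 18 at half filling, S_z = 0, is about
#' 2.4e9).
#'
#' @param n_sites Number of sites.
#' @param n_electrons Electron count.
#' @param s_z Spin projection (integer or half-integer).
#' @return A double; 0 for infeasible quantum numbers.
#' @export
sector_dimension <- function(n_sites, n_electrons, s_z) {
  n_up <- (n_electrons + 2 * s_z) / 2
  n_dn <- (n_electrons - 2 * s_z) / 2
  if (abs(n_up - round(n_up)) > 1e-9 || abs(n_dn - round(n_dn)) > 1e-9) return(0)
  n_up <- round(n_up); n_dn <- round(n_dn)
  if (n_up < 0 || n_dn < 0 || n_up > n_sites || n_dn > n_sites) return(0)
  choose(n_sites, n_up) * choose(n_sites, n_dn)
}

#' Retained-states bound from the entanglement entropy
#'
#' The number of renormalised block states needed to faithfully represent a
#' state whose bipartite von Neumann entropy is `S` grows exponentially:
#' `m = exp(S)`. At the maximum entropy `S = 4.0` reached in the carotenoid
#' simulations this gives m of about 55 states; practical truncation-error
#' targets require retaining many more.
#'
#' @param entropy Von Neumann entanglement entropy (natural log units).
#' @return The bound `exp(entropy)` (a double, not rounded).
#' @export
retained_states_bound <- function(entropy) {
  stopifnot(is.numeric(entropy), all(entropy >= 0))
  exp(entropy)
}
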