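# Exact-diagonalization and exact-propagation reference engine for short
# chains. Every renormalised-basis module is validated against this engine.

#' A many-body state in an exact sector basis
#'
#' Thin container pairing an amplitude vector with its [sector_basis()].
#'
#' @param vec Complex (or numeric) amplitude vector over the sector basis.
#' @param basis The [sector_basis()] the amplitudes refer to.
#' @param normalize Normalise the amplitudes (default `TRUE`).
#' @return Object of class `sector_state`.
#' @export
sector_state <- function(vec, basis, normalize = TRUE) {
  stopifnot(inherits(basis, "sector_basis"), length(vec) == basis$dim)
  vec <- as.complex(vec)
  if (normalize) {
    nrm <- sqrt(Re(sum(Conj(vec) * vec)))
    if (nrm == 0) stop("zero-norm state")
    vec <- vec / nrm
  }
  structure(list(vec = vec, basis = basis), class = "sector_state")
}

#' @exportS3Method base::print
print.sector_state <- function(x, ...) {
  cat("<sector_state> dim", x$basis$dim, " norm",
      signif(sqrt(Re(sum(Conj(x$vec) * x$vec))), 8), "\n")
  invisible(x)
}

resolve_state <- function(state, basis = NULL) {
  if (inherits(state, "sector_state")) {
    list(vec = state$vec, basis = state$basis)
  } else {
    if (is.null(basis)) stop("supply a `sector_basis` for a raw amplitude vector")
    list(vec = as.complex(state), basis = basis)
  }
}

check_normalized <- function(vec, tol = 1e-6) {
  nrm2 <- Re(sum(Conj(vec) * vec))
  if (abs(nrm2 - 1) > tol) {
    stop("state is not normalized (|psi|^2 = ", signif(nrm2, 8), ")")
  }
  invisible(TRUE)
}

#' Full electronic-plus-elastic Hamiltonian in an exact sector basis
#'
#' Assembles `H = H_UVP + H_eps + lambda * S^2` as a sparse matrix over a
#' [sector_basis()], plus the classical elastic energy as a scalar shift, so
#' that eigenvalues are Born-Oppenheimer totals at the given geometry.
#'
#' @param params A [model_params()] object.
#' @param chain A [chain_state()].
#' @param basis A [sector_basis()]; defaults to half filling, `S_z = 0`.
#' @param spin_penalty Include the `lambda * S^2` term (default `TRUE`).
#'   The symmetric UV-Peierls diabatic Hamiltonian of the population analysis
#'   is obtained with `spin_penalty = FALSE` and zero `eps`.
#' @param elastic Include the scalar elastic shift (default `TRUE`).
#' @return A sparse symmetric `Matrix` of dimension `basis$dim`.
#' @export
full_hamiltonian <- function(params, chain,
                             basis = sector_basis(params$n_sites, params$n_sites, 0),
                             spin_penalty = TRUE, elastic = TRUE) {
  stopifnot(basis$n_sites == params$n_sites)
  hs <- ham_structure(basis)
  dvec <- params$u_coulomb * hs$docc + params$v_coulomb * hs$vnn +
    as.vector(hs$nm1 %*% params$eps)
  if (spin_penalty) dvec <- dvec + params$lambda_spin * hs$s2_diag
  if (elastic) dvec <- dvec + elastic_energy(params, chain)
  xs <- c(-chain$bond_hoppings[hs$hop_bond] * hs$hop_sign,
          if (spin_penalty) rep(params$lambda_spin, length(hs$s2_i)) else numeric(0),
          dvec)
  is <- c(hs$hop_i, if (spin_penalty) hs$s2_i else integer(0), seq_len(basis$dim))
  js <- c(hs$hop_j, if (spin_penalty) hs$s2_j else integer(0), seq_len(basis$dim))
  Matrix::sparseMatrix(i = is, j = js, x = xs, dims = c(basis$dim, basis$dim),
                       symmetric = FALSE)
}

# cached triplet decomposition of the sector Hamiltonian (geometry- and
# parameter-independent): hopping pattern with bond tags, S^2 pattern, and
# the diagonal ingredients
ham_structure <- function(basis) {
  get_cached(basis, "hstruct", {
    N <- basis$n_sites
    hi <- list(); hj <- list(); hx <- list(); hb <- list()
    for (n in seq_len(N - 1)) {
      tn <- bond_order_matrix(basis, n)
      tt <- methods::as(tn, "TsparseMatrix")
      hi[[n]] <- tt@i + 1L; hj[[n]] <- tt@j + 1L; hx[[n]] <- tt@x
      hb[[n]] <- rep(n, length(tt@x))
    }
    s2 <- methods::as(spin_squared_matrix(basis), "TsparseMatrix")
    offd <- s2@i != s2@j
    occ <- site_occupations(basis)
    nm1 <- occ - 1
    vnn <- numeric(basis$dim)
    for (n in seq_len(N - 1)) vnn <- vnn + nm1[, n] * nm1[, n + 1]
    list(hop_i = unlist(hi), hop_j = unlist(hj), hop_sign = unlist(hx),
         hop_bond = unlist(hb),
         s2_i = s2@i[offd] + 1L, s2_j = s2@j[offd] + 1L,
         s2_diag = basis$s_z^2 +
           rowSums(site_codes(basis) == 1L | site_codes(basis) == 2L) / 2,
         docc = double_occupancy_diag(basis), vnn = vnn, nm1 = nm1)
  })
}

# Parity label conventions: raw operator parities are multiplied by an
# N-dependent anchor so that the half-filled undistorted ground state of the
# symmetric UV model carries the conventional 1^1 A_g^- labels (C2 = +1,
# particle-hole = -1), the experimental-community sign convention.
c2_convention <- function(n_sites) 1
ph_convention <- function(n_sites) if ((n_sites / 2) %% 2 == 0) -1 else 1

# Joint-diagonalize a commuting symmetry within degenerate eigenspaces so each
# state gets a definite parity.
rotate_for_symmetry <- function(vectors, energies, sym, tol = 1e-8) {
  groups <- split(seq_along(energies), cumsum(c(1, diff(energies) > tol)))
  for (g in groups) {
    if (length(g) == 1) next
    sub <- vectors[, g, drop = FALSE]
    m <- t(sub) %*% as.matrix(sym %*% sub)
    m <- (m + t(m)) / 2
    rot <- eigen(m, symmetric = TRUE)$vectors
    vectors[, g] <- sub %*% rot
  }
  vectors
}

state_parity <- function(vec, sym, tol = 1e-6) {
  sv <- sp_mult(sym, vec)
  p <- Re(sum(Conj(vec) * sv))
  resid <- sqrt(sum(Mod(sv - p * vec)^2))
  if (resid > tol) return(NA_real_)
  round(p)
}

#' Exact eigenstates of the full Hamiltonian, with symmetry labels
#'
#' Dense diagonalization in an enumerable sector. When the chain is
#' symmetric (all `eps_n = 0` and mirror-symmetric hoppings) the states are
#' rotated within degenerate subspaces to carry definite C2 (g/u) and
#' particle-hole (+/-) parities, the diabatic labels `1^1B_u^+`,
#' `2^1A_g^-`, .... Labels follow the convention in which the ground state is
#' `1^1A_g^-`.
#'
#' @inheritParams full_hamiltonian
#' @param k Number of lowest eigenstates to return.
#' @param label_symmetries Attach C2/particle-hole parities. Default: only
#'   when the Hamiltonian actually commutes with them (symmetric chain).
#' @return A tibble with one row per state: `state`, `energy` (eV),
#'   `s_squared`, `ionicity`, `c2_parity`, `ph_parity`, `label` and a
#'   list-column `vector` of sector amplitude vectors. The basis is attached
#'   as attribute `"basis"`.
#' @export
exact_eigenstates <- function(params, chain,
                              basis = sector_basis(params$n_sites, params$n_sites, 0),
                              k = 6, spin_penalty = TRUE,
                              label_symmetries = NULL) {
  if (k > basis$dim) stop("k = ", k, " exceeds sector dimension ", basis$dim)
  h <- full_hamiltonian(params, chain, basis, spin_penalty = spin_penalty)
  ee <- eigen(as.matrix(h), symmetric = TRUE)
  ord <- order(ee$values)
  energies <- ee$values[ord][seq_len(k)]
  vectors <- ee$vectors[, ord[seq_len(k)], drop = FALSE]

  symmetric_geom <- all(abs(params$eps) < 1e-12) &&
    max(abs(chain$bond_hoppings - rev(chain$bond_hoppings))) < 1e-10
  half_filled <- basis$n_electrons == basis$n_sites
  if (is.null(label_symmetries)) label_symmetries <- symmetric_geom && half_filled
  if (label_symmetries && !(symmetric_geom && half_filled)) {
    stop("symmetry labels requested but the Hamiltonian breaks C2/particle-hole symmetry")
  }

  c2p <- rep(NA_real_, k); php <- rep(NA_real_, k)
  if (label_symmetries) {
    c2 <- c2_matrix(basis); ph <- ph_matrix(basis)
    vectors <- rotate_for_symmetry(vectors, energies, c2)
    vectors <- rotate_for_symmetry(vectors, energies, ph)
    c2anchor <- c2_convention(basis$n_sites)
    phanchor <- ph_convention(basis$n_sites)
    for (i in seq_len(k)) {
      c2p[i] <- state_parity(vectors[, i], c2) * c2anchor
      php[i] <- state_parity(vectors[, i], ph) * phanchor
    }
  }
  s2m <- spin_squared_matrix(basis)
  docc <- double_occupancy_diag(basis)
  s2 <- vapply(seq_len(k), function(i) {
    Re(sum(vectors[, i] * as.vector(s2m %*% vectors[, i])))
  }, numeric(1))
  ion <- vapply(seq_len(k), function(i) sum(docc * vectors[, i]^2), numeric(1))

  lab <- rep(NA_character_, k)
  if (label_symmetries) {
    irr <- ifelse(c2p > 0, "Ag", "Bu")
    pm <- ifelse(php > 0, "+", "-")
    key <- paste0(irr, pm)
    cnt <- stats::ave(seq_len(k), key, FUN = seq_along)
    lab <- ifelse(is.na(c2p) | is.na(php), NA_character_,
                  paste0(cnt, "^1", irr, pm))
  }
  out <- tibble::tibble(
    state = seq_len(k) - 1L, energy = energies, s_squared = s2,
    ionicity = ion, c2_parity = c2p, ph_parity = php, label = lab,
    vector = lapply(seq_len(k), function(i) vectors[, i])
  )
  attr(out, "basis") <- basis
  out
}

# Lanczos/Krylov action of exp(theta * H) on a vector, H sparse Hermitian,
# theta complex (propagation uses theta = -i dt / hbar).
krylov_expv <- function(h, v, theta, m = 25, tol = 1e-12) {
  n <- length(v)
  m <- min(m, n)
  beta0 <- sqrt(Re(sum(Conj(v) * v)))
  if (beta0 == 0) return(v)
  vs <- matrix(0 + 0i, n, m)
  alpha <- numeric(m); beta <- numeric(m - 1)
  vs[, 1] <- v / beta0
  w <- sp_mult(h, vs[, 1])
  alpha[1] <- Re(sum(Conj(vs[, 1]) * w))
  w <- w - alpha[1] * vs[, 1]
  used <- 1L
  for (j in 2:m) {
    b <- sqrt(Re(sum(Conj(w) * w)))
    if (b < tol) break
    beta[j - 1] <- b
    vs[, j] <- w / b
    w <- sp_mult(h, vs[, j])
    alpha[j] <- Re(sum(Conj(vs[, j]) * w))
    w <- w - alpha[j] * vs[, j] - b * vs[, j - 1]
    # full reorthogonalization: cheap at these Krylov sizes
    w <- w - vs[, 1:j] %*% (Conj(t(vs[, 1:j])) %*% w)
    used <- j
  }
  tmat <- diag(alpha[seq_len(used)], used)
  if (used > 1) {
    for (j in seq_len(used - 1)) {
      tmat[j, j + 1] <- beta[j]; tmat[j + 1, j] <- beta[j]
    }
  }
  et <- eigen(tmat, symmetric = TRUE)
  coef <- et$vectors %*% (exp(theta * et$values) * t(et$vectors)[, 1])
  as.vector(vs[, seq_len(used), drop = FALSE] %*% coef) * beta0
}

#' Exact unitary propagation in a sector basis
#'
#' Integrates the time-dependent Schroedinger equation for a frozen geometry
#' by Krylov (Lanczos) exponentiation of the sparse sector Hamiltonian. Norm
#' is preserved to near machine precision; energy is conserved for the
#' time-independent Hamiltonian.
#'
#' @param state A [sector_state()] or amplitude vector.
#' @inheritParams full_hamiltonian
#' @param duration Total propagation time (fs).
#' @param dt Substep (fs); defaults to `min(duration, 0.05)`.
#' @return A `sector_state` at time `duration`.
#' @export
exact_propagate <- function(state, params, chain, duration, dt = NULL,
                            basis = NULL) {
  st <- resolve_state(state, basis)
  check_normalized(st$vec)
  if (duration == 0) return(sector_state(st$vec, st$basis, normalize = FALSE))
  if (is.null(dt)) dt <- min(duration, 0.05)
  h <- full_hamiltonian(params, chain, st$basis)
  nstep <- ceiling(duration / dt - 1e-9)
  dts <- rep(duration / nstep, nstep)
  v <- st$vec
  for (s in dts) v <- krylov_expv(h, v, -1i * s / .hbar())
  sector_state(v, st$basis, normalize = FALSE)
}

#' Dipole moment operator
#'
#' `mu = -sum_n x_n (n_n - 1)` with site positions
#' `x_n = (n - 1) * lattice_spacing + u_n`, measured from the chain origin.
#' Traceless on the charge-neutral (half-filled) sector; for a
#' mirror-symmetric geometry it anticommutes with C2 there, so only
#' `Ag <-> Bu` transitions carry dipole strength.
#'
#' @inheritParams full_hamiltonian
#' @return A sparse diagonal `Matrix` over the sector basis (units e A).
#' @export
dipole_operator <- function(params, chain,
                            basis = sector_basis(params$n_sites, params$n_sites, 0)) {
  x <- (seq_len(params$n_sites) - 1) * params$lattice_spacing +
    chain$displacements
  # centre positions so mirror geometries give an exactly C2-odd operator
  x <- x - mean(x)
  occ <- site_occupations(basis)
  Matrix::Diagonal(basis$dim, -as.vector((occ - 1) %*% x))
}

#' Total-spin expectation of a state
#'
#' @param state A [sector_state()] or amplitude vector (must be normalized).
#' @param basis Basis for a raw vector.
#' @return `<S^2>` (dimensionless, >= 0).
#' @export
spin_squared_expectation <- function(state, basis = NULL) {
  st <- resolve_state(state, basis)
  check_normalized(st$vec)
  s2 <- spin_squared_matrix(st$basis)
  max(0, Re(sum(Conj(st$vec) * sp_mult(s2, st$vec))))
}

#' Ionicity (double-occupancy expectation) of a state
#'
#' The expectation of `sum_n n_up,n * n_dn,n`. Ionic (positive particle-hole
#' parity) states carry larger ionicity than covalent ones, which is how
#' states are classified when symmetry labels are unavailable.
#'
#' @inheritParams spin_squared_expectation
#' @return Dimensionless ionicity, in `[0, N/2]` for N electrons.
#' @export
ionicity <- function(state, basis = NULL) {
  st <- resolve_state(state, basis)
  sum(double_occupancy_diag(st$basis) * Mod(st$vec)^2)
}

#' Bipartite von Neumann entanglement entropy
#'
#' Entropy `-sum omega log(omega)` of the Schmidt spectrum across the bond
#' between sites `cut` and `cut + 1`. Zero iff the state factorizes there.
#'
#' @inheritParams spin_squared_expectation
#' @param cut Bond position, `1 <= cut <= N - 1`.
#' @return Entropy in nats.
#' @export
reduced_density_entropy <- function(state, cut, basis = NULL) {
  st <- resolve_state(state, basis)
  N <- st$basis$n_sites
  if (cut < 1 || cut > N - 1) stop("cut must be an interior bond 1..", N - 1)
  v <- dense_from_sector(st$vec, st$basis)
  m <- matrix(v, nrow = 4^cut)
  sv <- svd(m, nu = 0, nv = 0)$d
  omega <- sv^2
  omega <- omega / sum(omega)
  omega <- omega[omega > 1e-16]
  -sum(omega * log(omega))
}

#' Site charge densities of a state
#'
#' @inheritParams spin_squared_expectation
#' @return Numeric vector of `<n_n>` per site (sums to the electron count).
#' @export
site_densities <- function(state, basis = NULL) {
  st <- resolve_state(state, basis)
  as.vector(Mod(st$vec)^2 %*% site_occupations(st$basis))
}

#' Bond-order expectations of a state
#'
#' `<T_n>` per bond, the electronic ingredient of the Hellmann-Feynman force.
#'
#' @inheritParams spin_squared_expectation
#' @return Numeric vector of length `N - 1`.
#' @export
bond_order_expectations <- function(state, basis = NULL) {
  st <- resolve_state(state, basis)
  vapply(seq_len(st$basis$n_sites - 1), function(n) {
    Re(sum(Conj(st$vec) * sp_mult(bond_order_matrix(st$basis, n), st$vec)))
  }, numeric(1))
}

#' Total Born-Oppenheimer energy of an electronic state
#'
#' `<H>` including the spin penalty and the scalar elastic energy.
#'
#' @inheritParams full_hamiltonian
#' @param state A [sector_state()] or amplitude vector.
#' @return Energy in eV.
#' @export
state_energy <- function(state, params, chain, basis = NULL) {
  st <- resolve_state(state, basis)
  h <- full_hamiltonian(params, chain, st$basis)
  Re(sum(Conj(st$vec) * sp_mult(h, st$vec)))
}
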