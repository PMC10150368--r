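# Shared fixtures, lazily computed once per test session.

.fx_cache <- new.env(parent = emptyenv())

fx <- function(name, expr) {
  if (is.null(.fx_cache[[name]])) .fx_cache[[name]] <- force(expr)
  .fx_cache[[name]]
}

# N = 6 symmetric chain, spin penalty 2 eV (clears the singlet window),
# weakly dimerized geometry
fx_p6 <- function() fx("p6", model_params(6, lambda_spin = 2))
fx_ch6 <- function() fx("ch6", chain_state(fx_p6(), displacements = 0.03 * (-1)^(1:6)))
fx_b6 <- function() fx("b6", sector_basis(6, 6, 0))
fx_ee6 <- function() fx("ee6", exact_eigenstates(fx_p6(), fx_ch6(), fx_b6(), k = 8))

# S0-relaxed N = 6 geometry (Peierls-dimerized) and the photoexcited initial
# condition at that geometry
fx_rel6 <- function() fx("rel6", relax_geometry(fx_p6(), 0, "exact"))
fx_init6 <- function() fx("init6", prepare_initial_state(fx_p6()))

# N = 4 system with broken symmetry for generic checks
fx_p4 <- function() fx("p4", model_params(4, eps = c(0.3, -0.1, 0.2, -0.4)))
fx_ch4 <- function() fx("ch4", chain_state(fx_p4(), displacements = c(0.02, -0.01, 0.03, -0.02)))
fx_b4 <- function() fx("b4", sector_basis(4, 4, 0))

# dense full-Fock Hamiltonian assembled from oracle sector blocks (site-major)
dense_fock_hamiltonian <- function(params, chain) {
  N <- params$n_sites
  h <- matrix(0, 4^N, 4^N)
  for (ne in 0:(2 * N)) {
    for (sz in seq(-ne / 2, ne / 2, by = 1)) {
      if (sector_dimension(N, ne, sz) == 0) next
      b <- sector_basis(N, ne, sz)
      hb <- as.matrix(full_hamiltonian(params, chain, b, spin_penalty = FALSE))
      h[b$words + 1, b$words + 1] <- h[b$words + 1, b$words + 1] + hb
    }
  }
  h
}

embed_bond <- function(op16, n, N) {
  kronecker(diag(4^(N - n - 1)), kronecker(op16, diag(4^(n - 1))))
}

expect_close <- function(x, y, tol) {
  expect_lt(max(abs(x - y)), tol)
}
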