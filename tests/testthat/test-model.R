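test_that("bond hoppings depend only on bond distortions", {
  p <- model_params(6)
  expect_equal(hopping_from_geometry(p, rep(0, 6)), rep(p$beta0, 5))
  expect_equal(hopping_from_geometry(p, rep(0.37, 6)), rep(p$beta0, 5))
  u0 <- 0.02
  beta <- hopping_from_geometry(p, u0 * (-1)^(1:6))
  # staggered displacements: alternating hoppings symmetric about beta0
  expect_equal(beta, p$beta0 - p$alpha * diff(u0 * (-1)^(1:6)))
  expect_equal(beta[c(1, 3, 5)], rep(beta[1], 3))
  expect_equal(beta[c(2, 4)], rep(2 * p$beta0 - beta[1], 2))
  expect_error(hopping_from_geometry(p, rep(0, 5)), "length")
})

test_that("parameter validation enforces the model invariants", {
  expect_error(model_params(5), "n_sites")
  expect_error(model_params(6, lambda_spin = 0), "lambda_spin")
  expect_error(model_params(6, dt_trotter = 3e-3, dt_nuclear = 1e-2),
               "integer multiple")
  expect_error(model_params(6, eps = rep(2, 6), eps_max = 1), "eps_max")
  expect_error(model_params(6, eps = rep(0, 4)), "length")
  p <- model_params(6)
  expect_identical(p$u_coulomb, 7.25)
  expect_identical(p$v_coulomb, 3.25)
  expect_identical(p$beta0, 2.4)
  expect_identical(p$spring_k, 46)
  expect_identical(p$alpha, 4.593)
})

test_that("chain_state keeps hoppings consistent with displacements", {
  p <- model_params(4)
  ch <- chain_state(p, displacements = c(0.1, -0.1, 0.05, 0))
  expect_equal(ch$bond_hoppings,
               hopping_from_geometry(p, ch$displacements))
  tb <- as_tibble(ch)
  expect_equal(nrow(tb), 4)
  expect_true(is.na(tb$bond_hopping[4]))
})

test_that("site operators obey the fermion algebra through the parity dressing", {
  op <- site_operators()
  expect_equal(diag(op$n_tot), c(0, 1, 1, 2))
  # on-site anticommutation {c, cdag} = 1, {c_up, c_dn} = 0
  expect_equal(op$c_up %*% op$cdag_up + op$cdag_up %*% op$c_up, diag(4))
  expect_equal(op$c_up %*% op$c_dn + op$c_dn %*% op$c_up, matrix(0, 4, 4))
  # cross-site anticommutation via Jordan-Wigner parity:
  # {c_1, c_2} -> (c P) x c' + ... must vanish; check on the two-site algebra
  c1 <- kronecker(diag(4), op$c_up)            # site 1 (fast index)
  c2 <- kronecker(op$c_up, op$parity)          # site 2 with string on site 1
  expect_equal(c1 %*% c2 + c2 %*% c1, matrix(0, 16, 16))
  cd2 <- t(c2)
  expect_equal(c1 %*% cd2 + cd2 %*% c1, matrix(0, 16, 16))
})

test_that("bond Hamiltonians sum exactly to the full Hamiltonian (N = 4)", {
  p <- fx_p4(); ch <- fx_ch4()
  hfull <- dense_fock_hamiltonian(p, ch)
  hsum <- matrix(0, 4^4, 4^4)
  for (n in 1:3) hsum <- hsum + embed_bond(bond_hamiltonian(p, ch, n), n, 4)
  expect_close(hfull, hsum, 1e-12)
  expect_error(bond_hamiltonian(p, ch, 4), "range")
})

test_that("bond Hamiltonians are self-adjoint and particle-hole covariant", {
  p <- fx_p4(); ch <- fx_ch4()
  for (n in 1:3) {
    h <- bond_hamiltonian(p, ch, n)
    expect_close(h, t(h), 1e-12)
  }
  # with eps = 0, each bond operator commutes with the two-site
  # particle-hole transformation (explicit 16x16 check)
  p0 <- model_params(4)
  h <- bond_hamiltonian(p0, chain_state(p0), 2)
  # the ph map acts within the half-filled S_z = 0 two-site block
  bb <- sector_basis(2, 2, 0)
  jb <- as.matrix(polyenedyn:::ph_matrix(bb))
  sel <- bb$words + 1
  hb <- h[sel, sel]
  expect_close(hb %*% jb, jb %*% hb, 1e-10)
})

test_that("sector dimensions count configurations", {
  expect_equal(sector_dimension(2, 2, 0), 4)
  expect_equal(sector_dimension(1, 0, 0), 1)
  expect_equal(sector_dimension(6, 6, 0), choose(6, 3)^2)
  expect_equal(sector_dimension(4, 3, 1 / 2), choose(4, 2) * choose(4, 1))
  expect_equal(sector_dimension(4, 3, 1), 0)   # infeasible
  # completeness: sum over all sectors is 4^N
  for (N in c(2, 4, 6)) {
    tot <- 0
    for (ne in 0:(2 * N)) {
      for (sz in seq(-ne / 2, ne / 2, by = 1)) {
        tot <- tot + sector_dimension(N, ne, sz)
      }
    }
    expect_equal(tot, 4^N)
  }
})

test_that("the half-filled Hubbard dimer reproduces the closed form", {
  fxd <- make_fixture("hubbard_dimer")
  ee <- exact_eigenstates(fxd$params, fxd$chain, sector_basis(2, 2, 0), k = 4,
                          spin_penalty = FALSE)
  expect_close(ee$energy, fxd$closed_form, 1e-12)
})

test_that("spin penalty shifts triplet-containing states by 2 lambda", {
  p0 <- model_params(2, u_coulomb = 4, v_coulomb = 1, beta0 = 1,
                     lambda_spin = 1)
  b <- sector_basis(2, 2, 0)
  ch <- chain_state(p0)
  e_off <- exact_eigenstates(p0, ch, b, k = 4, spin_penalty = FALSE)
  e_on <- exact_eigenstates(p0, ch, b, k = 4, spin_penalty = TRUE)
  trip_off <- e_off$energy[e_off$s_squared > 1.9]
  trip_on <- sort(e_on$energy[e_on$s_squared > 1.9])
  expect_close(trip_on, sort(trip_off) + 2 * p0$lambda_spin, 1e-10)
})

test_that("a uniform on-site shift moves every eigenvalue by N_e * shift", {
  p <- model_params(4, lambda_spin = 2)
  ch <- chain_state(p)
  b <- fx_b4()
  e0 <- exact_eigenstates(p, ch, b, k = 5, label_symmetries = FALSE)$energy
  pshift <- model_params(4, lambda_spin = 2, eps = rep(0.11, 4), eps_max = 1)
  # H_eps = sum eps (n - 1): at half filling sum(n - 1) = 0, so the
  # charge-neutral convention makes a uniform shift a no-op in this sector
  e1 <- exact_eigenstates(pshift, ch, b, k = 5, label_symmetries = FALSE)$energy
  expect_close(e1, e0, 1e-10)
})

test_that("the entropy bound on retained states is exponential", {
  expect_equal(retained_states_bound(0), 1)
  expect_equal(retained_states_bound(log(2)), 2)
  expect_error(retained_states_bound(-1))
})
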