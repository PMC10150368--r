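test_that("warm-up with no truncation reaches the exact ground energy (N = 4)", {
  p <- fx_p4(); ch <- fx_ch4()
  e_or <- min(eigen(as.matrix(full_hamiltonian(p, ch, fx_b4())),
                    symmetric = TRUE, only.values = TRUE)$values)
  eng <- dmrg_warmup(p, ch, n_states = 1, max_states = 10000, cutoff = 0)
  expect_equal(eng$energies[1], e_or, tolerance = 1e-10)
  # block dimensions never exceed 4 * max_states before truncation
  eng2 <- dmrg_warmup(p, ch, n_states = 1, max_states = 8, cutoff = 0)
  dims <- vapply(Filter(Negate(is.null), eng2$A), function(a) dim(a)[3],
                 numeric(1))
  expect_true(all(dims <= 8))
})

test_that("warm-up energy decreases variationally with the retained dimension", {
  p <- fx_p6()
  ch <- fx_ch6()
  e_m <- vapply(c(8, 16, 32), function(m) {
    dmrg_warmup(p, ch, n_states = 1, max_states = m, cutoff = 0)$energies[1]
  }, numeric(1))
  expect_true(all(diff(e_m) < 1e-10))
})

test_that("finite sweeps converge the N = 8 ground state to the oracle", {
  fx8 <- make_fixture("n8_dmrg")
  res <- dmrg_run(fx8$params, fx8$chain, n_states = 1, max_states = 64,
                  cutoff = 0, n_sweeps = 4)
  b8 <- sector_basis(8, 8, 0)
  e_or <- min(eigen(as.matrix(full_hamiltonian(fx8$params, fx8$chain, b8)),
                    symmetric = TRUE, only.values = TRUE)$values)
  expect_lt(abs(res$energies[1] - e_or), 1e-6)
  # wavefunction-mapped guesses are immediately close to the solution
  # (after the first full sweep has healed the warm-up state)
  swept <- res$log[res$log$direction != "warmup" & res$log$sweep >= 2, ]
  expect_true(all(swept$guess_overlap > 0.99, na.rm = TRUE))
  # truncation report invariants
  expect_true(all(res$log$discarded >= 0 & res$log$discarded < 1))
  expect_true(all(res$log$entropy >= 0))
})

test_that("multi-state targeting reproduces and labels the lowest singlets", {
  p <- fx_p6(); ch <- fx_ch6(); b <- fx_b6()
  ee <- fx_ee6()
  sing <- ee[ee$s_squared < 0.1, ]
  res <- dmrg_run(p, ch, n_states = 3, max_states = 256, cutoff = 1e-12,
                  n_sweeps = 4)
  expect_close(res$energies, sing$energy[1:3], 1e-5)
  # Gram-Schmidt-quality orthogonality by construction
  expect_lt(Mod(mps_overlap(res$states[[1]], res$states[[2]])), 1e-8)
  expect_lt(Mod(mps_overlap(res$states[[2]], res$states[[3]])), 1e-8)
  # C2 parity of each converged state (end-to-end reversal on the densified
  # state) matches the oracle label
  c2 <- polyenedyn:::c2_matrix(b)
  for (i in 1:3) {
    v <- mps_sector_state(res$states[[i]], b)$vec
    par <- Re(sum(Conj(v) * polyenedyn:::sp_mult(c2, v)))
    expect_equal(round(par), sing$c2_parity[i] /
                   polyenedyn:::c2_convention(6) * 1)
  }
  td <- tidy(res)
  expect_true(all(abs(td$n_electrons - 6) < 1e-6))
  expect_true(all(td$s_squared < 1e-6))
  gl <- glance(res)
  expect_true(gl$ground_energy < res$energies[2])
})

test_that("Hellmann-Feynman forces agree with numerical differentiation", {
  p <- fx_p6(); b <- fx_b6()
  ch <- fx_ch6()
  ee <- exact_eigenstates(p, ch, b, k = 1, label_symmetries = FALSE)
  st <- sector_state(ee$vector[[1]], b, normalize = FALSE)
  f <- hellmann_feynman_forces(st, p, ch)
  # alpha channel + elastic channel telescope: total force is zero
  expect_lt(abs(sum(f)), 1e-10)
  # central finite difference of the ground-state total energy wrt u_3
  h <- 1e-5
  e_at <- function(du) {
    u <- ch$displacements; u[3] <- u[3] + du
    ch2 <- chain_state(p, u)
    exact_eigenstates(p, ch2, b, k = 1, label_symmetries = FALSE)$energy[1]
  }
  f3_num <- -(e_at(h) - e_at(-h)) / (2 * h)
  expect_lt(abs(f3_num - f[3]), 1e-5)
  # MPS route gives the same forces
  fm <- hellmann_feynman_forces(as_mps(st), p, ch)
  expect_close(fm, f, 1e-8)
})

test_that("geometry relaxation dimerizes the ground state", {
  p <- fx_p6()
  rel <- fx_rel6()
  expect_true(rel$converged)
  expect_lt(max(abs(rel$forces)), 1e-4)
  # Peierls dimerization: (beta_n - beta0) alternates in magnitude
  dev <- rel$chain$bond_hoppings - mean(rel$chain$bond_hoppings)
  expect_true(all(sign(dev) == c(1, -1, 1, -1, 1)))
  # relaxed energy is below the vertical energy at the starting geometry
  b <- fx_b6()
  e_vert <- exact_eigenstates(p, chain_state(p), b, k = 1,
                              label_symmetries = FALSE)$energy[1]
  expect_lt(rel$energy, e_vert)
})

test_that("oracle-driven and DMRG-driven relaxation agree on the geometry", {
  p <- fx_p6()
  rel <- fx_rel6()
  # start the DMRG relaxation close to the fixed point: both engines must
  # agree on where the forces vanish
  rel_dmrg <- relax_geometry(p, 0, engine = "dmrg", tol = 1e-4,
                             chain0 = chain_state(p, rel$chain$displacements * 0.98),
                             max_states = 64, cutoff = 1e-10)
  expect_close(rel_dmrg$chain$displacements, rel$chain$displacements, 1e-4)
})
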