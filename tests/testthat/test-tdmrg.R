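test_that("link propagators are exact bond exponentials", {
  p <- fx_p6(); ch <- fx_ch6()
  u0 <- link_propagator(p, ch, 2, 0)
  expect_close(u0, diag(16) + 0i, 1e-14)
  u1 <- link_propagator(p, ch, 2, 0.3)
  # unitarity
  expect_close(Conj(t(u1)) %*% u1, diag(16) + 0i, 1e-12)
  # composition: same generator
  expect_close(u1 %*% u1, link_propagator(p, ch, 2, 0.6), 1e-12)
  # eigenphase: acting on a bond eigenstate multiplies by exp(-i E dt / hbar)
  h <- bond_hamiltonian(p, ch, 2)
  es <- eigen(h, symmetric = TRUE)
  phase <- Conj(es$vectors[, 3]) %*% (u1 %*% es$vectors[, 3])
  expect_lt(Mod(phase - exp(-1i * es$values[3] * 0.3 /
                              pd_constants[["hbar_ev_fs"]])), 1e-12)
})

test_that("an eigenstate is stationary under Trotter evolution", {
  p <- fx_p6(); ch <- fx_ch6(); b <- fx_b6()
  ee <- fx_ee6()
  i2 <- which(ee$s_squared < 0.1)[2]
  m <- as_mps(sector_state(ee$vector[[i2]], b))
  ev <- tdmrg_evolve(m, p, ch, duration = 0.5, dt = 5e-3, max_states = 64,
                     cutoff = 1e-12)
  vf <- mps_sector_state(ev$mps, b)$vec
  pops <- vapply(seq_len(6), function(i) {
    Mod(sum(Conj(ee$vector[[i]]) * vf))^2
  }, numeric(1))
  expect_lt(abs(pops[i2] - 1), 1e-6)
  # global phase removed: modulus of the self-overlap stays 1
  expect_gt(Mod(sum(Conj(ee$vector[[i2]]) * vf)), 1 - 1e-7)
  # duration 0 returns the input state
  ev0 <- tdmrg_evolve(m, p, ch, duration = 0)
  expect_identical(ev0$mps, m)
})

test_that("Trotter evolution tracks the exact propagator at second order", {
  p <- fx_p6(); ch <- fx_ch6(); b <- fx_b6()
  ee <- fx_ee6()
  i2 <- which(ee$s_squared < 0.1)[2]
  v <- (ee$vector[[1]] + ee$vector[[i2]]) / sqrt(2)
  st0 <- sector_state(v, b)
  m0 <- as_mps(st0)
  tt <- 1
  ex <- exact_propagate(st0, p, ch, duration = tt, dt = 0.02)
  ev <- tdmrg_evolve(m0, p, ch, duration = tt, dt = 2e-3, max_states = 64,
                     cutoff = 1e-12)
  vf <- mps_sector_state(ev$mps, b)$vec
  pops_err <- max(abs(vapply(1:6, function(i) {
    Mod(sum(Conj(ee$vector[[i]]) * vf))^2 -
      Mod(sum(Conj(ee$vector[[i]]) * ex$vec))^2
  }, numeric(1))))
  expect_lt(pops_err, 1e-4)
  expect_lt(max(ev$log$norm_drift), 1e-8)
  # halving dt shrinks the end-state error by ~4 (second-order Trotter)
  err_vs_exact <- function(dt) {
    exs <- exact_propagate(st0, p, ch, duration = 0.5, dt = 0.01)
    evs <- tdmrg_evolve(m0, p, ch, duration = 0.5, dt = dt, max_states = 64,
                        cutoff = 1e-13)
    vfs <- mps_sector_state(evs$mps, b)$vec
    sqrt(max(0, 2 - 2 * Mod(sum(Conj(exs$vec) * vfs))))
  }
  ratio <- err_vs_exact(0.02) / err_vs_exact(0.01)
  expect_gt(ratio, 3)
  expect_lt(ratio, 5)
})

test_that("a prepared superposition oscillates at the Bohr period", {
  p <- fx_p6(); ch <- fx_ch6(); b <- fx_b6()
  ee <- fx_ee6()
  i2 <- which(ee$s_squared < 0.1)[2]
  gap <- ee$energy[i2] - ee$energy[1]
  hbar <- pd_constants[["hbar_ev_fs"]]
  quarter <- 2 * pi * hbar / gap / 4
  v <- (ee$vector[[1]] + ee$vector[[i2]]) / sqrt(2)
  m0 <- as_mps(sector_state(v, b))
  # at a quarter period the relative phase has advanced by pi/2
  dtq <- quarter / ceiling(quarter / 5e-3) # commensurate step
  ev <- tdmrg_evolve(m0, p, ch, duration = quarter, dt = dtq,
                     max_states = 64, cutoff = 1e-12)
  vf <- mps_sector_state(ev$mps, b)$vec
  c1 <- sum(Conj(ee$vector[[1]]) * vf)
  c2 <- sum(Conj(ee$vector[[i2]]) * vf)
  expect_lt(abs(Arg(c2 / c1) + pi / 2) %% (2 * pi), 1e-3)
})

test_that("energy is conserved by frozen-nuclei Trotter evolution", {
  p <- fx_p6(); ch <- fx_ch6(); b <- fx_b6()
  ee <- fx_ee6()
  i2 <- which(ee$s_squared < 0.1)[2]
  v <- (0.8 * ee$vector[[1]] + 0.6 * ee$vector[[i2]])
  m0 <- as_mps(sector_state(v, b))
  mpo <- polyenedyn:::build_mpo(p, ch, number_penalty = 0)
  e0 <- polyenedyn:::mpo_expectation(m0, mpo)
  ev <- tdmrg_evolve(m0, p, ch, duration = 2, dt = 2e-3, max_states = 64,
                     cutoff = 1e-12)
  e1 <- polyenedyn:::mpo_expectation(ev$mps, mpo)
  expect_lt(abs(e1 - e0), 1e-5)
})
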