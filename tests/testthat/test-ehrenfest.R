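test_that("damped velocity Verlet reproduces harmonic-chain normal modes", {
  # decouple the electrons (alpha = 0): pure bond-spring dynamics whose
  # normal-mode frequencies are sqrt(K/m * (2 - 2 cos(pi k / N)))
  p <- model_params(6, alpha = 0, gamma = 0)
  m_int <- p$nuclear_mass * pd_constants[["amu_ev_fs2_A2"]]
  lap <- matrix(0, 6, 6)
  for (n in 1:5) {
    lap[n, n] <- lap[n, n] + 1; lap[n + 1, n + 1] <- lap[n + 1, n + 1] + 1
    lap[n, n + 1] <- lap[n, n + 1] - 1; lap[n + 1, n] <- lap[n + 1, n] - 1
  }
  es <- eigen(lap, symmetric = TRUE)
  mode <- es$vectors[, 1]              # highest-frequency mode
  omega <- sqrt(p$spring_k * es$values[1] / m_int)
  ffun <- function(ch) {
    polyenedyn:::force_from_bond_orders(rep(0, 5), p, ch)
  }
  a0 <- 0.01
  ch <- chain_state(p, displacements = a0 * mode)
  dt <- 0.02
  nstep <- 2000
  proj <- numeric(nstep)
  e_tot <- numeric(nstep)
  for (s in seq_len(nstep)) {
    ch <- verlet_step(ch, ffun, p, dt = dt)
    proj[s] <- sum(ch$displacements * mode)
    e_tot[s] <- elastic_energy(p, ch) + sum(ch$momenta^2) / (2 * m_int)
  }
  # energy conserved to O(dt^2)
  expect_lt(max(e_tot) - min(e_tot), 1e-5)
  # period from zero crossings of the mode coordinate
  sgn <- sign(proj)
  crossings <- which(diff(sgn) != 0)
  crossings <- crossings[c(TRUE, diff(crossings) > 10)]
  period_est <- 2 * mean(diff(crossings)) * dt
  expect_lt(abs(period_est - 2 * pi / omega) / (2 * pi / omega), 0.01)
})

test_that("damping gives an exponential momentum envelope", {
  p <- model_params(6, alpha = 0, gamma = 0.1)
  zero_f <- function(ch) rep(0, 6)
  ch <- chain_state(p, momenta = c(1, -1, 2, -2, 1, -1))
  p0 <- ch$momenta
  nstep <- 200
  for (s in seq_len(nstep)) ch <- verlet_step(ch, zero_f, p, dt = 0.05)
  expected <- exp(-p$gamma * nstep * 0.05)
  # discretised damping factor per step: (1 - g dt/2)/(1 + g dt/2)
  expect_close(ch$momenta / p0, rep(expected, 6), 1e-3)
  # zero forces, zero momenta: geometry unchanged
  ch0 <- chain_state(p, displacements = c(0.1, -0.1, 0, 0, 0.1, -0.1))
  ch1 <- verlet_step(ch0, zero_f, p)
  expect_close(ch1$displacements, ch0$displacements, 1e-14)
  expect_close(ch1$momenta, rep(0, 6), 1e-14)
})

test_that("the photoexcited initial condition selects the bright adiabat", {
  init <- fx_init6()
  # eps = 0: the selected adiabat IS the bright diabat (overlap 1)
  expect_equal(init$overlap, 1, tolerance = 1e-8)
  expect_identical(init$diabats$label[init$bright], "1^1Bu+")
  expect_lt(spin_squared_expectation(init$state), 1e-6)
  # weak symmetry breaking: overlap stays > 0.9
  fxw <- make_fixture("n6_weak_eps")
  initw <- prepare_initial_state(fxw$params)
  expect_gt(initw$overlap, 0.9)
  expect_lt(spin_squared_expectation(initw$state), 1e-6)
})

test_that("frozen-nuclei trajectories reduce to pure electronic evolution", {
  p <- fx_p6()
  init <- fx_init6()
  tr <- run_trajectory(p, 1, engine = "exact", init = init,
                       frozen_nuclei = TRUE, analyse_every = NA)
  st <- attr(tr, "state")
  ref <- exact_propagate(init$state, p, init$chain, duration = 1, dt = 0.01)
  expect_gt(Mod(sum(Conj(ref$vec) * st$vec)), 1 - 1e-8)
  # geometry untouched
  expect_identical(attr(tr, "chain")$displacements, init$chain$displacements)
})

test_that("coupled dynamics conserve and dissipate energy as gamma dictates", {
  p <- model_params(6, gamma = 0, lambda_spin = 2)
  init <- fx_init6()
  tr <- run_trajectory(p, 5, engine = "exact", init = init,
                       analyse_every = NA)
  expect_lt(max(tr$total) - min(tr$total), 1e-3)
  pd <- model_params(6, gamma = 0.05, lambda_spin = 2)
  trd <- run_trajectory(pd, 5, engine = "exact", init = init,
                        analyse_every = NA)
  # monotone energy decay after the initial record
  expect_true(all(diff(trd$total[-1]) < 1e-9))
  expect_lt(trd$total[nrow(trd)], trd$total[1])
})

test_that("exact and tDMRG trajectory engines agree", {
  p <- fx_p6()
  init <- fx_init6()
  tr1 <- run_trajectory(p, 0.5, engine = "exact", init = init,
                        analyse_every = 50)
  tr2 <- run_trajectory(p, 0.5, engine = "tdmrg", init = init,
                        analyse_every = 50, max_states = 64, cutoff = 1e-10)
  last1 <- tr1$adiabatic[[nrow(tr1)]]
  last2 <- tr2$adiabatic[[nrow(tr2)]]
  expect_close(last1, last2, 1e-3)
  expect_close(attr(tr1, "chain")$displacements,
               attr(tr2, "chain")$displacements, 1e-5)
})
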