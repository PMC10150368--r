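test_that("the projected dipole seed lives in the dark sector", {
  p <- fx_p6(); b <- fx_b6()
  rel <- fx_rel6()
  ee <- exact_eigenstates(p, rel$chain, b, k = 12)
  mu <- dipole_operator(p, rel$chain, b)
  ibright <- which(ee$c2_parity < 0 & ee$ph_parity > 0)[1]
  src <- sector_state(ee$vector[[ibright]], b, normalize = FALSE)
  sd <- seed_state(src, mu, ee$vector[seq_len(ibright)])
  # orthogonal to every projected-out state
  for (j in seq_len(ibright)) {
    expect_lt(Mod(sum(Conj(ee$vector[[j]]) * sd$state$vec)), 1e-10)
  }
  # the seed from a Bu state lies entirely in the Ag sector
  c2 <- polyenedyn:::c2_matrix(b)
  par <- Re(sum(Conj(sd$state$vec) *
                  polyenedyn:::sp_mult(c2, sd$state$vec)))
  expect_equal(par, 1, tolerance = 1e-8)
  # dipole diagonal in the source basis from the top state: zero seed
  top <- sector_state(ee$vector[[12]], b, normalize = FALSE)
  expect_error(seed_state(top, Matrix::Diagonal(b$dim, 0), ee$vector[1:12]),
               "no stimulated absorption")
})

test_that("Lanczos chains reproduce dense spectra in the invariant subspace", {
  p <- fx_p4()
  ch <- fx_ch4()
  b <- fx_b4()
  ee <- exact_eigenstates(p, ch, b, k = b$dim, label_symmetries = FALSE)
  h <- full_hamiltonian(p, ch, b)
  happ <- function(x) polyenedyn:::sp_mult(h, x)
  # seeding with an exact eigenstate: chain length 1, a0 = its energy
  lc1 <- lanczos_tridiagonalize(ee$vector[[3]], happ, 10)
  expect_equal(length(lc1$a), 1)
  expect_equal(lc1$a[1], ee$energy[3], tolerance = 1e-8)
  # full-dimension chain: tridiagonal spectrum = spectrum of the seed's
  # invariant subspace (matches sum-over-states lines)
  mu <- dipole_operator(p, ch, b)
  src <- sector_state(ee$vector[[2]], b, normalize = FALSE)
  sd <- seed_state(src, mu, ee$vector[1:2])
  lc <- lanczos_tridiagonalize(sd$state$vec, happ, b$dim, seed_norm = sd$norm)
  sp <- spectrum_from_chain(lc, ee$energy[2], strength_tol = 1e-10)
  oracle <- spectrum_sum_over_states(p, ch, source_index = 1,
                                     strength_tol = 1e-10)
  # match every oracle line with strength above the floor
  for (i in seq_len(nrow(oracle))) {
    j <- which.min(abs(sp$energy - oracle$energy[i]))
    expect_lt(abs(sp$energy[j] - oracle$energy[i]), 1e-6)
    expect_lt(abs(sp$strength[j] - oracle$strength[i]), 1e-6)
  }
  # total line strength equals the squared seed norm
  expect_equal(sum(sp$strength), sd$norm^2, tolerance = 1e-6)
})

test_that("extremal Ritz values converge monotonically with chain length", {
  p <- fx_p6(); ch <- fx_ch6(); b <- fx_b6()
  h <- full_hamiltonian(p, ch, b)
  happ <- function(x) polyenedyn:::sp_mult(h, x)
  seed <- sin(seq_len(b$dim)) + 0.5
  seed <- seed / sqrt(sum(seed^2))
  tops <- vapply(c(3, 6, 12, 24), function(nv) {
    lc <- lanczos_tridiagonalize(seed, happ, nv)
    min(polyenedyn:::tridiag_eigen(lc)$values)
  }, numeric(1))
  expect_true(all(diff(tops) < 1e-12))
})

test_that("spectral weights are normalized and scale-invariant", {
  p <- fx_p4(); ch <- fx_ch4(); b <- fx_b4()
  ee <- exact_eigenstates(p, ch, b, k = b$dim, label_symmetries = FALSE)
  h <- full_hamiltonian(p, ch, b)
  happ <- function(x) polyenedyn:::sp_mult(h, x)
  mu <- dipole_operator(p, ch, b)
  src <- sector_state(ee$vector[[2]], b, normalize = FALSE)
  sd <- seed_state(src, mu, ee$vector[1:2])
  lc <- lanczos_tridiagonalize(sd$state$vec, happ, 8, seed_norm = sd$norm)
  w <- lanczos_weights(lc)
  expect_true(all(w >= -1e-14))
  expect_equal(sum(w), 1, tolerance = 1e-10)
  # rescaling the seed leaves the weights untouched
  lc2 <- lanczos_tridiagonalize(2.5 * sd$state$vec, happ, 8,
                                seed_norm = 2.5 * sd$norm)
  expect_close(lanczos_weights(lc2), w, 1e-10)
  # chain of length 1: w0 = 1
  lcone <- lanczos_tridiagonalize(ee$vector[[5]], happ, 1)
  expect_equal(lanczos_weights(lcone), 1)
})

test_that("the targeting protocol reduces to the static absorption at t = 0", {
  # acceptance-grade full comparison runs in the acceptance suite; here a
  # lean protocol run checks bookkeeping on the weak-eps system
  fxw <- make_fixture("n6_weak_eps")
  p <- fxw$params
  rel <- relax_geometry(p, 0, "exact")
  init <- prepare_initial_state(p)
  sp <- transient_spectrum(init$state, p, init$chain, n_lanczos = 5,
                           n_spectrum = 40, max_states = 96, cutoff = 1e-8,
                           time = 0)
  expect_true(all(sp$strength >= 0))
  expect_equal(sp$intensity[1], 1)
  expect_identical(attr(sp, "source_index"), init$index)
  expect_lt(attr(sp, "max_discarded"), 1e-4)
  # positions are physical absorption energies (above the source)
  expect_true(all(sp$energy > 0))
})
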