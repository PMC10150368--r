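test_that("populations are squared overlaps with the expected structure", {
  p <- fx_p6(); ch <- fx_ch6(); b <- fx_b6()
  adia <- exact_eigenstates(p, ch, b, k = 6, label_symmetries = FALSE)
  diab <- exact_eigenstates(p, ch, b, k = 6)   # eps = 0: identical operator
  pp <- populations(sector_state(adia$vector[[2]], b), adia, diab)
  # the state IS S1: unit population there, zero elsewhere
  expect_equal(pp$adiabatic$prob[2], 1, tolerance = 1e-10)
  expect_lt(max(pp$adiabatic$prob[-2]), 1e-10)
  # eps = 0: overlap matrix is permutation-like 0/1
  expect_close(pp$overlap, diag(6), 1e-8)
  # weak eps: the adiabats are near-complete in the tracked diabats
  fxw <- make_fixture("n6_weak_eps")
  adw <- exact_eigenstates(fxw$params, fxw$chain, b, k = 6,
                           label_symmetries = FALSE)
  diw <- exact_eigenstates(polyenedyn:::strip_symmetry_breaking(fxw$params),
                           fxw$chain, b, k = 6)
  ppw <- populations(sector_state(adw$vector[[2]], b), adw, diw)
  expect_gt(sum(ppw$overlap[2, ]), 0.99)
})

test_that("ionicity classifies bright vs dark diabats", {
  ee <- fx_ee6(); b <- fx_b6()
  sing <- ee[ee$s_squared < 0.1, ]
  ibright <- which(sing$c2_parity < 0 & sing$ph_parity > 0)[1]
  idark <- which(sing$c2_parity > 0 & sing$ph_parity < 0 & sing$state > 0)[1]
  expect_identical(classify_diabat(sing$vector[[ibright]], ee, b), "ionic")
  expect_identical(classify_diabat(sing$vector[[idark]], ee, b), "covalent")
  # covalent product configuration is covalent
  word <- sum(4^(0:5) * c(1, 2, 1, 2, 1, 2))
  vec <- rep(0, b$dim); vec[match(word, b$words)] <- 1
  expect_identical(classify_diabat(vec, ee, b), "covalent")
})

test_that("the classical probability is the period-average of the coherence", {
  # synthetic two-level system: adiabats rotated from diabats by a mixing
  # angle, state a fixed superposition of the adiabats
  theta <- 0.6
  a <- cos(theta); bcoef <- sin(theta)
  psi1 <- sqrt(0.7); psi2 <- sqrt(0.3)
  gap <- 1.3
  hbar <- pd_constants[["hbar_ev_fs"]]
  # P(phi2)(t) = |psi1 b + psi2 a e^{-i gap t/hbar}|^2
  pt <- function(t) Mod(psi1 * bcoef + psi2 * a * exp(-1i * gap * t / hbar))^2
  period <- 2 * pi * hbar / gap
  ts <- seq(0, 3 * period, length.out = 3001)[-3001]
  avg <- mean(pt(ts))
  pcl <- psi1^2 * bcoef^2 + psi2^2 * a^2
  expect_lt(abs(avg - pcl), 1e-3)
  # the oscillation frequency equals the adiabatic gap / hbar
  ft <- pt(ts) - mean(pt(ts))
  zero_cross <- which(diff(sign(ft)) != 0)
  # collapse double counts where the signal grazes zero on a grid point
  zero_cross <- zero_cross[c(TRUE, diff(zero_cross) > 10)]
  period_est <- 2 * mean(diff(zero_cross)) * diff(ts)[1]
  expect_lt(abs(period_est - period) / period, 0.01)
  # exact two-level closure: probabilities for phi1 and phi2 sum to 1
  pcl1 <- psi1^2 * a^2 + psi2^2 * bcoef^2
  expect_equal(pcl + pcl1, 1, tolerance = 1e-12)
})

test_that("classical_probability handles the single-adiabat and invalid limits", {
  fxw <- make_fixture("n6_weak_eps")
  b <- fx_b6()
  adw <- exact_eigenstates(fxw$params, fxw$chain, b, k = 6,
                           label_symmetries = FALSE)
  diw <- exact_eigenstates(polyenedyn:::strip_symmetry_breaking(fxw$params),
                           fxw$chain, b, k = 6)
  # state = S1 exactly: psi2 = 0, P_classical = P(S1; phi_target)
  st <- sector_state(adw$vector[[2]], b)
  tlm <- two_level_model(st, adw, diw, i1 = 2, i2 = 3, j1 = 2, j2 = 3)
  pcl <- classical_probability(tlm, target = 1)
  expect_equal(as.numeric(pcl), tlm$overlap_sq[1, 1], tolerance = 1e-10)
  expect_true(attr(pcl, "valid"))
  # a state spread over many adiabats invalidates the two-level reduction
  vbad <- Reduce(`+`, adw$vector[1:5])
  stb <- sector_state(vbad, b)
  tlb <- two_level_model(stb, adw, diw)
  expect_false(tlb$valid)
  expect_warning(classical_probability(tlb), "two-level")
})

test_that("the Landau-Zener scan isolates per-point failures", {
  fxz <- make_fixture("lz_mini")
  p <- fxz$params
  # an absurd zeta breaks model validation inside the scan but the scan
  # continues and flags the row
  expect_warning(sc <- lz_scan(p, zeta = c(NA), probe_time = 0.1), "failed")
  expect_true(is.na(sc$p_s1[1]))
})
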