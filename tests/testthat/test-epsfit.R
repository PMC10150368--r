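test_that("ground-state densities respect symmetry and perturbations", {
  p <- model_params(4, lambda_spin = 2)
  # eps = 0, mirror-symmetric geometry: all densities 1 at half filling
  d0 <- ground_state_densities(p)
  expect_close(d0, rep(1, 4), 1e-8)
  expect_equal(sum(d0), 4, tolerance = 1e-8)
  # a strong single-site well attracts density > 1
  pw <- model_params(4, lambda_spin = 2, eps = c(-0.8, 0, 0, 0))
  dw <- ground_state_densities(pw)
  expect_gt(dw[1], 1)
  # mirror-symmetric eps gives mirror-symmetric densities
  pm <- model_params(4, lambda_spin = 2, eps = c(0.3, -0.3, -0.3, 0.3))
  dm <- ground_state_densities(pm)
  expect_close(dm, rev(dm), 1e-8)
  # exact and DMRG engines agree
  ddm <- ground_state_densities(pw, engine = "dmrg", max_states = 64,
                                cutoff = 1e-12)
  expect_close(ddm, dw, 1e-6)
})

test_that("r_squared behaves as a coefficient of determination", {
  d_opt <- c(0.9, 1.1, 1.05, 0.95)
  expect_equal(r_squared(d_opt, d_opt), 1)
  expect_equal(r_squared(d_opt, rep(mean(d_opt), 4)), 0)
  # invariant under common mean shift
  expect_equal(r_squared(d_opt + 0.3, d_opt + 0.3 + c(0.01, -0.01, 0, 0)),
               r_squared(d_opt, d_opt + c(0.01, -0.01, 0, 0)))
  # monotone degradation under growing perturbation
  set.seed(7)
  noise <- rnorm(4, 0, 0.01)
  r1 <- r_squared(d_opt, d_opt + noise)
  r2 <- r_squared(d_opt, d_opt + 3 * noise)
  expect_gt(r1, r2)
  expect_error(r_squared(rep(1, 4), rep(1, 4)), "zero-variance")
  expect_error(r_squared(d_opt, d_opt[1:3]), "length")
})

test_that("density_target enforces charge neutrality", {
  t1 <- density_target(c(0.5, 0.7, 0.6, 0.4))
  expect_equal(mean(t1$d_opt), 1)
  expect_error(density_target(c(1, NA)), "invalid")
})

test_that("the all-ones target has eps = 0 as its fixed point", {
  p <- model_params(4, lambda_spin = 2)
  tgt <- density_target(rep(1, 4))
  fit <- projected_gradient_fit(tgt, p, max_iter = 3)
  expect_lt(max(abs(fit$eps)), 1e-6)
  expect_lt(fit$objective, 1e-6)
  # r^2 is undefined against a zero-variance target and reported as NA
  expect_true(is.na(fit$r_squared))
})

test_that("parameter recovery and box projection work at N = 4", {
  p <- model_params(4, lambda_spin = 2)
  eps_star <- c(0.4, -0.25, 0.15, -0.3)
  pstar <- model_params(4, lambda_spin = 2, eps = eps_star)
  d_opt <- ground_state_densities(pstar)
  fit <- projected_gradient_fit(density_target(d_opt), p, max_iter = 40)
  expect_gt(fit$r_squared, 0.99)
  # objective non-increasing on accepted steps
  expect_true(all(diff(fit$trace$objective) <= 1e-12))
  expect_true(all(abs(fit$eps) <= 1 + 1e-12))
  # an extreme target saturates the box but never violates it
  tgt_ex <- density_target(c(0.2, 1.8, 0.2, 1.8), eps_max = 0.3)
  fit_ex <- projected_gradient_fit(tgt_ex, p, max_iter = 15)
  expect_true(all(abs(fit_ex$eps) <= 0.3 + 1e-12))
  expect_gt(sum(abs(abs(fit_ex$eps) - 0.3) < 1e-9), 0)
  # descent direction agrees in sign with the objective decrease
  expect_lt(fit$trace$objective[2], fit$trace$objective[1])
})
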