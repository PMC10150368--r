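# DMRG core machinery: MPO of the UV-Peierls Hamiltonian, block environments,
# effective two-site Hamiltonian application, Davidson diagonalization and
# ensemble (multi-state) density-matrix truncation.
#
# The MPO is lower-bandwidth sparse and stored per site as a list of
# (from-lane, to-lane, 4x4 operator) triplets. Lane layout:
#   1 start | 2-5 hopping in flight | 6 nearest-neighbour V | 7-9 total-spin
#   lanes (Sz, S+, S-) with identity continuation | 10 electron-number lane |
#   11 end.
#
# The renormalised basis spans all occupation sectors, so the working MPO can
# carry a quadratic electron-number penalty w_N (N_hat - N_e)^2. It vanishes
# identically on the physical fixed-filling sector and pushes every other
# sector up, playing the role the quantum-number bookkeeping plays in
# symmetry-adapted DMRG codes.

mpo_lanes <- 11L

# MPO site tensors for H = H_UVP + H_eps (+ lambda S^2) + elastic scalar
# (+ number penalty).
build_mpo <- function(params, chain, spin_penalty = TRUE,
                      n_electrons = params$n_sites, number_penalty = 20) {
  op <- site_operators()
  N <- params$n_sites
  w <- mpo_lanes
  id <- diag(4)
  nm1 <- op$n_tot - id
  beta <- chain$bond_hoppings
  lam <- params$lambda_spin
  wn <- number_penalty
  lapply(seq_len(N), function(n) {
    terms <- list()
    add <- function(from, to, mat) {
      terms[[length(terms) + 1]] <<- list(from = from, to = to, op = mat)
    }
    add(1, 1, id)
    add(w, w, id)
    local <- params$u_coulomb * op$n_up %*% op$n_dn +
      params$eps[n] * nm1
    if (spin_penalty) local <- local + lam * op$s2_local
    if (wn > 0) {
      local <- local + wn * (op$n_tot %*% op$n_tot - 2 * n_electrons * op$n_tot) +
        (wn * n_electrons^2 / N) * id
    }
    if (n == 1) local <- local + elastic_energy(params, chain) * id
    add(1, w, local)
    if (n < N) {             # starters for bond n
      add(1, 2, op$cdag_up %*% op$parity)
      add(1, 3, op$parity %*% op$c_up)
      add(1, 4, op$cdag_dn %*% op$parity)
      add(1, 5, op$parity %*% op$c_dn)
      add(1, 6, params$v_coulomb * nm1)
      if (spin_penalty) {
        add(1, 7, op$s_z); add(1, 8, op$s_plus); add(1, 9, op$s_minus)
      }
      if (wn > 0) add(1, 10, op$n_tot)
    }
    if (n > 1) {             # finishers for bond n-1
      b <- beta[n - 1]
      add(2, w, -b * op$c_up)
      add(3, w, -b * op$cdag_up)
      add(4, w, -b * op$c_dn)
      add(5, w, -b * op$cdag_dn)
      add(6, w, nm1)
      if (spin_penalty) {
        add(7, w, 2 * lam * op$s_z)
        add(8, w, lam * op$s_minus)
        add(9, w, lam * op$s_plus)
      }
      if (wn > 0) add(10, w, 2 * wn * op$n_tot)
    }
    if (n > 1 && n < N) {
      if (spin_penalty) { add(7, 7, id); add(8, 8, id); add(9, 9, id) }
      if (wn > 0) add(10, 10, id)
    }
    terms
  })
}

# Dipole moment as a 2-lane MPO (for superblock dipole application).
build_dipole_mpo <- function(params, chain) {
  op <- site_operators()
  N <- params$n_sites
  x <- (seq_len(N) - 1) * params$lattice_spacing + chain$displacements
  x <- x - mean(x)
  lapply(seq_len(N), function(n) {
    list(list(from = 1, to = 1, op = diag(4)),
         list(from = 2, to = 2, op = diag(4)),
         list(from = 1, to = 2, op = -x[n] * (op$n_tot - diag(4))))
  })
}

mpo_width <- function(mpo) max(vapply(mpo[[1]], function(t) t$to, numeric(1)))

# environment boundaries: list of per-lane matrices (NULL = absent lane)
# boundaries are real; complex states promote the contraction type as needed
env_left_boundary <- function(w) {
  e <- vector("list", w); e[[1]] <- matrix(1, 1, 1); e
}
env_right_boundary <- function(w) {
  e <- vector("list", w); e[[w]] <- matrix(1, 1, 1); e
}

tensor_slices <- function(a) lapply(1:4, function(s) {
  matrix(a[, s, ], dim(a)[1], dim(a)[3])
})

# absorb site tensor `a` (ket = a, bra = Conj(a)) into a left environment
env_absorb_left <- function(env, terms, a) {
  w <- length(env)
  as_ <- tensor_slices(a)
  dr <- dim(a)[3]
  out <- vector("list", w)
  pre <- vector("list", w)  # pre[[lane]][[s]] = env_lane %*% a_s
  for (tm in terms) {
    L <- env[[tm$from]]
    if (is.null(L)) next
    if (is.null(pre[[tm$from]])) {
      pre[[tm$from]] <- lapply(as_, function(m) L %*% m)
    }
    p <- pre[[tm$from]]
    acc <- matrix(0, dr, dr)
    for (sp in 1:4) {
      comb <- NULL
      for (s in 1:4) {
        if (tm$op[sp, s] != 0) {
          comb <- if (is.null(comb)) tm$op[sp, s] * p[[s]] else comb + tm$op[sp, s] * p[[s]]
        }
      }
      if (!is.null(comb)) acc <- acc + Conj(t(as_[[sp]])) %*% comb
    }
    out[[tm$to]] <- if (is.null(out[[tm$to]])) acc else out[[tm$to]] + acc
  }
  out
}

# absorb site tensor into a right environment
env_absorb_right <- function(env, terms, a) {
  w <- length(env)
  as_ <- tensor_slices(a)
  dl <- dim(a)[1]
  out <- vector("list", w)
  pre <- vector("list", w)  # pre[[lane]][[s]] = R_lane %*% t(a_s):  (Drbra x Dl)
  for (tm in terms) {
    R <- env[[tm$to]]
    if (is.null(R)) next
    if (is.null(pre[[tm$to]])) {
      pre[[tm$to]] <- lapply(as_, function(m) R %*% t(m))
    }
    p <- pre[[tm$to]]
    acc <- matrix(0, dl, dl)
    for (sp in 1:4) {
      comb <- NULL
      for (s in 1:4) {
        if (tm$op[sp, s] != 0) {
          comb <- if (is.null(comb)) tm$op[sp, s] * p[[s]] else comb + tm$op[sp, s] * p[[s]]
        }
      }
      if (!is.null(comb)) acc <- acc + Conj(as_[[sp]]) %*% comb
    }
    # acc[i_bra, i_ket]
    out[[tm$from]] <- if (is.null(out[[tm$from]])) acc else out[[tm$from]] + acc
  }
  out
}

# Effective two-site operator application: theta (Dl,4,4,Dr) -> H_eff theta.
# The two-site wavefunction is handled as 16 (Dl x Dr) slices indexed by
# (s1, s2), so every contraction is a plain matrix product.
eff_apply <- function(theta, lenv, t1, t2, renv) {
  d <- dim(theta)
  w <- length(lenv)
  dl <- d[1]; dr <- d[4]
  idx <- function(s1, s2) s1 + 4L * (s2 - 1L)
  sl <- vector("list", 16L)
  for (s2 in 1:4) for (s1 in 1:4) {
    sl[[idx(s1, s2)]] <- matrix(theta[, s1, s2, ], dl, dr)
  }
  # left environment per active lane
  lsl <- vector("list", w)
  for (a in seq_len(w)) {
    if (!is.null(lenv[[a]])) lsl[[a]] <- lapply(sl, function(m) lenv[[a]] %*% m)
  }
  # first site MPO (acts on s1)
  w1 <- vector("list", w)
  for (tm in t1) {
    x <- lsl[[tm$from]]
    if (is.null(x)) next
    tgt <- w1[[tm$to]]
    if (is.null(tgt)) tgt <- vector("list", 16L)
    for (s1o in 1:4) {
      cf <- tm$op[s1o, ]
      nz <- which(cf != 0)
      if (!length(nz)) next
      for (s2 in 1:4) {
        acc <- tgt[[idx(s1o, s2)]]
        for (s in nz) {
          term <- cf[s] * x[[idx(s, s2)]]
          acc <- if (is.null(acc)) term else acc + term
        }
        if (!is.null(acc)) tgt[[idx(s1o, s2)]] <- acc
      }
    }
    w1[[tm$to]] <- tgt
  }
  # second site MPO (acts on s2)
  w2 <- vector("list", w)
  for (tm in t2) {
    x <- w1[[tm$from]]
    if (is.null(x)) next
    tgt <- w2[[tm$to]]
    if (is.null(tgt)) tgt <- vector("list", 16L)
    for (s2o in 1:4) {
      cf <- tm$op[s2o, ]
      nz <- which(cf != 0)
      if (!length(nz)) next
      for (s1 in 1:4) {
        acc <- tgt[[idx(s1, s2o)]]
        for (s in nz) {
          x1 <- x[[idx(s1, s)]]
          if (is.null(x1)) next
          term <- cf[s] * x1
          acc <- if (is.null(acc)) term else acc + term
        }
        if (!is.null(acc)) tgt[[idx(s1, s2o)]] <- acc
      }
    }
    w2[[tm$to]] <- tgt
  }
  # right environment and reassembly
  out <- array(if (is.complex(theta)) 0 + 0i else 0, d)
  for (c_ in seq_len(w)) {
    x <- w2[[c_]]; R <- renv[[c_]]
    if (is.null(x) || is.null(R)) next
    tr_ <- t(R)
    for (s2 in 1:4) for (s1 in 1:4) {
      m <- x[[idx(s1, s2)]]
      if (is.null(m)) next
      out[, s1, s2, ] <- out[, s1, s2, ] + m %*% tr_
    }
  }
  out
}

# diagonal of the effective two-site Hamiltonian (for preconditioning)
eff_diag <- function(lenv, t1, t2, renv, d) {
  out <- array(0, d)
  for (tm1 in t1) {
    if (is.null(lenv[[tm1$from]])) next
    dl <- Re(diag(lenv[[tm1$from]]))
    o1 <- Re(diag(tm1$op))
    if (all(o1 == 0)) next
    for (tm2 in t2) {
      if (tm2$from != tm1$to || is.null(renv[[tm2$to]])) next
      o2 <- Re(diag(tm2$op))
      if (all(o2 == 0)) next
      dr <- Re(diag(renv[[tm2$to]]))
      out <- out + outer(dl, o1) %o% outer(o2, dr)
    }
  }
  array(out, d)
}

orthonormalize_cols <- function(v, against = NULL, tol = 1e-10) {
  keep <- NULL
  for (j in seq_len(ncol(v))) {
    x <- v[, j]
    if (!is.null(against)) x <- x - against %*% (Conj(t(against)) %*% x)
    if (!is.null(keep)) x <- x - keep %*% (Conj(t(keep)) %*% x)
    # second pass for numerical safety
    if (!is.null(against)) x <- x - against %*% (Conj(t(against)) %*% x)
    if (!is.null(keep)) x <- x - keep %*% (Conj(t(keep)) %*% x)
    nx <- sqrt(Re(sum(Conj(x) * x)))
    if (nx > tol) keep <- cbind(keep, x / nx)
  }
  keep
}

# Block Davidson for the k lowest eigenpairs of a Hermitian operator given as
# a matvec closure, with diagonal preconditioning and thick restarts.
davidson <- function(matvec, diag_h, k, guesses, tol = 1e-9, max_iter = 200,
                     max_basis = NULL, augment = FALSE) {
  n <- length(diag_h)
  k <- min(k, n)
  if (is.null(max_basis)) max_basis <- min(n, max(4 * k + 12, 30))
  if (augment) {
    # unit vectors on the smallest diagonal entries: guarantees overlap with
    # the low-energy physical sector even when the structured guesses span an
    # invariant excited subspace
    low <- order(diag_h)[seq_len(min(k + 2, n))]
    aug <- matrix(0, n, length(low))
    aug[cbind(low, seq_along(low))] <- 1
    guesses <- cbind(guesses, aug)
  }
  v <- if (is.null(guesses)) NULL else orthonormalize_cols(guesses)
  if (is.null(v) || ncol(v) < k) {
    # deterministic (RNG-free) basis completion
    miss <- k - ifelse(is.null(v), 0, ncol(v)) + 1
    extra <- matrix(cos(outer(seq_len(n), seq_len(miss), function(i, j) {
      (i * 7919 + j * 104729) %% 1000 / 159
    })), n)
    v <- orthonormalize_cols(cbind(v, extra))
  }
  hv <- NULL
  for (iter in seq_len(max_iter)) {
    if (is.null(hv)) {
      hv <- do.call(cbind, lapply(seq_len(ncol(v)), function(j) matvec(v[, j])))
    } else if (ncol(hv) < ncol(v)) {
      newcols <- (ncol(hv) + 1):ncol(v)
      hv <- cbind(hv, do.call(cbind, lapply(newcols, function(j) matvec(v[, j]))))
    }
    hsub <- Conj(t(v)) %*% hv
    hsub <- (hsub + Conj(t(hsub))) / 2
    es <- eigen(hsub)
    ord <- order(Re(es$values))
    theta <- Re(es$values)[ord][seq_len(k)]
    y <- es$vectors[, ord[seq_len(k)], drop = FALSE]
    x <- v %*% y
    hx <- hv %*% y
    res <- hx - x %*% diag(theta, k)
    rn <- sqrt(Re(colSums(Conj(res) * res)))
    if (all(rn < tol) || ncol(v) >= n) {
      return(list(values = theta, vectors = x, resid = rn, iters = iter))
    }
    if (ncol(v) + k > max_basis) {     # thick restart from the Ritz vectors
      v <- orthonormalize_cols(x)
      hv <- do.call(cbind, lapply(seq_len(ncol(v)), function(j) matvec(v[, j])))
    }
    newdirs <- NULL
    for (i in seq_len(k)) {
      if (rn[i] < tol) next
      denom <- diag_h - theta[i]
      denom[abs(denom) < 1e-8] <- 1e-8
      newdirs <- cbind(newdirs, res[, i] / denom)
    }
    vadd <- orthonormalize_cols(newdirs, against = v)
    if (is.null(vadd)) {
      return(list(values = theta, vectors = x, resid = rn, iters = iter))
    }
    v <- cbind(v, vadd)
  }
  list(values = theta, vectors = x, resid = rn, iters = max_iter)
}

#' Ensemble density-matrix truncation
#'
#' Builds the reduced density matrix of a weighted ensemble of superblock
#' states (all sharing one two-site factorization), diagonalizes it, and
#' retains the eigenvectors with the largest eigenvalues. For a single state
#' this is identical to the Schmidt truncation and the discarded weight equals
#' the quadratic-norm loss of the optimal truncated state.
#'
#' @param thetas List of arrays `(Dl, 4, 4, Dr)` (need not be normalized).
#' @param weights Ensemble weights `kappa_i` (normalised internally).
#' @param side `"left"` (truncate the augmented system block, spanning
#'   `Dl x 4`) or `"right"` (`4 x Dr`).
#' @param max_states,cutoff Retention cap and discarded-weight target.
#' @return List: `proj` (isometry, columns orthonormal), and `report`
#'   (a one-row tibble: discarded, retained, entropy).
#' @export
dm_truncate <- function(thetas, weights = NULL, side = c("left", "right"),
                        max_states = Inf, cutoff = 0) {
  side <- match.arg(side)
  if (is.null(weights)) weights <- rep(1 / length(thetas), length(thetas))
  stopifnot(length(weights) == length(thetas), all(weights >= 0))
  wsum <- sum(weights)
  if (wsum <= 0) stop("zero-weight ensemble")
  weights <- weights / wsum
  d <- dim(thetas[[1]])
  rho <- NULL
  for (i in seq_along(thetas)) {
    nrm2 <- Re(sum(Conj(thetas[[i]]) * thetas[[i]]))
    if (nrm2 < 1e-300) {
      if (weights[i] > 0) stop("zero-norm state in ensemble")
      next
    }
    m <- if (side == "left") {
      matrix(thetas[[i]], d[1] * 4L, 4L * d[4])
    } else {
      t(matrix(thetas[[i]], d[1] * 4L, 4L * d[4]))
    }
    contrib <- (weights[i] / nrm2) * (m %*% Conj(t(m)))
    rho <- if (is.null(rho)) contrib else rho + contrib
  }
  rho <- (rho + Conj(t(rho))) / 2
  es <- eigen(rho)
  ev <- pmax(Re(es$values), 0)
  keep <- trunc_rank(sqrt(ev), max_states, cutoff)
  disc <- sum(ev[-seq_len(keep)])
  omega <- ev[seq_len(keep)]
  omega_n <- omega[omega > 1e-16]
  entropy <- -sum(omega_n * log(omega_n))
  list(proj = es$vectors[, seq_len(keep), drop = FALSE],
       report = tibble::tibble(discarded = disc, retained = keep,
                               entropy = entropy))
}

# Total-spin-squared operator as a standalone MPO (diagnostics).
build_s2_mpo <- function(n_sites) {
  op <- site_operators()
  id <- diag(4)
  lapply(seq_len(n_sites), function(n) {
    terms <- list(
      list(from = 1, to = 1, op = id), list(from = 5, to = 5, op = id),
      list(from = 1, to = 5, op = op$s2_local)
    )
    if (n < n_sites) {
      terms <- c(terms, list(
        list(from = 1, to = 2, op = op$s_z),
        list(from = 1, to = 3, op = op$s_plus),
        list(from = 1, to = 4, op = op$s_minus)
      ))
    }
    if (n > 1) {
      terms <- c(terms, list(
        list(from = 2, to = 5, op = 2 * op$s_z),
        list(from = 3, to = 5, op = op$s_minus),
        list(from = 4, to = 5, op = op$s_plus)
      ))
    }
    if (n > 1 && n < n_sites) {
      terms <- c(terms, list(
        list(from = 2, to = 2, op = id), list(from = 3, to = 3, op = id),
        list(from = 4, to = 4, op = id)
      ))
    }
    terms
  })
}

# expectation <mps| MPO |mps> via left-to-right environment contraction
mpo_expectation <- function(mps, mpo) {
  w <- mpo_width(mpo)
  env <- env_left_boundary(w)
  for (n in seq_len(mps$n_sites)) {
    env <- env_absorb_left(env, mpo[[n]], mps$tensors[[n]])
  }
  Re(env[[w]][1, 1])
}
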