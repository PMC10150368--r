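# Static two-site DMRG: infinite-algorithm warm-up, finite sweeps with
# wavefunction-mapped initial guesses, multi-state (ensemble) targeting and
# Davidson diagonalization of the effective superblock Hamiltonian.

new_dmrg_engine <- function(params, chain, mpo, n_states, max_states, cutoff,
                            weights = NULL) {
  N <- params$n_sites
  w <- mpo_width(mpo)
  if (is.null(weights)) weights <- rep(1 / n_states, n_states)
  list(
    params = params, chain = chain, mpo = mpo, N = N, w = w,
    n_states = n_states, weights = weights / sum(weights),
    max_states = max_states, cutoff = cutoff,
    A = vector("list", N), B = vector("list", N),
    Lenv = c(list(env_left_boundary(w)), vector("list", N)),   # Lenv[[n+1]]: sites 1..n
    Renv = c(vector("list", N), list(env_right_boundary(w))),  # Renv[[n]]: sites n..N
    pos = NA_integer_, thetas = NULL, energies = NULL,
    log = list(), sweep_id = 0L
  )
}

bond_dims <- function(eng) {
  dl <- if (eng$pos == 1) 1L else dim(eng$A[[eng$pos - 1]])[3]
  dr <- if (eng$pos == eng$N - 1) 1L else dim(eng$B[[eng$pos + 2]])[1]
  c(dl, 4L, 4L, dr)
}

solve_bond <- function(eng, guesses = NULL, k = eng$n_states, tol = 1e-9) {
  d <- bond_dims(eng)
  lenv <- eng$Lenv[[eng$pos]]
  renv <- eng$Renv[[eng$pos + 2]]
  t1 <- eng$mpo[[eng$pos]]; t2 <- eng$mpo[[eng$pos + 1]]
  nvec <- prod(d)
  mv <- function(x) as.vector(eff_apply(array(x, d), lenv, t1, t2, renv))
  dg <- as.vector(eff_diag(lenv, t1, t2, renv, d))
  gm <- if (!is.null(guesses)) {
    do.call(cbind, lapply(guesses, as.vector))
  } else NULL
  sol <- davidson(mv, dg, k = min(k, nvec), guesses = gm, tol = tol)
  gov <- if (!is.null(gm)) {
    Mod(sum(Conj(gm[, 1] / sqrt(sum(Mod(gm[, 1])^2))) * sol$vectors[, 1]))
  } else NA_real_
  list(energies = sol$values,
       thetas = lapply(seq_len(ncol(sol$vectors)),
                       function(i) array(sol$vectors[, i], d)),
       iters = sol$iters, guess_overlap = gov)
}

log_row <- function(eng, bond, direction, rep, extra = list()) {
  eng$log[[length(eng$log) + 1]] <- tibble::tibble(
    sweep = eng$sweep_id, bond = bond, direction = direction,
    discarded = rep$discarded, retained = rep$retained,
    entropy = rep$entropy, energy = eng$energies[1],
    guess_overlap = if (!is.null(extra$guess_overlap)) extra$guess_overlap else NA_real_
  )
  eng
}

#' Infinite-algorithm DMRG warm-up
#'
#' Grows system and environment blocks two sites per step from the chain ends,
#' solving the superblock at each growth step and truncating both augmented
#' blocks with the (ensemble) density matrix, until the superblock spans the
#' full chain. The final step diagonalizes the true Hamiltonian at the middle
#' bond.
#'
#' @param params,chain Model and geometry.
#' @param n_states Number of targeted states.
#' @param max_states,cutoff Truncation controls (default from `params`).
#' @param spin_penalty Include `lambda * S^2`.
#' @param weights Targeting weights `kappa_i` (default equal).
#' @return A DMRG engine object (list) positioned at the middle bond, for use
#'   with [dmrg_sweep()] or [dmrg_run()].
#' @export
dmrg_warmup <- function(params, chain, n_states = 1,
                        max_states = params$max_states,
                        cutoff = params$trunc_cutoff,
                        spin_penalty = TRUE, weights = NULL,
                        n_electrons = params$n_sites, number_penalty = 20) {
  mpo <- build_mpo(params, chain, spin_penalty = spin_penalty,
                   n_electrons = n_electrons, number_penalty = number_penalty)
  eng <- new_dmrg_engine(params, chain, mpo, n_states, max_states, cutoff,
                         weights)
  N <- eng$N
  for (k in seq_len(N / 2)) {
    eng$pos <- k
    # during warm-up the right block starts at site N - k + 1
    rsite <- N - k + 1
    dfix <- c(if (k == 1) 1L else dim(eng$A[[k - 1]])[3], 4L, 4L,
              if (k == 1) 1L else dim(eng$B[[rsite + 1]])[1])
    # solve with mpo tensors of sites k and rsite
    lenv <- eng$Lenv[[k]]; renv <- eng$Renv[[rsite + 1]]
    t1 <- mpo[[k]]; t2 <- mpo[[rsite]]
    nvec <- prod(dfix)
    mv <- function(x) as.vector(eff_apply(array(x, dfix), lenv, t1, t2, renv))
    dg <- as.vector(eff_diag(lenv, t1, t2, renv, dfix))
    keff <- min(eng$n_states, nvec)
    # seed with the previous growth step's states projected onto the new
    # blocks, expanded over the two fresh sites
    gm <- NULL
    if (!is.null(eng$warm_cores)) {
      gm <- do.call(cbind, lapply(eng$warm_cores, function(core) {
        g <- array(0, dfix)
        cols <- matrix(0, nvec, 16L)
        for (s2 in 1:4) for (s1 in 1:4) {
          g[] <- 0
          g[, s1, s2, ] <- core
          cols[, s1 + 4L * (s2 - 1L)] <- as.vector(g)
        }
        cols
      }))
      # one dense deterministic direction so the Davidson space cannot get
      # trapped in an invariant subspace of the structured guesses
      gm <- cbind(gm, cos(seq_len(nvec) * 0.7) + 0.3)
    }
    sol <- davidson(mv, dg, k = keff, guesses = gm, augment = TRUE,
                    max_basis = max(30, 4 * keff + 12,
                                    if (is.null(gm)) 0 else ncol(gm) + 3 * keff + 8))
    eng$energies <- sol$values
    thetas <- lapply(seq_len(ncol(sol$vectors)),
                     function(i) array(sol$vectors[, i], dfix))
    eng$thetas <- thetas
    wts <- eng$weights[seq_len(keff)]
    if (k < N / 2) {
      trl <- dm_truncate(thetas, wts, "left", max_states, cutoff)
      trr <- dm_truncate(thetas, wts, "right", max_states, cutoff)
      eng$A[[k]] <- array(trl$proj, c(dfix[1], 4, ncol(trl$proj)))
      eng$B[[rsite]] <- array(t(trr$proj), c(ncol(trr$proj), 4, dfix[4]))
      eng$Lenv[[k + 1]] <- env_absorb_left(eng$Lenv[[k]], mpo[[k]], eng$A[[k]])
      eng$Renv[[rsite]] <- env_absorb_right(eng$Renv[[rsite + 1]], mpo[[rsite]],
                                            eng$B[[rsite]])
      eng$warm_cores <- lapply(thetas, function(th) {
        Conj(t(trl$proj)) %*% matrix(th, dfix[1] * 4L, 4L * dfix[4]) %*% Conj(trr$proj)
      })
      eng <- log_row(eng, k, "warmup", trl$report)
    }
  }
  eng$pos <- as.integer(N / 2)
  eng
}

# one step of the finite algorithm: truncate at the current bond and move
step_right <- function(eng) {
  d <- bond_dims(eng)
  wts <- eng$weights[seq_along(eng$thetas)]
  tr <- dm_truncate(eng$thetas, wts, "left", eng$max_states, eng$cutoff)
  u <- tr$proj
  eng$A[[eng$pos]] <- array(u, c(d[1], 4, ncol(u)))
  eng$Lenv[[eng$pos + 1]] <- env_absorb_left(eng$Lenv[[eng$pos]],
                                             eng$mpo[[eng$pos]],
                                             eng$A[[eng$pos]])
  bnext <- eng$B[[eng$pos + 2]]
  guesses <- lapply(eng$thetas, function(th) {
    cmat <- Conj(t(u)) %*% matrix(th, d[1] * 4L, 4L * d[4])  # (M, 4*Dr)
    cten <- array(cmat, c(ncol(u), 4, d[4]))
    g <- matrix(cten, ncol(u) * 4L, d[4]) %*% matrix(bnext, d[4], 4L * dim(bnext)[3])
    array(g, c(ncol(u), 4, 4, dim(bnext)[3]))
  })
  eng$pos <- eng$pos + 1L
  sol <- solve_bond(eng, guesses)
  eng$energies <- sol$energies; eng$thetas <- sol$thetas
  eng <- log_row(eng, eng$pos - 1L, "right", tr$report,
                 list(guess_overlap = sol$guess_overlap))
  eng
}

step_left <- function(eng) {
  d <- bond_dims(eng)
  wts <- eng$weights[seq_along(eng$thetas)]
  tr <- dm_truncate(eng$thetas, wts, "right", eng$max_states, eng$cutoff)
  v <- tr$proj    # (4*Dr) x M, orthonormal columns
  eng$B[[eng$pos + 1]] <- array(t(v), c(ncol(v), 4, d[4]))
  eng$Renv[[eng$pos + 1]] <- env_absorb_right(eng$Renv[[eng$pos + 2]],
                                              eng$mpo[[eng$pos + 1]],
                                              eng$B[[eng$pos + 1]])
  aprev <- eng$A[[eng$pos - 1]]
  guesses <- lapply(eng$thetas, function(th) {
    cmat <- matrix(th, d[1] * 4L, 4L * d[4]) %*% Conj(v)     # (Dl*4, M)
    cten <- array(cmat, c(d[1], 4, ncol(v)))
    g <- matrix(aprev, dim(aprev)[1] * 4L, d[1]) %*% matrix(cten, d[1], 4L * ncol(v))
    array(g, c(dim(aprev)[1], 4, 4, ncol(v)))
  })
  eng$pos <- eng$pos - 1L
  sol <- solve_bond(eng, guesses)
  eng$energies <- sol$energies; eng$thetas <- sol$thetas
  eng <- log_row(eng, eng$pos + 1L, "left", tr$report,
                 list(guess_overlap = sol$guess_overlap))
  eng
}

#' One finite-lattice DMRG sweep segment
#'
#' Moves the two-site window from its current bond to `to` (a bond index or
#' `"right"`, `"left"`, `"middle"`), diagonalizing at every step with the
#' previous state mapped as the Davidson initial guess and truncating the
#' growing block with the targeted density matrix.
#'
#' @param eng Engine from [dmrg_warmup()].
#' @param to Target bond.
#' @return The updated engine.
#' @export
dmrg_sweep <- function(eng, to) {
  N <- eng$N
  target <- switch(as.character(to),
                   right = N - 1L, left = 1L, middle = as.integer(N / 2),
                   as.integer(to))
  while (eng$pos < target) eng <- step_right(eng)
  while (eng$pos > target) eng <- step_left(eng)
  eng
}

engine_states <- function(eng) {
  N <- eng$N
  lapply(seq_along(eng$thetas), function(i) {
    sp <- split_theta(eng$thetas[[i]], max_states = Inf, cutoff = 0,
                      center = "right")
    tensors <- vector("list", N)
    for (n in seq_len(eng$pos - 1)) tensors[[n]] <- eng$A[[n]]
    tensors[[eng$pos]] <- sp$a
    tensors[[eng$pos + 1]] <- sp$b
    for (n in seq.int(eng$pos + 2, length.out = N - eng$pos - 1)) {
      tensors[[n]] <- eng$B[[n]]
    }
    new_mps(tensors, center = eng$pos + 1L)
  })
}

#' Run static DMRG for the lowest eigenstates
#'
#' Infinite warm-up followed by finite sweeps until the ground-state energy
#' changes by less than `etol` per sweep (or `n_sweeps` is reached). With
#' `n_states > 1`, that many lowest states are targeted simultaneously in the
#' density matrix with weights `kappa` (equal by default); the returned states
#' are mutually orthogonal by construction.
#'
#' @inheritParams dmrg_warmup
#' @param n_sweeps Maximum number of full sweeps.
#' @param etol Per-sweep ground-energy convergence tolerance (eV).
#' @return A `dmrg_result`: list with `energies` (eV), `states` (list of
#'   [mps][mps_dense] objects), `log` (tibble of per-truncation reports:
#'   discarded weight, retained dimension, entropy), `converged`, `sweeps`,
#'   and the final `engine` for reuse.
#' @export
dmrg_run <- function(params, chain, n_states = 1,
                     max_states = params$max_states,
                     cutoff = params$trunc_cutoff,
                     n_sweeps = 8, etol = 1e-8,
                     spin_penalty = TRUE, weights = NULL,
                     n_electrons = params$n_sites, number_penalty = 20) {
  eng <- dmrg_warmup(params, chain, n_states, max_states, cutoff,
                     spin_penalty, weights, n_electrons, number_penalty)
  e_prev <- eng$energies[1]
  converged <- FALSE
  sweeps <- 0L
  for (s in seq_len(n_sweeps)) {
    eng$sweep_id <- s
    eng <- dmrg_sweep(eng, "right")
    eng <- dmrg_sweep(eng, "left")
    eng <- dmrg_sweep(eng, "middle")
    sweeps <- s
    if (abs(eng$energies[1] - e_prev) < etol) { converged <- TRUE; break }
    e_prev <- eng$energies[1]
  }
  structure(
    list(energies = eng$energies, states = engine_states(eng),
         log = dplyr::bind_rows(eng$log), converged = converged,
         sweeps = sweeps, engine = eng, params = params, chain = chain),
    class = "dmrg_result"
  )
}

#' @exportS3Method base::print
print.dmrg_result <- function(x, ...) {
  cat("<dmrg_result>", length(x$energies), "state(s),",
      x$sweeps, "sweep(s),", ifelse(x$converged, "converged", "NOT converged"), "\n")
  cat("  energies (eV):", paste(signif(x$energies, 10), collapse = ", "), "\n")
  cat("  max discarded weight:", signif(max(x$log$discarded), 3),
      " max retained:", max(x$log$retained), "\n")
  invisible(x)
}

#' @describeIn dmrg_run broom-style per-state summary of a fit.
#' @param x A `dmrg_result`.
#' @param ... Unused.
#' @export
tidy.dmrg_result <- function(x, ...) {
  op <- site_operators()
  docc <- op$n_up %*% op$n_dn
  s2mpo <- build_s2_mpo(x$params$n_sites)
  tibble::tibble(
    state = seq_along(x$energies) - 1L,
    energy = x$energies,
    s_squared = vapply(x$states, function(m) mpo_expectation(m, s2mpo),
                       numeric(1)),
    ionicity = vapply(x$states, function(m) {
      sum(mps_site_expectations(m, docc))
    }, numeric(1)),
    n_electrons = vapply(x$states, function(m) {
      sum(mps_site_expectations(m, op$n_tot))
    }, numeric(1))
  )
}

#' @describeIn dmrg_run one-row convergence summary.
#' @export
glance.dmrg_result <- function(x, ...) {
  tibble::tibble(
    n_states = length(x$energies), sweeps = x$sweeps, converged = x$converged,
    ground_energy = x$energies[1],
    max_discarded = max(x$log$discarded),
    max_retained = max(x$log$retained),
    max_entropy = max(x$log$entropy)
  )
}

#' broom-style generics
#'
#' @param x Object to summarise.
#' @param ... Method-specific arguments.
#' @name tidiers
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidiers
#' @export
glance <- function(x, ...) UseMethod("glance")
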