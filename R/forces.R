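# Hellmann-Feynman forces and geometry relaxation.
#
# Force derivation for beta_n = beta0 - alpha (u_{n+1} - u_n), hopping term
# -sum_n beta_n T_n and elastic energy K/2 sum (u_{n+1} - u_n)^2:
#   f_n = -dE/du_n = -alpha (<T_{n-1}> - <T_n>) - K [(u_n - u_{n-1}) - (u_{n+1} - u_n)]
# with out-of-range terms dropped. Both channels telescope, so the total force
# vanishes up to truncation error.

#' Hellmann-Feynman forces on the nuclei
#'
#' Analytic forces from the bond-order expectations of the electronic state
#' (the electron-nuclear channel, proportional to `alpha`) plus the harmonic
#' elastic channel. Works for exact sector states and for MPS states.
#'
#' @param state A [sector_state()], raw amplitude vector, or `uvp_mps`.
#' @param params,chain Model and geometry.
#' @param basis Basis when `state` is a raw vector.
#' @return Numeric vector of `N` forces (eV/A).
#' @export
hellmann_feynman_forces <- function(state, params, chain, basis = NULL) {
  tvals <- if (inherits(state, "uvp_mps")) {
    mps_bond_orders(state)
  } else {
    bond_order_expectations(state, basis)
  }
  force_from_bond_orders(tvals, params, chain)
}

force_from_bond_orders <- function(tvals, params, chain) {
  N <- params$n_sites
  u <- chain$displacements
  tpad <- c(0, tvals, 0)           # T_0 = T_N = 0
  dpad <- c(0, diff(u), 0)         # bond stretches, padded
  f_alpha <- -params$alpha * (tpad[seq_len(N)] - tpad[seq_len(N) + 1])
  f_el <- -params$spring_k * (dpad[seq_len(N)] - dpad[seq_len(N) + 1])
  f_alpha + f_el
}

#' Relax a geometry on one adiabatic surface
#'
#' Preconditioned steepest descent `u <- u + eta f` with `eta = 0.5 / K`,
#' starting from the undistorted chain, until `max |f_n| < tol`. The state is
#' recomputed at every geometry (exact diagonalization or DMRG); the surface
#' is selected by adiabat index (0 = ground state).
#'
#' @param params A [model_params()] object.
#' @param state_index Adiabat to relax on (0 = S0 ground state).
#' @param engine `"exact"` (sector diagonalization, N <= ~10) or `"dmrg"`.
#' @param tol Force tolerance (eV/A).
#' @param max_iter Iteration cap.
#' @param chain0 Starting geometry (default undistorted).
#' @param max_states,cutoff DMRG truncation controls (engine = "dmrg").
#' @return List of class `relax_result`: `chain` (relaxed, zero momenta),
#'   `energy` (eV), `forces`, `state` (at the relaxed geometry), `iterations`,
#'   `converged`, and a per-iteration `trace` tibble.
#' @export
relax_geometry <- function(params, state_index = 0, engine = c("exact", "dmrg"),
                           tol = 1e-4, max_iter = 2000, chain0 = NULL,
                           max_states = params$max_states,
                           cutoff = params$trunc_cutoff) {
  engine <- match.arg(engine)
  chain <- if (is.null(chain0)) chain_state(params) else chain0
  eta <- 0.5 / params$spring_k
  basis <- if (engine == "exact") {
    sector_basis(params$n_sites, params$n_sites, 0)
  } else NULL
  trace <- list()
  prev_fmax <- Inf
  stall <- 0L
  state <- NULL
  energy <- NA_real_
  for (it in seq_len(max_iter)) {
    if (engine == "exact") {
      ee <- exact_eigenstates(params, chain, basis, k = state_index + 1,
                              label_symmetries = FALSE)
      state <- sector_state(ee$vector[[state_index + 1]], basis,
                            normalize = FALSE)
      energy <- ee$energy[state_index + 1]
      f <- hellmann_feynman_forces(state, params, chain)
    } else {
      res <- dmrg_run(params, chain, n_states = state_index + 1,
                      max_states = max_states, cutoff = cutoff, n_sweeps = 4)
      state <- res$states[[state_index + 1]]
      energy <- res$energies[state_index + 1]
      f <- hellmann_feynman_forces(state, params, chain)
    }
    fmax <- max(abs(f))
    trace[[it]] <- tibble::tibble(iteration = it, energy = energy, fmax = fmax)
    if (fmax < tol) {
      return(structure(list(chain = chain, energy = energy, forces = f,
                            state = state, iterations = it, converged = TRUE,
                            trace = dplyr::bind_rows(trace)),
                       class = "relax_result"))
    }
    # damped-update fallback against oscillatory non-convergence
    if (fmax > prev_fmax) stall <- stall + 1L else stall <- 0L
    if (stall >= 10L) { eta <- eta / 2; stall <- 0L }
    if (eta < 1e-4 / params$spring_k) {
      stop("geometry relaxation failed to converge (step collapsed; max|f| = ",
           signif(fmax, 4), " eV/A)")
    }
    prev_fmax <- fmax
    u <- chain$displacements + eta * f
    u <- u - mean(u)
    chain <- chain_state(params, u, chain$momenta)
  }
  stop("geometry relaxation did not converge in ", max_iter,
       " iterations (max|f| = ", signif(prev_fmax, 4), " eV/A)")
}

#' @exportS3Method base::print
print.relax_result <- function(x, ...) {
  cat("<relax_result>", ifelse(x$converged, "converged", "NOT converged"),
      "in", x$iterations, "iterations\n")
  cat("  energy:", signif(x$energy, 10), "eV,  max|f|:",
      signif(max(abs(x$forces)), 3), "eV/A\n")
  invisible(x)
}
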