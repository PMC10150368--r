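# Ehrenfest mixed quantum-classical dynamics: classical nuclei on the mean
# Hellmann-Feynman force of the evolving electronic state, integrated with a
# damped velocity Verlet scheme, coupled to the electronic propagation (10
# Trotter steps per nuclear update by default).

#' One damped velocity-Verlet step
#'
#' Integrates `du/dt = p/m`, `dp/dt = f - gamma p` over `params$dt_nuclear`:
#' half-kick with damping, drift, then an implicit half-kick
#' `p <- (p_half + dt/2 f_new) / (1 + gamma dt/2)`. The mean force is removed
#' (centre-of-mass channel) and the geometry re-centred each step; bond
#' hoppings are recomputed from the new displacements.
#'
#' @param chain Current [chain_state()].
#' @param forces_fn Function `chain -> numeric(N)` returning the forces at a
#'   geometry (for coupled dynamics, close over the electronic state).
#' @param params A [model_params()] object.
#' @param dt Nuclear time step (fs), default `params$dt_nuclear`.
#' @return The advanced `chain_state`.
#' @export
verlet_step <- function(chain, forces_fn, params, dt = params$dt_nuclear) {
  m <- .mass_internal(params$nuclear_mass)
  g <- params$gamma
  f0 <- forces_fn(chain)
  f0 <- f0 - mean(f0)
  p_half <- chain$momenta + dt / 2 * (f0 - g * chain$momenta)
  u <- chain$displacements + dt * p_half / m
  u <- u - mean(u)
  mid <- chain_state(params, u, p_half)
  f1 <- forces_fn(mid)
  f1 <- f1 - mean(f1)
  p_new <- (p_half + dt / 2 * f1) / (1 + g * dt / 2)
  chain_state(params, u, p_new)
}

#' Prepare the photoexcited initial condition
#'
#' Relaxes the ground-state (S0) geometry, then selects the adiabatic singlet
#' with the largest squared projection onto the bright `1^1B_u^+` diabat of
#' the symmetric Hamiltonian at that geometry: a dipole-allowed vertical
#' excitation. If two adiabats project within 0.01 of each other the lower one
#' is chosen with a warning.
#'
#' @param params A [model_params()] object.
#' @param n_track Number of adiabats/diabats examined.
#' @param relax_tol Force tolerance of the S0 relaxation (eV/A).
#' @return List: `chain` (relaxed S0 geometry, zero momenta), `state` (the
#'   selected adiabat as a [sector_state()]), `index` (adiabat index, 0 = S0),
#'   `overlap` (squared projection), `adiabats`, `diabats` (tibbles at the S0
#'   geometry), `bright` (row index of the 1^1B_u^+ diabat).
#' @export
prepare_initial_state <- function(params, n_track = 6, relax_tol = 1e-4) {
  rel <- relax_geometry(params, state_index = 0, engine = "exact",
                        tol = relax_tol)
  chain <- rel$chain
  basis <- sector_basis(params$n_sites, params$n_sites, 0)
  k <- min(n_track, basis$dim)
  symm <- strip_symmetry_breaking(params)
  diabats <- exact_eigenstates(symm, chain, basis, k = k)
  bright <- which(diabats$c2_parity < 0 & diabats$ph_parity > 0)[1]
  if (is.na(bright)) stop("no 1^1B_u^+ diabat among the ", k, " tracked states")
  adiabats <- exact_eigenstates(params, chain, basis, k = k,
                                label_symmetries = FALSE)
  phi <- diabats$vector[[bright]]
  ovl <- vapply(adiabats$vector, function(v) Mod(sum(Conj(v) * phi))^2,
                numeric(1))
  ord <- order(ovl, decreasing = TRUE)
  if (length(ord) > 1 && ovl[ord[1]] - ovl[ord[2]] < 0.01) {
    sel <- min(ord[1:2])
    warning("ambiguous bright-state projection (", signif(ovl[ord[1]], 3),
            " vs ", signif(ovl[ord[2]], 3), "); choosing the lower adiabat")
  } else {
    sel <- ord[1]
  }
  list(chain = chain,
       state = sector_state(adiabats$vector[[sel]], basis, normalize = FALSE),
       index = sel - 1L, overlap = ovl[sel],
       adiabats = adiabats, diabats = diabats, bright = bright)
}

# symmetric (diabatic) Hamiltonian: same model without the symmetry breaking
strip_symmetry_breaking <- function(params) {
  params$eps <- rep(0, params$n_sites)
  params
}

#' Run a coupled tDMRG-Ehrenfest trajectory
#'
#' Interleaves electronic propagation (`dt_nuclear / dt_trotter` Trotter steps
#' per nuclear update, 10 by default) with damped velocity-Verlet nuclear
#' updates on the Hellmann-Feynman mean force, recording energies, geometry
#' and adiabatic/diabatic populations along the way.
#'
#' The `"exact"` engine propagates the sector amplitude vector by Krylov
#' exponentiation (chains short enough to enumerate); the `"tdmrg"` engine
#' uses the adaptive time-dependent DMRG of [tdmrg_evolve()].
#'
#' @param params A [model_params()] object.
#' @param duration Trajectory length (fs).
#' @param engine `"exact"` or `"tdmrg"`.
#' @param init Initial condition from [prepare_initial_state()], or a list
#'   with elements `chain` and `state`.
#' @param record_every Record a row every this many nuclear steps.
#' @param analyse_every Population analysis stride in nuclear steps (the
#'   eigensolves are the expensive part); `NA` disables population tracking.
#' @param n_track Number of adiabats/diabats tracked in the analysis.
#' @param frozen_nuclei Keep the geometry fixed (decouples to pure electronic
#'   propagation).
#' @param max_states,cutoff tDMRG truncation controls (engine = "tdmrg").
#' @return A tibble of class `uvp_trajectory`: one row per record with time,
#'   energies (electronic, elastic, kinetic, total, eV), norm drift, maximum
#'   discarded weight, midpoint entanglement entropy, list-columns
#'   `displacements`, `adiabatic` and `diabatic` population vectors. The final
#'   electronic state and chain are attached as attributes `state`, `chain`.
#' @export
run_trajectory <- function(params, duration, engine = c("exact", "tdmrg"),
                           init = NULL, record_every = 10L,
                           analyse_every = 50L, n_track = 6,
                           frozen_nuclei = FALSE,
                           max_states = params$max_states,
                           cutoff = params$trunc_cutoff) {
  engine <- match.arg(engine)
  if (is.null(init)) init <- prepare_initial_state(params, n_track = n_track)
  chain <- init$chain
  dt <- params$dt_nuclear
  nsub <- round(params$dt_nuclear / params$dt_trotter)
  nstep <- round(duration / dt)
  if (abs(nstep * dt - duration) > 1e-9) {
    stop("`duration` must be a multiple of dt_nuclear = ", dt)
  }
  m <- .mass_internal(params$nuclear_mass)
  g <- params$gamma
  basis <- NULL
  if (engine == "exact") {
    st <- resolve_state(init$state, attr(init$state, "basis"))
    psi <- st$vec; basis <- st$basis
  } else {
    psi <- if (inherits(init$state, "uvp_mps")) init$state else as_mps(init$state)
    if (params$n_sites <= 10) {
      basis <- sector_basis(params$n_sites, params$n_sites, 0)
    }
  }
  symm <- strip_symmetry_breaking(params)

  bond_orders <- function() {
    if (engine == "exact") bond_order_expectations(psi, basis)
    else mps_bond_orders(psi)
  }
  electronic_energy <- function(ch) {
    if (engine == "exact") {
      h <- full_hamiltonian(params, ch, basis, elastic = FALSE)
      Re(sum(Conj(psi) * sp_mult(h, psi)))
    } else {
      mpo_expectation(psi, build_mpo(params, ch, number_penalty = 0)) -
        elastic_energy(params, ch)
    }
  }
  propagate <- function(ch, time) {
    if (engine == "exact") {
      # Krylov exponentiation is exact to tolerance over the whole nuclear
      # step, so no Trotter substepping is needed on this engine
      h <- full_hamiltonian(params, ch, basis)
      psi <<- krylov_expv(h, psi, -1i * dt / .hbar(), m = 20)
      nrm <- sqrt(Re(sum(Conj(psi) * psi)))
      psi <<- psi / nrm
      c(drift = abs(1 - nrm), disc = 0, ent = NA_real_)
    } else {
      ev <- tdmrg_evolve(psi, params, ch, duration = dt,
                         dt = params$dt_trotter, max_states = max_states,
                         cutoff = cutoff, record_every = nsub)
      psi <<- ev$mps
      c(drift = sum(ev$log$norm_drift), disc = max(ev$log$max_discarded),
        ent = max(ev$log$max_entropy))
    }
  }
  analyse <- function(ch) {
    if (is.na(analyse_every) || is.null(basis)) {
      return(list(ad = NULL, di = NULL))
    }
    k <- min(n_track, basis$dim)
    ad <- exact_eigenstates(params, ch, basis, k = k, label_symmetries = FALSE)
    di <- exact_eigenstates(symm, ch, basis, k = k)
    vec <- if (engine == "exact") psi else mps_sector_state(psi, basis)$vec
    list(
      ad = vapply(ad$vector, function(v) Mod(sum(Conj(v) * vec))^2, numeric(1)),
      di = vapply(di$vector, function(v) Mod(sum(Conj(v) * vec))^2, numeric(1)),
      gap = ad$energy[min(3, k)] - ad$energy[min(2, k)],   # S1/S2 gap
      labels = di$label
    )
  }
  entropy_mid <- function() {
    cut <- as.integer(params$n_sites / 2)
    if (engine == "exact") {
      reduced_density_entropy(psi, cut, basis)
    } else {
      mps_entropy_profile(psi)[cut]
    }
  }

  rows <- list()
  record <- function(time, diag, ana) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      time = time,
      electronic = electronic_energy(chain),
      elastic = elastic_energy(params, chain),
      kinetic = sum(chain$momenta^2) / (2 * m),
      norm_drift = diag[["drift"]],
      max_discarded = diag[["disc"]],
      entropy_mid = entropy_mid(),
      s1_s2_gap = if (!is.null(ana$gap)) ana$gap else NA_real_,
      displacements = list(chain$displacements),
      adiabatic = list(ana$ad), diabatic = list(ana$di)
    )
  }
  ana <- analyse(chain)
  record(0, c(drift = 0, disc = 0, ent = NA_real_), ana)

  for (s in seq_len(nstep)) {
    diagv <- c(drift = 0, disc = 0, ent = NA_real_)
    if (frozen_nuclei) {
      diagv <- propagate(chain, s * dt)
    } else {
      f0 <- force_from_bond_orders(bond_orders(), params, chain)
      f0 <- f0 - mean(f0)
      p_half <- chain$momenta + dt / 2 * (f0 - g * chain$momenta)
      u <- chain$displacements + dt * p_half / m
      u <- u - mean(u)
      chain <- chain_state(params, u, p_half)
      diagv <- propagate(chain, s * dt)
      f1 <- force_from_bond_orders(bond_orders(), params, chain)
      f1 <- f1 - mean(f1)
      p_new <- (p_half + dt / 2 * f1) / (1 + g * dt / 2)
      chain <- chain_state(params, u, p_new)
    }
    if (s %% record_every == 0 || s == nstep) {
      do_ana <- !is.na(analyse_every) && (s %% analyse_every == 0 || s == nstep)
      ana <- if (do_ana) analyse(chain) else list()
      record(s * dt, diagv, ana)
    }
  }
  out <- dplyr::bind_rows(rows)
  out$total <- out$electronic + out$elastic + out$kinetic
  out <- structure(out, class = c("uvp_trajectory", class(out)))
  attr(out, "state") <- if (engine == "exact") sector_state(psi, basis, normalize = FALSE) else psi
  attr(out, "chain") <- chain
  attr(out, "params") <- params
  attr(out, "engine") <- engine
  out
}
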