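# Adiabatic/diabatic population bookkeeping, ionicity classification, the
# quasi-stationary two-level reduction and the Landau-Zener crossover scan.
#
# Adiabats are eigenstates of the full Hamiltonian (with the symmetry-breaking
# site potentials); diabats are eigenstates of the symmetric UV-Peierls
# Hamiltonian at the same instantaneous geometry and carry definite C2 and
# particle-hole labels. All probabilities are squared moduli of overlaps, so
# no phase convention enters.

#' Adiabatic and diabatic populations of a state
#'
#' `P(Psi; S_i) = |<S_i|Psi>|^2` per adiabat, `P(Psi; phi_j) = |<phi_j|Psi>|^2`
#' per diabat, and the adiabat-on-diabat overlap matrix
#' `P(S_i; phi_j) = |<phi_j|S_i>|^2`.
#'
#' @param state A [sector_state()] (or raw vector with `basis`).
#' @param adiabats,diabats Eigenstate tibbles from [exact_eigenstates()] over
#'   the same basis.
#' @param basis Basis for a raw `state` vector.
#' @return Object of class `population_set`: list with tibbles `adiabatic`
#'   (`state`, `prob`), `diabatic` (`state`, `label`, `prob`) and matrix
#'   `overlap` (`P(S_i; phi_j)`, adiabats in rows).
#' @export
populations <- function(state, adiabats, diabats, basis = NULL) {
  st <- resolve_state(state, basis)
  if (length(adiabats$vector[[1]]) != st$basis$dim ||
      length(diabats$vector[[1]]) != st$basis$dim) {
    stop("adiabat/diabat basis dimension does not match the state")
  }
  pa <- vapply(adiabats$vector, function(v) Mod(sum(Conj(v) * st$vec))^2,
               numeric(1))
  pd <- vapply(diabats$vector, function(v) Mod(sum(Conj(v) * st$vec))^2,
               numeric(1))
  ovl <- outer(seq_along(adiabats$vector), seq_along(diabats$vector),
               Vectorize(function(i, j) {
                 Mod(sum(Conj(diabats$vector[[j]]) * adiabats$vector[[i]]))^2
               }))
  rownames(ovl) <- paste0("S", adiabats$state)
  colnames(ovl) <- if (!is.null(diabats$label)) diabats$label else
    paste0("phi", diabats$state)
  structure(
    list(adiabatic = tibble::tibble(state = adiabats$state, prob = pa),
         diabatic = tibble::tibble(state = diabats$state,
                                   label = if (!is.null(diabats$label))
                                     diabats$label else NA_character_,
                                   prob = pd),
         overlap = ovl),
    class = "population_set"
  )
}

#' @exportS3Method base::print
print.population_set <- function(x, ...) {
  cat("<population_set> sum P(adiabats):", signif(sum(x$adiabatic$prob), 6),
      " sum P(diabats):", signif(sum(x$diabatic$prob), 6), "\n")
  invisible(x)
}

#' Classify a state as ionic or covalent by its ionicity
#'
#' Ionic (positive particle-hole parity) diabats carry systematically larger
#' double occupancy than covalent ones. The threshold is placed midway between
#' the ionicity clusters of the supplied labelled diabats; a state falling
#' inside the dead band around the threshold is `"indeterminate"`.
#'
#' @param state A [sector_state()] or raw vector with `basis`.
#' @param diabats Labelled eigenstate tibble from [exact_eigenstates()]
#'   (symmetric Hamiltonian) providing the ionicity clusters.
#' @param basis Basis for a raw vector.
#' @param dead_band Fraction of the cluster gap treated as indeterminate.
#' @return `"ionic"`, `"covalent"` or `"indeterminate"`.
#' @export
classify_diabat <- function(state, diabats, basis = NULL, dead_band = 0.2) {
  st <- resolve_state(state, basis)
  if (all(is.na(diabats$ph_parity))) stop("diabats carry no particle-hole labels")
  ion_i <- diabats$ionicity[diabats$ph_parity > 0]
  ion_c <- diabats$ionicity[diabats$ph_parity < 0]
  if (!length(ion_i) || !length(ion_c)) stop("need both ionic and covalent diabats")
  lo <- max(ion_c); hi <- min(ion_i)
  if (hi <= lo) {
    # clusters overlap: fall back to the midpoint of the cluster means
    lo <- mean(ion_c); hi <- mean(ion_i)
  }
  thr <- (lo + hi) / 2
  band <- dead_band * max(hi - lo, 1e-12) / 2
  x <- ionicity(sector_state(st$vec, st$basis, normalize = FALSE))
  if (x > thr + band) "ionic" else if (x < thr - band) "covalent" else "indeterminate"
}

#' Two-level decomposition of a state
#'
#' Expresses the state in the two dominant adiabats `S_1`, `S_2` and their
#' diabatic decomposition over two target diabats, the quasi-stationary
#' reduction in which the diabatic populations oscillate at the adiabatic gap
#' frequency while the adiabatic amplitudes stay constant.
#'
#' @inheritParams populations
#' @param i1,i2 Row indices (in `adiabats`) of the two contributing adiabats.
#' @param j1,j2 Row indices (in `diabats`) of the two target diabats.
#' @return List of class `two_level_model`: `psi_sq` (`|psi_1|^2, |psi_2|^2`),
#'   `overlap_sq` (2x2, `[i, j] = P(S_i; phi_j)`), `gap` (eV), `valid`
#'   (two-level weight `>` 0.9), `weight` (sum of the two adiabat populations).
#' @export
two_level_model <- function(state, adiabats, diabats, i1 = 2, i2 = 3,
                            j1 = 2, j2 = 3, basis = NULL) {
  st <- resolve_state(state, basis)
  pp <- populations(st$vec, adiabats, diabats, st$basis)
  psi_sq <- pp$adiabatic$prob[c(i1, i2)]
  ovl <- pp$overlap[c(i1, i2), c(j1, j2)]
  weight <- sum(psi_sq)
  structure(
    list(psi_sq = psi_sq, overlap_sq = ovl,
         gap = adiabats$energy[i2] - adiabats$energy[i1],
         weight = weight, valid = weight > 0.9),
    class = "two_level_model"
  )
}

#' Oscillation-free ("classical") diabatic probability
#'
#' The diabatic population of a two-level nonstationary state oscillates at
#' the adiabatic gap frequency; averaging over full periods leaves
#' `P_classical(phi) = sum_i |psi_i|^2 P(S_i; phi)`, the incoherent mixture of
#' the adiabat-on-diabat weights. With a single populated adiabat it reduces
#' to that adiabat's overlap with the target diabat.
#'
#' @param model A [two_level_model()], or a state (with `adiabats`, `diabats`
#'   supplied) from which one is built.
#' @param target Which of the two target diabats (1 or 2).
#' @param ... Passed to [two_level_model()] when `model` is a state.
#' @return `P_classical` (scalar). If the two-level reduction is invalid
#'   (combined adiabat population below 0.9) the value is still returned, with
#'   attribute `valid = FALSE` and a warning.
#' @export
classical_probability <- function(model, target = 2, ...) {
  if (!inherits(model, "two_level_model")) model <- two_level_model(model, ...)
  p <- sum(model$psi_sq * model$overlap_sq[, target])
  if (!model$valid) {
    warning("two-level reduction invalid (combined adiabat population ",
            signif(model$weight, 3), " < 0.9)")
  }
  structure(p, valid = model$valid)
}

#' Landau-Zener crossover scan over the symmetry-breaking strength
#'
#' Scales a base on-site potential profile by each factor `zeta`, runs one
#' photoexcited trajectory per value, and records the adiabatic populations
#' and the classical diabatic yield at the probe time, together with the
#' minimum `S1/S2` gap encountered. At `zeta = 0` diabats and adiabats
#' coincide and the gap may close (true crossing); any `zeta > 0` opens an
#' avoided crossing, and increasing `zeta` drives the passage from
#' nonadiabatic (diabat-following) to adiabatic.
#'
#' @param params A [model_params()] whose `eps` is the base (zeta = 1)
#'   symmetry-breaking profile.
#' @param zeta Numeric vector of scale factors.
#' @param probe_time Time (fs) at which populations are reported.
#' @param engine Trajectory engine (see [run_trajectory()]).
#' @param target_label Diabat whose classical yield is reported.
#' @param n_track,analyse_every Passed to [run_trajectory()].
#' @return A tibble of class `lz_scan`: one row per `zeta` with `p_s1`,
#'   `p_s2`, `p_classical`, `min_gap`, `two_level_weight`. Failed trajectories
#'   yield NA rows with a warning; the scan continues.
#' @export
lz_scan <- function(params, zeta, probe_time, engine = "exact",
                    target_label = "2^1Ag-", n_track = 6,
                    analyse_every = 25L) {
  base_eps <- params$eps
  rows <- lapply(zeta, function(z) {
    out <- tibble::tibble(zeta = z, p_s1 = NA_real_, p_s2 = NA_real_,
                          p_classical = NA_real_, min_gap = NA_real_,
                          two_level_weight = NA_real_)
    tryCatch({
      pz <- params
      pz$eps <- z * base_eps
      pz$eps_max <- max(params$eps_max, max(abs(pz$eps)) + 1e-9)
      init <- prepare_initial_state(pz, n_track = n_track)
      tr <- run_trajectory(pz, probe_time, engine = engine, init = init,
                           analyse_every = analyse_every, n_track = n_track)
      basis <- sector_basis(pz$n_sites, pz$n_sites, 0)
      chain <- attr(tr, "chain")
      st <- attr(tr, "state")
      if (inherits(st, "uvp_mps")) st <- mps_sector_state(st, basis)
      adia <- exact_eigenstates(pz, chain, basis, k = n_track,
                                label_symmetries = FALSE)
      diab <- exact_eigenstates(strip_symmetry_breaking(pz), chain, basis,
                                k = n_track)
      jt <- which(diab$label == target_label)[1]
      if (is.na(jt)) jt <- 2L
      tlm <- two_level_model(st, adia, diab, i1 = 2, i2 = 3, j1 = jt, j2 = jt)
      pcl <- suppressWarnings(classical_probability(tlm, target = 1))
      out$p_s1 <- tlm$psi_sq[1]; out$p_s2 <- tlm$psi_sq[2]
      out$p_classical <- as.numeric(pcl)
      out$two_level_weight <- tlm$weight
      out$min_gap <- min(tr$s1_s2_gap, na.rm = TRUE)
      out
    }, error = function(e) {
      warning("zeta = ", z, " failed: ", conditionMessage(e))
      out
    })
  })
  structure(dplyr::bind_rows(rows), class = c("lz_scan", class(rows[[1]])))
}
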